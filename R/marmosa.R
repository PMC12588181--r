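#' Example data: masticatory apparatus of *Marmosa murina*
#'
#' Dissection-based measurements of the masticatory muscles of two adult
#' male *Marmosa murina* (murine mouse opossum) specimens, M1496 and M2851:
#' preserved muscle masses and mean fibre lengths for thirteen muscles
#' (closers plus the digastric jaw opener), the closed-mouth mechanics of
#' specimen M2851 (maximum 3D and sagittal forces, action-line angles,
#' per-muscle resultants at the incisor and the last lower molar m4), and
#' in vivo bite-force measurements with their model summaries.
#'
#' The published record contains no landmark coordinates, so absolute
#' levers are unrecoverable; [marmosa_synthetic_geometry()] builds a
#' synthetic landmark set consistent with the recorded angles and
#' resultants (see its help page).
#'
#' @param specimen `"M2851"` or `"M1496"`.
#' @return `marmosa_architecture()`: a [muscle_architecture()] table.
#' @name marmosa
NULL

marmosa_extdata <- function(file) {
  path <- system.file("extdata", file, package = "jawforce")
  if (path == "")  # during development, before installation
    path <- file.path("inst", "extdata", file)
  path
}

#' @rdname marmosa
#' @export
marmosa_roster <- function() {
  c("Di", "MS", "MIant", "MIpos", "MP", "ZMant", "ZMpos",
    "TZ", "TS", "TPlat", "TPmed", "PtLat", "PtMed")
}

#' @rdname marmosa
#' @export
marmosa_architecture <- function(specimen = c("M2851", "M1496")) {
  specimen <- match.arg(specimen)
  df <- utils::read.csv(marmosa_extdata("marmosa_architecture.csv"),
                        stringsAsFactors = FALSE)
  df <- df[df$specimen == specimen, ]
  muscle_architecture(df$muscle, df$mass_g, df$fibre_length_mm,
                      role = df$role, roster = marmosa_roster())
}

#' @rdname marmosa
#' @return `marmosa_reference_pcsa()`: data frame of recorded PCSA values
#'   (cm^2) for both specimens, for cross-checking [pcsa()].
#' @export
marmosa_reference_pcsa <- function() {
  utils::read.csv(marmosa_extdata("marmosa_pcsa.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname marmosa
#' @return `marmosa_reference_mechanics()`: the recorded closed-mouth
#'   mechanics of specimen M2851 (forces in N, angles in degrees,
#'   3-decimal precision).
#' @export
marmosa_reference_mechanics <- function() {
  utils::read.csv(marmosa_extdata("marmosa_closed_mouth.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname marmosa
#' @return `marmosa_bite_table()`: in vivo bite forces and model summaries
#'   (closed-mouth and optimal-gape forces, optimal gape, fitted stress)
#'   per specimen and bite point.
#' @export
marmosa_bite_table <- function() {
  utils::read.csv(marmosa_extdata("marmosa_bite_forces.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname marmosa
#' @param d_cbp_incisor Out-lever to the incisor bite point, mm. The
#'   recorded resultants fix only the incisor/m4 out-lever ratio (2.337);
#'   14 mm is a realistic condyle-incisor distance for this ~30 mm skull.
#' @return `marmosa_out_levers()`: named vector of out-levers (mm) for the
#'   `incisor` and `m4` bite points.
#' @export
marmosa_out_levers <- function(d_cbp_incisor = 14) {
  c(incisor = d_cbp_incisor, m4 = d_cbp_incisor / 2.337)
}

#' @rdname marmosa
#' @param constants A [model_constants()] object.
#' @return `marmosa_action_table()`: geometry-free action-line table for
#'   specimen M2851 (`muscle`, `phi`, `theta`, `lever`, `moment_sign`).
#'   In-levers are back-solved from the recorded per-muscle incisor
#'   resultants at the given incisor out-lever, so the resulting
#'   [bite_model()] reproduces the recorded resultants. PtLat carries
#'   `moment_sign = +1` (jaw opener).
#' @export
marmosa_action_table <- function(d_cbp_incisor = 14,
                                 constants = model_constants()) {
  ref <- marmosa_reference_mechanics()
  arch <- marmosa_architecture("M2851")
  f2 <- project_sagittal(
    unname(f3dmax(arch, constants))[match(ref$muscle, arch$muscle)],
    ref$phi_deg)
  lever <- ref$ri_incisor_N * d_cbp_incisor /
    (sin(deg2rad(ref$theta_deg)) * f2)
  data.frame(muscle = ref$muscle, phi = ref$phi_deg, theta = ref$theta_deg,
             lever = lever,
             moment_sign = ifelse(ref$muscle == "PtLat", 1, -1),
             stringsAsFactors = FALSE)
}

#' Synthetic jaw geometry consistent with the *Marmosa murina* record
#'
#' No landmark coordinates were published for the dissected specimens, so
#' this constructs a synthetic landmark set (via [generate_geometry()])
#' whose derived action lines reproduce specimen M2851's recorded
#' closed-mouth angles and resultants exactly. The free construction
#' choices are fixed a priori: incisor out-lever 14 mm (realistic for the
#' species, with the m4 out-lever at the recorded ratio 1/2.337) and
#' origin distance 10 mm. Gape behaviour away from 0 degrees is an
#' emergent property of this synthetic geometry, not a recorded datum.
#'
#' @inheritParams marmosa_action_table
#' @param origin_distance Insertion-origin distance, mm.
#' @param noise_sd,seed Passed to [generate_geometry()].
#' @return A [jaw_geometry()] with bite points `incisor` and `m4`.
#' @export
marmosa_synthetic_geometry <- function(d_cbp_incisor = 14,
                                       origin_distance = 10,
                                       constants = model_constants(),
                                       noise_sd = 0, seed = NULL) {
  generate_geometry(marmosa_action_table(d_cbp_incisor, constants),
                    d_cbp = marmosa_out_levers(d_cbp_incisor),
                    origin_distance = origin_distance,
                    noise_sd = noise_sd, seed = seed)
}
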