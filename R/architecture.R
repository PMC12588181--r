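#' Muscle-architecture table
#'
#' Validates a per-muscle table of dissection measurements: preserved muscle
#' mass and mean fibre length, plus the functional role of the muscle
#' (jaw closer or jaw opener). These are the inputs from which PCSA and the
#' maximum 3D muscle force are computed.
#'
#' @param muscle Character vector of muscle labels, unique within the table.
#' @param mass Preserved muscle mass in grams, strictly positive.
#' @param fibre_length Mean fibre length in millimetres, strictly positive.
#' @param role `"closer"` or `"opener"` per muscle (recycled). Openers (the
#'   digastric, typically) are carried through the model but never summed
#'   into the bite force.
#' @param roster Optional character vector of admissible muscle labels; by
#'   default any label is accepted. Use [marmosa_roster()] for the standard
#'   didelphid set.
#'
#' @return A `data.frame` of class `muscle_architecture` with columns
#'   `muscle`, `mass`, `fibre_length`, `role`.
#' @seealso [pcsa()], [f3dmax()], [read_architecture()]
#' @examples
#' muscle_architecture(c("MS", "TS"), mass = c(0.0485, 0.0483),
#'                     fibre_length = c(3.138, 3.779))
#' @export
muscle_architecture <- function(muscle, mass, fibre_length,
                                role = "closer", roster = NULL) {
  muscle <- as.character(muscle)
  n <- length(muscle)
  if (n == 0L)
    stop("architecture table must contain at least one muscle", call. = FALSE)
  if (anyDuplicated(muscle))
    stop("duplicate muscle labels: ",
         paste(unique(muscle[duplicated(muscle)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(roster)) {
    unknown <- setdiff(muscle, roster)
    if (length(unknown))
      stop("muscle label(s) not in roster: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  mass <- as.numeric(mass)
  fibre_length <- as.numeric(fibre_length)
  if (length(mass) != n || length(fibre_length) != n)
    stop("'mass' and 'fibre_length' must match the number of muscles",
         call. = FALSE)
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("muscle mass must be positive and finite", call. = FALSE)
  if (any(!is.finite(fibre_length)) || any(fibre_length <= 0))
    stop("fibre length must be positive and finite", call. = FALSE)
  role <- rep_len(as.character(role), n)
  if (!all(role %in% c("closer", "opener")))
    stop("role must be 'closer' or 'opener'", call. = FALSE)
  structure(data.frame(muscle = muscle, mass = mass,
                       fibre_length = fibre_length, role = role,
                       stringsAsFactors = FALSE),
            class = c("muscle_architecture", "data.frame"))
}

#' Read a muscle-architecture CSV
#'
#' Expects a header row and columns `muscle,mass_g,fibre_length_mm` with an
#' optional `role` column ('.' decimal separator, UTF-8).
#'
#' @param path Path to the CSV file.
#' @param roster Passed to [muscle_architecture()].
#' @return A `muscle_architecture` data frame.
#' @export
read_architecture <- function(path, roster = NULL) {
  if (!file.exists(path))
    stop("architecture file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("muscle", "mass_g", "fibre_length_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("architecture file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("architecture file ", path, " contains no rows", call. = FALSE)
  muscle_architecture(df$muscle, df$mass_g, df$fibre_length_mm,
                      role = if ("role" %in% names(df)) df$role else "closer",
                      roster = roster)
}

#' Physiological cross-sectional area
#'
#' PCSA = mass / (fibre length x density), with fibre length converted from
#' mm to cm, giving cm^2. The preserved-to-fresh mass correction is *not*
#' applied here; it enters only the force computation ([f3dmax()]), so that
#' reported PCSAs describe the preserved specimens as measured.
#'
#' @param arch A `muscle_architecture` table (or anything accepted by
#'   [muscle_architecture()] when given as a data frame with the same
#'   columns).
#' @param constants A [model_constants()] object; only `density` is used.
#' @return Named numeric vector of areas in cm^2.
#' @examples
#' a <- muscle_architecture("MS", 0.0485, 3.138)
#' pcsa(a)  # 0.1469 cm^2
#' @export
pcsa <- function(arch, constants = model_constants()) {
  arch <- as_architecture(arch)
  out <- arch$mass / ((arch$fibre_length / 10) * constants$density)
  names(out) <- arch$muscle
  out
}

#' Maximum three-dimensional muscle force
#'
#' The maximum tetanic force along each muscle's line of action:
#' `F3Dmax = muscle_stress * mass * mass_correction / (fibre_length_cm * density)`
#' which equals `muscle_stress * mass_correction * PCSA`. Units: N, with
#' stress in N cm^-2 and PCSA in cm^2.
#'
#' @inheritParams pcsa
#' @return Named numeric vector of forces in N.
#' @examples
#' a <- muscle_architecture("MS", 0.0485, 3.138)
#' f3dmax(a)  # 7.459 N
#' @export
f3dmax <- function(arch, constants = model_constants()) {
  constants$muscle_stress * constants$mass_correction * pcsa(arch, constants)
}

as_architecture <- function(arch) {
  if (inherits(arch, "muscle_architecture")) return(arch)
  if (is.data.frame(arch) &&
      all(c("muscle", "mass", "fibre_length") %in% names(arch))) {
    return(muscle_architecture(arch$muscle, arch$mass, arch$fibre_length,
                               role = if ("role" %in% names(arch))
                                 arch$role else "closer"))
  }
  stop("expected a muscle_architecture table", call. = FALSE)
}

#' @export
print.muscle_architecture <- function(x, ...) {
  cat("Muscle architecture:", nrow(x), "muscles\n")
  df <- as.data.frame(x)
  df$pcsa_cm2 <- round(unname(pcsa(x)), 4)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
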