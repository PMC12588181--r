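#' Model constants for the bite-force model
#'
#' Bundles the three scalar constants of the static-equilibrium bite model:
#' the muscle stress (specific tension), the muscle density used to convert
#' mass and fibre length into a physiological cross-sectional area, and the
#' multiplicative correction recovering fresh muscle mass from
#' formalin-fixed, ethanol-preserved mass.
#'
#' @param muscle_stress Maximum isometric force per unit PCSA, in N cm^-2.
#'   Default 30.
#' @param density Muscle density in g cm^-3. Default 1.0518, the head-muscle
#'   value; alternative published values are 1.0597, 1.0564, 1.0582 and the
#'   general-muscle 1.0558.
#' @param mass_correction Dimensionless factor converting preserved to fresh
#'   muscle mass. Default 1.692 (average 40.91% mass loss in fixation).
#'
#' @return An object of class `model_constants`: a named list with the three
#'   components above.
#' @examples
#' model_constants()
#' model_constants(muscle_stress = 44.36)
#' @export
model_constants <- function(muscle_stress = 30,
                            density = 1.0518,
                            mass_correction = 1.692) {
  for (nm in c("muscle_stress", "density", "mass_correction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  structure(list(muscle_stress = muscle_stress,
                 density = density,
                 mass_correction = mass_correction),
            class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Bite-model constants:\n")
  cat(sprintf("  muscle stress    %8.4f N cm^-2\n", x$muscle_stress))
  cat(sprintf("  muscle density   %8.4f g cm^-3\n", x$density))
  cat(sprintf("  mass correction  %8.4f (preserved -> fresh)\n",
              x$mass_correction))
  invisible(x)
}

#' Read model constants from a YAML or JSON configuration file
#'
#' Accepts a file holding any subset of `muscle_stress`, `density`,
#' `mass_correction`; missing entries take the defaults of
#' [model_constants()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `model_constants` object.
#' @export
read_constants <- function(path) {
  if (!file.exists(path))
    stop("constants file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("muscle_stress", "density", "mass_correction")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown constant(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(model_constants, cfg[intersect(names(cfg), known)])
}

## degree/radian helpers -- angles are degrees at every interface,
## radians only inside trigonometric calls.
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
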