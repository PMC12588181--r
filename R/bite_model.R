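#' Fit a static-equilibrium bite-force model
#'
#' The central constructor. From dissection-based muscle architecture and
#' jaw geometry it evaluates the full force chain — PCSA, maximum 3D muscle
#' force, sagittal projection, moment balance about the condyle — and
#' returns the bilateral bite force at each bite point, together with the
#' per-muscle mechanics table.
#'
#' Two input pathways are supported:
#' \describe{
#' \item{geometry mode}{supply `geometry`, a [jaw_geometry()]; action-line
#'   angles (`phi`, `theta`), in-levers and out-levers are derived from the
#'   landmarks, and the model can be re-evaluated at any gape by rigid
#'   rotation ([sweep_gape()], [predict.bite_model()]).}
#' \item{geometry-free mode}{supply `action`, a data frame with columns
#'   `muscle, phi, theta, lever` (degrees, mm) and optionally
#'   `moment_sign`, plus `d_cbp`, a named vector of condyle-bite point
#'   distances (mm). Rotation is unavailable since no coordinates exist.}
#' }
#'
#' Muscles whose moment about the condyle opens the jaw — a computed
#' outcome, not an assumption — and muscles whose architectural role is
#' `"opener"` are excluded from the bite-force sum.
#'
#' @param architecture A [muscle_architecture()] table.
#' @param geometry A [jaw_geometry()], or `NULL` for geometry-free mode.
#' @param action Geometry-free action-line table (see Details).
#' @param d_cbp Named numeric vector of out-levers in mm (geometry-free
#'   mode only; derived from landmarks otherwise).
#' @param constants A [model_constants()] object.
#' @param exclude Optional character vector of muscles to force into the
#'   excluded (opener) set regardless of computed sign — an override for
#'   geometry-free tables that lack reliable moment signs.
#'
#' @return An object of class `bite_model`: a list with components
#'   `mechanics` (per-muscle table: mass, fibre length, PCSA, F3Dmax, phi,
#'   F2Dmax, theta, lever, moment sign, and one resultant column per bite
#'   point), `forces` (named vector, total bilateral force per bite point,
#'   N), `excluded`, `gape`, plus the inputs.
#' @examples
#' arch <- marmosa_architecture("M2851")
#' geom <- marmosa_synthetic_geometry()
#' m <- bite_model(arch, geometry = geom)
#' m$forces
#' @export
bite_model <- function(architecture, geometry = NULL, action = NULL,
                       d_cbp = NULL, constants = model_constants(),
                       exclude = NULL) {
  cl <- match.call()
  architecture <- as_architecture(architecture)
  stopifnot(inherits(constants, "model_constants"))
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "jaw_geometry"))
    keep <- intersect(rownames(geometry$origins), architecture$muscle)
    if (!length(keep))
      stop("no muscle appears in both the geometry and the architecture",
           call. = FALSE)
    action <- action_lines(geometry)
    action <- action[action$muscle %in% keep, , drop = FALSE]
    d_cbp <- vapply(rownames(geometry$bite_points),
                    function(b) bite_distance(geometry, b), numeric(1))
    gape <- geometry$gape
  } else {
    if (is.null(action) || is.null(d_cbp))
      stop("geometry-free mode needs both 'action' and 'd_cbp'",
           call. = FALSE)
    need <- c("muscle", "phi", "theta", "lever")
    if (!is.data.frame(action) || !all(need %in% names(action)))
      stop("'action' must be a data.frame with columns ",
           paste(need, collapse = ", "), call. = FALSE)
    if (is.null(action$moment_sign)) action$moment_sign <- -1
    gape <- 0
  }
  if (!is.null(exclude)) {
    action$moment_sign[action$muscle %in% exclude] <- 1
  }
  mech <- build_mechanics(architecture, action, d_cbp, constants,
                          gape = gape)
  forces <- vapply(names(d_cbp),
                   function(bp) total_bite_force(mech, bp)$total_force,
                   numeric(1))
  role <- mech$role
  excluded <- mech$muscle[mech$moment_sign >= 0 | role == "opener"]
  structure(list(mechanics = mech, forces = forces, excluded = excluded,
                 gape = gape, architecture = architecture,
                 geometry = geometry, action = action, d_cbp = d_cbp,
                 constants = constants, exclude = exclude, call = cl),
            class = "bite_model")
}

#' Re-evaluate a bite model at another gape angle
#'
#' Rigidly rotates the mandible to the requested absolute gape and rebuilds
#' the entire mechanics table (action lines are re-derived from the rotated
#' landmarks, so both `phi` and `theta` change with gape). Requires a model
#' fitted in geometry mode.
#'
#' @param model A [bite_model()] with geometry.
#' @param gape Absolute opening angle, degrees.
#' @return A new `bite_model` at that gape.
#' @export
at_gape <- function(model, gape) {
  stopifnot(inherits(model, "bite_model"))
  if (is.null(model$geometry))
    stop("gape changes need a geometry-based model (no landmarks present)",
         call. = FALSE)
  g <- rotate_mandible(model$geometry, gape - model$geometry$gape)
  bite_model(model$architecture, geometry = g, constants = model$constants,
             exclude = model$exclude)
}

#' Total bite forces of a fitted model
#'
#' @param model A [bite_model()].
#' @return Named numeric vector: bilateral bite force (N) per bite point.
#' @export
bite_forces <- function(model) {
  stopifnot(inherits(model, "bite_model"))
  model$forces
}

#' Predict bite force at given gapes and bite points
#'
#' @param object A [bite_model()].
#' @param gape Numeric vector of absolute gape angles, degrees. Values other
#'   than the fitted gape require geometry mode. Default: the fitted gape.
#' @param bite_point Bite-point labels (default: all in the model).
#' @param ... Unused.
#' @return A matrix of forces (N), gapes in rows, bite points in columns.
#' @export
predict.bite_model <- function(object, gape = object$gape,
                               bite_point = names(object$forces), ...) {
  bad <- setdiff(bite_point, names(object$forces))
  if (length(bad))
    stop("unknown bite point(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- t(vapply(gape, function(g) {
    m <- if (isTRUE(all.equal(g, object$gape))) object else at_gape(object, g)
    m$forces[bite_point]
  }, numeric(length(bite_point))))
  dimnames(out) <- list(format(gape, trim = TRUE), bite_point)
  out
}

#' @export
coef.bite_model <- function(object, ...) {
  unlist(object$constants)
}

#' @export
print.bite_model <- function(x, ...) {
  cat("Static-equilibrium bite model —", nrow(x$mechanics), "muscles, gape",
      format(x$gape), "deg",
      if (is.null(x$geometry)) "(geometry-free)" else "", "\n")
  cat(sprintf("  muscle stress %.3f N cm^-2, density %.4f g cm^-3, mass correction %.3f\n",
              x$constants$muscle_stress, x$constants$density,
              x$constants$mass_correction))
  for (bp in names(x$forces))
    cat(sprintf("  Fcalc at %-8s %8.3f N  (out-lever %.3f mm)\n",
                bp, x$forces[[bp]], x$d_cbp[[bp]]))
  if (length(x$excluded))
    cat("  excluded from the sum:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bite_model <- function(object, ...) {
  structure(list(model = object), class = "summary.bite_model")
}

#' @export
print.summary.bite_model <- function(x, ...) {
  m <- x$model
  print(m)
  tab <- m$mechanics
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 3)
  cat("\nPer-muscle mechanics:\n")
  print.data.frame(tab[, !(names(tab) %in% c("role"))], row.names = FALSE)
  invisible(x)
}

#' Plot a bite model
#'
#' Geometry-based models are plotted as a gape profile (bite force against
#' gape angle, one curve per bite point); geometry-free models as a barplot
#' of per-muscle resultants at the first bite point.
#'
#' @param x A [bite_model()].
#' @param max_gape Upper end of the gape axis, degrees (geometry mode).
#' @param step Gape increment, degrees.
#' @param ... Passed to the underlying graphics call.
#' @return Invisibly, `x`.
#' @export
plot.bite_model <- function(x, max_gape = 30, step = 0.5, ...) {
  if (!is.null(x$geometry)) {
    gapes <- seq(0, max_gape, by = step)
    f <- predict(x, gape = gapes)
    graphics::matplot(gapes, f, type = "l", lty = 1,
                      xlab = "gape (degrees)",
                      ylab = "bilateral bite force (N)", ...)
    graphics::legend("topright", colnames(f), lty = 1,
                     col = seq_len(ncol(f)), bty = "n")
  } else {
    bp <- names(x$forces)[1]
    bf <- total_bite_force(x$mechanics, bp)
    graphics::barplot(bf$per_muscle, las = 2,
                      ylab = sprintf("resultant at %s (N)", bp), ...)
  }
  invisible(x)
}
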