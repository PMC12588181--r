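#' Project a 3D muscle force into the sagittal plane
#'
#' Discards the mediolateral component of the maximum 3D force: with `phi`
#' the angle between the action line and the mediolateral axis, the
#' sagittal (2D) force is `f3dmax * sin(phi)` — algebraically identical to
#' `sqrt(f3dmax^2 - (f3dmax * cos(phi))^2)` for `phi` in [0, 180].
#' Mediolateral components cancel in symmetric bilateral biting and do not
#' rotate the mandible.
#'
#' @param f3dmax Maximum 3D muscle force, N (vectorised).
#' @param phi Angle to the mediolateral axis, degrees, in [0, 180].
#' @return Sagittal force in N.
#' @examples
#' project_sagittal(7.458, 59.70)  # 6.439 N
#' @export
project_sagittal <- function(f3dmax, phi) {
  if (any(!is.finite(f3dmax)) || any(f3dmax < 0))
    stop("'f3dmax' must be non-negative and finite", call. = FALSE)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 180))
    stop("'phi' must lie in [0, 180] degrees", call. = FALSE)
  f3dmax * sin(deg2rad(phi))
}

#' Resultant force of one muscle at a bite point
#'
#' Moment balance about the condyle: the muscle's sagittal force `f2dmax`
#' acting on the in-lever `lever` at angle `theta` is matched by a reaction
#' at the bite point on the out-lever `d_cbp`:
#' `R = lever * sin(theta) * f2dmax / d_cbp`.
#'
#' @param f2dmax Sagittal muscle force, N (vectorised).
#' @param theta Angle between the in-lever vector and the sagittal action
#'   line, degrees.
#' @param lever In-lever (condyle-insertion sagittal distance), mm.
#' @param d_cbp Out-lever (condyle-bite point sagittal distance), mm; > 0.
#' @return Resultant force at the bite point, N.
#' @examples
#' bite_resultant(4, 30, 5, 10)  # 1 N
#' @export
bite_resultant <- function(f2dmax, theta, lever, d_cbp) {
  if (any(!is.finite(d_cbp)) || any(d_cbp <= 0))
    stop("'d_cbp' (condyle-bite point distance) must be positive",
         call. = FALSE)
  if (any(!is.finite(lever)) || any(lever < 0))
    stop("'lever' must be non-negative and finite", call. = FALSE)
  lever * sin(deg2rad(theta)) * f2dmax / d_cbp
}

#' Total bilateral bite force at a bite point
#'
#' Doubles the sum of per-muscle resultants over the jaw-closing muscles,
#' simulating simultaneous tetanic contraction of the musculature on both
#' sides of a symmetric skull. Muscles whose computed moment opens the jaw,
#' and muscles whose architectural role is `"opener"` (the digastric), are
#' excluded from the sum and reported in `excluded`.
#'
#' @param mechanics A per-muscle mechanics `data.frame` as found in a
#'   [bite_model()] (columns `muscle`, `moment_sign`, `role`, and a
#'   resultant column `R_<bite_point>` in N).
#' @param bite_point Bite-point label.
#' @return A list of class `bite_force` with `bite_point`, `gape`,
#'   `total_force` (N), `per_muscle` (named vector, included closers only)
#'   and `excluded`.
#' @export
total_bite_force <- function(mechanics, bite_point) {
  col <- paste0("R_", bite_point)
  if (!col %in% names(mechanics))
    stop("no resultants for bite point '", bite_point, "'", call. = FALSE)
  role <- if ("role" %in% names(mechanics)) mechanics$role else "closer"
  closer <- mechanics$moment_sign < 0 & role != "opener"
  if (!any(closer))
    stop("model error: no jaw-closing muscle in the mechanics table",
         call. = FALSE)
  per <- mechanics[[col]][closer]
  names(per) <- mechanics$muscle[closer]
  structure(list(bite_point = bite_point,
                 gape = attr(mechanics, "gape") %||% 0,
                 total_force = 2 * sum(per),
                 per_muscle = per,
                 excluded = mechanics$muscle[!closer]),
            class = "bite_force")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bite_force <- function(x, ...) {
  cat(sprintf("Bilateral bite force at '%s' (gape %.1f deg): %.3f N\n",
              x$bite_point, x$gape, x$total_force))
  if (length(x$excluded))
    cat("  excluded (openers):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

## Assemble the per-muscle mechanics table from architecture + per-muscle
## action data (phi, theta, lever, moment_sign) + out-levers.  The single
## place where the force chain PCSA -> F3D -> F2D -> R is evaluated.
build_mechanics <- function(arch, action, d_cbp, constants, gape = 0) {
  arch <- as_architecture(arch)
  if (!all(action$muscle %in% arch$muscle))
    stop("action table contains muscle(s) absent from the architecture: ",
         paste(setdiff(action$muscle, arch$muscle), collapse = ", "),
         call. = FALSE)
  a <- arch[match(action$muscle, arch$muscle), ]
  f3 <- unname(f3dmax(a, constants))
  f2 <- project_sagittal(f3, action$phi)
  mech <- data.frame(muscle = action$muscle, role = a$role,
                     mass = a$mass, fibre_length = a$fibre_length,
                     pcsa = unname(pcsa(a, constants)),
                     f3dmax = f3, phi = action$phi, f2dmax = f2,
                     theta = action$theta, lever = action$lever,
                     moment_sign = action$moment_sign,
                     stringsAsFactors = FALSE)
  if (is.null(names(d_cbp)) || any(!is.finite(d_cbp)) || any(d_cbp <= 0))
    stop("'d_cbp' must be a named vector of positive out-levers (mm)",
         call. = FALSE)
  for (bp in names(d_cbp))
    mech[[paste0("R_", bp)]] <-
      bite_resultant(f2, action$theta, action$lever, d_cbp[[bp]])
  attr(mech, "gape") <- gape
  mech
}
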