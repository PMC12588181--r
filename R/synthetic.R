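#' Generate a jaw geometry realising prescribed action-line targets
#'
#' Constructs 3D landmarks (condyle, per-muscle insertion and origin
#' centroids, bite points) such that [action_line()] recovers each muscle's
#' target angles and in-lever exactly (at `noise_sd = 0`), and
#' [bite_distance()] recovers each target out-lever.
#'
#' Construction: each insertion is placed at its in-lever distance from the
#' condyle in the sagittal plane along a placement ray; the sagittal pull
#' direction is the in-lever direction rotated by `theta` in the closing
#' (or opening, for `moment_sign = +1`) sense; the full 3D pull direction
#' tilts that sagittal direction out of plane so that it makes the angle
#' `phi` with the mediolateral axis; the origin sits `origin_distance` mm
#' along the pull direction from the insertion. Because the model is
#' invariant to a global rotation of the construction about the
#' mediolateral axis, the placement rays are cosmetic and do not affect
#' any derived quantity.
#'
#' With `noise_sd > 0`, every origin, insertion and bite-point coordinate
#' is jittered by a centred Gaussian whose standard deviation is
#' `noise_sd` times that landmark's distance from the condyle (relative
#' noise); the condyle itself stays fixed.
#'
#' @param targets Data frame with columns `muscle`, `phi`, `theta`,
#'   `lever` (degrees, degrees, mm) and optionally `moment_sign`
#'   (-1 closer, default; +1 opener).
#' @param d_cbp Named numeric vector of out-levers, mm (e.g.
#'   `c(incisor = 14, m4 = 6)`).
#' @param condyle Condyle position, mm. Default origin.
#' @param origin_distance Insertion-origin distance along the pull
#'   direction, mm. Unconstrained by the targets; default 10.
#' @param insertion_angles Optional placement-ray angles (degrees from the
#'   +x axis) for the insertions; spread over a mandible-like fan by
#'   default.
#' @param noise_sd Relative landmark noise (0 = exact construction).
#' @param seed Optional integer seed fixing the jitter.
#' @return A [jaw_geometry()].
#' @examples
#' tg <- data.frame(muscle = "MS", phi = 59.70, theta = 63.89, lever = 3.1)
#' g <- generate_geometry(tg, d_cbp = c(incisor = 14))
#' action_line(g, "MS")
#' @export
generate_geometry <- function(targets, d_cbp, condyle = c(0, 0, 0),
                              origin_distance = 10,
                              insertion_angles = NULL,
                              noise_sd = 0, seed = NULL) {
  need <- c("muscle", "phi", "theta", "lever")
  if (!is.data.frame(targets) || !all(need %in% names(targets)))
    stop("'targets' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  n <- nrow(targets)
  if (anyDuplicated(targets$muscle))
    stop("duplicate muscles in 'targets'", call. = FALSE)
  if (any(targets$phi <= 0) || any(targets$phi >= 180) ||
      any(targets$theta <= 0) || any(targets$theta >= 180))
    stop("target angles must lie strictly inside (0, 180) degrees",
         call. = FALSE)
  if (any(targets$lever <= 0))
    stop("infeasible target: angle targets need a positive in-lever",
         call. = FALSE)
  if (is.null(names(d_cbp)) || any(d_cbp <= 0))
    stop("'d_cbp' must be a named vector of positive out-levers",
         call. = FALSE)
  if (origin_distance <= 0)
    stop("'origin_distance' must be positive", call. = FALSE)
  sign <- if (is.null(targets$moment_sign)) rep(-1, n) else targets$moment_sign
  condyle <- as_point3(condyle, "condyle")
  if (is.null(insertion_angles))
    insertion_angles <- seq(-30, 50, length.out = max(n, 2L))[seq_len(n)]
  a <- deg2rad(insertion_angles)
  th <- deg2rad(targets$theta)
  ph <- deg2rad(targets$phi)

  u <- cbind(cos(a), sin(a))                     # in-lever directions
  ## sagittal pull direction: rotate u counter-clockwise by theta for a
  ## closing moment (right-handed +z moment closes; see rotate_mandible),
  ## clockwise for an opener
  rotdir <- ifelse(sign < 0, 1, -1)
  s <- cbind(cos(th) * u[, 1] - rotdir * sin(th) * u[, 2],
             rotdir * sin(th) * u[, 1] + cos(th) * u[, 2])
  v <- cbind(sin(ph) * s, cos(ph))               # unit 3D pull direction

  insertions <- cbind(condyle[1] + targets$lever * u[, 1],
                      condyle[2] + targets$lever * u[, 2],
                      condyle[3])
  origins <- insertions + origin_distance * v
  rownames(insertions) <- rownames(origins) <- targets$muscle

  bite_dirs <- deg2rad(seq(-15, -15 - 5 * (length(d_cbp) - 1), by = -5))
  bite_points <- cbind(condyle[1] + d_cbp * cos(bite_dirs),
                       condyle[2] + d_cbp * sin(bite_dirs),
                       condyle[3])
  rownames(bite_points) <- names(d_cbp)

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    jitter <- function(m) {
      scale <- sqrt(rowSums((m - matrix(condyle, nrow(m), 3,
                                        byrow = TRUE))^2))
      m + matrix(stats::rnorm(length(m), sd = rep(noise_sd * scale, 3)),
                 nrow(m), 3)
    }
    insertions <- jitter(insertions)
    origins <- jitter(origins)
    bite_points <- jitter(bite_points)
  }
  jaw_geometry(condyle, origins, insertions, bite_points)
}

#' Generate a plausible synthetic muscle-architecture table
#'
#' Draws masses and fibre lengths from log-normal distributions at the
#' scale of small didelphid masticatory muscles (masses of order hundredths
#' of a gram, fibre lengths of a few millimetres), for property tests and
#' calibration-recovery experiments.
#'
#' @param n_muscles Number of muscles.
#' @param mass_meanlog,mass_sdlog Log-normal parameters of the preserved
#'   mass, grams. Defaults `log(0.02)` and 0.5.
#' @param fl_meanlog,fl_sdlog Log-normal parameters of the fibre length,
#'   mm. Defaults `log(3.5)` and 0.2.
#' @param muscles Optional labels; `S01`, `S02`, ... by default.
#' @param seed Optional integer seed.
#' @return A [muscle_architecture()] table (all closers).
#' @export
generate_architecture <- function(n_muscles = 12,
                                  mass_meanlog = log(0.02),
                                  mass_sdlog = 0.5,
                                  fl_meanlog = log(3.5),
                                  fl_sdlog = 0.2,
                                  muscles = NULL, seed = NULL) {
  if (n_muscles < 1) stop("'n_muscles' must be >= 1", call. = FALSE)
  if (mass_sdlog < 0 || fl_sdlog < 0)
    stop("distribution spreads must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(muscles)) muscles <- sprintf("S%02d", seq_len(n_muscles))
  muscle_architecture(
    muscles,
    mass = stats::rlnorm(n_muscles, mass_meanlog, mass_sdlog),
    fibre_length = stats::rlnorm(n_muscles, fl_meanlog, fl_sdlog))
}
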