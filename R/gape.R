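#' Sweep the gape angle and locate the optimal gape
#'
#' Starting from the model's current gape, the mandible is rotated in
#' increments of `step` degrees; after each rotation every action line is
#' re-derived from the rotated landmarks and the bite force recomputed.
#' By default the sweep stops at the first decrease of the bite force (the
#' optimum is then the angle before the decrease); `full_sweep = TRUE`
#' scans all the way to `max_gape`, which guards against profiles with an
#' early local maximum. On a plateau the smallest gape attaining the
#' maximum is reported.
#'
#' @param model A geometry-based [bite_model()].
#' @param bite_point Bite-point label at which the force is tracked.
#' @param step Gape increment, degrees (> 0). Default 0.5.
#' @param max_gape Largest gape scanned, degrees. Default 60.
#' @param full_sweep Scan to `max_gape` even after the force decreases.
#' @return An object of class `gape_sweep`: list with `bite_point`, `step`,
#'   `profile` (data frame `gape`, `force`), `optimal_gape` (degrees) and
#'   `optimal_force` (N).
#' @examples
#' m <- bite_model(marmosa_architecture("M2851"),
#'                 geometry = marmosa_synthetic_geometry())
#' sweep_gape(m, "m4")
#' @export
sweep_gape <- function(model, bite_point, step = 0.5, max_gape = 60,
                       full_sweep = FALSE) {
  stopifnot(inherits(model, "bite_model"))
  if (is.null(model$geometry))
    stop("sweeping the gape needs a geometry-based model", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a positive angle in degrees", call. = FALSE)
  if (max_gape < step)
    stop("'max_gape' must be at least one step", call. = FALSE)
  if (!bite_point %in% names(model$forces))
    stop("unknown bite point: ", bite_point, call. = FALSE)

  gapes <- seq(model$gape, max_gape, by = step)
  forces <- numeric(0)
  geom <- model$geometry
  cur <- model
  for (i in seq_along(gapes)) {
    if (i > 1L) {
      geom <- rotate_mandible(geom, step)
      cur <- bite_model(model$architecture, geometry = geom,
                        constants = model$constants,
                        exclude = model$exclude)
    }
    forces[i] <- cur$forces[[bite_point]]
    if (!full_sweep && i > 1L && forces[i] < forces[i - 1L]) break
  }
  profile <- data.frame(gape = gapes[seq_along(forces)], force = forces)
  best <- which(profile$force == max(profile$force))[1L]
  structure(list(bite_point = bite_point, step = step, profile = profile,
                 optimal_gape = profile$gape[best],
                 optimal_force = profile$force[best],
                 full_sweep = full_sweep),
            class = "gape_sweep")
}

#' @export
print.gape_sweep <- function(x, ...) {
  cat(sprintf("Gape sweep at '%s' (step %.2f deg, %d evaluations%s)\n",
              x$bite_point, x$step, nrow(x$profile),
              if (x$full_sweep) ", full sweep" else ", early stop"))
  cat(sprintf("  optimal gape  %6.2f deg\n", x$optimal_gape))
  cat(sprintf("  peak force    %8.3f N\n", x$optimal_force))
  invisible(x)
}

#' @export
plot.gape_sweep <- function(x, ...) {
  plot(x$profile$gape, x$profile$force, type = "l",
       xlab = "gape (degrees)", ylab = "bilateral bite force (N)", ...)
  graphics::abline(v = x$optimal_gape, lty = 2)
  graphics::points(x$optimal_gape, x$optimal_force, pch = 19)
  invisible(x)
}
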