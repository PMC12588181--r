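#' Fit the muscle-stress constant to an in vivo bite force
#'
#' The modelled bite force is exactly linear in the muscle stress, so the
#' stress that reconciles the model with a measured in vivo force has the
#' closed form `fitted = reference * f_alive / f_calc_ref`. An iterative
#' mode reproduces the increase/decrease search as a bisection on the
#' stress and must agree with the closed form to the loop tolerance.
#'
#' @param f_alive In vivo maximum bite force, N (> 0).
#' @param f_calc_ref Modelled bite force at the reference stress, N (> 0).
#' @param reference_stress Muscle stress at which `f_calc_ref` was
#'   computed, N cm^-2. Default 30.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @param interval Search interval for bisection, N cm^-2.
#' @param tol Absolute force tolerance of the bisection, N.
#' @return An object of class `stress_fit`: list with `fitted_stress`,
#'   `f_alive`, `f_calc_ref`, `reference_stress`, `method`.
#' @examples
#' fit_muscle_stress(37.185, 25.148)  # 44.360 N cm^-2
#' @export
fit_muscle_stress <- function(f_alive, f_calc_ref, reference_stress = 30,
                              method = c("closed_form", "bisection"),
                              interval = c(0.1, 200), tol = 1e-3) {
  method <- match.arg(method)
  for (nm in c("f_alive", "f_calc_ref", "reference_stress")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  fitted <- if (method == "closed_form") {
    reference_stress * f_alive / f_calc_ref
  } else {
    ## literal search: scale the stress up or down until the
    ## recomputed force matches the in vivo force
    fcalc <- function(stress) f_calc_ref * stress / reference_stress
    lo <- interval[1]; hi <- interval[2]
    if ((fcalc(lo) - f_alive) * (fcalc(hi) - f_alive) > 0)
      stop("in vivo force not bracketed by the stress interval ",
           "[", lo, ", ", hi, "] N cm^-2", call. = FALSE)
    repeat {
      mid <- (lo + hi) / 2
      err <- fcalc(mid) - f_alive
      if (abs(err) < tol || (hi - lo) < 1e-12) break
      if (err > 0) hi <- mid else lo <- mid
    }
    mid
  }
  structure(list(fitted_stress = fitted, f_alive = f_alive,
                 f_calc_ref = f_calc_ref,
                 reference_stress = reference_stress, method = method),
            class = "stress_fit")
}

#' @export
print.stress_fit <- function(x, ...) {
  cat(sprintf("Muscle-stress calibration (%s)\n", x$method))
  cat(sprintf("  in vivo force      %8.3f N\n", x$f_alive))
  cat(sprintf("  model at %5.1f     %8.3f N\n", x$reference_stress,
              x$f_calc_ref))
  cat(sprintf("  fitted stress      %8.3f N cm^-2\n", x$fitted_stress))
  invisible(x)
}

#' Calibrate a bite model against an in vivo bite force
#'
#' Convenience wrapper: evaluates the model's bite force at the optimal
#' gape (located with [sweep_gape()]) or at the closed mouth, then fits the
#' muscle stress with [fit_muscle_stress()].
#'
#' @param model A [bite_model()].
#' @param f_alive In vivo maximum bite force, N.
#' @param bite_point Bite-point label.
#' @param at `"optimal"` (default; needs geometry) or `"closed"`.
#' @param ... Passed to [fit_muscle_stress()] (e.g. `method`).
#' @return A `stress_fit` with two extra components: `bite_point` and
#'   `gape` (the gape at which the calibration was performed).
#' @export
calibrate <- function(model, f_alive, bite_point,
                      at = c("optimal", "closed"), ...) {
  stopifnot(inherits(model, "bite_model"))
  at <- match.arg(at)
  if (at == "optimal") {
    sw <- sweep_gape(model, bite_point)
    f_ref <- sw$optimal_force
    gape <- sw$optimal_gape
  } else {
    base <- if (model$gape == 0 || is.null(model$geometry))
      model else at_gape(model, 0)
    f_ref <- base$forces[[bite_point]]
    gape <- base$gape
  }
  out <- fit_muscle_stress(f_alive, f_ref,
                           reference_stress = model$constants$muscle_stress,
                           ...)
  out$bite_point <- bite_point
  out$gape <- gape
  out
}
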