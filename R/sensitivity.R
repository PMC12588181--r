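#' One-at-a-time parameter sensitivity of the bite force
#'
#' For each jaw-closing muscle and each of the six per-muscle model
#' parameters — in-lever `lever`, angle `theta`, muscle mass `mass`, fibre
#' length `fibre_length`, angle `phi`, and the out-lever `d_cbp` (perturbed
#' only inside that muscle's moment term) — the parameter is scaled by
#' `1 - fraction` and `1 + fraction` while everything else is held fixed,
#' and the percent change of the total bite force is recorded.
#'
#' Parameters entering a muscle's term linearly (lever, mass) change the
#' force by exactly `+/- fraction x` that muscle's force share; angles act
#' through `sin`, so their entries follow sine ratios and are not
#' antisymmetric. Perturbations that leave the valid domain (an angle
#' scaled beyond 180 degrees) are flagged as `NA` rather than crashing.
#'
#' @param model A [bite_model()].
#' @param bite_point Bite-point label.
#' @param gape Gape angle (degrees) at which to evaluate; non-zero values
#'   (relative to the model's gape) require geometry mode. Default: the
#'   model's current gape.
#' @param fraction Relative perturbation, in (0, 1). Default 0.05.
#' @return An object of class `bite_sensitivity`: list with `entries`
#'   (matrix, rows = muscles, columns = `<parameter>.<-5%/+5%>`, percent
#'   change of Fcalc), `shares` (per-muscle force shares), `bite_point`,
#'   `gape`, `fraction`, `baseline` (N).
#' @examples
#' m <- bite_model(marmosa_architecture("M2851"),
#'                 action = marmosa_action_table(), d_cbp = marmosa_out_levers())
#' sensitivity(m, "incisor")
#' @export
sensitivity <- function(model, bite_point, gape = model$gape,
                        fraction = 0.05) {
  stopifnot(inherits(model, "bite_model"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie in (0, 1)", call. = FALSE)
  if (!isTRUE(all.equal(gape, model$gape))) model <- at_gape(model, gape)
  if (!bite_point %in% names(model$forces))
    stop("unknown bite point: ", bite_point, call. = FALSE)

  mech <- model$mechanics
  closer <- mech$moment_sign < 0 & mech$role != "opener"
  mech <- mech[closer, , drop = FALSE]
  d0 <- model$d_cbp[[bite_point]]
  stress_corr <- model$constants$muscle_stress * model$constants$mass_correction
  term <- function(mass, fl, phi, theta, lever, d) {
    f3 <- stress_corr * mass / ((fl / 10) * model$constants$density)
    lever * sin(deg2rad(theta)) * f3 * sin(deg2rad(phi)) / d
  }
  base_terms <- with(mech, term(mass, fibre_length, phi, theta, lever, d0))
  f0 <- 2 * sum(base_terms)

  params <- c("lever", "theta", "mass", "fibre_length", "phi", "d_cbp")
  dirs <- c(1 - fraction, 1 + fraction)
  dir_lab <- sprintf("%+g%%", 100 * (dirs - 1))
  entries <- matrix(NA_real_, nrow = nrow(mech),
                    ncol = length(params) * 2,
                    dimnames = list(mech$muscle,
                                    paste(rep(params, each = 2), dir_lab,
                                          sep = ".")))
  flagged <- character(0)
  for (i in seq_len(nrow(mech))) {
    for (p in seq_along(params)) {
      for (k in 1:2) {
        v <- c(mass = mech$mass[i], fibre_length = mech$fibre_length[i],
               phi = mech$phi[i], theta = mech$theta[i],
               lever = mech$lever[i], d_cbp = d0)
        v[[params[p]]] <- v[[params[p]]] * dirs[k]
        col <- (p - 1L) * 2L + k
        if (v[["phi"]] > 180 || v[["theta"]] > 180) {
          flagged <- c(flagged, paste0(mech$muscle[i], ":",
                                       colnames(entries)[col]))
          next
        }
        ti <- term(v[["mass"]], v[["fibre_length"]], v[["phi"]],
                   v[["theta"]], v[["lever"]], v[["d_cbp"]])
        f1 <- f0 + 2 * (ti - base_terms[i])
        entries[i, col] <- 100 * (f1 - f0) / f0
      }
    }
  }
  shares <- 2 * base_terms / f0
  names(shares) <- mech$muscle
  structure(list(entries = entries, shares = shares,
                 bite_point = bite_point, gape = model$gape,
                 fraction = fraction, baseline = f0, flagged = flagged),
            class = "bite_sensitivity")
}

#' @export
print.bite_sensitivity <- function(x, ...) {
  cat(sprintf(
    "One-at-a-time sensitivity at '%s', gape %.1f deg (+/-%g%% perturbation)\n",
    x$bite_point, x$gape, 100 * x$fraction))
  cat(sprintf("  baseline bite force %.3f N\n", x$baseline))
  tab <- round(x$entries, 2)
  ## mark the three largest magnitudes per column, as in printed reports
  marked <- matrix(format(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  for (j in seq_len(ncol(tab))) {
    top <- order(abs(tab[, j]), decreasing = TRUE)[1:min(3, nrow(tab))]
    marked[top, j] <- paste0(format(tab[top, j]), "*")
  }
  print(as.data.frame(marked), ...)
  cat("  (* three most impactful muscles per column)\n")
  if (length(x$flagged))
    cat("  flagged (out-of-domain perturbation):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
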