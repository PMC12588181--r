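# Independent oracles and fixture builders shared across the suite.

# Brute-force equilibrium: assemble each muscle's full 3D force vector,
# take the z-component of the explicit cross product of in-lever and force
# about the condyle, and balance moments at the out-lever.  No phi/theta
# decomposition anywhere, so it is independent of the implementation path.
oracle_bite_force <- function(geom, arch, constants, bite) {
  f3 <- f3dmax(arch, constants)
  muscles <- rownames(geom$origins)
  mz <- vapply(muscles, function(mu) {
    v <- geom$origins[mu, ] - geom$insertions[mu, ]
    f <- f3[[mu]] * v / sqrt(sum(v^2))
    l <- geom$insertions[mu, ] - geom$condyle
    l[1] * f[2] - l[2] * f[1]          # right-handed z moment; + closes
  }, numeric(1))
  role <- arch$role[match(muscles, arch$muscle)]
  closing <- mz > 0 & role != "opener"
  d <- sqrt(sum(((geom$bite_points[bite, ] - geom$condyle)[1:2])^2))
  2 * sum(mz[closing]) / d
}

# Fine-grid brute-force gape optimum using the oracle above at every step.
oracle_gape_optimum <- function(geom, arch, constants, bite,
                                step = 0.01, max_gape = 60) {
  gapes <- seq(0, max_gape, by = step)
  forces <- vapply(gapes, function(g) {
    oracle_bite_force(rotate_mandible(geom, g - geom$gape),
                      arch, constants, bite)
  }, numeric(1))
  list(gape = gapes[which.max(forces)], force = max(forces))
}

# Random raw-landmark geometry (not built through generate_geometry), with
# a matching architecture; redrawn until at least one closing muscle exists.
random_geometry_case <- function(n_muscles = 4) {
  repeat {
    condyle <- stats::runif(3, -2, 2)
    origins <- matrix(stats::runif(3 * n_muscles, -10, 10), ncol = 3)
    insertions <- matrix(stats::runif(3 * n_muscles, -10, 10), ncol = 3)
    rownames(origins) <- rownames(insertions) <-
      sprintf("S%02d", seq_len(n_muscles))
    bite <- condyle + c(stats::runif(1, 5, 20), stats::runif(1, -5, 5),
                        stats::runif(1, -1, 1))
    geom <- try(jaw_geometry(condyle, origins, insertions,
                             rbind(bp = bite)), silent = TRUE)
    if (inherits(geom, "try-error")) next
    al <- try(action_lines(geom), silent = TRUE)
    if (inherits(al, "try-error")) next
    if (!any(al$moment_sign < 0)) next
    arch <- generate_architecture(n_muscles,
                                  muscles = rownames(origins))
    return(list(geom = geom, arch = arch))
  }
}

# Geometry-free fit of the M2851 closed-mouth record.
marmosa_closed_model <- function(constants = model_constants()) {
  bite_model(marmosa_architecture("M2851"),
             action = marmosa_action_table(constants = constants),
             d_cbp = marmosa_out_levers(),
             constants = constants)
}

# A deliberately unimodal geometry: sagittal closers whose theta starts
# below 90 degrees with far-away origins, so the force rises towards
# theta = 90 and falls beyond it.
unimodal_geometry <- function() {
  targets <- data.frame(muscle = c("A", "B"),
                        phi = c(90, 90), theta = c(55, 70),
                        lever = c(5, 4), moment_sign = -1)
  generate_geometry(targets, d_cbp = c(bp = 12), origin_distance = 60)
}

unimodal_architecture <- function() {
  muscle_architecture(c("A", "B"), mass = c(0.05, 0.03),
                      fibre_length = c(4, 3.5))
}
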