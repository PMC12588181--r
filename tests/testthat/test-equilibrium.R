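test_that("sagittal projection matches the recorded values and the radical form", {
  expect_lt(abs(project_sagittal(7.458, 59.70) - 6.439), 2e-3)
  expect_lt(abs(project_sagittal(4.356, 8.14) - 0.617), 2e-3)
  expect_equal(project_sagittal(3.7, 90), 3.7)
  # sin form equals sqrt(F^2 - (F cos phi)^2) on [0, 180]
  set.seed(7)
  f <- runif(50, 0, 20); phi <- runif(50, 0, 180)
  expect_equal(project_sagittal(f, phi),
               sqrt(f^2 - (f * cos(phi * pi / 180))^2), tolerance = 1e-12)
  expect_error(project_sagittal(5, 190), "\\[0, 180\\]")
  expect_error(project_sagittal(-1, 90), "non-negative")
})

test_that("bite resultants follow the lever closed form", {
  expect_equal(bite_resultant(4, 30, 5, 10), 1)
  expect_equal(bite_resultant(4, 0, 5, 10), 0)  # line through the joint
  # scale invariance of the lever ratio
  expect_equal(bite_resultant(4, 30, 10, 20), bite_resultant(4, 30, 5, 10))
  expect_error(bite_resultant(4, 30, 5, 0), "positive")
})

test_that("closed-mouth totals reproduce the recorded bilateral forces", {
  m <- marmosa_closed_model()
  ref <- marmosa_reference_mechanics()
  # per-muscle chain against the printed mechanics (3-decimal record)
  mech <- m$mechanics[match(ref$muscle, m$mechanics$muscle), ]
  expect_true(all(abs(mech$f3dmax - ref$f3dmax_N) < 2e-3))
  expect_true(all(abs(mech$f2dmax - ref$f2dmax_N) < 2e-3))
  # bilateral doubling over the closers; PtLat sits in the excluded set
  expect_equal(m$excluded, "PtLat")
  expect_lt(abs(m$forces[["incisor"]] - 10.688), 0.02)
  expect_lt(abs(m$forces[["m4"]] - 24.992), 0.02)
  # anterior bite point is weaker than the posterior one
  expect_lt(m$forces[["incisor"]], m$forces[["m4"]])
  # the total is exactly twice the sum over included closers
  bf <- total_bite_force(m$mechanics, "incisor")
  expect_equal(bf$total_force, 2 * sum(bf$per_muscle), tolerance = 1e-9)
  # single closer doubles
  one <- data.frame(muscle = "A", role = "closer", moment_sign = -1,
                    R_bp = 1)
  expect_equal(total_bite_force(one, "bp")$total_force, 2)
  opener_only <- data.frame(muscle = "A", role = "closer",
                            moment_sign = 1, R_bp = 1)
  expect_error(total_bite_force(opener_only, "bp"), "no jaw-closing")
})

test_that("model equals the 3D cross-product oracle on random geometries", {
  set.seed(2851)
  k <- model_constants()
  for (i in 1:100) {
    case <- random_geometry_case(sample(2:6, 1))
    m <- bite_model(case$arch, geometry = case$geom, constants = k)
    want <- oracle_bite_force(case$geom, case$arch, k, "bp")
    expect_equal(unname(m$forces[["bp"]]), want, tolerance = 1e-9)
  }
})

test_that("bite force is exactly linear in muscle stress", {
  set.seed(99)
  case <- random_geometry_case(5)
  base <- bite_model(case$arch, geometry = case$geom)
  for (kf in c(0.25, 1.5, 7)) {
    scaled <- bite_model(case$arch, geometry = case$geom,
                         constants = model_constants(muscle_stress = 30 * kf))
    expect_equal(scaled$forces, kf * base$forces, tolerance = 1e-12)
  }
})

test_that("the opener override forces muscles out of the sum", {
  m <- marmosa_closed_model()
  m2 <- bite_model(marmosa_architecture("M2851"),
                   action = marmosa_action_table(),
                   d_cbp = marmosa_out_levers(),
                   exclude = c("PtLat", "MS"))
  ms_share <- 2 * m$mechanics$R_incisor[m$mechanics$muscle == "MS"]
  expect_equal(m2$forces[["incisor"]], m$forces[["incisor"]] - ms_share,
               tolerance = 1e-9)
  expect_setequal(m2$excluded, c("PtLat", "MS"))
})
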