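test_that("the generator is deterministic under a fixed seed", {
  tg <- data.frame(muscle = c("A", "B"), phi = c(60, 100),
                   theta = c(50, 120), lever = c(4, 6))
  g1 <- generate_geometry(tg, d_cbp = c(bp = 10), noise_sd = 0.02, seed = 5)
  g2 <- generate_geometry(tg, d_cbp = c(bp = 10), noise_sd = 0.02, seed = 5)
  expect_identical(g1, g2)
  g3 <- generate_geometry(tg, d_cbp = c(bp = 10), noise_sd = 0.02, seed = 6)
  expect_false(identical(g1$insertions, g3$insertions))
  a1 <- generate_architecture(8, seed = 3)
  a2 <- generate_architecture(8, seed = 3)
  expect_identical(a1, a2)
})

test_that("noise perturbs landmarks at the prescribed relative scale", {
  tg <- data.frame(muscle = "A", phi = 80, theta = 60, lever = 5)
  clean <- generate_geometry(tg, d_cbp = c(bp = 10))
  noisy <- generate_geometry(tg, d_cbp = c(bp = 10), noise_sd = 0.01,
                             seed = 11)
  shift <- sqrt(sum((noisy$insertions - clean$insertions)^2))
  expect_gt(shift, 0)
  expect_lt(shift, 5 * 0.01 * 10)  # well under 10 relative sd
  expect_equal(noisy$condyle, clean$condyle)  # rotation centre fixed
})

test_that("generator rejects infeasible targets", {
  expect_error(generate_geometry(
    data.frame(muscle = "A", phi = 80, theta = 60, lever = 0),
    d_cbp = c(bp = 10)), "in-lever")
  expect_error(generate_geometry(
    data.frame(muscle = "A", phi = 80, theta = 190, lever = 3),
    d_cbp = c(bp = 10)), "\\(0, 180\\)")
  expect_error(generate_geometry(
    data.frame(muscle = "A", phi = 80, theta = 60, lever = 3),
    d_cbp = c(bp = -1)), "positive")
})

test_that("full pipeline through generated coordinates matches geometry-free computation", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    tg <- data.frame(muscle = sprintf("S%02d", 1:n),
                     phi = runif(n, 10, 170),
                     theta = runif(n, 10, 170),
                     lever = runif(n, 1, 8),
                     moment_sign = sample(c(-1, 1), n, replace = TRUE,
                                          prob = c(0.8, 0.2)))
    if (!any(tg$moment_sign < 0)) tg$moment_sign[1] <- -1
    d <- c(bp = runif(1, 8, 20))
    arch <- generate_architecture(n, muscles = tg$muscle)
    direct <- bite_model(arch, action = tg, d_cbp = d)
    via_geom <- bite_model(arch,
                           geometry = generate_geometry(tg, d_cbp = d))
    expect_equal(via_geom$forces, direct$forces, tolerance = 1e-9)
    expect_setequal(via_geom$excluded, direct$excluded)
    cols <- c("phi", "theta", "lever", "f2dmax", "R_bp")
    expect_equal(via_geom$mechanics[cols], direct$mechanics[cols],
                 tolerance = 1e-9)
  }
})

test_that("architecture draws scale downstream and sit in a plausible PCSA range", {
  a <- generate_architecture(10, seed = 21)
  doubled <- muscle_architecture(a$muscle, a$mass * 2, a$fibre_length)
  expect_equal(f3dmax(doubled), 2 * f3dmax(a))
  # 1000 draws at the default didelphid scale: PCSAs mostly inside the
  # observed range of the example dissections (0.011 - 0.149 cm2)
  set.seed(99)
  draws <- pcsa(generate_architecture(1000))
  inside <- mean(draws >= 0.011 & draws <= 0.149)
  expect_gt(inside, 0.9)
})

test_that("resultant ratios across bite points equal the out-lever ratio", {
  g <- marmosa_synthetic_geometry()  # d_cbp ratio fixed at 2.337
  m <- bite_model(marmosa_architecture("M2851"), geometry = g)
  expect_equal(m$forces[["incisor"]] / m$forces[["m4"]], 1 / 2.337,
               tolerance = 1e-9)
  ref <- marmosa_reference_mechanics()
  # the recorded per-muscle resultants show the same ratio to 3 decimals
  got <- m$mechanics[match(ref$muscle, m$mechanics$muscle), ]
  expect_true(all(abs(got$R_incisor - ref$ri_incisor_N) < 5e-4))
  expect_true(all(abs(got$R_m4 - ref$ri_m4_N) < 5e-3))
})
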