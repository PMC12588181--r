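test_that("PCSA and F3Dmax reproduce the recorded single-muscle values", {
  k <- model_constants()
  # MS of M2851
  ms <- muscle_architecture("MS", 0.0485, 3.138)
  expect_equal(unname(pcsa(ms, k)), 0.1469, tolerance = 1e-3)
  expect_lt(abs(pcsa(ms, k) - 0.1469), 2e-4)
  expect_lt(abs(f3dmax(ms, k) - 7.458), 2e-3)
  # PtMed of M1496
  ptmed <- muscle_architecture("PtMed", 0.0212, 2.109)
  expect_lt(abs(pcsa(ptmed, k) - 0.0956), 2e-4)
  # PtLat of M2851
  ptlat <- muscle_architecture("PtLat", 0.0028, 2.248)
  expect_lt(abs(f3dmax(ptlat, k) - 0.601), 2e-3)
  # units cancel exactly when mass equals density x fibre-length(cm)
  unitless <- muscle_architecture("U", 1.0518, 10)
  expect_equal(unname(pcsa(unitless, k)), 1)
  # zero stress gives zero force
  expect_equal(unname(f3dmax(ms, model_constants(muscle_stress = 1e-12))),
               0, tolerance = 1e-10)
})

test_that("F3Dmax is exactly stress x correction x PCSA and scales linearly", {
  set.seed(11)
  for (i in 1:20) {
    k <- model_constants(muscle_stress = runif(1, 5, 80),
                         density = runif(1, 0.9, 1.2),
                         mass_correction = runif(1, 1, 2.5))
    a <- generate_architecture(6)
    expect_equal(f3dmax(a, k),
                 k$muscle_stress * k$mass_correction * pcsa(a, k))
    a2 <- muscle_architecture(a$muscle, a$mass * 2, a$fibre_length)
    expect_equal(pcsa(a2, k), 2 * pcsa(a, k))
    a3 <- muscle_architecture(a$muscle, a$mass, a$fibre_length * 2)
    expect_equal(f3dmax(a3, k), f3dmax(a, k) / 2)
  }
})

test_that("every recorded PCSA of both specimens is reproduced to 2e-4 cm2", {
  ref <- marmosa_reference_pcsa()
  for (sp in c("M2851", "M1496")) {
    arch <- marmosa_architecture(sp)
    got <- pcsa(arch)
    want <- ref[ref$specimen == sp, ]
    expect_equal(length(got), 13L)
    expect_true(all(abs(got[want$muscle] - want$pcsa_cm2) < 2e-4),
                label = paste("PCSAs of", sp, "within 0.0002 cm2"))
  }
})

test_that("architecture validation rejects bad inputs", {
  expect_error(muscle_architecture("MS", -0.01, 3), "positive")
  expect_error(muscle_architecture("MS", 0.01, 0), "positive")
  expect_error(muscle_architecture(c("MS", "MS"), c(1, 1), c(2, 2)),
               "duplicate")
  expect_error(muscle_architecture("XX", 0.01, 3,
                                   roster = marmosa_roster()),
               "roster")
  expect_error(muscle_architecture("MS", 0.01, 3, role = "flexor"),
               "closer")
  expect_error(model_constants(muscle_stress = 0), "positive")
})

test_that("architecture CSV round-trips through the reader", {
  arch <- marmosa_architecture("M1496")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(muscle = arch$muscle, mass_g = arch$mass,
                       fibre_length_mm = arch$fibre_length,
                       role = arch$role),
            tmp, row.names = FALSE)
  back <- read_architecture(tmp, roster = marmosa_roster())
  expect_equal(as.data.frame(back), as.data.frame(arch))
  # schema errors name the missing column
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(muscle = "MS", grams = 1), bad, row.names = FALSE)
  expect_error(read_architecture(bad), "mass_g")
})
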