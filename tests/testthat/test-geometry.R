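test_that("mandible rotation is the expected rigid motion", {
  g <- generate_geometry(
    data.frame(muscle = "A", phi = 80, theta = 60, lever = 5),
    d_cbp = c(bp = 10), condyle = c(1, 2, 3))
  # identity
  expect_equal(rotate_mandible(g, 0)$insertions, g$insertions)
  expect_equal(rotate_mandible(g, 0)$bite_points, g$bite_points)
  # composition: two half-degree steps equal one degree
  twice <- rotate_mandible(rotate_mandible(g, 0.5), 0.5)
  once <- rotate_mandible(g, 1)
  expect_equal(twice$insertions, once$insertions, tolerance = 1e-12)
  expect_equal(twice$bite_points, once$bite_points, tolerance = 1e-12)
  expect_equal(twice$gape, 1)
  # opening quarter turn: (1,0,0) relative to condyle goes ventral
  g2 <- jaw_geometry(c(0, 0, 0),
                     origins = rbind(A = c(5, 8, 2)),
                     insertions = rbind(A = c(3, 1, 0)),
                     bite_points = rbind(bp = c(1, 0, 0)))
  r <- rotate_mandible(g2, 90)
  expect_equal(unname(r$bite_points["bp", ]), c(0, -1, 0))
  # origins and condyle never move
  expect_equal(r$origins, g2$origins)
  expect_equal(r$condyle, g2$condyle)
})

test_that("rotation is an isometry of mandibular points about the condyle", {
  set.seed(42)
  for (i in 1:25) {
    case <- random_geometry_case(3)
    g <- case$geom
    delta <- runif(1, -180, 180)
    r <- rotate_mandible(g, delta)
    d0 <- sqrt(rowSums((g$insertions -
                          matrix(g$condyle, 3, 3, byrow = TRUE))^2))
    d1 <- sqrt(rowSums((r$insertions -
                          matrix(g$condyle, 3, 3, byrow = TRUE))^2))
    expect_equal(d1, d0, tolerance = 1e-9)
    expect_equal(bite_distance(r, "bp"), bite_distance(g, "bp"),
                 tolerance = 1e-9)
  }
})

test_that("action lines are recovered from coordinates", {
  # pure sagittal pull perpendicular to the lever: phi = theta = 90
  g <- jaw_geometry(c(0, 0, 0),
                    origins = rbind(A = c(5, 10, 0)),
                    insertions = rbind(A = c(5, 0, 0)),
                    bite_points = rbind(bp = c(10, 0, 0)))
  al <- action_line(g, "A")
  expect_equal(al$phi, 90)
  expect_equal(al$theta, 90)
  expect_equal(al$lever, 5)
  expect_equal(al$moment_sign, -1)   # pulls the jaw shut
  # purely mediolateral pull: degenerate sagittal projection
  g2 <- jaw_geometry(c(0, 0, 0),
                     origins = rbind(A = c(5, 0, 7)),
                     insertions = rbind(A = c(5, 0, 0)),
                     bite_points = rbind(bp = c(10, 0, 0)))
  expect_error(action_line(g2, "A"), "mediolateral.*A|A.*mediolateral")
  expect_error(action_line(g, "nope"), "unknown muscle")
})

test_that("generator round-trips prescribed targets through action_line", {
  targets <- data.frame(muscle = c("MS", "TPmed", "PtLat"),
                        phi = c(59.70, 67.82, 49.30),
                        theta = c(63.89, 111.36, 5.91),
                        lever = c(3.1, 2.7, 0.4),
                        moment_sign = c(-1, -1, 1))
  g <- generate_geometry(targets, d_cbp = c(incisor = 14, m4 = 5.99))
  al <- action_lines(g)
  al <- al[match(targets$muscle, al$muscle), ]
  expect_equal(al$phi, targets$phi, tolerance = 1e-6)
  expect_equal(al$theta, targets$theta, tolerance = 1e-6)
  expect_equal(al$lever, targets$lever, tolerance = 1e-9)
  expect_equal(al$moment_sign, targets$moment_sign)
  expect_equal(bite_distance(g, "incisor"), 14, tolerance = 1e-9)
  expect_equal(bite_distance(g, "m4"), 5.99, tolerance = 1e-9)
})

test_that("landmark CSV and JSON readers build the same geometry", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("landmark,role,x_mm,y_mm,z_mm",
               "cond,condyle,0,0,0",
               "msO,origin:MS,4,6,2",
               "msI,insertion:MS,3,-1,0",
               "inc,bite:incisor,12,-2,0"), csv)
  g <- read_landmarks(csv)
  expect_s3_class(g, "jaw_geometry")
  expect_equal(unname(g$origins["MS", ]), c(4, 6, 2))
  expect_equal(rownames(g$bite_points), "incisor")
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(condyle = c(0, 0, 0),
                            origins = list(MS = c(4, 6, 2)),
                            insertions = list(MS = c(3, -1, 0)),
                            bite_points = list(incisor = c(12, -2, 0))),
                       js, auto_unbox = FALSE)
  g2 <- read_landmarks(js)
  expect_equal(g2$origins, g$origins)
  expect_equal(g2$bite_points, g$bite_points)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("landmark,role,x_mm,y_mm", "c,condyle,0,0"), bad)
  expect_error(read_landmarks(bad), "z_mm")
})

test_that("geometry validation catches degenerate configurations", {
  expect_error(jaw_geometry(c(0, 0, 0),
                            origins = rbind(A = c(1, 1, 0)),
                            insertions = rbind(A = c(1, 1, 0)),
                            bite_points = rbind(bp = c(5, 0, 0))),
               "coincides")
  expect_error(jaw_geometry(c(0, 0, 0),
                            origins = rbind(A = c(1, 1, 0)),
                            insertions = rbind(A = c(2, 1, 0)),
                            bite_points = rbind(bp = c(0, 0, 0))),
               "condyle")
  g <- generate_geometry(data.frame(muscle = "A", phi = 80, theta = 60,
                                    lever = 5), d_cbp = c(bp = 10))
  expect_error(bite_distance(g, "molar"), "unknown bite point")
})
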