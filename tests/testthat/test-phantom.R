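test_that("phantom slice areas match the analytic disc within a pixel ring
           and the volume is reproducible", {
  spec <- phantomSpec(noiseSD = 0, wobbleAmplitude = 0, waist = 0)
  vol <- generatePhantom(spec, "deep_end_expiration")
  gt <- groundTruth(vol)
  px <- prod(voxelSpacing(vol)[1:2])
  for (z in which(!is.na(gt$radius_mm))) {
    r <- gt$radius_mm[z]
    counted <- sum(volumeValues(vol)[, , z] < 120) * px
    ring <- 2 * pi * r * sqrt(2) * 0.5 + pi * 0.5^2   # one pixel-perimeter ring
    expect_lt(abs(counted - pi * r^2), ring)
  }

  spec2 <- phantomSpec(seed = 31L)
  v1 <- generatePhantom(spec2, "calm_breathing")
  v2 <- generatePhantom(spec2, "calm_breathing")
  expect_identical(volumeValues(v1), volumeValues(v2))
  # different phases draw different noise
  v3 <- generatePhantom(spec2, "muller")
  expect_false(identical(volumeValues(v1), volumeValues(v3)))
})

test_that("scaling a phase's radii by s scales its analytic areas by s^2", {
  base <- phantomSpec(noiseSD = 0)
  radii <- base@radii
  radii[, "deep_end_inspiration"] <- 0.7 * radii[, "deep_end_expiration"]
  scaled <- phantomSpec(noiseSD = 0, radii = radii)
  aExp <- groundTruth(generatePhantom(scaled, "deep_end_expiration"))$area_mm2
  aIns <- groundTruth(generatePhantom(scaled, "deep_end_inspiration"))$area_mm2
  keep <- !is.na(aExp)
  expect_equal(aIns[keep], 0.49 * aExp[keep])
})

test_that("subject generation realizes collapse targets analytically", {
  spec <- phantomSpec()
  sub <- generateSubject(spec, c(nasopharyngeal = 0, posterior_palatal = 0.64,
                                 retrolingual = 0.2, laryngopharyngeal = 0.5),
                         phases = "deep_end_inspiration")
  radii <- sub$groundTruth$radii
  expect_equal(radii["posterior_palatal", "deep_end_inspiration"],
               0.6 * radii["posterior_palatal", "deep_end_expiration"])
  expect_error(generateSubject(spec, c(nasopharyngeal = 0,
                                       posterior_palatal = 1,
                                       retrolingual = 0,
                                       laryngopharyngeal = 0)),
               "must be < 1")
  expect_error(generateSubject(spec, c(nasopharyngeal = 0)),
               "must name every region")
})

test_that("the segment-measure pipeline recovers collapse targets and is
           robust to noise up to 10% of the contrast", {
  targets <- c(nasopharyngeal = 0, posterior_palatal = 0.2,
               retrolingual = 0.4, laryngopharyngeal = 0.6)
  # noise at 5% of the 160-gray-level contrast (the default)
  sub <- generateSubject(phantomSpec(seed = 12L), targets,
                         phases = c("deep_end_expiration",
                                    "deep_end_inspiration"))
  meas <- measureSubject(sub$volumes, sub$groundTruth$landmarks)
  got <- meas$collapse$collapse_degree[match(names(targets),
                                             meas$collapse$region)]
  expect_true(all(abs(got - targets) < 0.05))

  # raising the noise to 10% of the contrast moves the recovered values
  # by less than 0.05
  noisy <- generateSubject(phantomSpec(seed = 12L, noiseSD = 16), targets,
                           phases = c("deep_end_expiration",
                                      "deep_end_inspiration"))
  measN <- measureSubject(noisy$volumes, noisy$groundTruth$landmarks)
  gotN <- measN$collapse$collapse_degree[match(names(targets),
                                               measN$collapse$region)]
  expect_true(all(abs(gotN - got) < 0.05))
})

test_that("cohort generation matches its specified distributions at large n
           and is reproducible", {
  spec <- cohortSpec(nPerGroup = 10000L, seed = 99L)
  tab <- generateCohort(spec)
  test <- tab[tab$group == "test", ]
  # sample means within 2 standard errors of the specified means
  expect_lt(abs(mean(test$age_years) - 45.54), 2 * 10.15 / sqrt(10000))
  expect_lt(abs(mean(test$height_m) - 1.66), 2 * 0.08 / sqrt(10000))
  expect_lt(abs(mean(test$weight_kg) - 67.52), 2 * 10.51 / sqrt(10000))
  ctrl <- tab[tab$group == "control", ]
  expect_lt(abs(mean(ctrl$age_years) - 47.69), 2 * 11.12 / sqrt(10000))
  expect_lt(abs(mean(test$sex == "male") - 24 / 30), 2 * sqrt(0.8 * 0.2 / 10000))
  # collapse draws respect the truncation range
  cl <- unlist(tab[grep("^collapse_", names(tab))])
  expect_true(all(cl > -0.5 & cl < 1))

  expect_identical(generateCohort(cohortSpec(seed = 4L)),
                   generateCohort(cohortSpec(seed = 4L)))
  # nasopharyngeal means are equal across groups by default
  expect_equal(cohortSpec()@collapseMean["nasopharyngeal", "test"],
               cohortSpec()@collapseMean["nasopharyngeal", "control"])
})
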