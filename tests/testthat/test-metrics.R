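test_that("slice areas are foreground counts scaled by pixel area", {
  m <- array(FALSE, c(8, 8, 3))
  m[1:5, 1:2, 2] <- TRUE                       # 10 pixels in slice 2
  bm <- BinaryMask(m, spacing = c(0.5, 0.5, 2.5))
  expect_equal(sliceArea(bm, 2), 2.5)
  expect_equal(sliceArea(bm, 1), 0)
  # doubling the in-plane spacing quadruples the area of the same mask
  bm2 <- BinaryMask(m, spacing = c(1, 1, 2.5))
  expect_equal(sliceArea(bm2, 2), 4 * sliceArea(bm, 2))
  expect_error(sliceArea(bm, 4), "out of range")
})

test_that("region partition is half-open, disjoint and covering", {
  lm <- airwayLandmarks(1, 11, 21, 31, 41)
  pr <- partitionRegions(lm)
  expect_named(pr, airwayRegions())
  expect_equal(pr$nasopharyngeal, c(start = 1, end = 11))
  expect_equal(pr$laryngopharyngeal, c(start = 31, end = 41))

  set.seed(3)
  for (i in 1:25) {
    z <- sort(sample(1:60, 5))
    if (any(diff(z) == 0)) next
    pr <- partitionRegions(airwayLandmarks(z[1], z[2], z[3], z[4], z[5]))
    covered <- unname(unlist(lapply(pr, function(r)
      seq.int(r[["start"]], r[["end"]] - 1L))))
    expect_equal(sort(covered), seq.int(z[1], z[5] - 1L))  # exact cover
    expect_equal(anyDuplicated(covered), 0L)               # disjoint
  }

  expect_error(airwayLandmarks(1, 11, 5, 31, 41), "landmarks out of order")
})

test_that("region area summaries follow the slice-area profile", {
  bm <- maskFromProfile(c(4, 2, 6))
  expect_equal(as.numeric(regionArea(bm, c(1, 4), summary = "min")), 2)
  expect_equal(as.numeric(regionArea(bm, c(1, 4), summary = "mean")), 4)
  const <- maskFromProfile(c(3, 3, 3))
  expect_equal(as.numeric(regionArea(const, c(1, 4), "min")),
               as.numeric(regionArea(const, c(1, 4), "mean")))
  expect_warning(a0 <- regionArea(maskFromProfile(c(0, 0)), c(1, 3)),
                 "zero foreground")
  expect_equal(as.numeric(a0), 0)
})

test_that("collapse degree follows its defining formula", {
  expect_equal(collapseDegree(100, 100), 0)
  expect_equal(collapseDegree(100, 40), 0.6)
  expect_equal(collapseDegree(50, 60), -0.2)
  expect_error(collapseDegree(0, 10), "zero expiratory area")
  # invariance under common rescaling of both areas
  set.seed(8)
  ae <- runif(20, 1, 100); ai <- runif(20, 0, 100)
  expect_equal(collapseDegree(3.7 * ae, 3.7 * ai), collapseDegree(ae, ai))
})

test_that("measuring a subject with identical phases gives zero collapse
           and input errors are caught", {
  spec <- phantomSpec(shape = c(48L, 48L, 44L), noiseSD = 0, seed = 5L)
  sub <- generateSubject(spec, c(nasopharyngeal = 0, posterior_palatal = 0,
                                 retrolingual = 0, laryngopharyngeal = 0),
                         phases = c("deep_end_expiration",
                                    "deep_end_inspiration"))
  meas <- measureSubject(sub$volumes, sub$groundTruth$landmarks)
  expect_equal(meas$collapse$collapse_degree, rep(0, 4))

  expect_error(measureSubject(sub$volumes["deep_end_expiration"],
                              sub$groundTruth$landmarks),
               "missing phase: deep_end_inspiration")
  bad <- sub$volumes
  bad$deep_end_inspiration <- generatePhantom(
    phantomSpec(shape = c(56L, 56L, 44L), noiseSD = 0),
    "deep_end_inspiration")
  expect_error(measureSubject(bad, sub$groundTruth$landmarks),
               "mismatched geometry")
  names(bad) <- c("deep_end_expiration", "exhale")
  expect_error(measureSubject(bad, sub$groundTruth$landmarks),
               "unknown phase")
})

test_that("a retrolingual narrowing to 40% of the expiratory area is
           measured as collapse 0.6 within 10%", {
  spec <- phantomSpec(noiseSD = 0, seed = 2L)
  sub <- generateSubject(spec, c(nasopharyngeal = 0, posterior_palatal = 0,
                                 retrolingual = 0.6, laryngopharyngeal = 0),
                         phases = c("deep_end_expiration",
                                    "deep_end_inspiration"))
  meas <- measureSubject(sub$volumes, sub$groundTruth$landmarks)
  rl <- meas$collapse$collapse_degree[meas$collapse$region == "retrolingual"]
  expect_lt(abs(rl - 0.6), 0.06)
})
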