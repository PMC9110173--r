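test_that("summary-level t-test matches its formula, its antisymmetry and
           the published-table worked case", {
  g1 <- groupSummary(30, 45.54, 10.15)
  g2 <- groupSummary(30, 47.69, 11.12)
  r <- tTestFromSummaries(g1, g2)
  # textbook pooled-variance recomputation
  sp2 <- (29 * 10.15^2 + 29 * 11.12^2) / 58
  tExp <- (45.54 - 47.69) / sqrt(sp2 * (2 / 30))
  expect_equal(r@statistic, tExp)
  expect_equal(r@df, 58)
  expect_equal(r@p, 2 * pt(-abs(tExp), 58))

  sw <- tTestFromSummaries(g2, g1)
  expect_equal(sw@statistic, -r@statistic)
  expect_equal(sw@p, r@p)

  same <- tTestFromSummaries(g1, g1)
  expect_equal(same@statistic, 0)
  expect_equal(same@p, 1)

  expect_error(tTestFromSummaries(groupSummary(5, 1, 0), groupSummary(5, 2, 0)),
               "degenerate variance")
  expect_equal(tTestFromSummaries(groupSummary(5, 1, 0),
                                  groupSummary(5, 1, 0))@p, 1)
})

test_that("raw-data t-test agrees exactly with the summary route and with
           stats::t.test", {
  expect_equal(tTestFromRaw(c(1, 2, 3), c(1, 2, 3))@statistic, 0)
  set.seed(21)
  for (i in 1:20) {
    x1 <- rnorm(sample(3:20, 1)); x2 <- rnorm(sample(3:20, 1), mean = 0.5)
    r <- tTestFromRaw(x1, x2)
    viaSummaries <- tTestFromSummaries(
      groupSummary(length(x1), mean(x1), sd(x1)),
      groupSummary(length(x2), mean(x2), sd(x2)))
    expect_identical(r@statistic, viaSummaries@statistic)
    ref <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(r@statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r@p, ref$p.value, tolerance = 1e-10)
    refW <- t.test(x1, x2)
    rw <- tTestFromRaw(x1, x2, variant = "welch")
    expect_equal(rw@statistic, unname(refW$statistic), tolerance = 1e-10)
    expect_equal(rw@df, unname(refW$parameter), tolerance = 1e-10)
    # shifting both samples leaves t unchanged
    expect_equal(tTestFromRaw(x1 + 7, x2 + 7)@statistic, r@statistic)
  }
})

test_that("rank-sum test: exact enumeration, tie handling and agreement
           with the normal approximation and wilcox.test", {
  # most extreme ranking of 2 vs 2: one-sided 1/6, two-sided 2/6
  r <- rankSumTest(c(1, 2), c(3, 4))
  expect_equal(r@statistic, 0)               # U for group 1
  expect_equal(r@p, 2 / 6)

  expect_equal(rankSumTest(c(5, 6, 7), c(5, 6, 7))@p, 1)
  expect_equal(rankSumTest(rep(3, 4), rep(3, 5))@p, 1)  # everything tied

  # label swap leaves the two-sided p unchanged
  set.seed(31)
  x1 <- rnorm(12); x2 <- rnorm(15, 0.8)
  expect_equal(rankSumTest(x1, x2)@p, rankSumTest(x2, x1)@p)

  # exact enumeration vs normal approximation at combined n = 10, no ties
  for (i in 1:10) {
    a <- sample(100, 5); b <- sample(200, 5)
    while (anyDuplicated(c(a, b))) b <- sample(200, 5)
    pex <- rankSumTest(a, b)@p
    pap <- rankSumTest(a, b, exactMax = 0L)@p
    expect_lt(abs(pex - pap), 0.02 + 1e-12)
  }

  # large-sample branch matches wilcox.test's corrected normal approximation
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(30, 0.3)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    r <- rankSumTest(x, y)
    expect_equal(r@statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r@p, ref$p.value, tolerance = 1e-10)
  }
  # ... including with ties
  x <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 9, 10, 11)
  y <- c(2, 3, 3, 5, 6, 6, 7, 8, 8, 10, 12, 13)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(rankSumTest(x, y, exactMax = 0L)@p, ref$p.value,
               tolerance = 1e-10)
})

test_that("2x2 chi-square matches the expected-count formula, chisq.test,
           and its symmetries", {
  expect_equal(chiSquare2x2(matrix(c(10, 10, 10, 10), 2))@statistic, 0)
  expect_equal(chiSquare2x2(matrix(c(10, 10, 10, 10), 2))@p, 1)

  # brute-force sum((O - E)^2 / E) oracle on random tables
  set.seed(41)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chiSquare2x2(tab)@statistic, sum((tab - E)^2 / E),
                 tolerance = 1e-12)
    ref <- chisq.test(tab, correct = FALSE)
    expect_equal(chiSquare2x2(tab)@statistic, unname(ref$statistic),
                 tolerance = 1e-10)
    refY <- chisq.test(tab, correct = TRUE)
    expect_equal(chiSquare2x2(tab, correction = "yates")@statistic,
                 unname(refY$statistic), tolerance = 1e-10)
    expect_equal(chiSquare2x2(t(tab))@statistic, chiSquare2x2(tab)@statistic)
  }

  # the cohort's sex table: 24/6 males/females vs 22/8
  sex <- chiSquare2x2(matrix(c(24, 6, 22, 8), 2, byrow = TRUE))
  expect_equal(sex@statistic, 60 * (24 * 8 - 6 * 22)^2 / (30 * 30 * 46 * 14))
  expect_false(sex@significant)

  expect_error(chiSquare2x2(matrix(c(5, 7, 0, 0), 2, byrow = TRUE)),
               "degenerate table")
})

test_that("cohort comparison flags nothing when the groups are copies and
           honors the configured test choices", {
  base <- data.frame(metric1 = rnorm(30, 50, 5), metric2 = rexp(30))
  cohort <- rbind(cbind(group = "test", sex = rep(c("male", "female"), c(24, 6)), base),
                  cbind(group = "control", sex = rep(c("male", "female"), c(24, 6)), base))
  res <- compareCohort(cohort)
  expect_false(any(res$significant))
  expect_true(all(res$p[res$metric != "sex"] == 1))

  forcedT <- compareCohort(cohort, normality = "t")
  expect_true(all(grepl("t$", forcedT$method[forcedT$metric != "sex"])))
  forcedR <- compareCohort(cohort, normality = "ranksum")
  expect_true(all(grepl("rank-sum", forcedR$method[forcedR$metric != "sex"])))

  # the exponential metric fails the default normality gate
  set.seed(61)
  c2 <- data.frame(group = rep(c("test", "control"), each = 30),
                   skewed = rexp(60), normalish = rnorm(60))
  r2 <- compareCohort(c2)
  expect_match(r2$method[r2$metric == "skewed"], "rank-sum")
  expect_match(r2$method[r2$metric == "normalish"], "t$")

  expect_warning(compareCohort(c2, metrics = c("skewed", "absent")),
                 "not found")
  expect_error(compareCohort(data.frame(group = "only", x = 1)),
               "exactly two groups")
})

test_that("bonferroni correction rescales p-values and flags", {
  set.seed(71)
  c3 <- data.frame(group = rep(c("test", "control"), each = 20),
                   a = rnorm(40), b = rnorm(40), c = rnorm(40))
  plain <- compareCohort(c3)
  bonf <- compareCohort(c3, correction = "bonferroni")
  expect_equal(bonf$p, pmin(1, plain$p * nrow(plain)))
})
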