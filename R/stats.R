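#' Group summary for a summary-level t-test
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Sample standard deviation (>= 0).
#' @return A list with class \code{"groupSummary"}.
#' @export
groupSummary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "groupSummary")
}

.comparisonResult <- function(metric, method, statistic, df, p, alpha) {
  p <- min(max(p, 0), 1)
  new("ComparisonResult", metric = metric, method = method,
      statistic = unname(statistic), df = unname(df), p = unname(p),
      alpha = alpha, significant = unname(p < alpha))
}

#' @rdname accessors
#' @param row.names,optional,... Passed on from the \code{as.data.frame}
#'   generic; unused.
#' @export
as.data.frame.ComparisonResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(metric = x@metric, method = x@method, statistic = x@statistic,
             df = x@df, p = x@p, significant = x@significant)
}

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("%s: %s = %.4g%s, p = %.4g (%s at alpha = %g)\n",
              if (is.na(object@metric)) "comparison" else object@metric,
              object@method, object@statistic,
              if (is.na(object@df)) "" else sprintf(" (df = %.4g)", object@df),
              object@p,
              if (object@significant) "significant" else "not significant",
              object@alpha))
})

#' Two-sample t-test from group summaries
#'
#' Computes the independent-sample t-test directly from (n, mean, sd) per
#' group, as needed when only a published summary table is available.
#' The pooled variant uses
#' \eqn{t = (m_1 - m_2) / \sqrt{s_p^2 (1/n_1 + 1/n_2)}} with the pooled
#' variance \eqn{s_p^2} and \eqn{df = n_1 + n_2 - 2}; the Welch variant
#' uses per-group variances with Satterthwaite degrees of freedom. P-values
#' are two-sided.
#'
#' @param g1,g2 [groupSummary()] objects (or lists with \code{n, mean, sd}).
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @param alpha Significance level.
#' @param metric Optional label carried into the result.
#' @return A [ComparisonResult-class].
#' @examples
#' tTestFromSummaries(groupSummary(30, 45.54, 10.15),
#'                    groupSummary(30, 47.69, 11.12))
#' @export
tTestFromSummaries <- function(g1, g2, variant = c("pooled", "welch"),
                               alpha = 0.05, metric = NA_character_) {
  variant <- match.arg(variant)
  n1 <- g1$n; n2 <- g2$n
  v1 <- g1$sd^2; v2 <- g2$sd^2
  if (g1$sd == 0 && g2$sd == 0) {
    if (g1$mean == g2$mean)
      return(.comparisonResult(metric, paste(variant, "t"), 0,
                               n1 + n2 - 2, 1, alpha))
    stop("degenerate variance: both SDs are zero with unequal means")
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (g1$mean - g2$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  .comparisonResult(metric, paste(variant, "t"), t, df, p, alpha)
}

#' Two-sample t-test from raw data
#'
#' Computes the per-group summaries and delegates to
#' [tTestFromSummaries()], with which it agrees exactly by construction.
#'
#' @param x1,x2 Numeric vectors, each of length >= 2.
#' @inheritParams tTestFromSummaries
#' @return A [ComparisonResult-class].
#' @export
tTestFromRaw <- function(x1, x2, variant = c("pooled", "welch"),
                         alpha = 0.05, metric = NA_character_) {
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  tTestFromSummaries(groupSummary(length(x1), mean(x1), stats::sd(x1)),
                     groupSummary(length(x2), mean(x2), stats::sd(x2)),
                     variant = variant, alpha = alpha, metric = metric)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test on the Mann-Whitney U statistic. For a combined
#' sample size of at most \code{exactMax} the null distribution of U is
#' enumerated exactly over all group assignments of the observed pooled
#' values (ties included); otherwise the normal approximation with the
#' tie-corrected variance and a continuity correction is used, which stays
#' within 0.02 of the exact enumeration already at a combined n of 10.
#'
#' @param x1,x2 Numeric vectors, each nonempty.
#' @param alpha Significance level.
#' @param exactMax Combined-size cutoff for exact enumeration (default 10).
#' @param metric Optional label.
#' @return A [ComparisonResult-class]; \code{statistic} is U for group 1.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))  # most extreme ranking of n = 2 + 2
#' @export
rankSumTest <- function(x1, x2, alpha = 0.05, exactMax = 10L,
                        metric = NA_character_) {
  stopifnot(length(x1) >= 1, length(x2) >= 1)
  n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
  pooled <- c(x1, x2)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (length(unique(pooled)) == 1L)
    return(.comparisonResult(metric, "Wilcoxon rank-sum", U, NA_real_, 1,
                             alpha))
  if (N <= exactMax) {
    dev <- abs(U - mu)
    idx <- utils::combn(N, n1)
    us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= dev - 1e-9)
    method <- "Wilcoxon rank-sum (exact)"
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)   # continuity correction
    p <- 2 * stats::pnorm(-z)
    method <- "Wilcoxon rank-sum (normal approx)"
  }
  .comparisonResult(metric, method, U, NA_real_, p, alpha)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square
#' \eqn{\chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with 1 degree of
#' freedom; the Yates variant subtracts the continuity correction
#' \eqn{N/2} from \eqn{|ad - bc|} (floored at zero).
#'
#' @param counts 2x2 matrix of non-negative integer counts (groups x
#'   categories), or \code{c(a, b, c, d)} row-wise.
#' @param correction \code{"none"} (default) or \code{"yates"}.
#' @param alpha Significance level.
#' @param metric Optional label.
#' @return A [ComparisonResult-class].
#' @examples
#' chiSquare2x2(matrix(c(24, 22, 6, 8), 2))  # male/female by group
#' @export
chiSquare2x2 <- function(counts, correction = c("none", "yates"),
                         alpha = 0.05, metric = NA_character_) {
  correction <- match.arg(correction)
  if (is.null(dim(counts))) counts <- matrix(counts, 2, 2, byrow = TRUE)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0),
            all(counts == round(counts)))
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  N <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate table: zero margin")
  dev <- abs(a * d - b * c)
  if (correction == "yates") dev <- max(0, dev - N / 2)
  stat <- N * dev^2 / prod(margins)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  .comparisonResult(metric,
                    paste0("chi-square",
                           if (correction == "yates") " (Yates)" else ""),
                    stat, 1, p, alpha)
}

#' Compare the two groups of a cohort
#'
#' Applies the study's comparison machinery to every metric of a cohort
#' table: for each continuous metric a two-sample t-test, switching to the
#' rank-sum test when a Shapiro-Wilk normality check fails in either group
#' (at \code{normalityAlpha}); for sex, the chi-square test on the 2x2
#' male/female by group table. Optionally applies a Bonferroni correction
#' (none by default).
#'
#' @param cohort Data frame from [generateCohort()] (or the same layout:
#'   a \code{group} column with two levels, optional \code{sex}, numeric
#'   metric columns).
#' @param alpha Significance level (default 0.05).
#' @param variant t-test variant, \code{"pooled"} or \code{"welch"}.
#' @param normality \code{"shapiro"} (gate on Shapiro-Wilk), \code{"t"}
#'   (always t-test) or \code{"ranksum"} (always rank-sum).
#' @param normalityAlpha Level of the normality gate.
#' @param correction \code{"none"} or \code{"bonferroni"}.
#' @param metrics Metric columns to compare; default all numeric columns.
#' @return A data.frame with one row per metric: \code{metric, method,
#'   statistic, df, p, significant}.
#' @examples
#' compareCohort(generateCohort(cohortSpec(seed = 3)))
#' @export
compareCohort <- function(cohort, alpha = 0.05,
                          variant = c("pooled", "welch"),
                          normality = c("shapiro", "t", "ranksum"),
                          normalityAlpha = 0.05,
                          correction = c("none", "bonferroni"),
                          metrics = NULL) {
  variant <- match.arg(variant)
  normality <- match.arg(normality)
  correction <- match.arg(correction)
  grp <- unique(cohort$group)
  if (length(grp) != 2L) stop("cohort must contain exactly two groups")
  if (is.null(metrics))
    metrics <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  res <- list()
  for (m in metrics) {
    if (!m %in% names(cohort)) {
      warning("metric not found, skipped: ", m)
      next
    }
    x1 <- cohort[[m]][cohort$group == grp[1]]
    x2 <- cohort[[m]][cohort$group == grp[2]]
    useT <- switch(normality,
      t = TRUE, ranksum = FALSE,
      shapiro = stats::shapiro.test(x1)$p.value >= normalityAlpha &&
                stats::shapiro.test(x2)$p.value >= normalityAlpha)
    res[[m]] <- if (useT)
      tTestFromRaw(x1, x2, variant = variant, alpha = alpha, metric = m)
    else rankSumTest(x1, x2, alpha = alpha, metric = m)
  }
  if ("sex" %in% names(cohort)) {
    tab <- table(factor(cohort$group, levels = grp),
                 factor(cohort$sex, levels = c("male", "female")))
    res[["sex"]] <- chiSquare2x2(unclass(tab), alpha = alpha, metric = "sex")
  }
  out <- do.call(rbind, lapply(res, as.data.frame))
  rownames(out) <- NULL
  if (correction == "bonferroni") {
    out$p <- pmin(1, out$p * nrow(out))
    out$significant <- out$p < alpha
  }
  out
}
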