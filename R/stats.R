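#' Mann-Whitney rank test
#'
#' Two-sample rank test on the well-level micronucleus frequencies (or fold
#' changes). The U statistic is formed from midrank sums. With small
#' combined samples (`n1 + n2 <= 16`) and no ties, the p-value is exact by
#' full enumeration of all `choose(n1 + n2, n1)` rank assignments — the
#' replicate counts this assay produces are tiny, so exactness matters
#' there; otherwise the normal approximation with tie-corrected variance and
#' a 0.5 continuity correction is used. The two-sided p-value is
#' `min(1, 2 x one-sided)`. No multiple-testing correction is applied: each
#' comparison is judged against a fixed alpha, a documented limitation when
#' screening many genes.
#'
#' @param x,y Numeric samples (both non-empty). `x` is the group whose large
#'   values drive `alternative = "greater"`.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return An object of class `mn_test`; see [tidy.mn_test()].
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(c(x, y))) stop("samples must not contain missing values", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && n <= 16L) {
    # exact null distribution by full enumeration of rank assignments
    sets <- utils::combn(n, n1)
    u_null <- colSums(matrix(seq_len(n)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(u_null <= u)
    p_ge <- mean(u_null >= u)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le
    )
    method <- "MW-exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    z_of <- function(shift) (u - mu + shift) / sigma
    p <- switch(alternative,
      # continuity correction: 0.5 toward the mean
      greater = stats::pnorm(z_of(-0.5), lower.tail = FALSE),
      less = stats::pnorm(z_of(0.5)),
      two.sided = {
        z <- (abs(u - mu) - 0.5) / sigma
        min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
      }
    )
    method <- "MW-normal"
  }
  mn_test(statistic = u, p_value = p, method = method, n1 = n1, n2 = n2,
          alternative = alternative)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the cumulative size distributions of micronuclei between two
#' conditions: `D` is the supremum distance between the two empirical CDFs,
#' with the p-value from the asymptotic Kolmogorov distribution at the
#' effective sample size `n1 n2 / (n1 + n2)` (via [stats::ks.test()]; with
#' tied sizes the asymptotic p is approximate, as usual).
#'
#' @param sizes_a,sizes_b Numeric samples, e.g. micronuclear areas (um^2).
#' @param alternative As in [stats::ks.test()]; default two-sided.
#' @return An object of class `mn_test`.
#' @export
ks_two_sample <- function(sizes_a, sizes_b, alternative = "two.sided") {
  if (!length(sizes_a) || !length(sizes_b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::ks.test(sizes_a, sizes_b, alternative = alternative, exact = FALSE)
  )
  mn_test(statistic = unname(res$statistic), p_value = res$p.value,
          method = "KS", n1 = length(sizes_a), n2 = length(sizes_b),
          alternative = alternative)
}

mn_test <- function(statistic, p_value, method, n1, n2, alternative) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n1 = n1, n2 = n2, alternative = alternative),
    class = "mn_test"
  )
}

#' @export
print.mn_test <- function(x, ...) {
  cat(sprintf("%s test (n1 = %d, n2 = %d, %s): statistic = %g, p = %.4g\n",
              x$method, x$n1, x$n2, x$alternative, x$statistic, x$p_value))
  invisible(x)
}

#' Tidy a two-sample test result
#'
#' @param x An `mn_test`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p_value`, `method`, `n1`, `n2`,
#'   `alternative`.
#' @export
#' @importFrom generics tidy
#' @method tidy mn_test
tidy.mn_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n1 = x$n1, n2 = x$n2,
                 alternative = x$alternative)
}

#' @rdname tidy.mn_test
#' @export
#' @importFrom generics glance
#' @method glance mn_test
glance.mn_test <- function(x, ...) tidy(x)

#' Rank tests of every silenced condition against the siControl
#'
#' Convenience wrapper producing the per-condition comparison table the
#' silencing analysis reports: one Mann-Whitney test of each non-control
#' condition's fold changes against the siControl's.
#'
#' @param fc An [fold_change()] result.
#' @param alternative Passed to [mann_whitney()].
#' @return Tibble: `comparison`, `group1`, `group2`, `n1`, `n2`, `method`,
#'   `statistic`, `p_value`.
#' @export
silencing_tests <- function(fc, alternative = "two.sided") {
  stopifnot(inherits(fc, "mn_fold_change"))
  ctrl_cond <- unique(fc$condition[fc$role == "siControl"])
  ctrl <- fc$fold_change[fc$role == "siControl"]
  others <- unique(fc$condition[fc$role != "siControl"])
  purrr::map_dfr(others, function(cond) {
    grp <- fc$fold_change[fc$condition == cond]
    tt <- tidy(mann_whitney(grp, ctrl, alternative = alternative))
    tibble::tibble(
      comparison = paste(cond, "vs", ctrl_cond),
      group1 = cond, group2 = ctrl_cond,
      n1 = tt$n1, n2 = tt$n2, method = tt$method,
      statistic = tt$statistic, p_value = tt$p_value
    )
  })
}
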