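# Shared result container -----------------------------------------------------

new_test_result <- function(statistic, p_value, method, n1, n2 = NA_integer_,
                            extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  out <- c(list(statistic = unname(statistic),
                p_value = min(1, unname(p_value)),
                method = method,
                n1 = as.integer(n1),
                n2 = as.integer(n2)),
           extra)
  class(out) <- "ctc_test"
  out
}

#' @export
print.ctc_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.6g, p = %.4g (n1 = %d%s)\n",
              x$method, x$statistic, x$p_value, x$n1,
              if (is.na(x$n2)) "" else sprintf(", n2 = %d", x$n2)))
  invisible(x)
}

# Mann-Whitney ----------------------------------------------------------------

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Two-sample rank test used throughout the marker-dynamics analyses. For small
#' tie-free samples (`n1 + n2 <= exact_limit`) the p-value comes from the exact
#' null distribution of U; otherwise a normal approximation with tie and
#' continuity corrections is used. The reported statistic is U for `x`,
#' i.e. the number of (x, y) pairs with x > y (+ 1/2 per tied pair).
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param exact_limit Largest `n1 + n2` for which the exact tie-free branch is
#'   used (default 16).
#' @return A `ctc_test` list: `statistic` (U), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact_limit = 16L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))

  if (!ties && n1 + n2 <= exact_limit) {
    # exact null distribution of U; symmetric about n1*n2/2, so the two-sided
    # p equals twice the smaller tail (capped at 1)
    p <- switch(alternative,
      two.sided = min(1, 2 * stats::pwilcox(min(U, n1 * n2 - U), n1, n2)),
      less      = stats::pwilcox(U, n1, n2),
      greater   = stats::pwilcox(n1 * n2 - U, n1, n2))
    return(new_test_result(U, p, "exact", n1, n2))
  }

  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {                       # all values identical
    return(new_test_result(U, 1, "normal_approx", n1, n2))
  }
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
    two.sided = (U - mu - sign(U - mu) * 0.5) / sigma,
    greater   = (U - mu - 0.5) / sigma,
    less      = (U - mu + 0.5) / sigma)
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pnorm(-abs(z))),
    greater   = stats::pnorm(z, lower.tail = FALSE),
    less      = stats::pnorm(z))
  new_test_result(U, p, "normal_approx", n1, n2)
}

# Chi-squared -----------------------------------------------------------------

#' Chi-squared goodness-of-fit test
#'
#' Pearson statistic of observed counts against expected proportions,
#' with `k - 1` degrees of freedom.
#'
#' @param observed Non-negative integer vector of counts.
#' @param expected_proportions Probability vector of the same length summing
#'   to 1; all entries must be strictly positive.
#' @return A `ctc_test` list with `statistic`, `p_value`, `df`.
#' @export
chi_squared_gof <- function(observed, expected_proportions) {
  observed <- as.numeric(observed)
  p <- as.numeric(expected_proportions)
  if (length(observed) != length(p))
    stop("observed and expected_proportions must have equal length", call. = FALSE)
  if (any(observed < 0) || sum(observed) <= 0)
    stop("observed counts must be non-negative with a positive total", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("expected proportions must sum to 1", call. = FALSE)
  expected <- sum(observed) * p
  if (any(expected <= 0)) stop("zero expected cell", call. = FALSE)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  new_test_result(stat, stats::pchisq(stat, df, lower.tail = FALSE),
                  "chi_squared_gof", sum(observed), extra = list(df = df))
}

#' Chi-squared test of independence
#'
#' Pearson statistic on an r x c contingency table, expected cells from the
#' margin products, df = (r-1)(c-1). Used for cluster-composition association.
#'
#' @param table Non-negative integer matrix with all row and column totals > 0.
#' @return A `ctc_test` list with `statistic`, `p_value`, `df`, `expected`.
#' @export
chi_squared_independence <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate margins: every row and column total must be > 0", call. = FALSE)
  expected <- outer(rs, cs) / n
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  new_test_result(stat, stats::pchisq(stat, df, lower.tail = FALSE),
                  "chi_squared_independence", n,
                  extra = list(df = df, expected = expected))
}

# Spearman --------------------------------------------------------------------

# exact null distribution of rho for tie-free samples of size n, cached;
# enumerates all n! permutations once per n (n <= 9 kept cheap)
.spearman_cache <- new.env(parent = emptyenv())

spearman_exact_rhos <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  perms <- function(k) {
    if (k == 1L) return(matrix(1L, 1, 1))
    sub <- perms(k - 1L)
    m <- nrow(sub)
    out <- matrix(0L, k * m, k)
    for (i in seq_len(k)) {
      rows <- ((i - 1L) * m + 1L):(i * m)
      out[rows, 1L] <- i
      rest <- seq_len(k)[-i]
      out[rows, -1L] <- matrix(rest[sub], m)
    }
    out
  }
  P <- perms(as.integer(n))
  S <- rowSums((P - matrix(seq_len(n), nrow(P), n, byrow = TRUE))^2)
  rhos <- 1 - 6 * S / (n * (n^2 - 1))
  .spearman_cache[[key]] <- rhos
  rhos
}

#' Spearman rank correlation
#'
#' Correlation of midranks with a two-sided p-value. Tie-free samples of
#' length `n <= exact_limit` use the exact permutation null distribution of
#' rho; larger or tied samples use the t approximation with `n - 2` degrees
#' of freedom.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, neither constant.
#' @param exact_limit Largest tie-free `n` handled exactly (default 9).
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_corr <- function(x, y, exact_limit = 9L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rho undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rx, ry)
  ties <- any(duplicated(x)) || any(duplicated(y))
  if (!ties && n <= exact_limit) {
    rhos <- spearman_exact_rhos(n)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(list(rho = rho, p_value = p, n = n, method = "exact"))
  }
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tval), n - 2))
  }
  list(rho = rho, p_value = p, n = n, method = "t_approx")
}

# Multiplicity ----------------------------------------------------------------

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per p-value; `m` defaults to the number of tests supplied
#' but may be larger when additional untested hypotheses count toward the
#' family.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size, at least `length(p)`.
#' @return Adjusted p-values, order-preserving.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p)) stop("m must be >= length(p)", call. = FALSE)
  pmin(1, p * m)
}

# Robust summaries ------------------------------------------------------------

#' Robust location/scale summaries across measurement units
#'
#' Control-well QC summary: per-unit medians, the grand median of the pooled
#' values, the median absolute deviation (MAD) of the pooled values and the
#' MAD of the per-unit medians (MADM). The scale constant defaults to 1
#' (descriptive use); 1.4826 gives normal-consistent scale.
#'
#' @param groups Named list mapping unit id to a non-empty numeric vector.
#' @param scale_constant Multiplier applied to both MAD statistics.
#' @return List of class `ctc_robust_summary`: `medians` (named), `grand_median`,
#'   `mad`, `madm`, `scale_constant`.
#' @export
robust_summaries <- function(groups, scale_constant = 1.0) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("groups must be a non-empty list", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("every unit must be non-empty", call. = FALSE)
  meds <- vapply(groups, stats::median, numeric(1))
  pooled <- unlist(groups, use.names = FALSE)
  grand <- stats::median(pooled)
  out <- list(
    medians = meds,
    grand_median = grand,
    mad = scale_constant * stats::median(abs(pooled - grand)),
    madm = scale_constant * stats::median(abs(meds - stats::median(meds))),
    scale_constant = scale_constant)
  class(out) <- "ctc_robust_summary"
  out
}
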