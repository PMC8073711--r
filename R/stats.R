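#' Statistical results container
#'
#' Lightweight holder for a test outcome: the statistic, a p-value in
#' \[0, 1\], the sample/block sizes involved and a method label.
#'
#' @param statistic numeric test statistic (or coefficient).
#' @param p_value p-value; must lie in \[0, 1\] (may be `NA`).
#' @param method label describing the procedure.
#' @param ... additional named fields (`n`, `df`, `k`, ...).
#' @return object of class `stat_result`.
#' @export
stat_result <- function(statistic, p_value, method, ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(c(list(statistic = as.numeric(statistic),
                   p_value = as.numeric(p_value), method = method),
              list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result>", x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value), "\n")
  invisible(x)
}

check_rater_table <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("rater table has missing cells")
  if (ncol(m) < 2L) stop("need at least 2 raters (columns)")
  if (nrow(m) < 3L) stop("need at least 3 subjects (rows)")
  m
}

#' Two-way intraclass correlation coefficient
#'
#' Single-measurement ICC from the two-way ANOVA mean squares of a
#' subjects x raters table. `ICC2_1` (default) is the two-way random-effects,
#' absolute-agreement form
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`;
#' `ICC3_1` is the two-way mixed, consistency form
#' `(MSR - MSE) / (MSR + (k-1) MSE)`. The reported p-value is from the
#' F-test `MSR / MSE` of the subject effect.
#'
#' @param table numeric matrix, subjects in rows, raters in columns
#'   (>= 3 subjects, >= 2 raters, no missing cells).
#' @param form `"ICC2_1"` or `"ICC3_1"`.
#' @return a [stat_result()] with fields `n` (subjects), `k` (raters),
#'   `msr`, `msc`, `mse`.
#' @export
icc_two_way <- function(table, form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  m <- check_rater_table(table)
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst < 1e-24)
    stop("zero total variance: ICC undefined")
  icc <- switch(form,
    ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3_1 = (msr - mse) / (msr + (k - 1) * mse))
  f <- msr / mse
  p <- if (mse > 0)
    stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE) else 0
  stat_result(icc, p, paste0("ICC(", sub("ICC(\\d)_(\\d)", "\\1,\\2", form),
                             ") two-way ANOVA"),
              n = n, k = k, msr = msr, msc = msc, mse = mse, f = f)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard algorithm with the argument checks used
#' throughout this package (3 <= n <= 5000, non-constant sample).
#'
#' @param sample numeric vector.
#' @return a [stat_result()] with the W statistic.
#' @export
shapiro_wilk <- function(sample) {
  x <- as.numeric(sample)
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000; got n = ", length(x))
  if (diff(range(x)) == 0) stop("constant sample: normality test undefined")
  sw <- stats::shapiro.test(x)
  stat_result(unname(sw$statistic), sw$p.value, "Shapiro-Wilk",
              n = length(x))
}

midranks_by_row <- function(m) {
  t(apply(m, 1L, rank))
}

#' Friedman rank test for blocked repeated measures
#'
#' Rank-based test that `k` related treatments (columns) have the same
#' location across `n` blocks (rows). Values are mid-ranked within each
#' block; the tie-corrected statistic
#' `chi^2 = 12 * sum_j (R_j - n(k+1)/2)^2 / (n k (k+1) - T / (k - 1))`,
#' with `T = sum (t^3 - t)` over tie groups, is referred to a
#' chi-square(k - 1) distribution. Blocks in which every treatment is tied
#' contribute nothing; if all blocks are fully tied the statistic is 0 and
#' p = 1 by convention.
#'
#' With `p_method = "exact"` the p-value is instead computed by exhaustive
#' enumeration of all `k!^n` within-block permutations of the observed
#' values (feasible only for small tables): the proportion of arrangements
#' whose statistic is at least the observed one.
#'
#' @param matrix numeric blocks x treatments matrix (>= 2 blocks,
#'   >= 2 treatments).
#' @param p_method `"chisq"` (default) for the chi-square(k - 1) reference,
#'   `"exact"` for the permutation null (requires `k!^n <= 2e5`).
#' @return a [stat_result()] with fields `df`, `n` (blocks), `k`, and
#'   `rank_sums`.
#' @export
friedman <- function(matrix, p_method = c("chisq", "exact")) {
  p_method <- match.arg(p_method)
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values not supported")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 blocks and >= 2 treatments")
  r <- midranks_by_row(m)
  Rj <- colSums(r)
  ties <- sum(apply(m, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  if (denom <= 0) {
    chi2 <- 0
    p <- 1
  } else {
    chi2 <- 12 * sum((Rj - n * (k + 1) / 2)^2) / denom
    p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  }
  if (p_method == "exact") {
    if (factorial(k)^n > 2e5)
      stop("exact permutation null infeasible: k!^n = ", factorial(k)^n)
    stat_fun <- function(rk) {
      Rj2 <- colSums(rk)
      if (denom <= 0) 0 else
        12 * sum((Rj2 - n * (k + 1) / 2)^2) / denom
    }
    perms <- all_permutations(k)
    combos <- rep(list(seq_len(nrow(perms))), n)
    grid <- as.matrix(expand.grid(combos))
    stats_all <- apply(grid, 1L, function(sel) {
      rk <- r[cbind(rep(seq_len(n), each = k),
                    as.vector(t(perms[sel, , drop = FALSE])))]
      stat_fun(matrix(rk, n, k, byrow = TRUE))
    })
    p <- mean(stats_all >= chi2 - 1e-12)
  }
  stat_result(chi2, p, paste0("Friedman rank test (", p_method, ")"),
              df = k - 1, n = n, k = k, rank_sums = Rj)
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

#' Scheffe-type post-hoc comparisons after a Friedman test
#'
#' All pairwise comparisons of treatment rank sums with a Scheffe-style
#' criterion: for treatments i, j the statistic
#' `(R_i - R_j)^2 / (n k (k + 1) / 6)` is referred to a chi-square(k - 1)
#' distribution, so any pair can be tested while the familywise level is
#' controlled in the Scheffe sense.
#'
#' @param matrix numeric blocks x treatments matrix.
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame with one row per pair: `treatment_i`, `treatment_j`,
#'   `rank_sum_i`, `rank_sum_j`, `statistic`, `p_value`, `significant`.
#' @export
scheffe_posthoc <- function(matrix, alpha = 0.05) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 blocks and >= 2 treatments")
  r <- midranks_by_row(m)
  Rj <- colSums(r)
  labs <- colnames(m)
  if (is.null(labs)) labs <- paste0("T", seq_len(k))
  denom <- n * k * (k + 1) / 6
  pairs <- utils::combn(k, 2L)
  out <- data.frame(
    treatment_i = labs[pairs[1L, ]],
    treatment_j = labs[pairs[2L, ]],
    rank_sum_i = Rj[pairs[1L, ]],
    rank_sum_j = Rj[pairs[2L, ]],
    stringsAsFactors = FALSE
  )
  out$statistic <- (out$rank_sum_i - out$rank_sum_j)^2 / denom
  out$p_value <- stats::pchisq(out$statistic, df = k - 1, lower.tail = FALSE)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `post - pre` are computed, zero differences dropped, and the
#' absolute differences mid-ranked; the statistic V is the sum of ranks of
#' the positive differences. The null distribution is exact for n <= 25
#' without ties in the absolute differences, and a normal approximation with
#' continuity and tie correction otherwise.
#'
#' @param pre_values,post_values paired numeric vectors, equal length >= 5.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (direction of `post - pre`).
#' @return a [stat_result()] with fields `n` (nonzero pairs) and `exact`.
#' @export
wilcoxon_signed_rank <- function(pre_values, post_values,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(pre_values)
  y <- as.numeric(post_values)
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 5L) stop("need at least 5 pairs")
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: no information for the test")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  exact <- n <= 25L
  if (exact) {
    # exact sign-flip null of V by convolution over the (mid-)ranks; doubled
    # ranks are integers even with ties, so the distribution is a vector over
    # 0 .. sum(2 * rank) and matches psignrank in the tie-free case
    r2 <- as.integer(round(2 * rk))
    dp <- numeric(sum(r2) + 1L)
    dp[1L] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), dp[seq_len(length(dp) - r)])
      dp <- (dp + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    p_ge <- sum(dp[(v2 + 1L):length(dp)])
    p_le <- sum(dp[seq_len(v2 + 1L)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z_num <- V - mu
    cc <- switch(alternative, two.sided = sign(z_num) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z_num - cc) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = min(1, 2 * stats::pnorm(abs(z),
                                                   lower.tail = FALSE)))
  }
  stat_result(V, p, paste0("Wilcoxon signed-rank (",
                           if (exact) "exact" else "normal approximation",
                           ", ", alternative, ")"),
              n = n, exact = exact)
}

#' Pearson product-moment correlation with t-test
#'
#' `r` from the covariance formula and a two-sided p-value from the
#' transform `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x_values,y_values numeric vectors of equal length >= 3, neither
#'   constant.
#' @return a [stat_result()] where `statistic` is r, with fields `n`, `df`,
#'   `t`.
#' @export
pearson_r <- function(x_values, y_values) {
  x <- as.numeric(x_values)
  y <- as.numeric(y_values)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- min(1, max(-1, r))
  if (abs(r) == 1) {
    t <- Inf * sign(r)
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  stat_result(r, p, "Pearson correlation", n = n, df = n - 2, t = t)
}
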