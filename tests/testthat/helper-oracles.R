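# independent oracles, deliberately written along different routes than the
# package implementations they check

# ICC oracle: mean squares via stats::aov + Shrout-Fleiss formulas
icc_oracle <- function(m, form = "ICC2_1") {
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][
    , "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  if (form == "ICC2_1")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else (msr - mse) / (msr + (k - 1) * mse)
}

# Friedman statistic from the rank-sum formula, coded independently
friedman_stat_oracle <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  ties <- sum(unlist(apply(m, 1, function(row) {
    tt <- table(row); tt^3 - tt
  })))
  den <- n * k * (k + 1) - ties / (k - 1)
  if (den <= 0) 0 else 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / den
}

# exact Friedman permutation p by explicit recursion over blocks
friedman_exact_oracle <- function(m) {
  k <- ncol(m)
  perms <- radius3d:::all_permutations(k)
  obs <- friedman_stat_oracle(m)
  rows <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  count <- 0L
  total <- 0L
  rec <- function(i, acc) {
    if (i > length(rows)) {
      stat <- friedman_stat_oracle(do.call(rbind, acc))
      count <<- count + (stat >= obs - 1e-12)
      total <<- total + 1L
      return(invisible())
    }
    for (j in seq_len(nrow(perms)))
      rec(i + 1L, c(acc, list(rows[[i]][perms[j, ]])))
  }
  rec(1L, list())
  count / total
}

# brute-force sign-flip oracle for the signed-rank null
wilcoxon_exact_oracle <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% rk)
  p_ge <- mean(v_all >= v_obs - 1e-12)
  p_le <- mean(v_all <= v_obs + 1e-12)
  switch(alternative, greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
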