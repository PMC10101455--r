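# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation they check.

# Naive triple-loop threshold segmentation: voxels of `search` with
# intensity strictly above mu + k * sigma.
naive_segment <- function(data, search, mu, sigma, k) {
  d <- dim(data)
  out <- array(FALSE, dim = d)
  thr <- mu + k * sigma
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (kk in seq_len(d[3]))
    if (search[i, j, kk] && data[i, j, kk] > thr) out[i, j, kk] <- TRUE
  out
}

# Mann-Whitney AUC by exhaustive pair counting (ties count 1/2).
# `pos_low`: positives are expected to have LOW scores.
pairwise_auc <- function(scores, pos, pos_low = TRUE) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) {
    if (pos_low) tot <- tot + (a < b) + 0.5 * (a == b)
    else tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# Welch statistic/df written out directly from the defining formulas.
welch_formulas <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Least squares by explicit normal equations; partial F for the last
# column block (the group dummy).
normal_equations_group_F <- function(y, covariate_matrix, group01) {
  X1 <- cbind(1, covariate_matrix)
  X2 <- cbind(X1, group01)
  bhat1 <- solve(t(X1) %*% X1, t(X1) %*% y)
  bhat2 <- solve(t(X2) %*% X2, t(X2) %*% y)
  rss1 <- sum((y - X1 %*% bhat1)^2)
  rss2 <- sum((y - X2 %*% bhat2)^2)
  df2 <- length(y) - ncol(X2)
  F <- (rss1 - rss2) / (rss2 / df2)
  list(F = F, df = c(1, df2), p = pf(F, 1, df2, lower.tail = FALSE))
}

# Hand-built reference statistics (for tests that control mu/sigma exactly).
ref_stats_of <- function(mu, sigma, n = 100) {
  structure(list(mu_ref = mu, sigma_ref = sigma, n_ref = n),
            class = "reference_stats")
}

# Tiny helper: grid-on-affine image with given data.
toy_image <- function(data, vdims = c(1, 1, 1)) {
  voxel_image(data, affine_scaling(vdims, dim(data)))
}
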