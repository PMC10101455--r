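#' Shapiro-Wilk normality check
#'
#' Thin wrapper over the stock Shapiro-Wilk routine, with an explicit
#' degenerate-sample error so constant volumes fail loudly.
#'
#' @param values numeric sample, n >= 3
#' @return list with `W` and `p_value`
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("Shapiro-Wilk needs at least 3 observations")
  if (stats::sd(values) == 0)
    stop("degenerate sample: W is undefined for constant data")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

new_group_comparison <- function(statistic, df, p, means, ses, test_name,
                                 extra = list()) {
  structure(c(list(statistic = unname(statistic), df = unname(df),
                   p_value = unname(p), group_means = means,
                   group_ses = ses, test_name = test_name), extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test_name,
              x$statistic, paste(signif(x$df, 5), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Two-tailed unequal-variance t-test comparing group means, from raw
#' samples (`welch_t`, delegating to the stock routine) or from printed
#' summary statistics (`welch_t_from_summary`):
#' t = (m_a - m_b) / sqrt(se_a^2 + se_b^2), with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param sample_a,sample_b numeric vectors, n >= 2 each
#' @return a `group_comparison` (statistic t, fractional df, two-tailed p)
#' @export
welch_t <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]; sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("need at least 2 observations per group")
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  new_group_comparison(tt$statistic, tt$parameter, tt$p.value,
                       means = c(a = mean(sample_a), b = mean(sample_b)),
                       ses = c(a = stats::sd(sample_a) / sqrt(length(sample_a)),
                               b = stats::sd(sample_b) / sqrt(length(sample_b))),
                       test_name = "Welch t")
}

#' @rdname welch_t
#' @param mean_a,se_a,n_a,mean_b,se_b,n_b group summary statistics
#'   (mean, standard error of the mean, group size)
#' @export
welch_t_from_summary <- function(mean_a, se_a, n_a, mean_b, se_b, n_b) {
  stopifnot(se_a > 0, se_b > 0, n_a >= 2, n_b >= 2)
  v <- se_a^2 + se_b^2
  t <- (mean_a - mean_b) / sqrt(v)
  df <- v^2 / (se_a^4 / (n_a - 1) + se_b^4 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t), df)
  new_group_comparison(t, df, p,
                       means = c(a = mean_a, b = mean_b),
                       ses = c(a = se_a, b = se_b),
                       test_name = "Welch t (from summaries)")
}

#' ANCOVA group effect on a volume outcome
#'
#' Least-squares linear model `outcome ~ group + covariates`; the group
#' effect is the partial F on (1, n - p - 1) df from comparing the model
#' with and without the group term. Covariate p-values are reported
#' alongside (the adjusted analysis also asks whether e.g. age carries
#' signal). With an empty covariate set this is one-way ANOVA, so F equals
#' the square of the pooled-variance t.
#'
#' @param records data.frame with a 2-level `group` column, the outcome
#'   column, and any covariate columns
#' @param outcome outcome column name (e.g. "snc_volume")
#' @param covariates character vector of numeric covariate column names
#'   (e.g. c("age", "education")); may be empty
#' @return a `group_comparison` (statistic F, df = c(1, resid df)), with
#'   `covariate_p` attached
#' @export
ancova_group_effect <- function(records, outcome,
                                covariates = c("age", "education")) {
  stopifnot(outcome %in% names(records), all(covariates %in% names(records)),
            "group" %in% names(records))
  dat <- records[, c(outcome, "group", covariates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$group <- factor(dat$group)
  if (nlevels(dat$group) != 2) stop("group must have exactly two levels")
  constant <- vapply(covariates, function(cv) stats::sd(dat[[cv]]) == 0,
                     logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  p <- length(covariates) + 1
  if (nrow(dat) < p + 2) stop("too few subjects for the design")
  rhs <- paste(c(covariates, "group"), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(outcome, "~", rhs)), data = dat)
  if (full$rank < p + 1)
    stop("rank-deficient design: aliased predictors")
  reduced <- stats::lm(
    stats::as.formula(paste(outcome, "~",
                            if (length(covariates)) paste(covariates, collapse = " + ")
                            else "1")), data = dat)
  av <- stats::anova(reduced, full)
  Fstat <- av$F[2]; pval <- av$`Pr(>F)`[2]; df2 <- av$Res.Df[2]
  coefs <- summary(full)$coefficients
  cov_p <- if (length(covariates))
    stats::setNames(coefs[covariates, 4], covariates) else numeric(0)
  means <- tapply(dat[[outcome]], dat$group, mean)
  ses <- tapply(dat[[outcome]], dat$group,
                function(v) stats::sd(v) / sqrt(length(v)))
  new_group_comparison(Fstat, c(1, df2), pval, means, ses,
                       test_name = paste0("ANCOVA (",
                                          paste(covariates, collapse = ", "),
                                          ")"),
                       extra = list(covariate_p = cov_p))
}

#' Age-adjusted (partial) Pearson correlation
#'
#' Pearson correlation between the residuals of x and y after least-squares
#' regression on the covariate; p-value from t = r sqrt((n-3)/(1-r^2)) on
#' n - 3 df.
#'
#' @param x,y numeric vectors
#' @param covariate numeric covariate (age, by default, in the cohort
#'   analyses)
#' @return list with `r`, `p_value`, `n`, `covariates`
#' @export
partial_correlation <- function(x, y, covariate) {
  keep <- stats::complete.cases(x, y, covariate)
  x <- x[keep]; y <- y[keep]; covariate <- covariate[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  rx <- stats::resid(stats::lm(x ~ covariate))
  ry <- stats::resid(stats::lm(y ~ covariate))
  if (stats::sd(rx) < 1e-12 * max(1, stats::sd(x)) ||
      stats::sd(ry) < 1e-12 * max(1, stats::sd(y)))
    stop("degenerate: zero residual variance after covariate adjustment")
  r <- stats::cor(rx, ry)
  tval <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), n - 3)
  list(r = r, p_value = p, n = n, covariates = "covariate")
}

#' Empirical ROC curve and AUC for a diagnostic marker
#'
#' Builds the empirical ROC over all score thresholds and integrates it by
#' the trapezoid rule (equal to the Mann-Whitney concordance probability
#' with ties counted 1/2). Volumes shrink with disease, so by default the
#' score is negated internally (`higher_is_positive = FALSE`) and the
#' orientation is recorded in the result. The AUC standard error uses the
#' Hanley-McNeil formula by default (DeLong available); the 95% CI is
#' AUC +/- 1.96 SE truncated to \[0, 1\], and p tests AUC = 0.5.
#'
#' @param scores numeric marker values
#' @param labels group labels
#' @param positive_label label of the diseased class
#' @param higher_is_positive if FALSE (default), low scores indicate the
#'   positive class and the score sign is flipped internally
#' @param se_method "hanley" (default) or "delong"
#' @return object of class `roc_result`: `auc`, `se`, `ci95`, `p_value`,
#'   `curve` (data.frame FPR/TPR), `n_positive`, `n_negative`, orientation
#'   and SE method used
#' @export
roc_auc <- function(scores, labels, positive_label = "pd",
                    higher_is_positive = FALSE,
                    se_method = c("hanley", "delong")) {
  se_method <- match.arg(se_method)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- labels == positive_label
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  s <- if (higher_is_positive) scores else -scores

  # empirical curve over unique thresholds, ties grouped
  ord <- order(s, decreasing = TRUE)
  ss <- s[ord]; pp <- pos[ord]
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(pp); fp <- cumsum(!pp)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n1); fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  if (se_method == "hanley") {
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  } else {
    # DeLong: variance from placement values
    v10 <- vapply(s[pos], function(si)
      mean((si > s[!pos]) + 0.5 * (si == s[!pos])), numeric(1))
    v01 <- vapply(s[!pos], function(sj)
      mean((s[pos] > sj) + 0.5 * (s[pos] == sj)), numeric(1))
    se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  }
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else NA_real_
  structure(list(auc = auc, se = se, ci95 = ci, p_value = p,
                 curve = data.frame(fpr = fpr, tpr = tpr),
                 n_positive = n1, n_negative = n0,
                 higher_is_positive = higher_is_positive,
                 se_method = se_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f, p = %.3g; %s)\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$p_value, x$se_method))
  invisible(x)
}

#' Combine two volumetric markers into one diagnostic score
#'
#' Fits a binary logistic model `group ~ marker1 + marker2` by maximum
#' likelihood and uses the fitted disease probability as the combined
#' score, whose ROC/AUC is returned. Under perfect separation (the MLE
#' diverges) a warning is issued and a lightly ridge-penalized fit
#' (lambda = 1e-4 on standardized predictors) is used instead.
#'
#' @param records data.frame with `group` plus the marker columns
#' @param markers character vector of two marker column names
#' @param positive_label diseased class label
#' @param se_method passed to [roc_auc()]
#' @return list: `scores` (fitted probabilities), `coefficients`, `roc`
#'   (`roc_result` on the combined score), `method`
#' @export
combine_markers <- function(records, markers = c("snc_volume", "lc_volume"),
                            positive_label = "pd",
                            se_method = c("hanley", "delong")) {
  se_method <- match.arg(se_method)
  stopifnot(all(markers %in% names(records)))
  dat <- records[, c("group", markers)]
  if (anyNA(dat)) stop("both markers must be present for all subjects")
  y <- as.integer(dat$group == positive_label)
  X <- as.matrix(dat[, markers])
  fit <- withCallingHandlers(
    stats::glm(y ~ X, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  separated <- any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8)
  if (separated || !fit$converged) {
    warning("perfect separation: falling back to a ridge-penalized logistic fit")
    co <- ridge_logistic(X, y, lambda = 1e-4)
    eta <- co$intercept + X %*% co$beta
    scores <- as.vector(1 / (1 + exp(-eta)))
    coefs <- c(intercept = co$intercept, stats::setNames(co$beta, markers))
    method <- "logistic (ridge fallback)"
  } else {
    scores <- unname(fit$fitted.values)
    coefs <- stats::setNames(stats::coef(fit), c("intercept", markers))
    method <- "logistic MLE"
  }
  roc <- roc_auc(scores, dat$group, positive_label,
                 higher_is_positive = TRUE, se_method = se_method)
  list(scores = scores, coefficients = coefs, roc = roc, method = method)
}

# Newton/IRLS ridge-penalized logistic regression on standardized
# predictors (intercept unpenalized). Small, deterministic fallback used
# only under perfect separation.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 200, tol = 1e-10) {
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, mu), 2, sdv, "/"))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  b <- rep(0, ncol(Z))
  for (it in seq_len(maxit)) {
    eta <- as.vector(Z %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    g <- crossprod(Z, y - p) - pen %*% b
    H <- crossprod(Z * W, Z) + pen
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  beta <- b[-1] / sdv
  list(intercept = b[1] - sum(beta * mu), beta = beta)
}
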