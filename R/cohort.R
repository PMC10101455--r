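#' Cohort specification for a synthetic case-control study
#'
#' Group sizes and per-group distributions of true SNc/LC volumes and age.
#' Defaults reproduce the validation cohort this pipeline is calibrated
#' against: 33 controls vs 39 Parkinson's disease (PD) patients, SNc group
#' means 429/329 mm^3 and LC means 8.0/5.2 mm^3 (control/PD), with
#' per-subject SDs recovered from the printed standard errors as SE*sqrt(n)
#' (SNc 114.9/106.2, LC 3.45/3.75 mm^3).
#'
#' @param n_control,n_pd group sizes
#' @param snc_mean_control,snc_mean_pd,snc_sd_control,snc_sd_pd SNc true
#'   volume distribution per group, mm^3
#' @param lc_mean_control,lc_mean_pd,lc_sd_control,lc_sd_pd LC analogue
#' @param age_control,age_pd length-2 (mean, sd) in years
#' @param seed RNG seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_control = 33L, n_pd = 39L,
                        snc_mean_control = 429, snc_sd_control = 20 * sqrt(33),
                        snc_mean_pd = 329, snc_sd_pd = 17 * sqrt(39),
                        lc_mean_control = 8.0, lc_sd_control = 0.6 * sqrt(33),
                        lc_mean_pd = 5.2, lc_sd_pd = 0.6 * sqrt(39),
                        age_control = c(63.5, 1.6 * sqrt(33)),
                        age_pd = c(63.8, 1.6 * sqrt(39)),
                        seed = 1L) {
  spec <- list(n_control = as.integer(n_control), n_pd = as.integer(n_pd),
               snc_mean_control = snc_mean_control, snc_sd_control = snc_sd_control,
               snc_mean_pd = snc_mean_pd, snc_sd_pd = snc_sd_pd,
               lc_mean_control = lc_mean_control, lc_sd_control = lc_sd_control,
               lc_mean_pd = lc_mean_pd, lc_sd_pd = lc_sd_pd,
               age_control = age_control, age_pd = age_pd,
               seed = as.integer(seed))
  stopifnot(spec$n_control >= 0, spec$n_pd >= 0,
            spec$snc_sd_control >= 0, spec$snc_sd_pd >= 0,
            spec$lc_sd_control >= 0, spec$lc_sd_pd >= 0)
  class(spec) <- "cohort_spec"
  spec
}

# Normal draw with a positive floor at 5% of the group mean: the PD LC mean
# sits ~1.4 SD above zero, so naive normal sampling can go nonphysical.
draw_volumes <- function(n, mean, sd) {
  pmax(stats::rnorm(n, mean, sd), 0.05 * mean)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject true volumes from group-specific truncated normal
#' distributions plus demographics/clinical scores, and (optionally) a full
#' phantom image series per subject. Demographic and clinical score
#' distributions follow the validation-cohort summary table (age ~63.5 y in
#' both groups, education ~17 y, UPDRS-III 1.8 vs 18.9, MoCA ~28, NMSQ 3.2
#' vs 6.6, RBD-SQ 2.7 vs 3.7; disease duration and levodopa-equivalent dose
#' for PD only).
#'
#' @param cspec a [cohort_spec()]
#' @param pspec a [phantom_spec()] used as the template when imaging
#'   subjects (per-subject true volumes and seeds override it)
#' @param images if TRUE, also generate the measurement series + ground
#'   truth per subject (slow; use for small cohorts)
#' @return list with `table` (one row per subject: subject_id, group, age,
#'   sex, education, disease_duration, updrs3, ledd, moca, nmsq, rbdsq,
#'   snc_volume_true, lc_volume_true, seed) and `subjects` (list of
#'   [generate_subject()] outputs, or NULL)
#' @export
generate_cohort <- function(cspec, pspec = phantom_spec(), images = FALSE) {
  set.seed(cspec$seed)
  n <- cspec$n_control + cspec$n_pd
  if (n == 0L)
    return(list(table = empty_cohort_table(), subjects = NULL))
  group <- rep(c("control", "pd"), c(cspec$n_control, cspec$n_pd))
  is_pd <- group == "pd"

  snc <- numeric(n); lc <- numeric(n); age <- numeric(n)
  snc[!is_pd] <- draw_volumes(sum(!is_pd), cspec$snc_mean_control, cspec$snc_sd_control)
  snc[is_pd] <- draw_volumes(sum(is_pd), cspec$snc_mean_pd, cspec$snc_sd_pd)
  lc[!is_pd] <- draw_volumes(sum(!is_pd), cspec$lc_mean_control, cspec$lc_sd_control)
  lc[is_pd] <- draw_volumes(sum(is_pd), cspec$lc_mean_pd, cspec$lc_sd_pd)
  age[!is_pd] <- stats::rnorm(sum(!is_pd), cspec$age_control[1], cspec$age_control[2])
  age[is_pd] <- stats::rnorm(sum(is_pd), cspec$age_pd[1], cspec$age_pd[2])

  pos <- function(x, lo = 0) pmax(x, lo)
  sex <- ifelse(stats::runif(n) < ifelse(is_pd, 22 / 39, 11 / 33), "M", "F")
  education <- round(pos(stats::rnorm(n, ifelse(is_pd, 17.0, 16.7),
                                      ifelse(is_pd, 3.7, 2.3)), 8))
  updrs3 <- round(pos(stats::rnorm(n, ifelse(is_pd, 18.9, 1.8),
                                   ifelse(is_pd, 6.9, 1.9))))
  moca <- round(pmin(30, pos(stats::rnorm(n, ifelse(is_pd, 27.8, 28.0),
                                          ifelse(is_pd, 1.9, 1.7)), 20)))
  nmsq <- round(pos(stats::rnorm(n, ifelse(is_pd, 6.6, 3.2),
                                 ifelse(is_pd, 4.4, 2.9))))
  rbdsq <- round(pos(stats::rnorm(n, ifelse(is_pd, 3.7, 2.7),
                                  ifelse(is_pd, 2.5, 2.3))))
  duration <- ifelse(is_pd, round(pos(stats::rnorm(n, 3.5, 3.7), 0.2), 1), NA)
  ledd <- ifelse(is_pd, round(pos(stats::rnorm(n, 623.3, 442), 0)), NA)

  subject_seed <- (cspec$seed %% 1000000L) * 1000L + seq_len(n)
  tab <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group, age = round(age, 1), sex = sex, education = education,
    disease_duration = duration, updrs3 = updrs3, ledd = ledd,
    moca = moca, nmsq = nmsq, rbdsq = rbdsq,
    snc_volume_true = round(snc, 2), lc_volume_true = round(lc, 2),
    seed = subject_seed, stringsAsFactors = FALSE)

  subjects <- NULL
  if (images) {
    subjects <- lapply(seq_len(n), function(i) {
      sp <- pspec
      sp$snc_volume_true <- snc[i]
      sp$lc_volume_true <- lc[i]
      sp$seed <- subject_seed[i]
      generate_subject(sp)
    })
    names(subjects) <- tab$subject_id
  }
  list(table = tab, subjects = subjects)
}

empty_cohort_table <- function() {
  data.frame(subject_id = character(), group = character(), age = numeric(),
             sex = character(), education = numeric(),
             disease_duration = numeric(), updrs3 = numeric(),
             ledd = numeric(), moca = numeric(), nmsq = numeric(),
             rbdsq = numeric(), snc_volume_true = numeric(),
             lc_volume_true = numeric(), seed = integer(),
             stringsAsFactors = FALSE)
}
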