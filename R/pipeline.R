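#' Pipeline configuration
#'
#' One nested list drives simulation, segmentation and statistics. All
#' defaults are explicit here and echoed into the run manifest, so no
#' silent default exists anywhere downstream. Threshold multipliers default
#' to k = 2.8 (SNc) and 3.9 (LC); the atlas cut to 5%; alpha to 0.05.
#'
#' @param output_dir run directory; created on demand
#' @param seed integer seed for the whole run
#' @param cohort named list of [cohort_spec()] overrides
#' @param phantom named list of [phantom_spec()] overrides
#' @param images simulate full image series per subject (set FALSE for
#'   volumes-only statistical simulations)
#' @param moco apply motion correction before averaging
#' @param write_masks write segmentation masks next to the volumes CSV
#' @param params segmentation parameters: `k_snc`, `k_lc`,
#'   `atlas_threshold`, `dilation_iterations`
#' @param stats statistics options: `covariates`, `alpha`, `roc_se_method`,
#'   `positive_label`
#' @return config list (class `pipeline_config`)
#' @export
pipeline_config <- function(output_dir = tempfile("nmrun"), seed = 1L,
                            cohort = list(), phantom = list(),
                            images = TRUE, moco = TRUE, write_masks = FALSE,
                            params = list(), stats = list()) {
  p <- utils::modifyList(list(k_snc = 2.8, k_lc = 3.9, atlas_threshold = 0.05,
                              dilation_iterations = 2L), params)
  s <- utils::modifyList(list(covariates = c("age", "education"),
                              alpha = 0.05, roc_se_method = "hanley",
                              positive_label = "pd"), stats)
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              cohort = cohort, phantom = phantom, images = images,
              moco = moco, write_masks = write_masks, params = p, stats = s)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$params$k_snc > 0, cfg$params$k_lc > 0,
            cfg$params$atlas_threshold > 0, cfg$params$atlas_threshold < 1,
            cfg$stats$alpha > 0, cfg$stats$alpha < 1,
            cfg$stats$roc_se_method %in% c("hanley", "delong"))
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()] fields
#' @return validated config list
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage_manifest <- function(cfg, stage, files, t0) {
  files <- files[file.exists(files)]
  man <- list(stage = stage,
              version = as.character(utils::packageVersion("nmvolumetry")),
              seed = cfg$seed,
              config = unclass(cfg),
              checksums = as.list(tools::md5sum(files)),
              elapsed_sec = round(as.numeric(Sys.time()) - t0, 2))
  path <- file.path(cfg$output_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Simulate a phantom cohort to disk
#'
#' Writes the subject table as CSV and, when `images` is enabled, one
#' directory per subject holding the 4D measurement series, ground-truth
#' masks, the phantom's standard-space atlases, and the (identity)
#' standard-to-native transform chain as JSON.
#'
#' @param cfg a [pipeline_config()]
#' @return the subject table, invisibly
#' @export
run_simulate <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  cspec <- do.call(cohort_spec, utils::modifyList(list(seed = cfg$seed),
                                                  cfg$cohort))
  pspec <- do.call(phantom_spec, utils::modifyList(list(seed = cfg$seed),
                                                   cfg$phantom))
  res <- generate_cohort(cspec, pspec, images = cfg$images)
  csv <- file.path(cfg$output_dir, "subjects.csv")
  utils::write.csv(res$table, csv, row.names = FALSE)
  written <- csv
  if (cfg$images && length(res$subjects)) {
    for (id in names(res$subjects)) {
      sub <- res$subjects[[id]]
      d <- file.path(cfg$output_dir, id)
      dir.create(d, showWarnings = FALSE)
      write_series(sub$measurements, file.path(d, "measurements.nii.gz"))
      gt <- sub$ground_truth
      write_image(gt$snc_mask, file.path(d, "gt_snc_mask.nii.gz"))
      write_image(gt$lc_mask, file.path(d, "gt_lc_mask.nii.gz"))
      write_image(gt$ref_mask, file.path(d, "ref_mask.nii.gz"))
      write_image(gt$snc_atlas, file.path(d, "snc_atlas.nii.gz"))
      write_image(gt$lc_atlas, file.path(d, "lc_atlas.nii.gz"))
      write_transform(transform_chain(list(rigid_transform()),
                                      c("standard", "native")),
                      file.path(d, "chain.json"))
      for (t in seq_along(gt$true_transforms))
        write_transform(gt$true_transforms[[t]],
                        file.path(d, sprintf("true_transform_%02d.json", t)))
      written <- c(written, list.files(d, full.names = TRUE))
    }
  }
  stage_manifest(cfg, "simulate", written, t0)
  invisible(res$table)
}

segment_one_subject <- function(dir, cfg) {
  measurements <- read_series(file.path(dir, "measurements.nii.gz"))
  mc <- motion_correct_and_average(measurements, moco = cfg$moco)
  avg <- mc$average
  chain <- read_transform(file.path(dir, "chain.json"))
  ref_mask <- map_roi_to_native(read_image(file.path(dir, "ref_mask.nii.gz"),
                                           as = "mask"), chain, avg)
  snc_atlas <- map_roi_to_native(read_image(file.path(dir, "snc_atlas.nii.gz"),
                                            as = "atlas"), chain, avg)
  lc_atlas <- map_roi_to_native(read_image(file.path(dir, "lc_atlas.nii.gz"),
                                           as = "atlas"), chain, avg)
  seg <- segment_subject(
    avg, snc_atlas, lc_atlas, ref_mask,
    params_snc = segmentation_params(cfg$params$k_snc,
                                     cfg$params$atlas_threshold,
                                     cfg$params$dilation_iterations),
    params_lc = segmentation_params(cfg$params$k_lc,
                                    cfg$params$atlas_threshold,
                                    cfg$params$dilation_iterations))
  if (cfg$write_masks) {
    write_image(seg$snc$mask, file.path(dir, "seg_snc_mask.nii.gz"))
    write_image(seg$lc$mask, file.path(dir, "seg_lc_mask.nii.gz"))
  }
  seg
}

#' Segment every subject of a simulated (or prepared) cohort
#'
#' Per subject: motion correction and averaging, single-step ROI mapping,
#' reference statistics and threshold segmentation of SNc and LC. Subjects
#' that fail are logged and skipped; their count is attached to the result.
#'
#' @param cfg a [pipeline_config()] whose `output_dir` holds a simulated
#'   cohort
#' @return long-format data.frame (one row per subject x structure) with
#'   voxel counts, volumes, reference statistics and threshold metadata;
#'   also written to `volumes.csv`
#' @export
run_segment <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  tab <- utils::read.csv(file.path(cfg$output_dir, "subjects.csv"),
                         stringsAsFactors = FALSE)
  dirs <- file.path(cfg$output_dir, tab$subject_id)
  dirs <- dirs[dir.exists(dirs)]
  if (length(dirs) == 0) stop("no subject image directories found under ",
                              cfg$output_dir)
  rows <- list(); failed <- character(0)
  for (d in dirs) {
    id <- basename(d)
    seg <- tryCatch(segment_one_subject(d, cfg), error = function(e) {
      message("subject ", id, " failed: ", conditionMessage(e)); NULL
    })
    if (is.null(seg)) { failed <- c(failed, id); next }
    for (st in c("snc", "lc")) {
      r <- seg[[st]]
      rows[[paste(id, st)]] <- data.frame(
        subject_id = id, structure = st, voxel_count = r$voxel_count,
        volume_mm3 = r$volume, mu_ref = r$ref_stats$mu_ref,
        sigma_ref = r$ref_stats$sigma_ref,
        threshold_value = r$threshold_value, k = r$params$k,
        dilation_iterations = r$params$dilation_iterations,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("all subjects failed segmentation")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  csv <- file.path(cfg$output_dir, "volumes.csv")
  utils::write.csv(out, csv, row.names = FALSE)
  attr(out, "failed_subjects") <- failed
  stage_manifest(cfg, "segment", csv, t0)
  out
}

#' Cohort statistics report
#'
#' Merges measured volumes with the subject table and runs the cohort
#' analyses: Shapiro-Wilk normality per group, Welch t-tests and ANCOVA per
#' structure, age-adjusted correlations of volumes with clinical scores in
#' the PD group, single-marker ROC/AUC and the combined two-marker ROC.
#' Written as JSON and Markdown under the run directory.
#'
#' @param cfg a [pipeline_config()]
#' @param volumes optional volumes data.frame (else read from
#'   `volumes.csv`); pass the subject table's true volumes via
#'   `use_true_volumes` to analyze a volumes-only simulation
#' @param use_true_volumes analyze `*_volume_true` columns of the subject
#'   table instead of measured volumes
#' @return report list, invisibly (also on disk as `stats_report.json`/`.md`)
#' @export
run_stats <- function(cfg, volumes = NULL, use_true_volumes = FALSE) {
  t0 <- as.numeric(Sys.time())
  tab <- utils::read.csv(file.path(cfg$output_dir, "subjects.csv"),
                         stringsAsFactors = FALSE)
  if (use_true_volumes) {
    merged <- tab
    merged$snc_volume <- tab$snc_volume_true
    merged$lc_volume <- tab$lc_volume_true
  } else {
    if (is.null(volumes))
      volumes <- utils::read.csv(file.path(cfg$output_dir, "volumes.csv"),
                                 stringsAsFactors = FALSE)
    wide <- stats::reshape(
      volumes[, c("subject_id", "structure", "volume_mm3")],
      idvar = "subject_id", timevar = "structure", direction = "wide")
    names(wide) <- sub("^volume_mm3\\.", "", names(wide))
    names(wide)[names(wide) == "snc"] <- "snc_volume"
    names(wide)[names(wide) == "lc"] <- "lc_volume"
    merged <- merge(tab, wide, by = "subject_id")
  }
  report <- cohort_statistics(merged, cfg$stats)
  jsonlite::write_json(report, file.path(cfg$output_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(render_report_md(report),
             file.path(cfg$output_dir, "stats_report.md"))
  stage_manifest(cfg, "stats",
                 file.path(cfg$output_dir,
                           c("stats_report.json", "stats_report.md")), t0)
  invisible(report)
}

#' Cohort statistics on a merged subject table
#'
#' The computational core behind [run_stats()]: takes a data.frame with
#' `group`, `age`, clinical scores and `snc_volume`/`lc_volume` columns and
#' returns the full analysis as a nested list.
#'
#' @param merged merged subject data.frame
#' @param opts statistics options (see [pipeline_config()])
#' @return nested report list
#' @export
cohort_statistics <- function(merged,
                              opts = list(covariates = c("age", "education"),
                                          alpha = 0.05,
                                          roc_se_method = "hanley",
                                          positive_label = "pd")) {
  pos <- opts$positive_label
  n_pd <- sum(merged$group == pos)
  n_ctrl <- sum(merged$group != pos)
  report <- list(n_control = n_ctrl, n_pd = n_pd,
                 alpha = opts$alpha, tests_performed = character(0))
  log_test <- function(name)
    report$tests_performed <<- c(report$tests_performed, name)

  if (n_pd == 0 || n_ctrl == 0) {
    report$notice <- "group comparisons skipped: only one group present"
    return(report)
  }
  for (st in c("snc_volume", "lc_volume")) {
    v_ctrl <- merged[[st]][merged$group != pos]
    v_pd <- merged[[st]][merged$group == pos]
    blk <- list()
    blk$normality <- lapply(list(control = v_ctrl, pd = v_pd), function(v) {
      if (length(v) >= 3 && stats::sd(v) > 0) shapiro_wilk(v)
      else list(W = NA, p_value = NA)
    })
    log_test(paste("shapiro", st))
    blk$welch <- tryCatch(unclass(welch_t(v_ctrl, v_pd)),
                          error = function(e) list(error = conditionMessage(e)))
    log_test(paste("welch", st))
    covs <- intersect(opts$covariates, names(merged))
    blk$ancova <- tryCatch(
      unclass(ancova_group_effect(merged, st, covs)),
      error = function(e) list(error = conditionMessage(e)))
    log_test(paste("ancova", st))
    roc <- roc_auc(merged[[st]], merged$group, pos,
                   se_method = opts$roc_se_method)
    blk$roc <- unclass(roc)[c("auc", "se", "ci95", "p_value",
                              "n_positive", "n_negative", "se_method")]
    log_test(paste("roc", st))
    report[[st]] <- blk
  }

  pd <- merged[merged$group == pos, , drop = FALSE]
  cors <- list()
  for (pair in list(c("snc_volume", "updrs3"), c("snc_volume", "moca"),
                    c("snc_volume", "disease_duration"),
                    c("snc_volume", "lc_volume"),
                    c("lc_volume", "updrs3"), c("lc_volume", "moca"))) {
    if (!all(pair %in% names(pd))) next
    nm <- paste(pair, collapse = "_vs_")
    cors[[nm]] <- tryCatch(
      partial_correlation(pd[[pair[1]]], pd[[pair[2]]], pd$age),
      error = function(e) list(error = conditionMessage(e)))
    log_test(paste("partial_cor", nm))
  }
  report$correlations_pd <- cors

  comb <- tryCatch(combine_markers(merged, c("snc_volume", "lc_volume"),
                                   pos, se_method = opts$roc_se_method),
                   error = function(e) NULL)
  if (!is.null(comb)) {
    report$combined <- list(
      coefficients = as.list(comb$coefficients), method = comb$method,
      roc = unclass(comb$roc)[c("auc", "se", "ci95", "p_value", "se_method")])
    log_test("roc combined")
  }
  report
}

render_report_md <- function(report) {
  fmt <- function(x, d = 3) ifelse(is.numeric(x), signif(x, d), x)
  lines <- c("# Cohort statistics report", "",
             sprintf("Groups: %d control, %d PD (alpha = %g)",
                     report$n_control, report$n_pd, report$alpha), "")
  if (!is.null(report$notice)) return(c(lines, report$notice))
  for (st in c("snc_volume", "lc_volume")) {
    b <- report[[st]]
    lines <- c(lines, paste0("## ", toupper(sub("_volume", "", st)), " volume"), "")
    if (is.null(b$welch$error))
      lines <- c(lines, sprintf(
        "- Welch t = %.3f (df %.1f), p = %.4g; means %s vs %s mm^3",
        b$welch$statistic, b$welch$df, b$welch$p_value,
        fmt(b$welch$group_means[1]), fmt(b$welch$group_means[2])))
    if (is.null(b$ancova$error))
      lines <- c(lines, sprintf("- ANCOVA group F = %.3f (df %g, %g), p = %.4g",
                                b$ancova$statistic, b$ancova$df[1],
                                b$ancova$df[2], b$ancova$p_value))
    lines <- c(lines, sprintf("- AUC = %.3f (SE %.3f, CI %.3f-%.3f)",
                              b$roc$auc, b$roc$se, b$roc$ci95[1],
                              b$roc$ci95[2]), "")
  }
  if (!is.null(report$combined))
    lines <- c(lines, sprintf(
      "Combined SNc+LC marker (%s): AUC = %.3f (SE %.3f)",
      report$combined$method, report$combined$roc$auc, report$combined$roc$se))
  lines
}

#' Run the full pipeline: simulate, segment, stats
#' @param cfg a [pipeline_config()]
#' @return the statistics report, invisibly
#' @export
run_all <- function(cfg) {
  run_simulate(cfg)
  if (cfg$images) {
    run_segment(cfg)
    run_stats(cfg)
  } else {
    run_stats(cfg, use_true_volumes = TRUE)
  }
}
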