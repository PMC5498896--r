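# End-to-end pipeline: simulate -> melt-call -> sex-call -> trisomy-call ->
# evaluate, with all intermediate tables written out and a JSON summary.

#' Run the full simulated-cohort pipeline
#'
#' Simulates a cohort under `config`, calls the melt plate, classifies sex by
#' the GSD index and by the amelogenin rules, calls trisomies from the Ct
#' panel, and evaluates every caller against the simulated truth. When
#' `out_dir` is given, writes the intermediate CSV/TSV tables, a JSON summary
#' of the diagnostic statistics, and a run log recording the seed and a
#' configuration hash; partial outputs are preserved if a stage fails.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param seed Optional seed overriding the config's cohort seed.
#' @param melt_curves Simulate and call actual melt traces (slower) rather
#'   than using the detection table directly.
#' @return An object of class `pgt_pipeline`: list with `truth`, `detections`,
#'   `gsd`, `amel`, `trisomy`, `evaluation`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL, melt_curves = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed %||% config$cohort$seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(x, name, schema) {
    if (!is.null(out_dir)) write_pgt_table(x, file.path(out_dir, name), schema)
  }

  sim <- simulate_cohort(config, seed = seed, melt_curves = melt_curves)
  emit(sim$truth, "truth.csv", "truth")
  emit(sim$peaks, "peaks.tsv", "peaks")
  emit(sim$ct, "ct.csv", "ct")

  if (melt_curves) {
    emit(sim$melt, "melt.csv", "melt")
    det <- melt_call(sim$melt, tm = config$melt$tm, tol = config$cutoffs$tm_tol)
  } else {
    # detection table stands in for the melt plate read-out
    det <- data.frame(embryo_id = sim$detections$embryo_id,
                      gene = sim$detections$locus,
                      detected = sim$detections$detected,
                      tm_observed = NA_real_, stringsAsFactors = FALSE)
    gap <- det[det$gene == "GAPDH", c("embryo_id", "detected")]
    det$qc_pass <- gap$detected[match(det$embryo_id, gap$embryo_id)]
    det <- det[det$gene %in% c("GAPDH", "SRY", "DYS14"), , drop = FALSE]
  }
  emit(det, "detections.csv", "detections")

  fit <- fit_category_logistic(gsd_counts(det, sim$truth))
  gsd <- gsd_classify(det, mode = config$gsd_mode, fit = fit)
  amel <- amel_classify(
    amel_peakset(sim$peaks, size_x = config$amel$size_x,
                 size_y = config$amel$size_y,
                 size_tol = config$cutoffs$size_tol,
                 noise_floor = config$amel$noise_floor),
    cutoff_height = config$cutoffs$amel_height,
    cutoff_ratio = config$cutoffs$amel_ratio
  )
  trisomy <- call_trisomy(sim$ct, cutoffs = config$cutoffs)

  evaluation <- evaluate_calls(sim$truth, gsd = gsd, amel = amel,
                               trisomy = trisomy,
                               detections = sim$detections)

  if (!is.null(out_dir)) {
    utils::write.csv(gsd, file.path(out_dir, "gsd_calls.csv"), row.names = FALSE)
    utils::write.csv(amel, file.path(out_dir, "amel_calls.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(trisomy),
                     file.path(out_dir, "trisomy_calls.csv"), row.names = FALSE)
    jsonlite::write_json(summary_list(evaluation),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_tmp <- tempfile(fileext = ".yaml")
    write_config(config, cfg_tmp)
    log_lines <- c(
      sprintf("pgtqpcr %s", as.character(utils::packageVersion("pgtqpcr"))),
      sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      sprintf("seed: %d", seed),
      sprintf("config_sha: %s", substr(paste(tools::md5sum(cfg_tmp)), 1, 12)),
      sprintf("R: %s", R.version.string)
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
    file.copy(cfg_tmp, file.path(out_dir, "config.yaml"), overwrite = TRUE)
  }

  structure(list(truth = sim$truth, detections = sim$detections, gsd = gsd,
                 amel = amel, trisomy = trisomy, fit = fit,
                 evaluation = evaluation, seed = seed),
            class = "pgt_pipeline")
}

# Category count table (one row per SRY/DYS14 detection pattern) from a
# detections table plus truth sex labels, for the logistic fit.
gsd_counts <- function(detections, truth) {
  ids <- unique(detections$embryo_id)
  pick <- function(g) {
    d <- detections[detections$gene == g, c("embryo_id", "detected")]
    d$detected[match(ids, d$embryo_id)]
  }
  sry <- pick("SRY"); dys <- pick("DYS14")
  qc <- if ("qc_pass" %in% names(detections)) {
    tapply(detections$qc_pass, detections$embryo_id, all)[ids]
  } else rep(TRUE, length(ids))
  male <- truth$sex[match(ids, truth$embryo_id)] == "male"
  keep <- qc & !is.na(sry) & !is.na(dys) & !is.na(male)
  agg <- stats::aggregate(cbind(male = male[keep], female = !male[keep]),
                          by = list(sry = sry[keep], dys14 = dys[keep]), FUN = sum)
  agg
}

#' Evaluate caller output against ground truth
#'
#' Builds the per-method diagnostic summaries: GSD index vs sex, the three
#' amelogenin rules vs sex, trisomy calls vs chromosome 18/21 copy number
#' (negatives pool euploid and other-trisomy embryos by default), AUCs of the
#' delta-Ct scores, and per-locus ADO/FA re-estimates when a detection table
#' with truth presence is available.
#'
#' @param truth A `karyotype_truth` data frame.
#' @param gsd Output of [gsd_classify()] (optional).
#' @param amel Output of [amel_classify()] (optional).
#' @param trisomy Output of [call_trisomy()] (optional).
#' @param detections Output of [simulate_locus_detections()] (optional).
#' @param pool_other_trisomy Pool the other trisomy with euploid embryos as
#'   negatives (the study's arithmetic implies pooling).
#' @return An object of class `pgt_evaluation` (named list of
#'   [diagnostic_summary()] objects and ADO/FA rate lists).
#' @export
evaluate_calls <- function(truth, gsd = NULL, amel = NULL, trisomy = NULL,
                           detections = NULL, pool_other_trisomy = TRUE) {
  out <- list()
  if (!is.null(gsd)) {
    sex <- truth$sex[match(gsd$embryo_id, truth$embryo_id)]
    out$gsd <- diagnostic_summary(sex, gsd$call, positive = "male")
  }
  if (!is.null(amel)) {
    sex <- truth$sex[match(amel$embryo_id, truth$embryo_id)]
    out$amel_presence <- diagnostic_summary(sex, amel$call_by_presence, "male")
    out$amel_height <- diagnostic_summary(sex, amel$call_by_height, "male",
                                          scores = amel$amely_height,
                                          direction = "high")
    out$amel_ratio <- diagnostic_summary(sex, amel$call_by_ratio, "male",
                                         scores = amel$ratio,
                                         direction = "low")
  }
  if (!is.null(trisomy)) {
    idx <- match(trisomy$embryo_id, truth$embryo_id)
    t21 <- ifelse(truth$chr21_copies[idx] >= 3, "positive", "negative")
    t18 <- ifelse(truth$chr18_copies[idx] >= 3, "positive", "negative")
    keep21 <- if (pool_other_trisomy) rep(TRUE, length(idx)) else
      !(truth$chr18_copies[idx] >= 3)
    keep18 <- if (pool_other_trisomy) rep(TRUE, length(idx)) else
      !(truth$chr21_copies[idx] >= 3)
    out$trisomy21 <- diagnostic_summary(t21[keep21], trisomy$call_t21[keep21],
                                        "positive",
                                        scores = trisomy$delta_ct_ttc3[keep21],
                                        direction = "low")
    out$trisomy18 <- diagnostic_summary(t18[keep18], trisomy$call_t18[keep18],
                                        "positive",
                                        scores = trisomy$delta_ct_rpl17[keep18],
                                        direction = "low")
  }
  if (!is.null(detections)) {
    for (l in intersect(unique(detections$locus), c("SRY", "DYS14", "AMELY"))) {
      out[[paste0("rates_", tolower(l))]] <-
        ado_fa_rates(detections, truth, locus = l)
    }
  }
  structure(out, class = "pgt_evaluation")
}

summary_list <- function(evaluation) {
  lapply(unclass(evaluation), function(e) {
    if (inherits(e, "diagnostic_summary")) {
      list(tp = e$confusion$tp, fp = e$confusion$fp, fn = e$confusion$fn,
           tn = e$confusion$tn, excluded = e$confusion$n_excluded,
           accuracy = e$accuracy, sensitivity = e$sensitivity,
           specificity = e$specificity, youden_j = e$youden_j,
           kappa = e$kappa, odds_ratio = e$odds_ratio[c("or", "lo", "hi", "p")],
           auc = if (!is.null(e$auc)) e$auc[c("auc", "lo", "hi", "p")])
    } else e
  })
}

#' @export
print.pgt_evaluation <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}

#' @export
print.pgt_pipeline <- function(x, ...) {
  cat(sprintf("PGT pipeline run (seed %d): %d embryos\n", x$seed, nrow(x$truth)))
  print(x$evaluation)
  invisible(x)
}
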