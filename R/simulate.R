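# Synthetic single-cell WGA cohort simulator: karyotypes, locus detections
# under ADO/FA, quantitative Ct panels, melting curves and electropherograms.

Y_LOCI <- c("SRY", "DYS14", "AMELY")

#' Simulate embryo karyotypes
#'
#' Draws a cohort of embryo ground-truth karyotypes: CGH sex label, Y copy
#' number (0 for females and for Y-loss males), trisomy status for
#' chromosomes 18 and 21, XX-male-type translocation flags, and sample-level
#' WGA failure. Sex, trisomy and failure events are drawn independently.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A data frame of class `karyotype_truth` with columns `embryo_id`,
#'   `sex`, `y_copies`, `x_copies`, `chr18_copies`, `chr21_copies`,
#'   `xx_male_translocation`, `wga_failure`.
#' @export
simulate_karyotypes <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_embryos
  with_seed(seed %||% config$seed, {
    male <- stats::runif(n) < config$p_male
    y_loss <- male & stats::runif(n) < config$p_y_loss_in_males
    y_frag <- !male & stats::runif(n) < config$p_y_fragment_in_females
    u <- stats::runif(n)
    chr18 <- ifelse(u < config$p_trisomy18, 3L, 2L)
    chr21 <- ifelse(u >= config$p_trisomy18 &
                      u < config$p_trisomy18 + config$p_trisomy21, 3L, 2L)
    fail <- stats::runif(n) < config$p_wga_failure
    out <- data.frame(
      embryo_id = sprintf("E%05d", seq_len(n)),
      sex = ifelse(male, "male", "female"),
      y_copies = ifelse(male & !y_loss, 1L, 0L),
      x_copies = ifelse(male, 1L, 2L),
      chr18_copies = chr18,
      chr21_copies = chr21,
      xx_male_translocation = y_frag,
      wga_failure = fail,
      stringsAsFactors = FALSE
    )
    class(out) <- c("karyotype_truth", "data.frame")
    out
  })
}

#' Y-material carrier status per locus
#'
#' A Y-linked locus is present when the embryo retains at least one Y copy or
#' carries translocated Y material; GAPDH is present in every sample.
#'
#' @param truth A `karyotype_truth` data frame.
#' @param locus Locus name.
#' @return Logical vector of presence per embryo.
#' @export
locus_present <- function(truth, locus) {
  if (locus == "GAPDH") return(rep(TRUE, nrow(truth)))
  if (!locus %in% Y_LOCI) stop(sprintf("unknown locus '%s'", locus), call. = FALSE)
  truth$y_copies >= 1L | truth$xx_male_translocation
}

#' Simulate per-locus detections under ADO/FA
#'
#' Applies the error model to the cohort's true locus presence: a present
#' locus is detected with probability 1 - ADO, an absent locus with
#' probability FA. The GAPDH control is detected with its own probability and
#' never in WGA-failed samples; no locus amplifies in a WGA-failed sample.
#'
#' @param truth A `karyotype_truth` data frame.
#' @param errors An [error_model()].
#' @param seed Optional integer seed.
#' @return A long data frame with columns `embryo_id`, `locus`, `present`,
#'   `detected`.
#' @export
simulate_locus_detections <- function(truth, errors = error_model(), seed = NULL) {
  stopifnot(inherits(errors, "error_model"))
  with_seed(seed, {
    loci <- c(names(errors$ado), "GAPDH")
    res <- lapply(loci, function(l) {
      pres <- locus_present(truth, l)
      p_det <- if (l == "GAPDH") {
        rep(errors$gapdh_detect, nrow(truth))
      } else {
        ifelse(pres, 1 - errors$ado[[l]], errors$fa[[l]])
      }
      det <- stats::runif(nrow(truth)) < p_det & !truth$wga_failure
      data.frame(embryo_id = truth$embryo_id, locus = l,
                 present = pres, detected = det, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}

#' Simulate a quantitative Ct panel
#'
#' Generates raw Ct values for the trisomy panel (target genes plus the HSDB
#' reference) at each standard-curve input mass. The reference gene anchors at
#' `ct_ref_base` plus a sample-level WGA offset shared by all genes of the
#' sample; target genes sit above the reference by the model's delta-Ct (see
#' [ct_model_params()]). Lower input mass raises Ct along the standard-curve
#' slope, with per-well technical noise on the non-anchor wells.
#'
#' @param truth A `karyotype_truth` data frame.
#' @param params A [ct_model_params()].
#' @param masses Input masses in ng; 15 ng must be included (the analysis
#'   anchor).
#' @param seed Optional integer seed.
#' @return A long data frame `embryo_id`, `gene`, `input_ng`, `ct`.
#' @export
simulate_ct_panel <- function(truth, params = ct_model_params(),
                              masses = c(3.75, 7.5, 15), seed = NULL) {
  stopifnot(inherits(params, "ct_model_params"))
  check_pos(masses, "masses")
  if (!any(abs(masses - 15) < 1e-9)) {
    stop("`masses` must include the 15 ng analysis anchor", call. = FALSE)
  }
  n <- nrow(truth)
  copies_of <- list(TTC3 = truth$chr21_copies, RPL17 = truth$chr18_copies)
  with_seed(seed, {
    b <- stats::rnorm(n, 0, params$sigma_sample)
    ct15 <- list(HSDB = params$ct_ref_base + b)
    for (g in names(params$mu)) {
      copies <- copies_of[[g]]
      if (is.null(copies)) {
        stop(sprintf("no chromosome mapping for target gene '%s'", g),
             call. = FALSE)
      }
      gamma <- stats::rnorm(n, params$gamma_mean[[g]], params$gamma_sd[[g]])
      dct <- params$mu[[g]] - gamma * log2(copies / 2) +
        stats::rnorm(n, 0, params$sigma_delta[[g]])
      ct15[[g]] <- ct15$HSDB + dct
    }
    rows <- lapply(names(ct15), function(g) {
      do.call(rbind, lapply(masses, function(m) {
        anchor <- abs(m - 15) < 1e-9
        ct <- ct15[[g]] + params$standard_slope * log10(m / 15) +
          if (anchor) 0 else stats::rnorm(n, 0, params$sigma_tech)
        data.frame(embryo_id = truth$embryo_id, gene = g, input_ng = m, ct = ct,
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    out[order(out$embryo_id, out$gene, out$input_ng), , drop = FALSE]
  })
}

# One noiseless trace: logistic transitions + linear baseline.
melt_trace <- function(amplicons_present, params) {
  Tg <- params$temperature_grid
  f <- params$baseline_intercept + params$baseline_slope * Tg
  for (a in amplicons_present) {
    tm <- params$tm[[a]]
    if (is.null(tm)) stop(sprintf("no Tm configured for amplicon '%s'", a),
                          call. = FALSE)
    f <- f + params$amplitude / (1 + exp((Tg - tm) / params$transition_width))
  }
  f
}

#' Simulate one melting curve
#'
#' Fluorescence over the configured temperature grid: each present amplicon
#' contributes one logistic melt transition centred at its Tm, on a linear
#' baseline with Gaussian noise. The -dF/dT of a single transition peaks at
#' Tm with height amplitude/(4 width).
#'
#' @param amplicons_present Character vector of amplicons in the well (subset
#'   of `names(params$tm)`); may be empty.
#' @param params A [melt_model_params()].
#' @param seed Optional integer seed.
#' @return A data frame `temperature_c`, `fluorescence`.
#' @export
simulate_melt_curve <- function(amplicons_present, params = melt_model_params(),
                                seed = NULL) {
  stopifnot(inherits(params, "melt_model_params"))
  if (!all(amplicons_present %in% names(params$tm))) {
    stop("unknown amplicon in `amplicons_present`", call. = FALSE)
  }
  with_seed(seed, {
    f <- melt_trace(amplicons_present, params) +
      stats::rnorm(length(params$temperature_grid), 0, params$noise_sd)
    data.frame(temperature_c = params$temperature_grid, fluorescence = f)
  })
}

#' Simulate melting curves for a detection table
#'
#' One well per embryo and melt-assayed gene (GAPDH, SRY, DYS14 by default):
#' the well contains product exactly when the detection table marks the locus
#' detected, so drop-out and false alleles propagate into the traces.
#'
#' @param detections Output of [simulate_locus_detections()].
#' @param params A [melt_model_params()].
#' @param genes Genes read out by melting curve.
#' @param seed Optional integer seed.
#' @return Long data frame `embryo_id`, `gene`, `temperature_c`,
#'   `fluorescence`.
#' @export
simulate_melt_curves <- function(detections, params = melt_model_params(),
                                 genes = c("GAPDH", "SRY", "DYS14"),
                                 seed = NULL) {
  stopifnot(inherits(params, "melt_model_params"))
  det <- detections[detections$locus %in% genes, , drop = FALSE]
  Tg <- params$temperature_grid
  npt <- length(Tg)
  with_seed(seed, {
    # vectorized over wells: one logistic transition where product is present
    tm_well <- unname(params$tm[det$locus])
    temp <- rep(Tg, times = nrow(det))
    tm_rep <- rep(tm_well, each = npt)
    has <- rep(det$detected, each = npt)
    f <- params$baseline_intercept + params$baseline_slope * temp +
      ifelse(has,
             params$amplitude / (1 + exp((temp - tm_rep) /
                                           params$transition_width)),
             0) +
      stats::rnorm(npt * nrow(det), 0, params$noise_sd)
    data.frame(embryo_id = rep(det$embryo_id, each = npt),
               gene = rep(det$locus, each = npt),
               temperature_c = temp, fluorescence = f,
               stringsAsFactors = FALSE)
  })
}

#' Simulate amelogenin electropherograms
#'
#' Produces a fragment-analysis peak table. Samples with successful WGA always
#' show an AMELX peak near 104 bp; an AMELY peak near 110 bp appears when the
#' detection table marks AMELY detected. Heights are lognormal, with a
#' separate low-height distribution for false-allele peaks (AMELY detected in
#' an embryo carrying no Y material); sizes carry Gaussian jitter.
#'
#' @param truth A `karyotype_truth` data frame.
#' @param detections Output of [simulate_locus_detections()] (must contain
#'   AMELY rows).
#' @param params An [amel_model_params()].
#' @param seed Optional integer seed.
#' @return A data frame `embryo_id`, `size_bp`, `height_rfu`.
#' @export
simulate_electropherograms <- function(truth, detections,
                                       params = amel_model_params(),
                                       seed = NULL) {
  stopifnot(inherits(params, "amel_model_params"))
  am <- detections[detections$locus == "AMELY", , drop = FALSE]
  if (nrow(am) == 0) stop("detection table has no AMELY rows", call. = FALSE)
  am <- am[match(truth$embryo_id, am$embryo_id), ]
  with_seed(seed, {
    n <- nrow(truth)
    ok <- !truth$wga_failure
    x_height <- stats::rlnorm(n, params$height_log_mean, params$height_log_sd)
    y_true <- stats::rlnorm(n, params$height_log_mean, params$height_log_sd)
    y_fa <- stats::rlnorm(n, params$fa_height_log_mean, params$fa_height_log_sd)
    x_size <- params$size_x + stats::rnorm(n, 0, params$size_jitter_sd)
    y_size <- params$size_y + stats::rnorm(n, 0, params$size_jitter_sd)
    xs <- data.frame(embryo_id = truth$embryo_id[ok],
                     size_bp = x_size[ok], height_rfu = x_height[ok],
                     stringsAsFactors = FALSE)
    sel <- ok & am$detected
    ys <- data.frame(embryo_id = truth$embryo_id[sel],
                     size_bp = y_size[sel],
                     height_rfu = ifelse(am$present[sel], y_true[sel], y_fa[sel]),
                     stringsAsFactors = FALSE)
    out <- rbind(xs, ys)
    out[order(out$embryo_id, out$size_bp), , drop = FALSE]
  })
}

#' Simulate a full assay cohort
#'
#' Convenience wrapper chaining karyotype, detection, melt-curve,
#' electropherogram and Ct-panel simulation under one configuration. Child
#' seeds are derived deterministically from the cohort seed, so identical
#' configurations give byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param seed Optional seed overriding the cohort config's.
#' @param melt_curves Simulate the (bulky) melt traces? When `FALSE` the
#'   detection table stands in for melt-called results.
#' @return A list with elements `truth`, `detections`, `melt` (or `NULL`),
#'   `peaks`, `ct`.
#' @export
simulate_cohort <- function(config = pipeline_config(), seed = NULL,
                            melt_curves = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed %||% config$cohort$seed)
  truth <- simulate_karyotypes(config$cohort, seed = seed)
  detections <- simulate_locus_detections(truth, config$errors, seed = seed + 1L)
  melt <- if (melt_curves) {
    simulate_melt_curves(detections, config$melt, seed = seed + 2L)
  }
  peaks <- simulate_electropherograms(truth, detections, config$amel,
                                      seed = seed + 3L)
  ct <- simulate_ct_panel(truth, config$ct, seed = seed + 4L)
  list(truth = truth, detections = detections, melt = melt,
       peaks = peaks, ct = ct)
}
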