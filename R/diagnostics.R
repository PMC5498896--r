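# Diagnostic-evaluation statistics, written out in full: confusion matrices,
# accuracy, sensitivity/specificity, Youden J and optimal cutoff, Cohen's
# kappa, odds ratio with Woolf interval, Mann-Whitney AUC with Hanley-McNeil
# interval, and allele drop-out / false-allele rates.

#' Build a confusion matrix
#'
#' Cross-tabulates reference labels against test calls for a chosen positive
#' class. Calls in `exclude` (unclassified, no-result, excluded, QC failures)
#' are counted separately and left out of the matrix, as are reference labels
#' outside the two compared classes.
#'
#' @param truth Reference labels.
#' @param calls Test calls, same length.
#' @param positive The positive class label (e.g. `"male"`, `"trisomy"`).
#' @param negative Optional negative class label; by default every
#'   non-positive, non-excluded label is pooled as negative.
#' @param exclude Call labels treated as not evaluable.
#' @return An object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `fn`, `tn`, `positive`, `n_excluded`.
#' @export
confusion <- function(truth, calls, positive,
                      negative = NULL,
                      exclude = c("unclassified", "no_result", "excluded",
                                  "qc_fail")) {
  if (length(truth) != length(calls)) {
    stop("`truth` and `calls` must have equal length", call. = FALSE)
  }
  drop <- calls %in% exclude | is.na(calls) | is.na(truth)
  n_excluded <- sum(drop)
  truth <- truth[!drop]; calls <- calls[!drop]
  lab <- unique(c(truth, calls))
  known <- c(positive, negative %||% setdiff(lab, c(positive, exclude)))
  if (!all(calls %in% known)) {
    stop("calls contain labels outside the compared classes: ",
         paste(setdiff(calls, known), collapse = ", "), call. = FALSE)
  }
  t_pos <- truth == positive
  c_pos <- calls == positive
  if (!is.null(negative)) {
    keep <- truth %in% c(positive, negative)
    t_pos <- t_pos[keep]; c_pos <- c_pos[keep]
  }
  structure(list(tp = sum(t_pos & c_pos), fp = sum(!t_pos & c_pos),
                 fn = sum(t_pos & !c_pos), tn = sum(!t_pos & !c_pos),
                 positive = positive, n_excluded = n_excluded),
            class = "confusion_matrix")
}

#' Assemble a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Cell counts.
#' @param positive Positive class label.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn, positive = "positive") {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative",
                                       call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, positive = positive,
                 n_excluded = 0L), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c(x$positive, "other"),
                              call = c(x$positive, "other")))
  print(m)
  if (x$n_excluded > 0) cat(sprintf("(%d not evaluable, excluded)\n",
                                    x$n_excluded))
  invisible(x)
}

#' Accuracy and Cohen's kappa of a confusion matrix
#'
#' Accuracy is observed agreement (tp + tn)/n. Cohen's kappa corrects for
#' chance agreement, \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, with the expected
#' agreement computed from the marginal products. Degenerate marginals (both
#' raters constant, p_e = 1) give an undefined kappa, returned as `NA` with a
#' flag.
#'
#' @param cm A `confusion_matrix`.
#' @return A list `accuracy`, `kappa`, `kappa_defined`.
#' @export
accuracy_kappa <- function(cm) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
           (cm$fp + cm$tn) * (cm$fn + cm$tn)) / n^2
  if (abs(1 - pe) < 1e-12) {
    return(list(accuracy = po, kappa = NA_real_, kappa_defined = FALSE))
  }
  list(accuracy = po, kappa = (po - pe) / (1 - pe), kappa_defined = TRUE)
}

#' Sensitivity, specificity and Youden J of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return A list `sensitivity`, `specificity`, `youden_j`.
#' @export
sens_spec <- function(cm) {
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  list(sensitivity = sens, specificity = spec, youden_j = sens + spec - 1)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' OR = (tp * tn) / (fp * fn), i.e. correct-positive times correct-negative
#' over the two error cells, with the log-scale (Woolf) interval
#' \eqn{\exp(\ln OR \pm 1.96 \sqrt{\sum 1/n_{ij}})} and a Wald-type p-value
#' against OR = 1. A zero cell is an error unless `haldane = TRUE`, which
#' adds 0.5 to every cell and flags the correction.
#'
#' @param cm A `confusion_matrix`.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction when a cell is 0?
#' @return A list `or`, `lo`, `hi`, `p`, `corrected`.
#' @export
odds_ratio <- function(cm, haldane = FALSE) {
  cells <- c(cm$tp, cm$fp, cm$fn, cm$tn)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell; rerun with haldane = TRUE for the 0.5 correction",
           call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  list(or = or, lo = exp(log(or) - 1.96 * se), hi = exp(log(or) + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)), corrected = corrected)
}

# Positive-class indicator and orientation: with direction "low" a LOW score
# marks the positive class (delta-Ct: trisomy lowers the score), with "high"
# a high score does (peak height: males higher).
score_classes <- function(scores, labels, positive, direction) {
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (direction == "low") scores <- -scores
  list(scores = scores, pos = pos)
}

#' Mann-Whitney AUC with Hanley-McNeil confidence interval
#'
#' The area under the ROC curve computed through the Mann-Whitney U identity
#' on midranks (ties contribute 1/2), equal to the probability that a random
#' positive sample scores on the positive side of a random negative one. The
#' standard error follows Hanley and McNeil's formula, the interval is Wald
#' on the AUC scale (clipped to [0, 1]) and the p-value tests AUC = 0.5 by
#' normal approximation.
#'
#' @param scores Numeric scores.
#' @param labels Class labels.
#' @param positive Positive class label.
#' @param direction `"low"` if low scores indicate the positive class (as for
#'   delta-Ct, where trisomy lowers the value), `"high"` otherwise.
#' @return A list `auc`, `se`, `lo`, `hi`, `p`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive, direction = c("low", "high")) {
  direction <- match.arg(direction)
  sc <- score_classes(scores, labels, positive, direction)
  n1 <- sum(sc$pos); n0 <- sum(!sc$pos)
  r <- rank(sc$scores)  # midranks handle ties
  auc <- (sum(r[sc$pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- if (se > 0) (auc - 0.5) / se else Inf * sign(auc - 0.5)
  list(auc = auc, se = se,
       lo = max(0, auc - 1.96 * se), hi = min(1, auc + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)), n_pos = n1, n_neg = n0)
}

#' Youden-optimal classification cutoff
#'
#' Scans candidate cutoffs at the midpoints between adjacent distinct scores
#' (plus open ends) and returns the one maximizing Youden's J = sensitivity +
#' specificity - 1. With `direction = "low"` a sample is called positive when
#' its score is at or below the cutoff; with `"high"`, at or above. Ties on J
#' are broken toward higher sensitivity, then toward the cutoff that calls
#' more conservatively low (the smaller cutoff under `"low"`-direction
#' ordering of candidates).
#'
#' @inheritParams roc_auc
#' @return A list `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_optimal_cutoff <- function(scores, labels, positive,
                                  direction = c("low", "high")) {
  direction <- match.arg(direction)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else s
  cand <- c(min(s) - 1, cand, max(s) + 1)
  eval_cut <- function(cut) {
    called_pos <- if (direction == "low") scores <= cut else scores >= cut
    sens <- sum(called_pos & pos) / sum(pos)
    spec <- sum(!called_pos & !pos) / sum(!pos)
    c(j = sens + spec - 1, sens = sens, spec = spec)
  }
  stats <- vapply(cand, eval_cut, numeric(3))
  best_j <- max(stats["j", ])
  at_best <- which(stats["j", ] == best_j)
  at_best <- at_best[stats["sens", at_best] == max(stats["sens", at_best])]
  pick <- at_best[which.min(cand[at_best])]
  list(cutoff = cand[pick], j = unname(stats["j", pick]),
       sensitivity = unname(stats["sens", pick]),
       specificity = unname(stats["spec", pick]))
}

#' Allele drop-out and false-allele rates
#'
#' ADO is the fraction of carrier samples (locus truly present) in which the
#' locus went undetected. For FA two denominators are reported: `fa`, the
#' study's convention of spurious detections over ALL analyzed samples (the
#' convention under which the published per-locus rates 13.5%/0.5%,
#' 5.2%/3.4% and 2.0%/6.3% arise from their printed count fractions), and
#' `fa_noncarrier`, spurious detections over non-carriers only, which is the
#' per-absent-locus event probability and therefore the quantity that
#' re-estimates a simulator's generating FA parameter.
#'
#' Rates are computed over analyzable samples only: when the detection table
#' carries rows for the amplification control (`control_locus`), embryos
#' whose control failed are dropped first, mirroring a study design in which
#' control-negative samples yield "no result" rather than entering the error
#' arithmetic.
#'
#' @param detections Detection table `embryo_id`, `locus`, `detected` (and
#'   optionally `present`).
#' @param truth A `karyotype_truth` data frame used to derive carrier status
#'   when `present` is absent.
#' @param locus Locus name.
#' @param control_locus Amplification-control locus gating analyzability;
#'   `NULL` disables the gate.
#' @return A list `ado`, `fa`, `fa_noncarrier`, `n_carriers`,
#'   `n_noncarriers`, `n`; `ado` is `NA` (flagged by `ado_defined`) when
#'   there are no carriers.
#' @export
ado_fa_rates <- function(detections, truth = NULL, locus,
                         control_locus = "GAPDH") {
  if (!is.null(control_locus) && control_locus %in% detections$locus) {
    ctrl <- detections[detections$locus == control_locus, , drop = FALSE]
    ok <- ctrl$embryo_id[ctrl$detected]
    detections <- detections[detections$embryo_id %in% ok, , drop = FALSE]
  }
  d <- detections[detections$locus == locus, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no detection rows for locus '%s'", locus),
                     call. = FALSE)
  if (!"present" %in% names(d)) {
    if (is.null(truth)) stop("need `truth` or a `present` column", call. = FALSE)
    d$present <- locus_present(truth, locus)[match(d$embryo_id, truth$embryo_id)]
  }
  carriers <- sum(d$present)
  noncarriers <- sum(!d$present)
  misses <- sum(d$present & !d$detected)
  spurious <- sum(!d$present & d$detected)
  list(ado = if (carriers > 0) misses / carriers else NA_real_,
       ado_defined = carriers > 0,
       fa = spurious / nrow(d),
       fa_noncarrier = if (noncarriers > 0) spurious / noncarriers else NA_real_,
       n_carriers = carriers, n_noncarriers = noncarriers, n = nrow(d))
}

#' Full diagnostic summary of a test against a reference standard
#'
#' Bundles the module's statistics for one binary test: confusion matrix,
#' accuracy, sensitivity/specificity, Youden J, Cohen's kappa, odds ratio
#' with Woolf interval, and (when scores are supplied) Mann-Whitney AUC with
#' Hanley-McNeil interval.
#'
#' @param truth Reference labels.
#' @param calls Test calls.
#' @param positive Positive class label.
#' @param scores Optional continuous scores underlying the calls.
#' @param direction Score orientation, see [roc_auc()].
#' @param haldane Passed to [odds_ratio()].
#' @return An object of class `diagnostic_summary`.
#' @export
diagnostic_summary <- function(truth, calls, positive, scores = NULL,
                               direction = "low", haldane = TRUE) {
  cm <- confusion(truth, calls, positive)
  ak <- accuracy_kappa(cm)
  ss <- sens_spec(cm)
  or <- odds_ratio(cm, haldane = haldane)
  auc <- if (!is.null(scores)) {
    keep <- !is.na(scores) & !is.na(truth)
    roc_auc(scores[keep], truth[keep], positive, direction)
  }
  structure(list(confusion = cm, accuracy = ak$accuracy, kappa = ak$kappa,
                 sensitivity = ss$sensitivity, specificity = ss$specificity,
                 youden_j = ss$youden_j, odds_ratio = or, auc = auc),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("Diagnostic summary (positive class: %s)\n", cm$positive))
  cat(sprintf("  counts      : tp %d  fp %d  fn %d  tn %d  (excluded %d)\n",
              cm$tp, cm$fp, cm$fn, cm$tn, cm$n_excluded))
  cat(sprintf("  accuracy    : %.1f%%\n", 100 * x$accuracy))
  cat(sprintf("  sens / spec : %.1f%% / %.1f%%  (Youden J = %.3f)\n",
              100 * x$sensitivity, 100 * x$specificity, x$youden_j))
  cat(sprintf("  kappa       : %.3f\n", x$kappa))
  cat(sprintf("  odds ratio  : %.0f (95%% CI %.0f-%.0f)%s\n",
              x$odds_ratio$or, x$odds_ratio$lo, x$odds_ratio$hi,
              if (x$odds_ratio$corrected) " [Haldane-corrected]" else ""))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC         : %.2f (95%% CI %.2f-%.2f, p = %.2g)\n",
                x$auc$auc, x$auc$lo, x$auc$hi, x$auc$p))
  }
  invisible(x)
}
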