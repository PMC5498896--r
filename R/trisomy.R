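# Delta-Ct trisomy calling: standard-curve QC, 15 ng delta-Ct, published
# cutoffs and the raw-Ct exclusion rule.

ct_at <- function(ct, embryo, gene, mass = NULL) {
  sel <- ct$embryo_id == embryo & ct$gene == gene
  if (!is.null(mass)) sel <- sel & abs(ct$input_ng - mass) < 1e-9
  ct[sel, , drop = FALSE]
}

#' Standard-curve slope quality control
#'
#' Ordinary least-squares slope of Ct on log10(input mass) over the dilution
#' series of one gene in one sample. Comparable amplification efficiency
#' across the panel requires the slope to sit in the acceptance band
#' (-3.3 +/- 0.4 cycles/decade by default; -3.32 corresponds to perfect
#' doubling).
#'
#' @param ct Long Ct table `embryo_id`, `gene`, `input_ng`, `ct`.
#' @param embryo_id,gene Which standard curve to assess.
#' @param band Acceptance interval for the slope.
#' @return A list `gene`, `slope` (cycles/decade), `pass`.
#' @export
standard_curve_qc <- function(ct, embryo_id, gene, band = c(-3.7, -2.9)) {
  rows <- ct_at(ct, embryo_id, gene)
  rows <- rows[is.finite(rows$ct), , drop = FALSE]
  if (nrow(rows) < 2) {
    stop("standard-curve QC needs Ct at >= 2 masses", call. = FALSE)
  }
  x <- log10(rows$input_ng)
  slope <- sum((x - mean(x)) * (rows$ct - mean(rows$ct))) / sum((x - mean(x))^2)
  list(gene = gene, slope = slope, pass = slope >= band[1] & slope <= band[2])
}

#' Delta-Ct of a target gene versus the reference
#'
#' Ct(target) - Ct(reference) at the 15 ng analysis mass. Any plate- or
#' sample-level offset common to both genes cancels.
#'
#' @param ct Long Ct table.
#' @param embryo_id Sample.
#' @param target Target gene (e.g. `"TTC3"`, `"RPL17"`).
#' @param reference Endogenous-control gene.
#' @param mass Analysis input mass (ng).
#' @return Delta-Ct in cycles.
#' @export
delta_ct <- function(ct, embryo_id, target, reference = "HSDB", mass = 15) {
  tg <- ct_at(ct, embryo_id, target, mass)
  rf <- ct_at(ct, embryo_id, reference, mass)
  if (nrow(rf) != 1 || !is.finite(rf$ct)) {
    stop(sprintf("missing %g ng reference (%s) Ct for %s", mass, reference,
                 embryo_id), call. = FALSE)
  }
  if (nrow(tg) != 1 || !is.finite(tg$ct)) {
    stop(sprintf("missing %g ng %s Ct for %s", mass, target, embryo_id),
         call. = FALSE)
  }
  tg$ct - rf$ct
}

#' Call Trisomy 18 and Trisomy 21 from a Ct panel
#'
#' For each embryo, computes the 15 ng delta-Ct of TTC3 (chromosome 21) and
#' RPL17 (chromosome 18) against the HSDB reference and calls a trisomy when
#' the delta-Ct is at or below the published cutoff (3.85 for TTC3/Trisomy 21,
#' 0.985 for RPL17/Trisomy 18): an extra chromosome copy lowers the target's
#' delta-Ct. A gene whose raw 15 ng Ct exceeds `exclusion_ct` (30 cycles) is
#' excluded, as is a gene whose own or whose reference's standard-curve slope
#' fails QC - an uncallable sample is never reported as a negative. Both
#' calls may be positive; double aneuploidy is not adjudicated.
#'
#' Cutoffs live on the delta-Ct scale by default. `scale = "raw"` instead
#' compares the raw 15 ng target Ct to the cutoffs, for deployments that
#' calibrate cutoffs on raw threshold cycles.
#'
#' @param ct Long Ct table `embryo_id`, `gene`, `input_ng`, `ct`.
#' @param cutoffs A [caller_cutoffs()] (fields `ttc3`, `rpl17`,
#'   `exclusion_ct`, `slope_band`).
#' @param qc Apply standard-curve slope QC? Requires >= 2 masses per gene.
#' @param scale `"delta"` (default) or `"raw"`.
#' @param reference Endogenous-control gene.
#' @return A data frame of class `trisomy_calls`: `embryo_id`,
#'   `delta_ct_ttc3`, `delta_ct_rpl17`, `slope_ttc3`, `slope_rpl17`,
#'   `slope_hsdb`, `call_t21`, `call_t18`, `reason`.
#' @export
call_trisomy <- function(ct, cutoffs = caller_cutoffs(), qc = TRUE,
                         scale = c("delta", "raw"), reference = "HSDB") {
  scale <- match.arg(scale)
  targets <- c(TTC3 = cutoffs$ttc3, RPL17 = cutoffs$rpl17)
  ids <- unique(ct$embryo_id)
  genes <- c("TTC3", "RPL17", reference)
  masses <- sort(unique(ct$input_ng))

  # wide layout: one Ct vector per gene x mass, aligned on `ids`
  ct_wide <- lapply(genes, function(g) {
    cols <- lapply(masses, function(m) {
      rows <- ct[ct$gene == g & abs(ct$input_ng - m) < 1e-9, , drop = FALSE]
      rows$ct[match(ids, rows$embryo_id)]
    })
    matrix(unlist(cols), nrow = length(ids))
  })
  names(ct_wide) <- genes
  at15 <- which(abs(masses - 15) < 1e-9)
  if (!length(at15)) stop("Ct table lacks the 15 ng analysis mass", call. = FALSE)
  raw15 <- lapply(ct_wide, function(m) m[, at15])
  if (anyNA(raw15[[reference]])) {
    stop("missing 15 ng reference (", reference, ") Ct for: ",
         paste(utils::head(ids[is.na(raw15[[reference]])], 3), collapse = ", "),
         call. = FALSE)
  }

  slopes <- lapply(genes, function(g) rep(NA_real_, length(ids)))
  names(slopes) <- genes
  if (qc) {
    if (length(masses) < 2) {
      stop("standard-curve QC needs Ct at >= 2 masses", call. = FALSE)
    }
    x <- log10(masses)
    xc <- x - mean(x)
    for (g in genes) {
      slopes[[g]] <- as.numeric(ct_wide[[g]] %*% xc) / sum(xc^2)
    }
  }
  in_band <- function(s) {
    !qc | (!is.na(s) & s >= cutoffs$slope_band[1] & s <= cutoffs$slope_band[2])
  }
  ref_ok <- in_band(slopes[[reference]])

  one_gene <- function(g) {
    dct <- raw15[[g]] - raw15[[reference]]
    score <- if (scale == "delta") dct else raw15[[g]]
    hot <- is.finite(raw15[[g]]) & raw15[[g]] > cutoffs$exclusion_ct
    qc_bad <- !hot & (!in_band(slopes[[g]]) | !ref_ok)
    call <- ifelse(hot | qc_bad, "excluded",
                   ifelse(score <= targets[[g]], "positive", "negative"))
    reason <- ifelse(hot, sprintf("%s Ct > %g", g, cutoffs$exclusion_ct),
                     ifelse(qc_bad, "standard-curve QC fail", ""))
    list(dct = dct, call = call, reason = reason)
  }
  t21 <- one_gene("TTC3"); t18 <- one_gene("RPL17")
  r1 <- t21$reason; r2 <- t18$reason
  reason <- ifelse(r1 == "", r2,
                   ifelse(r2 == "" | r2 == r1, r1,
                          paste(r1, r2, sep = "; ")))
  out <- data.frame(embryo_id = ids,
                    delta_ct_ttc3 = t21$dct, delta_ct_rpl17 = t18$dct,
                    slope_ttc3 = slopes[["TTC3"]],
                    slope_rpl17 = slopes[["RPL17"]],
                    slope_hsdb = slopes[[reference]],
                    call_t21 = t21$call, call_t18 = t18$call,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("trisomy_calls", "data.frame")
  out
}

#' @export
print.trisomy_calls <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Trisomy calls for %d embryos\n", n))
  cat(sprintf("  T21 (TTC3): %d positive, %d negative, %d excluded\n",
              sum(x$call_t21 == "positive"), sum(x$call_t21 == "negative"),
              sum(x$call_t21 == "excluded")))
  cat(sprintf("  T18 (RPL17): %d positive, %d negative, %d excluded\n",
              sum(x$call_t18 == "positive"), sum(x$call_t18 == "negative"),
              sum(x$call_t18 == "excluded")))
  invisible(x)
}
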