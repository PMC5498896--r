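# Sex determination: the GSD index over SRY/DYS14 detections with
# logistic-regression category probabilities, and the amelogenin
# electropherogram classifier with height and ratio cutoffs.

GSD_CATEGORIES <- c("neither", "dys14_only", "sry_only", "both", "qc_fail")

gsd_category <- function(sry, dys14) {
  ifelse(sry & dys14, "both",
         ifelse(sry, "sry_only",
                ifelse(dys14, "dys14_only", "neither")))
}

#' Fit the category logistic model for the GSD index
#'
#' Logistic regression of embryo sex (male = 1) on indicators for SRY and
#' DYS14 detection, fitted by iteratively reweighted least squares
#' (`stats::glm`). With the three detection categories observed in practice
#' (neither / DYS14 only / both) the model is saturated, so the fitted
#' per-category male probabilities equal the empirical proportions. Reports
#' per-predictor odds ratios with Wald 95% intervals; complete separation is
#' flagged and reported as an infinite odds ratio rather than an error. With
#' fewer than two informative categories the fit falls back to empirical
#' proportions with a warning.
#'
#' @param counts Data frame with logical/0-1 columns `sry`, `dys14` and count
#'   columns `male`, `female`, one row per detection category.
#' @return An object of class `gsd_fit` with components `categories` (fitted
#'   `p_male` per category, including the extrapolated, unobserved
#'   `sry_only`), `coefficients`, `odds_ratios`, `separation`, `glm`.
#' @examples
#' counts <- data.frame(sry = c(0, 0, 1), dys14 = c(0, 1, 1),
#'                      male = c(5, 8, 83), female = c(101, 6, 1))
#' fit <- fit_category_logistic(counts)
#' coef(fit)
#' predict(fit, data.frame(sry = TRUE, dys14 = TRUE))
#' @export
fit_category_logistic <- function(counts) {
  need <- c("sry", "dys14", "male", "female")
  if (!all(need %in% names(counts))) {
    stop("`counts` must have columns sry, dys14, male, female", call. = FALSE)
  }
  counts$sry <- as.numeric(counts$sry)
  counts$dys14 <- as.numeric(counts$dys14)
  informative <- sum(counts$male + counts$female > 0)
  if (informative < 2) {
    warning("fewer than two informative categories; using empirical proportions")
    p <- sum(counts$male) / sum(counts$male + counts$female)
    cats <- data.frame(category = gsd_category(counts$sry > 0, counts$dys14 > 0),
                       p_male = p, extrapolated = FALSE)
    return(structure(list(categories = cats, coefficients = c(intercept = qlogis(p)),
                          odds_ratios = NULL, separation = FALSE, glm = NULL),
                     class = "gsd_fit"))
  }
  fit <- suppressWarnings(
    stats::glm(cbind(male, female) ~ sry + dys14, family = stats::binomial(),
               data = counts)
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separation <- any(abs(beta) > 15, na.rm = TRUE) ||
    any(fitted(fit) > 1 - 1e-8) || any(fitted(fit) < 1e-8)
  or <- data.frame(
    predictor = names(beta)[-1],
    or = exp(beta[-1]),
    lo = exp(beta[-1] - 1.96 * se[-1]),
    hi = exp(beta[-1] + 1.96 * se[-1]),
    row.names = NULL
  )
  if (separation) or$or[abs(beta[-1]) > 15] <- Inf
  grid <- data.frame(sry = c(0, 0, 1, 1), dys14 = c(0, 1, 0, 1))
  # rank-deficient fits (fewer observed categories than coefficients) still
  # yield usable within-sample predictions; extrapolated cells are flagged
  p <- suppressWarnings(stats::predict(fit, newdata = grid, type = "response"))
  observed <- interaction(grid$sry, grid$dys14) %in%
    interaction(counts$sry, counts$dys14)
  cats <- data.frame(
    category = gsd_category(grid$sry > 0, grid$dys14 > 0),
    p_male = as.numeric(p),
    extrapolated = !observed,
    row.names = NULL
  )
  structure(list(categories = cats, coefficients = beta, odds_ratios = or,
                 separation = separation, glm = fit),
            class = "gsd_fit")
}

#' @export
print.gsd_fit <- function(x, ...) {
  cat("GSD index category logistic fit\n")
  tab <- x$categories
  tab$p_male <- sprintf("%5.1f%%%s", 100 * tab$p_male,
                        ifelse(tab$extrapolated, " (extrapolated)", ""))
  print(tab[, c("category", "p_male")], row.names = FALSE)
  if (isTRUE(x$separation)) cat("note: complete separation detected\n")
  invisible(x)
}

#' @export
coef.gsd_fit <- function(object, ...) object$coefficients

#' @export
summary.gsd_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$odds_ratios)) {
    cat("\nOdds ratios (Wald 95% CI):\n")
    print(object$odds_ratios, row.names = FALSE)
  }
  invisible(object)
}

#' @export
predict.gsd_fit <- function(object, newdata, ...) {
  cat_tab <- object$categories
  key <- gsd_category(as.logical(newdata$sry), as.logical(newdata$dys14))
  cat_tab$p_male[match(key, cat_tab$category)]
}

#' Classify embryo sex from SRY/DYS14 detections (GSD index)
#'
#' In `index` mode any detected Y marker calls the embryo male and a fully
#' negative sample female. In `clinical` mode a single-marker detection is
#' left unclassified (both markers are required for a male call, a fully
#' negative sample is called female). Samples whose GAPDH control failed give
#' `no_result` regardless of marker status. The call is a pure function of
#' the per-embryo booleans.
#'
#' @param detections Data frame with columns `embryo_id`, `gene` (or `locus`),
#'   `detected`, and optionally `qc_pass`; must contain SRY, DYS14 and (unless
#'   `qc_pass` is supplied) GAPDH rows per embryo.
#' @param mode `"index"` or `"clinical"`.
#' @param fit Optional [fit_category_logistic()] result used to annotate each
#'   call with its fitted P(male).
#' @return A data frame `embryo_id`, `category`, `call`, `p_male`,
#'   `extrapolated`.
#' @export
gsd_classify <- function(detections, mode = c("index", "clinical"), fit = NULL) {
  mode <- match.arg(mode)
  if (!"gene" %in% names(detections) && "locus" %in% names(detections)) {
    names(detections)[names(detections) == "locus"] <- "gene"
  }
  wide <- function(g) {
    d <- detections[detections$gene == g, c("embryo_id", "detected")]
    d[match(ids, d$embryo_id), "detected"]
  }
  ids <- unique(detections$embryo_id)
  sry <- wide("SRY"); dys <- wide("DYS14")
  if (anyNA(sry) || anyNA(dys)) {
    stop("every embryo needs SRY and DYS14 detection records", call. = FALSE)
  }
  if ("qc_pass" %in% names(detections)) {
    qc <- tapply(detections$qc_pass, detections$embryo_id, all)[ids]
  } else {
    gap <- wide("GAPDH")
    if (anyNA(gap)) stop("GAPDH detection required for QC gating", call. = FALSE)
    qc <- gap
  }
  category <- ifelse(!qc, "qc_fail", gsd_category(sry, dys))
  call <- vapply(category, function(cg) {
    switch(cg,
           qc_fail = "no_result",
           neither = "female",
           both = "male",
           dys14_only = if (mode == "index") "male" else "unclassified",
           sry_only = if (mode == "index") "male" else "unclassified")
  }, character(1))
  p_male <- rep(NA_real_, length(ids))
  extrap <- rep(FALSE, length(ids))
  if (!is.null(fit)) {
    idx <- match(category, fit$categories$category)
    p_male <- fit$categories$p_male[idx]
    extrap <- fit$categories$extrapolated[idx] %in% TRUE
  }
  data.frame(embryo_id = ids, category = unname(category), call = unname(call),
             p_male = p_male, extrapolated = extrap, stringsAsFactors = FALSE)
}

#' Derive AMELX/AMELY heights and the X/Y ratio from a peak table
#'
#' For each embryo, the AMELX (resp. AMELY) height is the tallest peak within
#' `size_tol` bp of 104 bp (resp. 110 bp), zero when no such peak exists. The
#' X/Y ratio divides by `max(amely_height, noise_floor)` so it stays finite
#' (and large) in females with no AMELY peak.
#'
#' @param peaks Data frame `embryo_id`, `size_bp`, `height_rfu`.
#' @param size_x,size_y Expected fragment sizes (bp).
#' @param size_tol Matching tolerance (bp).
#' @param noise_floor Ratio denominator floor (RFU).
#' @return A data frame `embryo_id`, `amelx_height`, `amely_height`, `ratio`.
#' @export
amel_peakset <- function(peaks, size_x = 104, size_y = 110, size_tol = 1.0,
                         noise_floor = 1) {
  need <- c("embryo_id", "size_bp", "height_rfu")
  if (!all(need %in% names(peaks))) {
    stop("peak table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(peaks$size_bp) | !is.finite(peaks$height_rfu) |
                 peaks$height_rfu < 0)
  if (length(bad)) {
    stop("malformed peak records at rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tallest <- function(p, target) {
    p <- p[abs(p$size_bp - target) <= size_tol, , drop = FALSE]
    if (nrow(p)) max(p$height_rfu) else 0
  }
  by_embryo <- split(peaks, peaks$embryo_id)
  out <- data.frame(
    embryo_id = names(by_embryo),
    amelx_height = vapply(by_embryo, tallest, numeric(1), target = size_x),
    amely_height = vapply(by_embryo, tallest, numeric(1), target = size_y),
    stringsAsFactors = FALSE
  )
  out$ratio <- out$amelx_height / pmax(out$amely_height, noise_floor)
  rownames(out) <- NULL
  out
}

#' Classify embryo sex from amelogenin peaks
#'
#' Three decision rules on the same peak set: by presence (any AMELY peak =>
#' male, X only => female), by AMELY height (male iff strictly above the 23.5
#' RFU cutoff), and by X/Y height ratio (male iff at or below the 21.8
#' cutoff; females, lacking AMELY, have large ratios). An embryo with no
#' AMELX peak failed amplification and is reported `qc_fail`, not female.
#'
#' @param peakset Output of [amel_peakset()], or a raw peak table (then
#'   converted with defaults).
#' @param cutoff_height AMELY height cutoff (RFU), male strictly above.
#' @param cutoff_ratio X/Y ratio cutoff, male at or below.
#' @return A data frame `embryo_id`, `amelx_height`, `amely_height`, `ratio`,
#'   `call_by_presence`, `call_by_height`, `call_by_ratio`.
#' @export
amel_classify <- function(peakset, cutoff_height = 23.5, cutoff_ratio = 21.8) {
  if (!"amelx_height" %in% names(peakset)) peakset <- amel_peakset(peakset)
  qc_ok <- peakset$amelx_height > 0
  out <- peakset
  out$call_by_presence <- ifelse(!qc_ok, "qc_fail",
                                 ifelse(peakset$amely_height > 0, "male", "female"))
  out$call_by_height <- ifelse(!qc_ok, "qc_fail",
                               ifelse(peakset$amely_height > cutoff_height,
                                      "male", "female"))
  out$call_by_ratio <- ifelse(!qc_ok, "qc_fail",
                              ifelse(peakset$ratio <= cutoff_ratio,
                                     "male", "female"))
  out
}
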