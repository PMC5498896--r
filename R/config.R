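# Parameter objects for the simulator and the callers, with the study's
# default values embedded, plus YAML round-tripping of the full configuration.

#' Cohort composition parameters
#'
#' Defines the karyotype mix of a simulated embryo cohort. Defaults follow the
#' observed composition of the study cohorts: 146/328 male embryos in the sex
#' cohort, and 9 Trisomy 18 / 13 Trisomy 21 among the 43 embryos analysed for
#' aneuploidy. `p_y_loss_in_males` models males that lost the Y chromosome
#' (Y-linked markers truly absent despite a male CGH label);
#' `p_y_fragment_in_females` models XX-male-type translocations (Y-linked
#' material present in a cytogenetic female). `p_wga_failure` is the
#' sample-level rate of whole-genome amplification producing no usable
#' product at all (6/342 in the study; GAPDH-control failures are modelled
#' separately in [error_model()]), which renders a sample uncallable.
#'
#' @param n_embryos Number of embryos to simulate.
#' @param p_male Probability an embryo is male.
#' @param p_trisomy18,p_trisomy21 Trisomy prevalences (must sum to at most 1).
#' @param p_y_loss_in_males Probability a male embryo carries no Y material.
#' @param p_y_fragment_in_females Probability a female embryo carries
#'   translocated Y material (AMELY/SRY/DYS14 present).
#' @param p_wga_failure Sample-level amplification-failure probability.
#' @param seed Integer seed used when this config drives a simulation.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_embryos = 328L,
                          p_male = 146 / 328,
                          p_trisomy18 = 9 / 43,
                          p_trisomy21 = 13 / 43,
                          p_y_loss_in_males = 0.04,
                          p_y_fragment_in_females = 0.02,
                          p_wga_failure = 6 / 342,
                          seed = 1L) {
  n_embryos <- check_count(n_embryos, "n_embryos")
  check_prob(p_male, "p_male")
  check_prob(p_trisomy18, "p_trisomy18")
  check_prob(p_trisomy21, "p_trisomy21")
  check_prob(p_y_loss_in_males, "p_y_loss_in_males")
  check_prob(p_y_fragment_in_females, "p_y_fragment_in_females")
  check_prob(p_wga_failure, "p_wga_failure")
  if (p_trisomy18 + p_trisomy21 > 1) {
    stop("p_trisomy18 + p_trisomy21 must not exceed 1", call. = FALSE)
  }
  structure(list(
    n_embryos = n_embryos, p_male = p_male,
    p_trisomy18 = p_trisomy18, p_trisomy21 = p_trisomy21,
    p_y_loss_in_males = p_y_loss_in_males,
    p_y_fragment_in_females = p_y_fragment_in_females,
    p_wga_failure = p_wga_failure,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Per-locus allele drop-out and false-allele error model
#'
#' ADO (allele drop-out) is the probability that a truly present locus is not
#' detected; FA (false allele) is the probability that an absent locus is
#' spuriously detected. Defaults are the study's per-locus embryo rates:
#' SRY 13.5%/0.5%, DYS14 5.2%/3.4%, AMELY 2.0%/6.3%. DYS14's lower drop-out
#' reflects its multicopy status (within TSPY); the model captures that solely
#' through the rate, not by explicit copy counting. `gapdh_detect` is the
#' detection probability of the GAPDH amplification control in samples whose
#' WGA succeeded (1 - 8/342 in the study).
#'
#' @param ado Named numeric vector of drop-out probabilities per locus.
#' @param fa Named numeric vector of false-allele probabilities per locus.
#' @param gapdh_detect GAPDH control detection probability.
#' @return An object of class `error_model`.
#' @export
error_model <- function(ado = c(SRY = 0.135, DYS14 = 0.052, AMELY = 0.020),
                        fa = c(SRY = 0.005, DYS14 = 0.034, AMELY = 0.063),
                        gapdh_detect = 1 - 8 / 342) {
  if (is.null(names(ado)) || is.null(names(fa)) ||
      !setequal(names(ado), names(fa))) {
    stop("`ado` and `fa` must be named vectors over the same loci", call. = FALSE)
  }
  for (l in names(ado)) {
    check_prob(unname(ado[[l]]), paste0("ado[", l, "]"))
    check_prob(unname(fa[[l]]), paste0("fa[", l, "]"))
  }
  check_prob(gapdh_detect, "gapdh_detect")
  structure(list(ado = ado, fa = fa[names(ado)], gapdh_detect = gapdh_detect),
            class = "error_model")
}

#' Ct-generation model parameters
#'
#' Generative model for the quantitative panel (TTC3 on chromosome 21, RPL17
#' on chromosome 18, HSDB as copy-neutral endogenous reference). For target
#' gene g with copy number c in an embryo,
#' \deqn{\Delta Ct_g = \mu_g - \gamma_g \log_2(c/2) + \epsilon_g,}
#' where `mu` is the diploid delta-Ct mean, `gamma` the WGA distortion
#' exponent (1 under ideal amplification, where a trisomy shifts delta-Ct by
#' exactly -log2(3/2) = -0.585 cycles), and `epsilon ~ N(0, sigma_delta_g)`.
#' `gamma` is drawn per embryo from `N(gamma_mean, gamma_sd)`, which lets the
#' trisomic groups be over-dispersed relative to the diploid group, as seen in
#' WGA material. Defaults are calibrated to the study's group statistics:
#' diploid TTC3 delta-Ct 4.77 +/- 0.56 vs Trisomy 21 3.39 +/- 0.99 (gamma_mean
#' = 1.38/0.585 = 2.36), diploid RPL17 2.19 +/- 0.80 vs Trisomy 18 0.53
#' (gamma_mean = 1.66/0.585 = 2.84).
#'
#' Raw Ct values anchor at `ct_ref_base` for the reference gene at 15 ng plus
#' a sample-level WGA offset `b ~ N(0, sigma_sample)` shared by all genes of a
#' sample (it therefore cancels from every delta-Ct). The standard-curve
#' series at lower input masses follows
#' `Ct(m) = Ct(15) + slope * log10(m/15)` with per-well technical noise
#' `N(0, sigma_tech)`; the slope defaults to -1/log10(1 + efficiency) =
#' -3.32 cycles/decade at 100% efficiency, inside the -3.3 +/- 0.4 acceptance
#' band.
#'
#' @param mu Named diploid delta-Ct means (cycles) for the target genes.
#' @param gamma_mean,gamma_sd Named mean and between-embryo SD of the WGA
#'   distortion exponent per target gene (dimensionless).
#' @param sigma_delta Named SD (cycles) of delta-Ct noise per target gene.
#' @param sigma_sample SD (cycles) of the sample-level WGA offset.
#' @param sigma_tech SD (cycles) of per-well technical noise on the
#'   standard-curve wells.
#' @param efficiency Amplification efficiency E in (0, 1].
#' @param standard_slope Ct-vs-log10(mass) slope (cycles/decade); default
#'   derived from `efficiency`.
#' @param ct_ref_base Reference-gene raw Ct at 15 ng for an average sample.
#' @return An object of class `ct_model_params`.
#' @export
ct_model_params <- function(mu = c(TTC3 = 4.77, RPL17 = 2.19),
                            gamma_mean = c(TTC3 = 1.38 / log2(1.5),
                                           RPL17 = 1.66 / log2(1.5)),
                            gamma_sd = c(TTC3 = sqrt(0.99^2 - 0.56^2) / log2(1.5),
                                         RPL17 = 0),
                            sigma_delta = c(TTC3 = 0.56, RPL17 = 0.80),
                            sigma_sample = 1.2,
                            sigma_tech = 0.05,
                            efficiency = 1,
                            standard_slope = NULL,
                            ct_ref_base = 23.5) {
  genes <- names(mu)
  if (is.null(genes) || !all(vapply(list(gamma_mean, gamma_sd, sigma_delta),
                                    function(v) setequal(names(v), genes),
                                    logical(1)))) {
    stop("mu, gamma_mean, gamma_sd and sigma_delta must share gene names",
         call. = FALSE)
  }
  check_pos(unname(gamma_mean), "gamma_mean")
  check_pos(unname(gamma_sd), "gamma_sd", strict = FALSE)
  check_pos(unname(sigma_delta), "sigma_delta", strict = FALSE)
  check_pos(sigma_sample, "sigma_sample", strict = FALSE)
  check_pos(sigma_tech, "sigma_tech", strict = FALSE)
  if (!is.numeric(efficiency) || efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(standard_slope)) standard_slope <- -1 / log10(1 + efficiency)
  if (standard_slope >= 0) stop("`standard_slope` must be negative", call. = FALSE)
  structure(list(
    mu = mu, gamma_mean = gamma_mean[genes], gamma_sd = gamma_sd[genes],
    sigma_delta = sigma_delta[genes], sigma_sample = sigma_sample,
    sigma_tech = sigma_tech, efficiency = efficiency,
    standard_slope = standard_slope, ct_ref_base = ct_ref_base
  ), class = "ct_model_params")
}

#' Melting-curve generation parameters
#'
#' Each amplicon contributes one logistic melt transition to the fluorescence
#' trace, \eqn{F(T) = \sum_g A / (1 + \exp((T - Tm_g)/w)) + c_0 + c_1 T +
#' N(0, \sigma)}, so the negative first derivative -dF/dT peaks at the
#' amplicon's melting temperature with height A/(4w). The instrument prints no
#' reference Tm values, so the defaults are plausible per-amplicon settings
#' (larger/GC-richer products melting higher) and are deployment
#' configuration, not measured constants.
#'
#' @param tm Named melting temperatures (degrees C) per amplicon.
#' @param transition_width Logistic width w (degrees C).
#' @param amplitude Transition amplitude A (RFU).
#' @param baseline_intercept,baseline_slope Linear baseline (RFU, RFU/degree C).
#' @param noise_sd Gaussian noise SD (RFU).
#' @param temperature_grid Ascending temperature grid (degrees C).
#' @return An object of class `melt_model_params`.
#' @export
melt_model_params <- function(tm = c(GAPDH = 87.5, SRY = 84.0, DYS14 = 80.5),
                              transition_width = 0.8,
                              amplitude = 100,
                              baseline_intercept = 1200,
                              baseline_slope = -0.8,
                              noise_sd = 0.15,
                              temperature_grid = seq(60, 95, by = 0.2)) {
  if (is.null(names(tm))) stop("`tm` must be a named vector", call. = FALSE)
  check_pos(transition_width, "transition_width")
  check_pos(amplitude, "amplitude")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (length(temperature_grid) < 2 || any(diff(temperature_grid) <= 0)) {
    stop("`temperature_grid` must be ascending with at least 2 points",
         call. = FALSE)
  }
  if (any(tm < min(temperature_grid)) || any(tm > max(temperature_grid))) {
    stop("every `tm` must lie within the temperature grid", call. = FALSE)
  }
  structure(list(
    tm = tm, transition_width = transition_width, amplitude = amplitude,
    baseline_intercept = baseline_intercept, baseline_slope = baseline_slope,
    noise_sd = noise_sd, temperature_grid = temperature_grid
  ), class = "melt_model_params")
}

#' Amelogenin electropherogram generation parameters
#'
#' AMELX amplifies at 104 bp and AMELY at 110 bp (the 6 bp intron-1 insertion
#' on the Y copy). Peak heights are lognormal; spurious (false-allele) AMELY
#' peaks draw from a separate, much lower height distribution, which is what
#' makes the downstream 23.5 RFU height cutoff informative. Fragment sizes
#' jitter by `size_jitter_sd` to emulate capillary sizing error.
#'
#' @param size_x,size_y Fragment sizes (bp); their difference must be 6.
#' @param height_log_mean,height_log_sd Log-scale mean/SD of true allele peak
#'   heights (log RFU).
#' @param fa_height_log_mean,fa_height_log_sd Log-scale mean/SD of
#'   false-allele peak heights.
#' @param noise_floor Height floor (RFU) used as ratio denominator when AMELY
#'   is absent.
#' @param size_jitter_sd Sizing jitter SD (bp).
#' @return An object of class `amel_model_params`.
#' @export
amel_model_params <- function(size_x = 104, size_y = 110,
                              height_log_mean = log(300), height_log_sd = 0.5,
                              fa_height_log_mean = log(15), fa_height_log_sd = 0.7,
                              noise_floor = 1, size_jitter_sd = 0.15) {
  if (!isTRUE(all.equal(size_y - size_x, 6))) {
    stop("size_y - size_x must equal 6 bp (AMELY intron-1 insertion)",
         call. = FALSE)
  }
  check_pos(height_log_sd, "height_log_sd", strict = FALSE)
  check_pos(fa_height_log_sd, "fa_height_log_sd", strict = FALSE)
  check_pos(noise_floor, "noise_floor")
  check_pos(size_jitter_sd, "size_jitter_sd", strict = FALSE)
  structure(list(
    size_x = size_x, size_y = size_y,
    height_log_mean = height_log_mean, height_log_sd = height_log_sd,
    fa_height_log_mean = fa_height_log_mean, fa_height_log_sd = fa_height_log_sd,
    noise_floor = noise_floor, size_jitter_sd = size_jitter_sd
  ), class = "amel_model_params")
}

#' Caller cutoffs and quality-control bands
#'
#' The published decision constants: AMELY peak-height cutoff 23.5 RFU (male
#' if strictly above), X/Y peak-height-ratio cutoff 21.8 (male if at or
#' below), delta-Ct cutoffs 3.85 (TTC3, Trisomy 21) and 0.985 (RPL17,
#' Trisomy 18) with "at or below" calling positive, raw-Ct exclusion above 30
#' cycles, and the standard-curve slope acceptance band -3.3 +/- 0.4
#' cycles/decade.
#'
#' @param amel_height AMELY height cutoff (RFU).
#' @param amel_ratio X/Y ratio cutoff.
#' @param ttc3,rpl17 Delta-Ct cutoffs (cycles).
#' @param exclusion_ct Raw target Ct above which a call is excluded.
#' @param slope_band Standard-curve slope acceptance interval.
#' @param size_tol Fragment-size matching tolerance (bp).
#' @param tm_tol Melting-temperature matching tolerance (degrees C).
#' @return An object of class `caller_cutoffs`.
#' @export
caller_cutoffs <- function(amel_height = 23.5, amel_ratio = 21.8,
                           ttc3 = 3.85, rpl17 = 0.985,
                           exclusion_ct = 30,
                           slope_band = c(-3.7, -2.9),
                           size_tol = 1.0, tm_tol = 1.5) {
  if (length(slope_band) != 2 || slope_band[1] >= slope_band[2]) {
    stop("`slope_band` must be an ordered interval", call. = FALSE)
  }
  structure(list(
    amel_height = amel_height, amel_ratio = amel_ratio,
    ttc3 = ttc3, rpl17 = rpl17, exclusion_ct = exclusion_ct,
    slope_band = slope_band, size_tol = size_tol, tm_tol = tm_tol
  ), class = "caller_cutoffs")
}

#' Full pipeline configuration
#'
#' Bundles all parameter groups. Every default is either a value reported by
#' the study or a documented design choice; `write_config()` dumps them and
#' `read_config()` restores them losslessly.
#'
#' @param cohort A [cohort_config()].
#' @param errors An [error_model()].
#' @param ct A [ct_model_params()].
#' @param melt A [melt_model_params()].
#' @param amel An [amel_model_params()].
#' @param cutoffs A [caller_cutoffs()].
#' @param gsd_mode `"index"` (any Y marker calls male) or `"clinical"`
#'   (single-marker categories left unclassified).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            errors = error_model(),
                            ct = ct_model_params(),
                            melt = melt_model_params(),
                            amel = amel_model_params(),
                            cutoffs = caller_cutoffs(),
                            gsd_mode = c("index", "clinical")) {
  gsd_mode <- match.arg(gsd_mode)
  stopifnot(inherits(cohort, "cohort_config"), inherits(errors, "error_model"),
            inherits(ct, "ct_model_params"), inherits(melt, "melt_model_params"),
            inherits(amel, "amel_model_params"),
            inherits(cutoffs, "caller_cutoffs"))
  structure(list(cohort = cohort, errors = errors, ct = ct, melt = melt,
                 amel = amel, cutoffs = cutoffs, gsd_mode = gsd_mode),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("PGT pipeline configuration\n")
  cat(sprintf("  cohort : n = %d, P(male) = %.3f, P(T18) = %.3f, P(T21) = %.3f\n",
              x$cohort$n_embryos, x$cohort$p_male,
              x$cohort$p_trisomy18, x$cohort$p_trisomy21))
  cat(sprintf("  loci   : %s\n", paste(names(x$errors$ado), collapse = ", ")))
  cat(sprintf("  cutoffs: AMELY height > %.1f, ratio <= %.1f, TTC3 <= %.2f, RPL17 <= %.3f, exclude Ct > %g\n",
              x$cutoffs$amel_height, x$cutoffs$amel_ratio,
              x$cutoffs$ttc3, x$cutoffs$rpl17, x$cutoffs$exclusion_ct))
  cat(sprintf("  GSD mode: %s\n", x$gsd_mode))
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `pipeline_config` equal to the one written.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  as_plain <- function(x) {
    if (is.list(x)) lapply(unclass(x), as_plain)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(as_plain(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  nv <- function(x) unlist(x)  # named list -> named numeric vector
  pipeline_config(
    cohort = do.call(cohort_config, raw$cohort),
    errors = error_model(ado = nv(raw$errors$ado), fa = nv(raw$errors$fa),
                         gapdh_detect = raw$errors$gapdh_detect),
    ct = ct_model_params(mu = nv(raw$ct$mu), gamma_mean = nv(raw$ct$gamma_mean),
                         gamma_sd = nv(raw$ct$gamma_sd),
                         sigma_delta = nv(raw$ct$sigma_delta),
                         sigma_sample = raw$ct$sigma_sample,
                         sigma_tech = raw$ct$sigma_tech,
                         efficiency = raw$ct$efficiency,
                         standard_slope = raw$ct$standard_slope,
                         ct_ref_base = raw$ct$ct_ref_base),
    melt = melt_model_params(tm = nv(raw$melt$tm),
                             transition_width = raw$melt$transition_width,
                             amplitude = raw$melt$amplitude,
                             baseline_intercept = raw$melt$baseline_intercept,
                             baseline_slope = raw$melt$baseline_slope,
                             noise_sd = raw$melt$noise_sd,
                             temperature_grid = nv(raw$melt$temperature_grid)),
    amel = do.call(amel_model_params, raw$amel),
    cutoffs = caller_cutoffs(amel_height = raw$cutoffs$amel_height,
                             amel_ratio = raw$cutoffs$amel_ratio,
                             ttc3 = raw$cutoffs$ttc3, rpl17 = raw$cutoffs$rpl17,
                             exclusion_ct = raw$cutoffs$exclusion_ct,
                             slope_band = nv(raw$cutoffs$slope_band),
                             size_tol = raw$cutoffs$size_tol,
                             tm_tol = raw$cutoffs$tm_tol),
    gsd_mode = raw$gsd_mode
  )
}
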