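# Shared fixtures: the published contingency tables and group statistics,
# plus small builders for hand-made inputs.

# Sex-cohort 2x2 tables (correct/incorrect per CGH): SRY alone and the
# combined GSD index.
tab_sry <- function() confusion_from_counts(tp = 83, fp = 1, fn = 13, tn = 107,
                                            positive = "male")
tab_gsd <- function() confusion_from_counts(tp = 91, fp = 7, fn = 5, tn = 101,
                                            positive = "male")

# Three SRY/DYS14 detection categories reconstructed from the cohort row
# sums: 106 double-negative (5 male), 14 DYS14-only (8 male), 84
# double-positive (83 male).
category_counts <- function() {
  data.frame(sry = c(0, 0, 1), dys14 = c(0, 1, 1),
             male = c(5, 8, 83), female = c(101, 6, 1))
}

# Trisomy-panel group statistics: delta-Ct mean/SD and group sizes.
table3 <- function() {
  list(ttc3 = list(normal = c(mean = 4.77, sd = 0.56, n = 21),
                   t21 = c(mean = 3.39, sd = 0.99, n = 13)),
       rpl17 = list(normal = c(mean = 2.19, sd = 0.80, n = 21),
                    t18 = c(mean = 0.53, sd = 0.53, n = 9)))
}

# A hand-built Ct panel in long format.
make_ct_panel <- function(embryo_id = "E1",
                          ttc3 = c(30, 29, 28), rpl17 = c(28, 27, 26),
                          hsdb = c(26, 25, 24), masses = c(3.75, 7.5, 15)) {
  data.frame(
    embryo_id = embryo_id,
    gene = rep(c("TTC3", "RPL17", "HSDB"), each = length(masses)),
    input_ng = rep(masses, 3),
    ct = c(ttc3, rpl17, hsdb),
    stringsAsFactors = FALSE
  )
}

# A minimal detections table for one embryo.
make_detections <- function(embryo_id = "E1", sry, dys14, gapdh = TRUE) {
  data.frame(embryo_id = embryo_id,
             gene = c("SRY", "DYS14", "GAPDH"),
             detected = c(sry, dys14, gapdh),
             stringsAsFactors = FALSE)
}

# A noiseless single-transition melting curve.
make_melt_curve <- function(tm = 84, amplitude = 100, width = 0.8,
                            baseline_intercept = 1000, baseline_slope = -0.5,
                            grid = seq(60, 95, by = 0.2)) {
  f <- amplitude / (1 + exp((grid - tm) / width)) +
    baseline_intercept + baseline_slope * grid
  list(temperature = grid, fluorescence = f)
}
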