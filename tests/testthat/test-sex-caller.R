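test_that("the saturated category fit returns the empirical male fractions", {
  fit <- fit_category_logistic(category_counts())
  cats <- fit$categories
  p <- function(cat) cats$p_male[cats$category == cat]
  expect_equal(p("neither"), 5 / 106, tolerance = 1e-6)
  expect_equal(p("dys14_only"), 8 / 14, tolerance = 1e-6)
  expect_equal(p("both"), 83 / 84, tolerance = 1e-6)
  expect_true(cats$extrapolated[cats$category == "sry_only"])
  expect_false(fit$separation)
  expect_s3_class(fit, "gsd_fit")
  expect_length(coef(fit), 3)
  expect_equal(predict(fit, data.frame(sry = TRUE, dys14 = TRUE)),
               83 / 84, tolerance = 1e-6)
})

test_that("saturated fits match direct proportions on random count tables", {
  set.seed(99)
  for (i in 1:20) {
    counts <- data.frame(sry = c(0, 0, 1), dys14 = c(0, 1, 1),
                         male = sample(1:60, 3), female = sample(1:60, 3))
    fit <- fit_category_logistic(counts)
    emp <- counts$male / (counts$male + counts$female)
    got <- fit$categories$p_male[match(
      c("neither", "dys14_only", "both"),
      fit$categories$category)]
    expect_equal(got, emp, tolerance = 1e-6)
  }
})

test_that("degenerate category tables fall back or flag separation", {
  expect_warning(
    fit1 <- fit_category_logistic(
      data.frame(sry = 0, dys14 = 0, male = 5, female = 5)),
    "empirical")
  expect_equal(fit1$categories$p_male, 0.5)

  sep <- fit_category_logistic(
    data.frame(sry = c(0, 1), dys14 = c(0, 1),
               male = c(0, 40), female = c(40, 0)))
  expect_true(sep$separation)
  expect_true(any(!is.finite(sep$odds_ratios$or)) ||
                any(sep$odds_ratios$or > 1e6))
})

test_that("GSD classification follows the category rules in both modes", {
  fit <- fit_category_logistic(category_counts())
  both <- gsd_classify(make_detections(sry = TRUE, dys14 = TRUE), "index", fit)
  expect_equal(both$call, "male")
  expect_equal(both$p_male, 0.988, tolerance = 1e-3)

  neither <- gsd_classify(make_detections(sry = FALSE, dys14 = FALSE), "index", fit)
  expect_equal(neither$call, "female")

  d_only <- make_detections(sry = FALSE, dys14 = TRUE)
  expect_equal(gsd_classify(d_only, "index")$call, "male")
  expect_equal(gsd_classify(d_only, "clinical")$call, "unclassified")

  no_ctrl <- gsd_classify(make_detections(sry = TRUE, dys14 = TRUE,
                                          gapdh = FALSE), "index", fit)
  expect_equal(no_ctrl$call, "no_result")
  expect_equal(no_ctrl$category, "qc_fail")

  expect_error(gsd_classify(make_detections(sry = TRUE, dys14 = TRUE)[-1, ]),
               "SRY and DYS14")
})

test_that("GSD calls depend only on the per-embryo booleans", {
  det <- do.call(rbind, list(
    make_detections("E1", TRUE, TRUE), make_detections("E2", FALSE, FALSE),
    make_detections("E3", FALSE, TRUE), make_detections("E4", TRUE, TRUE)))
  fwd <- gsd_classify(det, "index")
  rev <- gsd_classify(det[nrow(det):1, ], "index")
  rev <- rev[match(fwd$embryo_id, rev$embryo_id), ]
  expect_equal(fwd$call, rev$call)
})

test_that("amelogenin rules reproduce the worked examples and boundaries", {
  male <- amel_classify(data.frame(embryo_id = "E1",
                                   size_bp = c(104, 110),
                                   height_rfu = c(800, 650)))
  expect_equal(male$call_by_presence, "male")
  expect_equal(male$call_by_height, "male")
  expect_equal(male$call_by_ratio, "male")

  fem <- amel_classify(data.frame(embryo_id = "E1", size_bp = 104,
                                  height_rfu = 900))
  expect_equal(fem$call_by_presence, "female")
  expect_equal(fem$call_by_height, "female")
  expect_equal(fem$call_by_ratio, "female")   # ratio 900 > 21.8
  expect_equal(fem$ratio, 900)                # floor = 1 when AMELY absent

  # height exactly at the cutoff is NOT male (strict >)
  tie <- amel_classify(data.frame(embryo_id = "E1", size_bp = c(104, 110),
                                  height_rfu = c(500, 23.5)))
  expect_equal(tie$call_by_height, "female")
  # ratio exactly at the cutoff IS male (<=)
  rt <- amel_classify(data.frame(embryo_id = "E1", size_bp = c(104, 110),
                                 height_rfu = c(21.8 * 30, 30)))
  expect_equal(rt$call_by_ratio, "male")

  noX <- amel_classify(data.frame(embryo_id = "E1", size_bp = 96,
                                  height_rfu = 50))
  expect_equal(noX$call_by_presence, "qc_fail")

  expect_error(amel_peakset(data.frame(embryo_id = "E1", size_bp = NA,
                                       height_rfu = 5)), "rows: 1")
})

test_that("error-free cohorts are sexed perfectly by both assays", {
  cfg <- pipeline_config(
    cohort = cohort_config(n_embryos = 400, p_y_loss_in_males = 0,
                           p_y_fragment_in_females = 0, p_wga_failure = 0,
                           seed = 61),
    errors = error_model(ado = c(SRY = 0, DYS14 = 0, AMELY = 0),
                         fa = c(SRY = 0, DYS14 = 0, AMELY = 0),
                         gapdh_detect = 1))
  sim <- simulate_cohort(cfg, melt_curves = FALSE)
  det <- data.frame(embryo_id = sim$detections$embryo_id,
                    gene = sim$detections$locus,
                    detected = sim$detections$detected)
  gsd <- gsd_classify(det, "index")
  expect_identical(gsd$call,
                   sim$truth$sex[match(gsd$embryo_id, sim$truth$embryo_id)])
  am <- amel_classify(amel_peakset(sim$peaks))
  expect_identical(am$call_by_presence,
                   sim$truth$sex[match(am$embryo_id, sim$truth$embryo_id)])
})
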