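test_that("the report contains eight parameter models plus two type models", {
  co <- generate_cohort(default_cohort_params(), seed = 7)
  rep <- analyze_cohort(co)
  expect_length(rep$models, 10L)
  expect_setequal(
    names(rep$models),
    c(paste0(rep(c("area_mm2", "suml_mm", "fd", "flow_density_pct"), 2),
             rep(c("_vs_ivi", "_vs_va"), each = 4)),
      "mnv_type_vs_ivi", "mnv_type_vs_va")
  )
  # type models carry a joint test; parameter models do not
  expect_false(is.na(rep$models$mnv_type_vs_ivi$joint_p))
  expect_false(is.na(rep$models$mnv_type_vs_va$joint_p))
  expect_true(is.na(rep$models$fd_vs_ivi$joint_p))
  # VA models adjust for baseline acuity
  expect_true("bcva_baseline_logmar" %in%
                rep$models$fd_vs_va$terms$term)
})

test_that("the report is invariant to cohort row order", {
  co <- generate_cohort(default_cohort_params(), seed = 19)
  r1 <- analyze_cohort(co)
  set.seed(1)
  r2 <- analyze_cohort(co[sample(nrow(co)), ])
  expect_equal(r1$table$estimate, r2$table$estimate, tolerance = 1e-12)
  expect_equal(r1$table$p_value, r2$table$p_value, tolerance = 1e-12)
})

test_that("disabling fence weights yields unit weights throughout", {
  co <- generate_cohort(default_cohort_params(), seed = 7)
  rep <- analyze_cohort(co, analysis_config(weights = "none"))
  for (m in rep$models) expect_true(all(m$weights == 1))
  repf <- analyze_cohort(co)
  expect_true(any(unlist(lapply(repf$models, `[[`, "weights")) < 1))
  expect_true(all(unlist(lapply(repf$models, `[[`, "weights")) > 0))
})

test_that("unfittable models are reported as failed, not dropped", {
  co <- generate_cohort(default_cohort_params(), seed = 5)
  co$fd <- 1.5   # constant predictor -> singular design for the fd models
  rep <- suppressWarnings(analyze_cohort(co))
  expect_true(rep$models$fd_vs_ivi$failed)
  expect_match(rep$models$fd_vs_ivi$error, "collinear|constant")
  expect_length(rep$models, 10L)
  expect_false(rep$models$area_mm2_vs_ivi$failed)
  expect_true(any(is.na(rep$table$p_value[rep$table$model == "fd_vs_ivi"])))
})

test_that("alternative outcome and adjustment options run end to end", {
  co <- generate_cohort(default_cohort_params(), seed = 13)
  r_final <- analyze_cohort(co, analysis_config(va_outcome = "final"))
  expect_equal(unique(r_final$table$outcome[grepl("_vs_va",
                                                  r_final$table$model)]),
               "bcva_3y_logmar")
  r_holm <- analyze_cohort(co, analysis_config(holm = TRUE))
  raw <- analyze_cohort(co)
  iv <- function(r, m, t) report_p(r, m, t)
  expect_gte(iv(r_holm, "flow_density_pct_vs_ivi", "flow_density_pct"),
             iv(raw, "flow_density_pct_vs_ivi", "flow_density_pct"))
  r_pois <- analyze_cohort(co, analysis_config(count_model = "poisson"))
  expect_false(r_pois$models$area_mm2_vs_ivi$failed)
})

test_that("per-model weights multiply the fence weights of the involved variables", {
  co <- generate_cohort(default_cohort_params(), seed = 23)
  rep <- analyze_cohort(co)
  m <- rep$models$area_mm2_vs_ivi
  wa <- outlier_weight(co$area_mm2, fence_thresholds(co$area_mm2))
  wy <- outlier_weight(co$ivi_count_3y, fence_thresholds(co$ivi_count_3y))
  expect_equal(m$weights, sqrt(wa * wy), tolerance = 1e-12)
})
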