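test_that("quantile calibration has the documented closed form and round-trips", {
  deg <- calibrate_lognormal_from_quantiles(1, 1, 1)
  expect_equal(c(deg$mu, deg$sigma), c(0, 0))

  ben <- calibrate_lognormal_from_quantiles(45.4, 35.6, 60.8)
  expect_equal(ben$mu, 3.815512105047, tolerance = 1e-10)
  expect_equal(ben$sigma, 0.396777082942, tolerance = 1e-10)

  fig4 <- calibrate_lognormal_from_quantiles(1260.7, 790.6, 2905.1)
  expect_equal(fig4$mu, 7.139422401237, tolerance = 1e-10)
  expect_equal(fig4$sigma, 0.964752200356, tolerance = 1e-10)

  # implied median and quartile ratio reproduce the inputs
  expect_equal(exp(fig4$mu), 1260.7)
  expect_equal(exp(2 * qnorm(0.75) * fig4$sigma), 2905.1 / 790.6, tolerance = 1e-12)

  expect_error(calibrate_lognormal_from_quantiles(10, 12, 20), "q1 <= median")
  expect_error(calibrate_lognormal_from_quantiles(10, -1, 20), "q1")
})

test_that("the default configuration embeds the reference cohort composition", {
  cfg <- default_cohort_config()
  expect_equal(cfg$n_benign, 228L)
  expect_equal(cfg$n_malignant, 161L)
  expect_equal(cfg$menopause_post_prob[["benign"]], 86 / 228)
  expect_equal(cfg$menopause_post_prob[["malignant"]], 119 / 161)

  bg <- cfg$benign_groups
  labels <- vapply(bg, `[[`, character(1), "label")
  weights <- vapply(bg, `[[`, numeric(1), "weight")
  expect_equal(weights[labels == "endometriosis"] / sum(weights), 66 / 228)
  expect_equal(weights[labels == "mature_teratoma"] / sum(weights), 29 / 228)

  mg <- cfg$malignant_groups
  mlabels <- vapply(mg, `[[`, character(1), "label")
  mweights <- vapply(mg, `[[`, numeric(1), "weight")
  # stage III is 66/131 of epithelial disease, which is 135/161 of malignant
  expect_equal(mweights[mlabels == "stage_III"] /
                 sum(mweights[mlabels != "metastatic"]), 66 / 131)
  expect_equal(mweights[mlabels == "metastatic"] / sum(mweights), 26 / 161)

  # the pooled "other benign" group carries the all-benign CA125 median
  other <- bg[[which(labels == "other_benign")]]
  expect_equal(exp(other$ca125$mu), 12.8)
  expect_match(other$ca125$provenance, "benign_all")
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- perturb_config(default_cohort_config(seed = 5L),
                        list(n_benign = 50L, n_malignant = 40L))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(perturb_config(cfg, list(seed = 6L)))
  expect_false(identical(a$ca125_u_ml, c2$ca125_u_ml))
})

test_that("generated cohorts respect the configured structure", {
  co <- small_cohort(120, 90, seed = 31L)
  expect_equal(sum(co$diagnosis == "benign"), 120L)
  expect_equal(sum(co$diagnosis == "malignant"), 90L)
  expect_true(all(co$ca125_u_ml > 0))
  expect_true(all(co$he4_pm > 0))
  expect_true(all(co$age >= 18))
  # stage/grade only for epithelial cancers
  non_eoc <- co$histology_group != "eoc"
  expect_true(all(co$figo_stage[non_eoc] == "not_applicable"))
  expect_true(all(co$grade[non_eoc] == "not_applicable"))
  # borderline tumours only arise in early-stage disease by construction
  expect_true(all(co$figo_stage[co$grade == "borderline"] %in% c("I", "II")))
})

test_that("group proportions converge to the configured weights", {
  cfg <- perturb_config(default_cohort_config(seed = 8L),
                        list(n_benign = 20000L, n_malignant = 0L))
  co <- generate_cohort(cfg)
  frac_endo <- mean(co$histology_group == "endometriosis")
  # binomial 3-sigma band around 66/228
  p <- 66 / 228
  expect_lt(abs(frac_endo - p), 3 * sqrt(p * (1 - p) / 20000))
  p_post <- 86 / 228
  expect_lt(abs(mean(co$menopausal_status == "post") - p_post),
            3 * sqrt(p_post * (1 - p_post) / 20000))
})

test_that("large-sample marker medians recover the calibration targets", {
  # single-group benign cohort carrying the all-benign HE4 distribution
  cfg <- default_cohort_config(seed = 12L)
  one_group <- cfg$benign_groups[vapply(cfg$benign_groups, `[[`,
                                        character(1), "label") == "other_benign"]
  cfg <- perturb_config(cfg, list(n_benign = 200000L, n_malignant = 0L,
                                  benign_groups = one_group))
  co <- generate_cohort(cfg)
  expect_equal(median(co$he4_pm), 45.4, tolerance = 0.01)
  expect_equal(median(co$ca125_u_ml), 12.8, tolerance = 0.01)
  # sample quartile ratio matches the implied log-normal quartile ratio (2%)
  spec <- one_group[[1]]$he4
  q <- quantile(co$he4_pm, c(0.25, 0.75), names = FALSE)
  expect_equal(q[2] / q[1], exp(2 * qnorm(0.75) * spec$sigma), tolerance = 0.02)
})

test_that("copula rank correlation is imposed and removable", {
  cfg <- default_cohort_config(seed = 19L)
  one_group <- cfg$benign_groups[1]
  cfg <- perturb_config(cfg, list(n_benign = 30000L, n_malignant = 0L,
                                  benign_groups = one_group))
  co <- generate_cohort(cfg)
  rs <- cor(co$ca125_u_ml, co$he4_pm, method = "spearman")
  expect_equal(rs, 0.3, tolerance = 0.1)

  co0 <- generate_cohort(perturb_config(cfg, list(rank_corr = 0)))
  rs0 <- cor(co0$ca125_u_ml, co0$he4_pm, method = "spearman")
  expect_lt(abs(rs0), 0.02)
})

test_that("perturb_config is a pure, validated update", {
  cfg <- default_cohort_config(seed = 2L)
  expect_identical(perturb_config(cfg, list()), cfg)
  cfg2 <- perturb_config(cfg, list(n_benign = 10L))
  expect_equal(cfg2$n_benign, 10L)
  expect_equal(cfg$n_benign, 228L)  # original untouched
  expect_equal(nrow(generate_cohort(cfg2)), 10L + 161L)
  expect_error(perturb_config(cfg, list(not_a_field = 1)), "unknown field")
})
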