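test_that("generated panels are complete, in range, and seed-deterministic", {
  cfg <- synthetic_config(seed = 101)
  p1 <- generate_panel(cfg)
  expect_s3_class(p1, "rating_panel")   # constructor already validated it
  expect_equal(dim(p1$records), c(8400L, 5L))
  expect_true(all(p1$records$rating %in% 1:5))
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  p3 <- generate_panel(synthetic_config(seed = 102))
  expect_false(identical(p1$records$rating, p3$records$rating))
})

test_that("exchangeable protocols give pooled AUC near 0.5", {
  cfg <- function(s) synthetic_config(
    n_cases = 200, protocol_shifts = c(a = 0, b = 0), seed = s)
  sims <- vapply(1:25, function(s) {
    average_auc(per_observer_auc(generate_panel(cfg(300 + s)), "b", "a"))
  }, numeric(1))
  se <- sd(sims)
  expect_lt(abs(average_auc(
    per_observer_auc(generate_panel(cfg(999)), "b", "a")) - 0.5), 3 * se)
  expect_lt(abs(mean(sims) - 0.5), 3 * se / sqrt(25))
})

test_that("the latent closed form behaves as the comparison probability", {
  expect_equal(true_auc(0, 1), 0.5)
  expect_equal(true_auc(1e6, 1), 1.0)          # limit of a huge shift
  expect_equal(true_auc(1, 1), pnorm(1 / sqrt(2)))
  expect_equal(true_auc(-1, 1), 1 - true_auc(1, 1))
  expect_error(true_auc(1, 0), "positive")
  expect_equal(latent_scale(synthetic_config()), sqrt(1 + 2 * 0.25))
})

test_that("empirical AUC tracks the latent truth over a shift grid", {
  s <- latent_scale(synthetic_config())
  aucs <- vapply(c(0, 0.5, 1.0), function(d) {
    p <- generate_panel(synthetic_config(
      n_cases = 300, protocol_shifts = c(ref = 0, test = d), seed = 500))
    average_auc(per_observer_auc(p, "test", "ref"))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_true(all(abs(aucs - true_auc(c(0, 0.5, 1.0), s)) < 0.025))
})

test_that("synthetic configs reject invalid parameters", {
  expect_error(synthetic_config(protocol_shifts = c(a = 0.2, b = 0)),
               "shift 0")
  expect_error(synthetic_config(protocol_shifts = c(0, 1)), "named")
  expect_error(synthetic_config(noise_sd = 0), "> 0")
  expect_error(synthetic_config(n_categories = 1), ">= 2")
})

test_that("dose cohorts scale exactly and reproduce group-level ratios", {
  coh <- generate_dose_cohort(seed = 8)
  expect_equal(nrow(coh), 50 * 3)
  s <- summarize_by_bmi(coh, 10)
  expect_equal(s$percent_vs_reference[s$dose_ratio == 7], rep(70L, 3))
  expect_equal(s$percent_vs_reference[s$dose_ratio == 5], rep(50L, 3))
  expect_identical(generate_dose_cohort(seed = 8), coh)

  # group-dependent achieved reductions: per-group factor lists
  fac <- list("<25"  = c("10" = 1, "7" = 0.39 / 0.56, "5" = 0.29 / 0.56),
              "25-30" = c("10" = 1, "7" = 0.60 / 0.90, "5" = 0.43 / 0.90),
              ">30"  = c("10" = 1, "7" = 0.63 / 1.01, "5" = 0.45 / 1.01))
  coh2 <- generate_dose_cohort(ratio_factors = fac, seed = 9)
  s2 <- summarize_by_bmi(coh2, 10)
  expect_equal(s2$percent_vs_reference[s2$dose_ratio == 7],
               c(70L, 67L, 62L))
  expect_equal(s2$percent_vs_reference[s2$dose_ratio == 5],
               c(52L, 48L, 45L))
})

test_that("generator configs can be read from YAML files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cases: 12", "seed: 31", "protocol_shifts:",
               "  ref: 0", "  lowdose: -0.2"), path)
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$n_cases, 12L)
  expect_equal(cfg$protocol_shifts, c(ref = 0, lowdose = -0.2))
  expect_identical(generate_panel(cfg),
                   generate_panel(synthetic_config(
                     n_cases = 12, seed = 31,
                     protocol_shifts = c(ref = 0, lowdose = -0.2))))
  writeLines("bogus_key: 1", path)
  expect_error(read_synthetic_config(path), "bogus_key")
})
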