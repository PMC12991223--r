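test_that("identical ratings across protocols give AUC 0.5 and p = 1", {
  p <- identical_panel(n_obs = 3, n_cases = 8)
  r <- bootstrap_vgc(p, "test", "ref",
                     config = bootstrap_config(n_boot = 400, seed = 2))
  expect_identical(r$auc, 0.5)
  expect_identical(r$p_value, 1)
  expect_true(all(r$replicates == 0.5))   # every replicate fully tied
  expect_identical(r$effect_size, 0)
  expect_lte(r$ci_low, r$ci_high)
})

test_that("the bootstrap is deterministic given its seed", {
  p <- generate_panel(synthetic_config(n_cases = 20, seed = 5))
  cfg <- bootstrap_config(n_boot = 300, seed = 99)
  r1 <- bootstrap_vgc(p, "ratio5", "ratio10", config = cfg)
  r2 <- bootstrap_vgc(p, "ratio5", "ratio10", config = cfg)
  expect_identical(r1, r2)
  r3 <- bootstrap_vgc(p, "ratio5", "ratio10",
                      config = bootstrap_config(n_boot = 300, seed = 100))
  expect_false(identical(r1$replicates, r3$replicates))
  # a bootstrap call must not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(bootstrap_vgc(p, "ratio5", "ratio10", config = cfg))
  expect_identical(rnorm(1), before)
})

test_that("replicate AUCs agree with direct recomputation on the resample", {
  # re-draw the same multiplicities and recompute each observer's AUC by
  # expanding the resampled panel explicitly
  p <- generate_panel(synthetic_config(n_cases = 12, n_criteria = 4,
                                       seed = 21))
  cfg <- bootstrap_config(n_boot = 25, seed = 17)
  r <- bootstrap_vgc(p, "ratio7", "ratio10", config = cfg)
  W <- withr::with_seed(cfg$seed,
    stats::rmultinom(cfg$n_boot, length(p$cases), rep(1, length(p$cases))))
  rec <- p$records
  for (b in c(1, 7, 25)) {
    draw <- rep(p$cases, W[, b])
    aucs <- vapply(p$observers, function(o) {
      ro <- rec[rec$observer == o, ]
      te <- unlist(lapply(draw, function(cs)
        ro$rating[ro$case == cs & ro$protocol == "ratio7"]))
      re <- unlist(lapply(draw, function(cs)
        ro$rating[ro$case == cs & ro$protocol == "ratio10"]))
      brute_auc(te, re)
    }, numeric(1))
    expect_equal(r$replicates[b], mean(aucs))
  }
})

test_that("compare_all runs every protocol-by-class comparison in order", {
  p <- generate_panel(synthetic_config(n_cases = 15, seed = 3))
  res <- compare_all(p, "ratio10", bundled_class_map(),
                     bootstrap_config(n_boot = 200, seed = 4))
  expect_length(res, 8)
  tab <- vgc_result_table(res)
  expect_equal(tab$test_protocol, rep(c("ratio5", "ratio7"), each = 4))
  expect_equal(tab$criterion_class,
               rep(c("demarcation", "disturbance", "bone", "tumor"), 2))
  expect_true(all(tab$ci_low <= tab$ci_high))
  expect_true(all(tab$effect_size == abs(tab$auc - 0.5)))

  ref_only <- rating_panel(
    p$records[p$records$protocol == "ratio10", ], 5)
  expect_error(compare_all(ref_only, "ratio10", bundled_class_map(),
                           bootstrap_config(n_boot = 10)),
               "nothing to compare")
  bad_map <- rbind(bundled_class_map(),
                   data.frame(criterion = "Q99", class = "bone"))
  expect_error(compare_all(p, "ratio10", bad_map), "Q99")
})

test_that("median bootstrap AUC increases strictly with the latent shift", {
  meds <- vapply(c(0, 0.3, 0.6, 1.0), function(d) {
    p <- generate_panel(synthetic_config(
      n_cases = 150, protocol_shifts = c(ref = 0, test = d), seed = 60))
    r <- bootstrap_vgc(p, "test", "ref",
                       config = bootstrap_config(n_boot = 500, seed = 61))
    median(r$replicates)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("bootstrap configuration is validated", {
  expect_error(bootstrap_config(n_boot = 0), "positive")
  expect_error(bootstrap_config(ci_level = 1), "between 0 and 1")
  expect_error(bootstrap_config(seed = "a"), "finite")
  p <- identical_panel(n_cases = 1)
  expect_error(bootstrap_vgc(p, "test", "ref"), "at least 2 cases")
})
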