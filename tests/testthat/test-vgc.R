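test_that("empirical AUC matches the pairwise half-tie oracle", {
  # frozen spot checks (last one enumerated by hand: pairs (3,2)+, (3,4)-,
  # (4,2)+, (4,4)= -> (2 + 0.5) / 4)
  expect_equal(empirical_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(empirical_auc(c(5, 5), c(1, 1)), 1.0)
  expect_equal(empirical_auc(c(3, 4), c(2, 4)), 0.625)
  expect_equal(brute_auc(c(3, 4), c(2, 4)), 0.625)

  # random multisets against the brute-force oracle
  set.seed(402)
  for (i in 1:50) {
    a <- sample(1:5, sample(1:8, 1), replace = TRUE)
    b <- sample(1:5, sample(1:8, 1), replace = TRUE)
    expect_equal(empirical_auc(a, b), brute_auc(a, b))
  }
  expect_error(empirical_auc(integer(0), 1:3), "non-empty")
})

test_that("empirical AUC is antisymmetric and rank invariant", {
  set.seed(77)
  relabel <- function(x) c(1, 4, 9, 16, 25)[x]  # strictly increasing map
  for (i in 1:60) {
    a <- sample(1:5, sample(1:10, 1), replace = TRUE)
    b <- sample(1:5, sample(1:10, 1), replace = TRUE)
    expect_equal(empirical_auc(a, b) + empirical_auc(b, a), 1)
    expect_equal(empirical_auc(relabel(a), relabel(b)), empirical_auc(a, b))
  }
})

test_that("VGC curve has valid operating points and trapezoidal area", {
  # identical uniform ratings: curve on the diagonal, area 0.5
  u <- rep(1:5, 20)
  cv <- vgc_curve(u, u, 5)
  expect_equal(cv$x, cv$y)
  expect_equal(auc(cv), 0.5)

  # complete separation: passes through (0, 1), area 1
  cv2 <- vgc_curve(rep(5L, 10), rep(1L, 10), 5)
  expect_true(any(cv2$x == 0 & cv2$y == 1))
  expect_equal(auc(cv2), 1.0)

  # hand-derived trapezoid over the 6 operating points
  cv3 <- vgc_curve(c(3, 4), c(2, 4), 5)
  expect_equal(nrow(cv3), 6)
  expect_equal(auc(cv3), 0.625)
  expect_equal(brute_trapezoid(cv3), 0.625)

  # structural invariants on random data
  set.seed(12)
  for (i in 1:25) {
    a <- sample(1:4, 6, replace = TRUE)
    b <- sample(1:4, 9, replace = TRUE)
    cv <- vgc_curve(a, b, 4)
    expect_equal(cv$x[1], 0); expect_equal(cv$y[1], 0)
    expect_equal(cv$x[nrow(cv)], 1); expect_equal(cv$y[nrow(cv)], 1)
    expect_true(all(diff(cv$x) >= 0) && all(diff(cv$y) >= 0))
    expect_lte(nrow(cv), 5)
    expect_equal(auc(cv), empirical_auc(a, b))
  }
  expect_error(vgc_curve(c(1, 6), c(1, 2), 5), class = "vgc_range_error")
})

test_that("per-observer AUCs never mix observers and average correctly", {
  p <- identical_panel(n_obs = 3)
  po <- per_observer_auc(p, "test", "ref")
  expect_named(po, c("o1", "o2", "o3"))
  expect_equal(unname(po), rep(0.5, 3))

  # one observer's test ratings strictly above their reference ratings
  recs <- p$records
  up <- recs$observer == "o2" & recs$protocol == "test"
  recs$rating[up] <- 5L
  recs$rating[recs$observer == "o2" & recs$protocol == "ref"] <- 1L
  p2 <- rating_panel(recs)
  po2 <- per_observer_auc(p2, "test", "ref")
  expect_equal(unname(po2["o2"]), 1.0)
  expect_equal(unname(po2["o1"]), 0.5)

  expect_error(per_observer_auc(p, "test", "nosuch"), "unknown protocol")
  expect_error(per_observer_auc(p, "test", "ref", criteria = "Q9"),
               "unknown criterion")

  expect_equal(average_auc(c(o1 = 0.4, o2 = 0.6)), 0.5)
  expect_equal(average_auc(po2), sum(po2) / 3)
  expect_error(average_auc(numeric(0)), "at least one")
})

test_that("null synthetic panels give per-observer AUCs centred at 0.5", {
  cfg <- function(seed) synthetic_config(
    n_cases = 200, protocol_shifts = c(ref = 0, test = 0), seed = seed)
  # Monte-Carlo SE of one observer's AUC, estimated by simulation
  sims <- vapply(1:30, function(s)
    per_observer_auc(generate_panel(cfg(1000 + s)), "test", "ref"),
    numeric(4))
  se <- sd(as.vector(sims))
  fresh <- per_observer_auc(generate_panel(cfg(7)), "test", "ref")
  expect_true(all(abs(fresh - 0.5) < 3 * se))
})

test_that("effect size is the absolute distance from the null AUC", {
  expect_equal(effect_size(0.51), 0.01)
  expect_equal(effect_size(0.5), 0)
  expect_equal(effect_size(0.46), 0.04)
  expect_equal(effect_size(c(0.47, 0.5)), c(0.03, 0))
  expect_error(effect_size(1.2), "0, 1")
})

test_that("binormal fit recovers the latent model and is self-consistent", {
  thr <- c(-0.8, 0, 0.8, 1.6)
  set.seed(31)
  # two identical large samples: a ~ 0, AUC ~ 0.5
  same <- findInterval(rnorm(4000), thr) + 1L
  same2 <- findInterval(rnorm(4000), thr) + 1L
  f0 <- fit_binormal(same, same2, 5)
  expect_equal(f0$auc_binormal, 0.5, tolerance = 0.02)

  # a = 1, b = 1 latent data, n = 5000 per arm
  te <- findInterval(rnorm(5000, 1), thr) + 1L
  re <- findInterval(rnorm(5000), thr) + 1L
  f1 <- fit_binormal(te, re, 5)
  expect_lt(abs(f1$a - 1), 0.1)
  expect_equal(f1$auc_binormal, pnorm(1 / sqrt(2)), tolerance = 0.02)

  # internal consistency and threshold ordering, any fit
  for (f in list(f0, f1)) {
    expect_identical(f$auc_binormal, pnorm(f$a / sqrt(1 + f$b^2)))
    expect_true(all(diff(f$thresholds) > 0))
    expect_gt(f$b, 0)
  }

  # all mass in one category on one arm: not identifiable
  expect_error(fit_binormal(rep(3L, 50), re[1:50], 5),
               class = "vgc_degenerate_error")
})
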