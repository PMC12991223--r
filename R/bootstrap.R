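#' Bootstrap settings for VGC inference
#'
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param ci_level confidence level of the percentile interval, in (0, 1).
#' @param seed integer seed; the bootstrap is fully deterministic given it.
#' @param alternative only `"two_sided"` is implemented: the p-value uses
#'   the doubled-tail convention with replicates equal to 0.5 counted in
#'   both tails.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 10000, ci_level = 0.95, seed = 1,
                             alternative = c("two_sided")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 1)
    stopf("`n_boot` must be a positive integer")
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1)
    stopf("`ci_level` must lie strictly between 0 and 1")
  assert_scalar_number(seed, "seed")
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed), alternative = alternative),
            class = "bootstrap_config")
}

#' Fixed-reader, paired-case bootstrap for one VGC comparison
#'
#' Inference for the averaged AUC treats the observer panel as fixed and
#' resamples *cases* (patients) with replacement: every drawn case carries
#' along all its criteria, both protocols and all observers' ratings, which
#' preserves both the within-patient pairing of the protocols and the
#' correlation between observers reading the same images.  For each
#' replicate the per-observer AUCs are recomputed on the resampled cases
#' and averaged; the confidence interval is the percentile interval of the
#' replicate distribution (asymmetric by construction), and the two-sided
#' p-value against the null AUC = 0.5 doubles the smaller tail fraction,
#' counting replicates exactly at 0.5 in both tails and capping at 1.
#'
#' Degenerate replicates (e.g. a resample in which an observer's ratings
#' are constant and identical across protocols) contribute AUC = 0.5
#' through the tie rule; no replicate is discarded.
#'
#' @inheritParams per_observer_auc
#' @param config a [bootstrap_config()].
#' @param criterion_class optional label stored in the result (e.g. the
#'   criterion-class name being analysed).
#' @return An object of class `vgc_result` with elements `auc`, `ci_low`,
#'   `ci_high`, `p_value`, `effect_size`, `per_observer_auc`, `n_boot`,
#'   `replicates` (the bootstrap distribution of the averaged AUC),
#'   `reference_protocol`, `test_protocol`, `criterion_class`, `seed`.
#' @export
bootstrap_vgc <- function(panel, test, ref, criteria = NULL,
                          config = bootstrap_config(),
                          criterion_class = NA_character_) {
  stopifnot(inherits(panel, "rating_panel"),
            inherits(config, "bootstrap_config"))
  check_protocols(panel, test, ref)
  criteria <- check_criteria(panel, criteria)
  n_cases <- length(panel$cases)
  if (n_cases < 2)
    stopf("bootstrap needs at least 2 cases")

  po <- per_observer_auc(panel, test, ref, criteria)
  point <- average_auc(po)

  counts <- case_category_counts(panel, test, ref, criteria)
  boot <- with_seed(config$seed, {
    # multiplicity of each case in each replicate: one multinomial draw
    W <- stats::rmultinom(config$n_boot, size = n_cases,
                          prob = rep(1, n_cases))
    boot_mean_auc(t(W), counts)
  })

  alpha <- 1 - config$ci_level
  # type 6 is the (B+1)*alpha-th order statistic, the conventional
  # percentile-bootstrap endpoint
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 6))
  p <- min(1, 2 * min(mean(boot <= 0.5), mean(boot >= 0.5)))

  structure(
    list(auc = point, ci_low = ci[1], ci_high = ci[2], p_value = p,
         effect_size = effect_size(point), per_observer_auc = po,
         n_boot = config$n_boot, replicates = boot,
         reference_protocol = ref, test_protocol = test,
         criterion_class = criterion_class, seed = config$seed),
    class = "vgc_result"
  )
}

# Per-observer case-by-category rating count matrices for both arms.
# Returns list of lists: counts[[obs]]$test and $ref are n_cases x K.
#' @noRd
case_category_counts <- function(panel, test, ref, criteria) {
  K <- panel$n_categories
  rec <- panel$records
  keep <- rec$criterion %in% criteria
  rec <- rec[keep, , drop = FALSE]
  case_idx <- match(rec$case, panel$cases)
  lapply(panel$observers, function(o) {
    is_o <- rec$observer == o
    one_arm <- function(prot) {
      sel <- is_o & rec$protocol == prot
      idx <- (case_idx[sel] - 1L) * K + rec$rating[sel]
      matrix(tabulate(idx, nbins = length(panel$cases) * K),
             ncol = K, byrow = TRUE)
    }
    list(test = one_arm(test), ref = one_arm(ref))
  })
}

# Averaged-over-observers AUC for each bootstrap replicate.
# Wt: n_boot x n_cases case multiplicities; counts as above.
#' @noRd
boot_mean_auc <- function(Wt, counts) {
  K <- ncol(counts[[1]]$test)
  # Lstrict[j, k] = 1 if category j < k: turns counts into "ref below" sums
  Lstrict <- matrix(0, K, K)
  Lstrict[upper.tri(Lstrict)] <- 1
  acc <- 0
  for (cnt in counts) {
    BT <- Wt %*% cnt$test          # n_boot x K test-arm category counts
    BR <- Wt %*% cnt$ref
    below <- BR %*% Lstrict        # ref ratings strictly below category k
    wins <- rowSums(BT * (below + 0.5 * BR))
    acc <- acc + wins / (rowSums(BT) * rowSums(BR))
  }
  acc / length(counts)
}

#' @export
print.vgc_result <- function(x, ...) {
  cat(sprintf("VGC comparison: %s vs %s (reference)%s\n",
              x$test_protocol, x$reference_protocol,
              if (is.na(x$criterion_class)) ""
              else sprintf(", class `%s`", x$criterion_class)))
  cat(sprintf("  AUC = %.3f  [%.3f, %.3f] 95%% bootstrap CI,  p = %.3g\n",
              x$auc, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  effect size = %.3f,  n_boot = %d, seed = %d\n",
              x$effect_size, x$n_boot, x$seed))
  cat("  per-observer AUC:",
      paste(sprintf("%s=%.3f", names(x$per_observer_auc),
                    x$per_observer_auc), collapse = "  "), "\n")
  invisible(x)
}

#' Run every protocol-by-class VGC comparison of a study
#'
#' For each non-reference protocol and each criterion class in `class_map`,
#' runs [bootstrap_vgc()] on the pooled ratings of that class.  Results are
#' ordered by test protocol and then by the class order of `class_map`.  No
#' multiple-testing correction is applied; each comparison is reported at
#' its nominal level.  Each comparison draws its own deterministic seed from
#' `config$seed`, so the full set of results is reproducible and does not
#' depend on evaluation order.
#'
#' @inheritParams bootstrap_vgc
#' @param class_map data frame (or CSV path) mapping `criterion` to
#'   `class`; must cover exactly the criteria present in the panel.
#' @return List of `vgc_result` objects, one per (protocol, class).
#' @export
compare_all <- function(panel, ref, class_map, config = bootstrap_config()) {
  stopifnot(inherits(panel, "rating_panel"))
  if (!ref %in% panel$protocols)
    stopf("reference protocol `%s` not present in panel", ref)
  tests <- setdiff(panel$protocols, ref)
  if (length(tests) == 0L)
    stopf("panel contains only the reference protocol; nothing to compare")
  map <- read_class_map(class_map)
  unknown <- setdiff(map$criterion, panel$criteria)
  if (length(unknown))
    stopf("class map references unknown criteria: %s",
          paste(unknown, collapse = ", "))
  unmapped <- setdiff(panel$criteria, map$criterion)
  if (length(unmapped))
    stopf("class map lacks an entry for criteria: %s",
          paste(unmapped, collapse = ", "))
  classes <- unique(map$class)
  grid <- expand.grid(class = classes, test = tests,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    crits <- map$criterion[map$class == grid$class[i]]
    out[[i]] <- bootstrap_vgc(panel, grid$test[i], ref, crits, cfg_i,
                              criterion_class = grid$class[i])
  }
  out
}

#' Tabulate a list of VGC results
#'
#' @param results list of `vgc_result` objects (from [compare_all()]).
#' @return Data frame with one row per result: protocol, class, AUC, CI
#'   bounds, p-value and effect size.
#' @export
vgc_result_table <- function(results) {
  stopifnot(length(results) > 0,
            all(vapply(results, inherits, logical(1), "vgc_result")))
  do.call(rbind, lapply(results, function(r) {
    data.frame(test_protocol = r$test_protocol,
               reference_protocol = r$reference_protocol,
               criterion_class = r$criterion_class,
               auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, effect_size = r$effect_size,
               n_boot = r$n_boot, stringsAsFactors = FALSE)
  }))
}
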