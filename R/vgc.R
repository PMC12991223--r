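#' Tie-corrected nonparametric AUC for two samples of ordinal ratings
#'
#' The figure-of-merit of visual grading characteristics analysis is the
#' probability that a randomly chosen rating from the test protocol exceeds
#' a randomly chosen rating from the reference protocol, with ties counted
#' as half:
#' \deqn{AUC = \frac{\#\{t > r\} + \tfrac12\,\#\{t = r\}}{n_t\, n_r}.}
#' This is the Mann-Whitney U statistic with the standard midrank tie
#' correction, and it equals the trapezoidal area under the VGC curve built
#' from the same two samples.  It is rank invariant: any strictly increasing
#' relabelling of the ordinal categories leaves it unchanged.  A value above
#' 0.5 means the test protocol was rated higher (better quality).
#'
#' @param test_ratings,ref_ratings non-empty numeric vectors of ordinal
#'   ratings for the test and reference protocol.
#' @return The AUC, a number in \eqn{[0, 1]}.
#' @examples
#' empirical_auc(c(3, 4), c(2, 4))   # 0.625
#' empirical_auc(1:3, 1:3)           # 0.5: identical distributions
#' @export
empirical_auc <- function(test_ratings, ref_ratings) {
  if (length(test_ratings) == 0L || length(ref_ratings) == 0L)
    stopf("both rating samples must be non-empty")
  if (anyNA(test_ratings) || anyNA(ref_ratings))
    stopf("ratings must not contain NA")
  nt <- length(test_ratings)
  nr <- length(ref_ratings)
  # midranks implement the half-tie rule exactly
  rk <- rank(c(test_ratings, ref_ratings), ties.method = "average")
  u <- sum(rk[seq_len(nt)]) - nt * (nt + 1) / 2
  u / (nt * nr)
}

#' Construct a VGC curve from two samples of ordinal ratings
#'
#' A VGC curve plots, for every possible rating threshold, the cumulative
#' proportion of test-protocol ratings at or above the threshold (y) against
#' the same proportion for the reference protocol (x).  Sweeping the
#' threshold from above the top category down to the bottom category yields
#' `K + 1` operating points running from (0, 0) to (1, 1); adjacent points
#' are joined by straight lines, so the area under the curve is the
#' trapezoidal area returned by [auc()], which provably equals
#' [empirical_auc()] on the same data.
#'
#' @inheritParams empirical_auc
#' @param n_categories number of ordinal categories `K`.
#' @return An object of class `vgc_curve`: a data frame of operating points
#'   with columns `x` and `y`, ordered from (0,0) to (1,1).
#' @examples
#' cv <- vgc_curve(c(3, 4), c(2, 4), n_categories = 5)
#' auc(cv)   # 0.625
#' @export
vgc_curve <- function(test_ratings, ref_ratings, n_categories = 5) {
  if (length(test_ratings) == 0L || length(ref_ratings) == 0L)
    stopf("both rating samples must be non-empty")
  K <- as.integer(n_categories)
  if (any(c(test_ratings, ref_ratings) < 1) ||
      any(c(test_ratings, ref_ratings) > K))
    stopf("ratings outside [1, %d]", K, class = "vgc_range_error")
  # threshold t = K, K-1, ..., 1: proportion rated >= t
  x <- vapply(K:1, function(t) mean(ref_ratings >= t), numeric(1))
  y <- vapply(K:1, function(t) mean(test_ratings >= t), numeric(1))
  pts <- data.frame(x = c(0, x), y = c(0, y))
  structure(pts, class = c("vgc_curve", "data.frame"),
            n_categories = K,
            n_test = length(test_ratings), n_ref = length(ref_ratings))
}

#' Area under a curve
#'
#' @param x object to compute an area for.
#' @param ... passed to methods.
#' @return The area, a number in \eqn{[0, 1]} for VGC curves.
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @describeIn auc trapezoidal area under the VGC operating points.
#' @export
auc.vgc_curve <- function(x, ...) {
  sum(diff(x$x) * (utils::head(x$y, -1) + utils::tail(x$y, -1)) / 2)
}

#' @export
print.vgc_curve <- function(x, ...) {
  cat(sprintf("VGC curve: %d operating points, trapezoidal AUC = %.4f\n",
              nrow(x), auc(x)))
  print(as.data.frame(unclass(x)), ...)
  invisible(x)
}

#' @export
plot.vgc_curve <- function(x, ..., main = "VGC curve") {
  plot(x$x, x$y, type = "b", pch = 16, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Cumulative proportion, reference protocol",
       ylab = "Cumulative proportion, test protocol", main = main, ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Per-observer AUC for a protocol comparison
#'
#' In MRMC visual grading analysis no rating is ever compared across
#' observers: each observer's own ratings form the test and reference
#' samples, one AUC is computed per observer, and the study figure-of-merit
#' is the average of those per-observer AUCs ([average_auc()]).  For a set
#' of criteria (usually one criterion class) every (case, criterion) rating
#' is pooled as one observation in the observer's sample.
#'
#' @param panel a [rating_panel].
#' @param test,ref protocol labels present in the panel.
#' @param criteria character vector of criterion labels to pool; `NULL`
#'   (default) pools all criteria in the panel.
#' @return Named numeric vector: one AUC per observer.
#' @export
per_observer_auc <- function(panel, test, ref, criteria = NULL) {
  stopifnot(inherits(panel, "rating_panel"))
  check_protocols(panel, test, ref)
  criteria <- check_criteria(panel, criteria)
  rec <- panel$records
  keep <- rec$criterion %in% criteria & rec$protocol %in% c(test, ref)
  rec <- rec[keep, , drop = FALSE]
  out <- vapply(panel$observers, function(o) {
    ro <- rec[rec$observer == o, , drop = FALSE]
    empirical_auc(ro$rating[ro$protocol == test],
                  ro$rating[ro$protocol == ref])
  }, numeric(1))
  names(out) <- panel$observers
  out
}

#' Average per-observer AUCs into the study figure-of-merit
#'
#' @param per_observer non-empty named numeric vector of per-observer AUCs.
#' @return The arithmetic mean.
#' @export
average_auc <- function(per_observer) {
  if (length(per_observer) == 0L)
    stopf("`per_observer` must contain at least one AUC")
  if (anyNA(per_observer)) stopf("`per_observer` contains NA")
  mean(per_observer)
}

#' Effect size of a VGC comparison
#'
#' The effect size is the absolute difference between an AUC and the null
#' value 0.5 (equal rated quality), quantifying the magnitude of a quality
#' difference irrespective of its direction.
#'
#' @param auc AUC value(s) in \eqn{[0, 1]}.
#' @return `|auc - 0.5|`, vectorised.
#' @examples
#' effect_size(0.51)  # 0.01
#' effect_size(0.46)  # 0.04
#' @export
effect_size <- function(auc) {
  if (!is.numeric(auc) || anyNA(auc) || any(auc < 0) || any(auc > 1))
    stopf("`auc` must lie in [0, 1]")
  abs(auc - 0.5)
}

#' @noRd
check_protocols <- function(panel, test, ref) {
  for (p in c(test, ref))
    if (!p %in% panel$protocols)
      stopf("unknown protocol label `%s` (panel has: %s)", p,
            paste(panel$protocols, collapse = ", "))
  if (identical(test, ref)) stopf("test and reference protocol must differ")
  invisible(NULL)
}

#' @noRd
check_criteria <- function(panel, criteria) {
  if (is.null(criteria)) return(panel$criteria)
  if (length(criteria) == 0L) stopf("`criteria` must be non-empty")
  unknown <- setdiff(criteria, panel$criteria)
  if (length(unknown))
    stopf("unknown criterion label(s): %s", paste(unknown, collapse = ", "))
  criteria
}
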