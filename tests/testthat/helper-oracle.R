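# Independent oracles and small fixture builders used across the suite.

# Brute-force pairwise AUC: enumerate every (test, ref) pair directly.
# Deliberately naive so it stays independent of the rank-based implementation.
brute_auc <- function(test, ref) {
  cmp <- outer(test, ref, function(t, r) (t > r) + 0.5 * (t == r))
  mean(cmp)
}

# Trapezoid rule written out by hand over a curve's points.
brute_trapezoid <- function(pts) {
  a <- 0
  for (i in seq_len(nrow(pts) - 1))
    a <- a + (pts$x[i + 1] - pts$x[i]) * (pts$y[i + 1] + pts$y[i]) / 2
  a
}

# All multisets of size n over categories 1..K, as sorted rating vectors.
all_multisets <- function(n, K) {
  if (n == 1) return(lapply(seq_len(K), identity))
  out <- list()
  rec <- function(prefix, lo, left) {
    if (left == 0) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in lo:K) rec(c(prefix, v), v, left - 1L)
  }
  rec(integer(0), 1L, n)
  out
}

# Small complete panel with identical ratings under every protocol: the
# archetypal null study (every AUC is exactly 0.5 by the tie rule).
identical_panel <- function(n_obs = 2, n_cases = 6, n_crit = 3,
                            protocols = c("ref", "test"), K = 5) {
  g <- expand.grid(observer = sprintf("o%d", 1:n_obs),
                   case = sprintf("c%d", 1:n_cases),
                   protocol = protocols,
                   criterion = sprintf("Q%d", 1:n_crit),
                   stringsAsFactors = FALSE)
  base <- expand.grid(observer = sprintf("o%d", 1:n_obs),
                      case = sprintf("c%d", 1:n_cases),
                      criterion = sprintf("Q%d", 1:n_crit),
                      stringsAsFactors = FALSE)
  base$rating <- ((seq_len(nrow(base)) * 7L) %% K) + 1L
  g$rating <- base$rating[match(paste(g$observer, g$case, g$criterion),
                                paste(base$observer, base$case,
                                      base$criterion))]
  rating_panel(g, n_categories = K)
}

bundled_class_map <- function() {
  read_class_map(system.file("extdata", "criterion_classes.csv",
                             package = "vgctools"))
}
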