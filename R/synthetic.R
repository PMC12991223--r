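#' Configuration of the synthetic MRMC rating generator
#'
#' The generator draws complete ordinal rating panels from a latent-variable
#' model with known ground truth, mirroring the design of a dose-reduction
#' visual grading study: by default 4 observers, 50 cases, 3 protocols and
#' 14 criteria on a 5-category scale.  Latent image quality for a
#' (case, protocol, criterion) cell is
#' \deqn{q = \delta_{protocol} + \gamma_{case} + \varepsilon,}
#' with the case effect \eqn{\gamma \sim N(0, \sigma_c^2)} shared across a
#' case's protocols (inducing the within-patient pairing the bootstrap
#' exploits) and \eqn{\varepsilon \sim N(0, \sigma_e^2)} independent per
#' cell.  Each observer reads `q` plus independent \eqn{N(0, \sigma_e^2)}
#' reading noise and discretizes through observer-specific strictly
#' increasing thresholds; base thresholds are equally spaced (step 0.7 times
#' the marginal latent SD, centred on the grand mean of the protocol
#' shifts) and jittered per observer, so observers differ only in their use
#' of the rating scale, not in the quality they perceive.
#'
#' The default shifts (reference 0, `ratio7` 0, `ratio5` -0.1) emulate a
#' study in which a 30% dose reduction leaves rated quality unchanged while
#' a 50% reduction degrades it slightly.
#'
#' @param n_observers,n_cases,n_criteria panel dimensions.
#' @param n_categories number of ordinal categories `K`.
#' @param protocol_shifts named numeric vector of latent mean shifts, one
#'   per protocol; the first entry is the reference and must be 0.
#' @param case_sd SD \eqn{\sigma_c} of the shared case effect.
#' @param noise_sd SD \eqn{\sigma_e} of both the per-cell latent noise and
#'   each observer's reading noise.
#' @param observer_threshold_jitter SD of the normal jitter applied to each
#'   observer's thresholds.
#' @param seed integer seed; generation is deterministic given it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_observers = 4, n_cases = 50, n_criteria = 14,
                             n_categories = 5,
                             protocol_shifts = c(ratio10 = 0, ratio7 = 0,
                                                 ratio5 = -0.1),
                             case_sd = 1, noise_sd = 0.5,
                             observer_threshold_jitter = 0.15, seed = 1) {
  for (nm in c("n_observers", "n_cases", "n_criteria"))
    if (get(nm) < 1) stopf("`%s` must be >= 1", nm)
  if (n_categories < 2) stopf("`n_categories` must be >= 2")
  if (is.null(names(protocol_shifts)) || any(!nzchar(names(protocol_shifts))))
    stopf("`protocol_shifts` must be a named vector of protocol labels")
  if (length(protocol_shifts) < 2)
    stopf("at least two protocols are needed")
  if (protocol_shifts[[1]] != 0)
    stopf("the first (reference) protocol must have shift 0")
  if (case_sd < 0) stopf("`case_sd` must be >= 0")
  if (noise_sd <= 0) stopf("`noise_sd` must be > 0")
  if (observer_threshold_jitter < 0)
    stopf("`observer_threshold_jitter` must be >= 0")
  assert_scalar_number(seed, "seed")
  structure(
    list(n_observers = as.integer(n_observers),
         n_cases = as.integer(n_cases),
         n_criteria = as.integer(n_criteria),
         n_categories = as.integer(n_categories),
         protocol_shifts = protocol_shifts,
         case_sd = case_sd, noise_sd = noise_sd,
         observer_threshold_jitter = observer_threshold_jitter,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Marginal latent scale of a synthetic configuration
#'
#' SD of one arm's latent reading, \eqn{\sqrt{\sigma_c^2 + 2\sigma_e^2}}:
#' case effect plus cell noise plus reading noise.  Together with a
#' protocol shift this gives the closed-form comparison AUC via
#' [true_auc()].
#'
#' @param config a [synthetic_config()].
#' @return The marginal latent SD.
#' @export
latent_scale <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sqrt(config$case_sd^2 + 2 * config$noise_sd^2)
}

#' Closed-form AUC of the equal-variance latent model
#'
#' The probability that one latent draw of an arm shifted by `delta`
#' exceeds one draw of the reference arm when both have SD `sigma`:
#' \eqn{\Phi(\delta / (\sigma\sqrt{2}))}.
#'
#' @param delta latent mean shift of the test arm.
#' @param sigma marginal latent SD of each arm, > 0.
#' @return The latent-model AUC.
#' @examples
#' true_auc(0, 1)                  # 0.5
#' true_auc(1, sqrt(1.5))          # default-generator truth at delta = 1
#' @export
true_auc <- function(delta, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0))
    stopf("`sigma` must be positive")
  stats::pnorm(delta / (sigma * sqrt(2)))
}

#' Generate a complete synthetic rating panel
#'
#' @param config a [synthetic_config()].
#' @return A validated [rating_panel] with observers `obs1..`, cases
#'   `case001..`, criteria `Q1..` and the protocols named in
#'   `config$protocol_shifts`.
#' @examples
#' panel <- generate_panel(synthetic_config(seed = 7))
#' panel
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  K <- config$n_categories
  shifts <- config$protocol_shifts
  observers <- sprintf("obs%d", seq_len(config$n_observers))
  cases <- sprintf("case%03d", seq_len(config$n_cases))
  criteria <- sprintf("Q%d", seq_len(config$n_criteria))
  protocols <- names(shifts)

  grid <- expand.grid(criterion = criteria, protocol = protocols,
                      case = cases, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n_cells <- nrow(grid)
  s_arm <- latent_scale(config)
  base_thr <- mean(shifts) +
    0.7 * s_arm * (seq_len(K - 1) - K / 2)

  with_seed(config$seed, {
    gamma <- stats::rnorm(config$n_cases, 0, config$case_sd)
    eps <- stats::rnorm(n_cells, 0, config$noise_sd)
    q <- shifts[grid$protocol] + gamma[match(grid$case, cases)] + eps

    parts <- lapply(seq_along(observers), function(o) {
      thr <- sort(base_thr +
                    stats::rnorm(K - 1, 0, config$observer_threshold_jitter))
      read <- q + stats::rnorm(n_cells, 0, config$noise_sd)
      data.frame(observer = observers[o], case = grid$case,
                 protocol = grid$protocol, criterion = grid$criterion,
                 rating = findInterval(read, thr) + 1L,
                 stringsAsFactors = FALSE)
    })
    rating_panel(do.call(rbind, parts), n_categories = K)
  })
}

#' Generate a synthetic dose cohort
#'
#' Draws per-patient dose-area products log-normally around BMI-group means
#' and derives per-ratio effective doses through [effective_dose()], with
#' exact (or optionally noisy) dose-ratio scaling.  Defaults reproduce a
#' 50-patient chest-tomosynthesis cohort: 52/36/12% of patients in the
#' BMI groups below 25 / 25-30 / above 30, group mean (SD) DAPs of
#' 2.53 (0.73), 4.11 (1.03) and 4.78 (0.57) Gy cm^2 at the full-dose ratio,
#' and ratio settings 10, 7 and 5.
#'
#' @param n_per_group named integer vector: patients per BMI group.
#' @param group_mean_dap,group_sd_dap named numeric vectors: mean and SD of
#'   the full-dose DAP per BMI group, Gy cm^2.
#' @param ratio_factors multiplicative DAP factor per dose-ratio setting,
#'   reference first with factor 1: either a single named numeric vector
#'   applied to every BMI group, or a named list of such vectors (one per
#'   BMI group) when the achieved dose reduction depends on patient size.
#' @param ratio_noise_sd SD of multiplicative log-normal noise on the
#'   reduced-ratio factors; 0 (default) scales exactly.
#' @param coefficient DAP-to-effective-dose conversion, mSv per Gy cm^2.
#' @param seed integer seed.
#' @return A [dose_records()] data frame, one row per patient and ratio.
#' @export
generate_dose_cohort <- function(n_per_group = c("<25" = 26, "25-30" = 18,
                                                 ">30" = 6),
                                 group_mean_dap = c("<25" = 2.53,
                                                    "25-30" = 4.11,
                                                    ">30" = 4.78),
                                 group_sd_dap = c("<25" = 0.73,
                                                  "25-30" = 1.03,
                                                  ">30" = 0.57),
                                 ratio_factors = c("10" = 1, "7" = 0.7,
                                                   "5" = 0.5),
                                 ratio_noise_sd = 0, coefficient = 0.26,
                                 seed = 1) {
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% names(group_mean_dap)) ||
      !all(groups %in% names(group_sd_dap)))
    stopf("group vectors must share the same BMI-group names")
  if (!is.list(ratio_factors))
    ratio_factors <- stats::setNames(rep(list(ratio_factors), length(groups)),
                                     groups)
  if (!all(groups %in% names(ratio_factors)))
    stopf("`ratio_factors` list must name every BMI group")
  if (any(n_per_group < 1) || any(group_mean_dap <= 0) ||
      any(group_sd_dap < 0) || any(unlist(ratio_factors) <= 0))
    stopf("cohort parameters must be positive")
  if (ratio_noise_sd < 0) stopf("`ratio_noise_sd` must be >= 0")
  bmi_range <- list("<25" = c(19, 24.9), "25-30" = c(25, 30),
                    ">30" = c(30.1, 36))
  ratios <- as.integer(names(ratio_factors[[1]]))

  with_seed(seed, {
    rows <- list()
    pid <- 0L
    for (g in groups) {
      m <- group_mean_dap[[g]]; s <- group_sd_dap[[g]]
      # log-normal matching the group mean and SD
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      dap_full <- stats::rlnorm(n_per_group[[g]], meanlog, sdlog)
      rng <- bmi_range[[g]] %||% stop("unknown BMI group ", g)
      bmi <- stats::runif(n_per_group[[g]], rng[1], rng[2])
      for (i in seq_len(n_per_group[[g]])) {
        pid <- pid + 1L
        fac <- ratio_factors[[g]]
        if (ratio_noise_sd > 0) {
          jit <- exp(stats::rnorm(length(fac), -ratio_noise_sd^2 / 2,
                                  ratio_noise_sd))
          jit[1] <- 1  # reference exposure is the anchor
          fac <- fac * jit
        }
        rows[[pid]] <- data.frame(
          patient = sprintf("pt%03d", pid),
          dap_gycm2 = dap_full[i] * unname(fac),
          dose_ratio = ratios, bmi = bmi[i], stringsAsFactors = FALSE)
      }
    }
    dose_records(do.call(rbind, rows), coefficient = coefficient)
  })
}

#' Read a synthetic-study configuration from a YAML file
#'
#' The file may set any [synthetic_config()] argument at the top level,
#' with `protocol_shifts` as a nested label-to-shift mapping:
#'
#' ```yaml
#' n_cases: 50
#' protocol_shifts:
#'   ratio10: 0
#'   ratio5: -0.1
#' seed: 7
#' ```
#'
#' @param path path to a YAML configuration file.
#' @return A [synthetic_config()] built from the file's values, with
#'   package defaults for anything unset.
#' @export
read_synthetic_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("reading config files requires the `yaml` package")
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(vals$protocol_shifts))
    vals$protocol_shifts <- unlist(vals$protocol_shifts)
  do.call(synthetic_config, vals)
}
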