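# Directional binomial Bayes factors (BF01) under truncated beta priors.
#
# M0: success rate exactly 0.5. M1: success rate p with a beta prior
# renormalised to (0.5, 1]. All marginal likelihoods are evaluated in log
# space through log-beta and regularised incomplete-beta functions:
#   m1 = C(n,k) B(k+a, n-k+b)/B(a,b) * (1 - I_0.5(k+a, n-k+b)) / (1 - I_0.5(a, b))

log_m0_binom <- function(k, n) stats::dbinom(k, n, 0.5, log = TRUE)

log_m1_binom <- function(k, n, alpha, beta, directional = TRUE) {
  lm1 <- lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
  if (directional) {
    lm1 <- lm1 +
      stats::pbeta(0.5, k + alpha, n - k + beta, lower.tail = FALSE, log.p = TRUE) -
      stats::pbeta(0.5, alpha, beta, lower.tail = FALSE, log.p = TRUE)
  }
  lm1
}

#' Directional Bayes factor for a binomial success count
#'
#' Computes BF01 = m0 / m1 contrasting M0 (success rate exactly 0.5) against
#' M1 (success rate above 0.5 with a truncated beta prior). Marginal
#' likelihoods are computed in log space; the Bayes factor is returned on the
#' natural scale together with its three-way classification (see
#' [classify_bf()]).
#'
#' @param k Success count(s), `0 <= k <= n` (vectorised).
#' @param n Trial count, a single positive integer.
#' @param prior A [prior_spec()]; defaults to the BUJ Beta(7, 7) prior.
#' @return A tibble with one row per `k`: `k`, `n`, `prior`, `log_m0`,
#'   `log_m1`, `bf01`, `support`.
#' @examples
#' bf01_one_sided(828, 1560, prior_spec("uniform"))
#' @export
bf01_one_sided <- function(k, n, prior = prior_spec("buj")) {
  stopifnot(inherits(prior, "prior_spec"), is.numeric(k), is.numeric(n),
            length(n) == 1)
  if (n < 1) stop("the test is undefined for n = 0", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("`k` must lie in [0, n]", call. = FALSE)
  lm0 <- log_m0_binom(k, n)
  lm1 <- log_m1_binom(k, n, prior$alpha, prior$beta, prior$directional)
  bf <- exp(lm0 - lm1)
  tibble::tibble(
    k = as.integer(k), n = as.integer(n), prior = prior$name,
    log_m0 = lm0, log_m1 = lm1, bf01 = bf, support = classify_bf(bf)
  )
}

#' Classify a Bayes factor against the 25-fold evidence thresholds
#'
#' BF01 above 25 supports M0; below 1/25 supports M1; anything else —
#' including exactly 25 or 1/25 — is inconclusive.
#'
#' @param bf01 Positive Bayes factor(s), M0 over M1.
#' @return Character vector in `{"M0", "M1", "inconclusive"}`.
#' @examples
#' classify_bf(c(40, 0.02, 25))
#' @export
classify_bf <- function(bf01) {
  stopifnot(is.numeric(bf01))
  if (any(!is.finite(bf01) & !is.infinite(bf01)) || any(bf01 <= 0)) {
    stop("`bf01` must be positive", call. = FALSE)
  }
  dplyr::case_when(bf01 > 25 ~ "M0", bf01 < 1 / 25 ~ "M1",
                   .default = "inconclusive")
}

#' Success counts consistent with a rounded percentage
#'
#' Published reports usually print the hit rate rounded to two decimals of a
#' percent; several integer counts can be consistent with the printed value.
#' This helper enumerates them all, so a Bayes factor can be checked across
#' the rounding ambiguity.
#'
#' @param pct Printed percentage (e.g. `49.48`).
#' @param n Trial count.
#' @param digits Decimals the percentage was rounded to (default 2).
#' @return Integer vector of all counts `k` with
#'   `round(100 * k / n, digits) == pct`, ordered; empty if none.
#' @examples
#' counts_for_proportion(49.48, 37836)
#' @export
counts_for_proportion <- function(pct, n, digits = 2) {
  stopifnot(length(pct) == 1, length(n) == 1, n >= 1)
  half <- 0.5 * 10^(-digits)
  lo <- ceiling((pct - half) * n / 100)
  hi <- floor((pct + half) * n / 100)
  ks <- seq.int(max(0L, lo), min(n, hi))
  ks[round(100 * ks / n, digits) == pct]
}

#' Bayes-factor battery over a trial table
#'
#' Pools hits per condition and arm and computes BF01 under each supplied
#' prior — the tabular entry point matching the TPP's three-prior analysis.
#'
#' @param trials A trial tibble as produced by [simulate_study()] or
#'   [read_trials()].
#' @param priors Named list of [prior_spec()] objects; defaults to
#'   [tpp_priors()].
#' @param conditions Conditions to test (default `"X"` and `"SX"`, the
#'   preregistered erotic and sham-erotic conditions).
#' @return A tibble with one row per (condition, arm, prior): counts, BF01
#'   and classification.
#' @export
bayes_battery <- function(trials, priors = tpp_priors(),
                          conditions = c("X", "SX")) {
  check_trials(trials)
  counts <- trials |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::group_by(.data$condition, .data$arm) |>
    dplyr::summarise(k = sum(.data$hit), n = dplyr::n(), .groups = "drop")
  if (nrow(counts) == 0) {
    stop("no trials found for the requested conditions", call. = FALSE)
  }
  purrr::map_dfr(priors, function(pr) {
    dplyr::bind_cols(
      counts[c("condition", "arm")],
      purrr::map2_dfr(counts$k, counts$n, bf01_one_sided, prior = pr)
    )
  })
}
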