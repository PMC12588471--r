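# Power and sample-size determination for the two-sided one-sample
# proportion test and for the full sequential design.

# cumulative hit counts at the design's analysis points, reps x looks;
# with heterogeneity, per-session 18-trial blocks get normal random
# intercepts on the log-odds scale before pooling
simulate_look_counts <- function(p_true, heterogeneity_sd, design, reps) {
  incr <- diff(c(0L, design$analysis_points))
  if (heterogeneity_sd == 0) {
    K_inc <- vapply(incr, function(m) stats::rbinom(reps, m, p_true),
                    numeric(reps))
  } else {
    block <- 18L  # per-session trials of the analysed condition
    K_inc <- vapply(incr, function(m) {
      n_part <- ceiling(m / block)
      sizes <- rep(block, n_part)
      sizes[n_part] <- m - block * (n_part - 1)
      vapply(seq_len(reps), function(r) {
        u <- stats::rnorm(n_part, 0, heterogeneity_sd)
        sum(stats::rbinom(n_part, sizes, inv_logit(logit(p_true) + u)))
      }, numeric(1))
    }, numeric(reps))
  }
  t(apply(matrix(K_inc, nrow = reps), 1, cumsum))
}

#' Normal-approximation power for the two-sided proportion test
#'
#' Power of the two-sided Wald test of H0: p = 0.5 at significance level
#' `alpha`, using the normal approximation with the variance evaluated at
#' `p_true`. Both rejection tails are included, so the null case
#' `p_true = 0.5` returns exactly `alpha`; away from the null the second
#' tail is negligible.
#'
#' @param n Number of trials.
#' @param p_true True success probability in (0, 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row tibble: `power`, `mc_se` (0), `method = "analytic"`.
#' @examples
#' analytic_power(127000, 0.4948)
#' @export
analytic_power <- function(n, p_true, alpha = 0.05) {
  stopifnot(n >= 1, p_true > 0, p_true < 1, alpha > 0, alpha < 1)
  se <- sqrt(p_true * (1 - p_true) / n)
  z <- stats::qnorm(1 - alpha / 2)
  delta <- p_true - 0.5
  power <- stats::pnorm(delta / se - z) + stats::pnorm(-delta / se - z)
  tibble::tibble(power = power, mc_se = 0, method = "analytic")
}

#' Monte-Carlo power for the two-sided proportion test
#'
#' Draws binomial counts at (`n`, `p_true`), applies the two-sided Wald
#' z-test against 0.5, and returns the rejection fraction with its
#' Monte-Carlo standard error.
#'
#' @inheritParams analytic_power
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed Optional seed.
#' @return A one-row tibble: `power`, `mc_se`, `method = "mc"`.
#' @examples
#' mc_power(127000, 0.4948, reps = 10000, seed = 1)
#' @export
mc_power <- function(n, p_true, alpha = 0.05, reps = 1e5, seed = NULL) {
  stopifnot(reps >= 1000)
  maybe_set_seed(seed)
  k <- stats::rbinom(reps, n, p_true)
  p_hat <- k / n
  z <- (p_hat - 0.5) / sqrt(p_hat * (1 - p_hat) / n)
  reject <- abs(z) > stats::qnorm(1 - alpha / 2)
  power <- mean(reject)
  tibble::tibble(power = power,
                 mc_se = sqrt(power * (1 - power) / reps),
                 method = "mc")
}

#' Smallest sample size reaching a target power
#'
#' Inverts the normal-approximation power formula,
#' `n = (z_{1-alpha/2} + z_{power})^2 p(1-p) / (p - 0.5)^2`, rounded up and
#' then refined to the smallest n whose [analytic_power()] meets the target.
#'
#' @param p_true Assumed true success probability (not 0.5).
#' @param target_power Desired power in (`alpha`, 1).
#' @param alpha Two-sided significance level.
#' @return Integer sample size.
#' @examples
#' required_n(0.4948, 0.95)
#' @export
required_n <- function(p_true, target_power = 0.95, alpha = 0.05) {
  stopifnot(p_true > 0, p_true < 1, alpha > 0, alpha < 1,
            target_power > alpha, target_power < 1)
  if (p_true == 0.5) {
    stop("`p_true` = 0.5 has no finite sample size", call. = FALSE)
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(target_power)
  n <- ceiling((z_a + z_b)^2 * p_true * (1 - p_true) / (p_true - 0.5)^2)
  while (n > 1 && analytic_power(n - 1, p_true, alpha)$power >= target_power) {
    n <- n - 1
  }
  while (analytic_power(n, p_true, alpha)$power < target_power) {
    n <- n + 1
  }
  as.integer(n)
}

#' Monte-Carlo power of the full sequential design
#'
#' Simulates whole studies through the three-look four-test design and
#' returns the fraction ending in a conclusive M1 stop. With
#' `heterogeneity_sd = 0` each study reduces to cumulative binomial counts
#' at the analysis points; with heterogeneity, per-participant 18-trial
#' blocks with normal random intercepts are aggregated instead (the battery
#' still tests the pooled counts).
#'
#' @param p_true True per-trial success probability.
#' @param heterogeneity_sd SD of participant random intercepts (log-odds).
#' @param design A [design_spec()].
#' @param reps Simulated studies (>= 1000).
#' @param seed Optional seed.
#' @return A one-row tibble: `power` (fraction stopping with M1), `mc_se`,
#'   `method = "sequential_mc"`, plus `stop_m0` and `inconclusive`
#'   fractions.
#' @examples
#' sequential_power_tpp(0.51, reps = 2000, seed = 1)
#' @export
sequential_power_tpp <- function(p_true, heterogeneity_sd = 0,
                                 design = design_spec(), reps = 1e4,
                                 seed = NULL) {
  stopifnot(p_true > 0, p_true < 1, heterogeneity_sd >= 0, reps >= 1000)
  maybe_set_seed(seed)
  K <- simulate_look_counts(p_true, heterogeneity_sd, design, reps)
  decision <- sequential_decide_counts(K, design)
  power <- mean(decision == "M1")
  tibble::tibble(
    power = power,
    mc_se = sqrt(power * (1 - power) / reps),
    method = "sequential_mc",
    stop_m0 = mean(decision == "M0"),
    inconclusive = mean(decision == "inconclusive")
  )
}
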