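# Intercept-only random-intercept logistic regression on per-participant
# binomial sufficient statistics, fitted by maximum likelihood with
# Gauss-Hermite quadrature:
#   l(b0, s) = sum_i log INT Binom(k_i; n_i, plogis(b0 + u)) N(u; 0, s^2) du
# The sigma = 0 boundary is handled by profiling: the boundary fit is the
# pooled binomial logit, reported whenever the interior search does not
# improve on it.

#' Aggregate a trial table to per-participant binomial counts
#'
#' The sufficient statistics of the intercept-only random-intercept logistic
#' model: hits and trials per participant for one condition.
#'
#' @param trials A trial tibble.
#' @param condition Condition to aggregate (`"X"`, `"O"`, `"SX"`, `"SO"`).
#' @return A tibble with columns `participant_id`, `k`, `n`, one row per
#'   participant with at least one trial of the condition. REG-arm trials
#'   have no participant grouping and collapse to a single pseudo-group.
#' @export
aggregate_by_participant <- function(trials, condition = "X") {
  check_trials(trials)
  sub <- dplyr::filter(trials, .data$condition == !!condition)
  if (nrow(sub) == 0) {
    stop(sprintf("condition `%s` is absent from the trial table", condition),
         call. = FALSE)
  }
  sub |>
    dplyr::mutate(group = ifelse(.data$arm == "reg", "reg",
                                 .data$participant_id)) |>
    dplyr::group_by(participant_id = .data$group) |>
    dplyr::summarise(k = sum(.data$hit), n = dplyr::n(), .groups = "drop")
}

gh_loglik <- function(beta0, sigma, k, n, gh) {
  if (sigma == 0) {
    return(sum(stats::dbinom(k, n, inv_logit(beta0), log = TRUE)))
  }
  lw <- log(gh$w) - 0.5 * log(pi)             # weights of the N(0,1) rule
  ll_nodes <- vapply(seq_along(gh$x), function(j) {
    stats::dbinom(k, n, inv_logit(beta0 + sqrt(2) * sigma * gh$x[j]),
                  log = TRUE) + lw[j]
  }, numeric(length(k)))
  ll_nodes <- matrix(ll_nodes, nrow = length(k))
  m <- apply(ll_nodes, 1, max)
  sum(m + log(rowSums(exp(ll_nodes - m))))
}

#' Fit the intercept-only random-intercept logistic model
#'
#' Maximum-likelihood fit of `logit P(hit) = beta0 + u_i`,
#' `u_i ~ N(0, sigma_u^2)`, to per-participant binomial counts, with the
#' participant integrals evaluated by Gauss-Hermite quadrature. The Wald
#' standard error of `beta0` comes from the observed information (numerical
#' Hessian over both parameters; binomial information at the `sigma_u = 0`
#' boundary).
#'
#' @param counts A tibble from [aggregate_by_participant()] (columns `k`,
#'   `n`; `participant_id` optional).
#' @param n_quad Number of quadrature nodes (>= 5; default 25).
#' @return An object of class `ri_logit` with elements `beta0`, `se_beta0`,
#'   `sigma_u`, `loglik`, `n_quad`, `converged`, `n_participants`,
#'   `k_total`, `n_total`.
#' @examples
#' counts <- tibble::tibble(k = c(10, 8, 12), n = 18)
#' fit_random_intercept_logit(counts)
#' @export
fit_random_intercept_logit <- function(counts, n_quad = 25) {
  stopifnot(is.data.frame(counts), all(c("k", "n") %in% names(counts)),
            nrow(counts) >= 1, n_quad >= 5)
  k <- as.numeric(counts$k)
  n <- as.numeric(counts$n)
  if (any(k < 0) || any(k > n) || any(n < 1)) {
    stop("invalid per-participant counts: need 0 <= k <= n, n >= 1",
         call. = FALSE)
  }
  gh <- pracma::gaussHermite(n_quad)
  p_pool <- sum(k) / sum(n)
  # degenerate pools (all hits/misses) cannot anchor a logit
  if (p_pool <= 0 || p_pool >= 1) {
    stop("pooled proportion is degenerate (0 or 1); the logit is undefined",
         call. = FALSE)
  }
  b0_start <- logit(p_pool)
  ll_boundary <- gh_loglik(b0_start, 0, k, n, gh)

  interior <- stats::optim(
    c(b0_start, 0.1),
    function(par) -gh_loglik(par[1], par[2], k, n, gh),
    method = "L-BFGS-B", lower = c(-Inf, 0), upper = c(Inf, Inf),
    control = list(factr = 1e-8 / .Machine$double.eps)
  )
  converged <- interior$convergence == 0
  beta0 <- interior$par[1]
  sigma <- interior$par[2]
  ll <- -interior$value

  at_boundary <- sigma < 1e-6 || ll <= ll_boundary + 1e-8
  if (at_boundary) {
    beta0 <- b0_start
    sigma <- 0
    ll <- ll_boundary
    p <- inv_logit(beta0)
    se <- 1 / sqrt(sum(n) * p * (1 - p))
    converged <- TRUE
  } else {
    H <- pracma::hessian(function(par) -gh_loglik(par[1], par[2], k, n, gh),
                         c(beta0, sigma))
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || V[1, 1] <= 0) {
      # ill-conditioned information near the boundary: profile out sigma
      se <- sqrt(1 / pracma::hessian(
        function(b) -gh_loglik(b, sigma, k, n, gh), beta0)[1, 1])
    } else {
      se <- sqrt(V[1, 1])
    }
  }
  structure(
    list(beta0 = beta0, se_beta0 = se, sigma_u = sigma, loglik = ll,
         n_quad = as.integer(n_quad), converged = converged,
         n_participants = nrow(counts), k_total = sum(k), n_total = sum(n)),
    class = "ri_logit"
  )
}

#' @export
print.ri_logit <- function(x, ...) {
  cat("Random-intercept logistic fit (Gauss-Hermite ML)\n")
  cat(sprintf("  groups: %d   trials: %d   hits: %d\n",
              x$n_participants, x$n_total, x$k_total))
  cat(sprintf("  beta0 = %.5f (SE %.5f)   sigma_u = %.4f   logLik = %.3f\n",
              x$beta0, x$se_beta0, x$sigma_u, x$loglik))
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
tidy.ri_logit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "sd_participant"),
    estimate = c(x$beta0, x$sigma_u),
    std.error = c(x$se_beta0, NA_real_)
  )
}

#' @export
glance.ri_logit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, sigma_u = x$sigma_u, nobs = x$n_total,
    n_groups = x$n_participants, n_quad = x$n_quad, converged = x$converged
  )
}

#' Probability-scale Wald interval from a fitted model
#'
#' Computes the Wald confidence interval for `beta0` on the log-odds scale,
#' maps the endpoints through the logistic function, and reports the hit
#' probability with its delta-method standard error in percentage points and
#' the two-sided Wald p-value against a 50% success rate.
#'
#' @param fit An `ri_logit` fit.
#' @param level Confidence level in (0, 1).
#' @return A one-row tibble: `p_hat`, `se_pct`, `ci_low`, `ci_high`,
#'   `level`, `p_value`.
#' @examples
#' counts <- tibble::tibble(k = 63050, n = 127000)
#' wald_interval(fit_random_intercept_logit(counts), 0.95)
#' @export
wald_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ri_logit"))
  if (!fit$converged) stop("model fit did not converge", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must lie in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p_hat <- inv_logit(fit$beta0)
  tibble::tibble(
    p_hat = p_hat,
    se_pct = 100 * fit$se_beta0 * p_hat * (1 - p_hat),
    ci_low = inv_logit(fit$beta0 - z * fit$se_beta0),
    ci_high = inv_logit(fit$beta0 + z * fit$se_beta0),
    level = level,
    p_value = 2 * stats::pnorm(-abs(fit$beta0 / fit$se_beta0))
  )
}

#' Preregistered frequentist decision rule
#'
#' Supports M0 when the CI upper bound is below 0.51; otherwise supports M1
#' when the lower bound exceeds 0.5; otherwise inconclusive.
#'
#' @param interval A one-row tibble from [wald_interval()].
#' @return `"M0"`, `"M1"` or `"inconclusive"`.
#' @export
decide_frequentist <- function(interval) {
  stopifnot(is.data.frame(interval),
            all(c("ci_low", "ci_high") %in% names(interval)))
  dplyr::case_when(
    interval$ci_high < 0.51 ~ "M0",
    interval$ci_low > 0.5 ~ "M1",
    .default = "inconclusive"
  )
}

#' Two-sided confirmation rule
#'
#' `TRUE` exactly when 0.5 falls outside the 95% confidence interval
#' (endpoints count as containment), the rule used to confirm the
#' exploratory below-chance finding.
#'
#' @param interval A one-row tibble from [wald_interval()] at `level = 0.95`.
#' @return Logical.
#' @export
confirm_bidirectional <- function(interval) {
  stopifnot(is.data.frame(interval), nrow(interval) == 1)
  if (!isTRUE(all.equal(interval$level, 0.95))) {
    stop("the bidirectional confirmation rule is defined for a 95% CI",
         call. = FALSE)
  }
  0.5 < interval$ci_low || 0.5 > interval$ci_high
}

#' Bonferroni-adjusted CI level for a sequential analysis point
#'
#' The preregistered design spreads repeated testing over three looks with
#' 99.5%, 99.75% and 99.875% confidence intervals.
#'
#' @param point_index 1, 2 or 3.
#' @return The confidence level.
#' @examples
#' ci_level_for_point(1)
#' @export
ci_level_for_point <- function(point_index) {
  if (!point_index %in% 1:3) {
    stop("`point_index` must be 1, 2 or 3", call. = FALSE)
  }
  c(0.995, 0.9975, 0.99875)[[point_index]]
}
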