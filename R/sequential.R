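# The preregistered three-look sequential design: inclusion rules, the
# four-test battery (one frequentist CI rule + three directional Bayes
# factors) evaluated at trial counts 37,836 / 62,388 / 86,958, and the
# all-agree stopping rule.

#' Specify the sequential design
#'
#' @param analysis_points Strictly increasing trial counts per condition at
#'   which the battery is evaluated (default 37836, 62388, 86958 — the
#'   minimum, intermediate and maximum sample sizes of the TPP design).
#' @param priors Named list of the Bayes-test priors (default
#'   [tpp_priors()]; must contain exactly three, completing the four-test
#'   battery with the frequentist CI rule).
#' @param ci_levels Per-look frequentist CI levels; default the
#'   Bonferroni-adjusted [ci_level_for_point()] values.
#' @return A `design_spec` object.
#' @examples
#' design_spec()
#' @export
design_spec <- function(analysis_points = c(37836L, 62388L, 86958L),
                        priors = tpp_priors(),
                        ci_levels = vapply(seq_along(analysis_points),
                                           ci_level_for_point, numeric(1))) {
  stopifnot(length(analysis_points) >= 1,
            all(diff(analysis_points) > 0),
            length(ci_levels) == length(analysis_points),
            all(ci_levels > 0), all(ci_levels < 1),
            length(priors) == 3,
            all(vapply(priors, inherits, logical(1), "prior_spec")))
  structure(list(analysis_points = as.integer(analysis_points),
                 priors = priors, ci_levels = ci_levels),
            class = "design_spec")
}

#' Apply the preregistered inclusion and truncation rules
#'
#' Incomplete sessions (< 36 trials) are retained, preventing optional
#' stopping through selective abandonment; over-run sessions are retained up
#' to 42 trials (more is an error); and each condition's trial stream is
#' truncated at exactly `n_max` trials in arrival (row) order, discarding
#' everything in excess of the pre-specified sample size.
#'
#' @param sessions A trial tibble ordered by completion time.
#' @param n_max Pre-specified sample size per condition.
#' @return The filtered trial tibble, original row order preserved.
#' @export
apply_inclusion_rules <- function(sessions, n_max) {
  check_trials(sessions)
  stopifnot(is.numeric(n_max), n_max >= 1)
  per_session <- dplyr::count(sessions, .data$session_id)
  if (any(per_session$n > 42)) {
    stop("session(s) exceed the 42-trial cap: ",
         paste(per_session$session_id[per_session$n > 42], collapse = ", "),
         call. = FALSE)
  }
  sessions |>
    dplyr::group_by(.data$condition) |>
    dplyr::filter(dplyr::row_number() <= n_max) |>
    dplyr::ungroup()
}

# four-test battery on pooled counts; the frequentist column uses the pooled
# binomial fit unless a fitted interval is supplied. Vectorised over k.
battery_on_counts <- function(k, n, level, priors) {
  p_hat <- k / n
  se <- 1 / sqrt(n * p_hat * (1 - p_hat))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- inv_logit(logit(p_hat) - z * se)
  hi <- inv_logit(logit(p_hat) + z * se)
  freq <- dplyr::case_when(hi < 0.51 ~ "M0", lo > 0.5 ~ "M1",
                           .default = "inconclusive")
  bfs <- lapply(priors, function(pr) {
    classify_bf(exp(log_m0_binom(k, n) -
                      log_m1_binom(k, n, pr$alpha, pr$beta, pr$directional)))
  })
  out <- c(list(frequentist = freq), bfs)
  names(out) <- c("frequentist", paste0("bf_", names(priors)))
  out
}

joint_decision <- function(supports) {
  mat <- do.call(cbind, supports)
  dplyr::case_when(
    rowSums(mat == "M0") == ncol(mat) ~ "stop_M0",
    rowSums(mat == "M1") == ncol(mat) ~ "stop_M1",
    .default = "continue"
  )
}

#' Evaluate the four-test battery at one analysis point
#'
#' Runs the frequentist CI decision at the look's Bonferroni-adjusted level
#' (random-intercept fit on the human arm, pooled fit on the REG arm) and
#' the three directional Bayes factors on the pooled hit count, and combines
#' them under the all-agree rule.
#'
#' @param trials Trial tibble containing exactly the analysis point's number
#'   of trials of `condition` (after [apply_inclusion_rules()]).
#' @param point_index Which look (1-based).
#' @param design A [design_spec()].
#' @param condition Condition under sequential analysis (default `"X"`).
#' @return A one-row tibble: `point_index`, `n`, `k`, per-test supports,
#'   `joint` in `{"stop_M0", "stop_M1", "continue"}`.
#' @export
evaluate_analysis_point <- function(trials, point_index,
                                    design = design_spec(),
                                    condition = "X") {
  check_trials(trials)
  stopifnot(inherits(design, "design_spec"),
            point_index %in% seq_along(design$analysis_points))
  sub <- dplyr::filter(trials, .data$condition == !!condition)
  n_point <- design$analysis_points[[point_index]]
  if (nrow(sub) != n_point) {
    stop(sprintf("analysis point %d expects %d `%s` trials, found %d",
                 point_index, n_point, condition, nrow(sub)), call. = FALSE)
  }
  level <- design$ci_levels[[point_index]]
  counts <- aggregate_by_participant(sub, condition)
  fit <- fit_random_intercept_logit(counts)
  interval <- wald_interval(fit, level)
  k <- sum(sub$hit)
  supports <- battery_on_counts(k, n_point, level, design$priors)
  supports$frequentist <- decide_frequentist(interval)
  dplyr::bind_cols(
    tibble::tibble(point_index = point_index, n = n_point, k = k),
    tibble::as_tibble(supports),
    tibble::tibble(joint = joint_decision(supports))
  )
}

#' Run the full sequential design over a trial stream
#'
#' Evaluates the analysis points in order on the growing trial stream and
#' stops at the first look where all four tests conclusively support the
#' same model; with no agreement by the final look the study ends
#' inconclusive at the maximum sample size.
#'
#' @param trials Trial tibble in arrival order (sessions as completed).
#' @param design A [design_spec()].
#' @param condition Condition under sequential analysis (default `"X"`).
#' @return A `study_outcome` object: `stopped_at` (look index, `NA` if never
#'   conclusive), `n_at_stop`, `decision` (`"M0"`, `"M1"` or
#'   `"inconclusive"`), and `points`, the per-look decision tibble.
#' @export
run_sequential <- function(trials, design = design_spec(), condition = "X") {
  check_trials(trials)
  stopifnot(inherits(design, "design_spec"))
  cond_stream <- dplyr::filter(apply_inclusion_rules(
    trials, max(design$analysis_points)), .data$condition == !!condition)
  points <- list()
  stopped_at <- NA_integer_
  decision <- "inconclusive"
  for (j in seq_along(design$analysis_points)) {
    n_j <- design$analysis_points[[j]]
    if (nrow(cond_stream) < n_j) {
      stop(sprintf(
        "trial stream exhausted: analysis point %d needs %d `%s` trials but only %d are available",
        j, n_j, condition, nrow(cond_stream)), call. = FALSE)
    }
    dec <- evaluate_analysis_point(cond_stream[seq_len(n_j), ], j, design,
                                   condition)
    points[[j]] <- dec
    if (dec$joint != "continue") {
      stopped_at <- j
      decision <- sub("^stop_", "", dec$joint)
      break
    }
  }
  structure(
    list(stopped_at = stopped_at,
         n_at_stop = if (is.na(stopped_at)) max(design$analysis_points)
                     else design$analysis_points[[stopped_at]],
         decision = decision,
         condition = condition,
         points = dplyr::bind_rows(points)),
    class = "study_outcome"
  )
}

#' @export
print.study_outcome <- function(x, ...) {
  cat(sprintf("Sequential study outcome (condition %s)\n", x$condition))
  if (is.na(x$stopped_at)) {
    cat(sprintf("  no all-agree stop; inconclusive at maximum N = %d\n",
                x$n_at_stop))
  } else {
    cat(sprintf("  stopped at look %d (N = %d) supporting %s\n",
                x$stopped_at, x$n_at_stop, x$decision))
  }
  print(x$points)
  invisible(x)
}

#' @export
tidy.study_outcome <- function(x, ...) x$points

#' @export
glance.study_outcome <- function(x, ...) {
  tibble::tibble(stopped_at = x$stopped_at, n_at_stop = x$n_at_stop,
                 decision = x$decision, condition = x$condition)
}

# fast count-level sequential runs for power work: K is a reps x looks
# matrix of cumulative hit counts; returns decisions "M0"/"M1"/"inconclusive"
sequential_decide_counts <- function(K, design) {
  reps <- nrow(K)
  decision <- rep("inconclusive", reps)
  open <- rep(TRUE, reps)
  for (j in seq_along(design$analysis_points)) {
    n_j <- design$analysis_points[[j]]
    supports <- battery_on_counts(K[, j], n_j, design$ci_levels[[j]],
                                  design$priors)
    joint <- joint_decision(supports)
    newly <- open & joint != "continue"
    decision[newly] <- sub("^stop_", "", joint[newly])
    open <- open & !newly
  }
  decision
}
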