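#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

trial_columns <- c("participant_id", "session_id", "session_type", "arm",
                   "condition", "trial_index", "guess_side", "target_side",
                   "hit", "reward_shown")

condition_levels <- c("X", "O", "SX", "SO")
side_levels <- c("left", "right")

check_trials <- function(trials, arg = deparse(substitute(trials))) {
  if (!is.data.frame(trials)) {
    stop(sprintf("`%s` must be a data frame of trial records", arg),
         call. = FALSE)
  }
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing)) {
    stop(sprintf("`%s` is missing trial column(s): %s", arg,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(trials)
}

# set.seed only when a seed is supplied; callers otherwise use the ambient
# RNG stream so composed simulations stay reproducible from one top seed
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

logit <- stats::qlogis
inv_logit <- stats::plogis
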