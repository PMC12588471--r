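#' Specify a beta prior for the directional proportion test
#'
#' A prior on the success probability under the alternative model M1. The
#' three named priors are the ones used by the Transparent Psi Project (TPP)
#' analysis plan: `"uniform"` is Beta(1, 1); `"buj"` is the knowledge-based
#' Beta(7, 7) prior of Bem, Utts and Johnson, constructed so that 90% of its
#' mass above 0.5 lies below the success probability equivalent to Cohen's
#' d = 0.5; `"replication"` is Beta(829, 733), the plus-one update from the
#' 828 successes and 732 failures in the original Bem Experiment 1 erotic
#' trials. Under M1 the prior is truncated to success rates above 0.5.
#'
#' @param name One of `"uniform"`, `"buj"`, `"replication"`, `"custom"`.
#' @param alpha,beta Beta shape parameters; required (and only honoured) for
#'   `name = "custom"`.
#' @param directional Should M1 restrict the success rate to (0.5, 1]?
#'   Defaults to `TRUE`, the TPP convention.
#' @param d90 Optional Cohen's d pinned to the prior's 90th directional
#'   percentile (informational; 0.5 for the BUJ prior).
#' @return A `prior_spec` object (a named list with `name`, `alpha`, `beta`,
#'   `directional`, `d90`).
#' @examples
#' prior_spec("buj")
#' prior_spec("custom", alpha = 4, beta = 2)
#' @export
prior_spec <- function(name = c("uniform", "buj", "replication", "custom"),
                       alpha = NULL, beta = NULL, directional = TRUE,
                       d90 = NULL) {
  name <- match.arg(name)
  shapes <- switch(name,
    uniform     = c(1, 1),
    buj         = c(7, 7),
    replication = c(829, 733),
    custom      = {
      if (is.null(alpha) || is.null(beta)) {
        stop("`alpha` and `beta` are required for a custom prior", call. = FALSE)
      }
      c(alpha, beta)
    }
  )
  if (any(!is.finite(shapes)) || any(shapes <= 0)) {
    stop("beta shape parameters must be positive and finite", call. = FALSE)
  }
  if (name == "buj" && is.null(d90)) d90 <- 0.5
  structure(
    list(name = name, alpha = shapes[[1]], beta = shapes[[2]],
         directional = isTRUE(directional), d90 = d90),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> %s: Beta(%g, %g)%s\n", x$name, x$alpha, x$beta,
              if (x$directional) ", truncated to (0.5, 1] under M1" else ""))
  invisible(x)
}

#' The three TPP analysis priors
#'
#' @return A named list of [prior_spec()] objects: `uniform`, `buj`,
#'   `replication`.
#' @examples
#' tpp_priors()
#' @export
tpp_priors <- function() {
  list(uniform     = prior_spec("uniform"),
       buj         = prior_spec("buj"),
       replication = prior_spec("replication"))
}

#' Convert a Cohen's d effect size to a success probability
#'
#' Uses the logistic-scale conversion `p = plogis(d * pi / sqrt(3))`: d is
#' first mapped to a log odds ratio through the standard-logistic scaling
#' factor pi/sqrt(3), then through the inverse logit. Strictly increasing
#' in d; d = 0 maps to 0.5 and d = 0.5 to 0.712.
#'
#' @param d Cohen's d (finite numeric, vectorised).
#' @return Success probability in (0, 1).
#' @examples
#' d_to_probability(0.5)
#' @export
d_to_probability <- function(d) {
  stopifnot(is.numeric(d), all(is.finite(d)))
  stats::plogis(d * pi / sqrt(3))
}

#' Build a replication prior from a previously observed success rate
#'
#' Converts an earlier study's observed proportion into a plus-one-updated
#' beta prior: with `successes = round(rate * n)`, the prior is
#' Beta(successes + 1, n - successes + 1). The TPP replication prior
#' Beta(829, 733) is `make_replication_prior(0.531, 1560)`.
#'
#' @param rate Observed success proportion in (0, 1).
#' @param n Number of trials the rate was observed on.
#' @return A directional [prior_spec()] with `name = "custom"`.
#' @examples
#' make_replication_prior(0.531, 1560)
#' @export
make_replication_prior <- function(rate, n) {
  stopifnot(is.numeric(rate), length(rate) == 1, rate > 0, rate < 1,
            is.numeric(n), length(n) == 1, n > 0)
  successes <- round(rate * n)
  prior_spec("custom", alpha = successes + 1, beta = n - successes + 1,
             directional = TRUE)
}
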