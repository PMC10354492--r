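#' Savage-Dickey density-ratio Bayes factor for a point null
#'
#' For a coefficient with Gaussian prior `Normal(0, prior_sd^2)` and
#' (approximately) Gaussian posterior, the Bayes factor in favour of a
#' nonzero effect is the ratio of the prior to the posterior density at
#' zero:
#' `BF = dnorm(0, 0, prior_sd) / dnorm(0, posterior_mean, posterior_sd)`.
#' Values above 1 favour the effect, below 1 the null.
#'
#' @param posterior_mean,posterior_sd Gaussian posterior of the coefficient.
#' @param prior_sd Prior sd (default 1).
#' @return The Bayes factor (> 0).
#' @examples
#' savage_dickey_bf(0, 1)        # 1: posterior equals prior
#' savage_dickey_bf(3, 0.5)      # overwhelming evidence for the effect
#' @export
savage_dickey_bf <- function(posterior_mean, posterior_sd, prior_sd = 1) {
  if (posterior_sd <= 0 || prior_sd <= 0) {
    stop("posterior_sd and prior_sd must be > 0", call. = FALSE)
  }
  stats::dnorm(0, 0, prior_sd) /
    stats::dnorm(0, posterior_mean, posterior_sd)
}

#' Evidence category for a Bayes factor
#'
#' Labels a Bayes factor using the conventional boundaries 1, 3, 10, 30 and
#' 100 (anecdotal / moderate / strong / very strong / extreme evidence for
#' the effect) and their reciprocals for evidence for the null; a Bayes
#' factor of exactly 1 carries no evidence either way.
#'
#' @param bf Bayes factor (> 0).
#' @return Character label, e.g. `"strong"` or `"moderate for null"`.
#' @examples
#' categorize_bf(22.64)  # "strong"
#' categorize_bf(0.28)   # "moderate for null"
#' @export
categorize_bf <- function(bf) {
  if (!is.finite(bf) && bf > 0) return("extreme")
  if (is.na(bf) || bf <= 0) stop("bf must be > 0", call. = FALSE)
  if (bf == 1) return("no evidence")
  bands <- c(1, 3, 10, 30, 100, Inf)
  labels <- c("anecdotal", "moderate", "strong", "very strong", "extreme")
  if (bf > 1) {
    labels[findInterval(bf, bands, left.open = TRUE)]
  } else {
    paste(labels[findInterval(1 / bf, bands, left.open = TRUE)], "for null")
  }
}

#' Display string for a Bayes factor
#'
#' Bayes factors above 1000 are reported as `"> 1000"`; otherwise the value
#' is printed with two decimals.
#'
#' @param bf Bayes factor.
#' @return Character display string.
#' @export
bf_display <- function(bf) {
  if (is.finite(bf) && bf <= 1000) sprintf("%.2f", bf) else "> 1000"
}
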