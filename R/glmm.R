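#' Z-score columns of a data frame
#'
#' Standardizes the named continuous columns over the supplied analysis
#' subset (mean 0, sd 1), so that Gaussian-model coefficients are
#' standardized effects (sd change per sd change) while 0/1 indicator
#' predictors stay on their natural scale and logistic coefficients
#' exponentiate to odds ratios. Centers and scales are stored as attributes
#' so the transform can be inverted with [unstandardize()].
#'
#' @param data A data frame.
#' @param cols Character vector of columns to z-score.
#' @return `data` with the columns replaced by their z-scores and an
#'   attribute `standardize` (named list of `c(center, scale)`).
#' @export
standardize <- function(data, cols) {
  info <- list()
  for (cl in cols) {
    if (!cl %in% names(data)) {
      stop("standardize(): no column named '", cl, "'", call. = FALSE)
    }
    x <- data[[cl]]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("standardize(): column '", cl,
           "' has zero variance over the analysis subset", call. = FALSE)
    }
    data[[cl]] <- (x - m) / s
    info[[cl]] <- c(center = m, scale = s)
  }
  attr(data, "standardize") <- info
  data
}

#' @rdname standardize
#' @param col Column to de-standardize (must have been standardized).
#' @export
unstandardize <- function(data, col) {
  info <- attr(data, "standardize")
  if (is.null(info[[col]])) {
    stop("column '", col, "' was not standardized", call. = FALSE)
  }
  data[[col]] * info[[col]]["scale"] + info[[col]]["center"]
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

# Internal: build the sparse random-effects design for the grouping factors.
build_ranef_design <- function(data, groups) {
  Z <- NULL
  sizes <- integer(0)
  for (g in groups) {
    f <- factor(data[[g]])
    Zg <- Matrix::sparseMatrix(
      i = seq_len(nrow(data)), j = as.integer(f), x = 1,
      dims = c(nrow(data), nlevels(f))
    )
    Z <- if (is.null(Z)) Zg else Matrix::cbind2(Z, Zg)
    sizes <- c(sizes, nlevels(f))
  }
  list(Z = Z, sizes = sizes)
}

#' Bayesian generalized linear mixed model via Laplace approximation
#'
#' Fits a logistic or Gaussian regression with independent Normal priors on
#' the fixed coefficients (`Normal(0, prior_sd^2)` on non-intercept terms; a
#' diffuse `Normal(0, 10^2)` on the intercept) and Normal random intercepts
#' for each grouping factor. For fixed variance parameters, the joint
#' penalized posterior of coefficients and random intercepts is maximized by
#' Newton iterations on a sparse system; random-effect (and residual)
#' standard deviations are chosen by maximizing the Laplace approximation to
#' the marginal likelihood. The posterior of each fixed coefficient is then
#' approximated as Gaussian using the corresponding block of the inverse
#' observed information at the mode, which also yields Savage-Dickey Bayes
#' factors ([savage_dickey_bf()]) and evidence categories
#' ([categorize_bf()]).
#'
#' @param formula Model formula, e.g. `steal ~ below * threshold + round_z`.
#'   Random intercepts are specified through `groups`, not the formula.
#' @param data Data frame holding the (already standardized) model frame.
#' @param groups Character vector of grouping-factor column names (possibly
#'   empty) for random intercepts, e.g. `c("player_id", "set_id")`.
#' @param family `"binomial"` (logit link) or `"gaussian"`.
#' @param prior_sd Prior standard deviation for non-intercept fixed
#'   coefficients (default 1).
#' @param intercept_prior_sd Prior sd for the intercept (default 10,
#'   effectively diffuse).
#' @return An object of class `"micsoc_fit"`: a data frame with one row per
#'   fixed term (`term`, `estimate`, `sd`, `ci_lo`, `ci_hi`, `or`, `bf`,
#'   `bf_display`, `category`) and attributes `n_obs`, `sigma` (named
#'   random-effect sds, plus `residual` for Gaussian), `logpost` (penalized
#'   log-posterior at the mode, a model-evidence proxy), `converged`,
#'   `family`.
#' @export
fit_bayes_glmm <- function(formula, data, groups = character(0),
                           family = c("binomial", "gaussian"),
                           prior_sd = 1, intercept_prior_sd = 10) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (is.logical(y) || is.factor(y)) y <- as.numeric(y) - is.factor(y)
  y <- as.numeric(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  groups <- intersect(groups, names(data))
  keep <- which(stats::complete.cases(y, X))
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n > 0L) {
    # with no data at all, the posterior is the prior (a valid degenerate
    # case); otherwise a constant outcome or predictor is an error
    if (family == "binomial" && (length(unique(y)) < 2L)) {
      stop("outcome '", all.vars(formula)[1],
           "' is constant over the analysis subset", call. = FALSE)
    }
    for (j in seq_len(p)) {
      if (colnames(X)[j] != "(Intercept)" && stats::sd(X[, j]) == 0) {
        stop("predictor '", colnames(X)[j],
             "' has zero variance over the analysis subset", call. = FALSE)
      }
    }
  }
  rd <- if (length(groups)) {
    build_ranef_design(data[keep, , drop = FALSE], groups)
  } else {
    list(Z = NULL, sizes = integer(0))
  }
  q <- sum(rd$sizes)
  M <- Matrix::Matrix(X, sparse = TRUE)
  if (q > 0) M <- Matrix::cbind2(M, rd$Z)
  ranef_block <- rep(seq_along(rd$sizes), rd$sizes)

  prior_prec_beta <- 1 / c(
    ifelse(colnames(X) == "(Intercept)", intercept_prior_sd, prior_sd)
  )^2

  warm <- new.env(parent = emptyenv())
  warm$b <- rep(0, p + q)

  # Penalized joint log-posterior, its mode and Laplace criterion for fixed
  # variance parameters. theta: log sds of random-effect factors, then (for
  # gaussian) log residual sd.
  inner_fit <- function(theta, want = "criterion") {
    sig_u <- exp(theta[seq_along(rd$sizes)])
    sig_e <- if (family == "gaussian") exp(theta[length(theta)]) else NA
    dpen <- c(prior_prec_beta,
              if (q > 0) 1 / sig_u[ranef_block]^2 else numeric(0))
    Dmat <- Matrix::Diagonal(x = dpen)
    b <- warm$b
    if (family == "gaussian") {
      H <- Matrix::crossprod(M) / sig_e^2 + Dmat
      b <- as.numeric(Matrix::solve(H, as.numeric(Matrix::crossprod(M, y)) /
                                      sig_e^2))
      resid <- y - as.numeric(M %*% b)
      loglik <- -n / 2 * log(2 * pi * sig_e^2) - sum(resid^2) / (2 * sig_e^2)
      converged <- TRUE
    } else {
      converged <- FALSE
      for (it in seq_len(100L)) {
        eta <- as.numeric(M %*% b)
        mu <- stats::plogis(eta)
        grad <- as.numeric(Matrix::crossprod(M, y - mu)) - dpen * b
        if (max(abs(grad)) < 1e-8) { converged <- TRUE; break }
        w <- pmax(mu * (1 - mu), 1e-10)
        H <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(w)) %*% M) + Dmat
        step <- as.numeric(Matrix::solve(H, grad))
        # step-halving on the penalized objective
        obj0 <- sum(y * eta - log1pexp(eta)) - sum(dpen * b^2) / 2
        tt <- 1
        repeat {
          bn <- b + tt * step
          etan <- as.numeric(M %*% bn)
          objn <- sum(y * etan - log1pexp(etan)) - sum(dpen * bn^2) / 2
          if (objn >= obj0 - 1e-12 || tt < 1e-4) break
          tt <- tt / 2
        }
        b <- bn
      }
      eta <- as.numeric(M %*% b)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      H <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(w)) %*% M) + Dmat
      loglik <- sum(y * eta - log1pexp(eta))
    }
    warm$b <- b
    # log prior of (beta, u) including normalizing constants that depend on
    # the variance parameters
    logprior <- -sum(dpen * b^2) / 2 +
      sum(log(dpen)) / 2 - (p + q) / 2 * log(2 * pi)
    logdetH <- as.numeric(Matrix::determinant(H, logarithm = TRUE)$modulus)
    crit <- loglik + logprior - logdetH / 2 + (p + q) / 2 * log(2 * pi)
    if (want == "criterion") return(crit)
    list(b = b, H = H, loglik = loglik, logpost = loglik + logprior,
         criterion = crit, converged = converged, sig_u = sig_u,
         sig_e = sig_e)
  }

  n_theta <- length(rd$sizes) + (family == "gaussian")
  if (n_theta == 0L) {
    theta_hat <- numeric(0)
  } else if (n_theta == 1L) {
    opt <- stats::optimize(function(th) -inner_fit(th), c(-6, 3), tol = 1e-4)
    theta_hat <- opt$minimum
  } else {
    opt <- stats::optim(rep(log(0.5), n_theta),
                        function(th) -inner_fit(th),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-6, maxit = 200))
    theta_hat <- opt$par
  }
  fit <- inner_fit(theta_hat, want = "all")
  if (!fit$converged) {
    stop("inner Newton iterations did not converge; check for separation ",
         "or a degenerate model frame", call. = FALSE)
  }
  beta <- fit$b[seq_len(p)]
  if (family == "binomial" && any(abs(beta) > 12)) {
    stop("apparent complete separation for term(s): ",
         paste(colnames(X)[abs(beta) > 12], collapse = ", "), call. = FALSE)
  }
  # posterior sds: beta block of the inverse observed information
  Ip <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                             dims = c(p + q, p))
  Vb <- Matrix::solve(fit$H, Ip)[seq_len(p), , drop = FALSE]
  post_sd <- sqrt(pmax(Matrix::diag(Vb), 0))

  eff_prior_sd <- ifelse(colnames(X) == "(Intercept)",
                         intercept_prior_sd, prior_sd)
  bf <- mapply(savage_dickey_bf, beta, post_sd, eff_prior_sd)
  res <- data.frame(
    term = colnames(X),
    estimate = beta,
    sd = post_sd,
    ci_lo = beta - 1.96 * post_sd,
    ci_hi = beta + 1.96 * post_sd,
    or = if (family == "binomial") exp(beta) else NA_real_,
    bf = bf,
    bf_display = vapply(bf, bf_display, character(1)),
    category = vapply(bf, categorize_bf, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  sig <- stats::setNames(fit$sig_u, groups)
  if (family == "gaussian") sig <- c(sig, residual = fit$sig_e)
  structure(res, class = c("micsoc_fit", "data.frame"),
            n_obs = n, sigma = sig, logpost = fit$logpost,
            criterion = fit$criterion, converged = fit$converged,
            family = family, prior_sd = prior_sd)
}

#' @export
print.micsoc_fit <- function(x, ...) {
  fam <- attr(x, "family")
  cat(sprintf("<micsoc_fit> %s, n = %d\n", fam, attr(x, "n_obs")))
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 3)
  df$sd <- round(df$sd, 3)
  df$ci_lo <- round(df$ci_lo, 3)
  df$ci_hi <- round(df$ci_hi, 3)
  df$or <- round(df$or, 3)
  df$bf <- NULL
  print.data.frame(df, row.names = FALSE)
  sig <- attr(x, "sigma")
  if (length(sig)) {
    cat("random-effect sd:",
        paste(sprintf("%s = %.3f", names(sig), sig), collapse = ", "), "\n")
  }
  invisible(x)
}
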