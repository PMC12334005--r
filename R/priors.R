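#' Scale parameters of the APC models
#'
#' Container for the likelihood standard deviation and the prior scales.
#' The random-effects and random-walk priors use one scale per effect block
#' (`sigmaA`, `sigmaP`, `sigmaC`); the ridge prior unifies the three block
#' scales into a single `lam`.
#'
#' @param sigma likelihood standard deviation (> 0).
#' @param sigmaA,sigmaP,sigmaC block prior standard deviations (> 0).
#' @param lam ridge scale (> 0); defaults to `sigmaA` when the three block
#'   scales are equal.
#' @return A list of class `scale_params`.
#' @export
scale_params <- function(sigma = 1, sigmaA = 1, sigmaP = sigmaA,
                         sigmaC = sigmaA, lam = NULL) {
  if (is.null(lam)) {
    lam <- if (sigmaA == sigmaP && sigmaA == sigmaC) sigmaA else NA_real_
  }
  out <- list(sigma = sigma, sigmaA = sigmaA, sigmaP = sigmaP,
              sigmaC = sigmaC, lam = lam)
  for (nm in c("sigma", "sigmaA", "sigmaP", "sigmaC"))
    if (!is.finite(out[[nm]]) || out[[nm]] <= 0)
      stop(sprintf("%s must be a positive number", nm), call. = FALSE)
  structure(out, class = "scale_params")
}

#' Gaussian APC log-likelihood
#'
#' `-N log(sigma) - sum((y - mu)^2) / (2 sigma^2)` with
#' `mu = b0 + bA[i] + bP[j] + bC[k]`, the additive constant dropped. The
#' likelihood is exactly invariant under [apply_shift()]: this is the
#' identification problem.
#'
#' @param data an [apc_data] with observed `y`.
#' @param e an [effect_set()] on the same grid.
#' @param sigma likelihood standard deviation (> 0).
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(data, e, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive number", call. = FALSE)
  if (anyNA(data$y)) stop("dataset has missing y values", call. = FALSE)
  mu <- cell_means(e, data)
  -nrow(data) * log(sigma) - sum((data$y - mu)^2) / (2 * sigma^2)
}

#' Log-priors of the three regularization models
#'
#' All three are Gaussian shrinkage priors over the sum-to-zero effect
#' blocks, with additive constants dropped:
#'
#' * **Random effects** (`log_prior_re`): independent `Normal(0, sigmaX)`
#'   levels per block; `-(I log sigmaA + J log sigmaP + K log sigmaC)`
#'   minus half the scale-weighted sums of squared levels. Penalizes the
#'   magnitude of each block with its own scale.
#' * **Ridge** (`log_prior_rr`): the same with one shared scale `lam`;
#'   its maximum-a-posteriori solution is the minimum-norm (intrinsic
#'   estimator) solution of the rank-deficient APC system.
#' * **Random walk** (`log_prior_rw`): first differences
#'   `bX[m + 1] - bX[m] ~ Normal(0, sigmaX)`; penalizes adjacent changes
#'   rather than magnitudes, so each block contributes `M - 1` log-scale
#'   terms.
#'
#' The equivalent index-weighted forms, which expose how each prior weights
#' the squared linear component of a block (`sum(v^2)` for magnitude
#' shrinkage, `M - 1` for the random walk), are available as
#' `log_prior_re_weighted` and `log_prior_rw_weighted`; they evaluate the
#' prior at the general solution [apply_shift()]`(e, s)` without forming it.
#'
#' @param e an [effect_set()].
#' @param scales a [scale_params()].
#' @param lam ridge scale (> 0).
#' @param s identification shift at which the weighted forms evaluate the
#'   prior (default 0: the particular solution `e` itself).
#' @return A scalar log-density (up to the stated constant).
#' @name log_priors
NULL

#' @rdname log_priors
#' @export
log_prior_re <- function(e, scales) {
  stopifnot(inherits(e, "effect_set"), inherits(scales, "scale_params"))
  g <- e$grid
  -(g$I * log(scales$sigmaA) + g$J * log(scales$sigmaP) +
      g$K * log(scales$sigmaC)) -
    0.5 * (sum(e$bA^2) / scales$sigmaA^2 +
           sum(e$bP^2) / scales$sigmaP^2 +
           sum(e$bC^2) / scales$sigmaC^2)
}

#' @rdname log_priors
#' @export
log_prior_rr <- function(e, lam) {
  stopifnot(inherits(e, "effect_set"))
  if (!is.finite(lam) || lam <= 0)
    stop("lam must be a positive number", call. = FALSE)
  g <- e$grid
  -(g$I + g$J + g$K) * log(lam) -
    (sum(e$bA^2) + sum(e$bP^2) + sum(e$bC^2)) / (2 * lam^2)
}

#' @rdname log_priors
#' @export
log_prior_rw <- function(e, scales) {
  stopifnot(inherits(e, "effect_set"), inherits(scales, "scale_params"))
  g <- e$grid
  -((g$I - 1) * log(scales$sigmaA) + (g$J - 1) * log(scales$sigmaP) +
      (g$K - 1) * log(scales$sigmaC)) -
    0.5 * (sum(diff(e$bA)^2) / scales$sigmaA^2 +
           sum(diff(e$bP)^2) / scales$sigmaP^2 +
           sum(diff(e$bC)^2) / scales$sigmaC^2)
}

#' @rdname log_priors
#' @export
log_prior_re_weighted <- function(e, scales, s = 0) {
  stopifnot(inherits(e, "effect_set"), inherits(scales, "scale_params"))
  g <- e$grid
  block <- function(b, M, sig, sgn) {
    v <- centered_index(M)
    d <- decompose(b, v)
    -M * log(sig) -
      ((d$slope + sgn * s)^2 * sum(v^2) + sum(d$nonlinear^2)) / (2 * sig^2)
  }
  block(e$bA, g$I, scales$sigmaA, +1) +
    block(e$bP, g$J, scales$sigmaP, -1) +
    block(e$bC, g$K, scales$sigmaC, +1)
}

#' @rdname log_priors
#' @export
log_prior_rw_weighted <- function(e, scales, s = 0) {
  stopifnot(inherits(e, "effect_set"), inherits(scales, "scale_params"))
  g <- e$grid
  block <- function(b, M, sig, sgn) {
    d <- decompose(b, centered_index(M))
    sl <- d$slope + sgn * s
    nl <- d$nonlinear
    -(M - 1) * log(sig) -
      (sl^2 * (M - 1) + 2 * sl * (nl[M] - nl[1L]) + sum(diff(nl)^2)) /
        (2 * sig^2)
  }
  block(e$bA, g$I, scales$sigmaA, +1) +
    block(e$bP, g$J, scales$sigmaP, -1) +
    block(e$bC, g$K, scales$sigmaC, +1)
}

#' Log-posterior kernel of an APC model
#'
#' Log-likelihood plus the model's log-prior. Scale hyperpriors are flat on
#' their allowed ranges and contribute zero, so the three models differ only
#' through their effect priors.
#'
#' @param kind one of `"random_effects"`, `"ridge"`, `"random_walk"`.
#' @param e an [effect_set()].
#' @param scales a [scale_params()] (for `"ridge"` its `lam` is used).
#' @param data an [apc_data].
#' @return A scalar log-posterior kernel value.
#' @export
log_posterior <- function(kind, e, scales, data) {
  kind <- match.arg(kind, apc_model_kinds())
  lp <- switch(kind,
    random_effects = log_prior_re(e, scales),
    ridge          = log_prior_rr(e, scales$lam),
    random_walk    = log_prior_rw(e, scales))
  log_likelihood(data, e, scales$sigma) + lp
}

#' The three model kinds
#'
#' @return Character vector of the recognized model names.
#' @export
apc_model_kinds <- function() c("random_effects", "ridge", "random_walk")
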