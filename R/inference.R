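#' Sampler configuration
#'
#' Default settings: 4 chains of 2000 iterations each, the first 500
#' discarded as warmup and the remainder thinned by 3, retaining 500 draws
#' per chain (2000 pooled). The random-effects model's block scales are
#' bounded below at 0.05 so chains can escape the degenerate small-scale
#' region; all other scales use a negligible bound.
#'
#' @param chains number of chains.
#' @param iterations total iterations per chain (including warmup).
#' @param warmup iterations discarded per chain (< `iterations`).
#' @param thin thinning interval for retained draws.
#' @param seed integer RNG seed for the whole fit.
#' @param re_sigma_lower lower bound on `sigmaA`, `sigmaP`, `sigmaC` in the
#'   random-effects model.
#' @param min_sigma negligible lower bound applied to every other scale.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, iterations = 2000L, warmup = 500L,
                           thin = 3L, seed = 1L, re_sigma_lower = 0.05,
                           min_sigma = 1e-6) {
  chains <- check_count(chains, "chains")
  iterations <- check_count(iterations, "iterations")
  warmup <- check_count(warmup, "warmup")
  thin <- check_count(thin, "thin")
  if (warmup >= iterations) stop("warmup must be < iterations", call. = FALSE)
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 thin = thin, seed = as.integer(seed),
                 re_sigma_lower = re_sigma_lower, min_sigma = min_sigma),
            class = "sampler_config")
}

#' Fit a Bayesian-regularized APC model by blocked Gibbs sampling
#'
#' The posterior combines the Gaussian APC likelihood with one of the three
#' shrinkage priors (see [log_posterior()]); scale hyperpriors are flat
#' above their lower bounds. Sum-to-zero is imposed hard: each block is
#' parameterized by its first M - 1 levels with the last level the negative
#' partial sum, which keeps every block's level identified against the
#' intercept. Because the model is conditionally conjugate, the sampler
#' alternates an exact joint multivariate-normal draw of the intercept and
#' all free effect coordinates with truncated inverse-gamma draws of the
#' squared scales -- an exact MCMC kernel for the stated posterior, fully
#' deterministic given the seed.
#'
#' @param kind one of `"random_effects"`, `"ridge"`, `"random_walk"`.
#' @param data an [apc_data] with observed `y`.
#' @param config a [sampler_config()].
#' @return An object of class `apc_fit`: pooled retained `draws` (matrix,
#'   one named column per parameter plus `lp__`), the `chain` id of each
#'   row, per-parameter posterior `medians` and split-R-hat values
#'   (`rhat`), the `converged` flag (all R-hat below 1.05), and the model
#'   metadata.
#' @export
fit_apc <- function(kind, data, config = sampler_config()) {
  kind <- match.arg(kind, apc_model_kinds())
  stopifnot(inherits(data, "apc_data"), inherits(config, "sampler_config"))
  if (nrow(data) == 0L || anyNA(data$y))
    stop("dataset must be nonempty with observed y", call. = FALSE)
  g <- attr(data, "grid")
  I <- g$I; J <- g$J; K <- g$K
  if (kind == "random_walk" && min(I, J, K) < 3L)
    stop("the random-walk prior needs at least 3 levels per block",
         call. = FALSE)

  # design in the free (sum-to-zero) parameterization
  N <- nrow(data)
  drop_last <- function(ind, M) {
    Full <- matrix(0, N, M)
    Full[cbind(seq_len(N), ind)] <- 1
    Full %*% rbind(diag(M - 1L), -1)
  }
  X <- cbind(1, drop_last(data$i, I), drop_last(data$j, J),
             drop_last(data$k, K))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, data$y))
  yty <- sum(data$y^2)

  # per-block prior structure matrices on the free coordinates
  Tmat <- function(M) rbind(diag(M - 1L), -1)
  struct <- function(M) {
    Tm <- Tmat(M)
    if (kind == "random_walk") {
      D <- diff(diag(M))
      crossprod(D %*% Tm)
    } else crossprod(Tm)
  }
  RA <- struct(I); RP <- struct(J); RC <- struct(K)

  model <- match(kind, apc_model_kinds()) - 1L
  block_lb <- if (kind == "random_effects")
    rep(config$re_sigma_lower, 3L) else rep(config$min_sigma, 3L)

  pars <- c("b0",
            sprintf("bA[%d]", seq_len(I)), sprintf("bP[%d]", seq_len(J)),
            sprintf("bC[%d]", seq_len(K)), "sigma",
            if (kind == "ridge") "lambda" else c("sigmaA", "sigmaP", "sigmaC"))

  p <- 1L + (I - 1L) + (J - 1L) + (K - 1L)
  set.seed(config$seed)
  chains <- lapply(seq_len(config$chains), function(ch) {
    theta0 <- stats::rnorm(p, 0, 0.1)
    sigma0 <- stats::sd(data$y) * stats::runif(1, 0.5, 2)
    scales0 <- pmax(stats::runif(3, 0.1, 1), block_lb + 1e-3)
    .gibbs_chain(XtX, Xty, yty, N, I, J, K, model, RA, RP, RC,
                 config$iterations, config$warmup, config$thin,
                 theta0, sigma0, scales0, config$min_sigma, block_lb)
  })
  per_chain <- nrow(chains[[1L]])
  draws <- do.call(rbind, chains)
  colnames(draws) <- c(pars, "lp__")
  chain_id <- rep(seq_len(config$chains), each = per_chain)

  rh <- apply(draws[, pars, drop = FALSE], 2L, function(x)
    rhat(matrix(x, nrow = per_chain)))
  medians <- apply(draws[, pars, drop = FALSE], 2L, stats::median)

  structure(list(kind = kind, grid = g, config = config, draws = draws,
                 chain = chain_id, medians = medians, rhat = rh,
                 converged = check_convergence(rh)),
            class = "apc_fit")
}

#' Split R-hat convergence diagnostic
#'
#' Classical split-R-hat: each chain is halved, and the diagnostic is the
#' usual between/within variance ratio over the resulting half-chains.
#' Inputs with zero variance everywhere return 1 by convention.
#'
#' @param draws a matrix with one column per chain (rows are iterations),
#'   or a list of equal-length numeric vectors.
#' @return The scalar R-hat.
#' @export
rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("rhat needs at least 2 chains", call. = FALSE)
  if (nrow(draws) < 2L) stop("rhat needs at least 2 draws per chain", call. = FALSE)
  half <- nrow(draws) %/% 2L
  split_mat <- cbind(draws[seq_len(half), , drop = FALSE],
                     draws[half + seq_len(half), , drop = FALSE])
  W <- mean(apply(split_mat, 2L, stats::var))
  B <- half * stats::var(colMeans(split_mat))
  if (W == 0) return(1)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

#' Declare convergence from R-hat values
#'
#' @param x an [fit_apc()] result or a named vector of R-hat values.
#' @param threshold convergence threshold (default 1.05).
#' @return `TRUE` iff every parameter's R-hat is below the threshold.
#' @export
check_convergence <- function(x, threshold = 1.05) {
  rh <- if (inherits(x, "apc_fit")) x$rhat else x
  if (length(rh) == 0L || anyNA(rh))
    stop("no R-hat values to check", call. = FALSE)
  all(rh < threshold)
}

#' Posterior-median point estimates of the effects
#'
#' Per-parameter medians of the pooled post-warmup thinned draws, returned
#' as an [effect_set()]. Medians of sum-to-zero draws are only approximately
#' zero-sum, so each block is recentred by its mean; block-wise constants do
#' not move the identification-shift statistic [solve_s()], so this has no
#' effect on any bias evaluation.
#'
#' @param fit an [fit_apc()] result.
#' @return An `effect_set` of posterior medians.
#' @export
point_estimates <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  g <- fit$grid
  m <- fit$medians
  pick <- function(block, M) {
    v <- m[sprintf("%s[%d]", block, seq_len(M))]
    v - mean(v)
  }
  effect_set(m[["b0"]], pick("bA", g$I), pick("bP", g$J), pick("bC", g$K),
             grid = g)
}

#' Posterior-median scale estimates
#'
#' @param fit an [fit_apc()] result.
#' @return A [scale_params()] built from the scale medians (for the ridge
#'   model the single `lambda` median fills all three block scales).
#' @export
scale_estimates <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  m <- fit$medians
  if (fit$kind == "ridge")
    scale_params(sigma = m[["sigma"]], sigmaA = m[["lambda"]])
  else
    scale_params(sigma = m[["sigma"]], sigmaA = m[["sigmaA"]],
                 sigmaP = m[["sigmaP"]], sigmaC = m[["sigmaC"]])
}

#' @export
print.apc_fit <- function(x, ...) {
  cat(sprintf("Bayesian APC fit (%s prior), %d x %d grid\n",
              gsub("_", " ", x$kind), x$grid$I, x$grid$J))
  cat(sprintf("  %d chains x %d retained draws; max R-hat = %.3f (%s)\n",
              x$config$chains, nrow(x$draws) / x$config$chains,
              max(x$rhat), if (x$converged) "converged" else "NOT converged"))
  print(point_estimates(x), ...)
  invisible(x)
}

#' Serialize a fit summary to JSON
#'
#' Writes the posterior medians, the R-hat table, and the convergence flag.
#'
#' @param fit an [fit_apc()] result.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "apc_fit"))
  obj <- list(kind = fit$kind,
              grid = list(I = fit$grid$I, J = fit$grid$J, K = fit$grid$K),
              medians = as.list(fit$medians),
              rhat = as.list(fit$rhat),
              converged = fit$converged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Export pooled draws as a long-format CSV
#'
#' Columns: `chain`, `iteration` (index among retained draws within the
#' chain), `parameter`, `value`.
#'
#' @param fit an [fit_apc()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "apc_fit"))
  pars <- setdiff(colnames(fit$draws), "lp__")
  per_chain <- nrow(fit$draws) / fit$config$chains
  long <- data.frame(
    chain = rep(fit$chain, times = length(pars)),
    iteration = rep(rep(seq_len(per_chain), fit$config$chains),
                    times = length(pars)),
    parameter = rep(pars, each = nrow(fit$draws)),
    value = as.vector(fit$draws[, pars]))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
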