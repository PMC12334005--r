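#' Trigonometric artificial parameters for simulation studies
#'
#' Builds true effect vectors of the form
#' `beta_m = beta0 + slope * v_m + amp * cos(pi * m)` per block, where `v`
#' is the centered index. The alternating cosine term carries the nonlinear
#' component; it is not exactly index-orthogonal (its projection onto `v`
#' leaks a slope of `amp * sum(v * (-1)^m) / sum(v^2)`, about 0.003 at
#' amplitude 0.05 on ten levels), and the decomposition reports that
#' leakage rather than correcting it. The intercept correction
#' `beta0 = -amp * (cos(pi * M) - 1) / (2 * M)` restores the exact
#' sum-to-zero condition, which the alternating cosine breaks when `M` is
#' odd. `cos(pi * m)` is evaluated as `(-1)^m` exactly.
#'
#' @param grid an [apc_grid()].
#' @param slopes length-3 numeric: linear slopes (age, period, cohort) per
#'   unit index.
#' @param amps length-3 numeric: nonlinear cosine amplitudes (age, period,
#'   cohort).
#' @param gamma observation noise standard deviation (> 0).
#' @return An object of class `apc_true_params`: the grid, the generating
#'   slopes/amplitudes/intercepts, the realized effect vectors `betaA`,
#'   `betaP`, `betaC` (each summing to zero), and `gamma`.
#' @examples
#' g <- apc_grid(10, 10)
#' tp <- make_trig_params(g, slopes = c(0, 0, 0.1), amps = c(0, 0, 0.05))
#' sum(tp$betaC)  # 0
#' @export
make_trig_params <- function(grid, slopes = c(0, 0, 0), amps = c(0, 0, 0),
                             gamma = 0.1) {
  stopifnot(inherits(grid, "apc_grid"))
  slopes <- as.numeric(slopes); amps <- as.numeric(amps)
  if (length(slopes) != 3L || length(amps) != 3L)
    stop("slopes and amps must each have length 3 (age, period, cohort)",
         call. = FALSE)
  if (!is.finite(gamma) || gamma < 0)
    stop("gamma must be a nonnegative number", call. = FALSE)
  lens <- c(grid$I, grid$J, grid$K)
  intercepts <- -amps * (alt_cos(lens) - 1) / (2 * lens)
  make_block <- function(b0, slope, amp, M)
    b0 + slope * centered_index(M) + amp * alt_cos(seq_len(M))
  betas <- Map(make_block, intercepts, slopes, amps, lens)
  structure(list(grid = grid, slopes = slopes, amps = amps,
                 intercepts = intercepts,
                 betaA = betas[[1L]], betaP = betas[[2L]], betaC = betas[[3L]],
                 gamma = gamma),
            class = "apc_true_params")
}

# cos(pi * m) for integer m, computed exactly as (-1)^m
alt_cos <- function(m) ifelse(m %% 2 == 0, 1, -1)

#' @export
print.apc_true_params <- function(x, ...) {
  cat(sprintf(
    "APC artificial parameters on a %d x %d grid, gamma = %g\n",
    x$grid$I, x$grid$J, x$gamma))
  m <- rbind(slope = x$slopes, amplitude = x$amps, intercept = x$intercepts)
  colnames(m) <- c("age", "period", "cohort")
  print(m, ...)
  invisible(x)
}

#' @export
as_effect_set.apc_true_params <- function(x, ...)
  effect_set(0, x$betaA, x$betaP, x$betaC, grid = x$grid, tol = 1e-10)

#' Generate artificial APC data
#'
#' Each row's response is the cell mean `betaA[i] + betaP[j] + betaC[k]`
#' plus independent `Normal(0, gamma)` noise. Row layout follows
#' [expand_design()] (age outermost, replicate innermost), so a fixed seed
#' reproduces the dataset bit for bit.
#'
#' @param params an [make_trig_params()] specification.
#' @param replicates observations per cell (default 10, giving
#'   `N = I * J * 10`).
#' @param seed integer RNG seed.
#' @return An [apc_data] with `N = I * J * replicates` rows.
#' @export
generate_data <- function(params, replicates = 10L, seed = 1L) {
  stopifnot(inherits(params, "apc_true_params"))
  skel <- expand_design(params$grid, replicates)
  mu <- cell_means(as_effect_set(params), skel)
  set.seed(seed)
  skel$y <- mu + stats::rnorm(nrow(skel), 0, params$gamma)
  skel
}

#' The 13 sign-pattern cases of the systematic simulation design
#'
#' All combinations of slope signs in \{-, 0, +\} over the three effects
#' give 27 patterns; removing the all-zero pattern and one member of each
#' global sign-flip pair leaves 13 canonical cases. A "+" sets the block's
#' linear slope to 0.1 and its nonlinear amplitude to 0.05; "-" negates
#' both; "0" zeroes both, so the nonlinear components stay small and the
#' index-weight pressure on the cohort slope dominates.
#'
#' @return A data frame with columns `case`, `A`, `P`, `C` (sign characters)
#'   and the numeric `slopeA`, `slopeP`, `slopeC`, `ampA`, `ampP`, `ampC`.
#' @export
enumerate_sim1_cases <- function() {
  signs <- matrix(c(
    "+", "0", "0",
    "0", "+", "0",
    "0", "0", "+",
    "+", "+", "0",
    "+", "0", "+",
    "0", "+", "+",
    "0", "+", "-",
    "-", "0", "+",
    "-", "+", "0",
    "+", "+", "-",
    "+", "+", "+",
    "-", "+", "+",
    "+", "-", "+"), ncol = 3L, byrow = TRUE)
  num <- matrix(c(`+` = 1, `0` = 0, `-` = -1)[signs], ncol = 3L)
  data.frame(case = seq_len(13L),
             A = signs[, 1L], P = signs[, 2L], C = signs[, 3L],
             slopeA = 0.1 * num[, 1L], slopeP = 0.1 * num[, 2L],
             slopeC = 0.1 * num[, 3L],
             ampA = 0.05 * num[, 1L], ampP = 0.05 * num[, 2L],
             ampC = 0.05 * num[, 3L])
}

#' Random component draws for the randomized simulation designs
#'
#' `draw_sim2` draws the six amounts of change (three linear slopes, three
#' nonlinear amplitudes) independently from a centered normal with variance
#' 0.1 (standard deviation `sqrt(0.1)`), so patterns with only linear
#' components and only nonlinear components are equally likely.
#'
#' `draw_sim3` first draws each block's nonlinear amplitude from the same
#' centered normal with variance 0.1 and then its slope from
#' `Normal(0, sd = |amplitude|)` -- the slopes keep the Sim-2 marginal
#' scale (`E[slope^2] = E[amp^2] = 0.1`) but shrink with the amplitude,
#' making near-pure-linear patterns vanishingly rare -- the data-generating
#' regime in which regularization's use of nonlinear components to assign
#' linear ones is coherent. With `literal = TRUE` the period and cohort
#' slope scales reuse the age amplitude's absolute value instead of their
#' own.
#'
#' @param seed integer RNG seed.
#' @param literal couple all three slope scales to the age amplitude
#'   (`draw_sim3` only).
#' @return A list of class `apc_component_draw` with numeric `slopes` and
#'   `amps`, each length 3 (age, period, cohort).
#' @export
draw_sim2 <- function(seed) {
  set.seed(seed)
  slopes <- stats::rnorm(3L, 0, sqrt(0.1))
  amps <- stats::rnorm(3L, 0, sqrt(0.1))
  structure(list(slopes = slopes, amps = amps), class = "apc_component_draw")
}

#' @rdname draw_sim2
#' @export
draw_sim3 <- function(seed, literal = FALSE) {
  set.seed(seed)
  amps <- stats::rnorm(3L, 0, sqrt(0.1))
  sd_slopes <- if (literal) rep(abs(amps[1L]), 3L) else abs(amps)
  slopes <- ifelse(sd_slopes == 0, 0, stats::rnorm(3L, 0, sd_slopes))
  structure(list(slopes = slopes, amps = amps), class = "apc_component_draw")
}

#' Random centered polynomial effect and its linear/nonlinear split
#'
#' Builds an effect vector `eta` over `M` levels as a random-weight
#' combination of standardized powers of the centered index:
#' `z[, h]` is `v^h` centered to mean zero and scaled to unit population
#' standard deviation, and `eta = z %*% w` recentered. The linear component
#' `eta_L` is the least-squares slope of `eta` on `v` (the minimizer of the
#' squared nonlinear residual), and `SD_NL` is the population standard
#' deviation of the residual. Used to study how often polynomial
#' data-generating processes produce near-pure-linear patterns as the
#' degree `H` grows.
#'
#' @param M number of levels (at least 3).
#' @param H polynomial degree (at least 1).
#' @param weights optional numeric vector of length `H`; drawn from
#'   `Normal(0, 0.1)` when omitted.
#' @param seed integer RNG seed used when `weights` is omitted.
#' @return A list of class `apc_poly_spec` with `M`, `H`, `weights`, the
#'   standardized power matrix `z`, `eta`, `eta_L`, `eta_NL`, and `SD_NL`.
#' @export
polynomial_params <- function(M, H, weights = NULL, seed = NULL) {
  M <- check_count(M, "M", min = 3L)
  H <- check_count(H, "H", min = 1L)
  if (is.null(weights)) {
    if (!is.null(seed)) set.seed(seed)
    weights <- stats::rnorm(H, 0, 0.1)
  }
  if (length(weights) != H) stop("weights must have length H", call. = FALSE)
  v <- centered_index(M)
  z <- vapply(seq_len(H), function(h) {
    p <- v^h
    ctr <- p - mean(p)
    sdp <- sqrt(mean(ctr^2))
    if (sdp == 0)
      stop(sprintf("power column h = %d has zero variance", h), call. = FALSE)
    ctr / sdp
  }, numeric(M))
  eta <- as.numeric(z %*% weights)
  eta <- eta - mean(eta)
  eta_L <- sum(v * eta) / sum(v^2)
  eta_NL <- eta - eta_L * v
  structure(list(M = M, H = H, weights = weights, z = z, eta = eta,
                 eta_L = eta_L, eta_NL = eta_NL,
                 SD_NL = sqrt(mean(eta_NL^2))),
            class = "apc_poly_spec")
}

#' Serialize artificial-parameter specifications to and from JSON
#'
#' Covers both [make_trig_params()] specifications (grid dimensions,
#' slopes, amplitudes, noise scale; realized vectors are rebuilt on read)
#' and [draw_sim2()]/[draw_sim3()] component draws.
#'
#' @param x an `apc_true_params` or `apc_component_draw`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return `params_to_json`: the JSON string (invisibly when `path` is
#'   given); `params_from_json`: the reconstructed object.
#' @export
params_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "apc_true_params")) {
    list(type = "trig_params", I = x$grid$I, J = x$grid$J,
         slopes = x$slopes, amps = x$amps, gamma = x$gamma)
  } else if (inherits(x, "apc_component_draw")) {
    list(type = "component_draw", slopes = x$slopes, amps = x$amps)
  } else stop("unsupported object", call. = FALSE)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname params_to_json
#' @param json a JSON string or path produced by `params_to_json`.
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  switch(obj$type,
    trig_params = make_trig_params(apc_grid(obj$I, obj$J), obj$slopes,
                                   obj$amps, obj$gamma),
    component_draw = structure(list(slopes = obj$slopes, amps = obj$amps),
                               class = "apc_component_draw"),
    stop("unrecognized parameter JSON", call. = FALSE))
}
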