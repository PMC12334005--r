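#' Sum-to-zero effect set
#'
#' The parameter container of the APC model: an intercept and one effect
#' vector per block (age, period, cohort), each constrained to sum to zero.
#' Construction fails if a block violates the constraint by more than `tol`.
#'
#' @param b0 intercept.
#' @param bA,bP,bC numeric effect vectors of lengths I, J, K.
#' @param grid optional [apc_grid()]; if supplied, block lengths are checked
#'   against it (and `K = I + J - 1` is implied).
#' @param tol absolute tolerance for the sum-to-zero check.
#' @return An object of class `effect_set`.
#' @export
effect_set <- function(b0, bA, bP, bC, grid = NULL, tol = 1e-8) {
  bA <- as.numeric(bA); bP <- as.numeric(bP); bC <- as.numeric(bC)
  if (length(bA) < 2L || length(bP) < 2L || length(bC) < 2L)
    stop("each effect block needs at least 2 levels", call. = FALSE)
  if (is.null(grid)) {
    if (length(bC) != length(bA) + length(bP) - 1L)
      stop("block lengths must satisfy K = I + J - 1", call. = FALSE)
    grid <- apc_grid(length(bA), length(bP))
  }
  stopifnot(inherits(grid, "apc_grid"))
  if (length(bA) != grid$I || length(bP) != grid$J || length(bC) != grid$K)
    stop("effect block lengths do not match the grid", call. = FALSE)
  for (s in c(A = sum(bA), P = sum(bP), C = sum(bC)))
    if (abs(s) > tol)
      stop(sprintf("effect block violates sum-to-zero (|sum| = %.3g > %.3g)",
                   abs(s), tol), call. = FALSE)
  structure(list(b0 = as.numeric(b0)[1L], bA = bA, bP = bP, bC = bC,
                 grid = grid),
            class = "effect_set")
}

#' @export
print.effect_set <- function(x, digits = 4L, ...) {
  cat(sprintf("APC effect set (I = %d, J = %d, K = %d), b0 = %.*g\n",
              x$grid$I, x$grid$J, x$grid$K, digits, x$b0))
  sl <- effect_slopes(x)
  cat(sprintf("  slopes: age %.*g, period %.*g, cohort %.*g\n",
              digits, sl[["age"]], digits, sl[["period"]],
              digits, sl[["cohort"]]))
  invisible(x)
}

#' Coerce to an effect set
#'
#' @param x an `effect_set`, or an object carrying realized effect vectors
#'   (such as the artificial-parameter specification of
#'   [make_trig_params()]).
#' @param ... unused.
#' @export
as_effect_set <- function(x, ...) UseMethod("as_effect_set")

#' @export
as_effect_set.effect_set <- function(x, ...) x

#' Linear/nonlinear decomposition of an effect vector
#'
#' Regresses an effect block on its centered index: the fitted slope is the
#' block's linear component (per unit index) and the residual its nonlinear
#' component, orthogonal to the index by construction. Only the nonlinear
#' component is identified in APC analysis; the slope absorbs the arbitrary
#' identification shift.
#'
#' @param b numeric effect vector (length at least 2).
#' @param v centered index; defaults to [centered_index()] of the matching
#'   length.
#' @return A list of class `apc_decomposition` with elements `slope`
#'   (numeric scalar) and `nonlinear` (numeric vector), satisfying
#'   `slope * v + nonlinear == b` and `sum(v * nonlinear) == 0`.
#' @export
decompose <- function(b, v = centered_index(length(b))) {
  b <- as.numeric(b)
  if (length(b) < 2L) stop("need at least 2 levels to decompose", call. = FALSE)
  if (length(v) != length(b)) stop("length mismatch between b and v", call. = FALSE)
  slope <- sum(v * b) / sum(v * v)
  structure(list(slope = slope, nonlinear = b - slope * v),
            class = "apc_decomposition")
}

#' Centered-index slopes of the three blocks of an effect set
#'
#' @param e an [effect_set()].
#' @return Named numeric vector with elements `age`, `period`, `cohort`.
#' @export
effect_slopes <- function(e) {
  stopifnot(inherits(e, "effect_set"))
  c(age    = decompose(e$bA)$slope,
    period = decompose(e$bP)$slope,
    cohort = decompose(e$bC)$slope)
}

#' Apply the identification shift to an effect set
#'
#' The APC general solution adds `s * v` to the age and cohort blocks and
#' subtracts `s * v` from the period block (with `v` the centered index of
#' each block). Every choice of `s` yields identical fitted cell means
#' because the centered indexes satisfy `vA_i - vP_j + vC_k = 0`; only the
#' split of the overall linear trend among the three effects changes.
#'
#' @param e an [effect_set()].
#' @param s shift (any real number).
#' @return A new `effect_set` with slopes changed by `(+s, -s, +s)` and
#'   nonlinear components untouched.
#' @export
apply_shift <- function(e, s) {
  stopifnot(inherits(e, "effect_set"))
  s <- as.numeric(s)[1L]
  g <- e$grid
  effect_set(e$b0,
             e$bA + s * centered_index(g$I),
             e$bP - s * centered_index(g$J),
             e$bC + s * centered_index(g$K),
             grid = g)
}

#' Fitted cell means of an effect set on a dataset's rows
#'
#' @param e an [effect_set()].
#' @param data an [apc_data] (only the index columns are used).
#' @return Numeric vector `b0 + bA[i] + bP[j] + bC[k]`, one entry per row.
#' @export
cell_means <- function(e, data) {
  stopifnot(inherits(e, "effect_set"), inherits(data, "apc_data"))
  g <- attr(data, "grid")
  if (g$I != e$grid$I || g$J != e$grid$J)
    stop("effect set and dataset use different grids", call. = FALSE)
  e$b0 + e$bA[data$i] + e$bP[data$j] + e$bC[data$k]
}
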