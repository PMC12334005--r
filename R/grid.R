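#' Construct an age-period-cohort index grid
#'
#' An APC grid records the number of age groups `I`, period groups `J`, and
#' the implied number of birth cohorts `K = I + J - 1` on an equal-interval
#' Lexis table. The cohort index of cell (i, j) is `k = j - i + I`, so the
#' oldest cohort (k = 1) is observed at (i = I, j = 1) and the youngest
#' (k = K) at (i = 1, j = J).
#'
#' @param I number of age groups (integer, at least 2).
#' @param J number of period groups (integer, at least 2).
#' @return An object of class `apc_grid` with elements `I`, `J`, `K`.
#' @examples
#' g <- apc_grid(10, 10)
#' g$K                 # 19
#' cohort_index(g, 10, 1)  # oldest cohort: k = 1
#' @export
apc_grid <- function(I, J) {
  I <- check_count(I, "I", min = 2L)
  J <- check_count(J, "J", min = 2L)
  structure(list(I = I, J = J, K = I + J - 1L), class = "apc_grid")
}

#' @export
print.apc_grid <- function(x, ...) {
  cat(sprintf("APC grid: I = %d age x J = %d period groups (K = %d cohorts)\n",
              x$I, x$J, x$K))
  invisible(x)
}

#' Cohort index of an age-period cell
#'
#' @param grid an [apc_grid()].
#' @param i,j age and period indices (vectorized, 1-based).
#' @return Integer cohort indices `k = j - i + I` in `1..K`.
#' @export
cohort_index <- function(grid, i, j) {
  stopifnot(inherits(grid, "apc_grid"))
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1L | i > grid$I) || any(j < 1L | j > grid$J))
    stop("age/period indices out of range for this grid", call. = FALSE)
  j - i + grid$I
}

#' Centered index of a block of M ordered levels
#'
#' Entry m is `m - (M + 1)/2`, so the vector sums to zero and steps by one.
#' These are the index vectors whose linear combinations span the
#' unidentified direction of the APC model.
#'
#' @param M block length (at least 2).
#' @return Numeric vector of length `M`.
#' @examples
#' centered_index(3)   # -1 0 1
#' @export
centered_index <- function(M) {
  M <- check_count(M, "M", min = 2L)
  seq_len(M) - (M + 1) / 2
}

#' Gap between the cohort/period index-weight ratios of the two prior families
#'
#' Magnitude-shrinkage priors weight the squared linear component of a block
#' by the sum of squared centered indexes, while the random-walk prior
#' weights it by the number of adjacent pairs (block length minus one). This
#' function returns the difference of the cohort-to-period weight ratios,
#' `sum(vC^2)/sum(vP^2) - (K - 1)/(J - 1)`, which is strictly positive for
#' every grid: magnitude shrinkage always presses harder on the cohort slope.
#'
#' @inheritParams apc_grid
#' @return A positive number, equal to the closed form
#'   `(K - 1) * (2 * J + I) * (I - 1) / (J * (J + 1) * (J - 1))`.
#' @export
index_weight_gap <- function(I, J) {
  g <- apc_grid(I, J)
  vP <- centered_index(g$J)
  vC <- centered_index(g$K)
  sum(vC^2) / sum(vP^2) - (g$K - 1) / (g$J - 1)
}

#' Expand a grid into a long-format dataset skeleton
#'
#' Rows are laid out deterministically: age index outermost, period index
#' next, replicate innermost, so seeded generation is reproducible.
#'
#' @param grid an [apc_grid()].
#' @param replicates observations per (i, j) cell (at least 1).
#' @return An [apc_data] object with `N = I * J * replicates` rows and
#'   `y = NA`, ready to be filled by a generator.
#' @export
expand_design <- function(grid, replicates = 1L) {
  stopifnot(inherits(grid, "apc_grid"))
  replicates <- check_count(replicates, "replicates", min = 1L)
  i <- rep(seq_len(grid$I), each = grid$J * replicates)
  j <- rep(rep(seq_len(grid$J), each = replicates), times = grid$I)
  apc_data(data.frame(i = i, j = j, k = j - i + grid$I, y = NA_real_), grid)
}

#' Long-format APC dataset
#'
#' Wraps a data frame with columns `i`, `j`, `k`, `y` and validates the
#' cohort relation `k = j - i + I` against the grid.
#'
#' @param df data frame with integer columns `i`, `j`, `k` and numeric `y`.
#' @param grid an [apc_grid()]; inferred from the index ranges if omitted.
#' @return The data frame, classed `apc_data`, with the grid attached as
#'   attribute `"grid"`.
#' @export
apc_data <- function(df, grid = NULL) {
  need <- c("i", "j", "k", "y")
  if (!all(need %in% names(df)))
    stop("apc_data needs columns i, j, k, y", call. = FALSE)
  df <- as.data.frame(df)[need]
  df$i <- as.integer(df$i); df$j <- as.integer(df$j); df$k <- as.integer(df$k)
  df$y <- as.numeric(df$y)
  if (is.null(grid)) grid <- apc_grid(max(df$i), max(df$j))
  stopifnot(inherits(grid, "apc_grid"))
  if (any(df$i < 1L | df$i > grid$I) || any(df$j < 1L | df$j > grid$J))
    stop("indices out of range for the grid", call. = FALSE)
  if (any(df$k != df$j - df$i + grid$I))
    stop("cohort index violates k = j - i + I", call. = FALSE)
  structure(df, grid = grid, class = c("apc_data", "data.frame"))
}

#' @export
print.apc_data <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("APC dataset: N = %d rows on a %d x %d grid (K = %d)\n",
              nrow(x), g$I, g$J, g$K))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read / write an APC dataset as CSV
#'
#' The on-disk format is a plain CSV with header `i,j,k,y`.
#'
#' @param path file path.
#' @param grid optional [apc_grid()]; inferred from the file if omitted.
#' @return `read_apc_csv` returns an [apc_data]; `write_apc_csv` returns
#'   `path` invisibly.
#' @export
read_apc_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  apc_data(df, grid)
}

#' @rdname read_apc_csv
#' @param data an [apc_data] object.
#' @export
write_apc_csv <- function(data, path) {
  stopifnot(inherits(data, "apc_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: validate a positive whole number
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("%s must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
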