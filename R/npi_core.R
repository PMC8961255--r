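#' Break ties in a sample by a small perturbation
#'
#' NPI's interval construction assumes no ties.  Tied observations are
#' separated by adding multiples of a small `epsilon` within each run of
#' equal values; equal values keep their original relative order.
#'
#' @param values Numeric vector of observations (any order).
#' @param epsilon Small positive perturbation.  Default is `1e-9` times the
#'   sample range.  Must be smaller than the smallest nonzero gap divided by
#'   `n + 1` so the perturbation cannot reorder distinct values.
#' @return Sorted, strictly ascending numeric vector of the same length.
#'   Each value is moved by at most `n * epsilon`.
#' @examples
#' break_ties(c(1, 1, 2))
#' break_ties(c(5, 5, 5), epsilon = 1e-6)
#' @export
break_ties <- function(values, epsilon = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1, all(is.finite(values)))
  v <- sort(values)  # stable: equal values keep original index order
  if (!anyDuplicated(v)) return(v)
  gaps <- diff(v)
  pos <- gaps[gaps > 0]
  if (length(pos) == 0 && is.null(epsilon)) {
    stop("all observations identical: cannot form a strict ordering ",
         "without an explicit positive epsilon")
  }
  if (is.null(epsilon)) epsilon <- 1e-9 * diff(range(v))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("epsilon must be a single positive number")
  }
  if (length(pos) > 0 && epsilon >= min(pos) / (length(v) + 1)) {
    stop("epsilon too large: must be below the smallest nonzero gap / (n + 1)")
  }
  # offset 0, 1, 2, ... within each run of equal values
  off <- sequence(rle(v)$lengths) - 1
  v <- v + off * epsilon
  if (any(diff(v) <= 0)) stop("tie-breaking failed to produce a strict ordering")
  v
}

#' Finite NPI support bounds from a sample
#'
#' The support end points are placed one maximum consecutive gap beyond the
#' extremes: `L = x_(1) - max_i(x_(i) - x_(i-1))` and
#' `R = x_(n) + max_i(x_(i) - x_(i-1))`, the gap maximised over
#' `i = 2, ..., n`.
#'
#' @param values Numeric vector, at least two strictly ascending values
#'   after sorting (break ties first, see [break_ties()]).
#' @return An object of class `"npi_bounds"`: list with elements `L` and `R`.
#' @examples
#' npi_bounds(c(1, 2, 4))  # L = -1, R = 6
#' @export
npi_bounds <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  v <- sort(values)
  n <- length(v)
  if (n < 2) stop("need at least two observations to determine bounds")
  if (any(diff(v) <= 0)) stop("observations contain ties; apply break_ties() first")
  gap <- max(diff(v))
  structure(list(L = v[1] - gap, R = v[n] + gap), class = "npi_bounds")
}

#' @export
print.npi_bounds <- function(x, ...) {
  cat(sprintf("NPI support bounds: L = %g, R = %g\n", x$L, x$R))
  invisible(x)
}

# Validate a (sorted, strictly ascending) sample against bounds; returns the
# sorted values.  Used by the sampling front ends.
.check_sample_bounds <- function(values, bounds) {
  v <- sort(values)
  if (any(diff(v) <= 0)) stop("sample contains ties; apply break_ties() first")
  if (!inherits(bounds, "npi_bounds")) {
    stopifnot(is.list(bounds), !is.null(bounds$L), !is.null(bounds$R))
  }
  if (bounds$L >= v[1] || bounds$R <= v[length(v)]) {
    stop("bounds must satisfy L < min(values) and R > max(values)")
  }
  v
}

#' Draw one NPI bootstrap future sample
#'
#' Sequentially draws `m` future values: each draw selects one of the current
#' intervals formed by the working ordered set (including the bounds) with
#' equal probability, then a value uniformly within that interval, and the
#' drawn value is inserted into the working set before the next draw.  The
#' bounds are computed once from the original sample and stay fixed while the
#' working set grows.
#'
#' @param values Numeric sample (strictly ascending after sorting).
#' @param m Number of future values; defaults to the size of `values`
#'   (a repeat of the experiment with the same sample size).
#' @param bounds Support bounds, by default [npi_bounds()] of `values`.
#' @return Numeric vector of `m` draws, all strictly inside `(L, R)`.
#' @examples
#' set.seed(1)
#' npi_b_sample(c(0, 1), m = 5)
#' @export
npi_b_sample <- function(values, m = length(values), bounds = npi_bounds(values)) {
  v <- .check_sample_bounds(values, bounds)
  stopifnot(length(m) == 1, m >= 0, m == as.integer(m))
  cpp_npib_sample(v, bounds$L, bounds$R, as.integer(m))
}

# N independent future samples of size m as rows of an N x m matrix; the
# working set resets to the original sample for every row.
.npi_b_matrix <- function(values, m, N, bounds) {
  v <- .check_sample_bounds(values, bounds)
  cpp_npib_matrix(v, bounds$L, bounds$R, as.integer(m), as.integer(N))
}

# Sort, tie-break if needed (with a one-line warning), return sorted values.
.prepare_sample <- function(values, label = "sample") {
  stopifnot(is.numeric(values), length(values) >= 2, all(is.finite(values)))
  if (anyDuplicated(values)) {
    warning(sprintf("ties in %s broken by a small perturbation", label),
            call. = FALSE)
    break_ties(values)
  } else {
    sort(values)
  }
}
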