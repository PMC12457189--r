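#' Discretized search spaces
#'
#' A `dante_space` describes the finite design domain the optimizer explores:
#' every dimension is a finite ordered set of admissible values (a numeric
#' grid `lower + j * step`, or a categorical alphabet of integer codes).
#' Mixed problems are handled uniformly because every dimension is indexed
#' internally by its grid position, never by its floating-point value.
#'
#' Constraints are named predicate functions over the numeric coordinate
#' vector of one candidate; a candidate belongs to the space only if every
#' predicate returns `TRUE`. Constraints are enforced by rejection: proposal
#' mechanisms discard violating candidates and retry.
#'
#' @param d Number of dimensions (positive integer).
#' @param lower,upper,step Per-dimension numeric grid definition. Scalars are
#'   recycled to length `d`. Grid values are generated by index
#'   (`lower + j * step`) so they are exactly reproducible.
#' @param n_levels Alphabet size for categorical dimensions; codes run
#'   `0 .. n_levels - 1`.
#' @param constraints Named list of functions; each takes the numeric
#'   coordinate vector of a single candidate and returns `TRUE`/`FALSE`.
#' @return A `dante_space` object.
#' @examples
#' sp <- grid_space(2, lower = -5, upper = 5, step = 0.1)
#' space_contains(sp, c(0, 0))
#' @export
grid_space <- function(d, lower = -5, upper = 5, step = 0.1, constraints = list()) {
  stopifnot(is.numeric(d), length(d) == 1, d >= 1, d == floor(d))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  step <- rep_len(as.numeric(step), d)
  if (any(step <= 0)) stop("`step` must be positive", call. = FALSE)
  levels <- lapply(seq_len(d), function(i) {
    m <- floor((upper[i] - lower[i]) / step[i] + 1e-9) + 1
    if (m < 2) stop("every dimension needs at least 2 grid values", call. = FALSE)
    lower[i] + (seq_len(m) - 1) * step[i]
  })
  new_space(levels, kind = "numeric", constraints = constraints)
}

#' @rdname grid_space
#' @export
categorical_space <- function(d, n_levels, constraints = list()) {
  stopifnot(is.numeric(d), length(d) == 1, d >= 1, d == floor(d))
  n_levels <- rep_len(as.integer(n_levels), d)
  if (any(n_levels < 2)) stop("every dimension needs at least 2 levels", call. = FALSE)
  levels <- lapply(n_levels, function(m) as.numeric(0:(m - 1)))
  new_space(levels, kind = "categorical", constraints = constraints)
}

new_space <- function(levels, kind, constraints = list(), fixed = integer(0)) {
  if (length(constraints) > 0 &&
      (is.null(names(constraints)) || any(!nzchar(names(constraints))))) {
    stop("constraints must be a named list of predicate functions", call. = FALSE)
  }
  structure(
    list(
      d = length(levels),
      levels = levels,
      n_levels = vapply(levels, length, integer(1)),
      kind = kind,
      constraints = constraints,
      fixed = as.integer(fixed)
    ),
    class = "dante_space"
  )
}

#' @export
print.dante_space <- function(x, ...) {
  cat(sprintf(
    "<dante_space> %s, d = %d, %s levels/dim, %d constraint(s)\n",
    x$kind, x$d, paste(unique(x$n_levels), collapse = "/"),
    length(x$constraints)
  ))
  invisible(x)
}

is_dante_space <- function(x) inherits(x, "dante_space")

#' Coerce candidate input to a coordinate matrix
#'
#' Accepts a numeric vector (one candidate), a matrix, or a data frame whose
#' first `d` numeric columns are coordinates, and returns an `n x d` numeric
#' matrix of coordinate values.
#'
#' @param space A `dante_space`.
#' @param data Candidates in any accepted form.
#' @return Numeric matrix, one row per candidate.
#' @keywords internal
cand_matrix <- function(space, data) {
  stopifnot(is_dante_space(space))
  if (is.data.frame(data)) {
    cols <- intersect(paste0("x", seq_len(space$d)), names(data))
    if (length(cols) == space$d) {
      data <- as.matrix(data[cols])
    } else {
      num <- vapply(data, is.numeric, logical(1))
      data <- as.matrix(data[num])
    }
  } else if (is.numeric(data) && is.null(dim(data))) {
    data <- matrix(data, nrow = 1)
  }
  data <- as.matrix(data)
  if (ncol(data) != space$d) {
    stop(sprintf("candidates have %d coordinates; space has d = %d",
                 ncol(data), space$d), call. = FALSE)
  }
  storage.mode(data) <- "double"
  colnames(data) <- paste0("x", seq_len(space$d))
  data
}

# values -> 1-based grid indices; NA where a value is off-grid.
cand_index <- function(space, X) {
  X <- cand_matrix(space, X)
  idx <- matrix(NA_integer_, nrow(X), ncol(X))
  for (j in seq_len(space$d)) {
    lv <- space$levels[[j]]
    stp <- if (length(lv) > 1) lv[2] - lv[1] else 1
    i <- as.integer(round((X[, j] - lv[1]) / stp)) + 1L
    ok <- !is.na(i) & i >= 1L & i <= length(lv) &
      abs(X[, j] - lv[pmin(pmax(i, 1L), length(lv))]) < stp * 1e-6
    idx[, j] <- ifelse(ok, i, NA_integer_)
  }
  idx
}

index_to_values <- function(space, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  out <- matrix(NA_real_, nrow(idx), ncol(idx))
  for (j in seq_len(space$d)) out[, j] <- space$levels[[j]][idx[, j]]
  colnames(out) <- paste0("x", seq_len(space$d))
  out
}

#' Canonical candidate identity keys
#'
#' Keys are derived from integer grid indices, never from floating values, so
#' two representations of the same grid cell always share a key. Used for
#' dataset deduplication and visitation counting.
#'
#' @inheritParams cand_matrix
#' @return Character vector of keys (`NA` for off-grid rows).
#' @export
cand_keys <- function(space, data) {
  idx <- cand_index(space, data)
  keys <- apply(idx, 1, paste, collapse = ".")
  keys[apply(idx, 1, anyNA)] <- NA_character_
  keys
}

check_constraints <- function(space, X) {
  ok <- rep(TRUE, nrow(X))
  for (fn in space$constraints) {
    ok <- ok & vapply(seq_len(nrow(X)),
                      function(i) isTRUE(fn(X[i, ])), logical(1))
  }
  ok
}

#' Space membership test
#'
#' A candidate is in the space iff every coordinate is on-grid and in-bounds
#' and every constraint predicate holds.
#'
#' @inheritParams cand_matrix
#' @return Logical vector, one entry per candidate.
#' @export
space_contains <- function(space, data) {
  X <- cand_matrix(space, data)
  idx <- cand_index(space, X)
  on_grid <- !apply(idx, 1, anyNA)
  out <- on_grid
  if (any(on_grid) && length(space$constraints) > 0) {
    out[on_grid] <- check_constraints(space, X[on_grid, , drop = FALSE])
  }
  out
}

#' Smallest admissible moves along one dimension
#'
#' Returns the (0 to 2) candidates differing from `cand` only at
#' `dim_index`, by exactly one grid step up or down, filtered to in-bounds
#' and constraint-satisfying candidates.
#'
#' @inheritParams cand_matrix
#' @param cand A single candidate (vector or one-row data frame).
#' @param dim_index Dimension to move along (1-based).
#' @return Tibble of neighboring candidates (possibly zero rows).
#' @export
one_step_neighbors <- function(space, cand, dim_index) {
  X <- cand_matrix(space, cand)
  if (nrow(X) != 1) stop("`cand` must be a single candidate", call. = FALSE)
  if (!space_contains(space, X)) stop("`cand` is not in the space", call. = FALSE)
  if (dim_index < 1 || dim_index > space$d) {
    stop(sprintf("`dim_index` must be in 1..%d", space$d), call. = FALSE)
  }
  i <- cand_index(space, X)[1, dim_index]
  lv <- space$levels[[dim_index]]
  props <- Filter(function(j) j >= 1 && j <= length(lv), list(i - 1L, i + 1L))
  out <- do.call(rbind, lapply(props, function(j) {
    Y <- X
    Y[1, dim_index] <- lv[[j]]
    Y
  }))
  if (is.null(out)) out <- X[0, , drop = FALSE]
  keep <- check_constraints(space, out)
  tibble::as_tibble(out[keep, , drop = FALSE])
}

#' Uniform random candidates
#'
#' Samples grid indices uniformly and independently per dimension, rejecting
#' candidates that violate constraints, up to `retry` attempts per requested
#' candidate. Draws from the current R random number stream.
#'
#' @inheritParams cand_matrix
#' @param n Number of candidates to draw.
#' @param retry Rejection-sampling cap per candidate.
#' @return Tibble of `n` candidates passing [space_contains()].
#' @export
random_candidates <- function(space, n = 1, retry = 50) {
  stopifnot(is_dante_space(space), n >= 0)
  draw <- function(m) {
    idx <- vapply(space$n_levels,
                  function(k) sample.int(k, m, replace = TRUE), integer(m))
    if (m == 1) idx <- matrix(idx, nrow = 1)
    index_to_values(space, idx)
  }
  if (n == 0) {
    return(tibble::as_tibble(draw(1)[0, , drop = FALSE]))
  }
  if (length(space$constraints) == 0) {
    return(tibble::as_tibble(draw(n)))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(retry)) {
      x <- draw(1)
      if (check_constraints(space, x)) {
        rows[[i]] <- x
        break
      }
    }
    if (is.null(rows[[i]])) {
      bad <- names(space$constraints)[!vapply(
        space$constraints, function(fn) isTRUE(fn(x[1, ])), logical(1))]
      stop(sprintf(
        "could not draw a feasible candidate in %d attempts (last failing constraint: %s)",
        retry, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
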