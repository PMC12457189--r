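#' Synthetic benchmark objectives
#'
#' Classic nonconvex minimization benchmarks with known global optima, used
#' to measure how many labeled data points the active-optimization loop needs
#' to reach the optimum. All functions accept a numeric vector (one point) or
#' a matrix / data frame with one point per row and evaluate vectorized.
#'
#' `ackley()` uses the standard constants a = 20, b = 0.2, c = 2*pi and is 0
#' at the origin. `rosenbrock()` (d >= 2) is 0 at the all-ones point.
#' `rastrigin()` uses the full-index form `10 d + sum(x_i^2 - 10 cos(2 pi x_i))`
#' so its optimum at the origin is exactly 0. `griewank()`, `schwefel()` and
#' `michalewicz()` follow their standard textbook forms.
#'
#' @param x Numeric vector, matrix, or data frame of points (rows).
#' @return Numeric vector of function values, one per point.
#' @name benchmarks
NULL

as_points <- function(x, min_d = 1) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  if (ncol(x) < min_d) {
    stop(sprintf("needs dimension >= %d, got %d", min_d, ncol(x)), call. = FALSE)
  }
  x
}

#' @rdname benchmarks
#' @export
ackley <- function(x) {
  x <- as_points(x)
  a <- 20; b <- 0.2; cc <- 2 * pi
  d <- ncol(x)
  rms <- sqrt(rowMeans(x^2))
  -a * exp(-b * rms) - exp(rowMeans(cos(cc * x))) + a + exp(1)
}

#' @rdname benchmarks
#' @export
rosenbrock <- function(x) {
  x <- as_points(x, min_d = 2)
  d <- ncol(x)
  i <- seq_len(d - 1)
  rowSums(100 * (x[, i + 1, drop = FALSE] - x[, i, drop = FALSE]^2)^2 +
            (x[, i, drop = FALSE] - 1)^2)
}

#' @rdname benchmarks
#' @export
rastrigin <- function(x) {
  x <- as_points(x)
  10 * ncol(x) + rowSums(x^2 - 10 * cos(2 * pi * x))
}

#' @rdname benchmarks
#' @export
griewank <- function(x) {
  x <- as_points(x)
  denom <- sqrt(seq_len(ncol(x)))
  prod_term <- apply(cos(sweep(x, 2, denom, "/")), 1, prod)
  rowSums(x^2) / 4000 - prod_term + 1
}

#' @rdname benchmarks
#' @export
schwefel <- function(x) {
  x <- as_points(x)
  418.9829 * ncol(x) - rowSums(x * sin(sqrt(abs(x))))
}

#' @rdname benchmarks
#' @export
michalewicz <- function(x) {
  x <- as_points(x)
  m <- 10
  i <- seq_len(ncol(x))
  -rowSums(sin(x) * sin(sweep(x^2, 2, i, "*") / pi)^(2 * m))
}

#' Construct an objective
#'
#' An objective bundles a labeling function with its optimization direction
#' and (when known) its global optimum. The labeling function is the
#' ground-truth oracle of the loop; for the shipped benchmarks it is
#' deterministic and cheap, standing in for an expensive validation source.
#'
#' @param name Objective name.
#' @param fn Function mapping a matrix of points (rows) to a numeric vector
#'   of labels.
#' @param direction `"minimize"` or `"maximize"`.
#' @param optimum Optional list with elements `location` (numeric vector or
#'   `NULL`) and `value` (the known optimal objective value).
#' @param d Dimension the objective expects, or `NA` for any.
#' @return A `dante_objective`.
#' @export
objective <- function(name, fn, direction = c("minimize", "maximize"),
                      optimum = NULL, d = NA_integer_) {
  direction <- match.arg(direction)
  structure(
    list(name = name, fn = fn, direction = direction,
         optimum = optimum, d = d),
    class = "dante_objective"
  )
}

#' @export
print.dante_objective <- function(x, ...) {
  opt <- if (is.null(x$optimum)) "unknown optimum" else
    sprintf("optimum %.6g", x$optimum$value)
  cat(sprintf("<dante_objective> %s (%s, %s)\n", x$name, x$direction, opt))
  invisible(x)
}

#' Evaluate an objective on candidates
#'
#' @param obj A `dante_objective`.
#' @param data Candidates (vector, matrix, or data frame).
#' @return Numeric label vector on the objective's natural scale.
#' @export
label_candidates <- function(obj, data) {
  stopifnot(inherits(obj, "dante_objective"))
  x <- as_points(data)
  y <- obj$fn(x)
  if (length(y) != nrow(x)) stop("objective returned wrong length", call. = FALSE)
  y
}

# Internal convention: the search engine always maximizes. Minimization
# objectives are negated at this boundary and never inside the engine.
internal_sign <- function(obj) if (obj$direction == "minimize") -1 else 1

benchmark_registry <- list(
  ackley = list(fn = ackley, domain = c(-5, 5), step = 0.1, min_d = 1,
                minimizer = function(d) rep(0, d), value = 0),
  rosenbrock = list(fn = rosenbrock, domain = c(-5, 5), step = 0.1, min_d = 2,
                    minimizer = function(d) rep(1, d), value = 0),
  rastrigin = list(fn = rastrigin, domain = c(-5, 5), step = 0.1, min_d = 1,
                   minimizer = function(d) rep(0, d), value = 0),
  griewank = list(fn = griewank, domain = c(-600, 600), step = 12, min_d = 1,
                  minimizer = function(d) rep(0, d), value = 0),
  schwefel = list(fn = schwefel, domain = c(-500, 500), step = 10, min_d = 1,
                  minimizer = NULL, value = NULL),
  michalewicz = list(fn = michalewicz, domain = c(0, pi), step = pi / 100,
                     min_d = 1, minimizer = NULL, value = NULL)
)

#' Benchmark objective plus its discretized domain
#'
#' Ackley, Rosenbrock and Rastrigin use the hypercube \[-5, 5\] with grid
#' step 0.1 (101 admissible values per dimension). Griewank, Schwefel and
#' Michalewicz use their standard domains discretized to 101 values per
#' dimension. All are minimization objectives; for Schwefel and Michalewicz
#' the on-grid optimum is not recorded (their continuous minimizers are
#' off-grid).
#'
#' @param name One of `"ackley"`, `"rosenbrock"`, `"rastrigin"`,
#'   `"griewank"`, `"schwefel"`, `"michalewicz"`.
#' @param d Dimension (`>= 2` for Rosenbrock).
#' @return List with elements `objective` and `space`.
#' @examples
#' bm <- make_benchmark("ackley", 20)
#' label_candidates(bm$objective, rep(0, 20))  # 0 at the origin
#' @export
make_benchmark <- function(name, d) {
  if (!name %in% names(benchmark_registry)) {
    stop(sprintf("unknown benchmark '%s' (supported: %s)", name,
                 paste(names(benchmark_registry), collapse = ", ")),
         call. = FALSE)
  }
  spec <- benchmark_registry[[name]]
  if (d < spec$min_d) {
    stop(sprintf("'%s' needs d >= %d", name, spec$min_d), call. = FALSE)
  }
  space <- grid_space(d, lower = spec$domain[1], upper = spec$domain[2],
                      step = spec$step)
  optimum <- NULL
  if (!is.null(spec$minimizer)) {
    loc <- spec$minimizer(d)
    stopifnot(all(space_contains(space, loc)))
    optimum <- list(location = loc, value = spec$value)
  }
  obj <- objective(sprintf("%s-%dd", name, d), spec$fn,
                   direction = "minimize", optimum = optimum, d = d)
  list(objective = obj, space = space)
}
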