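#' Labeled datasets
#'
#' The growing set of `(candidate, label)` pairs driving surrogate training.
#' Candidate identity is the integer grid index key, so deduplication is
#' exact regardless of floating-point representation. Labels are stored on
#' the objective's natural scale; the internal maximization convention is
#' applied at the surrogate/search boundary, not here.
#'
#' @param space A `dante_space`.
#' @param data Optional initial candidates (matrix or data frame).
#' @param y Labels for `data`.
#' @return A `dante_dataset`.
#' @export
labeled_dataset <- function(space, data = NULL, y = NULL) {
  stopifnot(is_dante_space(space))
  ds <- structure(
    list(space = space,
         X = matrix(numeric(0), 0, space$d,
                    dimnames = list(NULL, paste0("x", seq_len(space$d)))),
         y = numeric(0),
         keys = character(0)),
    class = "dante_dataset"
  )
  if (!is.null(data)) ds <- dataset_add(ds, data, y)
  ds
}

#' Append labeled records
#'
#' Appending a candidate whose key is already present is an error: a label
#' is never silently overwritten or duplicated. Use [dedup_against()] to
#' filter a batch first.
#'
#' @param ds A `dante_dataset`.
#' @param data Candidates (matrix or data frame).
#' @param y Numeric labels, one per candidate; must be finite.
#' @return The updated dataset.
#' @export
dataset_add <- function(ds, data, y) {
  stopifnot(inherits(ds, "dante_dataset"))
  X <- cand_matrix(ds$space, data)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("one label per candidate required", call. = FALSE)
  if (any(!is.finite(y))) stop("labels must be finite", call. = FALSE)
  keys <- cand_keys(ds$space, X)
  if (anyNA(keys)) stop("candidates must lie in the space", call. = FALSE)
  if (anyDuplicated(keys) || any(keys %in% ds$keys)) {
    stop("duplicate candidate key: dataset keys are unique", call. = FALSE)
  }
  ds$X <- rbind(ds$X, X)
  ds$y <- c(ds$y, y)
  ds$keys <- c(ds$keys, keys)
  ds
}

#' @export
print.dante_dataset <- function(x, ...) {
  cat(sprintf("<dante_dataset> n = %d, d = %d\n", length(x$y), x$space$d))
  invisible(x)
}

#' Number of labeled records
#' @param ds A `dante_dataset`.
#' @export
dataset_size <- function(ds) length(ds$y)

#' @importFrom tibble as_tibble
#' @export
as_tibble.dante_dataset <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$X))
  out$y <- x$y
  out
}

# labels in the internal maximization convention
internal_labels <- function(ds, direction = "maximize") {
  if (direction == "minimize") -ds$y else ds$y
}
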