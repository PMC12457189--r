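#' Remove already-labeled candidates from a batch
#'
#' Drops rows whose candidate key appears in the dataset; order is
#' preserved.
#'
#' @param batch Candidates (data frame or matrix).
#' @param ds A `dante_dataset`.
#' @param space Space used for key computation (defaults to `ds$space`).
#' @return The filtered batch as a tibble.
#' @export
dedup_against <- function(batch, ds, space = ds$space) {
  X <- cand_matrix(space, batch)
  keep <- !(cand_keys(space, X) %in% ds$keys)
  out <- tibble::as_tibble(as.data.frame(X[keep, , drop = FALSE]))
  if (is.data.frame(batch)) {
    extra <- setdiff(names(batch), names(out))
    for (nm in extra) out[[nm]] <- batch[[nm]][keep]
  }
  out
}

#' Top-visit sampling of the next labeling batch
#'
#' Converts a search trace into at most `k` unlabeled candidates by mixing
#' exploitation and search attention: the `ceiling(k/2)` highest
#' surrogate-scored trace candidates and the `floor(k/2)` most-visited ones
#' (after removing duplicates and already-labeled candidates; a deficit in
#' one list is filled from the other, and any remaining deficit by uniform
#' random candidates). Ties are broken uniformly at random from the current
#' RNG stream. With `top_visit = FALSE` in `config` (ablation) the batch is
#' exactly the top-`k` by surrogate score.
#'
#' @param trace A `dante_trace` from [run_search()].
#' @param ds The current labeled dataset.
#' @param k Batch size (`>= 0`).
#' @param space Search space (defaults to `ds$space`).
#' @param config An [nte_config()] (only the `top_visit` switch and `retry`
#'   cap are consulted).
#' @return A tibble of candidates with a `.provenance` column
#'   (`"best-scored"`, `"most-visited"`, or `"random-fill"`) and the
#'   surrogate's standardized prediction in `.pred`.
#' @export
top_visit_sample <- function(trace, ds, k = 20, space = ds$space,
                             config = nte_config()) {
  stopifnot(inherits(trace, "dante_trace"), inherits(ds, "dante_dataset"))
  if (k < 0) stop("k must be nonnegative", call. = FALSE)
  xcols <- paste0("x", seq_len(space$d))
  empty <- tibble::as_tibble(ds$X[0, , drop = FALSE])
  empty$.pred <- numeric(0)
  empty$.provenance <- character(0)
  if (k == 0) return(empty)
  if (nrow(trace) == 0) stop("empty trace with k > 0", call. = FALSE)

  X <- as.matrix(trace[xcols])
  keys <- cand_keys(space, X)
  dup <- duplicated(keys)
  labeled <- keys %in% ds$keys
  pool <- which(!dup & !labeled)

  pred <- trace$.pred
  visits <- trace$.visits
  n_pool <- length(pool)
  tiebreak <- sample.int(max(n_pool, 1))  # seeded uniform tie-breaking

  pick <- integer(0)
  prov <- character(0)
  if (n_pool > 0) {
    if (isTRUE(config$top_visit)) {
      by_score <- pool[order(-pred[pool], tiebreak)]
      by_visit <- pool[order(-visits[pool], tiebreak)]
      n_score <- ceiling(k / 2)
      take_s <- utils::head(by_score, n_score)
      remaining <- setdiff(by_visit, take_s)
      take_v <- utils::head(remaining, k - length(take_s))
      # deficit in the visit list is filled from the score list
      extra <- utils::head(setdiff(by_score, c(take_s, take_v)),
                           k - length(take_s) - length(take_v))
      pick <- c(take_s, take_v, extra)
      prov <- c(rep("best-scored", length(take_s)),
                rep("most-visited", length(take_v)),
                rep("best-scored", length(extra)))
    } else {
      pick <- utils::head(pool[order(-pred[pool], tiebreak)], k)
      prov <- rep("best-scored", length(pick))
    }
  }

  out <- tibble::as_tibble(as.data.frame(X[pick, , drop = FALSE]))
  out$.pred <- pred[pick]
  out$.provenance <- prov

  # random-fill the remaining deficit with unlabeled space candidates
  deficit <- k - nrow(out)
  tries <- 0
  while (deficit > 0 && tries < config$retry) {
    cand <- random_candidates(space, deficit)
    cand <- dedup_against(cand, ds, space)
    if (nrow(cand) > 0) {
      kk <- cand_keys(space, as.matrix(cand))
      seen <- cand_keys(space, as.matrix(out[xcols]))
      cand <- cand[!duplicated(kk) & !(kk %in% seen), , drop = FALSE]
    }
    if (nrow(cand) > 0) {
      cand$.pred <- NA_real_
      cand$.provenance <- "random-fill"
      out <- dplyr::bind_rows(out, utils::head(cand, deficit))
      deficit <- k - nrow(out)
    }
    tries <- tries + 1
  }
  out
}
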