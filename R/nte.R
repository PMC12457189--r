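#' Data-driven upper confidence bound
#'
#' The acquisition score of the tree search:
#' `v_ml + c0 * c_rho * sqrt(2 * log(N) / (n + 1))`, where `v_ml` is the
#' surrogate's value estimate, `N` the visit count of the current root and
#' `n` the visit count of the leaf. The `+ 1` in the denominator treats
#' every node as visited at least once, so the score is finite for unvisited
#' leaves and no exhaustive first-visit sweep is needed.
#'
#' @param v_ml Surrogate value estimate(s).
#' @param c0 Exploration constant in \[0.01, 1\].
#' @param c_rho Data-driven exploration scale (see [exploration_scale()]).
#' @param N Visit count of the current root (`>= 1`).
#' @param n Visit count(s) of the leaf (`>= 0`).
#' @return Numeric DUCB score(s), always finite.
#' @examples
#' ducb(0.5, c0 = 0.1, c_rho = 1, N = 1, n = 0)  # log(1) = 0 -> 0.5
#' @export
ducb <- function(v_ml, c0, c_rho, N, n) {
  if (any(N < 1)) stop("root visit count N must be >= 1 (roots start visited)",
                       call. = FALSE)
  if (any(n < 0) || c_rho < 0) stop("visit counts and c_rho are nonnegative",
                                    call. = FALSE)
  v_ml + c0 * c_rho * sqrt(2 * log(N) / (n + 1))
}

#' Data-driven exploration scale
#'
#' The exploration term of the DUCB is scaled by the maximum of the observed
#' label distribution. Labels are taken in the internal maximization
#' convention and standardized (z-scored), so the scale is positive and
#' comparable to the surrogate's standardized predictions; it is floored at
#' `floor`. Because new high-value points raise this maximum, exploration
#' strengthens right after improvements are found.
#'
#' @param ds A `dante_dataset`.
#' @param direction Objective direction (labels are negated for
#'   `"minimize"`).
#' @param floor Lower bound on the returned scale.
#' @return A single nonnegative scale value.
#' @export
exploration_scale <- function(ds, direction = c("maximize", "minimize"),
                              floor = 1) {
  direction <- match.arg(direction)
  stopifnot(inherits(ds, "dante_dataset"))
  if (dataset_size(ds) == 0) stop("empty dataset", call. = FALSE)
  y <- internal_labels(ds, direction)
  sdv <- stats::sd(y)
  z_max <- if (!is.finite(sdv) || sdv < 1e-12) 0 else (max(y) - mean(y)) / sdv
  max(z_max, floor)
}

#' Conditional selection rule
#'
#' Keeps the current root unless some leaf's DUCB strictly exceeds it; the
#' maximum-DUCB leaf then becomes the new root. Ties among leaves are broken
#' uniformly at random (from the current RNG stream); a tie with the root is
#' not an improvement. With `enabled = FALSE` (ablation) the maximum-DUCB
#' leaf is always selected, reproducing the value-deterioration-prone greedy
#' tree walk.
#'
#' @param root_score DUCB of the root.
#' @param leaf_scores DUCB of each leaf (may be empty).
#' @param enabled Conditional-selection switch.
#' @return Index of the selected node: `0` for the root, otherwise the
#'   1-based leaf index.
#' @export
conditional_select <- function(root_score, leaf_scores, enabled = TRUE) {
  if (length(leaf_scores) == 0) {
    warning("no leaves supplied; staying with the root")
    return(0L)
  }
  best <- max(leaf_scores)
  ties <- which(leaf_scores >= best - 1e-12)
  pick <- if (length(ties) > 1) ties[sample.int(length(ties), 1)] else ties
  if (!enabled) return(as.integer(pick))
  if (best > root_score + 1e-12) as.integer(pick) else 0L
}

#' Local backpropagation of visit counts
#'
#' Updates only the visitation data between the root and the selected node:
#' the root's count and the selected node's count each increase by one (one
#' increment in total when the search stayed at the root). No value
#' information is propagated and no other entry changes. With
#' `enabled = FALSE` (ablation) counts are not updated at all and the search
#' degenerates to a greedy stochastic walk.
#'
#' @param table Named integer vector of visit counts (candidate key ->
#'   count).
#' @param root,selected Candidate keys present in (or added to) the table.
#' @param enabled Local-backpropagation switch.
#' @return The updated table.
#' @export
local_backprop <- function(table, root, selected, enabled = TRUE) {
  if (!enabled) return(table)
  for (key in unique(c(root, selected))) {
    if (is.na(table[key])) table[key] <- 0L
  }
  table[root] <- table[root] + 1L
  if (!identical(selected, root)) table[selected] <- table[selected] + 1L
  table
}

#' Tree-search configuration
#'
#' @param c0 DUCB exploration constant, in \[0.01, 1\].
#' @param rollouts_per_dim Rollout budget of one search call, per dimension
#'   (total budget = `rollouts_per_dim * d`, split over tree restarts).
#' @param mode_probs Probabilities of the three expansion modes (one-step
#'   move, single mutation, scaled random mutation); must sum to 1.
#' @param frac_range Fraction range of positions resampled by the scaled
#'   random mutation mode.
#' @param top_roots Number of best dataset candidates used as restart roots
#'   (one uniformly random root is always added).
#' @param restart_len Target number of rollouts per tree restart; the root
#'   set is cycled until the budget is spent. Short restarts keep the walk
#'   concentrated near the current best candidates, which is where
#'   refinements live; one long walk per root diffuses away from them.
#' @param refine_after Refinement-phase trigger: after this many
#'   consecutive iterations without a new best label the loop is refining
#'   an incumbent rather than travelling, and the rollout and warm-refit
#'   budgets are multiplied by `refine_factor` until the next improvement.
#'   Set to `Inf` to disable.
#' @param refine_factor Budget multiplier applied in the refinement phase.
#' @param conditional_selection,local_backprop,adaptive_exploration,top_visit
#'   Ablation switches for the four search mechanisms.
#' @param c_rho_floor Lower bound for [exploration_scale()]; with adaptive
#'   exploration disabled the scale is pinned to this value.
#' @param retry Constraint/duplicate rejection cap per leaf proposal.
#' @param trace_cap Maximum number of scored-but-unvisited candidates kept
#'   in the returned trace (the best-scored ones are kept).
#' @param expand `"grid"` for the three numeric-grid modes, `"sequence"`
#'   for the sequence-design pair of strategies (point mutations / fresh
#'   random sequence).
#' @param p_fresh Probability of the fresh-random-sequence strategy
#'   (`expand = "sequence"` only).
#' @param max_mut Maximum number of positions changed by a sequence point
#'   mutation.
#' @return A list of class `dante_nte_config`.
#' @export
nte_config <- function(c0 = 0.1, rollouts_per_dim = 5,
                       mode_probs = c(1, 1, 1) / 3,
                       frac_range = c(0.1, 0.5), top_roots = 5,
                       restart_len = 40, refine_after = 2,
                       refine_factor = 0.5,
                       conditional_selection = TRUE, local_backprop = TRUE,
                       adaptive_exploration = TRUE, top_visit = TRUE,
                       c_rho_floor = 1, retry = 50, trace_cap = 2000,
                       expand = c("grid", "sequence"), p_fresh = 0.5,
                       max_mut = 3) {
  expand <- match.arg(expand)
  stopifnot(c0 >= 0, c0 <= 1, rollouts_per_dim >= 0,
            length(mode_probs) == 3, abs(sum(mode_probs) - 1) < 1e-9,
            length(frac_range) == 2, frac_range[1] <= frac_range[2])
  structure(as.list(environment()), class = "dante_nte_config")
}

new_visit_table <- function(space) {
  list(cands = matrix(integer(0), 0, space$d), visits = integer(0))
}

#' Run one neural-surrogate-guided tree search
#'
#' Starting from restart roots (the current best dataset candidates plus one
#' random candidate), repeatedly expands the root into `d` stochastic
#' leaves, scores root and leaves with the DUCB, applies conditional
#' selection and local backpropagation, and accumulates a visitation trace,
#' until the rollout budget is spent. Deterministic given `seed`.
#'
#' @param surrogate A fitted `dante_cnn` or any `dante_surrogate` (e.g.
#'   [exact_surrogate()]).
#' @param ds The current labeled dataset (supplies restart roots and the
#'   standardization statistics for non-network surrogates).
#' @param space The search space.
#' @param config An [nte_config()].
#' @param direction Objective direction.
#' @param seed Integer seed for the search RNG.
#' @param visit_table Persistent visitation state from previous search
#'   calls, or `NULL` to start fresh.
#' @param roots Optional explicit root candidates (matrix/data frame);
#'   defaults to the top `config$top_roots` dataset candidates plus one
#'   random candidate.
#' @return A `dante_trace`: a tibble of trace candidates with `.visits` and
#'   `.pred` (standardized surrogate score) columns, with the updated visit
#'   table and search counters as attributes.
#' @export
run_search <- function(surrogate, ds, space, config = nte_config(),
                       direction = c("maximize", "minimize"), seed = 1,
                       visit_table = NULL, roots = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(surrogate, "dante_surrogate"),
            inherits(ds, "dante_dataset"), is_dante_space(space))
  if (inherits(surrogate, "dante_cnn") &&
      !identical(surrogate$space$n_levels, space$n_levels)) {
    stop("surrogate was fitted on a different space", call. = FALSE)
  }
  if (is.null(visit_table)) visit_table <- new_visit_table(space)

  c_rho <- if (config$adaptive_exploration) {
    exploration_scale(ds, direction, floor = config$c_rho_floor)
  } else {
    config$c_rho_floor
  }

  # restart roots: exploit the best known candidates, plus one random draw
  if (is.null(roots)) {
    y_int <- internal_labels(ds, direction)
    top <- order(y_int, decreasing = TRUE)[seq_len(min(config$top_roots,
                                                       length(y_int)))]
    rand_root <- with_local_seed(seed, as.matrix(random_candidates(space, 1)))
    roots <- rbind(ds$X[top, , drop = FALSE], rand_root)
  }
  roots_idx <- cand_index(space, cand_matrix(space, roots))
  if (anyNA(roots_idx)) stop("roots must lie in the space", call. = FALSE)
  budget <- as.integer(round(config$rollouts_per_dim * space$d))
  cycles <- max(1L, as.integer(round(budget / (nrow(roots_idx) *
                                                 max(config$restart_len, 1)))))
  roots_idx <- roots_idx[rep(seq_len(nrow(roots_idx)), cycles), , drop = FALSE]

  # standardized internal-convention predictions for the engine
  net_ptr <- NULL
  r_predict <- NULL
  if (inherits(surrogate, "dante_cnn")) {
    net_ptr <- surrogate$ptr
  } else {
    y_int <- internal_labels(ds, direction)
    mu <- mean(y_int)
    sdv <- stats::sd(y_int)
    if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
    r_predict <- function(idx) {
      X <- index_to_values(space, idx)
      (predict(surrogate, X, type = "internal") - mu) / sdv
    }
  }
  r_constraint <- NULL
  if (length(space$constraints) > 0) {
    r_constraint <- function(idx) {
      x <- index_to_values(space, matrix(idx, nrow = 1))[1, ]
      all(vapply(space$constraints, function(fn) isTRUE(fn(x)), logical(1)))
    }
  }
  mutable <- setdiff(seq_len(space$d), space$fixed)

  res <- nte_search_cpp(
    net_ptr, r_predict, r_constraint,
    as.integer(space$n_levels), space$levels,
    roots_idx, budget,
    config$c0, c_rho,
    as.numeric(config$mode_probs), as.numeric(config$frac_range),
    isTRUE(config$conditional_selection), isTRUE(config$local_backprop),
    as.integer(config$retry), as.numeric(seed),
    visit_table$cands, visit_table$visits,
    as.integer(mutable), as.integer(config$trace_cap),
    if (config$expand == "sequence") 1L else 0L,
    config$p_fresh, as.integer(config$max_mut))

  vals <- index_to_values(space, res$cands)
  out <- tibble::as_tibble(as.data.frame(vals))
  out$.visits <- res$visits
  out$.pred <- res$preds
  structure(out,
            class = c("dante_trace", class(out)),
            idx = res$cands,
            visit_table = list(cands = res$table_cands,
                               visits = res$table_visits),
            root_log = res$root_log,
            n_evals = res$n_evals,
            rollouts = res$rollouts,
            c_rho = c_rho,
            space_d = space$d)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_state) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Stochastic expansion of a root candidate
#'
#' Generates up to `d` leaves from `root`, each by one of three modes drawn
#' with `config$mode_probs`: a one-step move (the smallest admissible change
#' at one position), a single mutation (one position resampled over its full
#' range), or a scaled random mutation (a sampled fraction -- default 10-50%
#' -- of positions resampled). Leaves identical to the root or violating
#' constraints are redrawn up to `config$retry` times; boundary moves clip
#' to the admissible range. Draws from the current R RNG stream. This is the
#' reference implementation used for unit and distributional tests; the
#' search engine applies the identical scheme internally.
#'
#' @param root A single candidate.
#' @param space A `dante_space`.
#' @param config An [nte_config()].
#' @return Tibble of leaves (rows may be fewer than `d` for degenerate
#'   spaces), with a `.mode` column naming the generating mode.
#' @export
stochastic_expand <- function(root, space, config = nte_config()) {
  stopifnot(is_dante_space(space))
  x <- cand_index(space, cand_matrix(space, root))[1, ]
  if (anyNA(x)) stop("root is not in the space", call. = FALSE)
  free <- setdiff(seq_len(space$d), space$fixed)
  modes <- c("one-step", "single-mutation", "scaled-mutation")
  rows <- list()
  mode_used <- character(0)
  feasible <- function(idx) {
    length(space$constraints) == 0 ||
      all(check_constraints(space, index_to_values(space, matrix(idx, 1))))
  }
  for (j in seq_len(space$d)) {
    for (attempt in seq_len(config$retry)) {
      mode <- sample(modes, 1, prob = config$mode_probs)
      leaf <- x
      if (mode == "one-step") {
        p <- if (length(free) == 1) free else sample(free, 1)
        v <- leaf[p] + sample(c(-1L, 1L), 1)
        if (v < 1 || v > space$n_levels[p]) v <- 2 * leaf[p] - v  # clip: flip
        if (v >= 1 && v <= space$n_levels[p]) leaf[p] <- v
      } else if (mode == "single-mutation") {
        p <- if (length(free) == 1) free else sample(free, 1)
        leaf[p] <- sample(setdiff(seq_len(space$n_levels[p]), leaf[p]), 1)
      } else {
        frac <- stats::runif(1, config$frac_range[1], config$frac_range[2])
        m <- max(1, round(frac * length(free)))
        pos <- if (length(free) == 1) free else sample(free, m)
        for (p in pos) {
          leaf[p] <- sample(setdiff(seq_len(space$n_levels[p]), leaf[p]), 1)
        }
      }
      if (!identical(leaf, x) && feasible(leaf)) break
      leaf <- x
    }
    if (!identical(leaf, x)) {
      rows[[length(rows) + 1]] <- leaf
      mode_used <- c(mode_used, mode)
    }
  }
  if (length(rows) == 0) {
    warning("could not generate any feasible leaf: degenerate space")
    out <- tibble::as_tibble(index_to_values(space, matrix(x, 1))[0, , drop = FALSE])
    out$.mode <- character(0)
    return(out)
  }
  out <- tibble::as_tibble(index_to_values(space, do.call(rbind, rows)))
  out$.mode <- mode_used
  out
}
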