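#' Active-optimization run configuration
#'
#' Bundles loop-level settings with the surrogate and search
#' configurations. Defaults follow the study conditions of the shipped
#' benchmarks: 200 initial random labels and batches of 20 per iteration.
#'
#' @param n_init Initial number of uniformly random labeled candidates.
#' @param k Labeling batch size per iteration (capped at 20 by default
#'   elsewhere in the literature this loop follows; any `k >= 1` is
#'   accepted).
#' @param max_samples Total labeling budget, including the initial set.
#' @param tol Absolute tolerance on the known optimum value for the
#'   reached-optimum flag.
#' @param surrogate A [surrogate_config()], or the string `"exact"` to use
#'   the ground-truth objective behind the surrogate interface (no network
#'   is trained; used to exercise the search loop in isolation).
#' @param nte An [nte_config()].
#' @param sampler `"top_visit"` (the full pipeline), `"greedy"`
#'   (top-visit-sampling ablation), or `"random"` (random-search baseline:
#'   batches are uniform draws and no surrogate or search runs).
#' @param refit_cold Refit the surrogate from scratch every iteration
#'   instead of warm-starting from the previous iteration's weights.
#' @param cold_every With warm starts, still refit from scratch every this
#'   many iterations; periodic cold restarts re-randomize the network and
#'   stop a long-lived weight basin from pinning the search's ranking of
#'   near-optimal candidates.
#' @param seed Master seed; every source of randomness in the run is
#'   derived from it.
#' @param verbose Print a per-iteration progress line.
#' @return A list of class `dante_run_config`.
#' @export
run_config <- function(n_init = 200, k = 20, max_samples = 1000, tol = 1e-6,
                       surrogate = surrogate_config(), nte = nte_config(),
                       sampler = c("top_visit", "greedy", "random"),
                       refit_cold = FALSE, cold_every = 10, seed = 1,
                       verbose = FALSE) {
  sampler <- match.arg(sampler)
  stopifnot(n_init >= 1, k >= 1, max_samples >= n_init)
  structure(as.list(environment()), class = "dante_run_config")
}

#' Draw and label the initial dataset
#'
#' Labels `n_init` distinct uniformly random candidates and returns the
#' initial loop state.
#'
#' @param obj A `dante_objective`.
#' @param space The search space.
#' @param config A [run_config()].
#' @return A loop state (list with the dataset, visit table, iteration
#'   counter and bookkeeping).
#' @export
ao_initialize <- function(obj, space, config = run_config()) {
  stopifnot(inherits(obj, "dante_objective"), is_dante_space(space))
  n_cells <- prod(as.numeric(space$n_levels))
  if (is.finite(n_cells) && n_cells < config$n_init) {
    stop("space has fewer candidates than n_init", call. = FALSE)
  }
  set.seed(config$seed)
  X <- as.matrix(random_candidates(space, config$n_init))
  keys <- cand_keys(space, X)
  tries <- 0
  while (anyDuplicated(keys) && tries < 100) {
    dup <- duplicated(keys)
    X[dup, ] <- as.matrix(random_candidates(space, sum(dup)))
    keys <- cand_keys(space, X)
    tries <- tries + 1
  }
  X <- X[!duplicated(keys), , drop = FALSE]
  ds <- labeled_dataset(space, X, label_candidates(obj, X))
  state <- list(
    objective = obj, space = space, config = config,
    ds = ds, visit_table = new_visit_table(space), iter = 0L,
    history = list(), batches = list(),
    attained = FALSE, attained_at = NA_integer_
  )
  update_best(state)
}

update_best <- function(state) {
  obj <- state$objective
  sgn <- internal_sign(obj)
  y_int <- sgn * state$ds$y
  i <- which.max(y_int)
  state$best_y <- state$ds$y[i]
  state$best_x <- state$ds$X[i, ]
  if (!state$attained && !is.null(obj$optimum)) {
    if (abs(state$best_y - obj$optimum$value) <= state$config$tol ||
        sgn * (state$best_y - obj$optimum$value) > 0) {
      state$attained <- TRUE
      state$attained_at <- dataset_size(state$ds)
    }
  }
  state
}

#' One iteration of the loop
#'
#' Refits the surrogate on the current dataset, runs the tree search,
#' samples at most `k` new candidates, labels them with the objective, and
#' appends them to the dataset. For the `"random"` sampler the batch is a
#' uniform draw and no surrogate is trained.
#'
#' @param state A loop state from [ao_initialize()].
#' @return The updated state.
#' @export
ao_step <- function(state) {
  cfg <- state$config
  obj <- state$objective
  space <- state$space
  if (dataset_size(state$ds) >= cfg$max_samples) {
    stop("labeling budget exhausted", call. = FALSE)
  }
  state$iter <- state$iter + 1L
  iter_seed <- (cfg$seed * 1000L + state$iter) %% .Machine$integer.max
  set.seed(iter_seed)
  k_eff <- min(cfg$k, cfg$max_samples - dataset_size(state$ds))
  t0 <- proc.time()[["elapsed"]]

  if (cfg$sampler == "random") {
    batch <- random_candidates(space, k_eff)
    batch <- dedup_against(batch, state$ds)
    batch <- batch[!duplicated(cand_keys(space, as.matrix(batch))), ,
                   drop = FALSE]
    batch$.pred <- NA_real_
    batch$.provenance <- "random-fill"
    sur <- NULL
    trace_info <- list(c_rho = NA_real_, rollouts = 0, n_evals = 0)
  } else {
    ncfg <- cfg$nte
    # refinement phase: a stalled best means the loop is polishing an
    # incumbent, which needs less search and less retraining per iteration
    refine <- (state$stall %||% 0L) >= ncfg$refine_after
    if (refine) {
      ncfg$rollouts_per_dim <- ncfg$rollouts_per_dim * ncfg$refine_factor
    }
    if (identical(cfg$surrogate, "exact")) {
      sur <- exact_surrogate(obj, space)
    } else {
      scfg <- cfg$surrogate
      scfg$seed <- iter_seed
      if (refine) {
        scfg$epochs_warm <- max(20L, as.integer(ceiling(
          scfg$epochs_warm * ncfg$refine_factor)))
      }
      cold <- isTRUE(cfg$refit_cold) ||
        (state$iter - 1L) %% max(cfg$cold_every, 1L) == 0L
      warm <- if (!cold && inherits(state$surrogate, "dante_cnn")) state$surrogate
      sur <- fit_surrogate(state$ds, space, scfg, direction = obj$direction,
                           warm_from = warm)
    }
    if (cfg$sampler == "greedy") ncfg$top_visit <- FALSE
    trace <- run_search(sur, state$ds, space, ncfg,
                        direction = obj$direction, seed = iter_seed,
                        visit_table = state$visit_table)
    state$visit_table <- attr(trace, "visit_table")
    trace_info <- list(c_rho = attr(trace, "c_rho"),
                       rollouts = attr(trace, "rollouts"),
                       n_evals = attr(trace, "n_evals"))
    batch <- top_visit_sample(trace, state$ds, k_eff, space, ncfg)
  }
  state$surrogate <- sur

  xcols <- paste0("x", seq_len(space$d))
  if (nrow(batch) == 0) {
    warning("batch deduplicated to zero candidates; dataset unchanged")
  } else {
    Xb <- as.matrix(batch[xcols])
    yb <- label_candidates(obj, Xb)
    state$ds <- dataset_add(state$ds, Xb, yb)
    batch$.y <- yb
  }
  prev_best <- state$best_y
  state <- update_best(state)
  state$stall <- if (identical(prev_best, state$best_y)) {
    (state$stall %||% 0L) + 1L
  } else {
    0L
  }
  state$batches[[state$iter]] <- tibble::as_tibble(batch)
  state$history[[state$iter]] <- tibble::tibble(
    iteration = state$iter,
    n = dataset_size(state$ds),
    batch_size = nrow(batch),
    best_value = state$best_y,
    c_rho = trace_info$c_rho,
    rollouts = trace_info$rollouts,
    surrogate_evals = trace_info$n_evals,
    val_loss = if (inherits(sur, "dante_cnn")) sur$diagnostics$best_val_loss else NA_real_,
    seconds = proc.time()[["elapsed"]] - t0
  )
  if (isTRUE(cfg$verbose)) {
    h <- state$history[[state$iter]]
    message(sprintf(
      "iter %3d | n %5d | best %.6g | c_rho %.3g | rollouts %d | %.1fs",
      h$iteration, h$n, h$best_value, h$c_rho, h$rollouts, h$seconds))
  }
  state
}

#' Run the full active-optimization loop
#'
#' Train surrogate, search, sample, label, update -- repeated until the
#' labeling budget `max_samples` is spent or the known optimum is attained
#' within `tol`.
#'
#' @inheritParams ao_initialize
#' @return A `dante_run` with the per-iteration history, final dataset,
#'   best candidate, and attainment record. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' bm <- make_benchmark("ackley", 3)
#' cfg <- run_config(n_init = 40, k = 10, max_samples = 120, seed = 1,
#'                   surrogate = surrogate_config(epochs = 40))
#' res <- run_dante(bm$objective, bm$space, cfg)
#' glance(res)
#' }
#' @export
run_dante <- function(obj, space, config = run_config()) {
  state <- ao_initialize(obj, space, config)
  while (!state$attained && dataset_size(state$ds) < config$max_samples) {
    state <- ao_step(state)
  }
  finalize_run(state)
}

finalize_run <- function(state) {
  history <- if (length(state$history) > 0) {
    dplyr::bind_rows(state$history)
  } else {
    tibble::tibble(iteration = integer(0), n = integer(0),
                   batch_size = integer(0), best_value = numeric(0),
                   c_rho = numeric(0), rollouts = numeric(0),
                   surrogate_evals = numeric(0), val_loss = numeric(0),
                   seconds = numeric(0))
  }
  init_row <- tibble::tibble(
    iteration = 0L, n = state$config$n_init, batch_size = state$config$n_init,
    best_value = {
      sgn <- internal_sign(state$objective)
      y0 <- state$ds$y[seq_len(min(state$config$n_init, dataset_size(state$ds)))]
      if (sgn < 0) min(y0) else max(y0)
    },
    c_rho = NA_real_, rollouts = 0, surrogate_evals = 0,
    val_loss = NA_real_, seconds = NA_real_
  )
  structure(
    list(objective = state$objective, space = state$space,
         config = state$config, dataset = state$ds,
         history = dplyr::bind_rows(init_row, history),
         batches = state$batches,
         best_value = state$best_y, best_candidate = state$best_x,
         attained = state$attained, attained_at = state$attained_at,
         n_labeled = dataset_size(state$ds)),
    class = "dante_run"
  )
}

#' @export
print.dante_run <- function(x, ...) {
  cat(sprintf("<dante_run> %s | n = %d | best = %.6g%s\n",
              x$objective$name, x$n_labeled, x$best_value,
              if (x$attained) sprintf(" | optimum reached at n = %d",
                                      x$attained_at) else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-iteration history of a run
#'
#' @param x A `dante_run`.
#' @param ... Unused.
#' @return A tibble with one row per iteration (iteration 0 is the initial
#'   random dataset): dataset size, best objective value so far, the
#'   exploration scale, rollout and surrogate-evaluation counters, the
#'   surrogate's validation loss and wall time.
#' @export
tidy.dante_run <- function(x, ...) x$history

#' One-row summary of a run
#'
#' @param x A `dante_run`.
#' @param ... Unused.
#' @return A one-row tibble: objective, dimension, labels used, best value,
#'   attainment flag and the dataset size at first attainment.
#' @export
glance.dante_run <- function(x, ...) {
  tibble::tibble(
    objective = x$objective$name,
    d = x$space$d,
    n_labeled = x$n_labeled,
    best_value = x$best_value,
    attained = x$attained,
    attained_at = x$attained_at,
    iterations = max(x$history$iteration)
  )
}

#' Convergence-curve plot of one or more runs
#'
#' @param object A `dante_run`.
#' @param ... Further `dante_run`s to overlay.
#' @return A ggplot of best objective value versus labeled data points.
#' @export
autoplot.dante_run <- function(object, ...) {
  runs <- c(list(object), Filter(function(z) inherits(z, "dante_run"),
                                 list(...)))
  df <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    h <- runs[[i]]$history
    h$run <- sprintf("%s [%d]", runs[[i]]$objective$name, i)
    h
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$best_value,
                                   colour = .data$run)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "labeled data points", y = "best objective value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fraction of runs reaching the optimum within a budget
#'
#' @param results List of `dante_run` objects.
#' @param budget Labeled-data budget (total points, including the initial
#'   set).
#' @return Fraction in \[0, 1\] of runs whose first attainment used at most
#'   `budget` labeled points.
#' @export
convergence_ratio <- function(results, budget) {
  if (length(results) == 0) stop("no runs supplied", call. = FALSE)
  hit <- vapply(results, function(r) {
    isTRUE(r$attained) && r$attained_at <= budget
  }, logical(1))
  mean(hit)
}
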