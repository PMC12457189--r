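# Shared fixtures, generated in code. Kept light: nothing here trains a
# network.
fx <- make_fixtures(seed = 42, L = 6)

# a tiny labeled dataset on a 2-d grid without duplicate keys
make_tiny_dataset <- function(space, objective, n = 20, seed = 1) {
  with_seed(seed, {
    X <- as.matrix(random_candidates(space, 5 * n))
    X <- X[!duplicated(cand_keys(space, X)), , drop = FALSE][seq_len(n), , drop = FALSE]
    labeled_dataset(space, X, label_candidates(objective, X))
  })
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# a fabricated search trace for sampler tests
fake_trace <- function(space, X, preds, visits) {
  out <- tibble::as_tibble(as.data.frame(cand_matrix(space, X)))
  out$.visits <- as.integer(visits)
  out$.pred <- as.numeric(preds)
  structure(out, class = c("dante_trace", class(out)),
            space_d = space$d)
}

# attainment counts -> fraction attained within budget (Inf = not attained)
convergence_ratio_from <- function(attained_at, budget) {
  mean(is.finite(attained_at) & attained_at <= budget)
}
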