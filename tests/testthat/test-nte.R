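test_that("the DUCB matches its closed form and limits", {
  expect_equal(ducb(0.5, c0 = 0.1, c_rho = 1, N = 1, n = 0), 0.5)  # log(1) = 0
  expect_equal(ducb(1.0, c0 = 0.1, c_rho = 2, N = exp(2), n = 1),
               1 + 0.2 * sqrt(2), tolerance = 1e-12)
  # the +1 denominator keeps unvisited leaves finite
  expect_true(is.finite(ducb(3, 1, 10, N = 1e6, n = 0)))
  # exploration vanishes as n grows
  expect_equal(ducb(0.7, 0.5, 2, N = 100, n = 1e9), 0.7, tolerance = 1e-3)
  expect_error(ducb(1, 0.1, 1, N = 0, n = 0), "N must be >= 1")
})

test_that("conditional selection keeps the root unless strictly beaten", {
  expect_equal(conditional_select(1.0, c(0.9, 0.8)), 0L)
  expect_equal(conditional_select(1.0, c(0.9, 1.2)), 2L)
  expect_equal(conditional_select(1.0, c(1.0, 1.0)), 0L)  # tie is no improvement
  # ablation: always the max-DUCB leaf
  expect_equal(conditional_select(1.0, c(0.9, 0.8), enabled = FALSE), 1L)
  expect_warning(sel <- conditional_select(1.0, numeric(0)), "no leaves")
  expect_equal(sel, 0L)
  # leaf ties break uniformly from the seeded stream
  picks <- with_seed(1, replicate(200, conditional_select(0.1, c(1, 1))))
  expect_setequal(unique(picks), c(1L, 2L))
})

test_that("local backpropagation touches only root and selected", {
  tab <- c(root = 3L, A = 1L, B = 0L)
  out <- local_backprop(tab, "root", "A")
  expect_equal(out, c(root = 4L, A = 2L, B = 0L))
  out2 <- local_backprop(tab, "root", "root")  # stayed: one increment total
  expect_equal(out2, c(root = 4L, A = 1L, B = 0L))
  expect_identical(local_backprop(tab, "root", "A", enabled = FALSE), tab)
})

test_that("exploration scale is the floored standardized label maximum", {
  sp <- grid_space(1, lower = 0, upper = 1, step = 0.01)
  X <- matrix(seq(0, 0.09, 0.01), ncol = 1)
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 30)
  ds <- labeled_dataset(sp, X, y)
  expect_equal(exploration_scale(ds), (30 - mean(y)) / sd(y))
  # floor engages for flat labels
  ds2 <- labeled_dataset(sp, X, rep(2, 10))
  expect_equal(exploration_scale(ds2), 1)
  expect_equal(exploration_scale(ds2, floor = 0.3), 0.3)
  # a new best that stretches the standardized maximum increases the scale
  ds3 <- dataset_add(ds, 0.10, 200)
  expect_gt(exploration_scale(ds3), exploration_scale(ds))
  # minimization: low labels are good
  ds4 <- labeled_dataset(sp, X, -y)
  expect_equal(exploration_scale(ds4, "minimize"), exploration_scale(ds))
  expect_error(exploration_scale(labeled_dataset(sp)), "empty")
})

test_that("repeated visits let a worse arm escape (two-armed recurrence)", {
  # brute-force simulation of the selection recurrence with fixed values
  v <- c(A = 1.0, B = 0.8)
  c0 <- 0.5; c_rho <- 1
  sim <- function(max_rollouts) {
    tab <- c(root = 1L, A = 0L, B = 0L)
    for (t in seq_len(max_rollouts)) {
      N <- tab[["root"]]
      scores <- ducb(v, c0, c_rho, N = N, n = c(tab[["A"]], tab[["B"]]))
      root_score <- ducb(0.9, c0, c_rho, N = N, n = N)
      sel <- conditional_select(root_score, scores)
      if (sel == 2L) return(t)  # arm B finally selected
      tab <- local_backprop(tab, "root", if (sel == 0L) "root" else "A")
    }
    Inf
  }
  t_escape <- with_seed(2, sim(5000))
  expect_true(is.finite(t_escape))
  # repeating A inflates its n (shrinking its bonus) while ln N grows,
  # so the escape time is where B's bonus overtakes A's score gap
  expect_gt(t_escape, 1)
})

test_that("exact-surrogate search finds the brute-force argmax on a toy grid", {
  sp <- fx$grid$space
  sur <- exact_surrogate(fx$grid$objective, sp)
  ds <- make_tiny_dataset(sp, fx$grid$objective, n = 15, seed = 3)
  hits <- 0
  for (s in 1:3) {
    tr <- run_search(sur, ds, sp, nte_config(rollouts_per_dim = 500,
                                             trace_cap = 1e5),
                     direction = "minimize", seed = s)
    best <- tr[which.max(tr$.pred), ]
    hits <- hits + (best$x1 == fx$grid$argmin$x1 && best$x2 == fx$grid$argmin$x2)
  }
  expect_gte(hits, 2)
})

test_that("search traces are deterministic, in-space, and budget-bounded", {
  sp <- fx$grid$space
  sur <- exact_surrogate(fx$grid$objective, sp)
  ds <- make_tiny_dataset(sp, fx$grid$objective, n = 12, seed = 4)
  cfg <- nte_config(rollouts_per_dim = 50)
  t1 <- run_search(sur, ds, sp, cfg, direction = "minimize", seed = 11)
  t2 <- run_search(sur, ds, sp, cfg, direction = "minimize", seed = 11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(space_contains(sp, as.matrix(t1[c("x1", "x2")]))))
  expect_equal(attr(t1, "rollouts"), 100)

  # budget 0: only the initialized roots appear
  t0 <- run_search(sur, ds, sp, nte_config(rollouts_per_dim = 0),
                   direction = "minimize", seed = 11)
  expect_lte(nrow(t0), cfg$top_roots + 1)
  expect_true(all(t0$.visits >= 1))
})

test_that("a greedy (c0 = 0) exact-surrogate walk climbs monotonically", {
  sp <- grid_space(2, lower = -2, upper = 2, step = 0.1)
  bowl <- objective("bowl", function(X) rowSums(X^2), "minimize",
                    optimum = list(location = c(0, 0), value = 0))
  sur <- exact_surrogate(bowl, sp)
  ds <- make_tiny_dataset(sp, bowl, n = 10, seed = 5)
  root <- ds$X[which.min(ds$y), , drop = FALSE]  # single explicit root
  tr <- run_search(sur, ds, sp,
                   nte_config(c0 = 0, rollouts_per_dim = 100, top_roots = 1,
                              restart_len = 1e9),
                   direction = "minimize", seed = 2, roots = root)
  walk <- attr(tr, "root_log")
  vals <- tr$.pred[walk[!is.na(walk)]]
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("one search rollout changes at most two visit-table entries", {
  sp <- fx$grid$space
  sur <- exact_surrogate(fx$grid$objective, sp)
  ds <- make_tiny_dataset(sp, fx$grid$objective, n = 10, seed = 6)
  roots <- ds$X[which.min(ds$y), , drop = FALSE]
  base <- run_search(sur, ds, sp, nte_config(rollouts_per_dim = 0),
                     direction = "minimize", seed = 3, roots = roots)
  one <- run_search(sur, ds, sp, nte_config(rollouts_per_dim = 1 / sp$d),
                    direction = "minimize", seed = 3, roots = roots)
  t_base <- attr(base, "visit_table")
  t_one <- attr(one, "visit_table")
  k_base <- apply(t_base$cands, 1, paste, collapse = ".")
  k_one <- apply(t_one$cands, 1, paste, collapse = ".")
  v0 <- stats::setNames(t_base$visits, k_base)
  v1 <- stats::setNames(t_one$visits, k_one)
  all_keys <- union(names(v0), names(v1))
  a <- ifelse(is.na(v0[all_keys]), 0L, v0[all_keys])
  b <- ifelse(is.na(v1[all_keys]), 0L, v1[all_keys])
  expect_lte(sum(a != b), 2)
})

test_that("stochastic expansion produces d in-space leaves under each mode", {
  sp <- grid_space(6)
  root <- rep(0, 6)
  leaves <- with_seed(1, stochastic_expand(root, sp))
  expect_equal(nrow(leaves), 6)
  M <- as.matrix(leaves[paste0("x", 1:6)])
  expect_true(all(space_contains(sp, M)))
  expect_true(all(rowSums(abs(sweep(M, 2, root)) > 1e-9) >= 1))

  # forced one-step mode: every leaf differs by exactly one grid step
  one <- with_seed(2, stochastic_expand(root, sp, nte_config(mode_probs = c(1, 0, 0))))
  D <- abs(sweep(as.matrix(one[paste0("x", 1:6)]), 2, root))
  expect_true(all(abs(rowSums(D) - 0.1) < 1e-9))
  expect_true(all(one$.mode == "one-step"))

  # boundary: moves clip inward
  corner <- rep(5, 6)
  oneb <- with_seed(3, stochastic_expand(corner, sp, nte_config(mode_probs = c(1, 0, 0))))
  expect_true(all(as.matrix(oneb[paste0("x", 1:6)]) <= 5))

  # scaled mutation changes between 10% and 50% of positions
  sp20 <- grid_space(20)
  sc <- with_seed(4, stochastic_expand(rep(0, 20), sp20,
                                       nte_config(mode_probs = c(0, 0, 1))))
  nch <- rowSums(abs(as.matrix(sc[paste0("x", 1:20)])) > 1e-9)
  expect_true(all(nch >= 2 & nch <= 10))
})

test_that("expansion modes occur at the configured 1/3 frequencies", {
  sp <- grid_space(4)
  modes <- with_seed(9, {
    out <- character(0)
    for (i in 1:700) {
      out <- c(out, stochastic_expand(rep(0, 4), sp)$.mode)
    }
    out
  })
  n <- length(modes)  # ~2800 leaves
  p <- 1 / 3
  sigma <- sqrt(n * p * (1 - p))
  counts <- table(factor(modes, c("one-step", "single-mutation", "scaled-mutation")))
  expect_true(all(abs(counts - n * p) < 5 * sigma))
})
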