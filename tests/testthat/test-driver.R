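bowl2 <- objective("bowl-2d", function(X) rowSums(X^2), "minimize",
                   optimum = list(location = c(0, 0), value = 0), d = 2)
bowl_space <- grid_space(2, lower = -2, upper = 2, step = 0.1)

exact_cfg <- function(...) {
  run_config(surrogate = "exact", nte = nte_config(rollouts_per_dim = 100), ...)
}

test_that("initialization labels n_init distinct candidates reproducibly", {
  st <- ao_initialize(bowl2, bowl_space, exact_cfg(n_init = 50, max_samples = 60, seed = 1))
  expect_equal(dataset_size(st$ds), 50)
  expect_equal(anyDuplicated(st$ds$keys), 0)
  expect_true(all(is.finite(st$ds$y)))

  st2 <- ao_initialize(bowl2, bowl_space, exact_cfg(n_init = 50, max_samples = 60, seed = 1))
  expect_identical(st$ds$X, st2$ds$X)

  st1 <- ao_initialize(bowl2, bowl_space, exact_cfg(n_init = 1, max_samples = 10, seed = 2))
  expect_equal(dataset_size(st1$ds), 1)

  tiny <- grid_space(1, lower = 0, upper = 0.4, step = 0.1)
  expect_error(ao_initialize(bowl2, bowl_space,
                             exact_cfg(n_init = 200, max_samples = 200,
                                       seed = 1)), NA)
  expect_error(
    ao_initialize(objective("id", function(X) X[, 1], "maximize"), tiny,
                  exact_cfg(n_init = 50, max_samples = 60)),
    "fewer candidates")
})

test_that("one step grows the dataset by at most k and never loses the best", {
  st <- ao_initialize(bowl2, bowl_space, exact_cfg(n_init = 30, k = 10,
                                                   max_samples = 100, seed = 3))
  before <- st$best_y
  st <- ao_step(st)
  expect_equal(dataset_size(st$ds), 40)
  expect_lte(st$best_y, before)
  expect_equal(st$history[[1]]$n, 40)
})

test_that("a zero-iteration budget reports the initial best", {
  res <- run_dante(bowl2, bowl_space, exact_cfg(n_init = 25, max_samples = 25, seed = 4))
  g <- glance(res)
  expect_equal(g$iterations, 0)
  expect_equal(g$n_labeled, 25)
  expect_equal(g$best_value, min(res$dataset$y))
})

test_that("the exact-surrogate loop nails a 2-d bowl within 3 iterations", {
  res <- run_dante(bowl2, bowl_space,
                   exact_cfg(n_init = 30, k = 10, max_samples = 200, seed = 5))
  expect_true(res$attained)
  expect_lte(res$attained_at, 60)  # n_init + 3 batches
  expect_equal(res$best_value, 0)
  # sample accounting: dataset size = n_init + sum of batch sizes
  expect_equal(res$n_labeled, 30 + sum(res$history$batch_size[-1]))
  # best-so-far curve is monotone for minimization
  expect_true(all(diff(res$history$best_value) <= 1e-12))
})

test_that("full runs are reproducible from (config, seed)", {
  cfg <- exact_cfg(n_init = 20, k = 5, max_samples = 40, seed = 9)
  r1 <- run_dante(bowl2, bowl_space, cfg)
  r2 <- run_dante(bowl2, bowl_space, cfg)
  drop_time <- function(h) h[setdiff(names(h), "seconds")]
  expect_identical(drop_time(r1$history), drop_time(r2$history))
  expect_identical(r1$best_value, r2$best_value)
})

test_that("the guided loop beats random search on the bowl at equal budget", {
  best_full <- best_rand <- numeric(0)
  for (s in 1:3) {
    full <- run_dante(bowl2, bowl_space,
                      exact_cfg(n_init = 20, k = 10, max_samples = 60, seed = s))
    rand <- run_dante(bowl2, bowl_space,
                      run_config(sampler = "random", n_init = 20, k = 10,
                                 max_samples = 60, seed = s))
    best_full <- c(best_full, full$best_value)
    best_rand <- c(best_rand, rand$best_value)
  }
  expect_lt(mean(best_full), mean(best_rand))
})

test_that("convergence ratio counts attainments within the budget", {
  runs <- list(list(attained = TRUE, attained_at = 900),
               list(attained = TRUE, attained_at = 1000),
               list(attained = FALSE, attained_at = NA))
  expect_equal(convergence_ratio(runs, 1000), 2 / 3)
  expect_equal(convergence_ratio(runs[1:2], 1200), 1.0)
  expect_equal(convergence_ratio(runs, 800), 0.0)
  expect_error(convergence_ratio(list(), 100), "no runs")
})

test_that("tidy, glance and autoplot expose the run history", {
  res <- run_dante(bowl2, bowl_space, exact_cfg(n_init = 20, k = 5,
                                                max_samples = 35, seed = 7))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("iteration", "n", "best_value", "c_rho") %in% names(td)))
  expect_equal(td$iteration[1], 0)
  g <- glance(res)
  expect_equal(nrow(g), 1)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("the deep-surrogate loop runs end to end at desk scale", {
  bm <- make_benchmark("ackley", 3)
  cfg <- run_config(n_init = 40, k = 10, max_samples = 90, seed = 1,
                    surrogate = surrogate_config(epochs = 60, epochs_warm = 30),
                    nte = nte_config(rollouts_per_dim = 30))
  res <- run_dante(bm$objective, bm$space, cfg)
  expect_lte(res$n_labeled, 90)
  expect_lt(res$best_value, min(res$dataset$y[1:40]) + 1e-9)
  expect_true(all(diff(res$history$best_value) <= 1e-12))
})
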