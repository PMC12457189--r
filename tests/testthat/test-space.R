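test_that("grid membership handles on-grid, off-grid and categorical codes", {
  sp <- grid_space(2, lower = -5, upper = 5, step = 0.1)
  expect_true(space_contains(sp, c(0, 0)))
  expect_false(space_contains(sp, c(0.05, 0)))
  expect_false(space_contains(sp, c(5.1, 0)))
  expect_equal(sp$n_levels, c(101L, 101L))

  cs <- categorical_space(3, 20)
  expect_true(space_contains(cs, c(0, 19, 7)))
  expect_false(space_contains(cs, c(0, 20, 7)))

  expect_error(space_contains(sp, c(1, 2, 3)), "coordinates")
})

test_that("index -> value -> index round-trips for every grid cell", {
  sp <- grid_space(1, lower = -5, upper = 5, step = 0.1)
  vals <- sp$levels[[1]]
  idx <- dante:::cand_index(sp, matrix(vals, ncol = 1))
  expect_equal(as.integer(idx), seq_along(vals))
  back <- dante:::index_to_values(sp, idx)
  expect_identical(as.numeric(back), vals)
  # keys are index-derived, so float noise below tolerance cannot split them
  expect_equal(cand_keys(sp, matrix(vals + 1e-9, ncol = 1)),
               cand_keys(sp, matrix(vals, ncol = 1)))
})

test_that("one-step neighbors respect bounds, constraints and dimension checks", {
  sp <- grid_space(2, lower = -5, upper = 5, step = 0.1)
  nb <- one_step_neighbors(sp, c(0, 0), 1)
  expect_equal(sort(nb$x1), c(-0.1, 0.1))
  expect_equal(nb$x2, c(0, 0))

  at_edge <- one_step_neighbors(sp, c(5, 0), 1)
  expect_equal(nrow(at_edge), 1)
  expect_equal(at_edge$x1, 4.9)

  spc <- grid_space(2, lower = -5, upper = 5, step = 0.1,
                    constraints = list(sum_le_0 = function(x) sum(x) <= 0))
  nbc <- one_step_neighbors(spc, c(0, 0), 1)
  expect_equal(nbc$x1, -0.1)

  expect_error(one_step_neighbors(sp, c(0, 0), 3), "dim_index")
  expect_error(one_step_neighbors(sp, c(0.05, 0), 1), "not in the space")
})

test_that("neighbors always lie inside the space (exhaustive 2-d toy)", {
  sp <- grid_space(2, lower = 0, upper = 0.4, step = 0.1,
                   constraints = list(ball = function(x) sum(x^2) <= 0.1))
  grid <- expand.grid(x1 = sp$levels[[1]], x2 = sp$levels[[2]])
  inside <- grid[space_contains(sp, as.matrix(grid)), ]
  for (i in seq_len(nrow(inside))) {
    for (j in 1:2) {
      nb <- one_step_neighbors(sp, as.numeric(inside[i, ]), j)
      if (nrow(nb) > 0) expect_true(all(space_contains(sp, as.matrix(nb))))
    }
  }
})

test_that("random candidates are uniform per cell and reproducible", {
  sp <- grid_space(1, lower = 0, upper = 1, step = 0.1)  # 11 cells
  draws <- with_seed(1, random_candidates(sp, 10000))
  counts <- table(factor(cand_keys(sp, as.matrix(draws)),
                         levels = cand_keys(sp, matrix(sp$levels[[1]], ncol = 1))))
  expect_equal(length(counts), 11)
  p <- 1 / 11
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) < 5 * sigma))

  a <- with_seed(7, random_candidates(sp, 5))
  b <- with_seed(7, random_candidates(sp, 5))
  expect_identical(a, b)

  expect_true(all(space_contains(grid_space(20), random_candidates(grid_space(20), 10))))
})

test_that("infeasible constraints fail loudly with the constraint name", {
  sp <- grid_space(1, lower = 0, upper = 1, step = 0.1,
                   constraints = list(impossible = function(x) FALSE))
  expect_error(random_candidates(sp, 1, retry = 10), "impossible")
})

test_that("datasets reject duplicate keys and off-space candidates", {
  sp <- grid_space(2, lower = -1, upper = 1, step = 0.1)
  ds <- labeled_dataset(sp, rbind(c(0, 0), c(0.1, 0)), c(1, 2))
  expect_equal(dataset_size(ds), 2)
  expect_error(dataset_add(ds, c(0, 0), 3), "duplicate")
  expect_error(dataset_add(ds, c(0.05, 0), 3), "in the space")
  expect_error(dataset_add(ds, c(0.2, 0), NaN), "finite")
  tb <- tibble::as_tibble(ds)
  expect_named(tb, c("x1", "x2", "y"))
  expect_equal(tb$y, c(1, 2))
})
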