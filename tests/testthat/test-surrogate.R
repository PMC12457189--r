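# Light configuration so each fit stays around a second.
quick_cfg <- function(...) {
  args <- utils::modifyList(list(epochs = 200, patience = 200, seed = 5),
                            list(...))
  do.call(surrogate_config, args)
}

test_that("the conv net learns the linear toy to the frozen thresholds", {
  ds <- fx$linear$dataset
  sp <- fx$linear$space
  sur <- fit_surrogate(ds, sp, quick_cfg())
  Xt <- with_seed(21, as.matrix(random_candidates(sp, 400)))
  truth <- rowSums(Xt)
  pred <- predict(sur, Xt)
  # thresholds frozen from a reference run of this configuration
  expect_gt(cor(pred, truth, method = "spearman"), 0.9)
  big <- abs(truth) > stats::sd(ds$y) / 2
  expect_lt(mape(pred[big], truth[big]), 0.10)
})

test_that("mse and mape losses both train the linear toy adequately", {
  ds <- fx$linear$dataset
  Xt <- with_seed(22, as.matrix(random_candidates(fx$linear$space, 200)))
  for (loss in c("mse", "mape")) {
    sur <- fit_surrogate(ds, config = quick_cfg(loss = loss))
    expect_gt(cor(predict(sur, Xt), rowSums(Xt), method = "spearman"), 0.85)
  }
})

test_that("degenerate constant labels reproduce the constant", {
  sp <- grid_space(4, lower = 0, upper = 1, step = 0.1)
  X <- with_seed(3, as.matrix(random_candidates(sp, 40)))
  X <- X[!duplicated(cand_keys(sp, X)), ]
  ds <- labeled_dataset(sp, X, rep(5, nrow(X)))
  sur <- fit_surrogate(ds, config = quick_cfg(epochs = 120))
  p <- predict(sur, X)
  expect_true(all(abs(p - 5) < 0.05))  # within 1% (exact by construction)
  expect_s3_class(sur, "dante_surrogate")
})

test_that("fits are reproducible and inference is batch-invariant", {
  ds <- fx$linear$dataset
  sp <- fx$linear$space
  s1 <- fit_surrogate(ds, config = quick_cfg(epochs = 60))
  s2 <- fit_surrogate(ds, config = quick_cfg(epochs = 60))
  Xt <- with_seed(9, as.matrix(random_candidates(sp, 100)))
  expect_identical(predict(s1, Xt), predict(s2, Xt))

  p_all <- predict(s1, Xt)
  expect_equal(predict(s1, Xt[1, , drop = FALSE]), p_all[1])
  expect_identical(predict(s1, Xt[0, , drop = FALSE]), numeric(0))
})

test_that("training loss decreases over epochs on a smoothed window", {
  sur <- fit_surrogate(fx$linear$dataset, config = quick_cfg())
  tl <- sur$diagnostics$train_loss
  expect_gt(length(tl), 20)
  expect_lt(mean(utils::tail(tl, 10)), mean(utils::head(tl, 10)))
})

test_that("warm starts continue training without touching the donor net", {
  ds <- fx$linear$dataset
  sp <- fx$linear$space
  donor <- fit_surrogate(ds, config = quick_cfg(epochs = 80))
  Xt <- with_seed(10, as.matrix(random_candidates(sp, 50)))
  before <- predict(donor, Xt)
  warm <- fit_surrogate(ds, config = quick_cfg(epochs_warm = 40), warm_from = donor)
  expect_identical(predict(donor, Xt), before)
  expect_true(all(is.finite(predict(warm, Xt))))
  expect_false(identical(predict(warm, Xt), before))
})

test_that("surrogate contract errors are raised", {
  sp <- grid_space(3, lower = 0, upper = 1, step = 0.5)
  X <- as.matrix(expand.grid(c(0, 0.5, 1), c(0, 0.5, 1), c(0, 0.5, 1)))[1:10, ]
  ds <- labeled_dataset(sp, X, rowSums(X))
  expect_error(fit_surrogate(ds, config = quick_cfg(min_n = 20)), "floor")
  sur <- fit_surrogate(fx$linear$dataset, config = quick_cfg(epochs = 30))
  expect_error(predict(sur, c(1, 2)), "coordinates")
})

test_that("the exact surrogate exposes the same interface as the net", {
  sp <- fx$grid$space
  obj <- fx$grid$objective
  sur <- exact_surrogate(obj, sp)
  X <- as.matrix(fx$grid$enumeration[, c("x1", "x2")])
  expect_equal(predict(sur, X), fx$grid$enumeration$y)
  # internal convention is maximization: minimization labels come back negated
  expect_equal(predict(sur, X, type = "internal"), -fx$grid$enumeration$y)
  expect_identical(predict(sur, X[0, ]), numeric(0))
})

test_that("mape follows its definition and guards zero truth", {
  expect_equal(mape(c(1, 4), c(1, 4)), 0)
  expect_equal(mape(1.1 * c(2, 5), c(2, 5)), 0.1)
  expect_equal(mape(c(2, 4), c(1, 4)), 0.5)
  expect_warning(m <- mape(c(1, 1), c(0, 2)), "excluded")
  expect_equal(m, 0.5)
  expect_error(mape(c(1, 1), c(0, 0)), "undefined")
})
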