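# Two well-separated 2-D Gaussian blobs; linearly separable by a margin.
separable_toy <- function(n_per_class = 10L, seed = 42L, gap = 6) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = gap, sd = 0.3), ncol = 2))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

test_that("configurations carry the published hyperparameter defaults", {
  gbt <- model_config("gradient_boosted_trees")
  expect_equal(gbt$hyperparameters,
               list(learning_rate = 0.01, n_estimators = 1000L,
                    max_depth = 4L, min_child_weight = 1, gamma = 0,
                    subsample = 0.8))
  expect_equal(model_config("rbf_svm")$hyperparameters,
               list(C = 1.0, gamma = 0.001))
  rf <- model_config("random_forest")$hyperparameters
  expect_equal(rf[c("n_estimators", "max_depth", "min_samples_split",
                    "min_samples_leaf", "max_features", "random_state")],
               list(n_estimators = 80L, max_depth = 13L,
                    min_samples_split = 150L, min_samples_leaf = 15L,
                    max_features = 7L, random_state = 10L))
  expect_true(rf$oob_score)
  expect_equal(model_config("knn")$hyperparameters$K, 5L)
})

test_that("overrides are applied and unknown keys rejected", {
  cfg <- model_config("gradient_boosted_trees",
                      list(n_estimators = 10L))
  expect_equal(cfg$hyperparameters$n_estimators, 10L)
  expect_equal(cfg$hyperparameters$max_depth, 4L)
  expect_error(model_config("rbf_svm", list(n_estimators = 9L)),
               "valid keys")
})

test_that("all families separate a linearly separable toy set", {
  toy <- separable_toy()
  for (fam in ALL_FAMILIES) {
    model <- fit_model(fast_config(fam), toy$x, toy$y, seed = 1L)
    p <- predict_proba(model, toy$x)
    expect_equal(as.integer(p > 0.5), toy$y,
                 label = paste("training predictions of", fam))
  }
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(77)
  x <- matrix(runif(60 * 5), ncol = 5)
  y <- rep(c(0L, 1L), 30)
  probe <- matrix(runif(10 * 5), ncol = 5)
  for (fam in ALL_FAMILIES) {
    cfg <- fast_config(fam)
    p1 <- predict_proba(fit_model(cfg, x, y, seed = 9L), probe)
    p2 <- predict_proba(fit_model(cfg, x, y, seed = 9L), probe)
    expect_identical(p1, p2, label = paste(fam, "repeat fit"))
  }
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(runif(20), ncol = 2)
  expect_error(fit_model(model_config("knn"), x, rep(1L, 10)),
               "single class")
  expect_error(fit_model(model_config("knn"), x, rep(c(0L, 1L), 3)),
               "mismatch")
  model <- fit_model(model_config("knn"), x, rep(c(0L, 1L), 5))
  expect_error(predict_proba(model, matrix(0, 2, 3)), "width")
})

test_that("missing features are tolerated only by gradient boosted trees", {
  set.seed(3)
  x <- matrix(runif(80), ncol = 4)
  y <- rep(c(0L, 1L), 10)
  x_na <- x; x_na[1, 2] <- NA
  expect_error(fit_model(model_config("rbf_svm"), x_na, y), "missing")
  expect_error(fit_model(model_config("knn"), x_na, y), "missing")
  m <- fit_model(fast_config("gradient_boosted_trees"), x_na, y)
  expect_true(all(predict_proba(m, x_na) >= 0 & predict_proba(m, x_na) <= 1))
})

test_that("k-NN probability is the positive fraction among K neighbours", {
  # probe at origin: 4 positives at distance 1, 1 negative at distance 2,
  # everything else far away
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),   # positives, d = 1
             c(2, 0),                                 # negative,  d = 2
             matrix(50 + runif(10), ncol = 2))        # far-away negatives
  y <- c(1L, 1L, 1L, 1L, 0L, rep(0L, 5))
  model <- fit_model(model_config("knn"), x, y)
  expect_equal(predict_proba(model, matrix(c(0, 0), 1)), 0.8)
})

test_that("k-NN distance ties break by training input order", {
  # four equidistant neighbours + K = 5 forces a tie at distance 1:
  # order() stability must pick the earlier training rows first
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
             c(0.6, 0.8), c(-0.6, 0.8))  # also distance 1
  y <- c(1L, 1L, 1L, 1L, 0L, 0L)
  model <- fit_model(model_config("knn"), x, y)
  # first 5 training rows in input order: 4 positives + 1 negative
  expect_equal(predict_proba(model, matrix(c(0, 0), 1)), 0.8)
})

test_that("tree model ranks a duplicated positive training point high", {
  set.seed(8)
  pos_point <- rep(0.9, 4)
  x <- rbind(matrix(rep(pos_point, 20), ncol = 4, byrow = TRUE),
             matrix(runif(20 * 4, 0, 0.3), ncol = 4))
  y <- rep(c(1L, 0L), each = 20)
  m <- fit_model(fast_config("gradient_boosted_trees"), x, y, seed = 2L)
  expect_gt(predict_proba(m, matrix(pos_point, 1)), 0.5)
})

test_that("probabilities stay within [0, 1] on random inputs", {
  set.seed(15)
  x <- matrix(rnorm(50 * 6), ncol = 6)
  y <- rep(c(0L, 1L), 25)
  probe <- matrix(rnorm(40 * 6, sd = 3), ncol = 6)
  for (fam in ALL_FAMILIES) {
    p <- predict_proba(fit_model(fast_config(fam), x, y, seed = 4L), probe)
    expect_true(all(p >= 0 & p <= 1), label = paste(fam, "range"))
    expect_length(p, 40L)
  }
})
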