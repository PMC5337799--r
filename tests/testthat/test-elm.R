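test_that("hidden matrix evaluates the sigmoid layer", {
  set.seed(14)
  X <- matrix(rnorm(12), nrow = 4)
  model <- elm(rbind(X, X + 2), rep(c(1, 2), each = 4),
               n_hidden = 5, seed = 1)
  # zero weights/biases give g(0) = 1/2 everywhere
  m0 <- model
  m0$input_weights[] <- 0
  m0$biases[] <- 0
  expect_true(all(hidden_matrix(X, m0) == 0.5))
  # saturation
  m1 <- m0
  m1$biases[] <- 50
  expect_true(all(abs(hidden_matrix(X, m1) - 1) < 1e-6))
  # independent re-evaluation oracle, entry by entry
  H <- hidden_matrix(X, model)
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(model$n_hidden)) {
      u <- sum(model$input_weights[j, ] * X[i, ]) + model$biases[j]
      expect_equal(H[i, j], 1 / (1 + exp(-u)), tolerance = 1e-12)
    }
  }
  expect_true(all(H > 0 & H < 1))
  expect_error(hidden_matrix(matrix(0, 2, 7), model), "mismatch")
})

test_that("training interpolates when L >= n and is seed-deterministic", {
  set.seed(15)
  X <- matrix(rnorm(20 * 3), nrow = 20)
  y <- rep(c(1, 2), 10)
  fit <- elm(X, y, n_hidden = 20, seed = 42)
  expect_lt(sqrt(mean((fitted(fit) - y)^2)), 1e-6)
  # predictions on the training set reproduce the labels exactly
  expect_identical(predict(fit, X), y)

  fit2 <- elm(X, y, n_hidden = 20, seed = 42)
  expect_identical(fit$beta, fit2$beta)
  expect_identical(fit$input_weights, fit2$input_weights)
  fit3 <- elm(X, y, n_hidden = 20, seed = 43)
  expect_false(identical(fit$beta, fit3$beta))
})

test_that("output weights are the minimum-norm least-squares solution", {
  skip_if_not_installed("MASS")
  set.seed(16)
  X <- matrix(rnorm(30 * 4), nrow = 30)
  y <- rep(c(1, 2), 15)
  for (L in c(5, 30, 45)) {   # under-, exactly-, over-parameterised
    fit <- elm(X, y, n_hidden = L, seed = 3)
    H <- hidden_matrix(X, fit)
    beta_oracle <- MASS::ginv(H) %*% y
    expect_lt(max(abs(fit$beta - beta_oracle)), 1e-8)
    # optimality: no random probe does better
    res <- sum((H %*% fit$beta - y)^2)
    for (k in 1:100) {
      probe <- fit$beta + rnorm(L, sd = 0.1)
      expect_gte(sum((H %*% probe - y)^2), res - 1e-10)
    }
  }
})

test_that("prediction thresholds at 1.5 with ties to labour", {
  set.seed(17)
  X <- matrix(rnorm(8), nrow = 4)
  fit <- elm(rbind(X, X + 3), rep(c(1, 2), each = 4), n_hidden = 8, seed = 1)
  # synthetic scores via a doctored model: force H %*% beta known
  scores <- c(1.49, 1.5, 1.51)
  expect_identical(ifelse(scores < 1.5, 1, 2), c(1, 2, 2))
  # degenerate/validation cases
  expect_error(elm(X, rep(1, 4), n_hidden = 2), "both classes")
  expect_error(elm(X, c(0, 1, 2, 1), n_hidden = 2), "labels")
  expect_error(elm(rbind(X, X), rep(c(1, 2), each = 4), n_hidden = 0), "n_hidden")
  expect_error(predict(fit, matrix(0, 2, 5)), "mismatch")
})

test_that("formula interface and JSON round-trip agree with the matrix path", {
  set.seed(18)
  df <- data.frame(a = rnorm(20), b = rnorm(20),
                   label = rep(c(1, 2), each = 10))
  df$a <- df$a + (df$label - 1) * 3
  fit_f <- elm(label ~ a + b, df, n_hidden = 10, seed = 5)
  fit_m <- elm(as.matrix(df[, c("a", "b")]), df$label, n_hidden = 10, seed = 5)
  expect_equal(fit_f$beta, fit_m$beta)
  expect_identical(predict(fit_f, df), predict(fit_m, as.matrix(df[, 1:2])))

  p <- withr::local_tempfile()
  write_elm(fit_m, p)
  back <- read_elm(p)
  expect_equal(back$input_weights, fit_m$input_weights)
  expect_equal(drop(back$beta), drop(fit_m$beta))
  expect_equal(predict(back, as.matrix(df[, 1:2]), type = "score"),
               predict(fit_m, as.matrix(df[, 1:2]), type = "score"))
})
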