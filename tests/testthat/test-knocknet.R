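test_that("importances reduce to filter weights for identity dense paths", {
  p <- 4
  fit <- list(features = paste0("f", 1:p),
              weights = list(ri = c(0.5, -1, 0, 2), rti = c(1, 1, 1, 1),
                             w0 = rep(1, p), W1 = diag(p), W2 = diag(p),
                             w3 = rep(1, p), b1 = rep(0, p), b2 = rep(0, p),
                             b3 = 0))
  imp <- importance_from_weights(fit)
  expect_equal(imp$RI, c(0.5, -1, 0, 2))
  expect_equal(imp$RI_tilde, rep(1, 4))
  expect_equal(imp$S, abs(c(0.5, -1, 0, 2)) - 1)
  # a zero filter weight gates the importance to zero regardless of the path
  expect_equal(imp$RI[3], 0)
})

test_that("importances match an independent path-product recomputation", {
  set.seed(71)
  p <- 6
  w <- list(ri = rnorm(p), rti = rnorm(p), w0 = rnorm(p),
            W1 = matrix(rnorm(p * p), p), W2 = matrix(rnorm(p * p), p),
            w3 = rnorm(p), b1 = rnorm(p), b2 = rnorm(p), b3 = 0)
  imp <- importance_from_weights(list(features = paste0("f", 1:p),
                                      weights = w))
  # oracle: accumulate the dense path entry by entry
  path <- numeric(p)
  for (j in 1:p) for (k in 1:p) for (l in 1:p)
    path[j] <- path[j] + w$W1[j, k] * w$W2[k, l] * w$w3[l]
  expect_equal(imp$RI, w$ri * w$w0 * path, tolerance = 1e-12)
  expect_equal(imp$RI_tilde, w$rti * w$w0 * path, tolerance = 1e-12)
})

test_that("knockoff threshold reproduces enumerated reference cases", {
  # at t = 1: (1 + 1) / 4 = 0.5 <= 0.5
  expect_equal(knockoff_threshold(c(4, 3, 2, 1, -1), q = 0.5, plus = TRUE), 1)
  expect_equal(sum(c(4, 3, 2, 1, -1) >=
                     knockoff_threshold(c(4, 3, 2, 1, -1), 0.5, TRUE)), 4)
  # no candidate qualifies
  expect_identical(knockoff_threshold(c(1, -1, 2), q = 0.1, plus = TRUE), Inf)
  # all positive: plus selects all iff 1/|S| <= q
  s_pos <- c(3, 2, 1)
  expect_identical(knockoff_threshold(s_pos, q = 0.2, plus = TRUE), Inf)
  expect_equal(knockoff_threshold(s_pos, q = 0.5, plus = TRUE), 1)
  # plain variant: zero negatives above t means the smallest candidate wins
  expect_equal(knockoff_threshold(s_pos, q = 0.05, plus = FALSE), 1)
  expect_identical(knockoff_threshold(numeric(0)), Inf)
})

test_that("knockoff threshold agrees with brute-force enumeration", {
  set.seed(72)
  for (rep in 1:200) {
    s <- round(rnorm(sample(3:25, 1)), 2)
    q <- runif(1, 0.02, 0.6)
    for (plus in c(TRUE, FALSE))
      expect_identical(knockoff_threshold(s, q, plus),
                       brute_threshold(s, q, plus))
  }
})

test_that("an untrained network still yields finite importances", {
  sim <- simulate_dataset(sim_config(3, 3, 60, seed = 73))
  fit <- fit_response_model(sim$dataset, "Y", cfg = net_config(epochs = 0,
                                                               seed = 73))
  expect_true(all(is.finite(fit$importance$S)))
  expect_identical(nrow(fit$importance), 6L)
})

test_that("training is deterministic given the seed", {
  sim <- simulate_dataset(sim_config(3, 3, 200, seed = 74))
  f1 <- fit_response_model(sim$dataset, "Y", cfg = fast_net(74, epochs = 10))
  f2 <- fit_response_model(sim$dataset, "Y", cfg = fast_net(74, epochs = 10))
  expect_identical(f1$importance$S, f2$importance$S)
})

test_that("a single strong cubic feature dominates the statistics", {
  hits <- vapply(1:6, function(s) {
    set.seed(s)
    n <- 1500; p <- 10
    x <- matrix(rnorm(n * p), n, p)
    y <- x[, 1]^3 + 0.1 * rnorm(n)
    meta <- lapply(c(paste0("f", 1:p), "Y"), variable_meta)
    d <- kd_dataset(cbind(x, y), meta)
    fit <- fit_response_model(d, "Y", cfg = fast_net(s, epochs = 60))
    which.max(fit$importance$S) == 1L
  }, logical(1))
  expect_gte(mean(hits), 5 / 6)
})

test_that("null statistics are sign-symmetric under exchangeability", {
  p <- 10
  signs <- unlist(lapply(1:30, function(s) {
    set.seed(1000 + s)
    n <- 200
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)  # pure-noise response: every feature is null
    d <- kd_dataset(cbind(x, y),
                    lapply(c(paste0("f", 1:p), "Y"), variable_meta))
    fit <- fit_response_model(d, "Y", cfg = fast_net(1000 + s, epochs = 15))
    sign(fit$importance$S)
  }))
  expect_lt(abs(mean(signs)), 3 / sqrt(30 * p))
})

test_that("nonlinear selection emits a well-formed edge list", {
  sim <- simulate_dataset(sim_config(4, 4, 800, seed = 76))
  edges <- select_nonlinear(sim$dataset, targets = "Y",
                            cfg = fast_net(76, epochs = 120))
  expect_true(all(edges$kind == "nonlinear"))
  expect_true(all(edges$effect_size >= 0))
  expect_true(all(edges$var_b == "Y"))
  expect_true(is.list(attr(edges, "stats")))

  # constant response triggers the standardization guard
  dc <- sim$dataset
  dc$values[, "Y"] <- 1
  expect_error(fit_response_model(dc, "Y", cfg = fast_net(1)), "zero variance")
})
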