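test_that("null-model objective equals the sum of per-node Gaussian losses", {
  d <- standardize(tiny_dataset(50, 4, seed = 41), "all")$dataset
  lay <- knockdag:::.mgm_layout(d)
  par0 <- knockdag:::.mgm_zero_params(lay)
  # intercept-only loss per standardized node: ||x_k||^2 / (2N)
  expected <- sum(colSums(d$values^2)) / (2 * nrow(d$values))
  expect_equal(neg_pseudolikelihood(d, par0), expected, tolerance = 1e-12)
})

test_that("continuous-only objective matches per-node regression losses", {
  d <- standardize(tiny_dataset(80, 4, seed = 42), "all")$dataset
  lay <- knockdag:::.mgm_layout(d)
  par <- knockdag:::.mgm_zero_params(lay)
  set.seed(43)
  b <- matrix(rnorm(16, sd = 0.2), 4, 4)
  b <- (b + t(b)) / 2
  diag(b) <- 0
  par$beta <- b
  par$alpha <- rnorm(4, sd = 0.1)

  x <- d$values
  n <- nrow(x)
  oracle <- sum(vapply(1:4, function(k) {
    pred <- par$alpha[k] + x[, -k, drop = FALSE] %*% b[-k, k]
    sum((x[, k] - pred)^2) / (2 * n)
  }, numeric(1)))
  expect_equal(neg_pseudolikelihood(d, par), oracle, tolerance = 1e-10)
})

test_that("analytic pseudo-likelihood gradient matches finite differences", {
  d <- standardize(mixed_dataset(120, seed = 44), "continuous_only")$dataset
  lay <- knockdag:::.mgm_layout(d)
  par <- knockdag:::.mgm_zero_params(lay)
  set.seed(45)
  par$beta[1, 2] <- par$beta[2, 1] <- 0.3
  par$nu[[1]][1, ] <- rnorm(3, sd = 0.2)
  sm <- knockdag:::.mgm_smooth(par, lay, grad = TRUE)
  h <- 1e-6
  fd <- function(mutate) {
    pp <- mutate(par, h); pm <- mutate(par, -h)
    (knockdag:::.mgm_smooth(pp, lay)$value -
       knockdag:::.mgm_smooth(pm, lay)$value) / (2 * h)
  }
  g_beta <- fd(function(p, e) { p$beta[1, 2] <- p$beta[1, 2] + e
                                p$beta[2, 1] <- p$beta[2, 1] + e; p })
  expect_equal(g_beta, sm$grad$beta[1, 2], tolerance = 1e-5)
  g_nu <- fd(function(p, e) { p$nu[[1]][2, 1] <- p$nu[[1]][2, 1] + e; p })
  expect_equal(unname(g_nu), unname(sm$grad$nu[[1]][2, 1]), tolerance = 1e-5)
  g_phi0 <- fd(function(p, e) { p$phi0[[1]][2] <- p$phi0[[1]][2] + e; p })
  expect_equal(unname(g_phi0), unname(sm$grad$phi0[[1]][2]), tolerance = 1e-5)
})

test_that("a dominating penalty zeroes every interaction block", {
  d <- mixed_dataset(200, seed = 46)
  fit <- fit_mgm(d, mgm_penalties(10, 10, 10))
  expect_true(all(fit$params$beta == 0))
  expect_true(all(vapply(fit$params$nu, function(m) all(m == 0), logical(1))))
  expect_identical(nrow(extract_linear_edges(fit)), 0L)
})

test_that("a sparse Gaussian graph is recovered at the default penalty", {
  # 5 variables, precision = identity except two strong partial correlations
  omega <- diag(5)
  omega[1, 2] <- omega[2, 1] <- -0.5
  omega[3, 4] <- omega[4, 3] <- -0.5
  sigma_mat <- solve(omega)
  set.seed(47)
  x <- matrix(rnorm(2000 * 5), 2000, 5) %*% chol(sigma_mat)
  d <- kd_dataset(x, lapply(paste0("v", 1:5), variable_meta))
  fit <- fit_mgm(d)
  edges <- extract_linear_edges(fit)
  got <- sort(paste(edges$var_a, edges$var_b))
  expect_identical(got, c("v1 v2", "v3 v4"))
  expect_true(all(edges$effect_size > 0))

  # objective trace is non-increasing
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("edge count is monotone non-increasing in the penalty", {
  set.seed(48)
  omega <- diag(6)
  for (k in 1:5) omega[k, k + 1] <- omega[k + 1, k] <- -0.35
  x <- matrix(rnorm(800 * 6), 800, 6) %*% chol(solve(omega))
  d <- kd_dataset(x, lapply(paste0("v", 1:6), variable_meta))
  counts <- vapply(c(0.05, 0.2, 0.4, 0.8), function(lam)
    nrow(extract_linear_edges(fit_mgm(d, mgm_penalties(lam, lam, lam)))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the fit is invariant to row permutation and tracks column moves", {
  d <- tiny_dataset(100, 4, seed = 49)
  fit1 <- fit_mgm(d, mgm_penalties(0.1, 0.1, 0.1))
  dp <- d
  perm <- sample(nrow(d$values))
  dp$values <- dp$values[perm, ]
  dp$sample_ids <- dp$sample_ids[perm]
  fit2 <- fit_mgm(dp, mgm_penalties(0.1, 0.1, 0.1))
  expect_equal(fit1$params$beta, fit2$params$beta, tolerance = 1e-9)
})

test_that("mixed continuous/ordinal associations are detected", {
  d <- mixed_dataset(400, seed = 50)
  edges <- extract_linear_edges(fit_mgm(d, mgm_penalties(0.1, 0.1, 0.1)))
  key <- paste(pmin(edges$var_a, edges$var_b), pmax(edges$var_a, edges$var_b))
  # the ordinal grade is a thresholded copy of x1, not of x2: the x1 edge
  # must be present and dominate any residual noise edge
  expect_true("grade x1" %in% key)
  e_x1 <- edges$effect_size[key == "grade x1"]
  expect_true(all(edges$effect_size[key != "grade x1"] < e_x1))
})
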