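#' Fit a Gaussian model-X knockoff model
#'
#' Estimates the feature mean and covariance and chooses the diagonal
#' `diag{S}` of the knockoff construction by the equicorrelated rule: on the
#' correlation scale `s_j = min(2 * lambda_min(R), 1)`, rescaled back to
#' covariance units, then shrunk geometrically until the conditional
#' covariance `2 diag{S} - diag{S} Sigma^{-1} diag{S}` is positive
#' semidefinite. The sample covariance is optionally shrunk toward its
#' diagonal, `(1 - gamma) S_emp + gamma diag(S_emp)`, which keeps `Sigma`
#' invertible when N is not much larger than M.
#'
#' @param X Numeric feature matrix (N x M), N >= 2.
#' @param shrinkage Diagonal shrinkage weight in `[0, 1]`; the default `NULL`
#'   uses 0.1 when `N < 2 * M` and 0 otherwise.
#' @param seed Integer seed used later by [sample_knockoffs()].
#' @return A `kd_knockoff_model` with fields `mu`, `Sigma`, `s_diag`, `seed`.
#' @export
fit_knockoff_model <- function(X, shrinkage = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  stopifnot(n >= 2, m >= 1)
  if (is.null(shrinkage)) shrinkage <- if (n < 2 * m) 0.1 else 0
  stopifnot(shrinkage >= 0, shrinkage <= 1)

  mu <- colMeans(X)
  s_emp <- stats::cov(X)
  sigma_mat <- (1 - shrinkage) * s_emp + shrinkage * diag(diag(s_emp), m)
  ev <- eigen(sigma_mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("estimated covariance is not positive definite; ",
         "increase the shrinkage")

  sd_vec <- sqrt(diag(sigma_mat))
  corr <- sigma_mat / tcrossprod(sd_vec)
  lam_min <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  s_corr <- min(2 * lam_min, 1)
  s_diag <- s_corr * diag(sigma_mat)

  omega <- chol2inv(chol(sigma_mat))
  for (k in 0:60) {
    cond_cov <- 2 * diag(s_diag, m) -
      (s_diag * omega) * rep(s_diag, each = m)  # diag{S} Omega diag{S}
    ev_c <- eigen((cond_cov + t(cond_cov)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
    if (min(ev_c) >= -1e-10 * max(abs(ev_c))) break
    s_diag <- s_diag * 0.95
  }
  structure(list(mu = mu, Sigma = sigma_mat, s_diag = s_diag,
                 seed = as.integer(seed)),
            class = "kd_knockoff_model")
}

#' Sample Gaussian model-X knockoff copies
#'
#' Draws the knockoff matrix row-wise from the conditional Gaussian
#' `xt | x ~ N(x - diag{S} Sigma^{-1} (x - mu) ... )` (mean-centered form),
#' whose joint with `x` has cross-covariance `Sigma - diag{S}` and marginal
#' covariance `Sigma`. Deterministic given `km$seed`.
#'
#' @param X Feature matrix the model was fitted on (or new data from the
#'   same distribution).
#' @param km A [fit_knockoff_model()] result.
#' @return A knockoff matrix of the same shape as `X`.
#' @export
sample_knockoffs <- function(X, km) {
  stopifnot(inherits(km, "kd_knockoff_model"))
  X <- as.matrix(X)
  m <- ncol(X)
  stopifnot(m == length(km$mu))

  omega <- chol2inv(chol(km$Sigma))
  xc <- sweep(X, 2, km$mu)
  cond_mean <- xc - xc %*% (omega * rep(km$s_diag, each = m))
  cond_cov <- 2 * diag(km$s_diag, m) -
    (km$s_diag * omega) * rep(km$s_diag, each = m)
  cond_cov <- (cond_cov + t(cond_cov)) / 2

  ev <- eigen(cond_cov, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  root <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(km$seed)
  noise <- matrix(stats::rnorm(nrow(X) * m), nrow(X), m) %*% root
  sweep(cond_mean + noise, 2, km$mu, "+")
}
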