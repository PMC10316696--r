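#' Configuration for the single-index benchmark simulator
#'
#' The simulator draws rows of a `(p + q)`-feature matrix i.i.d. from
#' `N(0, Sigma)` and computes a continuous outcome from the `p` signal
#' features through a single-index model with a cube link:
#' `Y = alpha * (x' beta)^3 + (1 - alpha) * x' gamma + eps`,
#' `eps ~ N(0, sigma^2)`. `alpha = 1` is the complete-nonlinear scenario,
#' `alpha = 0.5` the partial-nonlinear one. By default the feature
#' correlation is specified through its precision matrix
#' `Sigma^{-1} = (rho^|j-k|)` over all `p + q` features
#' (`cov_convention = "precision_ar"`); set `cov_convention =
#' "covariance_ar"` for the commoner AR(1) covariance reading.
#'
#' @param n_true Number `p` of outcome-driving features (>= 1).
#' @param n_null Number `q` of null features.
#' @param n_samples Number of samples `N` (>= 2).
#' @param alpha_mix Nonlinearity mixing weight in `[0, 1]`; 1 and 0.5
#'   reproduce the benchmark's complete- and partial-nonlinear scenarios.
#' @param rho AR parameter in `(-1, 1)` (default 0.5).
#' @param sigma Outcome noise standard deviation (default 1).
#' @param amplitude Magnitude of the `beta`/`gamma` entries; each entry is an
#'   independent random sign times this amplitude. Default `1.5 / sqrt(p)`,
#'   which keeps the index variance stable across `p`.
#' @param cov_convention `"precision_ar"` (default) or `"covariance_ar"`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `kd_sim_config` list.
#' @export
sim_config <- function(n_true, n_null, n_samples, alpha_mix = 1,
                       rho = 0.5, sigma = 1, amplitude = NULL,
                       cov_convention = c("precision_ar", "covariance_ar"),
                       seed = 1L) {
  stopifnot(n_true >= 1, n_null >= 0, n_samples >= 2,
            alpha_mix >= 0, alpha_mix <= 1, abs(rho) < 1, sigma >= 0)
  if (is.null(amplitude)) amplitude <- 1.5 / sqrt(n_true)
  stopifnot(amplitude > 0)
  structure(list(n_true = as.integer(n_true), n_null = as.integer(n_null),
                 n_samples = as.integer(n_samples), alpha_mix = alpha_mix,
                 rho = rho, sigma = sigma, amplitude = amplitude,
                 cov_convention = match.arg(cov_convention),
                 link = "cube", seed = as.integer(seed)),
            class = "kd_sim_config")
}

#' Feature covariance of the single-index simulator
#'
#' Under the default convention the AR(1) structure `rho^|j-k|` is placed on
#' the precision matrix and the covariance is its inverse (a near-tridiagonal
#' matrix); under `"covariance_ar"` it is the covariance itself.
#'
#' @param p_plus_q Total number of features.
#' @param rho AR parameter, `|rho| < 1`.
#' @param cov_convention See [sim_config()].
#' @return A symmetric positive-definite covariance matrix.
#' @export
make_feature_covariance <- function(p_plus_q, rho,
                                    cov_convention = c("precision_ar",
                                                       "covariance_ar")) {
  cov_convention <- match.arg(cov_convention)
  stopifnot(p_plus_q >= 1, abs(rho) < 1)
  ar <- rho^abs(outer(seq_len(p_plus_q), seq_len(p_plus_q), "-"))
  sigma_mat <- if (cov_convention == "precision_ar") chol2inv(chol(ar)) else ar
  sigma_mat <- (sigma_mat + t(sigma_mat)) / 2
  ev <- eigen(sigma_mat, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev > 0))
  sigma_mat
}

#' Generate a single-index benchmark dataset
#'
#' @param cfg A [sim_config()].
#' @return A `kd_sim_dataset` list with fields `dataset` (a [kd_dataset()]
#'   whose columns are the `p` true features `X1..Xp`, the `q` null features
#'   `Z1..Zq`, and the outcome `Y` last), `truth` (per-feature label
#'   `"true_assoc"`/`"null"`), `true_direction` (data frame of
#'   feature-to-outcome ground-truth edges), and the drawn `beta`, `gamma`,
#'   `Sigma`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "kd_sim_config"))
  p <- cfg$n_true; q <- cfg$n_null; n <- cfg$n_samples
  sigma_mat <- make_feature_covariance(p + q, cfg$rho, cfg$cov_convention)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  beta <- sample(c(-1, 1), p, replace = TRUE) * cfg$amplitude
  gamma <- sample(c(-1, 1), p, replace = TRUE) * cfg$amplitude
  X <- matrix(stats::rnorm(n * (p + q)), n, p + q) %*% chol(sigma_mat)
  u <- drop(X[, seq_len(p), drop = FALSE] %*% beta)
  lin <- drop(X[, seq_len(p), drop = FALSE] %*% gamma)
  y <- cfg$alpha_mix * u^3 + (1 - cfg$alpha_mix) * lin +
    stats::rnorm(n, sd = cfg$sigma)

  feat_names <- c(if (p > 0) paste0("X", seq_len(p)),
                  if (q > 0) paste0("Z", seq_len(q)))
  meta <- c(lapply(c(feat_names, "Y"), variable_meta, kind = "continuous"))
  d <- kd_dataset(cbind(X, y), meta)
  truth <- stats::setNames(c(rep("true_assoc", p), rep("null", q)), feat_names)
  structure(list(
    dataset = d,
    truth = truth,
    true_direction = data.frame(from = feat_names[seq_len(p)], to = "Y",
                                stringsAsFactors = FALSE),
    beta = beta, gamma = gamma, Sigma = sigma_mat, config = cfg
  ), class = "kd_sim_dataset")
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
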