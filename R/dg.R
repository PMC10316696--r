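#' Configuration of the degenerate-Gaussian orientation stage
#'
#' @param penalty_c Penalty discount `c > 0` in the conditional score; tunes
#'   graph density (default 1).
#' @param tie_tol Absolute log-likelihood differences at or below this value
#'   are reported as undirected ties; default `1e-6 * N`, resolved at call
#'   time when `NULL`.
#' @param scale `"raw"` (default) scores variables on their original scale;
#'   `"standardized"` rescales first. Raw scale is the default because after
#'   full standardization every continuous variable has unit variance and
#'   the marginal-likelihood comparison cannot discriminate continuous
#'   pairs.
#' @param direction_convention How the sign of the likelihood difference
#'   maps to a direction. Under `"higher_ll_is_cause"` (default) the
#'   variable with the larger marginal Gaussian log-likelihood (smaller
#'   generalized variance) is called the cause; the opposite mapping is
#'   available for sensitivity analysis. The raw statistic is always
#'   reported so the mapping can be audited.
#' @return A `kd_dg_config` list.
#' @export
dg_config <- function(penalty_c = 1, tie_tol = NULL,
                      scale = c("raw", "standardized"),
                      direction_convention = c("higher_ll_is_cause",
                                               "higher_ll_is_effect")) {
  stopifnot(penalty_c > 0)
  structure(list(penalty_c = penalty_c, tie_tol = tie_tol,
                 scale = match.arg(scale),
                 direction_convention = match.arg(direction_convention)),
            class = "kd_dg_config")
}

#' One-hot embedding of a variable into continuous space
#'
#' Continuous variables map to their own single column; an ordinal variable
#' with L levels maps to L-1 indicator columns (first declared level is the
#' dropped reference), which embeds the discrete variable in a continuous
#' space where a Gaussian likelihood is defined.
#'
#' @param d A [kd_dataset()].
#' @param var Variable name.
#' @return Numeric matrix with one or more embedded columns.
#' @export
dg_embed <- function(d, var) {
  stopifnot(inherits(d, "kd_dataset"))
  nm <- variable_names(d)
  j <- match(var, nm)
  if (is.na(j)) stop("unknown variable '", var, "'")
  m <- d$meta[[j]]
  x <- d$values[, j]
  if (m$kind == "continuous") {
    out <- matrix(x, ncol = 1, dimnames = list(NULL, var))
  } else {
    lev <- seq_along(m$levels) - 1L
    out <- vapply(lev[-1L], function(l) as.numeric(x == l),
                  numeric(length(x)))
    out <- matrix(out, ncol = length(lev) - 1L,
                  dimnames = list(NULL, paste0(var, "=", m$levels[-1L])))
  }
  out
}

#' Profile Gaussian log-likelihood of an embedded column block
#'
#' Evaluates the multivariate Gaussian log-likelihood at its maximum:
#' `-(N/2) * (k log(2 pi) + log det(Sigma_hat) + k)` with `Sigma_hat` the
#' maximum-likelihood (1/N) covariance of the `k` columns. A `1e-8` ridge is
#' added to the diagonal when the covariance is numerically singular.
#'
#' @param Z Numeric matrix (N x k), `N > k`.
#' @return The log-likelihood (a scalar).
#' @export
gaussian_loglik <- function(Z) {
  Z <- as.matrix(Z)
  n <- nrow(Z); k <- ncol(Z)
  stopifnot(n > k, k >= 1)
  if (any(apply(Z, 2, stats::var) == 0))
    stop("zero-variance column in log-likelihood block")
  S <- crossprod(sweep(Z, 2, colMeans(Z))) / n
  ld <- determinant(S, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    S <- S + diag(1e-8, k)
    ld <- determinant(S, logarithm = TRUE)
  }
  -(n / 2) * (k * log(2 * pi) + as.numeric(ld$modulus) + k)
}

#' Penalized conditional degenerate-Gaussian score
#'
#' Scores a child given a parent set on the one-hot-embedded columns:
#' `dg(child | parents) = l(child, parents) - l(parents)
#'  - (c/2) * |child| * |parents| * log(N)`,
#' where `| . |` counts embedded columns and `l` is [gaussian_loglik()]. An
#' empty parent set gives the marginal likelihood of the child with zero
#' penalty.
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (may be empty).
#' @param d A [kd_dataset()].
#' @param cfg A [dg_config()].
#' @return The penalized conditional score.
#' @export
dg_score <- function(child, parents, d, cfg = dg_config()) {
  stopifnot(inherits(d, "kd_dataset"), inherits(cfg, "kd_dg_config"))
  if (child %in% parents) stop("child must not be among its parents")
  d <- .dg_rescale(d, cfg)
  zc <- dg_embed(d, child)
  if (length(parents) == 0L) return(gaussian_loglik(zc))
  zp <- do.call(cbind, lapply(parents, dg_embed, d = d))
  n <- nrow(d$values)
  gaussian_loglik(cbind(zc, zp)) - gaussian_loglik(zp) -
    (cfg$penalty_c / 2) * ncol(zc) * ncol(zp) * log(n)
}

.dg_rescale <- function(d, cfg) {
  # standardized scale applies to the continuous columns; ordinal level
  # codes must stay intact so the one-hot embedding remains well defined
  if (cfg$scale == "standardized") standardize(d, "continuous_only")$dataset
  else d
}

#' Orient one association with the pairwise likelihood-ratio rule
#'
#' The difference of the two conditional scores of an (i, j) association
#' reduces algebraically to the difference of the marginal Gaussian
#' log-likelihoods (the joint terms and the symmetric penalties cancel):
#' `delta_ll = l(x_i) - l(x_j)`. Its sign is mapped to a direction by the
#' configured convention and near-zero differences are reported as
#' undirected ties.
#'
#' @param i,j Variable names of a selected association.
#' @param d A [kd_dataset()].
#' @param cfg A [dg_config()].
#' @return A list with `pair`, `delta_ll`, and `direction` (one of
#'   `"a_to_b"`, `"b_to_a"`, `"undirected"`, relative to `c(i, j)`).
#' @export
orient_pair <- function(i, j, d, cfg = dg_config()) {
  stopifnot(inherits(d, "kd_dataset"), inherits(cfg, "kd_dg_config"))
  d2 <- .dg_rescale(d, cfg)
  delta <- gaussian_loglik(dg_embed(d2, i)) - gaussian_loglik(dg_embed(d2, j))
  tie_tol <- if (is.null(cfg$tie_tol)) 1e-6 * nrow(d$values) else cfg$tie_tol
  direction <- if (abs(delta) <= tie_tol) {
    "undirected"
  } else if (xor(delta > 0,
                 cfg$direction_convention == "higher_ll_is_effect")) {
    "a_to_b"
  } else {
    "b_to_a"
  }
  list(pair = c(i, j), delta_ll = delta, direction = direction)
}
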