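#' Sparsity penalties of the mixed graphical model
#'
#' @param lambda_cc,lambda_cd,lambda_dd Nonnegative penalties on
#'   continuous-continuous (`|beta_ij|`), continuous-discrete
#'   (`||nu_ij||_2`) and discrete-discrete (`||Phi_ij||_F`) interaction
#'   blocks. Default 0.3 for all three.
#' @return A `kd_mgm_penalties` list.
#' @export
mgm_penalties <- function(lambda_cc = 0.3, lambda_cd = 0.3, lambda_dd = 0.3) {
  stopifnot(lambda_cc >= 0, lambda_cd >= 0, lambda_dd >= 0)
  structure(list(lambda_cc = lambda_cc, lambda_cd = lambda_cd,
                 lambda_dd = lambda_dd), class = "kd_mgm_penalties")
}

# Internal layout of the mixed data: standardized continuous block plus
# one-hot matrices for each ordinal variable.
.mgm_layout <- function(d) {
  kinds <- variable_kinds(d)
  nm <- variable_names(d)
  cont <- which(kinds == "continuous")
  disc <- which(kinds == "ordinal")
  Xc <- d$values[, cont, drop = FALSE]
  Dm <- lapply(disc, function(j) {
    lev <- seq_along(d$meta[[j]]$levels) - 1L
    out <- vapply(lev, function(l) as.numeric(d$values[, j] == l),
                  numeric(nrow(d$values)))
    matrix(out, ncol = length(lev))
  })
  list(Xc = Xc, Dm = Dm, cont = cont, disc = disc,
       cont_names = nm[cont], disc_names = nm[disc],
       levels = vapply(disc, function(j) length(d$meta[[j]]$levels),
                       integer(1)),
       n = nrow(d$values))
}

# Zero parameter set for a layout.
.mgm_zero_params <- function(lay) {
  C <- ncol(lay$Xc); D <- length(lay$Dm)
  nu <- lapply(seq_len(D), function(dd) matrix(0, C, lay$levels[dd]))
  phi <- if (D > 1) {
    out <- vector("list", D * D)
    dim(out) <- c(D, D)
    for (a in seq_len(D - 1)) for (b in (a + 1):D)
      out[[a, b]] <- matrix(0, lay$levels[a], lay$levels[b])
    out
  } else NULL
  list(beta = matrix(0, C, C), alpha = rep(0, C),
       phi0 = lapply(seq_len(D), function(dd) rep(0, lay$levels[dd])),
       nu = nu, phi = phi)
}

# Smooth part of the objective: node-conditional negative pseudo-likelihood
# (Gaussian least squares for continuous nodes scaled by 1/(2N), mean
# multinomial deviance for discrete nodes), plus its gradient when asked.
.mgm_smooth <- function(par, lay, grad = FALSE) {
  Xc <- lay$Xc; n <- lay$n
  C <- ncol(Xc); D <- length(lay$Dm)
  f <- 0
  g <- if (grad) .mgm_zero_params(lay) else NULL

  # continuous node conditionals
  if (C > 0) {
    pred <- Xc %*% par$beta
    pred <- sweep(pred, 2, par$alpha, "+")
    if (D > 0) for (dd in seq_len(D))
      pred <- pred + lay$Dm[[dd]] %*% t(par$nu[[dd]])
    R <- Xc - pred
    f <- f + sum(R^2) / (2 * n)
    if (grad) {
      # d f / d pred = -R / n; beta shared symmetrically with zero diagonal
      gb <- -crossprod(Xc, R) / n
      gb <- gb + t(gb)
      diag(gb) <- 0
      g$beta <- gb
      g$alpha <- -colSums(R) / n
      if (D > 0) for (dd in seq_len(D))
        g$nu[[dd]] <- g$nu[[dd]] - t(crossprod(lay$Dm[[dd]], R)) / n
    }
  }

  # discrete node conditionals (multinomial logistic)
  if (D > 0) for (dd in seq_len(D)) {
    L <- lay$levels[dd]
    eta <- matrix(rep(par$phi0[[dd]], each = n), n, L)
    if (C > 0) eta <- eta + Xc %*% par$nu[[dd]]
    if (D > 1) for (ee in seq_len(D)) {
      if (ee == dd) next
      blk <- if (ee < dd) t(par$phi[[ee, dd]]) else par$phi[[dd, ee]]
      eta <- eta + lay$Dm[[ee]] %*% t(blk)
    }
    mx <- apply(eta, 1, max)
    lse <- mx + log(rowSums(exp(eta - mx)))
    f <- f - (sum(eta[lay$Dm[[dd]] == 1]) - sum(lse)) / n
    if (grad) {
      P <- exp(eta - lse)
      E <- (P - lay$Dm[[dd]]) / n       # n x L
      g$phi0[[dd]] <- g$phi0[[dd]] + colSums(E)
      if (C > 0) g$nu[[dd]] <- g$nu[[dd]] + crossprod(Xc, E)
      if (D > 1) for (ee in seq_len(D)) {
        if (ee == dd) next
        ge <- crossprod(E, lay$Dm[[ee]]) # L_dd x L_ee
        if (ee < dd) g$phi[[ee, dd]] <- g$phi[[ee, dd]] + t(ge)
        else g$phi[[dd, ee]] <- g$phi[[dd, ee]] + ge
      }
    }
  }
  list(value = f, grad = g)
}

.mgm_penalty_value <- function(par, pen) {
  v <- 0
  C <- nrow(par$beta)
  if (C > 1) v <- v + pen$lambda_cc * sum(abs(par$beta[upper.tri(par$beta)]))
  for (nu in par$nu)
    if (!is.null(nu) && nrow(nu))
      v <- v + pen$lambda_cd * sum(sqrt(rowSums(nu^2)))
  if (!is.null(par$phi)) {
    D <- dim(par$phi)[1]
    for (a in seq_len(D)) for (b in seq_len(D))
      if (b > a && !is.null(par$phi[[a, b]]))
        v <- v + pen$lambda_dd * sqrt(sum(par$phi[[a, b]]^2))
  }
  v
}

# Proximal operator: soft-threshold beta entries, group-soft-threshold nu
# rows (one group per continuous-discrete pair) and Phi blocks.
.mgm_prox <- function(par, pen, step) {
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  b <- soft(par$beta, step * pen$lambda_cc)
  diag(b) <- 0
  par$beta <- (b + t(b)) / 2
  for (dd in seq_along(par$nu)) {
    nu <- par$nu[[dd]]
    if (!nrow(nu)) next
    nrm <- sqrt(rowSums(nu^2))
    shr <- ifelse(nrm > 0, pmax(1 - step * pen$lambda_cd / nrm, 0), 0)
    par$nu[[dd]] <- nu * shr
  }
  if (!is.null(par$phi)) {
    D <- dim(par$phi)[1]
    for (a in seq_len(D)) for (bb in seq_len(D)) {
      if (bb <= a || is.null(par$phi[[a, bb]])) next
      blk <- par$phi[[a, bb]]
      nrm <- sqrt(sum(blk^2))
      par$phi[[a, bb]] <- if (nrm > 0)
        blk * max(1 - step * pen$lambda_dd / nrm, 0) else blk
    }
  }
  par
}

.mgm_axpy <- function(par, g, step) {
  par$beta <- par$beta - step * g$beta
  par$alpha <- par$alpha - step * g$alpha
  for (dd in seq_along(par$nu)) {
    par$nu[[dd]] <- par$nu[[dd]] - step * g$nu[[dd]]
    par$phi0[[dd]] <- par$phi0[[dd]] - step * g$phi0[[dd]]
  }
  if (!is.null(par$phi)) {
    D <- dim(par$phi)[1]
    for (a in seq_len(D)) for (b in seq_len(D))
      if (b > a && !is.null(par$phi[[a, b]]))
        par$phi[[a, b]] <- par$phi[[a, b]] - step * g$phi[[a, b]]
  }
  par
}

#' Negative pseudo-likelihood of the mixed graphical model
#'
#' Sum over nodes of the node-conditional losses sharing one symmetric
#' parameter set: Gaussian least-squares conditionals (scaled by `1/(2N)`)
#' for continuous nodes and mean multinomial-logistic deviances for ordinal
#' nodes. The partition function of the joint model is never evaluated.
#'
#' @param d A [kd_dataset()] (continuous columns should be standardized).
#' @param params Parameter list as returned in a `kd_mgm_fit` (`beta`,
#'   `alpha`, `nu`, `phi`, `phi0`).
#' @return The scalar objective (penalties excluded).
#' @export
neg_pseudolikelihood <- function(d, params) {
  stopifnot(inherits(d, "kd_dataset"))
  lay <- .mgm_layout(d)
  bad <- !is.finite(params$beta)
  if (any(bad)) stop("non-finite parameter values")
  .mgm_smooth(params, lay)$value
}

#' Fit the penalized mixed graphical model by proximal gradient descent
#'
#' Minimizes the node-conditional pseudo-likelihood plus the three block
#' penalties with ISTA and backtracking line search; `beta` is kept
#' symmetric with a zero diagonal throughout, so node-conditional estimates
#' of each interaction agree by construction. The objective trace is
#' non-increasing.
#'
#' @param d A [kd_dataset()]; continuous columns are standardized
#'   internally.
#' @param pen A [mgm_penalties()].
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative objective-change convergence tolerance
#'   (default 1e-7).
#' @return A `kd_mgm_fit` with `params` (`beta`, `alpha`, `nu`, `phi`,
#'   `phi0`), `objective_trace`, `converged`, plus the variable layout used.
#' @export
fit_mgm <- function(d, pen = mgm_penalties(), max_iter = 500, tol = 1e-7) {
  stopifnot(inherits(d, "kd_dataset"), inherits(pen, "kd_mgm_penalties"))
  if (nrow(d$values) <= 10) stop("need more than 10 samples to fit the model")
  kinds <- variable_kinds(d)
  if (any(kinds == "continuous"))
    d <- standardize(d, "continuous_only")$dataset
  lay <- .mgm_layout(d)
  par <- .mgm_zero_params(lay)

  step <- 1
  sm <- .mgm_smooth(par, lay, grad = TRUE)
  obj <- sm$value + .mgm_penalty_value(par, pen)
  trace <- obj
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    repeat {
      cand <- .mgm_prox(.mgm_axpy(par, sm$grad, step), pen, step)
      f_cand <- .mgm_smooth(cand, lay)$value
      # sufficient-decrease test of the backtracking proximal step
      dq <- .mgm_dot_diff(cand, par, sm$grad)
      if (f_cand <= sm$value + dq$lin + dq$sq / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    obj_new <- f_cand + .mgm_penalty_value(cand, pen)
    if (obj_new > obj + 1e-12) {  # safeguard: never accept an increase
      step <- step / 2
      if (step < 1e-12) break
      next
    }
    par <- cand
    sm <- .mgm_smooth(par, lay, grad = TRUE)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(1, abs(obj))) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
    step <- min(step * 1.5, 1e3)
  }
  if (!converged)
    warning("mixed-model fit did not converge in ", max_iter,
            " iterations; returning the best iterate")
  structure(list(params = par, objective_trace = trace,
                 converged = converged, layout = lay, penalties = pen),
            class = "kd_mgm_fit")
}

# <cand - par, grad> and ||cand - par||^2 over all parameter blocks.
.mgm_dot_diff <- function(cand, par, g) {
  lin <- sum((cand$beta - par$beta) * g$beta) / 2 +  # symmetric double count
    sum((cand$alpha - par$alpha) * g$alpha)
  sq <- sum((cand$beta - par$beta)^2) / 2 + sum((cand$alpha - par$alpha)^2)
  for (dd in seq_along(par$nu)) {
    lin <- lin + sum((cand$nu[[dd]] - par$nu[[dd]]) * g$nu[[dd]]) +
      sum((cand$phi0[[dd]] - par$phi0[[dd]]) * g$phi0[[dd]])
    sq <- sq + sum((cand$nu[[dd]] - par$nu[[dd]])^2) +
      sum((cand$phi0[[dd]] - par$phi0[[dd]])^2)
  }
  if (!is.null(par$phi)) {
    D <- dim(par$phi)[1]
    for (a in seq_len(D)) for (b in seq_len(D))
      if (b > a && !is.null(par$phi[[a, b]])) {
        lin <- lin + sum((cand$phi[[a, b]] - par$phi[[a, b]]) * g$phi[[a, b]])
        sq <- sq + sum((cand$phi[[a, b]] - par$phi[[a, b]])^2)
      }
  }
  list(lin = lin, sq = sq)
}

#' Extract linear-association edges from a fitted mixed graphical model
#'
#' One edge per nonzero interaction block; the effect size is `|beta_ij|`
#' for continuous pairs, the Euclidean norm of the `nu_ij` level-weight
#' vector for continuous-ordinal pairs, and the Frobenius norm of the
#' `Phi_ij` block for ordinal pairs.
#'
#' @param fit A `kd_mgm_fit`.
#' @param zero_tol Blocks with effect below this are treated as zero
#'   (default 1e-10; the proximal step produces exact zeros).
#' @return An [edge_list()] data frame of kind `"linear"`.
#' @export
extract_linear_edges <- function(fit, zero_tol = 1e-10) {
  stopifnot(inherits(fit, "kd_mgm_fit"))
  lay <- fit$layout
  par <- fit$params
  rows <- list()
  C <- length(lay$cont_names); D <- length(lay$disc_names)
  if (C > 1) for (a in seq_len(C - 1)) for (b in (a + 1):C) {
    e <- abs(par$beta[a, b])
    if (e > zero_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = lay$cont_names[a], var_b = lay$cont_names[b],
        kind = "linear", effect_size = e, stringsAsFactors = FALSE)
  }
  if (C > 0 && D > 0) for (k in seq_len(C)) for (dd in seq_len(D)) {
    e <- sqrt(sum(par$nu[[dd]][k, ]^2))
    if (e > zero_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = lay$cont_names[k], var_b = lay$disc_names[dd],
        kind = "linear", effect_size = e, stringsAsFactors = FALSE)
  }
  if (D > 1) for (a in seq_len(D - 1)) for (b in (a + 1):D) {
    e <- sqrt(sum(par$phi[[a, b]]^2))
    if (e > zero_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = lay$disc_names[a], var_b = lay$disc_names[b],
        kind = "linear", effect_size = e, stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(var_a = character(), var_b = character(), kind = character(),
               effect_size = numeric(), stringsAsFactors = FALSE)
  edge_list(edges)
}
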