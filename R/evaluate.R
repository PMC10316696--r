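#' Mann-Whitney AUC of a score vector against binary labels
#'
#' Fraction of (true, false) feature pairs where the true feature scores
#' higher, ties counted one half; equivalently the normalized Mann-Whitney
#' U statistic of the score ranking.
#'
#' @param scores Named (or plain) numeric vector of per-feature scores.
#' @param labels Logical/character vector: `TRUE`/`"true"` marks a truly
#'   associated feature.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels) {
  if (is.character(labels)) labels <- labels %in% c("true", "true_assoc")
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Causal true/false-positive counts of a graph against simulation truth
#'
#' A directed edge from a true feature into the outcome counts as a causal
#' true positive. An edge directed out of the outcome, or any directed edge
#' not incident to the outcome, counts as a causal false positive.
#' Undirected tie edges count as neither.
#'
#' @param g A [causal_graph()].
#' @param truth A `kd_sim_dataset` (or a list with `truth` labels and the
#'   outcome named `Y`).
#' @param outcome Outcome variable name (default `"Y"`).
#' @return A list with `causal_tp` and `causal_fp` counts.
#' @export
causal_confusion <- function(g, truth, outcome = "Y") {
  stopifnot(inherits(g, "kd_causal_graph"))
  labels <- truth$truth
  dp <- .directed_pairs(g$edges)
  tp <- 0L; fp <- 0L
  if (nrow(dp)) for (r in seq_len(nrow(dp))) {
    from <- dp$from[r]; to <- dp$to[r]
    if (to == outcome && identical(unname(labels[from]), "true_assoc")) {
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  list(causal_tp = tp, causal_fp = fp)
}

#' Benchmark the nonlinear selector and orientation on simulated data
#'
#' For each replicate: simulate a single-index dataset, fit the knockoff
#' model and the pairwise filter network with the outcome as response,
#' rank all features by the knockoff statistic `S` (AUC), select at the
#' knockoff+ threshold (power, false discovery proportion), orient the
#' selected true associations with the degenerate-Gaussian rule, and count
#' causal true/false positives.
#'
#' @param cfg A [sim_config()]; its seed seeds replicate `r` as
#'   `cfg$seed + r - 1`.
#' @param n_reps Number of replicate datasets.
#' @param net_cfg A [net_config()] (its seed is replaced per replicate).
#' @param dg_cfg A [dg_config()].
#' @param q FDR level for selection (default 0.05).
#' @return A `kd_bench_result`: `per_rep` data frame (one row per
#'   replicate: `seed`, `auc`, `power`, `fdp`, `n_selected`, `causal_tp`,
#'   `causal_fp`, `orient_acc`) plus an `aggregate` row of means and
#'   standard errors.
#' @export
run_benchmark <- function(cfg, n_reps = 10, net_cfg = net_config(),
                          dg_cfg = dg_config(), q = 0.05) {
  stopifnot(inherits(cfg, "kd_sim_config"), n_reps >= 1)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    sim <- simulate_dataset(cfg_r)
    net_r <- net_cfg
    net_r$seed <- cfg_r$seed
    rows[[r]] <- cbind(seed = cfg_r$seed,
                       as.data.frame(benchmark_replicate(sim, net_r, dg_cfg,
                                                         q = q)))
  }
  per_rep <- do.call(rbind, rows)
  num <- setdiff(names(per_rep), "seed")
  agg <- data.frame(metric = num,
                    mean = vapply(per_rep[num], mean, numeric(1)),
                    se = vapply(per_rep[num], function(x)
                      stats::sd(x) / sqrt(length(x)), numeric(1)),
                    row.names = NULL)
  structure(list(per_rep = per_rep, aggregate = agg, n_reps = n_reps,
                 config = cfg), class = "kd_bench_result")
}

#' Metrics for a single simulated replicate
#'
#' @param sim A `kd_sim_dataset` from [simulate_dataset()].
#' @param net_cfg A [net_config()].
#' @param dg_cfg A [dg_config()].
#' @param q FDR level.
#' @return A list of replicate metrics (see [run_benchmark()]);
#'   `orient_acc` is `NA` when nothing was selected.
#' @export
benchmark_replicate <- function(sim, net_cfg = net_config(),
                                dg_cfg = dg_config(), q = 0.05) {
  d <- sim$dataset
  feat <- setdiff(variable_names(d), "Y")
  km <- fit_knockoff_model(d$values[, feat, drop = FALSE],
                           seed = net_cfg$seed + 1000003L)
  xk <- sample_knockoffs(d$values[, feat, drop = FALSE], km)
  fit <- fit_response_model(d, "Y", knockoffs = xk, cfg = net_cfg)
  imp <- fit$importance
  lab <- sim$truth[imp$feature] == "true_assoc"

  auc <- auc_from_scores(imp$S, lab)
  thr <- knockoff_threshold(imp$S, q = q)
  sel <- imp$feature[imp$S >= thr]
  n_true <- sum(sim$truth == "true_assoc")
  power <- sum(sim$truth[sel] == "true_assoc") / n_true
  fdp <- if (length(sel)) sum(sim$truth[sel] == "null") / length(sel) else 0

  # causal counts follow the outcome-centered reading: a selected true
  # feature oriented into Y is a true causality; any edge oriented out of
  # Y is a false causality. A selected null oriented into Y is a false
  # association (already accounted for in fdp), not a mis-orientation.
  sel_true <- sel[sim$truth[sel] == "true_assoc"]
  tp <- 0L; fp <- 0L; oriented_to_y <- 0L
  for (v in sel) {
    o <- orient_pair(v, "Y", d, dg_cfg)
    dir_to_y <- o$direction == "a_to_b"
    if (o$direction != "undirected" && !dir_to_y) fp <- fp + 1L
    if (sim$truth[v] == "true_assoc" && dir_to_y) {
      tp <- tp + 1L
      oriented_to_y <- oriented_to_y + 1L
    }
  }
  orient_acc <- if (length(sel_true)) oriented_to_y / length(sel_true)
                else NA_real_
  list(auc = auc, power = power, fdp = fdp, n_selected = length(sel),
       causal_tp = tp, causal_fp = fp, orient_acc = orient_acc)
}
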