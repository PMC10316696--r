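#' Construct or validate an edge-list data frame
#'
#' The common edge container of the package: one row per unordered variable
#' pair with columns `var_a`, `var_b`, `kind` (`"linear"`/`"nonlinear"`),
#' `effect_size` (nonnegative), `normalized_effect` (min-max within each
#' kind), `direction` (`"a_to_b"`, `"b_to_a"`, `"undirected"`) and
#' `orientation_stat`. Missing optional columns are filled with defaults.
#'
#' @param edges A data frame with at least `var_a`, `var_b`, `kind`,
#'   `effect_size`.
#' @return The validated, completed edge-list data frame.
#' @export
edge_list <- function(edges) {
  need <- c("var_a", "var_b", "kind", "effect_size")
  stopifnot(is.data.frame(edges), all(need %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$kind %in% c("linear", "nonlinear")),
              all(edges$effect_size >= 0),
              all(edges$var_a != edges$var_b))
    key <- paste(pmin(edges$var_a, edges$var_b),
                 pmax(edges$var_a, edges$var_b))
    if (anyDuplicated(key)) stop("duplicate unordered pairs in edge list")
  }
  if (is.null(edges$normalized_effect))
    edges$normalized_effect <- .minmax_by_kind(edges)
  if (is.null(edges$direction)) edges$direction <- rep("undirected", nrow(edges))
  if (is.null(edges$orientation_stat))
    edges$orientation_stat <- rep(NA_real_, nrow(edges))
  rownames(edges) <- NULL
  edges
}

# Min-max normalization within each edge kind; a kind with a single edge
# (or all-equal effects) gets 1, so the strongest edge is always 1.
.minmax_by_kind <- function(edges) {
  out <- rep(NA_real_, nrow(edges))
  for (k in unique(edges$kind)) {
    ix <- edges$kind == k
    e <- edges$effect_size[ix]
    rng <- range(e)
    out[ix] <- if (diff(rng) > 0) (e - rng[1]) / diff(rng) else 1
  }
  out
}

#' Merge linear and nonlinear edge lists
#'
#' Union by unordered pair. A pair found by both stages is kept once and
#' labeled `"linear"` (the simpler model is preferred); both raw effects
#' are retained in the audit columns `effect_linear` / `effect_nonlinear`.
#' Normalized effects are recomputed per kind after the merge.
#'
#' @param linear,nonlinear Edge lists from [extract_linear_edges()] and
#'   [select_nonlinear()].
#' @return A merged [edge_list()] with audit columns.
#' @export
merge_edges <- function(linear, nonlinear) {
  lin <- as.data.frame(linear)[, c("var_a", "var_b", "kind", "effect_size")]
  non <- as.data.frame(nonlinear)[, c("var_a", "var_b", "kind", "effect_size")]
  key <- function(e) paste(pmin(e$var_a, e$var_b), pmax(e$var_a, e$var_b))
  lin$effect_linear <- lin$effect_size
  lin$effect_nonlinear <- rep(NA_real_, nrow(lin))
  non$effect_linear <- rep(NA_real_, nrow(non))
  non$effect_nonlinear <- non$effect_size
  dup <- key(non) %in% key(lin)
  if (any(dup)) {
    m <- match(key(non)[dup], key(lin))
    lin$effect_nonlinear[m] <- non$effect_size[dup]
  }
  merged <- rbind(lin, non[!dup, , drop = FALSE])
  merged$normalized_effect <- .minmax_by_kind(merged)
  edge_list(merged)
}

#' Assemble a causal graph container
#'
#' @param nodes Character vector of variable names.
#' @param edges An [edge_list()] with directions filled in.
#' @return A `kd_causal_graph` with an empty removal audit.
#' @export
causal_graph <- function(nodes, edges) {
  edges <- edge_list(edges)
  stopifnot(all(c(edges$var_a, edges$var_b) %in% nodes))
  structure(list(nodes = nodes, edges = edges,
                 removed_edges = cbind(edges[0, , drop = FALSE],
                                       reason = character(0))),
            class = "kd_causal_graph")
}

#' @export
print.kd_causal_graph <- function(x, ...) {
  dirs <- x$edges$direction
  cat("<kd_causal_graph> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", sum(dirs != "undirected"), " directed, ",
      sum(dirs == "undirected"), " tie), ",
      nrow(x$removed_edges), " removed\n", sep = "")
  invisible(x)
}

# Directed adjacency as a from/to data frame (ties excluded).
.directed_pairs <- function(edges) {
  dirs <- edges$direction
  keep <- dirs != "undirected"
  data.frame(
    from = ifelse(dirs[keep] == "a_to_b", edges$var_a[keep], edges$var_b[keep]),
    to = ifelse(dirs[keep] == "a_to_b", edges$var_b[keep], edges$var_a[keep]),
    row = which(keep), stringsAsFactors = FALSE)
}

# Depth-first search for one directed cycle; returns the edge-list row
# indices along the cycle, or NULL when the directed subgraph is acyclic.
.find_cycle <- function(edges) {
  dp <- .directed_pairs(edges)
  if (!nrow(dp)) return(NULL)
  nodes <- unique(c(dp$from, dp$to))
  adj <- split(seq_len(nrow(dp)), factor(dp$from, levels = nodes))
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  stack_rows <- integer(0)
  result <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    for (ei in adj[[v]]) {
      w <- dp$to[ei]
      if (color[w] == 1L) {
        # walk the open stack back to w to recover the cycle rows
        path <- c(stack_rows, ei)
        starts <- dp$from[path]
        cut <- max(which(starts == w))
        result <<- dp$row[path[cut:length(path)]]
        return(TRUE)
      }
      if (color[w] == 0L) {
        stack_rows <<- c(stack_rows, ei)
        if (visit(w)) return(TRUE)
        stack_rows <<- stack_rows[-length(stack_rows)]
      }
    }
    color[v] <<- 2L
    FALSE
  }
  for (v in nodes) {
    if (color[v] == 0L && visit(v)) return(result)
  }
  NULL
}

#' Remove directed cycles by discarding the weakest cycle edge
#'
#' While the directed subgraph contains a cycle (found by depth-first
#' search), the cycle edge with the smallest normalized effect size is
#' removed (ties broken lexicographically by endpoint names) and logged in
#' the removal audit. Undirected tie edges never participate.
#'
#' @param g A [causal_graph()].
#' @return The graph with an acyclic directed subgraph and an updated
#'   `removed_edges` audit.
#' @export
break_cycles <- function(g) {
  stopifnot(inherits(g, "kd_causal_graph"))
  repeat {
    cyc <- .find_cycle(g$edges)
    if (is.null(cyc)) break
    sub <- g$edges[cyc, , drop = FALSE]
    ord <- order(sub$normalized_effect, pmin(sub$var_a, sub$var_b),
                 pmax(sub$var_a, sub$var_b))
    drop_row <- cyc[ord[1L]]
    removed <- cbind(g$edges[drop_row, , drop = FALSE],
                     reason = "cycle_repair")
    g$removed_edges <- rbind(g$removed_edges, removed)
    g$edges <- g$edges[-drop_row, , drop = FALSE]
    rownames(g$edges) <- NULL
  }
  g
}

#' Remove a user-specified edge
#'
#' @param g A [causal_graph()].
#' @param var_a,var_b The unordered pair to drop.
#' @return The graph without that edge, logged as `user_removed`.
#' @export
drop_edge <- function(g, var_a, var_b) {
  stopifnot(inherits(g, "kd_causal_graph"))
  hit <- (g$edges$var_a == var_a & g$edges$var_b == var_b) |
    (g$edges$var_a == var_b & g$edges$var_b == var_a)
  if (!any(hit)) stop("no edge between '", var_a, "' and '", var_b, "'")
  removed <- cbind(g$edges[hit, , drop = FALSE], reason = "user_removed")
  g$removed_edges <- rbind(g$removed_edges, removed)
  g$edges <- g$edges[!hit, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' Check the directed subgraph for acyclicity
#'
#' @param g A [causal_graph()].
#' @return `TRUE` when no directed cycle exists.
#' @export
is_acyclic <- function(g) is.null(.find_cycle(g$edges))

#' Run the full two-stage causal-structure pipeline
#'
#' Optionally screens candidate pairs on the inverse covariance, selects
#' linear associations with the penalized mixed graphical model and
#' nonlinear associations with the knockoff-filter network, merges the two
#' edge sets, orients every edge with the pairwise degenerate-Gaussian rule,
#' and repairs directed cycles. Deterministic given the seed carried by
#' `net_cfg`.
#'
#' @param d A [kd_dataset()].
#' @param targets Response variables for the nonlinear stage (default all).
#' @param pen [mgm_penalties()] for the linear stage.
#' @param net_cfg [net_config()] for the nonlinear stage.
#' @param dg_cfg [dg_config()] for orientation.
#' @param q FDR level of the knockoff selection (default 0.05).
#' @param plus Use the knockoff+ correction in the nonlinear stage (default
#'   `FALSE`; see [knockoff_threshold()]). The plain variant matches the
#'   power the method is built for; the `+` variant is more conservative on
#'   null data at the cost of a hard floor of `1/q` on the selection size.
#' @param screen Apply [precision_screen()] and keep only admissible pairs
#'   (default `FALSE`; the screen can drop hub nodes that matter
#'   downstream).
#' @param screen_tol Screen threshold (default 1e-4).
#' @param run_linear,run_nonlinear Stage switches (both `TRUE` by default).
#' @return A [causal_graph()] after orientation and cycle repair.
#' @export
run_pipeline <- function(d, targets = NULL, pen = mgm_penalties(),
                         net_cfg = net_config(), dg_cfg = dg_config(),
                         q = 0.05, plus = FALSE, screen = FALSE,
                         screen_tol = 1e-4, run_linear = TRUE,
                         run_nonlinear = TRUE) {
  stopifnot(inherits(d, "kd_dataset"))
  nm <- variable_names(d)

  empty <- data.frame(var_a = character(), var_b = character(),
                      kind = character(), effect_size = numeric(),
                      stringsAsFactors = FALSE)
  lin <- if (run_linear) extract_linear_edges(fit_mgm(d, pen)) else
    edge_list(empty)
  non <- if (run_nonlinear)
    select_nonlinear(d, targets = targets, cfg = net_cfg, q = q,
                     plus = plus) else
    edge_list(empty)

  if (screen) {
    adm <- precision_screen(d, tol = screen_tol)
    adm_key <- paste(pmin(adm$var_a, adm$var_b), pmax(adm$var_a, adm$var_b))
    keep_scr <- function(e) {
      if (!nrow(e)) return(e)
      e[paste(pmin(e$var_a, e$var_b), pmax(e$var_a, e$var_b)) %in% adm_key, ,
        drop = FALSE]
    }
    lin <- keep_scr(lin)
    non <- keep_scr(non)
  }

  merged <- merge_edges(lin, non)
  if (nrow(merged)) for (r in seq_len(nrow(merged))) {
    o <- orient_pair(merged$var_a[r], merged$var_b[r], d, dg_cfg)
    merged$direction[r] <- o$direction
    merged$orientation_stat[r] <- o$delta_ll
  }
  break_cycles(causal_graph(nm, merged))
}

#' Write an edge list to a tab-separated file
#'
#' @param edges An [edge_list()] (or the `edges` of a graph).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a causal graph in Graphviz DOT format
#'
#' Directed edges use arrows; tie edges are rendered undirected (dashed).
#'
#' @param g A [causal_graph()].
#' @param path Output `.dot` path.
#' @return Invisibly, `path`.
#' @export
write_dot <- function(g, path) {
  stopifnot(inherits(g, "kd_causal_graph"))
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c("digraph causal {", paste0("  ", q(g$nodes), ";"))
  if (nrow(g$edges)) for (r in seq_len(nrow(g$edges))) {
    e <- g$edges[r, ]
    lines <- c(lines, switch(e$direction,
      a_to_b = sprintf("  %s -> %s [label=\"%.3f\"];", q(e$var_a), q(e$var_b),
                       e$normalized_effect),
      b_to_a = sprintf("  %s -> %s [label=\"%.3f\"];", q(e$var_b), q(e$var_a),
                       e$normalized_effect),
      sprintf("  %s -> %s [dir=none, style=dashed];", q(e$var_a), q(e$var_b))))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
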