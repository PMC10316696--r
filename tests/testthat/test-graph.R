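mk_edges <- function(...) {
  rows <- list(...)
  edge_list(do.call(rbind, lapply(rows, function(r)
    data.frame(var_a = r[[1]], var_b = r[[2]], kind = r[[3]],
               effect_size = as.numeric(r[[4]]),
               direction = if (length(r) > 4) r[[5]] else "undirected",
               stringsAsFactors = FALSE))))
}

test_that("merging keeps disjoint pairs and prefers linear for shared ones", {
  lin <- mk_edges(list("a", "b", "linear", 0.4))
  non <- mk_edges(list("c", "d", "nonlinear", 2.0))
  m <- merge_edges(lin, non)
  expect_identical(nrow(m), 2L)
  expect_setequal(m$kind, c("linear", "nonlinear"))

  non2 <- mk_edges(list("b", "a", "nonlinear", 3.0),
                   list("c", "d", "nonlinear", 1.0))
  m2 <- merge_edges(lin, non2)
  expect_identical(nrow(m2), 2L)
  shared <- m2[m2$var_a == "a" | m2$var_b == "a", ]
  expect_identical(shared$kind, "linear")
  expect_equal(shared$effect_linear, 0.4)
  expect_equal(shared$effect_nonlinear, 3.0)
})

test_that("normalized effects are min-max scaled within each kind", {
  e <- mk_edges(list("a", "b", "linear", 0.1), list("a", "c", "linear", 0.5),
                list("b", "c", "nonlinear", 2), list("b", "d", "nonlinear", 6))
  expect_equal(e$normalized_effect, c(0, 1, 0, 1))
  # middle value lands proportionally
  e2 <- mk_edges(list("a", "b", "linear", 1), list("a", "c", "linear", 2),
                 list("b", "c", "linear", 5))
  expect_equal(e2$normalized_effect, c(0, 0.25, 1))
  # a single edge of a kind is its own maximum
  expect_equal(mk_edges(list("a", "b", "linear", 0.7))$normalized_effect, 1)
})

test_that("edge list validation rejects duplicates and self-loops", {
  expect_error(mk_edges(list("a", "b", "linear", 1),
                        list("b", "a", "linear", 2)), "duplicate")
  expect_error(mk_edges(list("a", "a", "linear", 1)))
})

test_that("cycle repair removes the weakest cycle edge and nothing else", {
  acyc <- mk_edges(list("a", "b", "linear", 1, "a_to_b"),
                   list("b", "c", "linear", 0.5, "a_to_b"))
  g <- causal_graph(c("a", "b", "c"), acyc)
  expect_true(is_acyclic(g))
  expect_identical(nrow(break_cycles(g)$removed_edges), 0L)

  cyc <- mk_edges(list("a", "b", "linear", 0.9, "a_to_b"),
                  list("b", "c", "linear", 0.5, "a_to_b"),
                  list("c", "a", "linear", 0.2, "a_to_b"))
  g2 <- break_cycles(causal_graph(c("a", "b", "c"), cyc))
  expect_true(is_acyclic(g2))
  expect_identical(nrow(g2$removed_edges), 1L)
  expect_identical(g2$removed_edges$var_a, "c")
  expect_identical(g2$removed_edges$reason, "cycle_repair")
})

test_that("random tournaments end acyclic, matching an independent check", {
  skip_if_not_installed("igraph")
  set.seed(91)
  for (rep in 1:10) {
    nodes <- letters[1:6]
    pairs <- t(combn(nodes, 2))
    dirs <- sample(c("a_to_b", "b_to_a"), nrow(pairs), replace = TRUE)
    e <- edge_list(data.frame(var_a = pairs[, 1], var_b = pairs[, 2],
                              kind = "nonlinear",
                              effect_size = runif(nrow(pairs)),
                              direction = dirs, stringsAsFactors = FALSE))
    g <- break_cycles(causal_graph(nodes, e))
    dp <- knockdag:::.directed_pairs(g$edges)
    ig <- igraph::graph_from_data_frame(dp[, c("from", "to")],
                                        vertices = nodes)
    expect_true(igraph::is_dag(ig))
    # audit completeness: every input edge is either kept or logged
    expect_identical(nrow(g$edges) + nrow(g$removed_edges), nrow(e))
  }
})

test_that("user edge removal is applied and audited", {
  e <- mk_edges(list("a", "b", "linear", 1, "a_to_b"),
                list("b", "c", "linear", 0.5, "a_to_b"))
  g <- drop_edge(causal_graph(c("a", "b", "c"), e), "c", "b")
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$removed_edges$reason, "user_removed")
  expect_error(drop_edge(g, "a", "c"), "no edge")
})

test_that("the full pipeline runs deterministically on a small dataset", {
  sim <- simulate_dataset(sim_config(3, 2, 400, seed = 92))
  cfg <- fast_net(92, epochs = 60)
  g1 <- run_pipeline(sim$dataset, targets = "Y", net_cfg = cfg)
  g2 <- run_pipeline(sim$dataset, targets = "Y", net_cfg = cfg)
  expect_identical(g1$edges, g2$edges)
  expect_true(is_acyclic(g1))
  expect_true(all(c("kind", "effect_size", "normalized_effect", "direction",
                    "orientation_stat") %in% names(g1$edges)))

  # DOT and TSV export round out the audit trail
  dot <- withr::local_tempfile(fileext = ".dot")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dot(g1, dot)
  write_edges(g1$edges, tsv)
  expect_true(any(grepl("digraph", readLines(dot))))
  expect_identical(nrow(utils::read.delim(tsv)), nrow(g1$edges))
})

test_that("independent noise columns yield an empty or near-empty graph", {
  # under the conservative knockoff+ variant almost nothing survives on
  # pure noise (the plain variant admits ~1/2 spurious pick per response)
  n_edges <- vapply(1:4, function(s) {
    set.seed(900 + s)
    x <- matrix(rnorm(400 * 4), 400, 4)
    d <- kd_dataset(x, lapply(paste0("v", 1:4), variable_meta))
    g <- run_pipeline(d, net_cfg = fast_net(900 + s, epochs = 20),
                      plus = TRUE)
    nrow(g$edges)
  }, integer(1))
  expect_lte(mean(n_edges), 0.5)
})
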