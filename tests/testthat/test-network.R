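toy_ct <- function() {
  cand <- toy_compounds(c("c1", "c2", "c3"), c("A", "A", "B"))
  acc <- toy_scores(c("c1", "c2", "c2"), c("t1", "t1", "t2"),
                    rf = rep(0.9, 3), svm = rep(0.9, 3))
  build_ct_network(cand, acc)
}

test_that("compound-target construction drops isolates and keeps incident targets", {
  ct <- toy_ct()
  s <- network_summary(ct$network)
  expect_equal(s$n_left, 2)
  expect_equal(s$n_right, 2)
  expect_equal(s$n_edges, 3)
  expect_equal(ct$dropped, "c3")
  expect_equal(node_degree(ct$network, "t1"), 2)
  expect_equal(node_degree(ct$network, "c1"), 1)
  expect_error(node_degree(ct$network, "nope"), "unknown node")

  # no accepted pairs: empty network, everything dropped
  cand <- toy_compounds()
  none <- build_ct_network(cand, toy_scores(character(), character(),
                                            numeric(), numeric()))
  expect_equal(network_summary(none$network)$n_nodes, 0)
  expect_setequal(none$dropped, cand$compound_id)

  expect_error(
    build_ct_network(cand, toy_scores("ghost", "t1", 0.9, 0.9)),
    "unknown compound")
})

test_that("degree sums equal edge counts on generated networks", {
  for (seed in c(2, 3, 4)) {
    cfg <- sim_config(seed = seed)
    cand <- gen_candidate_table(cfg)
    acc <- consensus_filter(gen_interaction_scores(cfg, cand))
    ct <- build_ct_network(cand, acc)
    g <- ct$network$graph
    v_type <- igraph::V(g)$type
    deg <- igraph::degree(g)
    expect_equal(sum(deg[!v_type]), igraph::ecount(g))
    expect_equal(sum(deg[v_type]), igraph::ecount(g))
    expect_equal(length(ct$dropped) + sum(!v_type), nrow(cand))
    expect_true(igraph::is_bipartite(g))
  }
})

test_that("duplicate accepted pairs collapse with a warning", {
  cand <- toy_compounds("c1", "A")
  acc <- toy_scores(c("c1", "c1"), c("t1", "t1"), rf = c(0.9, 0.95),
                    svm = c(0.9, 0.95))
  expect_warning(ct <- build_ct_network(cand, acc), "duplicate")
  expect_equal(network_summary(ct$network)$n_edges, 1)
})

test_that("herb aggregates compute per-herb compound counts, degrees and means", {
  ct <- toy_ct()
  agg <- herb_aggregates(ct$network)
  a <- agg[agg$herb_id == "A", ]
  expect_equal(a$n_active_compounds, 2)
  expect_equal(a$total_degree, 3)
  expect_equal(a$mean_targets_per_compound, 1.5)
  expect_false("B" %in% agg$herb_id)  # all of B's compounds were isolated
})

test_that("role classification follows the rank rule with deterministic ties", {
  aggs <- data.frame(herb_id = c("A", "B", "C"),
                     n_active_compounds = c(32, 8, 2),
                     total_degree = c(384, 58, 13))
  roles <- classify_roles(aggs, chen_fraction = 0.35)
  expect_equal(setNames(roles$role, roles$herb_id),
               c(A = "jun", B = "chen", C = "zuo_shi"))

  # 20 aggregates split 1 / 7 / 12 at the default fraction
  aggs20 <- data.frame(herb_id = sprintf("h%02d", 1:20),
                       n_active_compounds = 40:21,
                       total_degree = 400:381)
  roles20 <- classify_roles(aggs20)
  expect_equal(as.integer(table(roles20$role)[c("jun", "chen", "zuo_shi")]),
               c(1L, 7L, 12L))

  # all-equal input: lexicographic, flagged ties
  flat <- data.frame(herb_id = c("b", "a", "c"),
                     n_active_compounds = rep(3, 3), total_degree = rep(9, 3))
  r <- classify_roles(flat, chen_fraction = 0.35)
  expect_equal(r$herb_id, c("a", "b", "c"))
  expect_true(all(r$tied))

  # permutation invariance
  perm <- classify_roles(aggs[c(3, 1, 2), ], chen_fraction = 0.35)
  expect_equal(perm[order(perm$herb_id), ], roles[order(roles$herb_id), ])

  single <- classify_roles(data.frame(herb_id = "only",
                                      n_active_compounds = 1,
                                      total_degree = 5))
  expect_equal(single$role, "jun")
})

test_that("planted role tiers are recovered across seeded replicates", {
  hits <- 0L
  for (seed in 1:40) {
    cfg <- sim_config(seed = 1000 + seed)
    cand <- gen_candidate_table(cfg)
    acc <- consensus_filter(gen_interaction_scores(cfg, cand))
    roles <- classify_roles(herb_aggregates(build_ct_network(cand, acc)$network))
    truth <- sim_herbs(cfg)
    got <- roles$role[match(truth$herb_id, roles$herb_id)]
    if (identical(got, truth$role)) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("target-pathway network links targets to containing sets", {
  gs <- gene_set_collection(list(P1 = c("t1", "t2"), P2 = "t2"))
  tp <- build_tp_network(c("t1", "t2", "t3"), gs)
  expect_setequal(net_edge_pairs(tp$network), c("P1~t1", "P1~t2", "P2~t2"))
  expect_equal(tp$n_multi_pathway, 1)
  expect_equal(tp$multi_pathway_targets, "t2")
  s <- network_summary(tp$network)
  expect_equal(s$n_left * s$mean_degree_left, s$n_edges)

  empty <- build_tp_network(c("t1"), gene_set_collection(list(P = "zz")))
  expect_equal(network_summary(empty$network)$n_nodes, 0)
})

test_that("edges within one part are rejected", {
  expect_error(
    bipartite_network(data.frame(left = "x", right = "x"), "a", "b"),
    "both parts")
})
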