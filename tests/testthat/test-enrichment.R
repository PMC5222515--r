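toy_universe <- paste0("g", 1:20)

test_that("ORA p-values match direct enumeration", {
  # universe 20, term of 5, select 10, overlap 4:
  # (C(5,4)C(15,6) + C(5,5)C(15,5)) / C(20,10) = 28028/184756
  gs <- gene_set_collection(list(term = paste0("g", 1:5)),
                            universe = toy_universe)
  res <- ora(paste0("g", c(1:4, 6:11)), gs, alpha = 1)
  expect_equal(res$p_raw, 28028 / 184756, tolerance = 1e-12)
  expect_equal(res$k_overlap, 4)

  # seeded sweep over small universes against the enumeration oracle
  set.seed(31)
  for (rep in 1:30) {
    N <- sample(5:40, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample.int(N, 1)
    members <- sample(uni, K)
    n <- sample.int(N, 1)
    sel <- sample(uni, n)
    k <- length(intersect(members, sel))
    res <- ora(sel, gene_set_collection(list(t = members), universe = uni),
               alpha = 1)
    expect_equal(res$p_raw, enum_upper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("zero overlap gives p = 1 and saturation leaves nothing enriched", {
  gs <- gene_set_collection(list(t1 = paste0("g", 1:5)),
                            universe = toy_universe)
  res <- ora(paste0("g", 6:10), gs, alpha = 1)
  expect_equal(res$p_raw, 1)
  expect_equal(nrow(ora(paste0("g", 6:10), gs, alpha = 0.05)), 0)

  # selected = universe: every p_raw is 1, nothing retained at 0.05
  gs2 <- gene_set_collection(list(a = paste0("g", 1:5), b = paste0("g", 3:9)),
                             universe = toy_universe)
  all_sel <- ora(toy_universe, gs2, alpha = 1)
  expect_true(all(all_sel$p_raw == 1))
  expect_equal(nrow(ora(toy_universe, gs2, alpha = 0.05)), 0)
})

test_that("EASE variant discounts one overlap and is more conservative", {
  gs <- gene_set_collection(list(t = paste0("g", 1:5)),
                            universe = toy_universe)
  sel <- paste0("g", c(1:4, 6:11))
  std <- ora(sel, gs, alpha = 1)$p_raw
  ease <- ora(sel, gs, alpha = 1, variant = "ease")$p_raw
  expect_equal(ease, enum_upper_tail(20, 5, 10, 3), tolerance = 1e-12)
  expect_gt(ease, std)
})

test_that("selection validation and universe handling", {
  gs <- gene_set_collection(list(t = c("g1", "g2")), universe = toy_universe)
  expect_error(ora(c("g1", "zz"), gs), "outside the universe")
  expect_error(ora("g1", gene_set_collection(list(t = "g1")),
                   universe = character()), "empty universe")
})

test_that("BH adjustment is monotone, capped at 1, and never below raw p", {
  set.seed(41)
  sets <- setNames(lapply(1:15, function(i) sample(toy_universe, sample(3:8, 1))),
                   paste0("t", 1:15))
  gs <- gene_set_collection(sets, universe = toy_universe)
  res <- ora(sample(toy_universe, 8), gs, alpha = 1)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(all(res$p_adjusted <= 1))
  expect_true(all(diff(res$p_adjusted[order(res$p_raw)]) >= -1e-15))
  expect_equal(res$p_adjusted, p.adjust(res$p_raw, "BH"), tolerance = 1e-12)
  expect_equal(res$rank, seq_len(nrow(res)))
})

test_that("adding an in-term target never raises that term's p", {
  gs <- gene_set_collection(list(t = paste0("g", 1:6)),
                            universe = toy_universe)
  sel <- paste0("g", c(1, 2, 7, 8))
  p_before <- ora(sel, gs, alpha = 1)$p_raw
  p_after <- ora(c(sel, "g3"), gs, alpha = 1)$p_raw
  expect_lte(p_after, p_before)
})

test_that("top_terms truncates, keeps rank order and recovers a planted term", {
  cfg <- sim_config(seed = 51)
  targets <- tcmnp:::sim_targets(cfg)
  sel <- targets[1:12]
  gs <- gen_gene_sets(cfg, targets, selected = sel)
  res <- ora(sel, gs, alpha = 1)
  expect_equal(res$term_id[1], "term_planted")
  expect_equal(nrow(top_terms(res, 5)), 5)
  expect_equal(nrow(top_terms(res[1:3, ], 20)), 3)
  expect_equal(top_terms(res, 5)$p_raw, sort(res$p_raw)[1:5])
  expect_error(top_terms(res, -1), ">= 0")
})
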