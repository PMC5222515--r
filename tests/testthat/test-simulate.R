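test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 61)
  expect_identical(gen_compound_table(cfg), gen_compound_table(cfg))
  expect_identical(gen_corpus_counts(cfg), gen_corpus_counts(cfg))
  expect_identical(gen_gene_sets(cfg)$sets, gen_gene_sets(cfg)$sets)
  cand <- gen_candidate_table(cfg)
  expect_identical(gen_interaction_scores(cfg, cand),
                   gen_interaction_scores(cfg, cand))
  # different seeds give different draws
  expect_false(identical(gen_compound_table(cfg),
                         gen_compound_table(sim_config(seed = 62))))
})

test_that("generated tables pass reader validation unchanged", {
  cfg <- sim_config(seed = 63)
  dir <- withr::local_tempdir()
  paths <- simulate_study(cfg, dir)
  cmp <- read_compound_table(paths$compounds)
  expect_equal(nrow(cmp), cfg$n_compounds)
  expect_silent(read_herb_counts(paths$herb_counts))
  expect_silent(read_interaction_table(paths$interactions))
  expect_equal(nrow(read_target_table(paths$targets)), cfg$n_targets)
  expect_equal(length(read_gene_sets(paths$gene_sets)), cfg$n_gene_sets)
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$seed, 63)
})

test_that("descriptor draws match the configured distribution (CLT bound)", {
  cfg <- sim_config(seed = 64, n_compounds = 10000)
  cmp <- gen_compound_table(cfg)
  expect_lt(abs(mean(cmp$mw) - 344.15), 3 * 113.89 / 100)  # 3 sd / sqrt(1e4)
  expect_true(all(cmp$mw >= 0))
  expect_true(all(cmp[, c("ncic", "nhdon", "nhacc", "rbn")] >= 0))
  expect_true(all(cmp[, c("ncic", "nhdon", "nhacc", "rbn")] ==
                    round(cmp[, c("ncic", "nhdon", "nhacc", "rbn")])))
})

test_that("the expected pass fraction is realized within a binomial bound", {
  cfg <- sim_config(seed = 65)  # 1618 compounds, pass fraction 150/1618
  cmp <- gen_compound_table(cfg)
  n_cand <- nrow(apply_ob_dl_filter(cmp)$candidates)
  p <- 150 / 1618
  expect_lt(abs(n_cand - 150), 3 * sqrt(1618 * p * (1 - p)))
})

test_that("corpus generator calibrates to its enrichment factor", {
  cfg <- sim_config(seed = 66)
  # factor 0 forces k = 0, p = 1, never selected
  null0 <- gen_corpus_counts(cfg, factors = 0)
  expect_true(all(null0$herbs$k_disease_articles == 0))
  res0 <- herb_association(null0$herbs, null0$corpus)
  expect_true(all(res0$p_value == 1))
  expect_false(any(res0$selected))

  # factor 3 at the default article range: essentially always selected
  enr <- gen_corpus_counts(cfg, factors = 3)
  expect_true(all(herb_association(enr$herbs, enr$corpus)$selected))
})

test_that("planted gene set term dominates enrichment of the designated subset", {
  cfg <- sim_config(seed = 67, planted_term_fraction = 1)
  targets <- tcmnp:::sim_targets(cfg)
  gs <- gen_gene_sets(cfg, targets)
  res <- ora(targets, gs, alpha = 1)
  expect_equal(res$term_id[1], "term_planted")
  expect_equal(res$rank[res$term_id == "term_planted"], 1)

  none <- gen_gene_sets(sim_config(seed = 68, n_gene_sets = 0))
  expect_equal(length(none), 0)
})

test_that("tier means with zero rate drop every compound of that herb", {
  cfg <- sim_config(seed = 69,
                    tiers = list(jun = list(n = 1, compounds = 10, mean_targets = 6),
                                 chen = list(n = 1, compounds = 10, mean_targets = 0),
                                 zuo_shi = list(n = 1, compounds = 10, mean_targets = 3)),
                    decoys_per_compound = 0)
  cand <- gen_candidate_table(cfg)
  acc <- consensus_filter(gen_interaction_scores(cfg, cand))
  ct <- build_ct_network(cand, acc)
  h2 <- cand$compound_id[cand$herb_id == "h02"]
  expect_true(all(h2 %in% ct$dropped))
})
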