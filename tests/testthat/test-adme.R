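test_that("Tanimoto coefficient: identity, orthogonality, hand-derived value", {
  expect_equal(compute_dl(c(3, 4), c(3, 4)), 1)
  expect_equal(compute_dl(c(1, 0), c(0, 1)), 0)
  # A.B = 6, |A|^2 = 5, |B|^2 = 8 -> 6/7
  expect_equal(compute_dl(c(1, 2), c(2, 2)), 6 / 7, tolerance = 1e-12)
  expect_error(compute_dl(c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(compute_dl(c(0, 0), c(0, 0)), "zero")
})

test_that("Tanimoto is symmetric, bounded and 1 only on identical vectors", {
  set.seed(7)
  for (i in 1:50) {
    a <- runif(8, 0, 10); b <- runif(8, 0, 10)
    f <- compute_dl(a, b)
    expect_equal(f, compute_dl(b, a), tolerance = 1e-12)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_equal(compute_dl(a, a), 1, tolerance = 1e-12)
  }
})

test_that("reference centroid is the component-wise mean", {
  expect_equal(reference_centroid(rbind(c(0, 0), c(2, 2))), c(1, 1))
  expect_equal(reference_centroid(rbind(c(3, 1, 4))), c(3, 1, 4))
  expect_error(reference_centroid(matrix(numeric(), 0, 2)), "non-empty")

  # CLT bound: centroid of 1000 draws within 4*sigma/sqrt(1000) of mu
  set.seed(99)
  mu <- c(300, 3, 90); sigma <- c(100, 1.5, 60)
  draws <- sapply(seq_along(mu), function(j) rnorm(1000, mu[j], sigma[j]))
  expect_true(all(abs(reference_centroid(draws) - mu) <= 4 * sigma / sqrt(1000)))
})

test_that("drug-likeness against a reference table is scale-aware and bounded", {
  ref <- gen_reference_table(sim_config(seed = 3), 100)
  cand <- gen_compound_table(sim_config(seed = 4, n_compounds = 50))
  dl <- dl_against_reference(cand[, names(ref)], ref)
  expect_length(dl, 50)
  expect_true(all(dl >= 0 & dl <= 1))
  # an average-like molecule scores near 1
  expect_gt(dl_against_reference(t(reference_centroid(ref)), ref), 0.99)
})

test_that("joint OB/DL filter reproduces the Radix Salviae screen", {
  cmp <- read_compound_table(fixture("herb_compounds.tsv"))
  rs <- cmp[cmp$herb_id == "radix_salviae", ]
  expect_equal(nrow(rs), 32)

  plain <- apply_ob_dl_filter(rs, screen_config())
  expect_equal(nrow(plain$candidates), 28)

  with_rescue <- apply_ob_dl_filter(
    rs, screen_config(rescue_ids = rescue_radix_salviae))
  expect_equal(nrow(with_rescue$candidates), 32)
  expect_setequal(
    with_rescue$reasons$compound_id[with_rescue$reasons$reason == "rescued"],
    rescue_radix_salviae)
})

test_that("filter boundaries are inclusive and reason codes partition the input", {
  cmp <- toy_compounds(c("b1", "b2", "b3", "b4"), rep("h", 4),
                       ob = c(30.0, 29.999, 30, 10),
                       dl = c(0.18, 0.18, 0.1799, 0.1))
  res <- apply_ob_dl_filter(cmp, screen_config())
  expect_equal(res$reasons$reason,
               c("passed_both", "failed_ob", "failed_dl", "failed_both"))
  expect_equal(nrow(res$candidates) + nrow(res$excluded), 4)
  expect_error(
    apply_ob_dl_filter(toy_compounds("x", "h", ob = NA_real_, dl = 0.5)),
    "missing ob or dl")
})

test_that("screening is idempotent and monotone in its thresholds", {
  cmp <- read_compound_table(fixture("herb_compounds.tsv"))
  cfg <- screen_config(rescue_ids = rescue_radix_salviae)
  once <- apply_ob_dl_filter(cmp, cfg)
  twice <- apply_ob_dl_filter(once$candidates, cfg)
  expect_equal(twice$candidates, once$candidates)
  expect_equal(nrow(twice$excluded), 0)

  counts <- sapply(c(0, 20, 30, 40, 60, 120), function(ob_min)
    nrow(apply_ob_dl_filter(cmp, screen_config(ob_min = ob_min))$candidates))
  expect_true(all(diff(counts) <= 0))
  counts_dl <- sapply(c(0, 0.1, 0.18, 0.4, 0.8, 1), function(dl_min)
    nrow(apply_ob_dl_filter(cmp, screen_config(dl_min = dl_min))$candidates))
  expect_true(all(diff(counts_dl) <= 0))
})

test_that("full study fixture: candidates plus rescues cover all 150 records", {
  cmp <- read_compound_table(fixture("herb_compounds.tsv"))
  res <- apply_ob_dl_filter(
    cmp, screen_config(rescue_ids = cmp$compound_id[cmp$rescued]))
  expect_equal(nrow(res$candidates), 150)
})

test_that("deglycosylation cleaves O-linked sugars and names _qt derivatives", {
  # no sugar: record passes through unchanged
  plain <- toy_compounds("p1", "h")
  plain$smiles <- "CCO"
  expect_equal(deglycosylate(plain), plain)

  # toy aryl O-glucoside; expected aglycone derived independently by
  # deleting the glucosyl substructure: phenyl glucoside -> phenol
  rec <- toy_compounds("g1", "h")
  rec$smiles <- "c1ccccc1OC2OC(CO)C(O)C(O)C2O"
  out <- deglycosylate(rec)
  expect_equal(nrow(out), 2)
  expect_equal(out$name[2], "g1_qt")
  expect_equal(out$smiles[2], "c1ccccc1O")
  expect_true(out$is_aglycone_derivative[2])
  expect_true(is.na(out$ob[2]) && is.na(out$dl[2]))

  # annotation-flagged glycoside without a structure
  flagged <- toy_compounds("Paeoniflorin", "cortex_moutan")
  out2 <- deglycosylate(flagged, glycoside = TRUE)
  expect_equal(out2$name, c("Paeoniflorin", "Paeoniflorin_qt"))
})
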