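test_that("dual thresholds are strict and jointly required", {
  s <- toy_scores(rep("c", 4), paste0("t", 1:4),
                  rf = c(0.85, 0.80, 0.95, 0.79),
                  svm = c(0.75, 0.99, 0.70, 0.71))
  out <- consensus_filter(s)
  # 0.80 and 0.70 sit exactly on the thresholds: "greater than" excludes them
  expect_equal(out$target_id, "t1")
  expect_true(all(out$accepted))
  expect_error(
    consensus_filter(toy_scores("c", "t", rf = 1.2, svm = 0.5)),
    "outside \\[0, 1\\]")
})

test_that("whitelist restricts accepted targets", {
  s <- toy_scores(rep("c", 3), c("KEEP1", "KEEP2", "DROP"),
                  rf = rep(0.9, 3), svm = rep(0.9, 3))
  out <- consensus_filter(s, consensus_config(target_whitelist = c("KEEP1", "KEEP2")))
  expect_setequal(out$target_id, c("KEEP1", "KEEP2"))
})

test_that("consensus filtering is idempotent and monotone in both thresholds", {
  set.seed(14)
  s <- toy_scores(sample(paste0("c", 1:20), 300, replace = TRUE),
                  sample(paste0("t", 1:15), 300, replace = TRUE),
                  rf = runif(300), svm = runif(300))
  once <- consensus_filter(s)
  again <- consensus_filter(once)
  expect_equal(again[names(once)], once)

  for (th in list(c(0.5, 0.5), c(0.8, 0.7), c(0.9, 0.8), c(0.99, 0.99))) {
    prev <- consensus_filter(s, consensus_config(th[1], th[2]))
    tighter <- consensus_filter(s, consensus_config(min(th[1] + 0.05, 1),
                                                    min(th[2] + 0.05, 1)))
    expect_true(all(paste(tighter$compound_id, tighter$target_id) %in%
                      paste(prev$compound_id, prev$target_id)))
  }
})

test_that("surrogate scorer is deterministic and honors planted strength", {
  cmp <- toy_compounds(paste0("c", 1:30), rep(c("A", "B", "C"), each = 10))
  tiers <- c(A = 12, B = 7.24, C = 6.74)
  s1 <- surrogate_scores(cmp, paste0("t", 1:33), tiers, seed = 21)
  s2 <- surrogate_scores(cmp, paste0("t", 1:33), tiers, seed = 21)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, surrogate_scores(cmp, paste0("t", 1:33), tiers, seed = 22)))

  # edge strength 1: every planted pair survives the consensus filter,
  # decoys never do
  acc <- consensus_filter(s1)
  planted <- s1[s1$rf_score > 0.8 & s1$svm_score > 0.7, ]
  expect_equal(nrow(acc), nrow(planted))

  expect_error(surrogate_scores(cmp, paste0("t", 1:5), c(A = 1), seed = 1),
               "no tier mean")
})

test_that("surrogate accepted-degree tracks the planted tier mean", {
  cmp <- toy_compounds(sprintf("c%04d", 1:1000), rep("A", 1000))
  s <- surrogate_scores(cmp, sprintf("t%02d", 1:60), c(A = 12), seed = 33,
                        decoys_per_compound = 2)
  acc <- consensus_filter(s)
  mean_deg <- nrow(acc) / 1000
  expect_lt(abs(mean_deg - 12), 0.5)
})
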