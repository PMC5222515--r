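# Independent oracles and small in-code fixtures used across tests.

# Brute-force upper-tail hypergeometric by direct summation of the mass
# function with binomial coefficients; exact (to double rounding) for
# small N and fully independent of the survival-function implementation.
enum_upper_tail <- function(N, K, n, k) {
  i <- seq(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sided permutation test on the difference of means (oracle for the
# Welch default in compare_groups).
perm_test_oracle <- function(x, y, n_perm = 10000) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  hits <- sum(vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), length(x))
    abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
  }, logical(1)))
  (hits + 1) / (n_perm + 1)
}

toy_compounds <- function(ids = c("c1", "c2", "c3"),
                          herb = c("A", "A", "B"),
                          ob = 50, dl = 0.5) {
  data.frame(compound_id = ids, name = ids, herb_id = herb,
             smiles = NA_character_, ob = ob, dl = dl,
             rescued = FALSE, is_aglycone_derivative = FALSE,
             stringsAsFactors = FALSE)
}

toy_scores <- function(compound_id, target_id, rf, svm) {
  data.frame(compound_id = compound_id, target_id = target_id,
             rf_score = rf, svm_score = svm, stringsAsFactors = FALSE)
}

rescue_radix_salviae <- c("DS15", "DS19", "DS21", "DS32")

fixture <- function(name) tcmnp_example(name)

# order-free edge fingerprint of a bipartite_net
net_edge_pairs <- function(net) {
  e <- igraph::as_edgelist(net$graph)
  if (!nrow(e)) return(character())
  apply(e, 1, function(r) paste(sort(r), collapse = "~"))
}
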