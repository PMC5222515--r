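# Literature-based herb-disease association: upper-tail hypergeometric test
# over corpus article counts, with significance-based herb selection.

#' Corpus-level article counts
#'
#' Defaults are the PubMed + CNKI corpus of the packaged 20-herb
#' breast-cancer case: 104,544,921 articles in total, of which 791,592 are
#' disease-relevant.
#'
#' @param n_corpus total number of articles in the corpus (N).
#' @param k_disease_corpus number of disease-relevant articles (K).
#' @return list with `n_corpus`, `k_disease_corpus`.
#' @export
corpus_stats <- function(n_corpus = 104544921, k_disease_corpus = 791592) {
  if (k_disease_corpus > n_corpus || n_corpus < 1 || k_disease_corpus < 1) {
    stop_config("need 1 <= k_disease_corpus <= n_corpus")
  }
  list(n_corpus = n_corpus, k_disease_corpus = k_disease_corpus)
}

#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability
#' of observing at least `k` disease-relevant articles among the `n`
#' articles mentioning a herb, when `K` of the `N` corpus articles are
#' disease-relevant. Evaluated through the survival function of
#' [stats::phyper()], which works in log-space internally and is stable at
#' corpus scale (N of order 1e8); no factorials are ever formed.
#'
#' @param N corpus size (positive integer).
#' @param K number of disease-relevant articles in the corpus, `K <= N`.
#' @param n number of herb articles, `n <= N`.
#' @param k observed overlap; must satisfy `k <= min(n, K)`. Vectorized
#'   over `k`.
#' @param log.p return the log probability instead.
#' @return `P(X >= k)` in `[0, 1]` (or its log).
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 3)   # 55/210
hypergeom_upper_tail <- function(N, K, n, k, log.p = FALSE) {
  if (K > N || n > N || K < 0 || n < 0) {
    stop_validation("need 0 <= K <= N and 0 <= n <= N")
  }
  if (any(k < 0) || any(k > pmin(n, K))) {
    stop_validation("need 0 <= k <= min(n, K)")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE, log.p = log.p)
}

#' Herb-disease association over a set of herbs
#'
#' Applies the upper-tail hypergeometric test to every herb's literature
#' counts against the corpus totals and marks herbs whose p-value is at or
#' below `alpha` as selected. Mirrors the per-herb selection rule of the
#' packaged study (alpha = 0.01, no multiplicity correction); a
#' Benjamini-Hochberg adjustment is available but then selection is still
#' on the chosen column.
#'
#' @param herbs data.frame with `herb_id`, `n_total_articles`,
#'   `k_disease_articles` (see [read_herb_counts()]).
#' @param corpus a [corpus_stats()] list.
#' @param alpha selection threshold on the p-value (default 0.01).
#' @param adjust `"none"` (default, per-herb rule) or `"BH"`; when `"BH"`,
#'   selection uses the adjusted p-values.
#' @return data.frame, one row per input herb in input order: `herb_id`,
#'   `p_value`, `expected_k` (n*K/N), `enrichment_ratio` (k/expected_k),
#'   `p_adjusted` (when `adjust = "BH"`), `selected`.
#' @export
herb_association <- function(herbs, corpus = corpus_stats(), alpha = 0.01,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!nrow(herbs)) {
    return(data.frame(herb_id = character(), p_value = numeric(),
                      expected_k = numeric(), enrichment_ratio = numeric(),
                      selected = logical(), stringsAsFactors = FALSE))
  }
  if (any(herbs$k_disease_articles > herbs$n_total_articles)) {
    stop_validation("k_disease_articles exceeds n_total_articles")
  }
  N <- corpus$n_corpus; K <- corpus$k_disease_corpus
  # selection in log space so that p-values too small to represent are
  # still handled correctly (log(alpha = 0) is -Inf: nothing selected)
  lp <- mapply(function(n, k) hypergeom_upper_tail(N, K, n, k, log.p = TRUE),
               herbs$n_total_articles, herbs$k_disease_articles)
  expected <- herbs$n_total_articles * K / N
  out <- data.frame(
    herb_id = herbs$herb_id,
    p_value = exp(lp),
    expected_k = expected,
    enrichment_ratio = ifelse(expected > 0, herbs$k_disease_articles / expected, NA_real_),
    stringsAsFactors = FALSE
  )
  if (adjust == "BH") {
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
    out$selected <- out$p_adjusted <= alpha
  } else {
    out$selected <- lp <= log(alpha)
  }
  out
}
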