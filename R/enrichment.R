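# Gene-set over-representation analysis (hypergeometric ORA) with an
# optional EASE-style conservative variant and BH adjustment.

#' Over-representation analysis of a target set
#'
#' For each term the overlap between the selected targets and the term's
#' members (both intersected with the universe) is tested with the
#' upper-tail hypergeometric probability
#' `P(X >= k)` on `(N = |universe|, K = |set|, n = |selected|)`.
#' The `"ease"` variant discounts one overlapping gene (uses `k - 1` in the
#' tail), the conservative score popularized by the DAVID service.
#' Benjamini-Hochberg adjusted values are reported alongside; retention is
#' on the raw p-value by default.
#'
#' @param selected character vector of selected target ids; must be a
#'   subset of the universe.
#' @param sets a [gene_set_collection()].
#' @param universe gene universe; defaults to the collection's declared
#'   universe, else the union of all set members.
#' @param alpha retention threshold (default 0.05).
#' @param variant `"standard"` or `"ease"`.
#' @param retain_on `"raw"` (default) or `"adjusted"`.
#' @return data.frame of retained terms sorted by ascending `p_raw` (ties
#'   by term id), with `term_id`, `term_name`, `k_overlap`, `n_selected`,
#'   `K_term`, `N_universe`, `p_raw`, `p_adjusted`, `rank`.
#' @export
ora <- function(selected, sets, universe = NULL, alpha = 0.05,
                variant = c("standard", "ease"),
                retain_on = c("raw", "adjusted")) {
  variant <- match.arg(variant)
  retain_on <- match.arg(retain_on)
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(
    universe %||% sets$universe %||% unlist(sets$sets)))
  if (!length(universe)) stop_validation("empty universe")
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    stop_validation("selected id(s) outside the universe: ",
                    paste(outside, collapse = ", "))
  }
  N <- length(universe); n <- length(selected)
  res <- do.call(rbind, lapply(names(sets$sets), function(term) {
    members <- intersect(sets$sets[[term]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, selected))
    k_tail <- if (variant == "ease") max(k - 1L, 0L) else k
    p <- hypergeom_upper_tail(N, K, n, min(k_tail, min(n, K)))
    data.frame(term_id = term, term_name = sets$term_names[[term]],
               k_overlap = k, n_selected = n, K_term = K, N_universe = N,
               p_raw = p, stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    res <- data.frame(term_id = character(), term_name = character(),
                      k_overlap = integer(), n_selected = integer(),
                      K_term = integer(), N_universe = integer(),
                      p_raw = numeric(), stringsAsFactors = FALSE)
  }
  res$p_adjusted <- p.adjust(res$p_raw, method = "BH")
  keep <- if (retain_on == "raw") res$p_raw <= alpha else res$p_adjusted <= alpha
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Top enriched terms
#'
#' @param results ranked output of [ora()].
#' @param limit maximum number of terms (default 20).
#' @return the first `min(limit, nrow(results))` rows.
#' @export
top_terms <- function(results, limit = 20) {
  if (limit < 0) stop_validation("limit must be >= 0")
  head(results[order(results$p_raw, results$term_id), , drop = FALSE], limit)
}
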