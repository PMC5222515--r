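# Dual-threshold RF/SVM consensus acceptance of compound-target
# interactions, plus a deterministic surrogate scorer for synthetic tests.

#' Consensus configuration
#'
#' Thresholds are strict: a pair is accepted only when its random-forest
#' score exceeds `rf_min` AND its SVM score exceeds `svm_min` ("greater
#' than", not "at least"). An optional whitelist restricts accepted pairs
#' to a curated target set.
#'
#' @param rf_min random-forest score threshold (default 0.8).
#' @param svm_min SVM score threshold (default 0.7).
#' @param target_whitelist optional character vector of admissible target
#'   ids.
#' @return list of class `consensus_config`.
#' @export
consensus_config <- function(rf_min = 0.8, svm_min = 0.7,
                             target_whitelist = NULL) {
  if (rf_min < 0 || rf_min > 1 || svm_min < 0 || svm_min > 1) {
    stop_config("thresholds must lie in [0, 1]")
  }
  structure(list(rf_min = rf_min, svm_min = svm_min,
                 target_whitelist = if (is.null(target_whitelist)) NULL
                                    else as.character(target_whitelist)),
            class = "consensus_config")
}

#' Filter interaction scores by the dual-threshold consensus rule
#'
#' @param scores interaction table (`compound_id`, `target_id`,
#'   `rf_score`, `svm_score`), scores in `[0, 1]`.
#' @param cfg a [consensus_config()].
#' @return the accepted rows in input order, with an `accepted` column set
#'   to `TRUE`.
#' @export
#' @examples
#' s <- data.frame(compound_id = "c", target_id = c("t1", "t2"),
#'                 rf_score = c(0.85, 0.80), svm_score = c(0.75, 0.99))
#' consensus_filter(s)$target_id  # only t1: 0.80 is not > 0.8
consensus_filter <- function(scores, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  validate_interaction_scores(scores)
  keep <- scores$rf_score > cfg$rf_min & scores$svm_score > cfg$svm_min
  if (!is.null(cfg$target_whitelist)) {
    keep <- keep & scores$target_id %in% cfg$target_whitelist
  }
  out <- scores[keep, , drop = FALSE]
  out$accepted <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Deterministic surrogate compound-target scorer
#'
#' Stands in for pretrained chemogenomic RF/SVM models in synthetic
#' studies. Each herb has a tier mean: per compound the number of true
#' target links is drawn Poisson with that mean (capped at the number of
#' targets); each planted link receives supra-threshold scores with
#' probability `edge_strength`, otherwise sub-threshold scores. A
#' configurable number of decoy (non-edge) pairs with sub-threshold scores
#' is appended per compound.
#'
#' @param compounds compound table with `compound_id`, `herb_id`.
#' @param targets character vector of target ids (or a target table with a
#'   `target_id` column).
#' @param tier_means named numeric vector: herb_id -> mean number of
#'   accepted targets per compound.
#' @param seed integer seed; fixed seed gives identical output.
#' @param edge_strength probability a planted pair scores above both
#'   thresholds (default 1).
#' @param decoys_per_compound sub-threshold noise pairs per compound
#'   (default 2).
#' @param rf_min,svm_min thresholds the scores are drawn against.
#' @return interaction table with `compound_id`, `target_id`, `rf_score`,
#'   `svm_score`.
#' @export
surrogate_scores <- function(compounds, targets, tier_means, seed,
                             edge_strength = 1, decoys_per_compound = 2,
                             rf_min = 0.8, svm_min = 0.7) {
  if (is.data.frame(targets)) targets <- targets$target_id
  targets <- as.character(targets)
  unknown <- setdiff(unique(compounds$herb_id), names(tier_means))
  if (length(unknown)) {
    stop_config("no tier mean for herb(s): ", paste(unknown, collapse = ", "))
  }
  if (any(tier_means < 0)) stop_config("tier means must be >= 0")
  if (edge_strength < 0 || edge_strength > 1) {
    stop_config("edge_strength must lie in [0, 1]")
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(compounds)), function(i) {
      mu <- tier_means[[compounds$herb_id[i]]]
      n_link <- min(rpois(1, mu), length(targets))
      linked <- if (n_link > 0) sample(targets, n_link) else character()
      decoy_pool <- setdiff(targets, linked)
      n_decoy <- min(decoys_per_compound, length(decoy_pool))
      decoy <- if (n_decoy > 0) sample(decoy_pool, n_decoy) else character()
      strong <- runif(length(linked)) <= edge_strength
      rf <- c(ifelse(strong, runif(length(linked), rf_min + 1e-6, 1),
                     runif(length(linked), 0, rf_min)),
              runif(length(decoy), 0, rf_min))
      svm <- c(ifelse(strong, runif(length(linked), svm_min + 1e-6, 1),
                      runif(length(linked), 0, svm_min)),
               runif(length(decoy), 0, svm_min))
      if (!length(linked) && !length(decoy)) return(NULL)
      data.frame(compound_id = compounds$compound_id[i],
                 target_id = c(linked, decoy),
                 rf_score = rf, svm_score = svm,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(compound_id = character(), target_id = character(),
                        rf_score = numeric(), svm_score = numeric(),
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}
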