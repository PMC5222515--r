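# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; generators derive per-module seeds from one root so each stage is
# independently reproducible.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Seed offsets per generator module (kept < 2^31 together with any root seed).
SEED_OFFSETS <- c(
  compounds = 101L, interactions = 211L, corpus = 307L, gene_sets = 401L
)

#' Normalize a herb display name to a herb identifier
#'
#' Lower-cases the name, strips punctuation and joins words with
#' underscores, e.g. `"Radix Salviae"` becomes `"radix_salviae"`.
#'
#' @param x character vector of herb display names.
#' @return character vector of identifiers.
#' @export
#' @examples
#' normalize_herb_id("Radix Salviae")
normalize_herb_id <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[().,']", "", x)
  gsub("[[:space:]]+", "_", x)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("tcmnp_validation_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("tcmnp_config_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
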