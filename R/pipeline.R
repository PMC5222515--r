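# Orchestration of the full analysis: association -> screening ->
# consensus -> networks -> enrichment -> descriptors, with a serializable
# run report.

default_pipeline_config <- function() {
  list(
    inputs = list(compounds = NULL, herb_counts = NULL, targets = NULL,
                  interactions = NULL, gene_sets = NULL, reference = NULL),
    simulate = NULL,                     # a sim_config list to run synthetic
    association = list(alpha = 0.01),
    screen = list(ob_min = 30, dl_min = 0.18,
                  rescue_from_table = TRUE, rescue_ids = character()),
    consensus = list(rf_min = 0.8, svm_min = 0.7,
                     whitelist_from_targets = TRUE),
    network = list(chen_fraction = 0.35),
    enrichment = list(alpha = 0.05, variant = "standard", limit = 20),
    out_dir = NULL,
    seed = 1L
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML path")
  merge_config(default_pipeline_config(), config)
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the full systems-pharmacology pipeline
#'
#' Executes the stages in order: herb-disease association, OB/DL candidate
#' screening, compound-target consensus acceptance, compound-target and
#' target-pathway network construction with herb-role classification,
#' gene-set over-representation analysis of the accepted targets, and a
#' descriptor group comparison against a reference table (when one is
#' supplied). Inputs come either from files named in the `inputs` block or
#' from a seeded synthetic study (`simulate` block). When no herb passes
#' the association threshold, downstream stages are skipped with an
#' explicit notice in the report.
#'
#' @param config a configuration list or the path to a YAML file; see the
#'   package vignette for the block structure.
#' @return an object of class `pipeline_report`: per-stage counts, the
#'   herb role table, the top enriched terms, the configuration echo, the
#'   seed and per-stage timings (seconds).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_pipeline_config(config)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  timings <- list()
  clock <- function(expr) system.time(expr)[["elapsed"]]
  notices <- character()

  # --- inputs ------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- do.call(sim_config, sim_args)
    sim_dir <- out_dir %||% tempfile("tcmnp_sim_")
    files <- simulate_study(scfg, sim_dir)
    cfg$inputs <- files[c("compounds", "herb_counts", "targets",
                          "interactions", "gene_sets", "reference")]
  }
  inp <- cfg$inputs
  for (need in c("compounds", "herb_counts", "targets", "interactions")) {
    if (is.null(inp[[need]])) {
      stop_config("pipeline needs an input path (or simulate block) for: ", need)
    }
  }
  compounds <- read_compound_table(inp$compounds)
  herb_counts <- read_herb_counts(inp$herb_counts)
  targets <- read_target_table(inp$targets)
  scores <- read_interaction_table(inp$interactions)
  gene_sets <- if (!is.null(inp$gene_sets)) read_gene_sets(inp$gene_sets)
  reference <- if (!is.null(inp$reference)) read_table_dialect(inp$reference)

  counts <- list()
  report <- structure(list(counts = counts, herb_roles = NULL,
                           top_terms = NULL, descriptor_comparison = NULL,
                           notices = character(), config = cfg,
                           seed = cfg$seed, timings = NULL),
                      class = "pipeline_report")

  # --- stage 1: association ---------------------------------------------
  assoc <- NULL
  timings$association <- clock({
    assoc <- herb_association(herb_counts, alpha = cfg$association$alpha)
    write_stage_tsv(assoc, out_dir, "association.tsv")
  })
  counts$herbs_tested <- nrow(assoc)
  counts$herbs_selected <- sum(assoc$selected)
  selected_herbs <- assoc$herb_id[assoc$selected]
  if (!length(selected_herbs)) {
    notices <- c(notices,
                 "no herb passed the association threshold; downstream stages skipped")
    report$counts <- counts
    report$notices <- notices
    report$timings <- timings
    if (!is.null(out_dir)) write_report(report, file.path(out_dir, "report.json"))
    return(report)
  }

  # --- stage 2: screening -------------------------------------------------
  screened <- NULL
  timings$screening <- clock({
    pool <- compounds[compounds$herb_id %in% selected_herbs, , drop = FALSE]
    rescue <- cfg$screen$rescue_ids
    if (isTRUE(cfg$screen$rescue_from_table) && "rescued" %in% names(pool)) {
      rescue <- union(rescue, pool$compound_id[pool$rescued %in% TRUE])
    }
    screened <- apply_ob_dl_filter(
      pool, screen_config(cfg$screen$ob_min, cfg$screen$dl_min, rescue))
    write_stage_tsv(screened$reasons, out_dir, "screen_reasons.tsv")
    write_stage_tsv(screened$candidates, out_dir, "candidates.tsv")
  })
  counts$compounds_screened <- nrow(screened$reasons)
  counts$candidates <- nrow(screened$candidates)
  counts$rescued <- sum(screened$reasons$reason == "rescued")
  candidates <- screened$candidates

  # --- stage 3: consensus -------------------------------------------------
  accepted <- NULL
  timings$consensus <- clock({
    whitelist <- if (isTRUE(cfg$consensus$whitelist_from_targets)) {
      targets$target_id
    }
    ccfg <- consensus_config(cfg$consensus$rf_min, cfg$consensus$svm_min,
                             whitelist)
    accepted <- consensus_filter(
      scores[scores$compound_id %in% candidates$compound_id, , drop = FALSE],
      ccfg)
    write_stage_tsv(accepted, out_dir, "accepted_interactions.tsv")
  })
  counts$interactions_scored <- nrow(scores)
  counts$interactions_accepted <- nrow(accepted)

  # --- stage 4: networks --------------------------------------------------
  ct <- NULL; aggs <- NULL; roles <- NULL; tp <- NULL
  timings$networks <- clock({
    ct <- build_ct_network(candidates, accepted)
    aggs <- herb_aggregates(ct$network)
    roles <- classify_roles(aggs, cfg$network$chen_fraction)
    if (!is.null(out_dir)) {
      write_network(ct$network, file.path(out_dir, "ct_network.sif"), "sif")
      write_network(ct$network, file.path(out_dir, "ct_network.graphml"),
                    "graphml")
    }
    write_stage_tsv(aggs, out_dir, "herb_aggregates.tsv")
    write_stage_tsv(roles, out_dir, "herb_roles.tsv")
    if (!is.null(gene_sets)) {
      tp <- build_tp_network(unique(accepted$target_id), gene_sets)
      if (!is.null(out_dir)) {
        write_network(tp$network, file.path(out_dir, "tp_network.sif"), "sif")
      }
    }
  })
  s <- network_summary(ct$network)
  counts$compounds_dropped_isolated <- length(ct$dropped)
  counts$ct_compound_nodes <- s$n_left
  counts$ct_target_nodes <- s$n_right
  counts$ct_edges <- s$n_edges
  if (!is.null(tp)) {
    st <- network_summary(tp$network)
    counts$tp_nodes <- st$n_nodes
    counts$tp_edges <- st$n_edges
    counts$targets_multi_pathway <- tp$n_multi_pathway
  }

  # --- stage 5: enrichment --------------------------------------------------
  enriched <- NULL
  if (!is.null(gene_sets)) {
    timings$enrichment <- clock({
      universe <- union(unlist(gene_sets$sets),
                        union(gene_sets$universe, targets$target_id))
      enriched <- ora(intersect(unique(accepted$target_id), universe),
                      gene_sets, universe = universe,
                      alpha = cfg$enrichment$alpha,
                      variant = cfg$enrichment$variant)
      write_stage_tsv(enriched, out_dir, "enrichment.tsv")
    })
    counts$terms_enriched <- nrow(enriched)
    report$top_terms <- top_terms(enriched, cfg$enrichment$limit)
  } else {
    notices <- c(notices, "no gene sets supplied; enrichment stage skipped")
  }

  # --- stage 6: descriptors -------------------------------------------------
  if (!is.null(reference)) {
    timings$descriptors <- clock({
      cand_desc <- candidates[, intersect(DESCRIPTOR_COLS, names(candidates)),
                              drop = FALSE]
      cand_desc <- cand_desc[complete.cases(cand_desc), , drop = FALSE]
      if (nrow(cand_desc) >= 2) {
        cmp <- compare_groups(cand_desc, reference)
        report$descriptor_comparison <- cmp
        write_stage_tsv(cmp, out_dir, "descriptor_comparison.tsv")
        counts$descriptors_compared <- nrow(cmp)
      } else {
        notices <- c(notices,
                      "fewer than two candidates with full descriptors; descriptor stage skipped")
      }
    })
  } else {
    notices <- c(notices, "no reference table supplied; descriptor stage skipped")
  }

  report$counts <- counts
  report$herb_roles <- roles
  report$herb_aggregates <- aggs
  report$notices <- notices
  report$timings <- timings
  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"))
    write_report(report, file.path(out_dir, "report.txt"), format = "text")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (nm in names(x$counts)) cat(sprintf("  %-28s %s\n", nm, x$counts[[nm]]))
  if (!is.null(x$herb_roles)) {
    cat("  roles:", paste(sprintf("%s=%s", x$herb_roles$herb_id,
                                  x$herb_roles$role)[seq_len(min(5, nrow(x$herb_roles)))],
                          collapse = ", "), "...\n")
  }
  for (n in x$notices) cat("  note:", n, "\n")
  invisible(x)
}

#' Serialize a pipeline report
#'
#' JSON serialization round-trips losslessly through [read_report()]
#' (timings are retained but carry no semantic weight); the text format
#' lists the stage counts in pipeline order, one per line.
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "pipeline_report"))
  if (format == "json") {
    payload <- unclass(report)
    payload$config <- NULL  # config echo: keep serializable scalars only
    payload$config_echo <- rapply(report$config,
                                  function(x) x, how = "replace")
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE, force = TRUE)
  } else {
    lines <- c("tcmnp pipeline report",
               sprintf("seed: %s", report$seed),
               vapply(names(report$counts), function(nm) {
                 sprintf("%s: %s", nm, report$counts[[nm]])
               }, character(1)),
               vapply(report$notices, function(n) paste("note:", n),
                      character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a JSON pipeline report
#'
#' @param path path written by [write_report()] with `format = "json"`.
#' @return a `pipeline_report`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$config <- payload$config_echo
  payload$config_echo <- NULL
  payload$notices <- as.character(payload$notices %||% character())
  structure(payload, class = "pipeline_report")
}
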