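# Seeded generators producing inputs with the statistical structure the
# pipeline assumes: descriptor distributions matching the study's group
# summaries, OB/DL values spanning the filter thresholds, tiered
# compound-target link rates with a planted monarch herb, corpus counts
# with configurable per-herb enrichment, and gene sets with a planted
# enriched term. Every generator is a pure function of (config, seed).

# Group descriptor parameters (mean, sd) matching the study's printed
# summaries: herbal candidate compounds and the reference drug collection.
HERBAL_DESCRIPTOR_PARAMS <- data.frame(
  descriptor = DESCRIPTOR_COLS,
  mean = c(344.15, 3.52, 2.57, 5.63, 2.86, 0.83, 90.15, 1.87),
  sd   = c(113.89, 1.37, 2.47, 3.50, 2.67, 1.80, 57.95, 2.08),
  stringsAsFactors = FALSE
)
REFERENCE_DESCRIPTOR_PARAMS <- data.frame(
  descriptor = DESCRIPTOR_COLS,
  mean = c(346.57, 2.46, 3.17, 6.46, 5.58, 1.47, 99.93, 1.33),
  sd   = c(208.89, 1.72, 3.50, 5.59, 5.88, 2.76, 90.43, 2.50),
  stringsAsFactors = FALSE
)

#' Simulation configuration
#'
#' Defaults mirror the scale of the packaged 20-herb study: 20 herbs in
#' three role tiers (1 monarch / 7 minister / 12 assistant-guide), a
#' 1618-compound chemical pool of which an expected 150 survive the joint
#' OB/DL filter, 33 protein targets, and 20 gene sets of which one is the
#' planted enriched term. Tier mean link rates default to 12 / 7.24 / 6.74
#' accepted targets per compound.
#'
#' @param n_compounds total size of the chemical pool.
#' @param pass_fraction expected fraction of the pool passing the joint
#'   OB/DL filter (default 150/1618).
#' @param tiers named list of tiers (`jun`, `chen`, `zuo_shi`), each with
#'   `n` (herb count), `compounds` (candidate compounds per herb, used by
#'   [gen_candidate_table()] and as per-herb weights for the pool) and
#'   `mean_targets` (mean accepted targets per candidate compound).
#' @param descriptor_params,reference_params data.frames with columns
#'   `descriptor`, `mean`, `sd` for the herbal and reference groups.
#' @param ob_pass_range,dl_pass_range ranges OB and DL are drawn from for
#'   passing compounds (they start at the filter thresholds).
#' @param n_targets number of protein targets.
#' @param n_gene_sets number of gene sets including the planted term.
#' @param set_size_range size range of the decoy gene sets.
#' @param planted_term_fraction fraction of the designated selected subset
#'   covered by the planted term.
#' @param universe_multiplier the gene-set universe is this multiple of
#'   `n_targets` (the roster plus decoy genes), so a selected target set
#'   can show genuine over-representation.
#' @param corpus_n,corpus_k corpus totals (N, K) for literature counts.
#' @param herb_enrichment_factor per-herb literature enrichment factor
#'   (1 = null herb, recycled over herbs).
#' @param herb_articles_range range of per-herb article counts `n`.
#' @param edge_strength probability a planted compound-target link scores
#'   above both consensus thresholds.
#' @param decoys_per_compound sub-threshold noise pairs per compound.
#' @param seed root seed; per-generator streams are derived from it by
#'   fixed offsets.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_compounds = 1618,
                       pass_fraction = 150 / 1618,
                       tiers = list(
                         jun = list(n = 1, compounds = 32, mean_targets = 12),
                         chen = list(n = 7, compounds = 6, mean_targets = 7.24),
                         zuo_shi = list(n = 12, compounds = 4, mean_targets = 6.74)),
                       descriptor_params = HERBAL_DESCRIPTOR_PARAMS,
                       reference_params = REFERENCE_DESCRIPTOR_PARAMS,
                       ob_pass_range = c(30, 110),
                       dl_pass_range = c(0.18, 0.95),
                       n_targets = 33,
                       n_gene_sets = 20,
                       set_size_range = c(5, 25),
                       planted_term_fraction = 1,
                       universe_multiplier = 3,
                       corpus_n = 104544921,
                       corpus_k = 791592,
                       herb_enrichment_factor = 3,
                       herb_articles_range = c(5000, 100000),
                       edge_strength = 1,
                       decoys_per_compound = 2,
                       seed = 1L) {
  cfg <- list(n_compounds = n_compounds, pass_fraction = pass_fraction,
              tiers = tiers, descriptor_params = descriptor_params,
              reference_params = reference_params,
              ob_pass_range = ob_pass_range, dl_pass_range = dl_pass_range,
              n_targets = n_targets, n_gene_sets = n_gene_sets,
              set_size_range = set_size_range,
              planted_term_fraction = planted_term_fraction,
              universe_multiplier = universe_multiplier,
              corpus_n = corpus_n, corpus_k = corpus_k,
              herb_enrichment_factor = herb_enrichment_factor,
              herb_articles_range = herb_articles_range,
              edge_strength = edge_strength,
              decoys_per_compound = decoys_per_compound,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_compounds < 1 || cfg$n_targets < 1) {
    stop_config("counts must be positive")
  }
  if (cfg$pass_fraction < 0 || cfg$pass_fraction > 1 ||
      cfg$planted_term_fraction < 0 || cfg$planted_term_fraction > 1) {
    stop_config("probabilities must lie in [0, 1]")
  }
  for (t in cfg$tiers) {
    if (t$n < 1 || t$compounds < 0 || t$mean_targets < 0) {
      stop_config("tier counts must be positive and means >= 0")
    }
  }
  if (any(cfg$herb_enrichment_factor * cfg$corpus_k / cfg$corpus_n > 1)) {
    stop_config("herb_enrichment_factor * K/N exceeds 1")
  }
  invisible(cfg)
}

#' Simulated herb roster with planted role tiers
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `herb_id` (`h01`, `h02`, ...), planted `role`
#'   tier, per-herb `mean_targets` and nominal candidate `compounds`.
#' @export
sim_herbs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  role <- unlist(lapply(names(cfg$tiers),
                        function(t) rep(t, cfg$tiers[[t]]$n)))
  data.frame(
    herb_id = sprintf("h%02d", seq_along(role)),
    role = role,
    mean_targets = unlist(lapply(names(cfg$tiers), function(t)
      rep(cfg$tiers[[t]]$mean_targets, cfg$tiers[[t]]$n))),
    compounds = unlist(lapply(names(cfg$tiers), function(t)
      rep(cfg$tiers[[t]]$compounds, cfg$tiers[[t]]$n))),
    stringsAsFactors = FALSE
  )
}

sim_targets <- function(cfg) sprintf("T%02d", seq_len(cfg$n_targets))

draw_descriptors <- function(n, params) {
  out <- lapply(seq_len(nrow(params)), function(i) {
    d <- params$descriptor[i]
    x <- rnorm(n, params$mean[i], params$sd[i])
    if (d %in% c("mw", "tpsa")) x <- pmax(x, 0)          # truncated at 0
    if (d %in% COUNT_DESCRIPTORS) x <- pmax(round(x), 0) # counts
    x
  })
  names(out) <- params$descriptor
  as.data.frame(out)
}

#' Generate the chemical pool
#'
#' Draws `n_compounds` compounds spread over the herb roster (allocation
#' weighted by the tiers' nominal candidate counts), with descriptors from
#' the configured per-descriptor Gaussians (molecular weight and TPSA
#' truncated at zero, counts rounded and clipped at zero) and OB/DL values
#' placed on either side of the filter thresholds so that the expected
#' pass fraction matches `pass_fraction`.
#'
#' @param cfg a [sim_config()].
#' @return a compound table (see [read_compound_table()] for columns).
#' @export
gen_compound_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  herbs <- sim_herbs(cfg)
  w <- herbs$compounds / sum(herbs$compounds)
  m <- floor(cfg$n_compounds / nrow(herbs)) +
    (seq_len(nrow(herbs)) <= cfg$n_compounds %% nrow(herbs))
  # per-herb pass probability proportional to tier weight
  p_pass <- pmin(1, cfg$pass_fraction * cfg$n_compounds * w / m)
  with_seed(cfg$seed + SEED_OFFSETS[["compounds"]], {
    rows <- lapply(seq_len(nrow(herbs)), function(i) {
      ni <- m[i]
      desc <- draw_descriptors(ni, cfg$descriptor_params)
      pass <- runif(ni) <= p_pass[i]
      fail_mode <- sample(c("ob", "dl", "both"), ni, replace = TRUE)
      ob <- ifelse(pass, runif(ni, cfg$ob_pass_range[1], cfg$ob_pass_range[2]),
                   ifelse(fail_mode == "dl",
                          runif(ni, cfg$ob_pass_range[1], cfg$ob_pass_range[2]),
                          runif(ni, 0, cfg$ob_pass_range[1])))
      dl <- ifelse(pass, runif(ni, cfg$dl_pass_range[1], cfg$dl_pass_range[2]),
                   ifelse(fail_mode == "ob",
                          runif(ni, cfg$dl_pass_range[1], cfg$dl_pass_range[2]),
                          runif(ni, 0, cfg$dl_pass_range[1])))
      cbind(data.frame(
        compound_id = sprintf("%s_c%04d", herbs$herb_id[i], seq_len(ni)),
        name = sprintf("%s compound %d", herbs$herb_id[i], seq_len(ni)),
        herb_id = herbs$herb_id[i],
        smiles = NA_character_,
        ob = ob, dl = dl, stringsAsFactors = FALSE), desc)
    })
    out <- do.call(rbind, rows)
    out$rescued <- FALSE
    out$is_aglycone_derivative <- FALSE
    rownames(out) <- NULL
    validate_compound_table(out)
    out
  })
}

#' Generate candidate compounds with exact per-tier counts
#'
#' Bypasses the screening stage: every herb receives exactly its tier's
#' nominal number of candidate compounds, all with passing OB/DL draws.
#' Used for network-stage simulations where the planted tier structure
#' must be exact.
#'
#' @param cfg a [sim_config()].
#' @param compounds_per_herb optional named integer vector overriding the
#'   per-herb candidate counts.
#' @return a compound table.
#' @export
gen_candidate_table <- function(cfg, compounds_per_herb = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  herbs <- sim_herbs(cfg)
  m <- if (is.null(compounds_per_herb)) {
    setNames(herbs$compounds, herbs$herb_id)
  } else compounds_per_herb
  with_seed(cfg$seed + SEED_OFFSETS[["compounds"]] + 1L, {
    rows <- lapply(seq_len(nrow(herbs)), function(i) {
      ni <- m[[herbs$herb_id[i]]]
      if (ni == 0) return(NULL)
      desc <- draw_descriptors(ni, cfg$descriptor_params)
      cbind(data.frame(
        compound_id = sprintf("%s_c%04d", herbs$herb_id[i], seq_len(ni)),
        name = sprintf("%s compound %d", herbs$herb_id[i], seq_len(ni)),
        herb_id = herbs$herb_id[i],
        smiles = NA_character_,
        ob = runif(ni, cfg$ob_pass_range[1], cfg$ob_pass_range[2]),
        dl = runif(ni, cfg$dl_pass_range[1], cfg$dl_pass_range[2]),
        stringsAsFactors = FALSE), desc)
    })
    out <- do.call(rbind, rows)
    out$rescued <- FALSE
    out$is_aglycone_derivative <- FALSE
    rownames(out) <- NULL
    validate_compound_table(out)
    out
  })
}

#' Generate a synthetic reference-drug descriptor table
#'
#' A seeded stand-in for a reference drug collection's descriptor table
#' (for drug-likeness centroids and group comparisons).
#'
#' @param cfg a [sim_config()].
#' @param n number of reference molecules.
#' @return data.frame of descriptor columns.
#' @export
gen_reference_table <- function(cfg, n = 200) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + SEED_OFFSETS[["compounds"]] + 2L,
            draw_descriptors(n, cfg$reference_params))
}

#' Generate tiered compound-target interaction scores
#'
#' Wraps [surrogate_scores()] with the configuration's tier means: per
#' compound the number of supra-threshold links is Poisson with its herb's
#' tier mean, planted links score above both consensus thresholds with
#' probability `edge_strength`, everything else scores below.
#'
#' @param cfg a [sim_config()].
#' @param compounds a compound table (e.g. [gen_candidate_table()]).
#' @param targets target ids; defaults to the configured roster.
#' @return an interaction score table.
#' @export
gen_interaction_scores <- function(cfg, compounds, targets = sim_targets(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  herbs <- sim_herbs(cfg)
  tier_means <- setNames(herbs$mean_targets, herbs$herb_id)
  extra <- setdiff(unique(compounds$herb_id), names(tier_means))
  if (length(extra)) {
    stop_config("compounds reference herbs outside the roster: ",
                paste(extra, collapse = ", "))
  }
  surrogate_scores(compounds, targets, tier_means,
                   seed = cfg$seed + SEED_OFFSETS[["interactions"]],
                   edge_strength = cfg$edge_strength,
                   decoys_per_compound = cfg$decoys_per_compound)
}

#' Generate corpus literature counts
#'
#' Per herb, the total article count `n` is uniform over
#' `herb_articles_range` and the disease-relevant count `k` is binomial
#' with success probability `factor * K/N` (capped at `n`); factor 1 is a
#' null herb, larger factors plant genuine enrichment.
#'
#' @param cfg a [sim_config()].
#' @param factors per-herb enrichment factors (recycled; default the
#'   configured `herb_enrichment_factor`).
#' @return list with `corpus` (a [corpus_stats()]) and `herbs` (a herb
#'   count table as from [read_herb_counts()]).
#' @export
gen_corpus_counts <- function(cfg, factors = cfg$herb_enrichment_factor) {
  stopifnot(inherits(cfg, "sim_config"))
  herbs <- sim_herbs(cfg)
  factors <- rep_len(factors, nrow(herbs))
  if (any(factors < 0)) stop_config("enrichment factors must be >= 0")
  rate <- factors * cfg$corpus_k / cfg$corpus_n
  if (any(rate > 1)) stop_config("factor * K/N exceeds 1")
  with_seed(cfg$seed + SEED_OFFSETS[["corpus"]], {
    n <- sample(seq(cfg$herb_articles_range[1], cfg$herb_articles_range[2]),
                nrow(herbs), replace = TRUE)
    k <- pmin(rbinom(nrow(herbs), n, rate), n)
    list(corpus = corpus_stats(cfg$corpus_n, cfg$corpus_k),
         herbs = data.frame(herb_id = herbs$herb_id,
                            n_total_articles = n,
                            k_disease_articles = k,
                            stringsAsFactors = FALSE))
  })
}

#' Generate gene sets with one planted enriched term
#'
#' Produces `n_gene_sets - 1` uniform random decoy sets with sizes in
#' `set_size_range`, plus one planted term (`term_planted`) covering
#' `planted_term_fraction` of the designated selected subset. The
#' collection's universe is the target roster padded with decoy genes to
#' `universe_multiplier * n_targets`, so a selected target set can be
#' genuinely over-represented in the planted term.
#'
#' @param cfg a [sim_config()].
#' @param targets target roster; defaults to the configured one.
#' @param selected designated selected subset the planted term covers;
#'   defaults to the whole roster.
#' @return a [gene_set_collection()] with an explicit universe.
#' @export
gen_gene_sets <- function(cfg, targets = sim_targets(cfg), selected = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  targets <- as.character(targets)
  n_decoy_genes <- max(0, round((cfg$universe_multiplier - 1) * length(targets)))
  universe <- c(targets, sprintf("U%03d", seq_len(n_decoy_genes)))
  if (cfg$set_size_range[2] > length(universe)) {
    stop_config("set sizes exceed the universe size")
  }
  if (is.null(selected)) selected <- targets
  if (cfg$n_gene_sets == 0) {
    return(gene_set_collection(setNames(list(), character()),
                               universe = universe))
  }
  with_seed(cfg$seed + SEED_OFFSETS[["gene_sets"]], {
    n_decoy <- cfg$n_gene_sets - 1L
    sets <- list()
    if (n_decoy > 0) {
      sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                      n_decoy, replace = TRUE)
      for (i in seq_len(n_decoy)) {
        sets[[sprintf("term_%02d", i)]] <- sample(universe, sizes[i])
      }
    }
    n_plant <- max(1L, round(cfg$planted_term_fraction * length(selected)))
    sets[["term_planted"]] <- selected[seq_len(min(n_plant, length(selected)))]
    gene_set_collection(sets, universe = universe)
  })
}

#' Emit a full synthetic study to disk
#'
#' Writes the same TSV/GMT formats the readers consume, plus a JSON
#' manifest recording the configuration and seed.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible named list of the file paths written.
#' @export
simulate_study <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- gen_compound_table(cfg)
  corpus <- gen_corpus_counts(cfg)
  targets <- sim_targets(cfg)
  gs <- gen_gene_sets(cfg, targets)
  candidates <- apply_ob_dl_filter(compounds)$candidates
  scores <- gen_interaction_scores(cfg, candidates, targets)
  paths <- list(
    compounds = file.path(dir, "compounds.tsv"),
    herb_counts = file.path(dir, "herb_counts.tsv"),
    targets = file.path(dir, "targets.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    reference = file.path(dir, "reference_descriptors.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(compounds, paths$compounds)
  write_tsv(corpus$herbs, paths$herb_counts)
  write_tsv(data.frame(target_id = targets,
                       protein_name = paste("synthetic protein", targets),
                       uniprot_id = paste0("SYN", targets)), paths$targets)
  write_tsv(scores, paths$interactions)
  write_gene_sets(gs, paths$gene_sets)
  write_tsv(gen_reference_table(cfg), paths$reference)
  manifest <- unclass(cfg)
  manifest$tiers <- lapply(manifest$tiers, unclass)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
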