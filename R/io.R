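# Readers and writers for the tabular and graph formats the pipeline touches.

DESCRIPTOR_COLS <- c("mw", "ncic", "nhdon", "nhacc", "rbn", "hy", "tpsa", "mlogp")
COUNT_DESCRIPTORS <- c("ncic", "nhdon", "nhacc", "rbn")

#' Path to a packaged example data file
#'
#' The package ships plain-text study tables for the 20-herb breast-cancer
#' case: `herb_compounds.tsv` (150 screened ingredients with oral
#' bioavailability and drug-likeness values), `herb_literature.tsv`
#' (per-herb PubMed/CNKI article counts), `breast_cancer_targets.tsv`
#' (33 curated protein targets) and `synthetic_reference_drugs.tsv`
#' (a seeded synthetic stand-in for a reference-drug descriptor table).
#'
#' @param file file name, or `NULL` to list available files.
#' @return a file path (or a character vector of file names).
#' @export
#' @examples
#' tcmnp_example("breast_cancer_targets.tsv")
tcmnp_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "tcmnp")))
  }
  path <- system.file("extdata", file, package = "tcmnp")
  if (!nzchar(path)) stop_config("no packaged file named '", file, "'")
  path
}

#' Compound-code prefix to herb identifier lookup
#'
#' Two-letter compound-code prefixes (e.g. `DS` for Radix Salviae) mapped to
#' normalized herb identifiers, as used in the packaged compound table.
#'
#' @return named character vector: prefix -> herb_id.
#' @export
herb_prefix_map <- function() {
  c(AY = "folium_artemisiae_argyi",
    BJ = "dysosmae_verspiellis_rhixoma_et_radix",
    BZ = "atractylodes_macrocephala_koidz",
    BM = "mylabris",
    DS = "radix_salviae",
    WZ = "curcumae_rhizoma",
    FJ = "stephaniae_tetrandrae_radix",
    JH = "curcumae_longae_rhizoma",
    MD = "cortex_moutan",
    MT = "caulis_akebiae",
    SZ = "crataegi_folium",
    PP = "eriobotryae_folium",
    SC = "pseudobulbus_cremastrae_seu_pleiones",
    SY = "cornus_officinalis_sieb_et_zucc",
    TD = "asparagi_radix",
    TK = "semiaquilegiae_radix",
    YC = "artemisiae_scopariae_herba",
    ZJ = "gleditsiae_spina",
    BH = "hedyotis_diffusa",
    BL = "ampelopsis_japonica_thunb_makino")
}

read_table_dialect <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_config("file not found: ", path)
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("NA", ""), fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_config(what, " is missing required column(s): ",
                paste(missing, collapse = ", "))
  }
}

check_numeric_column <- function(df, col, what) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(val))
  if (length(bad)) {
    stop_validation(what, ": malformed numeric value in column '", col,
                    "' at row(s) ", paste(bad, collapse = ", "))
  }
  val
}

#' Read a compound table
#'
#' Ingests a delimited table of herbal ingredients with one row per
#' compound: identifier, name, herb membership, oral bioavailability (OB,
#' on the percentage scale: 36.91 means 36.91%), drug-likeness (DL, a
#' fraction) and optionally a SMILES string, the eight physicochemical
#' descriptors and a rescue flag.
#'
#' @param path file path.
#' @param sep field separator (tab by default; use `","` for CSV).
#' @return a `data.frame` with columns `compound_id`, `name`, `herb_id`,
#'   `smiles`, `ob`, `dl`, the eight descriptor columns (`NA` when absent),
#'   `rescued` and `is_aglycone_derivative`. Row order follows the file.
#' @export
#' @examples
#' cmp <- read_compound_table(tcmnp_example("herb_compounds.tsv"))
#' nrow(cmp)
read_compound_table <- function(path, sep = "\t") {
  df <- read_table_dialect(path, sep)
  require_columns(df, c("compound_id", "name", "herb_id", "ob", "dl"),
                  "compound table")
  out <- data.frame(
    compound_id = as.character(df$compound_id),
    name = as.character(df$name),
    herb_id = as.character(df$herb_id),
    smiles = if ("smiles" %in% names(df)) as.character(df$smiles)
             else rep(NA_character_, nrow(df)),
    ob = check_numeric_column(df, "ob", "compound table"),
    dl = check_numeric_column(df, "dl", "compound table"),
    stringsAsFactors = FALSE
  )
  for (col in DESCRIPTOR_COLS) {
    out[[col]] <- if (col %in% names(df)) {
      check_numeric_column(df, col, "compound table")
    } else rep(NA_real_, nrow(df))
  }
  out$rescued <- if ("rescued" %in% names(df)) {
    as.logical(df$rescued)
  } else rep(FALSE, nrow(df))
  out$is_aglycone_derivative <- if ("is_aglycone_derivative" %in% names(df)) {
    as.logical(df$is_aglycone_derivative)
  } else grepl("_qt$", out$name)
  validate_compound_table(out)
  out
}

validate_compound_table <- function(df) {
  dup <- unique(df$compound_id[duplicated(df$compound_id)])
  if (length(dup)) {
    stop_validation("duplicate compound_id: ", paste(dup, collapse = ", "))
  }
  if (any(!is.na(df$ob) & df$ob < 0)) stop_validation("ob must be >= 0")
  if (any(!is.na(df$dl) & (df$dl < 0 | df$dl > 1))) {
    stop_validation("dl must lie in [0, 1]")
  }
  invisible(df)
}

#' Read a herb literature-count table
#'
#' One row per herb with the total number of articles mentioning the herb
#' (`n_total_articles`) and the number also relevant to the disease
#' (`k_disease_articles`).
#'
#' @inheritParams read_compound_table
#' @return data.frame with `herb_id`, `n_total_articles`, `k_disease_articles`.
#' @export
read_herb_counts <- function(path, sep = "\t") {
  df <- read_table_dialect(path, sep)
  require_columns(df, c("herb_id", "n_total_articles", "k_disease_articles"),
                  "herb count table")
  out <- data.frame(
    herb_id = as.character(df$herb_id),
    n_total_articles = check_numeric_column(df, "n_total_articles", "herb counts"),
    k_disease_articles = check_numeric_column(df, "k_disease_articles", "herb counts"),
    stringsAsFactors = FALSE
  )
  if (any(out$k_disease_articles > out$n_total_articles)) {
    stop_validation("k_disease_articles exceeds n_total_articles for herb(s): ",
                    paste(out$herb_id[out$k_disease_articles > out$n_total_articles],
                          collapse = ", "))
  }
  out
}

#' Read a target annotation table
#'
#' @inheritParams read_compound_table
#' @return data.frame with `target_id` (gene symbol), `protein_name`,
#'   `uniprot_id`.
#' @export
read_target_table <- function(path, sep = "\t") {
  df <- read_table_dialect(path, sep)
  require_columns(df, c("target_id", "protein_name", "uniprot_id"),
                  "target table")
  out <- data.frame(
    target_id = as.character(df$target_id),
    protein_name = as.character(df$protein_name),
    uniprot_id = as.character(df$uniprot_id),
    stringsAsFactors = FALSE
  )
  dup <- unique(out$target_id[duplicated(out$target_id)])
  if (length(dup)) stop_validation("duplicate target_id: ", paste(dup, collapse = ", "))
  out
}

#' Read a compound-target interaction score table
#'
#' @inheritParams read_compound_table
#' @return data.frame with `compound_id`, `target_id`, `rf_score`,
#'   `svm_score`.
#' @export
read_interaction_table <- function(path, sep = "\t") {
  df <- read_table_dialect(path, sep)
  require_columns(df, c("compound_id", "target_id", "rf_score", "svm_score"),
                  "interaction table")
  out <- data.frame(
    compound_id = as.character(df$compound_id),
    target_id = as.character(df$target_id),
    rf_score = check_numeric_column(df, "rf_score", "interaction table"),
    svm_score = check_numeric_column(df, "svm_score", "interaction table"),
    stringsAsFactors = FALSE
  )
  validate_interaction_scores(out)
  out
}

validate_interaction_scores <- function(df) {
  bad <- df$rf_score < 0 | df$rf_score > 1 | df$svm_score < 0 | df$svm_score > 1
  if (any(bad)) {
    stop_validation("interaction scores outside [0, 1] for pair(s): ",
                    paste(paste(df$compound_id[bad], df$target_id[bad], sep = "-"),
                          collapse = ", "))
  }
  invisible(df)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members per term).
#' @param names optional named character vector of human-readable term
#'   names; defaults to the term ids.
#' @param universe optional explicit gene universe.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names = NULL, universe = NULL) {
  if (is.null(base::names(sets)) || anyNA(base::names(sets)) ||
      any(!nzchar(base::names(sets)))) {
    stop_validation("every gene set needs a non-empty term id")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(vapply(sets, function(s) any(!nzchar(s) | is.na(s)), logical(1)))) {
    stop_validation("gene-set members must be non-empty identifiers")
  }
  nm <- base::names(sets)
  term_names <- setNames(rep(NA_character_, length(sets)), nm)
  if (!is.null(names)) term_names[base::names(names)] <- names
  term_names[is.na(term_names)] <- nm[is.na(term_names)]
  structure(list(sets = sets, term_names = term_names,
                 universe = if (is.null(universe)) NULL else unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "terms,",
      length(unique(unlist(x$sets))), "distinct members\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Each non-empty line is `term_id <TAB> description <TAB> member...`.
#' Duplicate members within one set are collapsed.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_validation("GMT parse error at line ", i, ": fewer than 3 fields")
    }
    sets[[fields[[1]]]] <- unique(fields[-(1:2)])
    descs[[fields[[1]]]] <- fields[[2]]
  }
  gene_set_collection(sets, names = descs)
}

#' Write gene sets to a GMT file
#'
#' @param gs a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set_collection"))
  lines <- vapply(names(gs$sets), function(id) {
    paste(c(id, gs$term_names[[id]], gs$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
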