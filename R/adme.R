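# ADME candidate screening: Tanimoto drug-likeness against a reference-drug
# centroid, joint OB/DL thresholding with a literature-rescue list, and
# record-level deglycosylation of glycosides.

#' Tanimoto similarity between two property vectors
#'
#' `F(A, B) = A.B / (|A|^2 + |B|^2 - A.B)`. Equals 1 for identical nonzero
#' vectors and 0 for orthogonal ones; for non-negative vectors the value
#' lies in `[0, 1]`. Drug-likeness is this similarity between a compound's
#' descriptor vector and the average vector of a reference drug collection.
#'
#' @param a,b numeric vectors of identical length, not both all-zero.
#' @return the Tanimoto coefficient.
#' @export
#' @examples
#' compute_dl(c(1, 2), c(2, 2))  # 6/7
compute_dl <- function(a, b) {
  if (length(a) != length(b)) {
    stop_validation("vectors must have identical dimension (",
                    length(a), " vs ", length(b), ")")
  }
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom == 0) stop_validation("Tanimoto undefined: both vectors are zero")
  ab / denom
}

#' Component-wise mean of a reference descriptor table
#'
#' The reference centroid plays the role of the average drug-likeness
#' vector of a reference drug collection (e.g. a DrugBank snapshot).
#'
#' @param ref data.frame or matrix of descriptor vectors (rows = molecules).
#' @return named numeric vector of column means.
#' @export
reference_centroid <- function(ref) {
  ref <- as.matrix(ref)
  if (!nrow(ref)) stop_validation("reference set must be non-empty")
  colMeans(ref)
}

#' Drug-likeness of compounds against a reference descriptor table
#'
#' Each descriptor column is scaled by the reference set's per-column
#' standard deviation (so molecular weight does not dominate the dot
#' product), then each compound's scaled vector is compared with the scaled
#' reference centroid by [compute_dl()].
#'
#' @param descriptors data.frame/matrix of compound descriptor rows with the
#'   same columns as `ref`.
#' @param ref reference descriptor table.
#' @param scale scale columns by the reference standard deviations
#'   (default TRUE).
#' @return numeric vector of drug-likeness values, one per compound row.
#' @export
dl_against_reference <- function(descriptors, ref, scale = TRUE) {
  descriptors <- as.matrix(descriptors)
  ref <- as.matrix(ref)
  if (ncol(descriptors) != ncol(ref)) {
    stop_validation("descriptor and reference tables must share columns")
  }
  if (scale) {
    s <- apply(ref, 2, sd)
    s[s == 0 | is.na(s)] <- 1
    descriptors <- sweep(descriptors, 2, s, "/")
    ref <- sweep(ref, 2, s, "/")
  }
  centroid <- reference_centroid(ref)
  apply(descriptors, 1, compute_dl, b = centroid)
}

#' Screening configuration
#'
#' @param ob_min minimum oral bioavailability, percentage scale
#'   (default 30).
#' @param dl_min minimum drug-likeness fraction (default 0.18).
#' @param rescue_ids compound ids retained regardless of OB/DL, on
#'   explicit literature grounds.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(ob_min = 30, dl_min = 0.18,
                          rescue_ids = character()) {
  if (ob_min < 0) stop_config("ob_min must be >= 0")
  if (dl_min < 0 || dl_min > 1) stop_config("dl_min must lie in [0, 1]")
  structure(list(ob_min = ob_min, dl_min = dl_min,
                 rescue_ids = as.character(rescue_ids)),
            class = "screen_config")
}

#' Joint OB/DL candidate filter with rescue list
#'
#' A compound is a candidate iff `ob >= ob_min` and `dl >= dl_min`
#' (boundary values pass), or its id is on the rescue list. Every compound
#' receives a reason code: `passed_both`, `rescued`, `failed_ob`,
#' `failed_dl` or `failed_both`.
#'
#' @param compounds compound table (see [read_compound_table()]); `ob` and
#'   `dl` must be populated for every row.
#' @param cfg a [screen_config()].
#' @return list of class `screen_result`: `candidates` and `excluded`
#'   (partition of the input rows, original order) and `reasons`
#'   (data.frame `compound_id`, `candidate`, `reason`).
#' @export
apply_ob_dl_filter <- function(compounds, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  missing <- is.na(compounds$ob) | is.na(compounds$dl)
  if (any(missing)) {
    stop_validation("compound(s) missing ob or dl: ",
                    paste(compounds$compound_id[missing], collapse = ", "))
  }
  ob_ok <- compounds$ob >= cfg$ob_min
  dl_ok <- compounds$dl >= cfg$dl_min
  rescued <- compounds$compound_id %in% cfg$rescue_ids
  candidate <- (ob_ok & dl_ok) | rescued
  reason <- ifelse(ob_ok & dl_ok, "passed_both",
            ifelse(rescued, "rescued",
            ifelse(!ob_ok & !dl_ok, "failed_both",
            ifelse(!ob_ok, "failed_ob", "failed_dl"))))
  structure(list(
    candidates = compounds[candidate, , drop = FALSE],
    excluded = compounds[!candidate, , drop = FALSE],
    reasons = data.frame(compound_id = compounds$compound_id,
                         candidate = candidate, reason = reason,
                         stringsAsFactors = FALSE)
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  tab <- table(x$reasons$reason)
  cat("screen_result:", nrow(x$candidates), "candidates /",
      nrow(x$reasons), "compounds\n")
  for (r in names(tab)) cat(" ", r, ":", tab[[r]], "\n")
  invisible(x)
}

# Recognizable O-linked sugar fragments, written as SMILES substrings with a
# flexible ring-closure digit. Detection is a textual best-effort over a
# small fragment library (hexopyranoses and 6-deoxy variants as commonly
# drawn); it is not a full SMARTS engine.
SUGAR_FRAGMENTS <- c(
  glucopyranosyl = "C([0-9])OC\\(CO\\)C\\(O\\)C\\(O\\)C\\1O",
  rhamnopyranosyl = "C([0-9])OC\\(C\\)C\\(O\\)C\\(O\\)C\\1O"
)

has_sugar <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(FALSE)
  any(vapply(SUGAR_FRAGMENTS,
             function(p) grepl(paste0("O", p), smiles, perl = TRUE),
             logical(1)))
}

cleave_sugars <- function(smiles) {
  # replace every O-glycosidic "O<sugar>" unit with a hydroxyl O
  repeat {
    done <- TRUE
    for (p in SUGAR_FRAGMENTS) {
      new <- sub(paste0("O", p), "O", smiles, perl = TRUE)
      if (new != smiles) { smiles <- new; done <- FALSE }
    }
    if (done) return(smiles)
  }
}

#' Deglycosylate a compound record
#'
#' Models intestinal glycosidase hydrolysis at the record level: when an
#' O-linked sugar substructure is detected in the SMILES string (or the
#' record is flagged as a glycoside), an aglycone derivative record is
#' emitted, named with the `_qt` suffix, with descriptors and OB/DL cleared
#' for recomputation. The parent record is retained alongside the
#' derivative. Records without a sugar are returned unchanged. Unparsable
#' structures pass through untouched with a warning.
#'
#' @param compounds one or more compound-table rows.
#' @param glycoside optional logical vector flagging rows as glycosides
#'   when no structure is available.
#' @return a compound table containing the input rows plus any aglycone
#'   derivatives (deduplicated by cleaved structure).
#' @export
#' @examples
#' rec <- data.frame(compound_id = "X1", name = "Phenyl glucoside",
#'                   herb_id = "h", smiles = "c1ccccc1OC2OC(CO)C(O)C(O)C2O",
#'                   ob = NA_real_, dl = NA_real_)
#' deglycosylate(rec)$name
deglycosylate <- function(compounds, glycoside = NULL) {
  n <- nrow(compounds)
  if (is.null(glycoside)) glycoside <- rep(FALSE, n)
  if (!"smiles" %in% names(compounds)) compounds$smiles <- NA_character_
  if (!"is_aglycone_derivative" %in% names(compounds)) {
    compounds$is_aglycone_derivative <- FALSE
  }
  derivatives <- list()
  for (i in seq_len(n)) {
    smi <- compounds$smiles[i]
    detected <- tryCatch(has_sugar(smi), error = function(e) {
      warning("unparsable structure for ", compounds$compound_id[i],
              "; record passed through")
      FALSE
    })
    if (!detected && !glycoside[i]) next
    # cleaving every sugar yields one non-overlapping aglycone product
    product <- if (detected) cleave_sugars(smi) else NA_character_
    d <- compounds[i, , drop = FALSE]
    d$compound_id <- paste0(d$compound_id, "_qt")
    d$name <- paste0(d$name, "_qt")
    d$smiles <- product
    d$ob <- NA_real_; d$dl <- NA_real_
    for (col in intersect(DESCRIPTOR_COLS, names(d))) d[[col]] <- NA_real_
    d$is_aglycone_derivative <- TRUE
    derivatives[[length(derivatives) + 1L]] <- d
  }
  out <- rbind(compounds, do.call(rbind, derivatives))
  rownames(out) <- NULL
  out
}
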