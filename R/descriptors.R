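# Eight-descriptor physicochemical summaries and two-group comparison
# (herbal candidates versus a reference drug collection).

descriptor_matrix <- function(x) {
  x <- as.data.frame(x)
  cols <- intersect(DESCRIPTOR_COLS, names(x))
  if (!length(cols)) cols <- names(x)[vapply(x, is.numeric, logical(1))]
  as.matrix(x[, cols, drop = FALSE])
}

#' Per-descriptor mean and standard deviation of one group
#'
#' @param vectors data.frame/matrix of descriptor rows (any subset of the
#'   eight standard descriptors: mw, ncic, nhdon, nhacc, rbn, hy, tpsa,
#'   mlogp).
#' @return data.frame with `descriptor`, `mean`, `sd` (sample SD, n-1
#'   denominator) and `n`.
#' @export
summarize_group <- function(vectors) {
  m <- descriptor_matrix(vectors)
  if (!nrow(m)) stop_validation("group must be non-empty")
  data.frame(
    descriptor = colnames(m),
    mean = colMeans(m, na.rm = TRUE),
    sd = apply(m, 2, sd, na.rm = TRUE),
    n = nrow(m),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

significance_flag <- function(p) {
  ifelse(is.na(p), "ns",
  ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "p<0.05", "ns")))
}

permutation_p <- function(x, y, n_perm = 10000, seed = 1L) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  with_seed(seed, {
    exceed <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), nx)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
    }, logical(1))
    # add-one correction keeps p in (0, 1]
    (sum(exceed) + 1) / (n_perm + 1)
  })
}

#' Compare descriptor distributions between two groups
#'
#' Per-descriptor two-sample comparison of e.g. herbal candidate compounds
#' against a reference drug collection. The default test is Welch's
#' unequal-variance t-test; a two-sided permutation test on the mean
#' difference is available as a slower, assumption-free alternative.
#' Significance tiers are mutually exclusive: `p<0.01`, `p<0.05`
#' (meaning 0.01 <= p < 0.05) or `ns`. No multiplicity correction is
#' applied across descriptors.
#'
#' @param a,b data.frames/matrices of descriptor rows, each group of size
#'   >= 2, sharing descriptor columns.
#' @param test `"welch"` (default) or `"permutation"`.
#' @param n_perm permutation count for `test = "permutation"`.
#' @param seed RNG seed for the permutation test.
#' @return data.frame with per-descriptor `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `p_value` and `flag`.
#' @export
compare_groups <- function(a, b, test = c("welch", "permutation"),
                           n_perm = 10000, seed = 1L) {
  test <- match.arg(test)
  ma <- descriptor_matrix(a); mb <- descriptor_matrix(b)
  shared <- intersect(colnames(ma), colnames(mb))
  if (!length(shared)) stop_validation("groups share no descriptor columns")
  ma <- ma[, shared, drop = FALSE]; mb <- mb[, shared, drop = FALSE]
  if (nrow(ma) < 2 || nrow(mb) < 2) {
    stop_validation("both groups need size >= 2")
  }
  p <- vapply(shared, function(col) {
    x <- ma[, col]; y <- mb[, col]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (sd(x) == 0 && sd(y) == 0) {
      # identical constant groups carry no evidence of a difference
      if (isTRUE(all.equal(mean(x), mean(y)))) return(1) else return(0)
    }
    if (test == "welch") {
      t.test(x, y)$p.value
    } else {
      permutation_p(x, y, n_perm = n_perm, seed = seed)
    }
  }, numeric(1))
  data.frame(
    descriptor = shared,
    mean_a = colMeans(ma, na.rm = TRUE)[shared],
    sd_a = apply(ma, 2, sd, na.rm = TRUE)[shared],
    mean_b = colMeans(mb, na.rm = TRUE)[shared],
    sd_b = apply(mb, 2, sd, na.rm = TRUE)[shared],
    p_value = p,
    flag = significance_flag(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Histogram bins for one descriptor
#'
#' Count-conserving fixed-width binning for distribution profiles
#' (the per-descriptor group histograms).
#'
#' @param values numeric vector.
#' @param n_bins number of bins spanning the data range.
#' @return data.frame with `bin_left`, `bin_right`, `count`;
#'   `sum(count) == length(values)` (NA values are dropped first).
#' @export
descriptor_histogram <- function(values, n_bins = 20) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    return(data.frame(bin_left = numeric(), bin_right = numeric(),
                      count = integer()))
  }
  rng <- range(values)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             count = counts)
}
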