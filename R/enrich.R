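# Paired enrichment testing of collapsed small RNA counts (IP vs unbound,
# CMC+ vs mock): median-of-ratios normalization, method-of-moments NB
# dispersion with trend shrinkage, a Wald test on the log2 fold change, and
# Benjamini-Hochberg adjustment. The machinery is authored here from first
# principles and kept deliberately small: a two-condition log-link NB model,
# no shrinkage of the fold change itself.

#' Build a count matrix with library metadata
#'
#' Features are unique sequences (or pre-aggregated ids). Features whose
#' mean raw count across libraries is not above `min_mean` are removed
#' (strict `>`, matching the "average of more than 10 reads per sample"
#' rule; set `strict = FALSE` for `>=`).
#'
#' @param collapsed a `CollapsedReads`, or a numeric matrix with feature
#'   rownames and library colnames.
#' @param metadata data.frame with columns library, condition, pair,
#'   replicate, type ("biological"/"technical"); every count column must
#'   appear.
#' @param min_mean mean raw-count threshold.
#' @param strict use `mean > min_mean` (TRUE) or `mean >= min_mean`.
#' @return A list of class `CountMatrix`: `counts` (integer matrix),
#'   `meta`, and `removed` (number of features dropped by the filter).
#' @export
build_count_matrix <- function(collapsed, metadata, min_mean = 10,
                               strict = TRUE) {
  if (is.matrix(collapsed)) {
    counts <- collapsed
  } else {
    stopifnot(inherits(collapsed, "CollapsedReads"))
    libs <- setdiff(names(collapsed), "sequence")
    counts <- as.matrix(collapsed[, libs, drop = FALSE])
    rownames(counts) <- collapsed$sequence
  }
  missing <- setdiff(colnames(counts), metadata$library)
  if (length(missing))
    stop("libraries missing from metadata: ", paste(missing, collapse = ", "))
  need <- c("library", "condition", "pair")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns library, condition, pair")
  if (!"type" %in% names(metadata)) metadata$type <- "biological"
  metadata <- metadata[match(colnames(counts), metadata$library), ,
                       drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- rowMeans(counts)
  keep <- if (strict) m > min_mean else m >= min_mean
  structure(list(counts = counts[keep, , drop = FALSE], meta = metadata,
                 removed = sum(!keep)),
            class = "CountMatrix")
}

#' Median-of-ratios size factors
#'
#' For each library, the median over features of count divided by the
#' feature's geometric mean across libraries; only features with nonzero
#' counts in every library enter the median. Factors are reported raw (no
#' re-centering), so scaling one library's counts scales its factor
#' proportionally.
#'
#' @param x a `CountMatrix` or numeric matrix (features x libraries).
#' @param pseudo_reference if TRUE, geometric means are computed over
#'   positive counts only, allowing data with no feature expressed
#'   everywhere.
#' @return Named numeric vector of class `SizeFactors`.
#' @export
compute_size_factors <- function(x, pseudo_reference = FALSE) {
  counts <- if (inherits(x, "CountMatrix")) x$counts else x
  counts <- as.matrix(counts)
  lg <- log(counts)
  if (pseudo_reference) {
    lg[!is.finite(lg)] <- NA
    gm <- exp(rowMeans(lg, na.rm = TRUE))
    use <- rowSums(!is.na(lg)) > 0
  } else {
    gm <- exp(rowMeans(lg))
    use <- apply(counts, 1L, function(r) all(r > 0))
    if (!any(use))
      stop("no feature has nonzero counts in all libraries; ",
           "re-run with pseudo_reference = TRUE")
  }
  sf <- apply(counts[use, , drop = FALSE], 2L, function(col)
    median(col / gm[use], na.rm = TRUE))
  gmsf <- exp(mean(log(sf)))
  if (gmsf < 0.5 || gmsf > 2)
    log_msg("size_factors", "WARN",
            sprintf("geometric mean of size factors %.3f outside [0.5, 2]",
                    gmsf))
  structure(sf, class = "SizeFactors")
}

technical_average <- function(norm, meta) {
  if (!any(meta$type == "technical")) return(list(norm = norm, meta = meta))
  key <- paste(meta$condition, meta$pair, sep = "|")
  cols <- split(seq_len(ncol(norm)), key)
  out <- matrix(0, nrow = nrow(norm), ncol = length(cols),
                dimnames = list(rownames(norm), names(cols)))
  for (j in seq_along(cols))
    out[, j] <- rowMeans(norm[, cols[[j]], drop = FALSE])
  meta2 <- meta[!duplicated(key), , drop = FALSE]
  meta2 <- meta2[match(names(cols), paste(meta2$condition, meta2$pair,
                                          sep = "|")), , drop = FALSE]
  meta2$library <- names(cols)
  colnames(out) <- names(cols)
  list(norm = out, meta = meta2)
}

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Per feature, the raw moments estimator `(s^2 - mu) / mu^2` is computed
#' on size-factor-normalized counts within each condition (conditions with
#' at least two replicates) and averaged; features are then binned by mean
#' normalized count and each raw value is shrunk 50% toward its bin's mean
#' (the trend). The floor is applied to the shrunk value, so constant-count
#' features in an otherwise constant matrix return exactly the floor, and
#' the negative half of the sampling noise is retained in the trend rather
#' than truncated (truncating it first biases dispersion upward under
#' near-Poisson data).
#'
#' @param x a `CountMatrix`.
#' @param size_factors a `SizeFactors` vector.
#' @param n_bins expression bins used for the trend.
#' @param floor dispersion floor.
#' @param fallback dispersion used, with a warning, when no condition has
#'   two replicates.
#' @return Named numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(x, size_factors, n_bins = 20L,
                                floor = 1e-8, fallback = 0.1) {
  stopifnot(inherits(x, "CountMatrix"))
  norm <- sweep(x$counts, 2L, as.numeric(size_factors), "/")
  conds <- split(seq_len(ncol(norm)), x$meta$condition)
  conds <- conds[vapply(conds, length, 1L) >= 2L]
  nf <- nrow(norm)
  if (!length(conds)) {
    warning("no condition has >= 2 replicates; using trend-only fallback ",
            "dispersion ", fallback)
    return(setNames(rep(fallback, nf), rownames(norm)))
  }
  raw <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    a <- vapply(conds, function(ix) {
      xs <- norm[i, ix]
      mu <- mean(xs)
      if (mu <= 0) return(NA_real_)
      (var(xs) - mu) / mu^2
    }, numeric(1))
    raw[i] <- if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
  }
  mu_all <- rowMeans(norm)
  bins <- cut(rank(mu_all, ties.method = "first"),
              breaks = min(n_bins, nf), labels = FALSE)
  trend <- vapply(split(raw, bins), function(v)
    if (all(is.na(v))) 0 else mean(v, na.rm = TRUE), numeric(1))
  alpha <- 0.5 * raw + 0.5 * trend[as.character(bins)]
  alpha[is.na(alpha)] <- floor
  alpha <- pmax(alpha, floor)
  setNames(alpha, rownames(norm))
}

wald_two_group <- function(norm, disp, ix_t, ix_r, pseudo = 0.5) {
  m_t <- rowMeans(norm[, ix_t, drop = FALSE]) + pseudo
  m_r <- rowMeans(norm[, ix_r, drop = FALSE]) + pseudo
  lfc <- log2(m_t / m_r)
  se2 <- ((m_t + disp * m_t^2) / (length(ix_t) * m_t^2) +
            (m_r + disp * m_r^2) / (length(ix_r) * m_r^2)) / log(2)^2
  se <- sqrt(se2)
  stat <- ifelse(lfc == 0, 0, lfc / se)
  list(lfc = lfc, se = se, stat = stat)
}

wald_paired <- function(norm, ix_t, ix_r, pairs_t, pairs_r, pseudo = 0.5) {
  common <- intersect(pairs_t, pairs_r)
  if (!length(common)) stop("no matched pair ids between conditions")
  d <- vapply(common, function(p) {
    log2((norm[, ix_t[pairs_t == p][1]] + pseudo) /
           (norm[, ix_r[pairs_r == p][1]] + pseudo))
  }, numeric(nrow(norm)))
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(norm))
  lfc <- rowMeans(d)
  se <- apply(d, 1L, function(v) stats::sd(v)) / sqrt(ncol(d))
  stat <- ifelse(lfc == 0, 0, lfc / se)
  list(lfc = lfc, se = se, stat = stat)
}

#' Wald enrichment test for a two-condition contrast
#'
#' Fits, per feature, a two-condition NB model on normalized counts:
#' `log2FC` is the log2 ratio of condition means with pseudocount 0.5, the
#' standard error comes from the NB variance function with the estimated
#' dispersion, the Wald statistic is referred to the standard normal, and
#' p-values are BH-adjusted across tested features. Technical replicates of
#' a biological replicate are averaged before testing. With
#' `paired = TRUE`, per-pair log2 ratios are tested against zero instead
#' (pair ids must match between conditions).
#'
#' @param x a `CountMatrix`.
#' @param size_factors `SizeFactors`.
#' @param dispersions per-feature dispersions from [estimate_dispersion()].
#' @param contrast character(2): treated condition, reference condition.
#' @param paired use the strict paired (pair-factor) design.
#' @return data.frame of class `EnrichmentRecords`: feature_id, baseMean,
#'   log2FC, lfcSE, stat, pvalue, padj.
#' @export
test_enrichment <- function(x, size_factors, dispersions,
                            contrast, paired = FALSE) {
  stopifnot(inherits(x, "CountMatrix"), length(contrast) == 2L)
  meta <- x$meta
  if (!all(contrast %in% meta$condition))
    stop("contrast conditions not present in metadata")
  norm <- sweep(x$counts, 2L, as.numeric(size_factors), "/")
  ta <- technical_average(norm, meta)
  norm <- ta$norm; meta <- ta$meta
  ix_t <- which(meta$condition == contrast[1])
  ix_r <- which(meta$condition == contrast[2])
  disp <- dispersions[rownames(norm)]
  if (paired) {
    pt <- meta$pair[ix_t]; pr <- meta$pair[ix_r]
    if (!setequal(pt, pr)) stop("unmatched pair ids between conditions")
    w <- wald_paired(norm, ix_t, ix_r, pt, pr)
  } else {
    w <- wald_two_group(norm, disp, ix_t, ix_r)
  }
  pvalue <- 2 * pnorm(-abs(w$stat))
  pvalue[w$stat == 0] <- 1
  res <- data.frame(
    feature_id = rownames(norm),
    baseMean = rowMeans(norm[, c(ix_t, ix_r), drop = FALSE]),
    log2FC = w$lfc, lfcSE = w$se, stat = w$stat,
    pvalue = pvalue,
    padj = p.adjust(pvalue, method = "BH"),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("EnrichmentRecords", "data.frame")
  res
}
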