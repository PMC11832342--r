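# Feature-level rollups: TE-family x size-class enrichment means, AGO
# preference assignment, terminal nucleotide bias, tRNA-fragment
# classification, and metagene coverage profiles.

#' Aggregate per-sequence enrichment to TE families by size class
#'
#' Averages member log2 fold changes per family and size class. A sequence
#' matching several families (multimapping across copies) contributes once
#' to each matched family, or with weight `1/n_families` in fractional
#' mode. Families whose mean raw read count falls below `min_cluster_mean`
#' are excluded.
#'
#' @param results `EnrichmentRecords` keyed by sequence.
#' @param annotations data.frame with feature_id and families_all
#'   (comma-joined family labels; see [annotate_alignments()]).
#' @param size_classes named list of inclusive length ranges, e.g.
#'   `list("20-22" = c(20, 22), "23-25" = c(23, 25))`; classes must be
#'   disjoint.
#' @param min_cluster_mean minimum family mean raw reads per library (0
#'   disables); requires `counts`.
#' @param counts optional raw count matrix (sequences x libraries) for the
#'   cluster filter.
#' @param fractional weight multimapped sequences by `1/n_families`.
#' @return data.frame of class `FamilyEnrichment`: family, size_class,
#'   mean_log2FC, n.
#' @export
aggregate_family_enrichment <- function(results, annotations,
                                        size_classes =
                                          list("20-22" = c(20L, 22L),
                                               "23-25" = c(23L, 25L)),
                                        min_cluster_mean = 0,
                                        counts = NULL,
                                        fractional = FALSE) {
  rng <- do.call(rbind, size_classes)
  o <- order(rng[, 1])
  if (any(rng[o, 1][-1] <= rng[o, 2][-length(size_classes)]))
    stop("size classes must be disjoint")
  ann <- annotations[match(results$feature_id, annotations$feature_id), ,
                     drop = FALSE]
  len <- nchar(results$feature_id)
  size_of <- rep(NA_character_, length(len))
  for (nm in names(size_classes)) {
    r <- size_classes[[nm]]
    size_of[len >= r[1] & len <= r[2]] <- nm
  }
  rows <- list()
  for (i in seq_len(nrow(results))) {
    if (is.na(ann$families_all[i]) || is.na(size_of[i])) next
    fams <- strsplit(ann$families_all[i], ",")[[1]]
    w <- if (fractional) 1 / length(fams) else 1
    for (f in fams) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, size_class = size_of[i],
        log2FC = results$log2FC[i], w = w,
        feature_id = results$feature_id[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(family = character(0), size_class = character(0),
                      mean_log2FC = numeric(0), n = integer(0))
    class(out) <- c("FamilyEnrichment", "data.frame")
    return(out)
  }
  long <- do.call(rbind, rows)
  if (min_cluster_mean > 0) {
    if (is.null(counts)) stop("counts required when min_cluster_mean > 0")
    fam_mean <- vapply(split(long$feature_id, long$family), function(ids) {
      mean(colSums(counts[unique(ids), , drop = FALSE]))
    }, numeric(1))
    long <- long[fam_mean[long$family] >= min_cluster_mean, , drop = FALSE]
  }
  key <- paste(long$family, long$size_class, sep = "|")
  out <- do.call(rbind, lapply(split(seq_len(nrow(long)), key), function(ix) {
    data.frame(family = long$family[ix[1]],
               size_class = long$size_class[ix[1]],
               mean_log2FC = sum(long$log2FC[ix] * long$w[ix]) /
                 sum(long$w[ix]),
               n = length(ix), stringsAsFactors = FALSE)
  }))
  out <- out[order_radix(out$family, out$size_class), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("FamilyEnrichment", "data.frame")
  out
}

#' Assign each TE family to its preferred Argonaute
#'
#' Per family and size class, the AGO-IP library with the maximum
#' enrichment; exact ties yield "ambiguous". Assignments are invariant to
#' the order of the AGO columns.
#'
#' @param x data.frame with columns family, size_class, ago, mean_log2FC
#'   (long format, one row per family x size class x AGO).
#' @return data.frame: family, size_class, preferred_ago, plus an attribute
#'   `counts` tabulating preferred families per AGO.
#' @export
assign_ago_preference <- function(x) {
  stopifnot(all(c("family", "size_class", "ago", "mean_log2FC") %in%
                  names(x)))
  if (length(unique(x$ago)) < 2L) stop("need >= 2 AGO libraries")
  key <- paste(x$family, x$size_class, sep = "|")
  out <- do.call(rbind, lapply(split(seq_len(nrow(x)), key), function(ix) {
    e <- x$mean_log2FC[ix]
    best <- which(e == max(e))
    data.frame(family = x$family[ix[1]], size_class = x$size_class[ix[1]],
               preferred_ago = if (length(best) > 1L) "ambiguous" else
                 x$ago[ix[best]],
               stringsAsFactors = FALSE)
  }))
  out <- out[order_radix(out$family, out$size_class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- table(out$preferred_ago)
  out
}

#' Terminal nucleotide composition per group
#'
#' Frequencies of A/C/G/U at the first and last position of each sequence
#' group, after removing sequences of excluded structural classes.
#'
#' @param sequences character vector (DNA alphabet; reported as RNA).
#' @param groups grouping factor (e.g. pseudouridylated vs not); a single
#'   group when NULL.
#' @param classes optional per-sequence class labels used for exclusion.
#' @param exclude classes removed before computing the bias.
#' @return data.frame: group, end ("5p"/"3p"), base (A/C/G/U), freq;
#'   frequencies sum to 1 per group and end.
#' @export
terminal_nt_composition <- function(sequences, groups = NULL,
                                    classes = NULL,
                                    exclude = c("tRNA", "snoRNA", "snRNA",
                                                "rRNA")) {
  stopifnot(all(nchar(sequences) > 0))
  if (is.null(groups)) groups <- rep("all", length(sequences))
  keep <- if (is.null(classes)) rep(TRUE, length(sequences)) else
    !(classes %in% exclude)
  sequences <- sequences[keep]; groups <- groups[keep]
  rna <- c(A = "A", C = "C", G = "G", T = "U")
  rows <- list()
  for (g in sort(unique(as.character(groups)), method = "radix")) {
    s <- sequences[groups == g]
    for (end in c("5p", "3p")) {
      b <- if (end == "5p") substr(s, 1L, 1L) else
        substr(s, nchar(s), nchar(s))
      tab <- table(factor(b, levels = names(rna)))
      freq <- as.numeric(tab) / max(1L, length(b))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, end = end, base = unname(rna), freq = freq,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify tRNA-derived fragments
#'
#' Reads aligned sense within tRNA features are classified as 3'-tRF (read
#' 3' end at the tRNA 3' CCA end), 5'-tRF (read 5' end at the tRNA start)
#' or internal, flagged for the UNUAR motif (U-N-U-A-purine) and for
#' spanning the canonical position-55 uridine.
#'
#' @param aln alignment data.frame.
#' @param ref a `ToyReference` with tRNA features.
#' @return data.frame: sequence, feature_id, trf_class, unuar,
#'   spans_psi55.
#' @export
extract_trfs <- function(aln, ref) {
  fs <- ref$features[ref$features$class == "tRNA", , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(aln))) {
    hit <- which(fs$contig == aln$contig[k] & fs$start <= aln$start[k] &
                   aln$end[k] <= fs$end & fs$strand == aln$strand[k])
    if (!length(hit)) next
    i <- hit[1]
    if (fs$strand[i] == "+") {
      at3 <- aln$end[k] == fs$end[i]
      at5 <- aln$start[k] == fs$start[i]
      off5 <- aln$start[k] - fs$start[i]
    } else {
      at3 <- aln$start[k] == fs$start[i]
      at5 <- aln$end[k] == fs$end[i]
      off5 <- fs$end[i] - aln$end[k]
    }
    cls <- if (at3) "3p_tRF" else if (at5) "5p_tRF" else "internal"
    len <- nchar(aln$sequence[k])
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = aln$sequence[k], feature_id = fs$id[i], trf_class = cls,
      unuar = grepl("T[ACGT]TA[AG]", aln$sequence[k]),
      spans_psi55 = off5 <= 54L & 54L < off5 + len,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), feature_id = character(0),
               trf_class = character(0), unuar = logical(0),
               spans_psi55 = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

lib_coverage <- function(aln, counts, contig_lengths) {
  cov <- lapply(contig_lengths, function(L) numeric(L + 1L))
  if (nrow(aln)) {
    w <- as.numeric(counts[aln$sequence]); w[is.na(w)] <- 0
    for (k in seq_len(nrow(aln))) {
      cn <- aln$contig[k]
      cov[[cn]][aln$start[k] + 1L] <- cov[[cn]][aln$start[k] + 1L] + w[k]
      cov[[cn]][aln$end[k] + 1L] <- cov[[cn]][aln$end[k] + 1L] - w[k]
    }
  }
  lapply(names(contig_lengths), function(cn)
    cumsum(cov[[cn]])[seq_len(contig_lengths[[cn]])]) |>
    setNames(names(contig_lengths))
}

moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  zoo::rollapply(x, width, mean, na.rm = TRUE, partial = TRUE,
                 align = "center")
}

#' Metagene coverage profile over a gene set
#'
#' Coverage from single-placement alignments is normalized per library to
#' its total genomic coverage, averaged across the given libraries (one
#' treatment), then profiled over `[upstream flank | scaled body |
#' downstream flank]` for each gene: flanks are binned at the window size,
#' the body is rescaled to a fixed number of bins, minus-strand genes are
#' reversed, bins are averaged across genes and smoothed with a centered
#' moving average (partial at the edges, so totals are preserved up to
#' boundary effects). Flanks running off a contig are truncated with a
#' warning.
#'
#' @param aln alignments from the `"single_hit"` (or `"unique_only"`)
#'   policy.
#' @param collapsed a `CollapsedReads` providing per-library counts.
#' @param libraries library columns to merge (one treatment).
#' @param ref a `ToyReference`.
#' @param genes feature ids (e.g. a gene-set label's members); defaults to
#'   all class-"other" features.
#' @param flank flank size (nt).
#' @param body_bins fixed number of body bins.
#' @param window flank bin width (nt).
#' @param smooth smoothing window (bins).
#' @return data.frame of class `MetaProfile`: bin, region
#'   (upstream/body/downstream), coverage.
#' @export
metaplot_profile <- function(aln, collapsed, libraries, ref, genes = NULL,
                             flank = 1000L, body_bins = 60L, window = 25L,
                             smooth = 6L) {
  fs <- ref$features
  if (is.null(genes)) genes <- fs$id[fs$class == "other"]
  gs <- fs[fs$id %in% genes, , drop = FALSE]
  if (!nrow(gs)) stop("no genes to profile")
  clen <- lapply(ref$contigs, nchar)
  norm <- lapply(libraries, function(lab) {
    counts <- setNames(collapsed[[lab]], collapsed$sequence)
    cv <- lib_coverage(aln, counts, clen)
    tot <- sum(unlist(lapply(cv, sum)))
    if (tot == 0) cv else lapply(cv, function(v) v / tot)
  })
  merged <- lapply(names(clen), function(cn) {
    Reduce(`+`, lapply(norm, `[[`, cn)) / length(norm)
  })
  names(merged) <- names(clen)
  n_fl <- as.integer(flank %/% window)
  bin_mean <- function(v, nbins) {
    if (!length(v)) return(rep(NA_real_, nbins))
    idx <- ceiling(seq_along(v) / length(v) * nbins)
    out <- rep(NA_real_, nbins)
    agg <- tapply(v, idx, mean)
    out[as.integer(names(agg))] <- agg
    out
  }
  prof <- vapply(seq_len(nrow(gs)), function(i) {
    cv <- merged[[gs$contig[i]]]
    L <- length(cv)
    up_rng <- c(gs$start[i] - flank, gs$start[i])
    dn_rng <- c(gs$end[i], gs$end[i] + flank)
    if (up_rng[1] < 0 || dn_rng[2] > L)
      warning(sprintf("flank of %s truncated at contig end", gs$id[i]))
    grab <- function(a, b) {
      if (b <= 0 || a >= L) return(numeric(0))
      cv[(max(a, 0) + 1L):min(b, L)]
    }
    up <- grab(up_rng[1], up_rng[2])
    body <- grab(gs$start[i], gs$end[i])
    dn <- grab(dn_rng[1], dn_rng[2])
    # pad truncated flanks so bins stay aligned across genes
    up <- c(rep(NA_real_, flank - length(up)), up)
    dn <- c(dn, rep(NA_real_, flank - length(dn)))
    bins <- c(bin_mean(up, n_fl), bin_mean(body, body_bins),
              bin_mean(dn, n_fl))
    if (gs$strand[i] == "-") bins <- rev(bins)
    bins
  }, numeric(2L * n_fl + body_bins))
  if (is.null(dim(prof))) prof <- matrix(prof, ncol = nrow(gs))
  avg <- rowMeans(prof, na.rm = TRUE)
  sm <- moving_average(avg, smooth)
  out <- data.frame(bin = seq_along(sm),
                    region = c(rep("upstream", n_fl),
                               rep("body", body_bins),
                               rep("downstream", n_fl)),
                    coverage = sm)
  class(out) <- c("MetaProfile", "data.frame")
  attr(out, "params") <- list(flank = flank, body_bins = body_bins,
                              window = window, smooth = smooth,
                              n_genes = nrow(gs))
  out
}
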