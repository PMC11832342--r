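# Nucleotide-resolution pseudouridine inference from CMC/Mn2+ libraries:
# pileups with base-quality-aware altered counts, the mismatch-ratio
# fold-change calling rule, positional metaprofiles, rRNA known-site
# validation tracks, and the three-assay consensus.

#' Build a per-position pileup from alignments
#'
#' Coverage and "altered" counts per reference position for one library.
#' A read's 1-nt deletion increments `altered` at its reference position;
#' a mismatch increments `altered` at its reference position only when its
#' base quality is at least `min_base_quality` (the base-quality filter of
#' standard pileup/readcount tools: low-quality miscalls are sequencing
#' noise, not chemistry). Terminal tallies record how many reads have their
#' 5'/3' end at each position.
#'
#' @param aln alignment data.frame (one placement per sequence; use policy
#'   `"single_hit"` or `"unique_only"` upstream).
#' @param counts named integer vector: read count per sequence in this
#'   library.
#' @param ref a `ToyReference`.
#' @param quals optional named character vector of representative quality
#'   strings per sequence; when NULL all mismatches count as altered.
#' @param min_base_quality Phred threshold for counting a mismatch.
#' @param altered count `"both"` mismatches and deletions, or
#'   `"mismatch_only"`.
#' @return data.frame of class `PileupProfile`: contig, pos (0-based),
#'   coverage, altered, n_del, n_mis, five_prime_ends, three_prime_ends;
#'   positions with zero coverage are omitted.
#' @export
build_pileup <- function(aln, counts, ref, quals = NULL,
                         min_base_quality = 20L,
                         altered = c("both", "mismatch_only")) {
  altered <- match.arg(altered)
  if (any(!aln$contig %in% names(ref$contigs)))
    stop("alignment references unknown contig")
  cov <- lapply(ref$contigs, function(s) numeric(nchar(s) + 1L))
  ndel <- lapply(ref$contigs, function(s) numeric(nchar(s)))
  nmis <- lapply(ref$contigs, function(s) numeric(nchar(s)))
  p5 <- lapply(ref$contigs, function(s) numeric(nchar(s)))
  p3 <- lapply(ref$contigs, function(s) numeric(nchar(s)))
  if (nrow(aln)) {
    w <- as.numeric(counts[aln$sequence])
    w[is.na(w)] <- 0
    for (k in seq_len(nrow(aln))) {
      if (w[k] == 0) next
      cn <- aln$contig[k]
      cov[[cn]][aln$start[k] + 1L] <- cov[[cn]][aln$start[k] + 1L] + w[k]
      cov[[cn]][aln$end[k] + 1L] <- cov[[cn]][aln$end[k] + 1L] - w[k]
      e5 <- if (aln$strand[k] == "+") aln$start[k] else aln$end[k] - 1L
      e3 <- if (aln$strand[k] == "+") aln$end[k] - 1L else aln$start[k]
      p5[[cn]][e5 + 1L] <- p5[[cn]][e5 + 1L] + w[k]
      p3[[cn]][e3 + 1L] <- p3[[cn]][e3 + 1L] + w[k]
      if (!is.na(aln$del_ref_pos[k]))
        ndel[[cn]][aln$del_ref_pos[k] + 1L] <-
          ndel[[cn]][aln$del_ref_pos[k] + 1L] + w[k]
      if (nzchar(aln$mm_read_pos[k])) {
        rp <- as.integer(strsplit(aln$mm_ref_pos[k], ",")[[1]])
        qp <- as.integer(strsplit(aln$mm_read_pos[k], ",")[[1]])
        keep <- rep(TRUE, length(rp))
        if (!is.null(quals)) {
          q <- quals[aln$sequence[k]]
          if (!is.na(q)) {
            keep <- (utf8ToInt(q)[qp + 1L] - 33L) >= min_base_quality
          }
        }
        for (p in rp[keep])
          nmis[[cn]][p + 1L] <- nmis[[cn]][p + 1L] + w[k]
      }
    }
  }
  out <- lapply(names(ref$contigs), function(cn) {
    cv <- cumsum(cov[[cn]])[seq_len(nchar(ref$contigs[[cn]]))]
    nz <- which(cv > 0)
    if (!length(nz)) return(NULL)
    alt <- nmis[[cn]][nz] + if (altered == "both") ndel[[cn]][nz] else 0
    data.frame(contig = cn, pos = nz - 1L, coverage = cv[nz],
               altered = alt, n_del = ndel[[cn]][nz], n_mis = nmis[[cn]][nz],
               five_prime_ends = p5[[cn]][nz],
               three_prime_ends = p3[[cn]][nz],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(contig = character(0), pos = integer(0),
                                      coverage = numeric(0),
                                      altered = numeric(0),
                                      n_del = numeric(0), n_mis = numeric(0),
                                      five_prime_ends = numeric(0),
                                      three_prime_ends = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("PileupProfile", "data.frame")
  out
}

#' The pseudouridine calling rule
#'
#' A target is called when it has at least `min_reads` treated reads and
#' the treated/mock ratio of altered-read fractions reaches `min_fold`.
#' Optional pseudo-ratios stabilize the fold change when the mock fraction
#' is zero.
#'
#' @param reads_treated treated read support.
#' @param ratio_treated,ratio_mock altered-read fractions in `[0, 1]`.
#' @param min_reads,min_fold thresholds (defaults 5 reads, 1.5-fold).
#' @param eps_treated,eps_mock pseudo-ratios added to numerator and
#'   denominator (0 reproduces the plain ratio; positions with
#'   `ratio_mock = 0` then yield an infinite fold).
#' @return data.frame with fold_change and called.
#' @export
psi_call_rule <- function(reads_treated, ratio_treated, ratio_mock,
                          min_reads = 5, min_fold = 1.5,
                          eps_treated = 0, eps_mock = 0) {
  fold <- (ratio_treated + eps_treated) / (ratio_mock + eps_mock)
  data.frame(fold_change = fold,
             called = reads_treated >= min_reads & fold >= min_fold)
}

#' Call pseudouridine sites per position from a treated/mock pileup pair
#'
#' Applies [psi_call_rule()] at every position covered in the treated
#' pileup. A common pseudo-ratio `0.5 / treated coverage` (an add-half
#' continuity correction at the resolution of the treated library) is added
#' to both ratios, so positions with no altered reads in either arm give a
#' fold change of exactly 1 regardless of coverage imbalance; with
#' `use_pseudo = FALSE` the plain ratio is used and positions with a zero
#' mock ratio but nonzero treated ratio get an infinite fold change. A call
#' additionally requires `min_altered` altered treated reads (the usual
#' variant-support floor: a single altered read at high coverage is not
#' evidence). Positions with mock coverage below `min_mock_cov` are
#' reported untestable and never called.
#'
#' @param treated,mock `PileupProfile`s on the same reference.
#' @param min_reads,min_fold calling thresholds.
#' @param min_altered minimum altered treated reads supporting a call.
#' @param min_mock_cov minimum mock coverage for a testable position.
#' @param use_pseudo use the add-half pseudo-ratio.
#' @return data.frame of class `PsiSiteCalls`: contig, pos, reads_treated,
#'   altered_treated, ratio_treated, coverage_mock, ratio_mock,
#'   fold_change, testable, called.
#' @export
call_psi_sites <- function(treated, mock, min_reads = 5, min_fold = 1.5,
                           min_altered = 3, min_mock_cov = 5,
                           use_pseudo = TRUE) {
  key <- paste(mock$contig, mock$pos)
  mi <- match(paste(treated$contig, treated$pos), key)
  cov_m <- ifelse(is.na(mi), 0, mock$coverage[mi])
  alt_m <- ifelse(is.na(mi), 0, mock$altered[mi])
  r_t <- ifelse(treated$coverage > 0, treated$altered / treated$coverage, 0)
  r_m <- ifelse(cov_m > 0, alt_m / cov_m, 0)
  if (use_pseudo) {
    eps <- 0.5 / pmax(treated$coverage, 1)
  } else {
    eps <- 0
  }
  rule <- psi_call_rule(treated$coverage, r_t, r_m, min_reads, min_fold,
                        eps, eps)
  testable <- cov_m >= min_mock_cov
  out <- data.frame(contig = treated$contig, pos = treated$pos,
                    reads_treated = treated$coverage,
                    altered_treated = treated$altered,
                    ratio_treated = r_t, coverage_mock = cov_m,
                    ratio_mock = r_m, fold_change = rule$fold_change,
                    testable = testable,
                    called = rule$called & testable &
                      treated$altered >= min_altered,
                    stringsAsFactors = FALSE)
  class(out) <- c("PsiSiteCalls", "data.frame")
  out
}

#' Per-feature pseudouridine calls
#'
#' The per-miRNA phrasing of the calling rule: a feature's read support is
#' the number of treated reads whose 5' end lies inside it, its altered
#' ratios come from the position with the maximum fold change inside the
#' feature, and the rule is applied to that summary.
#'
#' @inheritParams call_psi_sites
#' @param ref a `ToyReference`; calls are made for each feature.
#' @param classes feature classes to call.
#' @return data.frame: feature_id, best position and its statistics,
#'   reads_treated, called.
#' @export
call_psi_features <- function(treated, mock, ref, min_reads = 5,
                              min_fold = 1.5, min_altered = 3,
                              min_mock_cov = 5, use_pseudo = TRUE,
                              classes = c("miRNA", "TE_copy", "tRNA")) {
  pos_calls <- call_psi_sites(treated, mock, min_reads = 0,
                              min_fold = min_fold,
                              min_altered = min_altered,
                              min_mock_cov = min_mock_cov,
                              use_pseudo = use_pseudo)
  fs <- ref$features[ref$features$class %in% classes, , drop = FALSE]
  rows <- lapply(seq_len(nrow(fs)), function(i) {
    inside <- pos_calls$contig == fs$contig[i] &
      pos_calls$pos >= fs$start[i] & pos_calls$pos < fs$end[i]
    tt <- treated$contig == fs$contig[i] &
      treated$pos >= fs$start[i] & treated$pos < fs$end[i]
    nreads <- sum(treated$five_prime_ends[tt])
    pc <- pos_calls[inside & pos_calls$testable, , drop = FALSE]
    if (!nrow(pc)) {
      return(data.frame(feature_id = fs$id[i], pos = NA_integer_,
                        reads_treated = nreads, ratio_treated = NA_real_,
                        ratio_mock = NA_real_, fold_change = NA_real_,
                        called = FALSE, stringsAsFactors = FALSE))
    }
    b <- pc[which.max(pc$fold_change), , drop = FALSE]
    data.frame(feature_id = fs$id[i], pos = b$pos, reads_treated = nreads,
               ratio_treated = b$ratio_treated, ratio_mock = b$ratio_mock,
               fold_change = b$fold_change,
               called = nreads >= min_reads &
                 b$fold_change >= min_fold &
                 b$altered_treated >= min_altered,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positional metaprofile of called sites
#'
#' Frequency of called sites by distance from the feature 5' and 3' ends,
#' normalized per offset by the number of features carrying a U at that
#' offset (so a class with few eligible uridines is not under-counted).
#'
#' @param calls data.frame with feature_id and pos (contig coordinates) of
#'   called sites, e.g. called rows of [call_psi_features()].
#' @param ref a `ToyReference`.
#' @param k offsets profiled from each end.
#' @param classes feature classes entering the denominator.
#' @return data.frame: end ("5p"/"3p"), offset (1-based from that end),
#'   n_called, n_feature_u, freq.
#' @export
positional_metaprofile <- function(calls, ref, k = 8L,
                                   classes = "miRNA") {
  fs <- ref$features[ref$features$class %in% classes, , drop = FALSE]
  senses <- vapply(which(ref$features$class %in% classes),
                   function(i) feature_sense_seq(ref, i), character(1))
  lens <- nchar(senses)
  off5 <- integer(0); off3 <- integer(0)
  if (nrow(calls)) {
    fi <- match(calls$feature_id, fs$id)
    keep <- !is.na(fi) & !is.na(calls$pos)
    for (j in which(keep)) {
      i <- fi[j]
      off <- if (fs$strand[i] == "+") calls$pos[j] - fs$start[i] else
        fs$end[i] - 1L - calls$pos[j]
      off5 <- c(off5, off)
      off3 <- c(off3, lens[i] - 1L - off)
    }
  }
  prof <- function(offs, uat) {
    vapply(seq_len(k), function(o) {
      denom <- uat[o]
      if (denom == 0) return(0)
      sum(offs == o - 1L) / denom
    }, numeric(1))
  }
  u5 <- vapply(seq_len(k), function(o)
    sum(substr(senses, o, o) == "T"), numeric(1))
  u3 <- vapply(seq_len(k), function(o)
    sum(substr(senses, lens - o + 1L, lens - o + 1L) == "T"), numeric(1))
  data.frame(end = rep(c("5p", "3p"), each = k),
             offset = rep(seq_len(k), 2L),
             n_called = c(vapply(seq_len(k), function(o)
               sum(off5 == o - 1L), numeric(1)),
               vapply(seq_len(k), function(o)
                 sum(off3 == o - 1L), numeric(1))),
             n_feature_u = c(u5, u3),
             freq = c(prof(off5, u5), prof(off3, u3)))
}

coverage_from_pileup <- function(pileup, contig, start, end) {
  cv <- numeric(end - start)
  sel <- pileup$contig == contig & pileup$pos >= start & pileup$pos < end
  cv[pileup$pos[sel] - start + 1L] <- pileup$coverage[sel]
  cv
}

#' rRNA known-site validation track
#'
#' Per-position coverage over a locus, normalized within each library to
#' the total locus coverage; the log2 paired ratio (treated/reference) is
#' averaged over pairs, and the mean of that track over a window around
#' each known site is reported. Depletion at a genuine site is negative
#' under the CMC contrast.
#'
#' @param pileups named list of `PileupProfile`s (one per library).
#' @param locus list(contig, start, end), 0-based half-open.
#' @param known_sites integer vector of 0-based site positions inside the
#'   locus.
#' @param pairs data.frame with columns treated, reference (library
#'   labels), one row per pair.
#' @param window half-width (nt) of the averaging window around each site.
#' @return list: `track` (pos, log2fc averaged over pairs) and `sites`
#'   (pos, mean_log2fc over the +/- window).
#' @export
rrna_site_validation <- function(pileups, locus, known_sites, pairs,
                                 window = 2L) {
  L <- locus$end - locus$start
  eps <- 0.5 / L
  norm_cov <- lapply(pileups, function(p) {
    cv <- coverage_from_pileup(p, locus$contig, locus$start, locus$end)
    tot <- sum(cv)
    if (tot == 0) stop("zero locus coverage in a library")
    cv / tot
  })
  lfc <- vapply(seq_len(nrow(pairs)), function(i) {
    log2((norm_cov[[pairs$treated[i]]] + eps) /
           (norm_cov[[pairs$reference[i]]] + eps))
  }, numeric(L))
  if (is.null(dim(lfc))) lfc <- matrix(lfc, nrow = L)
  track <- rowMeans(lfc)
  site_means <- vapply(known_sites, function(s) {
    ix <- (s - window):(s + window) - locus$start + 1L
    ix <- ix[ix >= 1L & ix <= L]
    mean(track[ix])
  }, numeric(1))
  list(track = data.frame(pos = locus$start:(locus$end - 1L),
                          log2fc = track),
       sites = data.frame(pos = known_sites, mean_log2fc = site_means))
}

#' Three-assay consensus classes
#'
#' Per feature: IP support means BH-adjusted p below `alpha` with positive
#' log2 fold change (enriched in the bound fraction); CMC support means
#' adjusted p below `alpha` with negative log2 fold change (depleted after
#' CMC treatment); MnCMC support means a mutational-readout call. The
#' intersection of all three is the high-confidence set.
#'
#' @param ip_results,cmc_results `EnrichmentRecords` keyed by feature_id.
#' @param mn_calls data.frame with feature_id and called.
#' @param alpha adjusted-p threshold.
#' @return data.frame: feature_id, ip, cmc, mn, support (e.g.
#'   "IP+CMC+MnCMC"), high_confidence; attribute `venn` holds the class
#'   size table.
#' @export
consensus_calls <- function(ip_results, cmc_results, mn_calls,
                            alpha = 0.01) {
  univ <- sort(unique(c(ip_results$feature_id, cmc_results$feature_id,
                        mn_calls$feature_id)), method = "radix")
  flag <- function(res, sign) {
    ok <- res$feature_id[!is.na(res$padj) & res$padj < alpha &
                           sign * res$log2FC > 0]
    univ %in% ok
  }
  ip <- flag(ip_results, +1)
  cmc <- flag(cmc_results, -1)
  mn <- univ %in% mn_calls$feature_id[mn_calls$called]
  support <- vapply(seq_along(univ), function(i) {
    s <- c("IP", "CMC", "MnCMC")[c(ip[i], cmc[i], mn[i])]
    if (length(s)) paste(s, collapse = "+") else "none"
  }, character(1))
  out <- data.frame(feature_id = univ, ip = ip, cmc = cmc, mn = mn,
                    support = support,
                    high_confidence = ip & cmc & mn,
                    stringsAsFactors = FALSE)
  attr(out, "venn") <- table(support)
  out
}
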