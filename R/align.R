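# Desk-scale alignment of collapsed small RNA sequences to the toy
# reference: exhaustive end-to-end (ungapped) placement with a mismatch
# budget, plus a mode admitting exactly one 1-nt internal reference deletion
# (the Mn2+ read-through signature). The scan examines every offset on both
# strands, so its contract is directly verifiable against a brute-force
# oracle.

empty_alignments <- function() {
  data.frame(sequence = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             n_mm = integer(0), del_ref_pos = integer(0),
             mm_read_pos = character(0), mm_ref_pos = character(0),
             edits = integer(0),
             n_best_hits = integer(0), capped = logical(0),
             stringsAsFactors = FALSE)
}

# Mismatch offsets come back from the scan in the orientation that was
# scanned; convert to reference coordinates (accounting for a deletion
# shifting downstream offsets by one) and to read 5'->3' coordinates.
mm_coords <- function(mmpos, start, del, L, minus) {
  ref <- character(length(mmpos)); readp <- character(length(mmpos))
  for (i in seq_along(mmpos)) {
    if (mmpos[i] == "") { ref[i] <- ""; readp[i] <- ""; next }
    p <- as.integer(strsplit(mmpos[i], ",")[[1]])
    d_off <- if (del[i] >= 0L) del[i] - start[i] else Inf
    rp <- start[i] + p + as.integer(p >= d_off)
    qp <- if (minus) L[i] - 1L - p else p
    o <- order(qp)
    ref[i] <- paste(rp[o], collapse = ",")
    readp[i] <- paste(qp[o], collapse = ",")
  }
  list(ref = ref, read = readp)
}

scan_contig <- function(contig_name, subject, seqs, max_mismatch, with_del) {
  hits <- list()
  fw <- .scan_queries_cpp(subject, seqs, max_mismatch, with_del)
  if (length(fw$qidx)) {
    L <- nchar(seqs[fw$qidx])
    w <- L + ifelse(fw$del >= 0L, 1L, 0L)
    mc <- mm_coords(fw$mmpos, fw$start, fw$del, L, minus = FALSE)
    hits$fw <- data.frame(
      sequence = seqs[fw$qidx], contig = contig_name, start = fw$start,
      end = fw$start + w, strand = "+", n_mm = fw$nmm,
      del_ref_pos = ifelse(fw$del >= 0L, fw$del, NA_integer_),
      mm_read_pos = mc$read, mm_ref_pos = mc$ref, stringsAsFactors = FALSE)
  }
  rc <- revcomp(seqs)
  rv <- .scan_queries_cpp(subject, rc, max_mismatch, with_del)
  if (length(rv$qidx)) {
    L <- nchar(seqs[rv$qidx])
    w <- L + ifelse(rv$del >= 0L, 1L, 0L)
    mc <- mm_coords(rv$mmpos, rv$start, rv$del, L, minus = TRUE)
    hits$rv <- data.frame(
      sequence = seqs[rv$qidx], contig = contig_name, start = rv$start,
      end = rv$start + w, strand = "-", n_mm = rv$nmm,
      del_ref_pos = ifelse(rv$del >= 0L, rv$del, NA_integer_),
      mm_read_pos = mc$read, mm_ref_pos = mc$ref, stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

finish_alignments <- function(hits, policy, hit_cap) {
  if (is.null(hits) || !nrow(hits)) return(empty_alignments())
  hits$edits <- hits$n_mm + !is.na(hits$del_ref_pos)
  # best stratum per sequence: fewest total edits; on ties an ungapped
  # placement beats a deletion placement (substitutions are the more
  # parsimonious explanation)
  sp <- split(seq_len(nrow(hits)), hits$sequence)
  keep <- unlist(lapply(sp, function(ix) {
    e <- hits$edits[ix]
    ix <- ix[e == min(e)]
    gapless <- ix[is.na(hits$del_ref_pos[ix])]
    if (length(gapless)) gapless else ix
  }), use.names = FALSE)
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order_radix(hits$sequence, hits$contig, hits$start,
                           hits$strand), , drop = FALSE]
  nb <- table(hits$sequence)
  hits$n_best_hits <- as.integer(nb[hits$sequence])
  hits$capped <- hits$n_best_hits > hit_cap
  if (any(hits$capped)) {
    # keep the first hit_cap placements of pathological repeats
    ix <- unlist(lapply(split(seq_len(nrow(hits)), hits$sequence),
                        function(i) head(i, hit_cap)), use.names = FALSE)
    hits <- hits[sort(ix), , drop = FALSE]
  }
  if (policy == "unique_only") {
    hits <- hits[hits$n_best_hits == 1L & !hits$capped, , drop = FALSE]
  } else if (policy == "single_hit") {
    # one placement per read even when it multimaps (deterministic: first
    # by contig/start/strand)
    first <- !duplicated(hits$sequence)
    hits <- hits[first, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Align collapsed sequences end-to-end with a mismatch budget
#'
#' For each sequence, finds all end-to-end ungapped placements on either
#' strand of the reference and keeps the best stratum (fewest mismatches).
#' Unmapped sequences are dropped. Hits are ordered by (sequence, contig,
#' start, strand).
#'
#' @param collapsed a `CollapsedReads` or a character vector of sequences.
#' @param ref a `ToyReference`.
#' @param max_mismatch mismatch budget, 0..3.
#' @param policy `"all_best"` reports every best-stratum hit,
#'   `"unique_only"` drops sequences with more than one best hit,
#'   `"single_hit"` keeps one deterministic placement per sequence (the
#'   single-mapping-event rule used for metagene profiles).
#' @param hit_cap placements kept per sequence before the hit is flagged
#'   `capped` (pathological repeats).
#' @return data.frame of alignments: sequence, contig, start, end (0-based
#'   half-open), strand, n_mm, del_ref_pos (NA here), mm_read_pos
#'   (comma-separated 0-based read offsets), edits, n_best_hits, capped.
#' @export
align_reads <- function(collapsed, ref, max_mismatch = 1L,
                        policy = c("all_best", "unique_only", "single_hit"),
                        hit_cap = 50L) {
  policy <- match.arg(policy)
  stopifnot(max_mismatch >= 0L, max_mismatch <= 3L)
  seqs <- if (is.character(collapsed)) unique(collapsed) else
    collapsed$sequence
  if (!length(seqs)) return(empty_alignments())
  hits <- do.call(rbind, lapply(names(ref$contigs), function(cn)
    scan_contig(cn, ref$contigs[[cn]], seqs, max_mismatch, FALSE)))
  finish_alignments(hits, policy, hit_cap)
}

#' Align admitting one 1-nt internal reference deletion
#'
#' As [align_reads()], but each sequence may additionally align with exactly
#' one internal 1-nt deletion relative to the reference. The best stratum is
#' by total edits (mismatches + deletion); ambiguous deletion placement
#' within a homopolymer is normalized to the leftmost position.
#'
#' @inheritParams align_reads
#' @return Alignment data.frame; `del_ref_pos` carries the 0-based reference
#'   coordinate of the deleted base for deletion placements.
#' @export
align_with_deletions <- function(collapsed, ref, max_mismatch = 1L,
                                 policy = c("all_best", "unique_only",
                                            "single_hit"),
                                 hit_cap = 50L) {
  policy <- match.arg(policy)
  stopifnot(max_mismatch >= 0L, max_mismatch <= 3L)
  seqs <- if (is.character(collapsed)) unique(collapsed) else
    collapsed$sequence
  if (!length(seqs)) return(empty_alignments())
  hits <- do.call(rbind, lapply(names(ref$contigs), function(cn)
    scan_contig(cn, ref$contigs[[cn]], seqs, max_mismatch, TRUE)))
  finish_alignments(hits, policy, hit_cap)
}

#' Annotate alignments with overlapping reference features
#'
#' Assigns each alignment the feature with the largest overlap (ties broken
#' by feature order) plus the set of TE families among all overlapped
#' features.
#'
#' @param aln alignment data.frame.
#' @param ref a `ToyReference`.
#' @return `aln` with columns feature_id, feature_class, family, gene_set,
#'   families_all (comma-joined TE families overlapped, NA if none).
#' @export
annotate_alignments <- function(aln, ref) {
  fs <- ref$features
  cols <- c("feature_id", "feature_class", "family", "gene_set",
            "families_all")
  if (!nrow(aln) || !nrow(fs)) {
    for (cl in cols) aln[[cl]] <- character(0)
    return(aln)
  }
  gr_a <- GenomicRanges::GRanges(aln$contig,
                                 IRanges::IRanges(aln$start + 1L, aln$end))
  gr_f <- GenomicRanges::GRanges(fs$contig,
                                 IRanges::IRanges(fs$start + 1L, fs$end))
  ov <- GenomicRanges::findOverlaps(gr_a, gr_f)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_a)[qh],
                                          IRanges::ranges(gr_f)[sh]))
  best <- rep(NA_integer_, nrow(aln))
  fam_all <- rep(NA_character_, nrow(aln))
  if (length(qh)) {
    o <- order(qh, -w, sh)
    first <- !duplicated(qh[o])
    best[qh[o][first]] <- sh[o][first]
    fam_split <- split(fs$family[sh], qh)
    fam_str <- vapply(fam_split, function(f) {
      f <- sort(unique(f[!is.na(f)]), method = "radix")
      if (length(f)) paste(f, collapse = ",") else NA_character_
    }, character(1))
    fam_all[as.integer(names(fam_str))] <- fam_str
  }
  aln$feature_id <- ifelse(is.na(best), NA_character_, fs$id[best])
  aln$feature_class <- ifelse(is.na(best), NA_character_, fs$class[best])
  aln$family <- ifelse(is.na(best), NA_character_, fs$family[best])
  aln$gene_set <- ifelse(is.na(best), NA_character_, fs$gene_set[best])
  aln$families_all <- fam_all
  aln
}

#' Write alignments as SAM
#'
#' Minimal valid SAM: `@HD`/`@SQ` header, ungapped records as `<L>M`,
#' deletion placements as `<a>M1D<b>M`, NM tag with total edits and a custom
#' `XD` tag carrying the 0-based reference position of the deletion.
#'
#' @param aln alignment data.frame.
#' @param ref a `ToyReference`.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (cn in names(ref$contigs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", cn, nchar(ref$contigs[[cn]])),
               con)
  }
  if (!nrow(aln)) return(invisible(path))
  L <- nchar(aln$sequence)
  cigar <- ifelse(is.na(aln$del_ref_pos), sprintf("%dM", L),
                  sprintf("%dM1D%dM", aln$del_ref_pos - aln$start,
                          L - (aln$del_ref_pos - aln$start)))
  flag <- ifelse(aln$strand == "+", 0L, 16L)
  seq_out <- ifelse(aln$strand == "+", aln$sequence, revcomp(aln$sequence))
  recs <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d%s",
                  sprintf("seq%06d", match(aln$sequence,
                                           unique(aln$sequence))),
                  flag, aln$contig, aln$start + 1L, cigar, seq_out,
                  aln$edits,
                  ifelse(is.na(aln$del_ref_pos), "",
                         sprintf("\tXD:i:%d", aln$del_ref_pos)))
  writeLines(recs, con)
  invisible(path)
}
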