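# FASTQ input, adapter trimming, length/quality filtering and collapsing of
# small RNA reads into unique-sequence count records. Reads are held as plain
# data.frames (id, seq, qual); Biostrings does the FASTQ parsing/writing.

#' Read a FASTQ file into a read table
#' @param path FASTQ path (`.gz` accepted).
#' @return data.frame with columns id, seq, qual (Phred+33 string).
#' @export
read_fastq <- function(path) {
  # Biostrings warns that mcols are dropped when it re-wraps the qualities;
  # nothing of ours is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(id = names(x),
             seq = unname(as.character(x)),
             qual = unname(as.character(Biostrings::quality(x))),
             stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#' @param reads data.frame with id, seq, qual.
#' @param path output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Leftmost match of `adapter` (or a prefix of it, >= min_overlap long, when
# the adapter runs off the read end) starting at read position p (1-based),
# allowing up to max_mismatch substitutions. Returns 0 when absent.
adapter_hit_pos <- function(seq, adapter, min_overlap, max_mismatch) {
  n <- nchar(seq); al <- nchar(adapter)
  rb <- strsplit(seq, "")[[1]]
  ab <- strsplit(adapter, "")[[1]]
  for (p in seq_len(n - min_overlap + 1L)) {
    w <- min(al, n - p + 1L)
    mm <- sum(rb[p:(p + w - 1L)] != ab[seq_len(w)])
    if (mm <= max_mismatch) return(p)
  }
  0L
}

#' Trim the 3' adapter and strip random end bases
#'
#' Removes the 3' adapter (or a terminal prefix of it at least `min_overlap`
#' bases long) and everything after it, allowing up to `max_mismatch`
#' substitutions in the match, then strips `random_ends` bases from each end
#' of the insert (NextFlex-style libraries). Reads with no adapter match are
#' discarded: small RNA inserts are shorter than the read, so a missing
#' adapter indicates a failed read.
#'
#' @param reads read table (id, seq, qual).
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter bases required at the read end.
#' @param random_ends random bases to strip from each end of the insert.
#' @param max_mismatch substitutions tolerated in the adapter match.
#' @return The trimmed read table, with a `trim_log` attribute counting
#'   kept / no_adapter / empty_insert reads (totals reconcile with input).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L, random_ends = 0L,
                         max_mismatch = 1L) {
  stopifnot(nchar(adapter) >= min_overlap, min_overlap >= 5L)
  n <- nrow(reads)
  pos <- vapply(reads$seq, adapter_hit_pos, integer(1), adapter = adapter,
                min_overlap = min_overlap, max_mismatch = max_mismatch,
                USE.NAMES = FALSE)
  ins_start <- 1L + random_ends
  ins_end <- pos - 1L - random_ends
  ok <- pos > 0L & ins_end >= ins_start
  out <- reads[ok, , drop = FALSE]
  out$seq <- substr(out$seq, ins_start, ins_end[ok])
  out$qual <- substr(out$qual, ins_start, ins_end[ok])
  rownames(out) <- NULL
  attr(out, "trim_log") <- data.frame(
    kept = sum(ok), no_adapter = sum(pos == 0L),
    empty_insert = sum(pos > 0L & ins_end < ins_start))
  out
}

phred_scores <- function(qual) utf8ToInt(qual) - 33L

#' Filter reads on length, ambiguity and base quality
#'
#' Retains reads with `min_len <= length <= max_len`, no N, and (when
#' quality filtering is on) at least `q_frac` of bases at Phred
#' `>= min_q`.
#'
#' @param reads read table.
#' @param min_len,max_len inclusive length bounds (nt).
#' @param min_q Phred threshold (default Q20).
#' @param q_frac required fraction of bases at or above `min_q`.
#' @param apply_quality apply the quality rule (off for presets that filter
#'   on length only).
#' @return Filtered read table with a `filter_log` attribute counting
#'   kept / bad_length / has_n / low_quality.
#' @export
filter_reads <- function(reads, min_len, max_len, min_q = 20L, q_frac = 0.9,
                         apply_quality = TRUE) {
  stopifnot(min_len <= max_len)
  len <- nchar(reads$seq)
  ok_len <- len >= min_len & len <= max_len
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  ok_q <- rep(TRUE, nrow(reads))
  if (apply_quality && nrow(reads)) {
    ok_q <- vapply(reads$qual, function(q) {
      s <- phred_scores(q)
      mean(s >= min_q) >= q_frac
    }, logical(1), USE.NAMES = FALSE)
  }
  keep <- ok_len & !has_n & ok_q
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- data.frame(
    kept = sum(keep), bad_length = sum(!ok_len),
    has_n = sum(ok_len & has_n),
    low_quality = sum(ok_len & !has_n & !ok_q))
  out
}

#' Collapse reads to unique sequences with per-library counts
#'
#' @param reads_list named list of read tables; names are library labels.
#' @param keep_quality if TRUE, attach a representative quality string per
#'   unique sequence (the lexicographically greatest among its reads, i.e.
#'   the cleanest observation) as attribute `qual`, for base-quality-aware
#'   pileups.
#' @return data.frame of class `CollapsedReads`: a `sequence` column
#'   (lexicographic order, C collation) plus one integer count column per
#'   library. Total counts are conserved.
#' @export
collapse_reads <- function(reads_list, keep_quality = FALSE) {
  stopifnot(is.list(reads_list), !is.null(names(reads_list)))
  labels <- names(reads_list)
  all_seq <- sort(unique(unlist(lapply(reads_list, `[[`, "seq"),
                                use.names = FALSE)),
                  method = "radix")
  counts <- vapply(reads_list, function(r) {
    tab <- table(factor(r$seq, levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  if (length(all_seq) == 0L)
    counts <- matrix(integer(0), nrow = 0, ncol = length(labels),
                     dimnames = list(NULL, labels))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = length(all_seq),
                     dimnames = list(NULL, labels))
  out <- data.frame(sequence = all_seq, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("CollapsedReads", "data.frame")
  if (keep_quality && length(all_seq)) {
    sq <- unlist(lapply(reads_list, `[[`, "seq"), use.names = FALSE)
    ql <- unlist(lapply(reads_list, `[[`, "qual"), use.names = FALSE)
    o <- order(sq, ql, method = "radix", decreasing = c(FALSE, TRUE))
    first <- !duplicated(sq[o])
    qual <- setNames(ql[o][first], sq[o][first])
    attr(out, "qual") <- qual[all_seq]
  }
  out
}

#' Write collapsed reads as a collapsed FASTA
#'
#' Headers follow the `>seq<rank>_x<count>` convention of collapsed small
#' RNA FASTA files, using the given library's counts (sequences with zero
#' count in that library are skipped).
#'
#' @param collapsed a `CollapsedReads`.
#' @param path output FASTA path.
#' @param library library column to take counts from; defaults to the sum
#'   over libraries.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path, library = NULL) {
  cnt <- if (is.null(library)) {
    rowSums(as.matrix(collapsed[, setdiff(names(collapsed), "sequence"),
                                drop = FALSE]))
  } else collapsed[[library]]
  keep <- cnt > 0
  dna <- Biostrings::DNAStringSet(collapsed$sequence[keep])
  names(dna) <- sprintf("seq%d_x%d", seq_len(sum(keep)), cnt[keep])
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' One-call preprocessing: trim (optional), filter, collapse
#'
#' @param reads_list named list of read tables.
#' @param adapter 3' adapter, or NULL for post-trim input.
#' @param random_ends random end bases stripped after adapter removal.
#' @param min_len,max_len length bounds.
#' @param min_q,q_frac,apply_quality quality rule, see [filter_reads()].
#' @return A `CollapsedReads` with a `preprocess_log` attribute (per-library
#'   kept/discard tallies).
#' @export
preprocess_reads <- function(reads_list, adapter = NULL, random_ends = 0L,
                             min_len = 15L, max_len = 30L, min_q = 20L,
                             q_frac = 0.9, apply_quality = TRUE) {
  logs <- list()
  out <- lapply(names(reads_list), function(lab) {
    r <- reads_list[[lab]]
    n0 <- nrow(r)
    if (!is.null(adapter)) {
      r <- trim_adapter(r, adapter, random_ends = random_ends)
    }
    r <- filter_reads(r, min_len, max_len, min_q, q_frac, apply_quality)
    logs[[lab]] <<- data.frame(library = lab, input = n0, kept = nrow(r))
    r
  })
  names(out) <- names(reads_list)
  collapsed <- collapse_reads(out)
  attr(collapsed, "preprocess_log") <- do.call(rbind, logs)
  collapsed
}
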