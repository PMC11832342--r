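# Fixtures built in code and independent oracles used across tests.

# A ToyReference assembled by hand, so tests control every base.
manual_reference <- function(contigs, features) {
  defaults <- data.frame(family = NA_character_, gene_set = NA_character_,
                         stringsAsFactors = FALSE)
  for (col in names(defaults)) {
    if (!col %in% names(features))
      features[[col]] <- rep(defaults[[col]], nrow(features))
  }
  structure(list(contigs = contigs, features = features,
                 known_sites = data.frame(contig = character(0),
                                          pos = integer(0))),
            class = "ToyReference")
}

manual_truth <- function(ref, feature_id, offset, stoich) {
  fs <- ref$features
  i <- match(feature_id, fs$id)
  pos <- ifelse(fs$strand[i] == "+", fs$start[i] + offset,
                fs$end[i] - 1L - offset)
  truth <- data.frame(site_id = sprintf("site%03d", seq_along(feature_id)),
                      contig = fs$contig[i], pos = as.integer(pos),
                      feature_id = feature_id, offset = as.integer(offset),
                      stoich = stoich, stringsAsFactors = FALSE)
  class(truth) <- c("PsiGroundTruth", "data.frame")
  validate_psi_truth(ref, truth)
  truth
}

reads_df <- function(seqs, qual = NULL) {
  if (is.null(qual)) qual <- strrep("F", nchar(seqs))
  data.frame(id = sprintf("r%04d", seq_along(seqs)), seq = seqs,
             qual = qual, stringsAsFactors = FALSE)
}

rc_chr <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(b)
    paste(rev(b), collapse = ""), character(1))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Exhaustive ungapped scan oracle: all placements of `read` on both strands
# of `refseq` with at most max_mm mismatches. Independent of the package's
# compiled scan.
oracle_hamming <- function(refseq, read, max_mm) {
  S <- nchar(refseq); L <- nchar(read)
  sb <- strsplit(refseq, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    rb <- strsplit(if (strand == "+") read else rc_chr(read), "")[[1]]
    if (L > S) next
    for (st in 0:(S - L)) {
      mm <- sum(sb[(st + 1):(st + L)] != rb)
      if (mm <= max_mm)
        hits[[length(hits) + 1L]] <- data.frame(start = st, strand = strand,
                                                n_mm = mm)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(0),
                                       strand = character(0),
                                       n_mm = integer(0)))
  do.call(rbind, hits)
}

# Median-of-ratios oracle written long-hand.
oracle_size_factors <- function(m) {
  gm <- apply(m, 1L, function(r) exp(mean(log(r))))
  use <- apply(m, 1L, function(r) all(r > 0))
  apply(m, 2L, function(col) median(col[use] / gm[use]))
}

# Benjamini-Hochberg step-up oracle from the definition: find the largest k
# with p_(k) <= k/m * q; here we return the standard adjusted values
# computed directly from the step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
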