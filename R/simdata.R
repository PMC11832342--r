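# Molecule-level synthetic data: toy reference, planted pseudouridine sites
# with known stoichiometry, and simulated libraries for all assay arms
# (IP bound/unbound, CMC+/mock under standard RT, CMC/Mn2+ mutational
# readout). Ground truth is emitted alongside, so every downstream stage can
# be tested as a parameter-recovery problem.

#' Specification of a toy reference
#'
#' Counts and length ranges per feature class for [build_toy_reference()].
#' Classes: miRNA-sized loci (fixed-sequence small RNAs), transposon (TE)
#' copies grouped into families, one rRNA-like locus with a designated list
#' of known uridine sites, tRNA loci (sense strand ending in CCA, with a
#' uridine at position 55 inside a UNUAR motif), and protein-coding-like
#' "other" genes with flanks for metagene profiles.
#'
#' @param n_mirna number of miRNA-sized loci.
#' @param mirna_len length range (nt) for miRNA loci.
#' @param mirna_start_u_frac fraction of miRNA loci forced to start with U,
#'   emulating the 5'-U bias of plant small RNAs.
#' @param n_te_families,te_copies_per_family,te_len TE family layout; copies
#'   within a family diverge from a family consensus.
#' @param te_divergence per-base substitution rate between family consensus
#'   and each copy.
#' @param rrna_len length of the rRNA-like locus (0 disables it).
#' @param n_rrna_known_sites number of designated known uridine sites on the
#'   rRNA locus.
#' @param n_trna number of tRNA loci (length 76, sense ends in CCA).
#' @param n_genes,gene_len,gene_flank "other"-class genes and the flank (nt)
#'   kept around them for metagene profiles.
#' @param gene_set_label label attached to half of the genes (a toy gene
#'   set, e.g. demeter-target-like loci).
#' @param spacer range of random spacer lengths between features.
#' @return A list of class `reference_spec`.
#' @export
reference_spec <- function(n_mirna = 200, mirna_len = c(20, 24),
                           mirna_start_u_frac = 0.6,
                           n_te_families = 4, te_copies_per_family = 3,
                           te_len = c(120, 200), te_divergence = 0.05,
                           rrna_len = 2000, n_rrna_known_sites = 5,
                           n_trna = 4,
                           n_genes = 0, gene_len = c(400, 600),
                           gene_flank = 1000,
                           gene_set_label = "DME_target",
                           spacer = c(40, 80)) {
  spec <- list(n_mirna = n_mirna, mirna_len = mirna_len,
               mirna_start_u_frac = mirna_start_u_frac,
               n_te_families = n_te_families,
               te_copies_per_family = te_copies_per_family,
               te_len = te_len, te_divergence = te_divergence,
               rrna_len = rrna_len, n_rrna_known_sites = n_rrna_known_sites,
               n_trna = n_trna, n_genes = n_genes, gene_len = gene_len,
               gene_flank = gene_flank, gene_set_label = gene_set_label,
               spacer = spacer)
  counts <- c(spec$n_mirna, spec$n_te_families, spec$n_trna, spec$n_genes)
  if (any(counts < 0)) stop("feature counts must be >= 0")
  class(spec) <- "reference_spec"
  spec
}

rand_len <- function(range) {
  if (length(range) == 1L) range else sample(range[1]:range[2], 1L)
}

# Lay features with random spacers on one contig; returns contig string and
# feature table. `seqs` are sense-strand sequences; minus-strand features are
# embedded as their reverse complement.
lay_contig <- function(contig_name, seqs, strands, ids, class, family,
                       gene_set, spacer, flank = 0L) {
  pieces <- character(0); feats <- list(); pos <- 0L
  lead <- max(rand_len(spacer), flank)
  pieces <- c(pieces, random_dna(lead)); pos <- pos + lead
  for (i in seq_along(seqs)) {
    emb <- if (strands[i] == "+") seqs[i] else revcomp(seqs[i])
    w <- nchar(emb)
    feats[[i]] <- data.frame(id = ids[i], contig = contig_name,
                             start = pos, end = pos + w,
                             strand = strands[i], class = class,
                             family = family[i], gene_set = gene_set[i],
                             stringsAsFactors = FALSE)
    pieces <- c(pieces, emb); pos <- pos + w
    gap <- max(rand_len(spacer), flank)
    pieces <- c(pieces, random_dna(gap)); pos <- pos + gap
  }
  list(seq = paste(pieces, collapse = ""), features = do.call(rbind, feats))
}

#' Build a toy reference with annotated small RNA features
#'
#' Generates contigs (A/C/G/T alphabet; U is represented as T) and a feature
#' table satisfying the reference invariants: all intervals within their
#' contig (0-based half-open), every TE copy carrying a family label, every
#' tRNA ending in CCA on its sense strand. The rRNA-like contig carries a
#' designated `known_sites` list of uridine positions emulating predicted
#' sites of rRNA pseudouridylation.
#'
#' @param spec a [reference_spec()].
#' @param seed integer seed; the same spec and seed give a byte-identical
#'   reference.
#' @return A list of class `ToyReference` with elements `contigs` (named
#'   character vector), `features` (data.frame with columns id, contig,
#'   start, end, strand, class, family, gene_set) and `known_sites`
#'   (data.frame contig/pos of designated rRNA uridines, possibly empty).
#' @export
build_toy_reference <- function(spec = reference_spec(), seed = 1L) {
  stopifnot(inherits(spec, "reference_spec"))
  with_seed(substream_seed(seed, "reference"), {
    contigs <- character(0)
    feats <- list()
    if (spec$n_mirna > 0) {
      n <- spec$n_mirna
      seqs <- vapply(seq_len(n), function(i) {
        s <- random_dna(rand_len(spec$mirna_len))
        if (runif(1) < spec$mirna_start_u_frac)
          s <- paste0("T", substr(s, 2L, nchar(s)))
        s
      }, character(1))
      strands <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.7, 0.3))
      laid <- lay_contig("chr_mir", seqs, strands,
                         sprintf("mir%03d", seq_len(n)), "miRNA",
                         rep(NA_character_, n), rep(NA_character_, n),
                         spec$spacer)
      contigs["chr_mir"] <- laid$seq; feats <- c(feats, list(laid$features))
    }
    if (spec$n_te_families > 0 && spec$te_copies_per_family > 0) {
      seqs <- character(0); fams <- character(0); ids <- character(0)
      for (f in seq_len(spec$n_te_families)) {
        cons <- random_dna(rand_len(spec$te_len))
        for (k in seq_len(spec$te_copies_per_family)) {
          b <- strsplit(cons, "")[[1]]
          mut <- runif(length(b)) < spec$te_divergence
          b[mut] <- vapply(b[mut], function(x)
            sample(setdiff(BASES, x), 1L), character(1))
          seqs <- c(seqs, paste(b, collapse = ""))
          fams <- c(fams, sprintf("TEfam%02d", f))
          ids <- c(ids, sprintf("TEfam%02d_copy%d", f, k))
        }
      }
      n <- length(seqs)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      laid <- lay_contig("chr_te", seqs, strands, ids, "TE_copy", fams,
                         rep(NA_character_, n), spec$spacer)
      contigs["chr_te"] <- laid$seq; feats <- c(feats, list(laid$features))
    }
    known_sites <- data.frame(contig = character(0), pos = integer(0))
    if (spec$rrna_len > 0) {
      seq <- random_dna(spec$rrna_len)
      laid <- lay_contig("chr_rrna", seq, "+", "rRNA1", "rRNA",
                         NA_character_, NA_character_, spec$spacer)
      contigs["chr_rrna"] <- laid$seq; feats <- c(feats, list(laid$features))
      fs <- laid$features
      tpos <- fs$start + which(strsplit(seq, "")[[1]] == "T") - 1L
      # keep designated sites away from the locus edges
      tpos <- tpos[tpos > fs$start + 50 & tpos < fs$end - 50]
      k <- min(spec$n_rrna_known_sites, length(tpos))
      if (k > 0) {
        known_sites <- data.frame(
          contig = "chr_rrna",
          pos = sort(sample(tpos, k)))
      }
    }
    if (spec$n_trna > 0) {
      n <- spec$n_trna
      seqs <- vapply(seq_len(n), function(i) {
        s <- random_dna(70L)
        # canonical T-arm: uridine at position 55 (1-based) inside a UNUAR
        # motif (U-N-U-A-purine), sense strand ends in CCA
        substr(s, 53L, 57L) <- "TATAG"
        paste0(s, "CCA")
      }, character(1))
      strands <- sample(c("+", "-"), n, replace = TRUE)
      laid <- lay_contig("chr_trna", seqs, strands,
                         sprintf("tRNA%02d", seq_len(n)), "tRNA",
                         rep(NA_character_, n), rep(NA_character_, n),
                         spec$spacer)
      contigs["chr_trna"] <- laid$seq; feats <- c(feats, list(laid$features))
    }
    if (spec$n_genes > 0) {
      n <- spec$n_genes
      seqs <- vapply(seq_len(n), function(i)
        random_dna(rand_len(spec$gene_len)), character(1))
      strands <- sample(c("+", "-"), n, replace = TRUE)
      gs <- rep(NA_character_, n)
      gs[seq_len(ceiling(n / 2))] <- spec$gene_set_label
      laid <- lay_contig("chr_gene", seqs, strands,
                         sprintf("gene%03d", seq_len(n)), "other",
                         rep(NA_character_, n), gs, spec$spacer,
                         flank = spec$gene_flank)
      contigs["chr_gene"] <- laid$seq; feats <- c(feats, list(laid$features))
    }
    features <- if (length(feats)) do.call(rbind, feats) else
      data.frame(id = character(0), contig = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 class = character(0), family = character(0),
                 gene_set = character(0), stringsAsFactors = FALSE)
    rownames(features) <- NULL
    ref <- structure(list(contigs = contigs, features = features,
                          known_sites = known_sites),
                     class = "ToyReference")
    validate_toy_reference(ref)
    ref
  })
}

#' Validate a ToyReference against its invariants
#' @param ref a `ToyReference`.
#' @return `ref`, invisibly; errors on violation.
#' @export
validate_toy_reference <- function(ref) {
  stopifnot(inherits(ref, "ToyReference"))
  fs <- ref$features
  if (nrow(fs)) {
    if (any(!fs$contig %in% names(ref$contigs)))
      stop("feature on unknown contig")
    if (any(fs$start < 0) || any(fs$start >= fs$end))
      stop("feature intervals must satisfy 0 <= start < end")
    if (any(fs$end > nchar(ref$contigs[fs$contig])))
      stop("feature extends past contig end")
    te <- fs$class == "TE_copy"
    if (any(te & (is.na(fs$family) | fs$family == "")))
      stop("TE copies must carry a family label")
    tr <- which(fs$class == "tRNA")
    for (i in tr) {
      if (substr(feature_sense_seq(ref, i), fs$end[i] - fs$start[i] - 2L,
                 fs$end[i] - fs$start[i]) != "CCA")
        stop("tRNA sense strand must end in CCA")
    }
  }
  if (any(grepl("[^ACGT]", ref$contigs)))
    stop("contigs must contain only A/C/G/T")
  invisible(ref)
}

# Sense-strand sequence of feature row i (5'->3' of the annotated strand).
feature_sense_seq <- function(ref, i) {
  fs <- ref$features[i, ]
  s <- substr(ref$contigs[[fs$contig]], fs$start + 1L, fs$end)
  if (fs$strand == "-") s <- revcomp(s)
  s
}

#' Plant pseudouridine sites with known stoichiometry
#'
#' Selects a fraction of features and places one uridine site per selected
#' feature, with stoichiometry (fraction of molecules modified) drawn
#' uniformly in `stoich_range`. With `five_prime_bias > 0`, probability mass
#' is moved to the first nucleotide of miRNA-sized features that start with
#' U, mirroring the observed 5'-terminal preference. Designated rRNA known
#' sites can be included at fixed stoichiometry.
#'
#' @param ref a `ToyReference`.
#' @param frac_modified_features fraction of eligible features receiving a
#'   site.
#' @param n_modified if not NULL, select exactly this many eligible
#'   features instead of the Bernoulli fraction.
#' @param stoich_range range of per-site stoichiometries, within (0, 1].
#' @param five_prime_bias probability that a miRNA-sized feature's site is
#'   forced to offset 0 (requires a 5' U).
#' @param classes feature classes eligible for random site placement.
#' @param include_known_rrna also plant the reference's designated rRNA
#'   sites.
#' @param rrna_stoich stoichiometry for the designated rRNA sites.
#' @param seed integer seed.
#' @return data.frame of class `PsiGroundTruth` with columns site_id,
#'   contig, pos (0-based contig coordinate of the sense-strand U),
#'   feature_id, offset (0-based 5'->3' within the feature), stoich.
#' @export
assign_psi_sites <- function(ref, frac_modified_features = 0.15,
                             n_modified = NULL,
                             stoich_range = c(0.5, 1),
                             five_prime_bias = 0,
                             classes = c("miRNA", "TE_copy", "tRNA"),
                             include_known_rrna = FALSE,
                             rrna_stoich = 0.9, seed = 1L) {
  stopifnot(frac_modified_features >= 0, frac_modified_features <= 1,
            all(stoich_range > 0), all(stoich_range <= 1))
  with_seed(substream_seed(seed, "psi_sites"), {
    fs <- ref$features
    rows <- list()
    idx <- which(fs$class %in% classes)
    sel <- if (!is.null(n_modified)) {
      sort(sample(idx, min(n_modified, length(idx))))
    } else idx[runif(length(idx)) < frac_modified_features]
    for (i in sel) {
      sense <- feature_sense_seq(ref, i)
      upos <- which(strsplit(sense, "")[[1]] == "T") - 1L
      if (!length(upos)) {
        warning(sprintf("feature %s has no U; skipped", fs$id[i]))
        next
      }
      len <- fs$end[i] - fs$start[i]
      off <- if (len <= 30 && 0L %in% upos && runif(1) < five_prime_bias)
        0L else sample(rep(upos, 2L), 1L)[1]
      st <- runif(1, stoich_range[1], stoich_range[2])
      pos <- if (fs$strand[i] == "+") fs$start[i] + off else
        fs$end[i] - 1L - off
      rows[[length(rows) + 1L]] <- data.frame(
        contig = fs$contig[i], pos = pos, feature_id = fs$id[i],
        offset = off, stoich = st, stringsAsFactors = FALSE)
    }
    if (include_known_rrna && nrow(ref$known_sites)) {
      ri <- which(fs$class == "rRNA")[1]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ref$known_sites$contig,
        pos = ref$known_sites$pos,
        feature_id = fs$id[ri],
        offset = ref$known_sites$pos - fs$start[ri],
        stoich = rrna_stoich, stringsAsFactors = FALSE)
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(contig = character(0), pos = integer(0),
                 feature_id = character(0), offset = integer(0),
                 stoich = numeric(0), stringsAsFactors = FALSE)
    truth <- truth[order_radix(truth$contig, truth$pos), , drop = FALSE]
    truth <- cbind(site_id = if (nrow(truth))
      sprintf("site%03d", seq_len(nrow(truth))) else character(0), truth)
    rownames(truth) <- NULL
    class(truth) <- c("PsiGroundTruth", "data.frame")
    validate_psi_truth(ref, truth)
    truth
  })
}

#' Validate planted sites against the reference
#' @param ref a `ToyReference`.
#' @param truth a `PsiGroundTruth`.
#' @return `truth`, invisibly; errors if a site is off the reference or does
#'   not coincide with a sense-strand U.
#' @export
validate_psi_truth <- function(ref, truth) {
  if (!nrow(truth)) return(invisible(truth))
  if (any(!truth$contig %in% names(ref$contigs)))
    stop("truth site on unknown contig")
  if (any(truth$pos < 0 | truth$pos >= nchar(ref$contigs[truth$contig])))
    stop("truth site off reference")
  fs <- ref$features
  fi <- match(truth$feature_id, fs$id)
  if (anyNA(fi)) stop("truth site on unknown feature")
  strand <- fs$strand[fi]
  base <- substr(ref$contigs[truth$contig], truth$pos + 1L, truth$pos + 1L)
  ok <- ifelse(strand == "+", base == "T", base == "A")
  if (!all(ok)) stop("truth site does not coincide with a sense-strand U")
  if (any(truth$stoich <= 0 | truth$stoich > 1))
    stop("stoichiometries must lie in (0, 1]")
  invisible(truth)
}

#' Simulation configuration
#'
#' Parameters of the molecule-level generative process. Defaults are the
#' package's standard study conditions: 5e4 molecules per library, log-normal
#' feature expression, antibody capture efficiency 0.8 per pseudouridylated
#' molecule with 0.05 background, CMC adduct probability 0.9, Mn2+
#' read-through converting an adduct to a 1-nt deletion or a mismatch with
#' probability 0.3 each, per-base sequencing error 1e-3, three replicate
#' pairs per assay.
#'
#' @param master_seed integer master seed; all substreams derive from it.
#' @param molecules_per_library molecules sampled into each input pool.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   per-feature molecule share.
#' @param ip_capture_eff per-pseudouridine antibody capture probability; a
#'   molecule carrying k sites is captured with probability
#'   `1 - (1 - ip_capture_eff)^k`.
#' @param ip_background capture probability for unmodified molecules.
#' @param adduct_prob probability a pseudouridine receives a CMC adduct.
#' @param p_del,p_mis per-adduct probabilities of a 1-nt deletion or a
#'   random non-cognate mismatch under Mn2+ reverse transcription
#'   (`p_del + p_mis <= 1`; the remainder reads through cleanly).
#' @param seq_error per-base sequencing miscall rate; miscalled bases are
#'   written at reduced quality.
#' @param jitter_prob,jitter_max probability and maximum extent (nt) of 3'
#'   trimming of short-feature molecules (read-length jitter).
#' @param frag_len fragment length range for molecules sampled from long
#'   features (rRNA/TE/tRNA/other longer than 35 nt).
#' @param replicates replicate pairs per assay arm.
#' @param assays assay groups to simulate, subset of
#'   `c("input", "ip", "cmc", "mn")`.
#' @param raw_mode if TRUE, emit raw reads: insert flanked by `random_ends`
#'   random bases on each side plus the 3' adapter (NextFlex-style);
#'   otherwise reads are emitted post-trim.
#' @param adapter3 3' adapter sequence used in raw mode.
#' @param random_ends random bases appended to each side of the insert in
#'   raw mode.
#' @param high_q,err_q Phred scores for correct and miscalled bases.
#' @param protocol_order metadata flag recording the intended order of
#'   adapter ligation relative to CMC treatment; it does not change the
#'   simulated output.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(master_seed = 1L, molecules_per_library = 50000L,
                       expression_meanlog = 0, expression_sdlog = 1,
                       ip_capture_eff = 0.8, ip_background = 0.05,
                       adduct_prob = 0.9, p_del = 0.3, p_mis = 0.3,
                       seq_error = 0.001, jitter_prob = 0.1, jitter_max = 1L,
                       frag_len = c(18L, 30L), replicates = 3L,
                       assays = c("input", "ip", "cmc", "mn"),
                       raw_mode = FALSE,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       random_ends = 0L, high_q = 37L, err_q = 10L,
                       protocol_order = c("three_prime_ligation_first",
                                          "five_prime_ligation_first")) {
  cfg <- list(master_seed = as.integer(master_seed),
              molecules_per_library = as.integer(molecules_per_library),
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              ip_capture_eff = ip_capture_eff,
              ip_background = ip_background,
              adduct_prob = adduct_prob, p_del = p_del, p_mis = p_mis,
              seq_error = seq_error, jitter_prob = jitter_prob,
              jitter_max = as.integer(jitter_max),
              frag_len = as.integer(frag_len),
              replicates = as.integer(replicates),
              assays = match.arg(assays, several.ok = TRUE),
              raw_mode = raw_mode, adapter3 = adapter3,
              random_ends = as.integer(random_ends),
              high_q = as.integer(high_q), err_q = as.integer(err_q),
              protocol_order = match.arg(protocol_order))
  probs <- c(cfg$ip_capture_eff, cfg$ip_background, cfg$adduct_prob,
             cfg$p_del, cfg$p_mis, cfg$seq_error, cfg$jitter_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$p_del + cfg$p_mis > 1) stop("p_del + p_mis must be <= 1")
  if (cfg$molecules_per_library <= 0) stop("molecules_per_library must be > 0")
  class(cfg) <- "SimConfig"
  cfg
}

# Draw one molecule pool: feature index, start offset within feature (sense
# coordinates), length, plus the per-molecule pseudouridine instances
# (molecule row, site row in truth, 0-based position within the molecule).
# `sense` is the precomputed vector of feature sense-strand sequences.
draw_pool <- function(ref, truth, cfg, shares, sense) {
  n <- cfg$molecules_per_library
  fs <- ref$features
  feat <- sample.int(nrow(fs), n, replace = TRUE, prob = shares)
  flen <- fs$end - fs$start
  len <- integer(n); s_off <- integer(n)
  short <- flen[feat] <= 35L
  len[short] <- flen[feat[short]]
  jit <- short & runif(n) < cfg$jitter_prob
  len[jit] <- pmax(15L, len[jit] - sample.int(cfg$jitter_max, sum(jit),
                                              replace = TRUE))
  if (any(!short)) {
    li <- which(!short)
    fl <- sample(seq(cfg$frag_len[1], cfg$frag_len[2]), length(li),
                 replace = TRUE)
    maxs <- flen[feat[li]] - fl
    s_off[li] <- floor(runif(length(li)) * (maxs + 1))
    len[li] <- fl
  }
  seqs <- substr(sense[feat], s_off + 1L, s_off + len)
  psi <- list(mol = integer(0), site = integer(0), pos = integer(0))
  if (nrow(truth)) {
    fi <- match(truth$feature_id, fs$id)
    for (k in seq_len(nrow(truth))) {
      m <- which(feat == fi[k] & s_off <= truth$offset[k] &
                   truth$offset[k] < s_off + len)
      if (!length(m)) next
      mod <- m[runif(length(m)) < truth$stoich[k]]
      psi$mol <- c(psi$mol, mod)
      psi$site <- c(psi$site, rep(k, length(mod)))
      psi$pos <- c(psi$pos, truth$offset[k] - s_off[mod])
    }
  }
  list(feat = feat, s_off = s_off, len = len, seqs = seqs,
       psi = as.data.frame(psi))
}

# Apply Mn2+ read-through outcomes to adducted instances: deletion with
# p_del, random non-cognate mismatch with p_mis, clean read-through
# otherwise. Returns edited sequences plus the per-site edit tally.
apply_mn_edits <- function(seqs, psi, adducted, cfg, n_sites) {
  n_del <- integer(n_sites); n_mis <- integer(n_sites)
  if (!any(adducted))
    return(list(seqs = seqs, n_del = n_del, n_mis = n_mis))
  u <- runif(sum(adducted))
  idx <- which(adducted)
  del <- idx[u < cfg$p_del]
  mis <- idx[u >= cfg$p_del & u < cfg$p_del + cfg$p_mis]
  for (j in mis) {
    m <- psi$mol[j]; p <- psi$pos[j] + 1L
    cur <- substr(seqs[m], p, p)
    substr(seqs[m], p, p) <- sample(setdiff(BASES, cur), 1L)
    n_mis[psi$site[j]] <- n_mis[psi$site[j]] + 1L
  }
  # deletions applied per molecule from rightmost position so earlier
  # positions stay valid when a molecule carries two edits
  if (length(del)) {
    dd <- data.frame(mol = psi$mol[del], pos = psi$pos[del],
                     site = psi$site[del])
    dd <- dd[order(dd$mol, -dd$pos), , drop = FALSE]
    for (r in seq_len(nrow(dd))) {
      m <- dd$mol[r]; p <- dd$pos[r]
      seqs[m] <- paste0(substr(seqs[m], 1L, p),
                        substr(seqs[m], p + 2L, nchar(seqs[m])))
      n_del[dd$site[r]] <- n_del[dd$site[r]] + 1L
    }
  }
  list(seqs = seqs, n_del = n_del, n_mis = n_mis)
}

# Per-base sequencing error with reduced quality at miscalled positions.
apply_seq_error <- function(seqs, cfg) {
  n <- length(seqs)
  len <- nchar(seqs)
  qual <- strrep(rawToChar(as.raw(cfg$high_q + 33L)), len)
  if (cfg$seq_error > 0 && n > 0) {
    nerr <- rbinom(n, len, cfg$seq_error)
    ec <- rawToChar(as.raw(cfg$err_q + 33L))
    for (m in which(nerr > 0)) {
      pos <- sample.int(len[m], nerr[m])
      for (p in pos) {
        cur <- substr(seqs[m], p, p)
        substr(seqs[m], p, p) <- sample(setdiff(BASES, cur), 1L)
        substr(qual[m], p, p) <- ec
      }
    }
  }
  list(seqs = seqs, qual = qual)
}

make_library <- function(label, assay, condition, pair, replicate,
                         pool_idx, seqs, qual, feat_count) {
  structure(list(label = label, assay = assay, condition = condition,
                 pair = pair, replicate = replicate,
                 reads = data.frame(
                   id = if (length(seqs))
                     sprintf("%s:%06d", label, seq_along(seqs)) else
                       character(0),
                   seq = seqs, qual = qual, stringsAsFactors = FALSE),
                 feature_counts = feat_count),
            class = "SimulatedLibrary")
}

#' Simulate small RNA libraries for all assay arms
#'
#' Runs the molecule-level generative process: molecules are sampled from
#' features in proportion to a log-normal expression vector; each planted
#' site is modified per-molecule at its stoichiometry; the three assay
#' chemistries are applied per molecule (antibody capture and bound/unbound
#' partition; CMC adduction with RT-stop dropout under standard RT;
#' deletion/mismatch conversion under Mn2+ RT); finally uniform per-base
#' sequencing error is added and reads are emitted 5'->3' on the sense
#' strand. Within each assay arm and replicate, treated and mock arms derive
#' from the same molecule pool, so they are paired by construction.
#'
#' @param ref a `ToyReference`.
#' @param truth a `PsiGroundTruth` on `ref` (may be empty).
#' @param cfg a [sim_config()].
#' @return A list of class `SimulationResult`: `libraries` (list of
#'   `SimulatedLibrary`), `metadata` (data.frame: library, assay, condition,
#'   pair, replicate, type), `truth` (list: `sites`, `molecule_counts` of
#'   emitted molecules per feature x library, `edits` of injected Mn2+
#'   deletion/mismatch tallies per site x library), and `config`.
#' @export
simulate_libraries <- function(ref, truth, cfg = sim_config()) {
  stopifnot(inherits(ref, "ToyReference"), inherits(cfg, "SimConfig"))
  validate_psi_truth(ref, truth)
  fs <- ref$features
  if (!nrow(fs)) stop("reference has no features")
  shares <- with_seed(substream_seed(cfg$master_seed, "sim/expression"), {
    s <- rlnorm(nrow(fs), cfg$expression_meanlog, cfg$expression_sdlog)
    s / sum(s)
  })
  sense <- vapply(seq_len(nrow(fs)), function(i) feature_sense_seq(ref, i),
                  character(1))
  libs <- list()
  counts <- list()
  edits <- list()
  add_counts <- function(label, feat) {
    counts[[label]] <<- tabulate(feat, nbins = nrow(fs))
  }
  emit <- function(label, assay, condition, pair, rep_i, pool, keep,
                   mn = NULL) {
    seqs <- if (is.null(mn)) pool$seqs[keep] else mn$seqs[keep]
    sq <- apply_seq_error(seqs, cfg)
    seqs <- sq$seqs; qual <- sq$qual
    if (cfg$raw_mode) {
      n <- length(seqs)
      re <- cfg$random_ends
      if (re > 0) {
        left <- vapply(seq_len(n), function(i) random_dna(re), character(1))
        right <- vapply(seq_len(n), function(i) random_dna(re), character(1))
        seqs <- paste0(left, seqs, right)
      }
      seqs <- paste0(seqs, cfg$adapter3)
      hq <- rawToChar(as.raw(cfg$high_q + 33L))
      pad <- function(q, extra) paste0(q, strrep(hq, extra))
      qual <- vapply(seq_len(n), function(i) {
        q <- qual[i]
        if (re > 0) q <- paste0(strrep(hq, re), q, strrep(hq, re))
        paste0(q, strrep(hq, nchar(cfg$adapter3)))
      }, character(1))
    }
    add_counts(label, pool$feat[keep])
    libs[[label]] <<- make_library(label, assay, condition, pair, rep_i,
                                   keep, seqs, qual, counts[[label]])
  }
  for (r in seq_len(cfg$replicates)) {
    if ("input" %in% cfg$assays) {
      with_seed(substream_seed(cfg$master_seed, sprintf("sim/input/rep%d", r)), {
        pool <- draw_pool(ref, truth, cfg, shares, sense)
        emit(sprintf("input_rep%d", r), "input", "input",
             sprintf("input_rep%d", r), r, pool, seq_along(pool$seqs))
      })
    }
    if ("ip" %in% cfg$assays) {
      with_seed(substream_seed(cfg$master_seed, sprintf("sim/ip/rep%d", r)), {
        pool <- draw_pool(ref, truth, cfg, shares, sense)
        k <- tabulate(pool$psi$mol, nbins = length(pool$seqs))
        p_cap <- ifelse(k > 0, 1 - (1 - cfg$ip_capture_eff)^k,
                        cfg$ip_background)
        bound <- runif(length(pool$seqs)) < p_cap
        pair <- sprintf("ip_rep%d", r)
        emit(sprintf("ip_bound_rep%d", r), "ip", "ip_bound", pair, r,
             pool, which(bound))
        emit(sprintf("ip_unbound_rep%d", r), "ip", "ip_unbound", pair, r,
             pool, which(!bound))
      })
    }
    # dividing a sample gives two independent halves, so the treated and
    # mock arms are independent pools from the same expression vector
    if ("cmc" %in% cfg$assays) {
      pair <- sprintf("cmc_rep%d", r)
      with_seed(substream_seed(cfg$master_seed,
                               sprintf("sim/cmc_plus/rep%d", r)), {
        pool <- draw_pool(ref, truth, cfg, shares, sense)
        adducted <- runif(nrow(pool$psi)) < cfg$adduct_prob
        dropped <- unique(pool$psi$mol[adducted])
        keep <- setdiff(seq_along(pool$seqs), dropped)
        emit(sprintf("cmc_plus_rep%d", r), "cmc", "cmc_plus", pair, r,
             pool, keep)
      })
      with_seed(substream_seed(cfg$master_seed,
                               sprintf("sim/cmc_mock/rep%d", r)), {
        pool <- draw_pool(ref, truth, cfg, shares, sense)
        emit(sprintf("cmc_mock_rep%d", r), "cmc", "cmc_mock", pair, r,
             pool, seq_along(pool$seqs))
      })
    }
    if ("mn" %in% cfg$assays) {
      pair <- sprintf("mn_rep%d", r)
      with_seed(substream_seed(cfg$master_seed,
                               sprintf("sim/mn_plus/rep%d", r)), {
        pool <- draw_pool(ref, truth, cfg, shares, sense)
        adducted <- runif(nrow(pool$psi)) < cfg$adduct_prob
        mn <- apply_mn_edits(pool$seqs, pool$psi, adducted, cfg, nrow(truth))
        lab <- sprintf("mn_plus_rep%d", r)
        emit(lab, "mn", "mn_plus", pair, r, pool,
             seq_along(pool$seqs), mn = mn)
        if (nrow(truth)) {
          edits[[lab]] <- data.frame(site_id = truth$site_id,
                                     n_del = mn$n_del, n_mis = mn$n_mis,
                                     stringsAsFactors = FALSE)
        }
      })
      with_seed(substream_seed(cfg$master_seed,
                               sprintf("sim/mn_mock/rep%d", r)), {
        pool <- draw_pool(ref, truth, cfg, shares, sense)
        emit(sprintf("mn_mock_rep%d", r), "mn", "mn_mock", pair, r,
             pool, seq_along(pool$seqs))
      })
    }
  }
  metadata <- do.call(rbind, lapply(libs, function(l) data.frame(
    library = l$label, assay = l$assay, condition = l$condition,
    pair = l$pair, replicate = l$replicate, type = "biological",
    stringsAsFactors = FALSE)))
  rownames(metadata) <- NULL
  mc <- do.call(cbind, lapply(libs, function(l) l$feature_counts))
  molecule_counts <- data.frame(feature_id = fs$id, mc, check.names = FALSE,
                                stringsAsFactors = FALSE)
  structure(list(libraries = libs, metadata = metadata,
                 truth = list(sites = truth,
                              molecule_counts = molecule_counts,
                              edits = edits),
                 config = cfg),
            class = "SimulationResult")
}

#' Write a ToyReference to FASTA and BED
#'
#' The BED6 name field is `id` for unlabelled features and `id|family` for
#' TE copies.
#'
#' @param ref a `ToyReference`.
#' @param fasta,bed output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta, bed) {
  dna <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(dna, fasta)
  fs <- ref$features
  name <- ifelse(is.na(fs$family), fs$id, paste0(fs$id, "|", fs$family))
  bed_df <- data.frame(fs$contig, fs$start, fs$end, name, 0L, fs$strand)
  write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(fasta = fasta, bed = bed))
}

#' Write simulated libraries as FASTQ plus truth tables and a manifest
#'
#' @param sim a `SimulationResult`.
#' @param outdir output directory (created if needed).
#' @param gzip write `.fastq.gz` instead of `.fastq`.
#' @return Invisibly, the output directory.
#' @export
write_libraries <- function(sim, outdir, gzip = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (l in sim$libraries) {
    path <- file.path(outdir, paste0(l$label, ".fastq", if (gzip) ".gz"))
    write_fastq(l$reads, path)
  }
  write_tsv(sim$truth$sites, file.path(outdir, "truth_sites.tsv"))
  write_tsv(sim$truth$molecule_counts,
            file.path(outdir, "truth_molecule_counts.tsv"))
  write_tsv(sim$metadata, file.path(outdir, "sample_sheet.tsv"))
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(outdir, "run_manifest.yaml"))
  invisible(outdir)
}
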