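# Simulator: reference construction, site planting, and the molecule-level
# chemistry of the three assay arms.

test_that("toy reference satisfies its invariants and bookkeeping", {
  spec <- reference_spec(n_mirna = 10, mirna_len = 21, n_te_families = 2,
                         te_copies_per_family = 2, rrna_len = 300,
                         n_trna = 2)
  ref <- build_toy_reference(spec, seed = 3)
  expect_silent(validate_toy_reference(ref))
  fs <- ref$features
  mir <- fs[fs$class == "miRNA", ]
  expect_equal(nrow(mir), 10L)
  expect_true(all(mir$end - mir$start == 21L))
  te <- fs[fs$class == "TE_copy", ]
  expect_true(all(!is.na(te$family) & te$family != ""))
  expect_true(all(grepl("^[ACGT]+$", ref$contigs)))
  # rRNA known sites are uridines on the locus
  ks <- ref$known_sites
  expect_gt(nrow(ks), 0L)
  expect_true(all(substr(ref$contigs[ks$contig], ks$pos + 1, ks$pos + 1)
                  == "T"))
  # tRNA sense strands end in CCA and carry a U at position 55
  for (i in which(fs$class == "tRNA")) {
    s <- psifinder:::feature_sense_seq(ref, i)
    expect_equal(substr(s, nchar(s) - 2, nchar(s)), "CCA")
    expect_equal(substr(s, 55, 55), "T")
  }
})

test_that("a spec with no TE families yields no TE features", {
  ref <- build_toy_reference(reference_spec(n_mirna = 5, n_te_families = 0,
                                            rrna_len = 0, n_trna = 0),
                             seed = 1)
  expect_false(any(ref$features$class == "TE_copy"))
})

test_that("same spec and seed give byte-identical FASTA/BED output", {
  spec <- reference_spec(n_mirna = 8, n_te_families = 1, rrna_len = 200,
                         n_trna = 1)
  d1 <- withr::local_tempdir()
  r1 <- build_toy_reference(spec, seed = 42)
  r2 <- build_toy_reference(spec, seed = 42)
  write_reference(r1, file.path(d1, "a.fa"), file.path(d1, "a.bed"))
  write_reference(r2, file.path(d1, "b.fa"), file.path(d1, "b.bed"))
  expect_identical(readBin(file.path(d1, "a.fa"), "raw", 1e6),
                   readBin(file.path(d1, "b.fa"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "a.bed"), "raw", 1e6),
                   readBin(file.path(d1, "b.bed"), "raw", 1e6))
})

test_that("site planting respects fraction, uridine placement and 5' bias", {
  ref <- build_toy_reference(reference_spec(n_mirna = 50, n_te_families = 0,
                                            rrna_len = 0, n_trna = 0,
                                            mirna_start_u_frac = 1),
                             seed = 5)
  expect_equal(nrow(assign_psi_sites(ref, frac_modified_features = 0,
                                     seed = 1)), 0L)
  truth <- assign_psi_sites(ref, frac_modified_features = 1,
                            five_prime_bias = 1, seed = 2)
  # every miRNA starts with U and bias is 1, so every site is at offset 0
  expect_true(all(truth$offset == 0L))
  # sites coincide with sense-strand uridines (validated internally too)
  expect_silent(validate_psi_truth(ref, truth))
})

test_that("planted site count follows the binomial law across seeds", {
  ref <- build_toy_reference(reference_spec(n_mirna = 200,
                                            n_te_families = 0,
                                            rrna_len = 0, n_trna = 0),
                             seed = 9)
  band <- qbinom(c(0.005, 0.995), 200, 0.5)
  counts <- vapply(1:400, function(s)
    nrow(assign_psi_sites(ref, frac_modified_features = 0.5, seed = s)),
    numeric(1))
  # ~99% of seeds should fall inside the central 99% binomial band
  expect_gte(mean(counts >= band[1] & counts <= band[2]), 0.95)
  expect_equal(mean(counts), 100, tolerance = 0.02)
})

test_that("IP conserves molecules and splits bound/unbound", {
  ref <- build_toy_reference(reference_spec(n_mirna = 20, n_te_families = 0,
                                            rrna_len = 0, n_trna = 0),
                             seed = 4)
  truth <- assign_psi_sites(ref, n_modified = 5, seed = 4)
  cfg <- sim_config(master_seed = 4, molecules_per_library = 5000,
                    replicates = 2, assays = "ip")
  sim <- simulate_libraries(ref, truth, cfg)
  mc <- sim$truth$molecule_counts
  for (r in 1:2) {
    tot <- sum(mc[[sprintf("ip_bound_rep%d", r)]]) +
      sum(mc[[sprintf("ip_unbound_rep%d", r)]])
    expect_equal(tot, 5000L)
  }
})

test_that("equal capture and background probabilities erase IP composition",
{
  # with ip_capture_eff == ip_background the bound fraction is a uniform
  # subsample: composition should not differ between bound and unbound
  ps <- vapply(1:20, function(s) {
    ref <- build_toy_reference(reference_spec(n_mirna = 15,
                                              n_te_families = 0,
                                              rrna_len = 0, n_trna = 0),
                               seed = 100)
    truth <- assign_psi_sites(ref, n_modified = 5, seed = 100)
    cfg <- sim_config(master_seed = s, molecules_per_library = 4000,
                      replicates = 1, assays = "ip", ip_capture_eff = 0.3,
                      ip_background = 0.3)
    sim <- simulate_libraries(ref, truth, cfg)
    mc <- sim$truth$molecule_counts
    tab <- cbind(mc$ip_bound_rep1, mc$ip_unbound_rep1)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    suppressWarnings(chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gte(min(ps), 0.01 / 20)     # no seed wildly significant
  expect_gte(mean(ps > 0.01), 0.8)   # and non-significant at alpha = 0.01
})

test_that("CMC chemistry off leaves treated and mock counts balanced", {
  ref <- build_toy_reference(reference_spec(n_mirna = 20, n_te_families = 0,
                                            rrna_len = 0, n_trna = 0),
                             seed = 6)
  truth <- assign_psi_sites(ref, n_modified = 10, seed = 6)
  cfg <- sim_config(master_seed = 6, molecules_per_library = 20000,
                    replicates = 3, assays = "cmc", adduct_prob = 0)
  sim <- simulate_libraries(ref, truth, cfg)
  mc <- sim$truth$molecule_counts
  lr <- vapply(1:3, function(r) {
    a <- mc[[sprintf("cmc_plus_rep%d", r)]]
    b <- mc[[sprintf("cmc_mock_rep%d", r)]]
    keep <- a + b > 20
    mean(log2((a[keep] + 0.5) / (b[keep] + 0.5)))
  }, numeric(1))
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("full stoichiometry and certain adduction empty the treated arm", {
  contig <- paste0(strrep("A", 30), "ACGTACTTGCAAGCTTACGGAC",
                   strrep("G", 30))
  ref <- manual_reference(
    c(chrA = contig),
    data.frame(id = "m1", contig = "chrA", start = 30L, end = 52L,
               strand = "+", class = "miRNA", stringsAsFactors = FALSE))
  truth <- manual_truth(ref, "m1", offset = 7L, stoich = 1)
  cfg <- sim_config(master_seed = 2, molecules_per_library = 2000,
                    replicates = 1, assays = "cmc", adduct_prob = 1,
                    jitter_prob = 0)
  sim <- simulate_libraries(ref, truth, cfg)
  expect_equal(nrow(sim$libraries$cmc_plus_rep1$reads), 0L)
  expect_equal(nrow(sim$libraries$cmc_mock_rep1$reads), 2000L)
})

test_that("CMC survival matches the closed form 1 - s*a", {
  contig <- paste0(strrep("A", 30), "ACGTACTTGCAAGCTTACGGAC",
                   strrep("G", 30))
  ref <- manual_reference(
    c(chrA = contig),
    data.frame(id = "m1", contig = "chrA", start = 30L, end = 52L,
               strand = "+", class = "miRNA", stringsAsFactors = FALSE))
  truth <- manual_truth(ref, "m1", offset = 7L, stoich = 0.6)
  n <- 1e5
  cfg <- sim_config(master_seed = 8, molecules_per_library = n,
                    replicates = 1, assays = "cmc", adduct_prob = 0.9,
                    jitter_prob = 0)
  sim <- simulate_libraries(ref, truth, cfg)
  surv <- 1 - 0.6 * 0.9
  ratio <- sum(sim$truth$molecule_counts$cmc_plus_rep1) / n
  se <- sqrt(surv * (1 - surv) / n)
  expect_lt(abs(ratio - surv), 3 * se)
})

test_that("Mn2+ edit frequency converges to s*a*(p_del + p_mis)", {
  contig <- paste0(strrep("A", 30), "ACGTACTTGCAAGCTTACGGAC",
                   strrep("G", 30))
  ref <- manual_reference(
    c(chrA = contig),
    data.frame(id = "m1", contig = "chrA", start = 30L, end = 52L,
               strand = "+", class = "miRNA", stringsAsFactors = FALSE))
  truth <- manual_truth(ref, "m1", offset = 7L, stoich = 0.5)
  n <- 5e4
  cfg <- sim_config(master_seed = 12, molecules_per_library = n,
                    replicates = 1, assays = "mn", adduct_prob = 0.8,
                    p_del = 0.25, p_mis = 0.35, jitter_prob = 0)
  sim <- simulate_libraries(ref, truth, cfg)
  ed <- sim$truth$edits$mn_plus_rep1
  p <- 0.5 * 0.8 * (0.25 + 0.35)
  freq <- (ed$n_del + ed$n_mis) / n
  expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("identical config produces identical FASTQ bytes", {
  ref <- build_toy_reference(reference_spec(n_mirna = 10, n_te_families = 0,
                                            rrna_len = 0, n_trna = 0),
                             seed = 13)
  truth <- assign_psi_sites(ref, n_modified = 3, seed = 13)
  cfg <- sim_config(master_seed = 13, molecules_per_library = 1500,
                    replicates = 1)
  d <- withr::local_tempdir()
  write_libraries(simulate_libraries(ref, truth, cfg), file.path(d, "a"))
  write_libraries(simulate_libraries(ref, truth, cfg), file.path(d, "b"))
  for (f in list.files(file.path(d, "a"), pattern = "fastq$")) {
    expect_identical(readBin(file.path(d, "a", f), "raw", 1e7),
                     readBin(file.path(d, "b", f), "raw", 1e7),
                     label = f)
  }
})

test_that("truth sites off the reference are rejected before simulation", {
  ref <- build_toy_reference(reference_spec(n_mirna = 3, n_te_families = 0,
                                            rrna_len = 0, n_trna = 0),
                             seed = 1)
  bad <- data.frame(site_id = "s1", contig = "chr_mir", pos = 10 ^ 6,
                    feature_id = ref$features$id[1], offset = 0L,
                    stoich = 0.5)
  class(bad) <- c("PsiGroundTruth", "data.frame")
  expect_error(simulate_libraries(ref, bad, sim_config()),
               "off reference")
})
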