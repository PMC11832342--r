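# Count matrix building, normalization, dispersion and the Wald test.

meta2 <- function(libs, conds, pairs = NULL) {
  data.frame(library = libs, assay = "x", condition = conds,
             pair = if (is.null(pairs)) libs else pairs,
             replicate = seq_along(libs), type = "biological",
             stringsAsFactors = FALSE)
}

test_that("the mean-count filter is strict at the boundary", {
  m <- rbind(a = c(11, 11, 11), b = c(10, 10, 10))
  colnames(m) <- paste0("l", 1:3)
  md <- meta2(colnames(m), c("t", "t", "c"))
  cm <- build_count_matrix(m, md, min_mean = 10)
  expect_equal(rownames(cm$counts), "a")
  expect_equal(cm$removed, 1L)
  cm2 <- build_count_matrix(m, md, min_mean = 10, strict = FALSE)
  expect_equal(nrow(cm2$counts), 2L)
  # unknown library is a hard error
  expect_error(build_count_matrix(m, md[1:2, ], min_mean = 0),
               "missing from metadata")
})

test_that("count matrix column sums reconcile with the simulator", {
  ref <- build_toy_reference(reference_spec(n_mirna = 15, n_te_families = 0,
                                            rrna_len = 0, n_trna = 0),
                             seed = 41)
  truth <- assign_psi_sites(ref, n_modified = 3, seed = 41)
  sim <- simulate_libraries(ref, truth, sim_config(
    master_seed = 41, molecules_per_library = 2000, replicates = 2,
    assays = "cmc", seq_error = 0))
  col <- collapse_reads(lapply(sim$libraries, `[[`, "reads"))
  cm <- build_count_matrix(col, sim$metadata, min_mean = 0,
                           strict = FALSE)
  mc <- sim$truth$molecule_counts
  for (lab in colnames(cm$counts)) {
    expect_equal(sum(cm$counts[, lab]), sum(mc[[lab]]), label = lab)
  }
})

test_that("size factors reproduce the hand-computed median-of-ratios", {
  m <- cbind(L1 = c(2, 8), L2 = c(4, 16))
  sf <- compute_size_factors(m)
  expect_equal(as.numeric(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  ident <- cbind(a = c(5, 9, 2), b = c(5, 9, 2))
  expect_equal(as.numeric(compute_size_factors(ident)), c(1, 1))
  # scale equivariance: multiplying one library's counts by c multiplies
  # its factor relative to the others by c (the geometric-mean reference
  # itself absorbs c^(1/n))
  m2 <- m; m2[, 2] <- m2[, 2] * 4
  sf2 <- compute_size_factors(m2)
  expect_equal(sf2[["L2"]] / sf2[["L1"]], 4 * sf[["L2"]] / sf[["L1"]])
  # invariance to feature order and duplication
  withr::local_seed(5)
  big <- matrix(rpois(300, 40) + 1, ncol = 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  sf_a <- compute_size_factors(big)
  sf_b <- compute_size_factors(big[sample(nrow(big)), ])
  sf_c <- compute_size_factors(rbind(big, big))
  expect_equal(sf_a, sf_b)
  expect_equal(sf_a, sf_c)
  # all-zero-somewhere data needs the pseudo-reference fallback
  z <- cbind(a = c(0, 3), b = c(4, 0))
  expect_error(compute_size_factors(z), "pseudo_reference")
  expect_no_error(compute_size_factors(z, pseudo_reference = TRUE))
})

test_that("size factors agree with DESeq2's implementation", {
  skip_if_not_installed("DESeq2")
  withr::local_seed(11)
  # odd number of all-positive features so the arithmetic median of ratios
  # coincides with DESeq2's median taken in log space
  m <- matrix(rnbinom(501 * 6, mu = 60, size = 5) + 1L, ncol = 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  ours <- as.numeric(compute_size_factors(m))
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-10)
})

test_that("dispersion estimates recover known values", {
  withr::local_seed(19)
  libs <- paste0("l", 1:12)
  md <- meta2(libs, rep(c("t", "c"), each = 6))
  pois <- matrix(rpois(500 * 12, 100), ncol = 12,
                 dimnames = list(paste0("f", 1:500), libs))
  cm <- build_count_matrix(pois, md, min_mean = 0, strict = FALSE)
  sf <- compute_size_factors(cm)
  a_pois <- estimate_dispersion(cm, sf)
  expect_lte(median(a_pois), 0.01)
  nb <- matrix(rnbinom(500 * 12, mu = 100, size = 1 / 0.2), ncol = 12,
               dimnames = list(paste0("f", 1:500), libs))
  cmn <- build_count_matrix(nb, md, min_mean = 0, strict = FALSE)
  a_nb <- estimate_dispersion(cmn, compute_size_factors(cmn))
  expect_gte(median(a_nb), 0.1)
  expect_lte(median(a_nb), 0.4)
  # constant counts floor exactly
  const <- matrix(7, nrow = 3, ncol = 12,
                  dimnames = list(paste0("f", 1:3), libs))
  cmc <- build_count_matrix(const, md, min_mean = 0, strict = FALSE)
  expect_equal(unname(estimate_dispersion(cmc, setNames(rep(1, 12), libs))),
               rep(1e-8, 3))
})

test_that("identical condition means give log2FC 0 and p 1", {
  m <- matrix(c(20, 20, 20, 20), nrow = 1,
              dimnames = list("f", paste0("l", 1:4)))
  md <- meta2(colnames(m), c("t", "t", "c", "c"))
  cm <- build_count_matrix(m, md, min_mean = 0, strict = FALSE)
  sf <- setNames(rep(1, 4), colnames(m))
  class(sf) <- "SizeFactors"
  res <- test_enrichment(cm, sf, setNames(0.01, "f"), c("t", "c"))
  expect_equal(res$log2FC, 0)
  expect_equal(res$stat, 0)
  expect_equal(res$pvalue, 1)
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  p <- c(0.005, 0.01, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(oracle_bh(p), c(0.02, 0.02, 0.04, 0.04))
  withr::local_seed(3)
  for (i in 1:20) {
    pv <- runif(sample(5:200, 1))
    expect_equal(p.adjust(pv, "BH"), oracle_bh(pv))
  }
})

test_that("swapping the contrast negates log2FC and preserves p", {
  withr::local_seed(29)
  libs <- paste0("l", 1:6)
  m <- matrix(rnbinom(50 * 6, mu = 80, size = 10), ncol = 6,
              dimnames = list(paste0("f", 1:50), libs))
  md <- meta2(libs, rep(c("t", "c"), each = 3))
  cm <- build_count_matrix(m, md, min_mean = 0, strict = FALSE)
  sf <- compute_size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  a <- test_enrichment(cm, sf, disp, c("t", "c"))
  b <- test_enrichment(cm, sf, disp, c("c", "t"))
  expect_equal(a$log2FC, -b$log2FC)
  expect_equal(a$pvalue, b$pvalue)
  expect_true(all(a$padj >= a$pvalue))
})

test_that("technical replicates are averaged before testing", {
  libs <- paste0("l", 1:6)
  m <- matrix(c(10, 30, 20, 20, 40, 40), nrow = 1,
              dimnames = list("f", libs))
  md <- data.frame(library = libs,
                   assay = "x",
                   condition = rep(c("t", "c"), each = 3),
                   pair = c("p1", "p1", "p2", "q1", "q2", "q2"),
                   replicate = 1:6,
                   type = c("technical", "technical", "biological",
                            "biological", "technical", "technical"),
                   stringsAsFactors = FALSE)
  cm <- build_count_matrix(m, md, min_mean = 0, strict = FALSE)
  sf <- setNames(rep(1, 6), libs); class(sf) <- "SizeFactors"
  res <- test_enrichment(cm, sf, setNames(1e-8, "f"), c("t", "c"))
  # technical averaging collapses t to (mean(10,30), 20) = (20, 20) and c
  # to (20, mean(40,40)) = (20, 40); condition means 20 vs 30
  expect_equal(res$log2FC, log2(20.5 / 30.5))
})

test_that("the paired design tests per-pair ratios", {
  libs <- paste0("l", 1:6)
  m <- matrix(c(40, 20, 80, 40, 20, 10), nrow = 1,
              dimnames = list("f", libs))
  md <- data.frame(library = libs, assay = "x",
                   condition = rep(c("t", "c"), 3),
                   pair = rep(c("p1", "p2", "p3"), each = 2),
                   replicate = 1:6, type = "biological",
                   stringsAsFactors = FALSE)
  cm <- build_count_matrix(m, md, min_mean = 0, strict = FALSE)
  sf <- setNames(rep(1, 6), libs); class(sf) <- "SizeFactors"
  res <- test_enrichment(cm, sf, setNames(1e-8, "f"), c("t", "c"),
                         paired = TRUE)
  d <- log2(c(40.5 / 20.5, 80.5 / 40.5, 20.5 / 10.5))
  expect_equal(res$log2FC, mean(d))
  expect_equal(res$lfcSE, sd(d) / sqrt(3))
  md_bad <- md; md_bad$pair[2] <- "zz"
  cmb <- build_count_matrix(m, md_bad, min_mean = 0, strict = FALSE)
  expect_error(test_enrichment(cmb, sf, setNames(1e-8, "f"), c("t", "c"),
                               paired = TRUE), "pair")
})

test_that("the null keeps BH false discoveries controlled across seeds", {
  # the simulation null: equal conditions, counts Poisson around log-normal
  # per-feature means (the count law the molecule sampler induces)
  fdrs <- vapply(1:20, function(s) {
    withr::local_seed(1000 + s)
    libs <- paste0("l", 1:6)
    mu <- rlnorm(500, meanlog = 4.5, sdlog = 1)
    m <- matrix(rpois(500 * 6, rep(mu, 6)), ncol = 6,
                dimnames = list(paste0("f", 1:500), libs))
    md <- meta2(libs, rep(c("t", "c"), each = 3))
    cm <- build_count_matrix(m, md, min_mean = 10)
    sf <- compute_size_factors(cm)
    disp <- estimate_dispersion(cm, sf)
    res <- test_enrichment(cm, sf, disp, c("t", "c"))
    r <- sum(res$padj < 0.05, na.rm = TRUE)
    if (r == 0) 0 else 1   # every rejection is a false discovery here
  }, numeric(1))
  expect_lte(mean(fdrs), 0.08)
})
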