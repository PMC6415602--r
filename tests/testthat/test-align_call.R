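test_that("map_read places exact, reverse-complement and ambiguous reads", {
  set.seed(1)
  contigs <- c(c1 = random_dna_test(600), c2 = random_dna_test(400))
  p <- caller_params()

  r <- substr(contigs[["c1"]], 101, 200)
  a <- map_read(r, contigs, p)
  expect_identical(a$contig, "c1")
  expect_identical(a$start, 100L)
  expect_identical(a$strand, "+")
  expect_identical(a$n_mismatch, 0L)

  rc <- revcomp(substr(contigs[["c1"]], 1, 100))
  a <- map_read(rc, contigs, p)
  expect_identical(a$start, 0L)
  expect_identical(a$strand, "-")

  ## duplicated placement -> unmapped-ambiguous
  dup <- c(c1 = paste0(contigs[["c1"]], substr(contigs[["c1"]], 101, 200)))
  aln <- map_reads(r, dup, p)
  expect_identical(nrow(aln), 0L)
  expect_identical(attr(aln, "n_ambiguous"), 1L)

  ## read shorter than the seed
  aln <- map_reads("ACGT", contigs, p)
  expect_identical(nrow(aln), 0L)
  expect_identical(attr(aln, "n_short"), 1L)
})

test_that("mapper agrees with the brute-force best-Hamming oracle", {
  set.seed(99)
  contigs <- c(cA = random_dna_test(1500), cB = random_dna_test(500))
  p <- caller_params()
  ## reads with an escalating number of planted errors (0..7)
  reads <- character(0)
  for (i in 1:60) {
    cn <- sample(names(contigs), 1)
    L <- nchar(contigs[[cn]])
    st <- sample(L - 99, 1)
    r <- substr(contigs[[cn]], st, st + 99)
    n_err <- sample(0:7, 1)
    if (n_err > 0) {
      at <- sample(100, n_err)
      for (j in at) {
        substr(r, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(r, j, j)), 1)
      }
    }
    if (runif(1) < 0.5) r <- revcomp(r)
    reads <- c(reads, r)
  }
  aln <- map_reads(reads, contigs, p)
  for (i in seq_along(reads)) {
    oracle <- bf_map(reads[i], contigs, p$max_mismatch)
    got <- aln[aln$read == i, ]
    if (is.null(oracle)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(nrow(got), 1L)
      expect_identical(got$contig, oracle$contig)
      expect_identical(got$start, oracle$start)
      expect_identical(got$strand, oracle$strand)
      expect_identical(got$n_mismatch, oracle$nm)
    }
  }
})

test_that("pileup counts every aligned base exactly once", {
  set.seed(12)
  contigs <- c(c1 = random_dna_test(36))
  p <- caller_params(k_seed = 8L, min_depth = 1L)
  reads <- c(substr(contigs[[1]], 1, 12), revcomp(substr(contigs[[1]], 5, 20)))
  aln <- map_reads(reads, contigs, p)
  pi <- pileup(aln, reads, contigs)[["c1"]]
  expect_identical(sum(pi), sum(nchar(reads)))      # conservation
  ref <- strsplit(contigs[[1]], "")[[1]]
  covered <- which(colSums(pi) > 0)
  for (j in covered) {
    expect_identical(sum(pi[, j]), unname(pi[ref[j], j]))  # all match ref
  }

  ## two overlapping disagreeing reads
  m <- pileup_disagreement_fixture()
  expect_identical(sum(m$pile[, m$pos]), 2L)
  expect_identical(sum(m$pile[, m$pos] > 0), 2L)
})

test_that("call_genotype implements the threshold rules", {
  p <- caller_params()
  g <- call_genotype(list(ref_base = "A", base_counts = c(A = 4, T = 4)), p)
  expect_identical(g$type, "het")
  expect_identical(g$alleles, c("A", "T"))

  g <- call_genotype(list(ref_base = "A", base_counts = c(A = 4, T = 3)), p)
  expect_identical(g$type, "missing")   # depth 7 < min_depth 8

  g <- call_genotype(list(ref_base = "G", base_counts = c(G = 18, A = 2)), p)
  expect_identical(g$type, "hom_ref")   # 0.9 >= 0.85; A fails count/frac

  g <- call_genotype(list(ref_base = "G", base_counts = c(T = 18, A = 2)), p)
  expect_identical(g$type, "hom_alt")

  g <- call_genotype(list(ref_base = "A",
                          base_counts = c(A = 3, C = 3, G = 3, T = 3)), p)
  expect_identical(g$type, "missing")   # > 2 qualifying alleles
})

test_that("call_all matches truth on error-free data and flags bad input", {
  cfg <- small_cfg(seed = 21, seq_error = 0, coverage = 30)
  ref <- simulate_reference(cfg)
  truth <- simulate_samples(cfg, ref)
  rs <- list(reference = simulate_reads(cfg, truth, "reference"),
             hybrid = simulate_reads(cfg, truth, "hybrid"),
             nonparent = simulate_reads(cfg, truth, "nonparent"))
  vcf <- call_all(rs, ref$contigs)
  ## every called genotype equals the truth genotype; asserted at depth
  ## >= 25, where the binomial het-as-hom miscall probability per site is
  ## < 1e-4 even with error-free reads (at marginal depth, 0.5-allele
  ## sampling can legitimately cross hom_frac)
  key_v <- paste(vcf$sites$contig, vcf$sites$pos)
  key_t <- paste(truth$variants$contig, truth$variants$pos)
  gb <- genotype_bases_test(vcf)
  both <- intersect(key_v, key_t)
  expect_gt(length(both), 100)
  mismatches <- 0
  for (s in c("reference", "hybrid", "nonparent")) {
    iv <- match(both, key_v); it <- match(both, key_t)
    called <- !is.na(gb$b1[iv, s]) & vcf$dp[iv, s] >= 25
    pair <- paste(pmin(gb$b1[iv, s], gb$b2[iv, s]),
                  pmax(gb$b1[iv, s], gb$b2[iv, s]), sep = "/")
    mismatches <- mismatches +
      sum(pair[called] != truth$variants[[s]][it][called])
  }
  expect_identical(mismatches, 0)

  ## two identical samples never disagree
  rs2 <- list(a = rs$reference, b = rs$reference, h = rs$hybrid)
  v2 <- call_all(rs2, ref$contigs)
  gb2 <- genotype_bases_test(v2)
  same <- is.na(gb2$b1[, "a"]) == is.na(gb2$b1[, "b"])
  called <- !is.na(gb2$b1[, "a"]) & !is.na(gb2$b1[, "b"])
  expect_true(all(same))
  expect_identical(gb2$b1[called, "a"], gb2$b1[called, "b"])
  expect_identical(gb2$b2[called, "a"], gb2$b2[called, "b"])

  ## a sample whose reads cannot be mapped is reported by name
  rs_bad <- list(good = rs$reference,
                 bad = data.frame(id = "x", seq = strrep("N", 100),
                                  qual = strrep("?", 100)))
  expect_error(call_all(rs_bad, ref$contigs), "sample 'bad'")
})
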