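test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$reads, b$reads)
  expect_identical(a$cp$alignment, b$cp$alignment)
  expect_identical(a$its$reads, b$its$reads)
  expect_identical(a$truth$variants, b$truth$variants)
})

test_that("simulate_reference: contig geometry and heterozygosity", {
  cfg <- sim_config(seed = 7, n_contigs = 6L, contig_length = 50000L)
  ref <- simulate_reference(cfg)
  expect_length(ref$contigs, 6L)
  expect_true(all(nchar(ref$contigs) == 50000L))

  ## defaults, 300 kb total: expected het sites = 2e-4 * 3e5 = 60,
  ## observed within 3 sigma of the Poisson mean
  n_het <- sum(vapply(ref$ref_haps, function(h) length(h$pos), integer(1)))
  expect_gt(n_het, 60 - 3 * sqrt(60))
  expect_lt(n_het, 60 + 3 * sqrt(60))

  ## degenerate rate: homozygous everywhere
  cfg0 <- small_cfg(seed = 7, het_rate_ref = 0)
  ref0 <- simulate_reference(cfg0)
  expect_true(all(vapply(ref0$ref_haps, function(h)
    identical(h$h1, h$h2), logical(1))))
})

test_that("simulate_samples: F1 construction and truth consistency", {
  cfg <- small_cfg(seed = 11)
  ref <- simulate_reference(cfg)
  truth <- simulate_samples(cfg, ref)

  ## hybrid het density within 3 sigma of the analytic Poisson mean
  L <- sum(nchar(ref$contigs))
  lambda <- (cfg$divergence_hidden_parent + cfg$het_rate_ref) * L
  gt <- truth$variants$hybrid
  n_het <- sum(substr(gt, 1, 1) != substr(gt, 3, 3))
  expect_gt(n_het, lambda - 3 * sqrt(lambda))
  expect_lt(n_het, lambda + 3 * sqrt(lambda))

  ## at hidden-parent-driven het sites (reference homozygous there),
  ## exactly one hybrid allele equals the reference-haplotype base
  rg <- truth$variants$reference
  hyb_het <- substr(gt, 1, 1) != substr(gt, 3, 3)
  ref_hom <- substr(rg, 1, 1) == substr(rg, 3, 3)
  sel <- hyb_het & ref_hom
  one_match <- (substr(gt[sel], 1, 1) == substr(rg[sel], 1, 1)) !=
    (substr(gt[sel], 3, 3) == substr(rg[sel], 1, 1))
  expect_true(all(one_match))

  ## zero hidden divergence degenerates to the reference individual
  cfg0 <- small_cfg(seed = 11, divergence_hidden_parent = 0)
  t0 <- simulate_samples(cfg0, simulate_reference(cfg0))
  expect_identical(t0$variants$hybrid, t0$variants$reference)

  ## truth consistency: every haplotype/contig mismatch is a recorded
  ## variant position with the matching genotype
  for (contig in names(ref$contigs)) {
    cs <- utf8ToInt(ref$contigs[[contig]])
    v <- truth$variants[truth$variants$contig == contig, ]
    for (s in c("reference", "hybrid", "nonparent")) {
      h <- truth$haplotypes[[contig]][[s]]
      mis <- which(utf8ToInt(h[1]) != cs | utf8ToInt(h[2]) != cs)
      expect_true(all(mis %in% (v$pos + 1L)))
      pair <- paste(pmin(substring(h[1], v$pos + 1, v$pos + 1),
                         substring(h[2], v$pos + 1, v$pos + 1)),
                    pmax(substring(h[1], v$pos + 1, v$pos + 1),
                         substring(h[2], v$pos + 1, v$pos + 1)),
                    sep = "/")
      expect_identical(pair, v[[s]])
    }
  }
})

test_that("simulate_reads: placement truth, counts, error rate", {
  cfg <- small_cfg(seed = 5, seq_error = 0, coverage = 10)
  truth <- simulate_samples(cfg, simulate_reference(cfg))
  reads <- simulate_reads(cfg, truth, "hybrid")
  ## coverage * L / read_length reads per contig
  expect_identical(nrow(reads), 2L * as.integer(10 * 8000 / 100))

  ## with zero error every read equals its source haplotype substring
  meta <- strsplit(reads$id, "|", fixed = TRUE)
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    m <- meta[[i]]
    h <- truth$haplotypes[[m[2]]][["hybrid"]][as.integer(substr(m[5], 2, 2))]
    frag <- substr(h, as.integer(m[3]) + 1, as.integer(m[3]) + 100)
    if (m[4] == "-") frag <- revcomp(frag)
    frag == reads$seq[i]
  }, logical(1))
  expect_true(all(ok))

  ## error rate within 3 sigma of binomial(seq_error) over >= 1e5 bases
  cfg_e <- small_cfg(seed = 6, seq_error = 1e-3, coverage = 10,
                     het_rate_ref = 0, divergence_hidden_parent = 0,
                     het_rate_nonparent = 0, divergence_nonparent = 0)
  t_e <- simulate_samples(cfg_e, simulate_reference(cfg_e))
  rd <- simulate_reads(cfg_e, t_e, "reference")
  meta <- strsplit(rd$id, "|", fixed = TRUE)
  n_mis <- vapply(seq_len(nrow(rd)), function(i) {
    m <- meta[[i]]
    h <- t_e$haplotypes[[m[2]]][["reference"]][1]
    frag <- substr(h, as.integer(m[3]) + 1, as.integer(m[3]) + 100)
    if (m[4] == "-") frag <- revcomp(frag)
    sum(utf8ToInt(frag) != utf8ToInt(rd$seq[i]))
  }, numeric(1))
  n_bases <- 100 * nrow(rd)
  expect_gt(n_bases, 1e5)
  lam <- n_bases * 1e-3
  expect_gt(sum(n_mis), lam - 3 * sqrt(lam))
  expect_lt(sum(n_mis), lam + 3 * sqrt(lam))
})

test_that("simulate_organelles: maternal signal and Poisson distances", {
  cfg <- small_cfg(seed = 9)
  cp <- simulate_organelles(cfg)
  d <- cp_pairwise(cp$alignment)
  hd <- d$counts["hybrid", ]
  expect_lt(hd[["reference"]], hd[["nonparent"]])
  expect_lt(hd[["reference"]], hd[["outgroup"]])
  lam <- cfg$cp_divergence[["hybrid_private"]] * cfg$cp_length
  expect_gt(hd[["reference"]], lam - 3 * sqrt(lam))
  expect_lt(hd[["reference"]], lam + 3 * sqrt(lam))

  cfg0 <- small_cfg(seed = 9, cp_divergence = c(hybrid_private = 0,
                                                nonparent = 0,
                                                outgroup = 0))
  cp0 <- simulate_organelles(cfg0)
  expect_length(unique(cp0$alignment), 1L)
})

test_that("simulate_its_reads: Fig-4-style allele pattern and supports", {
  cfg <- small_cfg(seed = 13)
  its <- simulate_its_reads(cfg)
  for (rg in names(its$truth)) {
    sa <- its$truth[[rg]]$sample_alleles
    expect_gt(length(intersect(sa$hybrid, sa$reference)), 0)
    expect_length(intersect(sa$hybrid, sa$nonparent), 0)
  }
  ## allele read support proportional to copy number (equal here) within
  ## 3 sigma of the multinomial count; read ids carry the true allele
  ids <- strsplit(its$reads$nonparent$id, "|", fixed = TRUE)
  counts <- table(vapply(ids[vapply(ids, `[`, "", 2) == "ITS1"],
                         `[`, "", 3))
  n <- sum(counts)
  p <- 1 / length(counts)
  for (k in counts) {
    expect_gt(k, n * p - 3 * sqrt(n * p * (1 - p)))
    expect_lt(k, n * p + 3 * sqrt(n * p * (1 - p)))
  }

  ## zero error + single allele per sample -> identical reads within
  ## region once strand-normalized (ids encode allele and region)
  spec1 <- list(R1 = list(name = "R1", start = 60L, length = 80L,
                          alleles = list(list(id = "a",
                                              samples = "reference",
                                              variants = data.frame(
                                                offset = integer(0),
                                                shift = integer(0))))))
  cfg0 <- small_cfg(seed = 13, seq_error = 0, its_allele_specs = spec1,
                    its_read_length = 80L)
  its0 <- simulate_its_reads(cfg0)
  r <- its0$reads$reference
  expect_gt(nrow(r), 0)
  norm <- r$seq
  truth_allele <- its0$truth$R1$alleles[["a"]]
  norm[norm != truth_allele] <- revcomp(norm[norm != truth_allele])
  expect_identical(unique(norm), truth_allele)

  ## config error: variant outside the region
  bad <- default_its_alleles(80L)
  bad$ITS1$alleles[[2]]$variants$offset[1] <- 80L
  expect_error(small_cfg(its_allele_specs = bad), "outside the region")
})
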