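ss <- c("hyb", "candA", "candB")

test_that("partition assigns alleles to candidate subsets by value", {
  ## hybrid A/T, candA A/A, candB A/A -> A in {A,B}, T private
  v <- make_vcf(ss, list(
    list(contig = "c1", pos = 10, ref = "A", alts = "T",
         gt = list(c(0, 1), c(0, 0), c(0, 0)))
  ))
  p <- partition_alleles(v, "hyb", c("candA", "candB"))
  expect_identical(p$informative_sites, 1L)
  expect_identical(unname(p$region_counts["candA,candB"]), 1L)
  expect_identical(unname(p$region_counts["private"]), 1L)

  ## hybrid A/T, candA A/A, candB T/T -> A in {A}, T in {B}
  v2 <- make_vcf(ss, list(
    list(contig = "c1", pos = 11, ref = "A", alts = "T",
         gt = list(c(0, 1), c(0, 0), c(1, 1)))
  ))
  p2 <- partition_alleles(v2, "hyb", c("candA", "candB"))
  expect_identical(unname(p2$region_counts["candA"]), 1L)
  expect_identical(unname(p2$region_counts["candB"]), 1L)

  ## sharing is by base value even across different allele indices
  v3 <- make_vcf(ss, list(
    list(contig = "c1", pos = 12, ref = "G", alts = "T,A",
         gt = list(c(1, 2), c(2, 2), c(1, 2)))
  ))
  p3 <- partition_alleles(v3, "hyb", c("candA", "candB"))
  ## T (index 1) in candB only; A (index 2) in candA and candB
  expect_identical(unname(p3$region_counts["candB"]), 1L)
  expect_identical(unname(p3$region_counts["candA,candB"]), 1L)

  expect_error(partition_alleles(v3, "nope", "candA"), "not in VCF")
})

test_that("partition matches brute force and conserves observations", {
  for (seed in 1:5) {
    v <- random_vcf(20, ss, seed = seed)
    p <- partition_alleles(v, "hyb", c("candA", "candB"))
    o <- bf_partition(v, "hyb", c("candA", "candB"))
    expect_identical(p$informative_sites, o$informative)
    expect_identical(p$region_counts[names(o$region_counts)],
                     o$region_counts)
    expect_identical(unname(sum(p$region_counts)),
                     2L * p$informative_sites)
    expect_equal(unname(p$n_shared_obs), unname(o$shared_obs))
  }

  ## candidate order never matters
  v <- random_vcf(20, ss, seed = 6)
  pa <- partition_alleles(v, "hyb", c("candA", "candB"))
  pb <- partition_alleles(v, "hyb", c("candB", "candA"))
  expect_identical(pa$region_counts[sort(names(pa$region_counts))],
                   pb$region_counts[sort(names(pb$region_counts))])
  expect_identical(pa$shared_fraction[c("candA", "candB")],
                   pb$shared_fraction[c("candA", "candB")])
})

test_that("sharing fractions: identity, forced halves, empty input", {
  ## candidate identical to the hybrid -> f = 1
  rows <- lapply(1:6, function(i) list(
    contig = "c1", pos = i, ref = "A", alts = "T",
    gt = list(c(0, 1), c(0, 1), c(0, 0))))
  v <- make_vcf(ss, rows)
  p <- partition_alleles(v, "hyb", c("candA", "candB"))
  expect_identical(unname(p$shared_fraction["candA"]), 1)
  ## candB carries only the reference allele: f = 0.5, g = 0
  expect_identical(unname(p$shared_fraction["candB"]), 0.5)
  expect_identical(unname(p$alt_shared_fraction["candB"]), 0)

  ## no informative sites
  v0 <- make_vcf(ss, list(list(contig = "c1", pos = 1, ref = "A",
                               alts = "T",
                               gt = list(c(1, 1), c(0, 0), c(0, 0)))))
  p0 <- partition_alleles(v0, "hyb", c("candA", "candB"))
  expect_error(sharing_fractions(p0), "informative")
})

test_that("exact binomial test matches the spec's frozen examples", {
  expect_identical(binom_exact_test(10, 20)$p_value, 1)
  expect_equal(binom_exact_test(0, 20)$p_value, 2 * 0.5^20,
               tolerance = 1e-12)
  expect_equal(binom_exact_test(20, 20)$p_value,
               binom_exact_test(0, 20)$p_value)
})

test_that("exact binomial test equals exhaustive enumeration (n <= 25)", {
  for (n in c(1L, 3L, 10L, 17L, 25L)) {
    for (k in unique(c(0L, 1L, n %/% 3L, n %/% 2L, n))) {
      expect_equal(binom_exact_test(k, n)$p_value, bf_binom_p(k, n),
                   tolerance = 1e-12,
                   label = sprintf("p(k=%d, n=%d)", k, n))
    }
  }
  ## Clopper-Pearson bounds against the closed beta-quantile form
  for (k in c(0L, 4L, 12L)) {
    ci <- binom_exact_test(k, 12L)$conf_int
    lo <- if (k == 0) 0 else qbeta(0.025, k, 12 - k + 1)
    hi <- if (k == 12) 1 else qbeta(0.975, k + 1, 12 - k)
    expect_equal(ci, c(lo, hi), tolerance = 1e-10)
  }
})

test_that("half_sharing_test wires the partition into the binomial test", {
  rows <- lapply(1:10, function(i) list(
    contig = "c1", pos = i, ref = "A", alts = "T",
    gt = list(c(0, 1), c(0, 0), c(0, 0))))
  v <- make_vcf(ss, rows)
  p <- partition_alleles(v, "hyb", c("candA", "candB"))
  t <- half_sharing_test(p, "candA")
  expect_identical(t$n_informative, 10L)
  expect_identical(t$n_trials, 20L)
  expect_identical(t$n_shared_obs, 10)   # one of two obs per site
  expect_identical(t$n_one_allele_shared, 10)
  expect_identical(t$point_estimate, 0.5)
  expect_identical(t$p_value, 1)
  expect_true(t$conf_int[1] <= 0.5 && 0.5 <= t$conf_int[2])
})
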