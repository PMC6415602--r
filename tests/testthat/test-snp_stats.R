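samples3 <- c("ref_sp", "hyb", "other")

test_that("summarize_contigs counts heterozygous and fixed-difference sites", {
  lens <- c(c1 = 1000L, c2 = 500L)
  ## single row: hybrid het, others hom_ref
  v <- make_vcf(samples3, list(
    list(contig = "c1", pos = 10, ref = "A", alts = "T",
         gt = list(c(0, 0), c(0, 1), c(0, 0)))
  ))
  s <- summarize_contigs(v, lens, c("ref_sp", "other"))
  expect_identical(s$hyb, c(1L, 0L))
  expect_identical(s$ref_sp, c(0L, 0L))
  expect_identical(s$other, c(0L, 0L))
  expect_identical(s$inter, c(0L, 0L))

  ## empty set
  v0 <- make_vcf(samples3, list())
  s0 <- summarize_contigs(v0, lens, c("ref_sp", "other"))
  expect_true(all(s0$hyb == 0L & s0$inter == 0L))

  ## fixed difference between the candidates; missing sites excluded
  v2 <- make_vcf(samples3, list(
    list(contig = "c1", pos = 1, ref = "A", alts = "T",
         gt = list(c(0, 0), c(0, 0), c(1, 1))),
    list(contig = "c1", pos = 2, ref = "A", alts = "T",
         gt = list(NULL, c(0, 1), c(1, 1)))
  ))
  s2 <- summarize_contigs(v2, lens, c("ref_sp", "other"))
  expect_identical(s2$inter, c(1L, 0L))      # second site: ref_sp missing
  expect_identical(s2$other, c(0L, 0L))      # hom-alt is not heterozygous
  expect_identical(attr(s2, "nonref_counts")["c1", "other"], 2L)
  expect_error(summarize_contigs(v2, lens, c("ref_sp", "nope")),
               "unknown sample")
})

test_that("summary equals a brute-force per-site tally on a random set", {
  v <- random_vcf(30, samples3, seed = 8)
  lens <- c(c1 = 400L, c2 = 400L)
  s <- summarize_contigs(v, lens, c("ref_sp", "other"))
  gb <- genotype_bases_test(v)
  for (cn in names(lens)) {
    sel <- which(v$sites$contig == cn)
    for (sm in samples3) {
      manual <- 0L
      for (i in sel) {
        if (!is.na(gb$b1[i, sm]) && gb$b1[i, sm] != gb$b2[i, sm]) {
          manual <- manual + 1L
        }
      }
      expect_identical(s[[sm]][s$contig == cn], manual)
    }
    manual_inter <- 0L
    for (i in sel) {
      a <- c(gb$b1[i, "ref_sp"], gb$b2[i, "ref_sp"])
      b <- c(gb$b1[i, "other"], gb$b2[i, "other"])
      if (!anyNA(a) && !anyNA(b) && length(intersect(a, b)) == 0) {
        manual_inter <- manual_inter + 1L
      }
    }
    expect_identical(s$inter[s$contig == cn], manual_inter)
  }
})

test_that("density_report arithmetic, degeneracies and scale invariance", {
  v <- random_vcf(40, samples3, seed = 9)
  lens <- c(c1 = 2000L, c2 = 2000L)
  s <- summarize_contigs(v, lens, c("ref_sp", "other"))
  r <- density_report(s, "hyb")
  expect_equal(unname(r$density_per_10kb["hyb"]),
               1e4 * sum(s$hyb) / 4000)
  ## equal counts across samples -> folds 1
  veq <- make_vcf(samples3, list(
    list(contig = "c1", pos = 5, ref = "A", alts = "T",
         gt = list(c(0, 1), c(0, 1), c(0, 1)))
  ))
  seq_ <- summarize_contigs(veq, lens["c1"], c("ref_sp", "other"))
  req <- density_report(seq_, "hyb")
  expect_true(all(req$fold_vs == 1))

  expect_error(density_from_totals(c(a = 1, hyb = 2), 0, "hyb"),
               "total_length")

  ## duplicating every contig doubles totals, densities unchanged
  s2 <- s
  s2 <- rbind(s, transform(s, contig = paste0(contig, "_dup")))
  attr(s2, "nonref_counts") <- rbind(attr(s, "nonref_counts"),
                                     attr(s, "nonref_counts"))
  attr(s2, "samples") <- attr(s, "samples")
  class(s2) <- class(s)
  r2 <- density_report(s2, "hyb")
  expect_identical(unname(r2$totals), unname(2 * r$totals))
  expect_equal(r2$density_per_10kb, r$density_per_10kb)
})

test_that("density_track bins match brute force and conserve totals", {
  set.seed(10)
  pos <- sort(sample(0:3999, 25))
  rows <- lapply(pos, function(p) list(
    contig = "c1", pos = p, ref = "A", alts = "T",
    gt = list(c(0, 1), if (runif(1) < 0.5) c(0, 1) else c(0, 0), c(0, 0))))
  v <- make_vcf(samples3, rows)
  tr <- density_track(v, "c1", 4000L, window_bp = 1000L)
  expect_identical(nrow(tr), 4L)
  gb <- genotype_bases_test(v)
  for (w in seq_len(nrow(tr))) {
    for (sm in samples3) {
      het <- !is.na(gb$b1[, sm]) & gb$b1[, sm] != gb$b2[, sm]
      manual <- sum(het & v$sites$pos >= tr$start[w] &
                      v$sites$pos < tr$end[w])
      expect_identical(tr[[sm]][w], manual)
    }
  }
  s <- summarize_contigs(v, c(c1 = 4000L), c("ref_sp", "other"))
  expect_identical(colSums(tr[samples3]), setNames(
    as.numeric(c(s$ref_sp, s$hyb, s$other)), samples3))

  ## single full-width window equals the per-contig count
  tr1 <- density_track(v, "c1", 4000L, window_bp = 4000L)
  expect_identical(nrow(tr1), 1L)
  expect_identical(tr1$hyb, s$hyb)
})
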