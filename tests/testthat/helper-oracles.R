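## Independent oracles and small fixture builders shared by the tests.
## Oracles are deliberately naive (brute force / exhaustive enumeration)
## and never call the code paths they check.

## brute-force best-Hamming placement over every offset and strand;
## NULL when no placement within max_mismatch or the best is tied
bf_map <- function(read, contigs, max_mismatch) {
  best <- Inf; n_best <- 0L; rec <- NULL
  rl <- nchar(read)
  for (orient in c("+", "-")) {
    s <- if (orient == "-") hybridly::revcomp(read) else read
    si <- utf8ToInt(s)
    for (cn in names(contigs)) {
      ci <- utf8ToInt(contigs[[cn]])
      L <- length(ci)
      if (rl > L) next
      for (st in 0:(L - rl)) {
        mm <- sum(si != ci[(st + 1):(st + rl)])
        if (mm < best) {
          best <- mm; n_best <- 1L
          rec <- list(contig = cn, start = st, strand = orient, nm = mm)
        } else if (mm == best) {
          n_best <- n_best + 1L
        }
      }
    }
  }
  if (best > max_mismatch || n_best > 1L) NULL else rec
}

## exhaustive minimum-likelihood two-sided binomial p-value
bf_binom_p <- function(k, n, p = 0.5) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= dbinom(k, n, p) * (1 + 1e-07)])
}

## least-squares branch-length fit of a 4-taxon distance matrix to each of
## the three unrooted topologies; returns the winning topology's newick
bf_best_topology <- function(d) {
  taxa <- rownames(d)
  stopifnot(length(taxa) == 4L)
  y <- c(d[1, 2], d[1, 3], d[1, 4], d[2, 3], d[2, 4], d[3, 4])
  ## columns: pendant e1..e4, internal e5; rows: pairs 12,13,14,23,24,34
  designs <- list(
    "12|34" = rbind(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 1),
                    c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 1), c(0, 0, 1, 1, 0)),
    "13|24" = rbind(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 0), c(1, 0, 0, 1, 1),
                    c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 0), c(0, 0, 1, 1, 1)),
    "14|23" = rbind(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 0),
                    c(0, 1, 1, 0, 0), c(0, 1, 0, 1, 1), c(0, 0, 1, 1, 1))
  )
  rss <- vapply(designs, function(X) {
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  key <- names(which.min(rss))
  pair <- as.integer(strsplit(strsplit(key, "|", fixed = TRUE)[[1]][1],
                              "")[[1]])
  other <- setdiff(1:4, pair)
  sprintf("((%s,%s),(%s,%s));", taxa[pair[1]], taxa[pair[2]],
          taxa[other[1]], taxa[other[2]])
}

## additive distances from a random 4-taxon tree; returns matrix + newick
random_additive_4taxa <- function(taxa = c("A", "B", "C", "D")) {
  e <- runif(5, 0.1, 2)  # e1..e4 pendant, e5 internal
  pair <- sort(sample(1:4, 2))
  other <- setdiff(1:4, pair)
  d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  path <- function(i, j) {
    same_i <- i %in% pair
    same_j <- j %in% pair
    if (same_i == same_j) e[i] + e[j] else e[i] + e[j] + e[5]
  }
  for (i in 1:3) for (j in (i + 1):4) d[i, j] <- d[j, i] <- path(i, j)
  list(d = d,
       newick = sprintf("((%s,%s),(%s,%s));", taxa[pair[1]], taxa[pair[2]],
                        taxa[other[1]], taxa[other[2]]))
}

same_topology <- function(tree, newick) {
  ref <- ape::read.tree(text = newick)
  ape::dist.topo(ape::unroot(tree), ape::unroot(ref)) == 0
}

## hand-built hy_vcf from a compact row spec:
## rows: list of list(contig, pos, ref, alts, gt = list per sample of
## c(i, j) or NULL, dp = int vector)
make_vcf <- function(samples, rows) {
  n <- length(rows)
  sites <- data.frame(
    contig = vapply(rows, `[[`, "", "contig"),
    pos = vapply(rows, function(r) as.integer(r$pos), integer(1)),
    ref = vapply(rows, `[[`, "", "ref"),
    alts = vapply(rows, `[[`, "", "alts"),
    stringsAsFactors = FALSE
  )
  gt1 <- gt2 <- dp <- matrix(NA_integer_, n, length(samples),
                             dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    for (j in seq_along(samples)) {
      g <- rows[[i]]$gt[[j]]
      if (!is.null(g)) { gt1[i, j] <- g[1]; gt2[i, j] <- g[2] }
    }
    dp[i, ] <- if (is.null(rows[[i]]$dp)) 20L else as.integer(rows[[i]]$dp)
  }
  hybridly::hy_vcf(samples, sites, gt1, gt2, dp)
}

## random multi-sample SNV set for property tests
random_vcf <- function(n_sites, samples, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(n_sites), function(i) {
    ref <- sample(bases, 1)
    alts <- sample(setdiff(bases, ref), sample(1:2, 1))
    n_all <- 1 + length(alts)
    gt <- lapply(samples, function(s) {
      if (runif(1) < 0.1) NULL else
        sort(sample(0:(n_all - 1), 2, replace = TRUE))
    })
    list(contig = sample(c("c1", "c2"), 1), pos = 10 * i, ref = ref,
         alts = paste(alts, collapse = ","), gt = gt,
         dp = sample(5:30, length(samples), replace = TRUE))
  })
  make_vcf(samples, rows)
}

## per-site brute-force allele partition tally
bf_partition <- function(vcf, hybrid, candidates, min_depth = 0) {
  al <- mapply(function(r, a) c(r, strsplit(a, ",")[[1]]),
               vcf$sites$ref, vcf$sites$alts, SIMPLIFY = FALSE)
  keys <- c("private", unlist(lapply(seq_along(candidates), function(k)
    vapply(utils::combn(sort(candidates), k, simplify = FALSE),
           paste, "", collapse = ","))))
  counts <- setNames(rep(0L, length(keys)), keys)
  informative <- 0L
  shared <- setNames(rep(0L, length(candidates)), candidates)
  for (i in seq_len(nrow(vcf$sites))) {
    gt_of <- function(s) {
      j <- match(s, vcf$samples)
      if (is.na(vcf$gt1[i, j])) return(NULL)
      c(al[[i]][vcf$gt1[i, j] + 1], al[[i]][vcf$gt2[i, j] + 1])
    }
    h <- gt_of(hybrid)
    if (is.null(h) || h[1] == h[2]) next
    cg <- lapply(candidates, gt_of)
    if (any(vapply(cg, is.null, TRUE))) next
    if (any(vcf$dp[i, match(c(hybrid, candidates), vcf$samples)] <
            min_depth)) next
    informative <- informative + 1L
    for (obs in h) {
      members <- candidates[vapply(cg, function(g) obs %in% g, TRUE)]
      key <- if (length(members) == 0) "private" else
        paste(sort(members), collapse = ",")
      counts[key] <- counts[key] + 1L
      shared[members] <- shared[members] + 1L
    }
  }
  list(region_counts = counts, informative = informative,
       shared_obs = shared)
}

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

genotype_bases_test <- function(vcf) hybridly:::genotype_bases(vcf)

## two overlapping reads that disagree at one site
pileup_disagreement_fixture <- function() {
  set.seed(4)
  contig <- c(c1 = random_dna_test(60))
  p <- hybridly::caller_params(k_seed = 10L, max_mismatch = 2L)
  r1 <- substr(contig[[1]], 1, 40)
  r2 <- substr(contig[[1]], 21, 60)
  disagree_at <- 30L
  old <- substr(r2, disagree_at - 20L, disagree_at - 20L)
  substr(r2, disagree_at - 20L, disagree_at - 20L) <-
    setdiff(c("A", "C", "G", "T"), old)[1]
  reads <- c(r1, r2)
  aln <- hybridly::map_reads(reads, contig, p)
  list(pile = hybridly::pileup(aln, reads, contig)[["c1"]],
       pos = disagree_at)
}

## tiny simulation worlds for cheap tests
small_cfg <- function(seed = 1, ...) {
  hybridly::sim_config(seed = seed, n_contigs = 2L, contig_length = 8000L,
                       ...)
}
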