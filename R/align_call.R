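## Ungapped seed-and-extend read mapping and threshold-based diploid
## genotype calling — the minimal substitute for an external aligner +
## variant caller in an SNV-only world. The caller is a pure function of a
## single pileup column and its parameters; no cross-site state.

#' Mapper/caller parameters
#'
#' @param k_seed exact-match k-mer seed length for the mapper.
#' @param max_mismatch maximum Hamming mismatches for a valid placement.
#' @param min_depth minimum read depth to emit a genotype call.
#' @param min_allele_frac minimum fraction of the column depth for a base
#'   to qualify as an allele.
#' @param min_allele_count minimum read count for a qualifying allele.
#' @param hom_frac top-allele fraction at or above which the call is
#'   homozygous.
#' @return an object of class `caller_params`.
#' @export
caller_params <- function(k_seed = 31L, max_mismatch = 5L, min_depth = 8L,
                          min_allele_frac = 0.2, min_allele_count = 3L,
                          hom_frac = 0.85) {
  stopifnot(k_seed >= 1L, k_seed <= 32L, max_mismatch >= 0L,
            min_depth >= 1L, min_allele_count >= 1L)
  if (!(min_allele_frac > 0 && min_allele_frac < 0.5 &&
        hom_frac >= 0.5 && hom_frac <= 1)) {
    stop("need 0 < min_allele_frac < 0.5 <= hom_frac <= 1", call. = FALSE)
  }
  structure(list(k_seed = as.integer(k_seed),
                 max_mismatch = as.integer(max_mismatch),
                 min_depth = as.integer(min_depth),
                 min_allele_frac = min_allele_frac,
                 min_allele_count = as.integer(min_allele_count),
                 hom_frac = hom_frac),
            class = "caller_params")
}

#' Map reads to reference contigs
#'
#' Seed-and-extend, ungapped: exact `k_seed`-mer lookups at every read
#' offset on both strands generate candidate placements, which are scored
#' by Hamming distance. The unique best placement with at most
#' `max_mismatch` mismatches wins; several equally good placements make
#' the read unmapped-ambiguous (deterministic pileups, no random
#' placement).
#'
#' @param reads character vector of read sequences, or a data frame with a
#'   `seq` column (as from [read_fastq()]).
#' @param contigs named character vector of reference contigs.
#' @param params a [caller_params()].
#' @return data frame of alignments (`read` index, `contig` name, `start`
#'   0-based, `strand`, `n_mismatch`) with unmapped-read counters in
#'   attributes `n_short`, `n_unmapped`, `n_ambiguous`.
#' @export
map_reads <- function(reads, contigs, params = caller_params()) {
  map_read_sets(list(reads), contigs, params)[[1L]]
}

## Map several read sets over one shared seed index (the index build is
## the expensive part at genome scale).
map_read_sets <- function(read_sets, contigs, params = caller_params()) {
  stopifnot(is.list(read_sets), is.character(contigs),
            !is.null(names(contigs)))
  read_sets <- lapply(read_sets, function(r) {
    if (is.data.frame(r)) r <- r$seq
    stopifnot(is.character(r))
    r
  })
  res <- map_read_sets_cpp(read_sets, unname(contigs), params$k_seed,
                           params$max_mismatch)
  out <- lapply(res, function(x) {
    aln <- x$alignments
    aln$contig <- names(contigs)[aln$contig]
    attr(aln, "n_short") <- x$n_short
    attr(aln, "n_unmapped") <- x$n_unmapped
    attr(aln, "n_ambiguous") <- x$n_ambiguous
    aln
  })
  names(out) <- names(read_sets)
  out
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read one read sequence.
#' @return a one-row alignment data frame, or `NULL` when the read is
#'   unmapped (too short, no acceptable placement, or ambiguous).
#' @export
map_read <- function(read, contigs, params = caller_params()) {
  stopifnot(is_string(read))
  aln <- map_reads(read, contigs, params)
  if (nrow(aln) == 0L) NULL else aln[1L, ]
}

#' Pileup of ungapped alignments
#'
#' Counts every aligned base exactly once; minus-strand reads contribute
#' their reverse complement.
#'
#' @param alignments data frame from [map_reads()].
#' @param reads character vector (or data frame) the alignments refer to.
#' @param contigs named character vector of contigs.
#' @return named list (one element per contig) of 4 x L integer matrices
#'   with rows `A`, `C`, `G`, `T`.
#' @export
pileup <- function(alignments, reads, contigs) {
  if (is.data.frame(reads)) reads <- reads$seq
  out <- lapply(setNames(names(contigs), names(contigs)), function(cn) {
    sel <- alignments$contig == cn
    m <- pileup_cpp(contigs[[cn]], alignments$start[sel],
                    alignments$strand[sel], reads[alignments$read[sel]])
    rownames(m) <- DNA_BASES
    m
  })
  out
}

## Vectorized caller over a 4 x L count matrix. Returns list(b1, b2, dp):
## b1/b2 are character vectors of the two called alleles (NA = missing),
## with b1 = ref allele when present, otherwise the higher-count allele.
call_genotypes_matrix <- function(counts, ref_chars, params) {
  L <- ncol(counts)
  dp <- colSums(counts)
  frac_ok <- counts >= params$min_allele_count &
    counts >= rep(dp, each = 4L) * params$min_allele_frac
  nqual <- colSums(frac_ok)
  masked <- counts
  masked[!frac_ok] <- -1L
  i1 <- max.col(t(masked), ties.method = "first")
  c1 <- counts[cbind(i1, seq_len(L))]
  masked[cbind(i1, seq_len(L))] <- -1L
  i2 <- max.col(t(masked), ties.method = "first")
  c2 <- counts[cbind(i2, seq_len(L))]
  b1 <- DNA_BASES[i1]
  b2 <- DNA_BASES[i2]
  hom <- nqual >= 1L & c1 >= dp * params$hom_frac
  het <- !hom & nqual == 2L
  out1 <- out2 <- rep(NA_character_, L)
  out1[hom] <- b1[hom]
  out2[hom] <- b1[hom]
  ## order het alleles: reference base first when it is one of them
  if (any(het)) {
    a <- b1[het]; b <- b2[het]
    swap <- b == ref_chars[het]
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out1[het] <- a; out2[het] <- b
  }
  miss <- dp < params$min_depth
  out1[miss] <- NA_character_
  out2[miss] <- NA_character_
  list(b1 = out1, b2 = out2, dp = dp)
}

#' Call a diploid genotype from one pileup column
#'
#' Missing when depth < `min_depth`; qualifying alleles are bases with
#' count >= `min_allele_count` and fraction >= `min_allele_frac`; the call
#' is homozygous when the top qualifying allele reaches `hom_frac` of the
#' depth, heterozygous when exactly two alleles qualify, and missing
#' (ambiguous) otherwise.
#'
#' @param column list with `ref_base` and `base_counts` (named counts over
#'   A/C/G/T), as one column of a [pileup()] matrix.
#' @param params a [caller_params()].
#' @return list with `type` (`"hom_ref"`, `"hom_alt"`, `"het"` or
#'   `"missing"`), `alleles` (the two called bases, or `NULL`), `depth`.
#' @export
call_genotype <- function(column, params = caller_params()) {
  counts <- integer(4L)
  names(counts) <- DNA_BASES
  counts[names(column$base_counts)] <- as.integer(column$base_counts)
  g <- call_genotypes_matrix(matrix(counts, 4L), column$ref_base, params)
  if (is.na(g$b1)) {
    return(list(type = "missing", alleles = NULL, depth = g$dp))
  }
  type <- if (g$b1 == g$b2) {
    if (g$b1 == column$ref_base) "hom_ref" else "hom_alt"
  } else "het"
  list(type = type, alleles = c(g$b1, g$b2), depth = unname(g$dp))
}

#' Map and genotype all samples into a multi-sample variant set
#'
#' Runs [map_reads()], [pileup()] and the genotype caller for every
#' sample, then collects the sites where at least one sample has a called
#' non-reference genotype. Sites missing in every sample are omitted.
#'
#' @param read_sets named list (>= 2 samples) of read data frames or
#'   character vectors.
#' @param contigs named character vector of reference contigs.
#' @param params a [caller_params()].
#' @return an [hy_vcf()] with per-sample GT and DP.
#' @export
call_all <- function(read_sets, contigs, params = caller_params()) {
  stopifnot(is.list(read_sets), length(read_sets) >= 2L,
            !is.null(names(read_sets)))
  samples <- names(read_sets)
  alns <- map_read_sets(read_sets, contigs, params)
  calls <- list()
  for (s in samples) {
    aln <- alns[[s]]
    if (nrow(aln) == 0L) {
      stop("no reads from sample '", s, "' could be mapped", call. = FALSE)
    }
    piles <- pileup(aln, read_sets[[s]], contigs)
    calls[[s]] <- lapply(names(contigs), function(cn) {
      ref_chars <- strsplit(contigs[[cn]], "", fixed = TRUE)[[1L]]
      call_genotypes_matrix(piles[[cn]], ref_chars, params)
    })
    names(calls[[s]]) <- names(contigs)
  }
  rows <- list()
  for (cn in names(contigs)) {
    ref_chars <- strsplit(contigs[[cn]], "", fixed = TRUE)[[1L]]
    L <- length(ref_chars)
    nonref <- rep(FALSE, L)
    for (s in samples) {
      g <- calls[[s]][[cn]]
      nonref <- nonref | (!is.na(g$b1) &
                            (g$b1 != ref_chars | g$b2 != ref_chars))
    }
    pos <- which(nonref)
    if (length(pos) == 0L) next
    ref <- ref_chars[pos]
    b1 <- vapply(samples, function(s) calls[[s]][[cn]]$b1[pos],
                 character(length(pos)))
    b2 <- vapply(samples, function(s) calls[[s]][[cn]]$b2[pos],
                 character(length(pos)))
    dp <- vapply(samples, function(s) calls[[s]][[cn]]$dp[pos],
                 numeric(length(pos)))
    if (length(pos) == 1L) {
      b1 <- matrix(b1, 1L); b2 <- matrix(b2, 1L); dp <- matrix(dp, 1L)
    }
    alts <- lapply(seq_along(pos), function(i) {
      g <- c(b1[i, ], b2[i, ])
      sort(setdiff(unique(g[!is.na(g)]), ref[i]))
    })
    gt1 <- gt2 <- matrix(NA_integer_, length(pos), length(samples))
    for (i in seq_along(pos)) {
      al <- c(ref[i], alts[[i]])
      gt1[i, ] <- match(b1[i, ], al) - 1L
      gt2[i, ] <- match(b2[i, ], al) - 1L
    }
    rows[[cn]] <- list(
      sites = data.frame(contig = cn, pos = pos - 1L, ref = ref,
                         alts = vapply(alts, paste, "", collapse = ","),
                         stringsAsFactors = FALSE),
      gt1 = gt1, gt2 = gt2, dp = dp)
  }
  if (length(rows) == 0L) {
    empty <- matrix(NA_integer_, 0L, length(samples),
                    dimnames = list(NULL, samples))
    return(hy_vcf(samples,
                  data.frame(contig = character(0), pos = integer(0),
                             ref = character(0), alts = character(0),
                             stringsAsFactors = FALSE),
                  empty, empty, empty))
  }
  sites <- do.call(rbind, lapply(rows, `[[`, "sites"))
  rownames(sites) <- NULL
  mk <- function(f) {
    m <- do.call(rbind, lapply(rows, `[[`, f))
    storage.mode(m) <- "integer"
    dimnames(m) <- list(NULL, samples)
    m
  }
  hy_vcf(samples, sites, mk("gt1"), mk("gt2"), mk("dp"))
}
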