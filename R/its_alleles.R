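## Intragenomic ITS allele characterization from region-spanning reads.
## An allele is a full-region haplotype observed on a single spanning
## read, which sidesteps short-read phasing entirely (the simulator
## guarantees spanning reads; on real data this module needs merged or
## long reads). Low-support haplotypes within `max_err_distinct`
## mismatches of a major allele are treated as sequencing errors and
## merged; farther ones are discarded as noise, never promoted.

#' Parse a 1-based inclusive region string
#'
#' CLI/reporting region syntax `NAME:start-end` (1-based, inclusive) is
#' converted to the package's 0-based half-open convention.
#'
#' @param x string like `"ITS1:101-180"`.
#' @return list with `name`, `start`, `end` (0-based half-open).
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1L]]
  if (length(m) != 4L) {
    stop("malformed region '", x, "'; expected NAME:start-end (1-based)",
         call. = FALSE)
  }
  start1 <- as.integer(m[3L]); end1 <- as.integer(m[4L])
  if (start1 < 1L || end1 < start1) stop("invalid region bounds", call. = FALSE)
  list(name = m[2L], start = start1 - 1L, end = end1)
}

#' Extract region-spanning haplotypes per sample
#'
#' Maps each sample's reads to the rDNA reference with the package mapper
#' and keeps reads that fully cover the region; the haplotype is the
#' read's strand-normalized projection onto region coordinates.
#'
#' @param read_sets named list of read data frames (or character vectors).
#' @param its_ref named character vector with the rDNA reference
#'   sequence(s).
#' @param region list with `name`, `start`, `end` (0-based half-open), as
#'   from [parse_region()] or the simulator; an optional `contig` names
#'   the reference sequence (default: the first).
#' @param params a [caller_params()] for the mapper.
#' @return named list of character vectors of region haplotypes.
#' @export
extract_spanning_reads <- function(read_sets, its_ref, region,
                                   params = caller_params()) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  contig <- region$contig %||% names(its_ref)[1L]
  lapply(setNames(names(read_sets), names(read_sets)), function(s) {
    reads <- read_sets[[s]]
    if (is.data.frame(reads)) reads <- reads$seq
    aln <- map_reads(reads, its_ref, params)
    len <- nchar(reads[aln$read])
    span <- aln$contig == contig & aln$start <= region$start &
      aln$start + len >= region$end
    aln <- aln[span, , drop = FALSE]
    if (nrow(aln) == 0L) {
      stop("no reads from sample '", s, "' span region '", region$name,
           "'", call. = FALSE)
    }
    oriented <- reads[aln$read]
    minus <- aln$strand == "-"
    oriented[minus] <- revcomp(oriented[minus])
    substr(oriented, region$start - aln$start + 1L,
           region$end - aln$start)
  })
}

hamming_str <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Cluster spanning haplotypes into ITS alleles
#'
#' Identical haplotypes are grouped; groups below `min_support` are merged
#' into the nearest major group when within `max_err_distinct` mismatches,
#' otherwise discarded as noise. Surviving groups are the alleles, labeled
#' `H1..Hn` in decreasing total-support order (ties broken
#' lexicographically by sequence).
#'
#' @param haplotypes named list (per sample) of region haplotype strings,
#'   as from [extract_spanning_reads()].
#' @param min_support minimum total read support for a real allele.
#' @param max_err_distinct maximal Hamming distance at which a low-support
#'   group is considered a sequencing-error shadow of a major allele.
#' @param region optional region name carried into the table.
#' @return object of class `its_allele_table`: `region`, `alleles` (data
#'   frame `id`, `seq`, `support`), `support` (alleles x samples matrix),
#'   `diffs` (pairwise SNP differences), `n_discarded`, `min_support`.
#' @export
cluster_alleles <- function(haplotypes, min_support = 3L,
                            max_err_distinct = 1L, region = NA_character_) {
  stopifnot(is.list(haplotypes), !is.null(names(haplotypes)))
  samples <- names(haplotypes)
  all_h <- unlist(haplotypes, use.names = FALSE)
  if (length(all_h) == 0L) stop("no haplotypes supplied", call. = FALSE)
  if (length(unique(nchar(all_h))) != 1L) {
    stop("haplotypes have unequal lengths", call. = FALSE)
  }
  seqs <- sort(unique(all_h))
  sup <- vapply(samples, function(s)
    vapply(seqs, function(q) sum(haplotypes[[s]] == q), integer(1L)),
    integer(length(seqs)))
  if (length(seqs) == 1L) sup <- matrix(sup, 1L,
                                        dimnames = list(NULL, samples))
  total <- rowSums(sup)
  major <- total >= min_support
  n_discarded <- 0L
  if (any(major) && any(!major)) {
    mj <- which(major)
    for (i in which(!major)) {
      dd <- vapply(mj, function(j) hamming_str(seqs[i], seqs[j]),
                   numeric(1L))
      ## nearest major; ties -> higher support, then lexicographic seq
      o <- order(dd, -total[mj], seqs[mj])
      if (dd[o[1L]] <= max_err_distinct) {
        tgt <- mj[o[1L]]
        sup[tgt, ] <- sup[tgt, ] + sup[i, ]
      } else {
        n_discarded <- n_discarded + sum(sup[i, ])
      }
    }
  } else if (!any(major)) {
    stop("no haplotype group reaches min_support = ", min_support,
         "; lower min_support", call. = FALSE)
  }
  keep <- which(major)
  seqs <- seqs[keep]
  sup <- sup[keep, , drop = FALSE]
  total <- rowSums(sup)
  o <- order(-total, seqs)
  seqs <- seqs[o]
  sup <- sup[o, , drop = FALSE]
  total <- total[o]
  ids <- paste0("H", seq_along(seqs))
  rownames(sup) <- ids
  m <- length(seqs)
  diffs <- matrix(0L, m, m, dimnames = list(ids, ids))
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        diffs[i, j] <- diffs[j, i] <- hamming_str(seqs[i], seqs[j])
      }
    }
  }
  structure(list(
    region = region,
    alleles = data.frame(id = ids, seq = seqs, support = as.integer(total),
                         stringsAsFactors = FALSE, row.names = NULL),
    support = sup, diffs = diffs, n_discarded = n_discarded,
    min_support = as.integer(min_support)
  ), class = "its_allele_table")
}

#' @export
print.its_allele_table <- function(x, ...) {
  cat("<its_allele_table>", if (!is.na(x$region)) x$region, "-",
      nrow(x$alleles), "alleles,", x$n_discarded, "noise reads\n")
  df <- cbind(x$alleles[, c("id", "support")], x$support)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Classify allele species-specificity
#'
#' An allele's sample set contains the samples supporting it with at least
#' `min_support` reads; an allele is exclusive when exactly one sample
#' supports it.
#'
#' @param table an [cluster_alleles()] result.
#' @param min_support per-sample support threshold (defaults to the
#'   clustering threshold).
#' @return data frame with `id`, `samples` (comma-joined supporting
#'   samples), `n_samples`, `exclusive`.
#' @export
classify_specificity <- function(table, min_support = table$min_support) {
  stopifnot(inherits(table, "its_allele_table"))
  sets <- apply(table$support >= min_support, 1L, function(r)
    colnames(table$support)[r], simplify = FALSE)
  data.frame(
    id = table$alleles$id,
    samples = vapply(sets, paste, "", collapse = ","),
    n_samples = lengths(sets),
    exclusive = lengths(sets) == 1L,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Neighbor-joining tree of ITS alleles
#'
#' NJ on the pairwise SNP-difference matrix; with exactly two alleles the
#' single edge is split at its midpoint.
#'
#' @param table an [cluster_alleles()] result with >= 2 alleles.
#' @return a `phylo` object.
#' @export
allele_nj_tree <- function(table) {
  stopifnot(inherits(table, "its_allele_table"))
  m <- nrow(table$alleles)
  if (m < 2L) stop("need >= 2 alleles for a tree", call. = FALSE)
  if (m == 2L) {
    d <- table$diffs[1L, 2L]
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                         table$alleles$id[1L], d / 2,
                                         table$alleles$id[2L], d / 2)))
  }
  nj_tree(table$diffs)
}
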