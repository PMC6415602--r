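## Alignment- and assembly-free phylogeny: inter-sample distances from
## shared canonical k-mer content of raw read sets, then neighbor joining.
## The distance is a containment transform, d = -ln(|P ∩ Q| / min(|P|,
## |Q|)) / k, a transparent stand-in for published k-mer phylogeny
## distances; the analysis surface is topology recovery, not
## branch-length equality with any particular program.

#' Build a canonical k-mer profile from reads
#'
#' k-mers containing `N` are dropped; k-mers seen fewer than `min_count`
#' times are dropped as likely sequencing errors; the survivors form a
#' set of canonical k-mers (lexicographic minimum of each k-mer and its
#' reverse complement). `k` must be odd so no k-mer is its own reverse
#' complement.
#'
#' @param reads character vector of read sequences, or a data frame with
#'   a `seq` column.
#' @param k odd k-mer length, at most 31.
#' @param min_count minimum k-mer multiplicity.
#' @param sample optional sample id stored in the profile.
#' @return object of class `kmer_profile`: `sample`, `k`, `min_count`,
#'   `kmers` (sorted character vector).
#' @export
build_profile <- function(reads, k = 31L, min_count = 2L, sample = NULL) {
  if (is.data.frame(reads)) reads <- reads$seq
  stopifnot(is.character(reads), length(reads) >= 1L)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (canonical k-mers)", call. = FALSE)
  if (k > 31L || k < 1L) stop("k must be in 1..31", call. = FALSE)
  if (max(nchar(reads)) < k) {
    stop("k = ", k, " exceeds the read length", call. = FALSE)
  }
  structure(list(sample = sample, k = k, min_count = as.integer(min_count),
                 kmers = kmer_profile_cpp(reads, k, as.integer(min_count))),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("<kmer_profile>", x$sample %||% "(unnamed)", "-",
      length(x$kmers), "canonical", paste0(x$k, "-mers"),
      paste0("(min_count ", x$min_count, ")"), "\n")
  invisible(x)
}

#' Containment k-mer distance between two profiles
#'
#' `d = -ln(|P intersect Q| / min(|P|, |Q|)) / k`. Zero iff the smaller
#' set is contained in the larger; `Inf` when the intersection is empty
#' (capped at `d_max` by [aaf_dist_matrix()] for tree building).
#'
#' @param p,q [build_profile()] results with equal `k`.
#' @return non-negative numeric distance (possibly `Inf`).
#' @export
aaf_distance <- function(p, q) {
  stopifnot(inherits(p, "kmer_profile"), inherits(q, "kmer_profile"))
  if (p$k != q$k) stop("profiles have different k", call. = FALSE)
  if (length(p$kmers) == 0L || length(q$kmers) == 0L) {
    stop("empty k-mer profile (all k-mers below min_count?)",
         call. = FALSE)
  }
  inter <- length(intersect(p$kmers, q$kmers))
  if (inter == 0L) return(Inf)
  -log(inter / min(length(p$kmers), length(q$kmers))) / p$k
}

#' Pairwise AAF distance matrix
#'
#' @param profiles named list of [build_profile()] results.
#' @param d_max cap applied to infinite (and any larger) distances so the
#'   matrix is tree-buildable.
#' @return symmetric numeric matrix.
#' @export
aaf_dist_matrix <- function(profiles, d_max = 1.0) {
  stopifnot(is.list(profiles), length(profiles) >= 2L,
            !is.null(names(profiles)))
  n <- length(profiles)
  taxa <- names(profiles)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- min(aaf_distance(profiles[[i]], profiles[[j]]), d_max)
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' AAF phylogeny from read sets
#'
#' Convenience wrapper: profiles, distance matrix, neighbor joining.
#'
#' @param read_sets named list of read data frames or character vectors.
#' @param k odd k-mer length.
#' @param min_count minimum k-mer multiplicity.
#' @param outgroup optional taxon to root on.
#' @param d_max distance cap.
#' @return list with `tree` (a `phylo`), `dist` (the matrix), `profiles`.
#' @export
aaf_phylogeny <- function(read_sets, k = 31L, min_count = 2L,
                          outgroup = NULL, d_max = 1.0) {
  profiles <- lapply(setNames(names(read_sets), names(read_sets)),
                     function(s) build_profile(read_sets[[s]], k = k,
                                               min_count = min_count,
                                               sample = s))
  d <- aaf_dist_matrix(profiles, d_max = d_max)
  list(tree = nj_tree(d, outgroup = outgroup), dist = d,
       profiles = profiles)
}
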