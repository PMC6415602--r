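## Pairwise substitution distances over positionally aligned organellar
## sequences, and maternal-parent assignment: under strictly maternal
## chloroplast inheritance, the hybrid's chloroplast is (nearly) the
## maternal parent's, so the candidate at minimal distance is the female
## genitor. The module consumes an alignment; it never aligns.

#' Pairwise SNP distances over an aligned multi-FASTA
#'
#' Columns where either base is outside `A,C,G,T` (ambiguity codes, `N`,
#' gaps) are skipped for that pair.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (e.g. from [read_fasta()] on an aligned multi-FASTA).
#' @return object of class `cp_dist`: `taxa`, `counts` (symmetric
#'   substitution counts), `prop` (per-compared-site proportions),
#'   `n_sites` (sites compared per pair).
#' @export
cp_pairwise <- function(aln) {
  stopifnot(is.character(aln), !is.null(names(aln)), length(aln) >= 2L)
  if (length(unique(nchar(aln))) != 1L) {
    stop("sequences have unequal lengths; supply a positional alignment ",
         "(this tool does not align)", call. = FALSE)
  }
  taxa <- names(aln)
  n <- length(taxa)
  ints <- lapply(aln, function(s) utf8ToInt(toupper(s)))
  ok <- lapply(ints, function(v) v %in% utf8ToInt("ACGT"))
  counts <- n_sites <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[[i]] & ok[[j]]
      d <- sum(both & ints[[i]] != ints[[j]])
      counts[i, j] <- counts[j, i] <- d
      n_sites[i, j] <- n_sites[j, i] <- sum(both)
    }
  }
  diag(n_sites) <- nchar(aln[[1L]])
  prop <- counts / n_sites
  diag(prop) <- 0
  structure(list(taxa = taxa, counts = counts, prop = prop,
                 n_sites = n_sites), class = "cp_dist")
}

#' @export
print.cp_dist <- function(x, ...) {
  cat("<cp_dist> pairwise substitution counts\n")
  print(x$counts)
  invisible(x)
}

#' Assign the maternal parent from organellar distances
#'
#' The maternal candidate minimizes the hybrid-candidate distance; the
#' margin is the ratio of the second-smallest to the smallest distance,
#' and assignments with margin below `tie_ratio` are reported ambiguous.
#'
#' @param dm a [cp_pairwise()] result.
#' @param hybrid hybrid taxon name.
#' @param candidates candidate taxon names (>= 2).
#' @param tie_ratio minimal second/best distance ratio for an unambiguous
#'   call.
#' @param inheritance organellar inheritance mode; only changes the
#'   wording of the assignment (`maternal` reports a female genitor,
#'   `paternal` a male one).
#' @return list with `maternal` (candidate name or `"ambiguous"`),
#'   `margin`, `distances` (hybrid-candidate counts), `inheritance`.
#' @export
assign_maternal <- function(dm, hybrid, candidates, tie_ratio = 1.1,
                            inheritance = c("maternal", "paternal")) {
  inheritance <- match.arg(inheritance)
  stopifnot(inherits(dm, "cp_dist"), hybrid %in% dm$taxa,
            length(candidates) >= 2L, all(candidates %in% dm$taxa))
  d <- dm$counts[hybrid, candidates]
  ord <- order(d, candidates)  # deterministic on ties
  best <- d[ord[1L]]
  second <- d[ord[2L]]
  margin <- if (best == 0 && second == 0) 1
    else if (best == 0) Inf else unname(second / best)
  list(
    maternal = if (margin < tie_ratio) "ambiguous" else
      candidates[ord[1L]],
    margin = margin,
    distances = d,
    inheritance = inheritance
  )
}
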