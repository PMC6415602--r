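## Classic neighbor joining with fully deterministic behaviour: taxa are
## processed in name order, ties in the Q criterion keep the first pair
## encountered, and negative branch lengths are clamped to zero.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining. For three taxa the branch lengths solve
#' the three-point formulas exactly. Tie-breaking is deterministic by
#' taxon-name order, so relabeling taxa permutes the output consistently.
#'
#' @param d symmetric numeric matrix with row/column names, or a
#'   [stats::dist].
#' @param outgroup optional taxon name; when given, the returned tree is
#'   rooted on that taxon's pendant edge.
#' @return an [ape] `phylo` object with branch lengths (clamped >= 0).
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), !is.null(rownames(d)),
            identical(rownames(d), colnames(d)))
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) {
    stop("distance matrix contains non-finite entries; cap them first",
         call. = FALSE)
  }
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  labs <- quote_newick_label(rownames(d))
  frag <- labs
  D <- d
  fmt <- function(x) format(x, digits = 10, trim = TRUE, scientific = FALSE)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    best_q <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) { best_q <- q; bi <- i; bj <- j }
      }
    }
    li <- D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    lj <- D[bi, bj] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_frag <- paste0("(", frag[bi], ":", fmt(li), ",", frag[bj], ":",
                       fmt(lj), ")")
    dk <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    keep <- setdiff(seq_len(m), c(bi, bj))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rownames(D2) <- colnames(D2) <- as.character(seq_len(m - 1L))
    D <- D2
  }
  ## final trifurcation by the three-point formulas
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2),
                ",", frag[3], ":", fmt(l3), ");")
  tree <- ape::read.tree(text = nwk)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not a taxon", call. = FALSE)
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}
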