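## Per-contig SNP statistics: intragenomic (heterozygous-site) counts per
## sample, interspecific fixed differences between two designated
## candidates, per-10-kb densities, and hybrid/candidate fold ratios.
##
## "Intraspecific SNP" here is a within-individual heterozygous call: one
## individual per species is sequenced, so a species' intraspecific
## variation can only register as heterozygosity. Fixed differences
## between species land in the separate interspecific column (and a
## non-reference-genotype count per sample is kept in the
## `nonref_counts` attribute for completeness).

#' Per-contig SNP summary
#'
#' @param vcf an [hy_vcf()].
#' @param contig_lengths named integer vector of contig lengths.
#' @param candidate_pair two sample names whose fixed differences define
#'   the interspecific count (sites where both are called and share no
#'   allele).
#' @return data frame (class `contig_snp_summary`): `contig`, `length`,
#'   one intraspecific (heterozygous-site) count column per sample, and
#'   `inter`. Attribute `nonref_counts` holds the per-sample
#'   non-reference-genotype counts.
#' @export
summarize_contigs <- function(vcf, contig_lengths, candidate_pair) {
  validate_hy_vcf(vcf)
  stopifnot(!is.null(names(contig_lengths)))
  if (!all(candidate_pair %in% vcf$samples)) {
    stop("unknown sample(s): ",
         paste(setdiff(candidate_pair, vcf$samples), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(candidate_pair) == 2L)
  gb <- genotype_bases(vcf)
  called <- !is.na(gb$b1)
  het <- called & gb$b1 != gb$b2
  nonref <- called & (gb$b1 != vcf$sites$ref | gb$b2 != vcf$sites$ref)
  a <- candidate_pair[1L]; b <- candidate_pair[2L]
  both <- called[, a] & called[, b]
  share <- gb$b1[, a] == gb$b1[, b] | gb$b1[, a] == gb$b2[, b] |
    gb$b2[, a] == gb$b1[, b] | gb$b2[, a] == gb$b2[, b]
  inter <- both & !share
  contigs <- names(contig_lengths)
  tally <- function(m, cn) {
    if (nrow(vcf$sites) == 0L) return(rep(0L, ncol(m)))
    sel <- vcf$sites$contig == cn
    as.integer(colSums(m[sel, , drop = FALSE]))
  }
  out <- data.frame(contig = contigs,
                    length = as.integer(contig_lengths),
                    stringsAsFactors = FALSE)
  intra <- t(vapply(contigs, function(cn) tally(het, cn),
                    integer(length(vcf$samples))))
  colnames(intra) <- vcf$samples
  out <- cbind(out, as.data.frame(intra))
  out$inter <- vapply(contigs, function(cn) {
    if (nrow(vcf$sites) == 0L) return(0L)
    as.integer(sum(inter[vcf$sites$contig == cn]))
  }, integer(1L))
  rownames(out) <- NULL
  nr <- t(vapply(contigs, function(cn) tally(nonref, cn),
                 integer(length(vcf$samples))))
  colnames(nr) <- vcf$samples
  attr(out, "nonref_counts") <- nr
  attr(out, "samples") <- vcf$samples
  class(out) <- c("contig_snp_summary", "data.frame")
  out
}

#' Density report from per-contig summaries
#'
#' Column sums, per-10-kb densities (`1e4 * total / total_length`) and
#' hybrid-vs-candidate fold ratios.
#'
#' @param summaries a `contig_snp_summary` from [summarize_contigs()].
#' @param hybrid_name the hybrid's sample name.
#' @return an object of class `density_report`; see
#'   [density_from_totals()] for the fields.
#' @export
density_report <- function(summaries, hybrid_name) {
  stopifnot(inherits(summaries, "contig_snp_summary"),
            nrow(summaries) >= 1L)
  samples <- attr(summaries, "samples")
  totals <- vapply(samples, function(s) sum(summaries[[s]]), numeric(1L))
  density_from_totals(totals, sum(summaries$length), hybrid_name,
                      inter_total = sum(summaries$inter))
}

#' Density report from printed totals
#'
#' The same arithmetic as [density_report()], but taking the per-sample
#' totals directly — e.g. the total row of a published table.
#'
#' @param totals named numeric vector of per-sample intraspecific SNP
#'   totals.
#' @param total_length summed contig length in bp.
#' @param hybrid_name the hybrid's sample name (must be in `totals`).
#' @param inter_total optional interspecific total, carried through.
#' @return an object of class `density_report`: `totals`, `total_length`,
#'   `density_per_10kb` (raw), `density_rounded` (integer, as printed
#'   means usually are), `fold_vs` (hybrid total / candidate total, one
#'   decimal), `fold_undefined` (candidates with zero total).
#' @export
density_from_totals <- function(totals, total_length, hybrid_name,
                                inter_total = NA_real_) {
  if (total_length <= 0) stop("total_length must be > 0", call. = FALSE)
  stopifnot(hybrid_name %in% names(totals))
  dens <- 1e4 * totals / total_length
  cand <- setdiff(names(totals), hybrid_name)
  fold <- round(totals[[hybrid_name]] / totals[cand], 1L)
  structure(list(
    totals = totals, total_length = total_length,
    inter_total = inter_total,
    hybrid = hybrid_name,
    density_per_10kb = dens,
    density_rounded = round(dens),
    fold_vs = fold,
    fold_undefined = names(totals[cand])[totals[cand] == 0]
  ), class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat("<density_report> total length ", x$total_length, " bp\n", sep = "")
  for (s in names(x$totals)) {
    cat(sprintf("  %-12s %6d SNPs  %7.1f /10kb%s\n", s, x$totals[[s]],
                x$density_per_10kb[[s]],
                if (s == x$hybrid) "  [hybrid]" else ""))
  }
  for (s in names(x$fold_vs)) {
    cat(sprintf("  fold %s vs %s: %.1f\n", x$hybrid, s, x$fold_vs[[s]]))
  }
  invisible(x)
}

#' Windowed SNP density track
#'
#' Heterozygous-site counts per sample in tiling windows along one contig
#' (the last window is truncated at the contig end).
#'
#' @param vcf an [hy_vcf()].
#' @param contig contig name.
#' @param contig_length contig length in bp.
#' @param window_bp window width.
#' @param step step between window starts (default: tiling).
#' @return data frame with `start`, `end` (0-based half-open) and one
#'   count column per sample.
#' @export
density_track <- function(vcf, contig, contig_length, window_bp = 10000L,
                          step = window_bp) {
  validate_hy_vcf(vcf)
  stopifnot(window_bp >= 1L, step >= 1L)
  gb <- genotype_bases(vcf)
  sel <- vcf$sites$contig == contig
  pos <- vcf$sites$pos[sel]
  het <- !is.na(gb$b1[sel, , drop = FALSE]) &
    gb$b1[sel, , drop = FALSE] != gb$b2[sel, , drop = FALSE]
  starts <- seq.int(0L, max(0L, contig_length - 1L), by = step)
  ends <- pmin(starts + window_bp, contig_length)
  counts <- vapply(vcf$samples, function(s) {
    p <- pos[het[, s]]
    vapply(seq_along(starts), function(i)
      sum(p >= starts[i] & p < ends[i]), integer(1L))
  }, integer(length(starts)))
  if (length(starts) == 1L) counts <- matrix(counts, 1L,
                                             dimnames = list(NULL, vcf$samples))
  cbind(data.frame(start = starts, end = ends), as.data.frame(counts))
}
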