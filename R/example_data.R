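#' Published per-contig SNP counts for the Spondias hybrid system
#'
#' The per-contig intraspecific SNP counts and interspecific fixed
#' differences reported for six ~50 kb nuclear contigs of *Spondias
#' tuberosa* (the reference species), the putative hybrid *S. bahiensis*,
#' and *S. mombin*, with the *S. tuberosa* assembly as reference. These
#' printed cells are the canonical worked example for [density_report()]
#' arithmetic.
#'
#' Note: the published total for the *S. tuberosa* column (66) is
#' arithmetically inconsistent with its printed cells, which sum to 63;
#' this accessor returns the cells as printed and leaves totals to the
#' caller.
#'
#' @return data frame with columns `contig`, `length_bp`, `s_tuberosa`,
#'   `s_bahiensis`, `s_mombin`, `interspecific`.
#' @export
spondias_snp_table <- function() {
  path <- system.file("extdata", "spondias_contig_snps.tsv",
                      package = "hybridly", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Published chloroplast pairwise SNP distances for the Spondias system
#'
#' Pairwise substitution counts between whole chloroplast genomes:
#' 856 (*S. tuberosa* vs *S. bahiensis*), 3042 (*S. tuberosa* vs
#' *S. mombin*), 3292 (*S. bahiensis* vs *S. mombin*). The worked example
#' for [assign_maternal()].
#'
#' @return a `cp_dist` object over the three taxa.
#' @export
spondias_cp_distances <- function() {
  taxa <- c("s_tuberosa", "s_bahiensis", "s_mombin")
  counts <- matrix(c(0L, 856L, 3042L,
                     856L, 0L, 3292L,
                     3042L, 3292L, 0L), 3L,
                   dimnames = list(taxa, taxa))
  n_sites <- matrix(NA_integer_, 3L, 3L, dimnames = list(taxa, taxa))
  structure(list(taxa = taxa, counts = counts,
                 prop = counts / NA_real_, n_sites = n_sites),
            class = "cp_dist")
}
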