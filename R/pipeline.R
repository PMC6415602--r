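## End-to-end pipeline on simulated (or user-supplied) inputs: calls,
## SNP statistics, allele partition, organellar assignment, ITS tables,
## AAF tree, verdict.

#' Run the full diagnosis pipeline on a simulated data set
#'
#' Chains every stage on a [simulate_dataset()] world: genotype calling
#' for the reference, hybrid and non-parent samples; per-contig SNP
#' statistics and densities; allele partition and half-sharing tests;
#' chloroplast distances and maternal assignment; optionally the ITS
#' allele tables and the AAF k-mer tree; and the integrated verdict.
#'
#' @param cfg a [sim_config()], or a ready-made [simulate_dataset()]
#'   result.
#' @param params a [caller_params()].
#' @param vparams a [verdict_params()].
#' @param include_aaf,include_its switch the AAF / ITS stages (both are
#'   extra evidence; the is-hybrid rule does not consult them).
#' @param aaf_k,aaf_min_count AAF profile parameters.
#' @return list with `sim`, `vcf`, `summary`, `report`, `partition`,
#'   `tests`, `cp`, `maternal`, `its_tables`, `aaf`, `verdict`.
#' @export
run_pipeline <- function(cfg, params = caller_params(),
                         vparams = verdict_params(),
                         include_aaf = TRUE, include_its = TRUE,
                         aaf_k = 31L, aaf_min_count = 2L) {
  sim <- if (inherits(cfg, "sim_config")) {
    keep <- unname(cfg$samples[c("reference", "hybrid", "nonparent",
                                 if (include_aaf) "outgroup")])
    simulate_dataset(cfg, read_samples = keep)
  } else cfg
  cfgx <- sim$config
  sm <- cfgx$samples
  hybrid <- sm[["hybrid"]]
  candidates <- unname(sm[c("reference", "nonparent")])
  genotyped <- c(sm[["reference"]], hybrid, sm[["nonparent"]])
  vcf <- call_all(sim$reads[genotyped], sim$contigs, params)
  contig_lengths <- setNames(nchar(sim$contigs), names(sim$contigs))
  summ <- summarize_contigs(vcf, contig_lengths, candidates)
  report <- density_report(summ, hybrid)
  partition <- partition_alleles(vcf, hybrid, candidates)
  tests <- lapply(setNames(candidates, candidates), function(cd)
    half_sharing_test(partition, cd, conf_level = vparams$conf_level))
  cp <- cp_pairwise(sim$cp$alignment)
  maternal <- assign_maternal(cp, hybrid, candidates,
                              tie_ratio = vparams$tie_ratio)
  its_tables <- NULL
  if (include_its) {
    its_tables <- lapply(sim$its$regions, function(rg) {
      haps <- extract_spanning_reads(sim$its$reads, sim$its$its_ref, rg,
                                     params)
      cluster_alleles(haps, region = rg$name)
    })
    names(its_tables) <- vapply(sim$its$regions, `[[`, "", "name")
  }
  aaf <- NULL
  if (include_aaf) {
    aaf <- aaf_phylogeny(sim$reads, k = aaf_k, min_count = aaf_min_count,
                         outgroup = sm[["outgroup"]])
  }
  verdict <- decide(report, tests, partition, maternal,
                    its_tables = its_tables, params = vparams)
  list(sim = sim, vcf = vcf, summary = summ, report = report,
       partition = partition, tests = tests, cp = cp, maternal = maternal,
       its_tables = its_tables, aaf = aaf, verdict = verdict)
}
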