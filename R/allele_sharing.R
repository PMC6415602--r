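## Venn-style partition of the hybrid's allele observations among
## candidate parents, and the exact binomial test of the F1 half-sharing
## expectation. Sharing is by allele VALUE (base), never by VCF allele
## index, so per-record allele ordering is irrelevant. Informative sites
## are restricted to hybrid-heterozygous, fully co-called sites:
## homozygous sites carry no F1 phasing signal, and a candidate's missing
## call is absence of evidence, not evidence of non-sharing.

#' Partition the hybrid's alleles among candidate parents
#'
#' At every informative site (hybrid heterozygous, every candidate
#' called), each of the hybrid's two allele observations is assigned to
#' the subset of candidates whose genotype contains that base. Region
#' counts over these subsets are the Venn diagram of the hybrid's allelic
#' distribution; the empty subset (key `""`) is the hybrid's private
#' alleles.
#'
#' @param vcf an [hy_vcf()].
#' @param hybrid hybrid sample name.
#' @param candidates candidate parent sample names (>= 1).
#' @param min_depth optional extra depth filter applied to the hybrid and
#'   every candidate (on top of the caller's own threshold).
#' @return object of class `allele_partition`: `candidates`,
#'   `region_counts` (named by comma-joined sorted candidate subsets;
#'   the empty subset is keyed `"private"`),
#'   `informative_sites`, `shared_fraction` (f), `alt_shared_fraction`
#'   (g), `n_shared_obs`, `n_one_allele_shared`.
#' @export
partition_alleles <- function(vcf, hybrid, candidates, min_depth = 0L) {
  validate_hy_vcf(vcf)
  if (!hybrid %in% vcf$samples) {
    stop("hybrid sample '", hybrid, "' not in VCF", call. = FALSE)
  }
  if (!all(candidates %in% vcf$samples)) {
    stop("unknown candidate(s): ",
         paste(setdiff(candidates, vcf$samples), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(candidates) >= 1L, !hybrid %in% candidates)
  gb <- genotype_bases(vcf)
  called <- !is.na(gb$b1)
  deep <- vcf$dp >= min_depth & !is.na(vcf$dp)
  ok <- called[, hybrid] & deep[, hybrid]
  for (cd in candidates) ok <- ok & called[, cd] & deep[, cd]
  informative <- ok & gb$b1[, hybrid] != gb$b2[, hybrid]
  idx <- which(informative)
  n <- length(idx)
  stopifnot(!"private" %in% candidates)
  subsets <- all_subsets(candidates)
  keys <- vapply(subsets, paste, "", collapse = ",")
  keys[keys == ""] <- "private"
  region_counts <- setNames(integer(length(subsets)), keys)
  in_cand <- function(obs) {
    ## n x n_candidates logical: candidate's genotype contains the base
    vapply(candidates, function(cd)
      gb$b1[idx, cd] == obs | gb$b2[idx, cd] == obs, logical(n))
  }
  shared_obs <- setNames(numeric(length(candidates)), candidates)
  one_shared <- setNames(numeric(length(candidates)), candidates)
  g_num <- setNames(numeric(length(candidates)), candidates)
  g_den <- 0
  if (n > 0L) {
    o1 <- gb$b1[idx, hybrid]
    o2 <- gb$b2[idx, hybrid]
    m1 <- in_cand(o1)
    m2 <- in_cand(o2)
    if (n == 1L) { m1 <- matrix(m1, 1L, dimnames = list(NULL, candidates))
                   m2 <- matrix(m2, 1L, dimnames = list(NULL, candidates)) }
    key_of <- function(m) {
      k <- apply(m, 1L, function(r) paste(sort(candidates[r]),
                                          collapse = ","))
      k[k == ""] <- "private"
      k
    }
    k1 <- key_of(m1); k2 <- key_of(m2)
    tab <- table(factor(c(k1, k2), levels = names(region_counts)))
    region_counts[] <- as.integer(tab)
    shared_obs <- colSums(m1) + colSums(m2)
    one_shared <- colSums((m1 * 1L + m2 * 1L) == 1L)
    ## alt-sharing: hybrid non-reference observations found among the
    ## candidate's non-reference alleles
    ref <- vcf$sites$ref[idx]
    for (cd in candidates) {
      cb1 <- gb$b1[idx, cd]; cb2 <- gb$b2[idx, cd]
      for (o in list(o1, o2)) {
        is_alt <- o != ref
        hit <- is_alt & ((cb1 == o & cb1 != ref) | (cb2 == o & cb2 != ref))
        g_num[cd] <- g_num[cd] + sum(hit)
      }
    }
    g_den <- sum(o1 != ref) + sum(o2 != ref)
  }
  structure(list(
    hybrid = hybrid, candidates = candidates,
    region_counts = region_counts, informative_sites = n,
    shared_fraction = if (n > 0L) shared_obs / (2 * n) else
      setNames(rep(NA_real_, length(candidates)), candidates),
    alt_shared_fraction = if (g_den > 0) g_num / g_den else
      setNames(rep(NA_real_, length(candidates)), candidates),
    n_alt_obs = g_den,
    n_shared_obs = shared_obs,
    n_one_allele_shared = one_shared
  ), class = "allele_partition")
}

all_subsets <- function(x) {
  n <- length(x)
  out <- list(character(0))
  for (k in seq_len(n)) {
    cmb <- utils::combn(sort(x), k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' @export
print.allele_partition <- function(x, ...) {
  cat("<allele_partition> hybrid '", x$hybrid, "', ",
      x$informative_sites, " informative sites\n", sep = "")
  for (k in seq_along(x$region_counts)) {
    cat(sprintf("  {%s}: %d\n", names(x$region_counts)[k],
                x$region_counts[k]))
  }
  for (cd in x$candidates) {
    cat(sprintf("  f_%s = %.4f   g_%s = %.4f\n", cd,
                x$shared_fraction[[cd]], cd, x$alt_shared_fraction[[cd]]))
  }
  invisible(x)
}

#' Sharing fractions per candidate
#'
#' @param partition an [partition_alleles()] result.
#' @return data frame with columns `candidate`, `f` (fraction of the
#'   hybrid's allele observations present in the candidate) and `g`
#'   (fraction of the hybrid's non-reference allele observations found
#'   among the candidate's non-reference alleles).
#' @export
sharing_fractions <- function(partition) {
  stopifnot(inherits(partition, "allele_partition"))
  if (partition$informative_sites < 1L) {
    stop("no informative sites; supply more data or lower filters",
         call. = FALSE)
  }
  data.frame(candidate = partition$candidates,
             f = unname(partition$shared_fraction[partition$candidates]),
             g = unname(partition$alt_shared_fraction[partition$candidates]),
             stringsAsFactors = FALSE)
}

#' Exact two-sided binomial test with Clopper-Pearson interval
#'
#' Minimum-likelihood two-sided convention: the p-value sums all outcome
#' probabilities not exceeding that of the observed count (the convention
#' of [stats::binom.test()]).
#'
#' @param x successes.
#' @param n trials.
#' @param p null probability.
#' @param conf_level confidence level for the Clopper-Pearson interval.
#' @return list with `estimate`, `p_value`, `conf_int`.
#' @export
binom_exact_test <- function(x, n, p = 0.5, conf_level = 0.95) {
  stopifnot(n >= 1L, x >= 0L, x <= n)
  bt <- stats::binom.test(x, n, p = p, alternative = "two.sided",
                          conf.level = conf_level)
  list(estimate = x / n, p_value = unname(bt$p.value),
       conf_int = as.numeric(bt$conf.int))
}

#' Test the F1 half-sharing expectation for one candidate
#'
#' Under the F1 model with this candidate as one parent (and the other
#' parent unsampled), each of the hybrid's `2 x informative_sites` allele
#' observations is present in the candidate with probability 1/2. The
#' test is an exact binomial test of the shared-observation count against
#' 0.5, with a Clopper-Pearson confidence interval on the sharing
#' fraction f.
#'
#' @param partition an [partition_alleles()] result.
#' @param candidate candidate sample name.
#' @param conf_level confidence level.
#' @return object of class `sharing_test`: `candidate`, `n_informative`,
#'   `n_one_allele_shared`, `n_shared_obs`, `n_trials`, `point_estimate`,
#'   `p_value`, `conf_int`.
#' @export
half_sharing_test <- function(partition, candidate, conf_level = 0.95) {
  stopifnot(inherits(partition, "allele_partition"),
            candidate %in% partition$candidates)
  n <- partition$informative_sites
  if (n < 1L) stop("no informative sites", call. = FALSE)
  k <- partition$n_shared_obs[[candidate]]
  bt <- binom_exact_test(k, 2L * n, p = 0.5, conf_level = conf_level)
  structure(list(
    candidate = candidate, n_informative = n,
    n_one_allele_shared = partition$n_one_allele_shared[[candidate]],
    n_shared_obs = k, n_trials = 2L * n,
    point_estimate = bt$estimate, p_value = bt$p_value,
    conf_int = bt$conf_int
  ), class = "sharing_test")
}

#' @export
print.sharing_test <- function(x, ...) {
  cat(sprintf(paste0("<sharing_test> %s: f = %.4f (%d/%d obs), 95%% CI ",
                     "[%.4f, %.4f], exact p vs 0.5 = %.3g\n"),
              x$candidate, x$point_estimate, x$n_shared_obs, x$n_trials,
              x$conf_int[1L], x$conf_int[2L], x$p_value))
  invisible(x)
}
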