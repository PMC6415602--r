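---
title: "Methods: diagnosing an F1 hybrid from shotgun reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnosing an F1 hybrid from shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridly)
```

## The problem and the model

A first-generation (F1) hybrid between two plant species carries one
complete haplotype from each parent. Mapped against an assembly of one
parent (the *reference species*), this architecture leaves four
independent signatures, each of which this package turns into a computed
statistic:

1. **Heterozygosity elevation.** At every site where the two parent
   species carry fixed differences, the F1 is heterozygous. Its
   within-individual ("intraspecific") SNP density is therefore elevated
   by one to two orders of magnitude over either parent's residual
   heterozygosity. `summarize_contigs()` + `density_report()` compute
   per-contig heterozygous-site counts, per-10-kb densities and
   hybrid/candidate fold ratios; the motivating *Spondias* system shows
   ~2, ~166 and ~5 SNPs/10 kb for the reference species, the hybrid and
   the second candidate, giving folds of 75.8 and 33.8.

   *A definitional note.* We count a sample's intraspecific SNPs as its
   *heterozygous* calls, not as all non-reference-containing genotypes.
   With one sequenced individual per species these are the only
   within-species variants observable, and it is the only reading under
   which a published table of this design is arithmetically coherent: a
   candidate with thousands of fixed differences from the reference
   (reported in a separate interspecific column) can still print a
   single-digit intraspecific density. The non-reference-genotype count
   is kept in the `nonref_counts` attribute for anyone who wants the
   other convention.

2. **Half sharing.** At the hybrid's heterozygous, fully co-called sites
   ("informative sites"), each of its `2n` allele observations is present
   in a true parent with probability 1/2 (the parent donated exactly one
   allele per site; the other comes from the second parent).
   `partition_alleles()` assigns every observation to the subset of
   candidates carrying that base — a Venn partition whose `"private"`
   region holds alleles seen in no candidate — and `half_sharing_test()`
   runs an exact binomial test of the shared-observation count against
   0.5 with a Clopper–Pearson interval. Sharing is defined on allele
   *values*, never VCF indices, and sites where any candidate is
   uncalled are ignored: a missing call is absence of evidence.

3. **Organellar inheritance.** The chloroplast is uniparentally,
   maternally inherited in the relevant family (Anacardiaceae), so the
   hybrid's chloroplast is essentially the maternal parent's.
   `cp_pairwise()` counts substitutions over a positional alignment
   (skipping non-ACGT columns pairwise; the tool never aligns), and
   `assign_maternal()` takes the argmin candidate with a
   second-best/best margin; margins under `tie_ratio` (default 1.1) are
   "ambiguous". On the published distances (856 vs 3292) the margin is
   3.85.

4. **Ribosomal spacer alleles.** Nuclear rDNA is a tandem array whose
   internal transcribed spacers (ITS1/ITS2) accumulate species-diagnostic
   variants; a hybrid carries one parent's allele alongside a private or
   other-parent allele. `extract_spanning_reads()` takes full-region
   haplotypes from single spanning reads — which sidesteps phasing
   entirely, at the documented cost of requiring reads (or merged/long
   reads) at least as long as the spacer — and `cluster_alleles()`
   groups identical haplotypes, merging low-support groups within
   `max_err_distinct` (default 1) mismatches of a major allele into it
   as sequencing-error shadows and discarding (never promoting) the
   rest. One mismatch is the smallest real allele difference observed in
   the motivating data, which is why it doubles as the error threshold;
   `min_support` (default 3 reads) is this package's own choice, as the
   original analysis does not state one.

A fifth, confirmatory line is an **alignment- and assembly-free (AAF)
phylogeny**: `build_profile()` collects canonical k-mers (odd k, default
31, matching the assembly k of the motivating study; `min_count = 2`
suppresses sequencing-error k-mers at ~20x coverage), and
`aaf_distance()` uses a containment transform
`d = -ln(|P∩Q| / min(|P|,|Q|)) / k`. This formula is this package's own
transparent stand-in for published AAF distances — the analysis surface
is topology recovery (the hybrid grouping with its parent), not
branch-length equality with any particular program. `nj_tree()` is
classic neighbor joining with deterministic taxon-name-order
tie-breaking and branch lengths clamped at zero.

## The verdict logic

`decide()` integrates the lines with thresholds in `verdict_params()`:

* `is_hybrid` iff the heterozygosity fold against *every* candidate is at
  least `fold_min` (default 10; the observed folds in a real F1 are
  3-8x that).
* A candidate is a **supported parent** iff its half-sharing
  Clopper–Pearson interval covers 0.5 *and* at least one corroborating
  line marks it as a genome donor: it is the assigned maternal parent,
  its alt-sharing fraction `g` reaches `g_min`, or it shares a supported
  ITS allele with the hybrid.
* A candidate is **excluded** iff it is not supported and `g < g_min`
  (default 0.2): its non-reference alleles do not account for the
  hybrid's non-reference alleles, so it cannot be the second parent.

The corroboration clause is a deliberate design decision. At the
hybrid's heterozygous sites every candidate — parent or not — carries
the reference allele, so `f ≈ 0.5` for all candidates and the CI rule
alone cannot name the parent; symmetrically, the true parent whose
genome *is* the reference contributes no non-reference alleles, so its
`g ≈ 0` and a bare `g < g_min` exclusion rule would exclude it. The
organelle, `g`, and ITS lines are precisely the evidence that breaks
this symmetry, and using them here reproduces the reasoning of the
motivating study: maternal organelle + half sharing support the
reference species; low `g` and no shared ITS allele exclude the other
candidate. When every candidate has `g < g_min`, the verdict notes that
the second parent is not among the sampled candidates — no computation
is attached to any unsampled species.

The half-sharing test is defined on allele observations (successes =
hybrid allele observations present in the candidate, trials =
`2 x informative sites`), whose expectation under the F1 model is 0.5.
A per-site "exactly one allele shared" statistic is reported
(`n_one_allele_shared`) but not tested against 0.5: for a true parent
that proportion sits near 1, not 0.5, so it carries no null of this
form.

## The synthetic world

`sim_config()` defaults state the world the pipeline is meant to
resolve, calibrated to the densities printed for the *Spondias* system:

| parameter | default | meaning |
|---|---|---|
| `n_contigs`, `contig_length` | 6 x 50 kb | six ~50 kb nuclear contigs, 300 kb total |
| `het_rate_ref` | 2e-4/bp | reference individual's heterozygosity (~2/10 kb) |
| `het_rate_nonparent` | 5e-4/bp | non-parent's heterozygosity (~5/10 kb) |
| `divergence_nonparent` | 1.55e-2/bp | non-parent fixed differences vs reference (~155/10 kb, the printed interspecific density) |
| `divergence_hidden_parent` | 1.66e-2/bp | unsampled parent vs reference-derived haplotype; the hybrid's expected het density (~166/10 kb) |
| `divergence_outgroup` | 6e-2/bp | outgroup genome (AAF/organelle/ITS outgroup) |
| `read_length`, `coverage`, `seq_error` | 100 nt, 20x, 1e-3 | single-end reads, constant Phred-30-style qualities |
| `cp_length`, `cp_divergence` | 20 kb; 5.3e-3 / 1.9e-2 / 6e-2 | chloroplast length (scaled down ~8x from a real plastome for runtime; rates chosen so pairwise counts keep the published ordering and ~4-5x maternal margin) |
| ITS geometry | 400 bp unit, two 80 bp regions, 20 copies, 200 reads/region | alleles mirror the published pattern: outgroup-private, non-parent pair 1-2 SNPs apart, hybrid shares one allele with the reference and carries private ones |

`divergence_hidden_parent` is set so the hybrid's heterozygous density
matches the printed ~166/10 kb. The hidden parent's haplotype is
derived by mutating the *second* haplotype of the reference individual,
which makes the zero-divergence limit collapse exactly onto the
reference individual (the natural degenerate case) and is statistically
indistinguishable from mutating the consensus under this
substitution-only model.

Divergence is apportioned on a tree, not a star: the reference species
and the non-parent each accrue half of `divergence_nonparent` from a
common ancestor, at which the outgroup attaches. Pairwise rates keep
their nominal values, but the reference lineage owns a positive branch
— without it the {hybrid, reference} split would have an internal
branch of essentially zero (the reference would *be* the ancestor) and
no distance method could recover the pairing reliably.

The generator is substitution-only (no indels, so mapping stays ungapped
and the chloroplast alignment is positional), uses uniform base
composition and constant quality strings (no computed statistic consults
either), emits no `N`s in reads, and is byte-deterministic under
`seed` — every stage draws from its own seed-derived stream. The
hybrid's reference-derived haplotype is a verbatim copy of one reference
haplotype, not a recombinant: an F1, not a backcross. What a green test
does **not** establish: robustness to indels and structural variation,
mapping bias on diverged regions, real base-quality error profiles,
paired-end information, rDNA concerted evolution, or contaminated/mixed
samples.

## Numerical and algorithmic choices

* **Coordinates** are 0-based half-open everywhere inside the package;
  VCF POS and the CLI's `NAME:start-end` region syntax are 1-based and
  converted exactly once at the I/O boundary.
* **Mapper**: exact k-mer seeds (default 31) at *every* read offset on
  both strands, ungapped Hamming extension, unique best placement wins,
  ties are discarded as ambiguous (deterministic pileups). If seeding
  yields no acceptable placement the mapper retries with short (13-mer)
  seeds — by pigeonhole these catch every placement within the mismatch
  budget on N-free reads of at least `(max_mismatch + 1) * 13` bp — and
  only short or N-containing reads ever reach the last-resort full
  Hamming scan. The mapper is therefore exactly equivalent to a
  brute-force best-placement oracle.
* **Caller**: a transparent threshold model, not a likelihood model —
  missing below `min_depth` (8, deliberately echoing the assembly
  coverage floor of the motivating study), qualifying alleles need
  `min_allele_count` = 3 reads and `min_allele_frac` = 0.2, homozygous
  at `hom_frac` = 0.85 of depth, heterozygous at exactly two qualifying
  alleles, missing otherwise. It is a pure function of one pileup
  column. At marginal depths (8-12) binomial allele sampling can
  legitimately cross `hom_frac`, which bounds attainable genotype
  concordance; at 20x this affects well under 1% of calls.
* **Exact binomial test**: minimum-likelihood two-sided convention
  (sum of all outcome probabilities not exceeding the observed one, the
  `binom.test()` convention), verified in the tests against exhaustive
  enumeration for all `n <= 25`; Clopper–Pearson intervals.
* **NJ**: taxa sorted by name before the first join; equal-Q ties keep
  the earliest pair; the last three nodes are resolved by the
  three-point formulas; negative branch lengths are clamped to 0.
  Two-allele ITS trees split the single edge at its midpoint.
* **Degenerate inputs** raise errors naming the offender: samples with
  zero mapped or zero spanning reads, empty k-mer profiles, zero
  informative sites, unequal-length "alignments", sub-minimum taxa.

## Known limitations

Real short-read data would need merged or long reads for the ITS module
and a gapped mapper for indel-rich genomes; the caller has no base
quality model; the AAF distance is not the published AAF program's
corrected distance and its branch lengths should be read comparatively,
not absolutely; and absolute SNP counts from any reanalysis of the
motivating system are out of reach by construction — its raw data are
not deposited under usable accessions, so the package's quantitative
claims are anchored to the printed tables (reproduced exactly from
their cells) and to truth-known simulation.
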