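## Truth-known synthetic data with the statistical structure an F1 hybrid
## diagnosis rests on: a reference-species individual with low residual
## heterozygosity, a divergent non-parent candidate, an F1 hybrid carrying
## one haplotype copied from the reference individual and one from an
## unsampled divergent parent, maternally inherited chloroplast sequences,
## and tandem rDNA spacer (ITS) arrays with species-diagnostic alleles.
## Substitution-only model throughout: no indels, so mapping stays ungapped
## and the chloroplast "alignment" is positional.

#' Default ITS allele specifications
#'
#' Two spacer regions on a single rDNA unit. The allele structure mirrors
#' the classic hybrid-diagnostic pattern: the outgroup's alleles are
#' private; the non-parent carries its own allele pair (differing by 1-2
#' SNPs, the intragenomic scale of real spacer arrays); the hybrid carries
#' one allele identical to the reference species' plus at least one private
#' allele.
#'
#' @param region_length spacer region length in bp.
#' @return list of region specs consumed by [sim_config()].
#' @export
default_its_alleles <- function(region_length = 80L) {
  v <- function(offset, shift) data.frame(offset = offset, shift = shift)
  list(
    ITS1 = list(
      name = "ITS1", start = 60L, length = region_length,
      alleles = list(
        list(id = "shared_ref",  samples = c("reference", "hybrid"),
             variants = v(integer(0), integer(0))),
        list(id = "hybrid_priv", samples = "hybrid",
             variants = v(c(12L, 50L), c(2L, 2L))),
        list(id = "nonpar_a",    samples = "nonparent",
             variants = v(c(8L, 18L, 28L), c(1L, 1L, 1L))),
        list(id = "nonpar_b",    samples = "nonparent",
             variants = v(c(8L, 18L, 28L, 40L), c(1L, 1L, 1L, 1L))),
        list(id = "outgrp",      samples = "outgroup",
             variants = v(c(5L, 15L, 25L, 35L), c(1L, 1L, 1L, 1L)))
      )
    ),
    ITS2 = list(
      name = "ITS2", start = 220L, length = region_length,
      alleles = list(
        list(id = "shared_ref",  samples = c("reference", "hybrid"),
             variants = v(integer(0), integer(0))),
        list(id = "ref_b",       samples = "reference",
             variants = v(10L, 1L)),
        list(id = "hybrid_priv", samples = "hybrid",
             variants = v(c(20L, 55L), c(2L, 2L))),
        list(id = "nonpar_a",    samples = "nonparent",
             variants = v(c(8L, 30L, 48L), c(1L, 1L, 1L))),
        list(id = "nonpar_b",    samples = "nonparent",
             variants = v(c(8L, 30L, 48L, 62L, 70L), c(1L, 1L, 1L, 1L, 1L))),
        list(id = "outgrp_a",    samples = "outgroup",
             variants = v(c(5L, 15L, 25L, 35L, 45L), rep(1L, 5))),
        list(id = "outgrp_b",    samples = "outgroup",
             variants = v(c(5L, 15L, 25L, 35L, 45L, 58L), rep(1L, 6)))
      )
    )
  )
}

#' Simulation configuration
#'
#' Defaults describe the three-genome design the pipeline is built for, at
#' the densities printed for the motivating system: residual
#' heterozygosity of ~2 sites/10 kb in the reference individual, ~5/10 kb
#' in the divergent non-parent (whose fixed differences from the
#' reference run at `divergence_nonparent`, ~155/10 kb), and a hybrid
#' heterozygous-site density of ~166/10 kb driven by the unsampled
#' second parent's divergence.
#'
#' @param seed integer master seed; every stage derives its own stream, so
#'   identical configs give byte-identical outputs.
#' @param n_contigs,contig_length reference contigs to simulate.
#' @param het_rate_ref,het_rate_nonparent heterozygous sites per bp.
#' @param divergence_nonparent fixed-difference rate per bp between the
#'   non-parent and the reference species (default 1.55e-2, i.e. ~155
#'   fixed differences per 10 kb, the printed interspecific density of
#'   the motivating system).
#' @param divergence_hidden_parent per-bp divergence of the unsampled
#'   second parent's haplotype from the reference-derived haplotype; this
#'   is the hybrid's expected heterozygous-site rate (default 1.66e-2,
#'   i.e. ~166/10 kb).
#' @param divergence_outgroup per-bp divergence of the outgroup genome.
#' @param read_length,coverage,seq_error read simulation parameters
#'   (single-end reads, constant Phred+33 qualities, substitution errors
#'   only).
#' @param cp_length chloroplast sequence length.
#' @param cp_divergence named per-bp substitution rates: `hybrid_private`
#'   (hybrid vs its maternal parent), `nonparent`, `outgroup` (each vs the
#'   reference chloroplast).
#' @param its_unit_length,its_region_length,its_copies,its_read_length,
#'   its_reads_per_region rDNA unit geometry, tandem copies per allele
#'   set, and ITS read simulation; ITS reads are at least as long as the
#'   region so every read can span it.
#' @param its_allele_specs region/allele structure, see
#'   [default_its_alleles()].
#' @param samples sample names in the fixed roles
#'   reference/hybrid/nonparent/outgroup.
#' @param hybrid_type `"f1"` for a true hybrid, `"clone"` for the negative
#'   control (the "hybrid" is a clone of the reference individual).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 6L,
                       contig_length = 50000L,
                       het_rate_ref = 2e-4,
                       het_rate_nonparent = 5e-4,
                       divergence_nonparent = 1.55e-2,
                       divergence_hidden_parent = 1.66e-2,
                       divergence_outgroup = 6e-2,
                       read_length = 100L,
                       coverage = 20,
                       seq_error = 1e-3,
                       cp_length = 20000L,
                       cp_divergence = c(hybrid_private = 5.3e-3,
                                         nonparent = 1.9e-2,
                                         outgroup = 6e-2),
                       its_unit_length = 400L,
                       its_region_length = 80L,
                       its_copies = 20L,
                       its_read_length = 100L,
                       its_reads_per_region = 200L,
                       its_allele_specs = default_its_alleles(its_region_length),
                       samples = c(reference = "reference",
                                   hybrid = "hybrid",
                                   nonparent = "nonparent",
                                   outgroup = "outgroup"),
                       hybrid_type = c("f1", "clone")) {
  hybrid_type <- match.arg(hybrid_type)
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              het_rate_ref = het_rate_ref,
              het_rate_nonparent = het_rate_nonparent,
              divergence_nonparent = divergence_nonparent,
              divergence_hidden_parent = divergence_hidden_parent,
              divergence_outgroup = divergence_outgroup,
              read_length = as.integer(read_length), coverage = coverage,
              seq_error = seq_error, cp_length = as.integer(cp_length),
              cp_divergence = cp_divergence,
              its_unit_length = as.integer(its_unit_length),
              its_region_length = as.integer(its_region_length),
              its_copies = as.integer(its_copies),
              its_read_length = as.integer(its_read_length),
              its_reads_per_region = as.integer(its_reads_per_region),
              its_allele_specs = its_allele_specs,
              samples = samples, hybrid_type = hybrid_type)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$het_rate_ref, cfg$het_rate_nonparent,
             cfg$divergence_nonparent, cfg$divergence_hidden_parent,
             cfg$divergence_outgroup, cfg$seq_error, cfg$cp_divergence)
  if (any(rates < 0 | rates > 0.25)) {
    stop("all mutation/error rates must lie in [0, 0.25]", call. = FALSE)
  }
  stopifnot(cfg$n_contigs >= 1L, cfg$contig_length >= 1L,
            cfg$read_length >= 1L, cfg$read_length <= cfg$contig_length,
            cfg$coverage > 0, cfg$cp_length >= 1L)
  if (cfg$its_read_length < cfg$its_region_length) {
    stop("its_read_length must be >= its_region_length so reads can span ",
         "the region", call. = FALSE)
  }
  req <- c("reference", "hybrid", "nonparent", "outgroup")
  if (!all(req %in% names(cfg$samples))) {
    stop("samples must name the roles: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (rg in cfg$its_allele_specs) {
    stopifnot(!is.null(rg$name), rg$length >= 1L,
              rg$start + rg$length <= cfg$its_unit_length)
    for (al in rg$alleles) {
      if (any(al$variants$offset >= rg$length | al$variants$offset < 0L)) {
        stop("ITS allele '", al$id, "' in region '", rg$name,
             "' has a variant position outside the region", call. = FALSE)
      }
      if (!all(al$variants$shift %in% 1:3)) {
        stop("ITS variant shifts must be in 1..3", call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

## het sites: Poisson(rate*L) positions; the alternate base goes on one of
## the two haplotypes at random. Returns list(h1, h2, pos, alt_on).
make_het_pair <- function(base_seq, rate) {
  mut <- mutate_seq(base_seq, rate)
  if (length(mut$pos) == 0L) {
    return(list(h1 = base_seq, h2 = base_seq, pos = integer(0),
                alt_on = integer(0)))
  }
  alt_on <- sample(1:2, length(mut$pos), replace = TRUE)
  ch1 <- strsplit(base_seq, "", fixed = TRUE)[[1L]]
  ch2 <- ch1
  sel1 <- mut$pos[alt_on == 1L]
  sel2 <- mut$pos[alt_on == 2L]
  ch1[sel1] <- mut$to[alt_on == 1L]
  ch2[sel2] <- mut$to[alt_on == 2L]
  list(h1 = paste(ch1, collapse = ""), h2 = paste(ch2, collapse = ""),
       pos = mut$pos, alt_on = alt_on)
}

#' Simulate reference contigs and the reference individual
#'
#' Contigs are i.i.d. uniform-base sequences; the reference individual's
#' two haplotypes differ at `Poisson(het_rate_ref * length)` sites per
#' contig.
#'
#' @param cfg a [sim_config()].
#' @return list with `contigs` (named character vector) and `ref_haps`
#'   (per-contig list of the individual's two haplotypes).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 101L), {
    nm <- sprintf("contig_%02d", seq_len(cfg$n_contigs))
    contigs <- setNames(vapply(nm, function(x) random_dna(cfg$contig_length),
                               ""), nm)
    ref_haps <- lapply(contigs, make_het_pair, rate = cfg$het_rate_ref)
    list(contigs = contigs, ref_haps = ref_haps)
  })
}

## character at 1-based positions of a string
chars_at <- function(seq, pos) {
  if (length(pos) == 0L) return(character(0))
  substring(seq, pos, pos)
}

sorted_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

#' Simulate the sample genomes and the truth set
#'
#' Builds diploid haplotypes for the reference individual, the non-parent
#' candidate (fixed differences at `divergence_nonparent` plus its own
#' heterozygous sites), the hybrid (one haplotype copied from the
#' reference individual, the other from the unsampled parent at
#' `divergence_hidden_parent`), and a homozygous outgroup. The truth set
#' records every variant site of the three genotyped samples.
#'
#' @param cfg a [sim_config()].
#' @param ref output of [simulate_reference()].
#' @return an object of class `truth_set`: `haplotypes` (per sample, per
#'   contig, two strings), `variants` (data frame of true variant sites
#'   with per-sample sorted genotype strings like `"A/T"`), `maternal`,
#'   and per-sample expected heterozygous-site rates.
#' @export
simulate_samples <- function(cfg, ref) {
  stopifnot(inherits(cfg, "sim_config"))
  sm <- cfg$samples
  with_seed(derive_seed(cfg$seed, 202L), {
    haps <- list()
    for (contig in names(ref$contigs)) {
      cs <- ref$contigs[[contig]]
      rh <- ref$ref_haps[[contig]]
      ## Divergence is apportioned on the species tree: the reference and
      ## the non-parent each accrue half of their pairwise divergence
      ## from a common ancestor, and the outgroup attaches at that
      ## ancestor. This keeps pairwise rates at their nominal values
      ## while giving the reference lineage its own positive branch (as
      ## in the real phylogeny), which is what makes the
      ## {hybrid, reference} split recoverable by distance methods.
      anc <- mutate_seq(cs, cfg$divergence_nonparent / 2)$seq
      np_base <- mutate_seq(anc, cfg$divergence_nonparent / 2)
      np <- make_het_pair(np_base$seq, cfg$het_rate_nonparent)
      if (cfg$hybrid_type == "f1") {
        hidden <- mutate_seq(rh$h2, cfg$divergence_hidden_parent)
        hy <- list(h1 = rh$h1, h2 = hidden$seq)
      } else {
        hy <- list(h1 = rh$h1, h2 = rh$h2)
      }
      og <- mutate_seq(anc, cfg$divergence_outgroup)
      haps[[contig]] <- list(
        reference = c(rh$h1, rh$h2),
        hybrid = c(hy$h1, hy$h2),
        nonparent = c(np$h1, np$h2),
        outgroup = c(og$seq, og$seq)
      )
    }
    genotyped <- c("reference", "hybrid", "nonparent")
    vars <- lapply(names(ref$contigs), function(contig) {
      cs <- ref$contigs[[contig]]
      h <- haps[[contig]]
      pos <- sort(unique(unlist(lapply(genotyped, function(s) {
        c1 <- utf8ToInt(h[[s]][1L]) != utf8ToInt(cs)
        c2 <- utf8ToInt(h[[s]][2L]) != utf8ToInt(cs)
        which(c1 | c2)
      }))))
      if (length(pos) == 0L) return(NULL)
      out <- data.frame(contig = contig, pos = pos - 1L,
                        ref = chars_at(cs, pos), stringsAsFactors = FALSE)
      for (s in genotyped) {
        out[[sm[[s]]]] <- sorted_pair(chars_at(h[[s]][1L], pos),
                                      chars_at(h[[s]][2L], pos))
      }
      out
    })
    vars <- do.call(rbind, vars[!vapply(vars, is.null, TRUE)])
    rownames(vars) <- NULL
    ## rename haplotype roles to configured sample names
    haps <- lapply(haps, function(h) setNames(h, sm[names(h)]))
    structure(list(
      samples = unname(sm), haplotypes = haps, variants = vars,
      maternal = sm[["reference"]],
      expected_het_rate = c(
        setNames(cfg$het_rate_ref, sm[["reference"]]),
        setNames(if (cfg$hybrid_type == "f1")
          cfg$divergence_hidden_parent + cfg$het_rate_ref
          else cfg$het_rate_ref, sm[["hybrid"]]),
        setNames(cfg$het_rate_nonparent, sm[["nonparent"]])),
      hybrid_type = cfg$hybrid_type
    ), class = "truth_set")
  })
}

#' Simulate single-end shotgun reads for one sample
#'
#' Reads are drawn uniformly from both haplotypes of each contig
#' (`coverage * length / read_length` reads per contig), placed on a
#' random strand, and hit by substitution errors at `seq_error` per base.
#' Qualities are a constant Phred+33 string. Read ids encode the true
#' source (`sample|contig|start|strand|haplotype|index`).
#'
#' @param cfg a [sim_config()].
#' @param truth a `truth_set` from [simulate_samples()].
#' @param sample sample name (one of the configured names).
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
simulate_reads <- function(cfg, truth, sample) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_set"))
  if (!sample %in% truth$samples) {
    stop("unknown sample '", sample, "'", call. = FALSE)
  }
  s_i <- match(sample, truth$samples)
  rl <- cfg$read_length
  with_seed(derive_seed(cfg$seed, 300L + s_i), {
    per_contig <- lapply(names(truth$haplotypes), function(contig) {
      h <- truth$haplotypes[[contig]][[sample]]
      L <- nchar(h[1L])
      n <- as.integer(round(cfg$coverage * L / rl))
      hap <- sample(1:2, n, replace = TRUE)
      start0 <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
      strand <- sample(c("+", "-"), n, replace = TRUE)
      seq <- character(n)
      for (k in 1:2) {
        sel <- hap == k
        seq[sel] <- substring(h[k], start0[sel] + 1L, start0[sel] + rl)
      }
      seq[strand == "-"] <- revcomp(seq[strand == "-"])
      data.frame(
        id = sprintf("%s|%s|%d|%s|h%d|%d", sample, contig, start0, strand,
                     hap, seq_len(n)),
        seq = seq, stringsAsFactors = FALSE)
    })
    reads <- do.call(rbind, per_contig)
    n_err <- rbinom(1L, nrow(reads) * rl, cfg$seq_error)
    if (n_err > 0L) {
      at <- sample.int(nrow(reads) * rl, n_err)
      ri <- ((at - 1L) %/% rl) + 1L
      pj <- ((at - 1L) %% rl) + 1L
      for (e in seq_len(n_err)) {
        old <- substr(reads$seq[ri[e]], pj[e], pj[e])
        substr(reads$seq[ri[e]], pj[e], pj[e]) <-
          sample(setdiff(DNA_BASES, old), 1L)
      }
    }
    reads$qual <- strrep("?", rl)  # constant Phred 30
    rownames(reads) <- NULL
    reads
  })
}

#' Simulate aligned chloroplast sequences
#'
#' The hybrid's chloroplast is the maternal parent's sequence with a small
#' number of private substitutions; all sequences are equal length with
#' substitutions only, i.e. positionally aligned.
#'
#' @param cfg a [sim_config()].
#' @return list with `alignment` (named character vector, one sequence per
#'   sample) and `maternal` (the true maternal parent's sample name).
#' @export
simulate_organelles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sm <- cfg$samples
  with_seed(derive_seed(cfg$seed, 404L), {
    ref_cp <- random_dna(cfg$cp_length)
    aln <- setNames(c(
      ref_cp,
      mutate_seq(ref_cp, cfg$cp_divergence[["hybrid_private"]])$seq,
      mutate_seq(ref_cp, cfg$cp_divergence[["nonparent"]])$seq,
      mutate_seq(ref_cp, cfg$cp_divergence[["outgroup"]])$seq
    ), sm[c("reference", "hybrid", "nonparent", "outgroup")])
    list(alignment = aln, maternal = sm[["reference"]])
  })
}

## region sequence of an allele: backbone region with cyclic-shift variants
its_allele_seq <- function(region_seq, variants) {
  if (nrow(variants) == 0L) return(region_seq)
  ch <- strsplit(region_seq, "", fixed = TRUE)[[1L]]
  i <- variants$offset + 1L
  ch[i] <- mapply(shift_base, ch[i], variants$shift)
  paste(ch, collapse = "")
}

#' Simulate ITS reads from tandem rDNA arrays
#'
#' Each sample carries a set of spacer alleles (per
#' `cfg$its_allele_specs`), each present in `its_copies` tandem copies
#' split equally among the sample's alleles; reads long enough to span
#' each region are drawn with allele probabilities proportional to copy
#' number. Under `hybrid_type = "clone"` the hybrid carries the
#' reference's alleles.
#'
#' @param cfg a [sim_config()].
#' @return list with `its_ref` (named character vector: the rDNA unit
#'   backbone), `regions` (per region: name, `start`/`end` 0-based
#'   half-open on the unit), `reads` (per sample data frame of spanning
#'   reads over all regions), and `truth` (per region: allele sequences
#'   and per-sample allele id sets).
#' @export
simulate_its_reads <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sm <- cfg$samples
  rl <- cfg$its_read_length
  with_seed(derive_seed(cfg$seed, 505L), {
    unit <- random_dna(cfg$its_unit_length)
    regions <- lapply(cfg$its_allele_specs, function(rg) {
      list(name = rg$name, start = rg$start, end = rg$start + rg$length)
    })
    truth <- list()
    reads_by_sample <- setNames(
      rep(list(data.frame(id = character(0), seq = character(0),
                          qual = character(0), stringsAsFactors = FALSE)),
          length(sm)), unname(sm))
    for (rg in cfg$its_allele_specs) {
      region_seq <- substr(unit, rg$start + 1L, rg$start + rg$length)
      allele_seqs <- setNames(
        vapply(rg$alleles, function(a) its_allele_seq(region_seq, a$variants),
               ""),
        vapply(rg$alleles, `[[`, "", "id"))
      membership <- lapply(rg$alleles, `[[`, "samples")
      names(membership) <- names(allele_seqs)
      sample_alleles <- lapply(
        setNames(names(sm), names(sm)),
        function(role) names(membership)[vapply(membership, function(s)
          role %in% s, TRUE)])
      if (cfg$hybrid_type == "clone") {
        sample_alleles$hybrid <- sample_alleles$reference
      }
      truth[[rg$name]] <- list(
        alleles = allele_seqs,
        sample_alleles = setNames(sample_alleles[names(sm)], unname(sm))
      )
      lo <- max(0L, rg$start + rg$length - rl)
      hi <- min(rg$start, cfg$its_unit_length - rl)
      stopifnot(lo <= hi)
      for (role in names(sm)) {
        ids <- sample_alleles[[role]]
        if (length(ids) == 0L) next
        copies <- rep(cfg$its_copies %/% length(ids), length(ids))
        copies[seq_len(cfg$its_copies %% length(ids))] <-
          copies[seq_len(cfg$its_copies %% length(ids))] + 1L
        n <- cfg$its_reads_per_region
        which_allele <- sample(ids, n, replace = TRUE, prob = copies)
        start0 <- if (lo == hi) rep(lo, n) else
          lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
        strand <- sample(c("+", "-"), n, replace = TRUE)
        seq <- character(n)
        for (aid in ids) {
          sel <- which_allele == aid
          if (!any(sel)) next
          unit_a <- unit
          substr(unit_a, rg$start + 1L, rg$start + rg$length) <-
            allele_seqs[[aid]]
          seq[sel] <- substring(unit_a, start0[sel] + 1L, start0[sel] + rl)
        }
        seq[strand == "-"] <- revcomp(seq[strand == "-"])
        n_err <- rbinom(1L, n * rl, cfg$seq_error)
        if (n_err > 0L) {
          at <- sample.int(n * rl, n_err)
          ri <- ((at - 1L) %/% rl) + 1L
          pj <- ((at - 1L) %% rl) + 1L
          for (e in seq_len(n_err)) {
            old <- substr(seq[ri[e]], pj[e], pj[e])
            substr(seq[ri[e]], pj[e], pj[e]) <-
              sample(setdiff(DNA_BASES, old), 1L)
          }
        }
        df <- data.frame(
          id = sprintf("%s|%s|%s|%d", sm[[role]], rg$name, which_allele,
                       seq_len(n)),
          seq = seq, qual = strrep("?", rl), stringsAsFactors = FALSE)
        reads_by_sample[[sm[[role]]]] <-
          rbind(reads_by_sample[[sm[[role]]]], df)
      }
    }
    list(its_ref = c(rdna_unit = unit), regions = regions,
         reads = reads_by_sample, truth = truth)
  })
}

#' Simulate a complete truth-known data set
#'
#' Convenience wrapper chaining [simulate_reference()],
#' [simulate_samples()], [simulate_reads()] (for every sample),
#' [simulate_organelles()] and [simulate_its_reads()].
#'
#' @param cfg a [sim_config()].
#' @param read_samples samples to simulate shotgun reads for (default:
#'   all).
#' @return list with `config`, `contigs`, `truth`, `reads` (named list of
#'   read data frames), `cp`, and `its`.
#' @export
simulate_dataset <- function(cfg, read_samples = unname(cfg$samples)) {
  ref <- simulate_reference(cfg)
  truth <- simulate_samples(cfg, ref)
  reads <- lapply(setNames(read_samples, read_samples),
                  function(s) simulate_reads(cfg, truth, s))
  list(config = cfg, contigs = ref$contigs, truth = truth, reads = reads,
       cp = simulate_organelles(cfg), its = simulate_its_reads(cfg))
}

#' Write a simulated data set to an output directory
#'
#' Emits `ref.fasta`, `<sample>.fastq`, `cp_aln.fasta`, `its_ref.fasta`,
#' `its_<sample>.fastq` and `truth.json`.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$contigs, file.path(outdir, "ref.fasta"))
  for (s in names(sim$reads)) {
    write_fastq(sim$reads[[s]], file.path(outdir, paste0(s, ".fastq")))
  }
  write_fasta(sim$cp$alignment, file.path(outdir, "cp_aln.fasta"))
  write_fasta(sim$its$its_ref, file.path(outdir, "its_ref.fasta"))
  for (s in names(sim$its$reads)) {
    if (nrow(sim$its$reads[[s]]) > 0L) {
      write_fastq(sim$its$reads[[s]],
                  file.path(outdir, paste0("its_", s, ".fastq")))
    }
  }
  truth_json <- list(
    maternal = sim$truth$maternal,
    hybrid_type = sim$truth$hybrid_type,
    expected_het_rate = as.list(sim$truth$expected_het_rate),
    n_true_variant_sites = nrow(sim$truth$variants),
    its = lapply(sim$its$truth, function(t)
      list(alleles = as.list(t$alleles),
           sample_alleles = t$sample_alleles)),
    regions = sim$its$regions
  )
  jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
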