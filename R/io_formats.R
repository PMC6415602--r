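## I/O for the standard formats the pipeline touches: FASTA, FASTQ
## (Sanger/Phred+33), a GT:DP subset of VCF v4.2, and Newick trees.
##
## Position conventions: everything inside the package is 0-based,
## half-open; VCF POS (and CLI region syntax) are 1-based and converted
## exactly once, here at the I/O boundary.

FASTA_ALPHABET_RE <- "^[ACGTN]*$"

#' Read a FASTA file
#'
#' Sequences are uppercased and validated against the `A,C,G,T,N`
#' alphabet; anything else (gaps, IUPAC ambiguity codes) is a format
#' error.
#'
#' @param path path to a FASTA file.
#' @return named character vector: names are record ids, values are
#'   uppercase DNA sequences.
#' @seealso [write_fasta()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(c(c1 = "ACGT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA in '", path, "': empty record id (record ",
         which(!nzchar(ids))[1L], ")", call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("malformed FASTA in '", path, "': empty sequence for record '",
         ids[which(nchar(seqs) == 0L)[1L]], "'", call. = FALSE)
  }
  bad <- !grepl(FASTA_ALPHABET_RE, seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    stop("invalid character '", ch, "' in record '", ids[i], "' of '",
         path, "' (allowed: A,C,G,T,N)", call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param records named character vector of DNA sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.character(records), !is.null(names(records)),
            all(nzchar(names(records))))
  x <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file (Sanger/Phred+33 qualities).
#' @return data frame with columns `id`, `seq`, `qual`.
#' @seealso [write_fastq()]
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    stop("malformed FASTQ in '", path, "': truncated record ",
         n_lines %/% 4L + 1L, call. = FALSE)
  }
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(seq = toupper(as.character(x)),
         qual = as.character(S4Vectors::mcols(x)$qualities),
         id = names(x))
  }, error = function(e) stop("malformed FASTQ in '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  qual <- parsed$qual
  seqs <- parsed$seq
  ids <- sub("\\s.*$", "", parsed$id)
  bad <- nchar(qual) != nchar(seqs)
  if (any(bad)) {
    stop("FASTQ record ", which(bad)[1L], " ('", ids[which(bad)[1L]],
         "') in '", path, "': quality length != sequence length",
         call. = FALSE)
  }
  data.frame(id = unname(ids), seq = unname(seqs), qual = unname(qual),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$qual) != nchar(reads$seq))) {
    stop("quality length != sequence length", call. = FALSE)
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

## ---- multi-sample VCF (GT:DP subset of v4.2) --------------------------

#' Construct a multi-sample genotype set
#'
#' The in-memory equivalent of a GT:DP multi-sample VCF. Sites carry
#' 0-based positions; allele values are single bases; genotypes are stored
#' as two allele-index matrices (`NA` = missing call).
#'
#' @param samples character vector of sample names.
#' @param sites data frame with columns `contig`, `pos` (0-based integer),
#'   `ref` (single base), `alts` (comma-joined alternate bases, non-empty).
#' @param gt1,gt2 integer matrices (sites x samples) of allele indices
#'   (0 = reference); both `NA` for a missing call.
#' @param dp integer matrix (sites x samples) of read depths.
#' @param n_skipped count of non-SNV records skipped at read time.
#' @return an object of class `hy_vcf`.
#' @export
hy_vcf <- function(samples, sites, gt1, gt2, dp, n_skipped = 0L) {
  obj <- structure(
    list(samples = as.character(samples), sites = sites,
         gt1 = gt1, gt2 = gt2, dp = dp, n_skipped = as.integer(n_skipped)),
    class = "hy_vcf"
  )
  validate_hy_vcf(obj)
  obj
}

validate_hy_vcf <- function(x) {
  stopifnot(inherits(x, "hy_vcf"))
  s <- x$sites
  stopifnot(is.data.frame(s),
            all(c("contig", "pos", "ref", "alts") %in% names(s)))
  n <- nrow(s)
  for (m in c("gt1", "gt2", "dp")) {
    stopifnot(is.matrix(x[[m]]), nrow(x[[m]]) == n,
              ncol(x[[m]]) == length(x$samples))
  }
  if (n > 0L) {
    stopifnot(all(s$pos >= 0L), all(nchar(s$ref) == 1L),
              all(nzchar(s$alts)))
    n_all <- 1L + lengths(strsplit(s$alts, ",", fixed = TRUE))
    stopifnot(all(x$gt1 < n_all | is.na(x$gt1)),
              all(x$gt2 < n_all | is.na(x$gt2)),
              all(is.na(x$gt1) == is.na(x$gt2)))
  }
  invisible(x)
}

#' @export
print.hy_vcf <- function(x, ...) {
  cat("<hy_vcf> ", nrow(x$sites), " SNV sites x ", length(x$samples),
      " samples (", paste(x$samples, collapse = ", "), ")",
      if (x$n_skipped > 0L) paste0("; ", x$n_skipped, " non-SNV skipped"),
      "\n", sep = "")
  invisible(x)
}

## list of per-site allele vectors c(ref, alt1, ...)
site_alleles <- function(vcf) {
  mapply(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1L]]),
         vcf$sites$ref, vcf$sites$alts, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

## sites x samples character matrices of the two genotype bases (NA missing)
genotype_bases <- function(vcf) {
  al <- site_alleles(vcf)
  n <- nrow(vcf$sites)
  pick <- function(gt) {
    out <- matrix(NA_character_, n, length(vcf$samples),
                  dimnames = list(NULL, vcf$samples))
    for (j in seq_along(vcf$samples)) {
      idx <- gt[, j]
      ok <- !is.na(idx)
      if (any(ok)) {
        out[ok, j] <- vapply(which(ok), function(i) al[[i]][idx[i] + 1L], "")
      }
    }
    out
  }
  list(b1 = pick(vcf$gt1), b2 = pick(vcf$gt2))
}

#' Read a multi-sample VCF
#'
#' Keeps biallelic and multiallelic SNV records; other records (indels,
#' symbolic alleles, missing ALT) are skipped and counted in the result's
#' `n_skipped` field. Half calls and non-diploid GT values are treated as
#' missing. POS is converted to the package-internal 0-based convention.
#'
#' @param path path to an uncompressed VCF v4.x file with a GT (and
#'   optionally DP) FORMAT field.
#' @return an object of class [hy_vcf()].
#' @export
read_vcf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0L) {
    stop("missing #CHROM header line in '", path, "'", call. = FALSE)
  }
  hdr <- hdr[1L]
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) {
    stop("VCF '", path, "' has no sample columns", call. = FALSE)
  }
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  n_skipped <- 0L
  recs <- strsplit(body, "\t", fixed = TRUE)
  keep <- logical(length(recs))
  alts_l <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    f <- recs[[i]]
    ref <- toupper(f[4L])
    alts <- toupper(strsplit(f[5L], ",", fixed = TRUE)[[1L]])
    snv <- nchar(ref) == 1L && ref %in% DNA_BASES &&
      length(alts) >= 1L && all(nchar(alts) == 1L) &&
      all(alts %in% DNA_BASES)
    if (snv) {
      keep[i] <- TRUE
      alts_l[[i]] <- alts
    } else {
      n_skipped <- n_skipped + 1L
    }
  }
  recs <- recs[keep]
  alts_l <- alts_l[keep]
  n <- length(recs)
  ns <- length(samples)
  gt1 <- gt2 <- dp <- matrix(NA_integer_, n, ns,
                             dimnames = list(NULL, samples))
  sites <- data.frame(
    contig = vapply(recs, `[`, "", 1L),
    pos = as.integer(vapply(recs, `[`, "", 2L)) - 1L,
    ref = toupper(vapply(recs, `[`, "", 4L)),
    alts = vapply(alts_l, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    f <- recs[[i]]
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    gt_i <- match("GT", fmt)
    dp_i <- match("DP", fmt)
    if (is.na(gt_i)) next
    for (j in seq_len(ns)) {
      parts <- strsplit(f[9L + j], ":", fixed = TRUE)[[1L]]
      g <- strsplit(parts[gt_i], "[/|]")[[1L]]
      if (length(g) == 2L && !any(g == ".")) {
        gt1[i, j] <- as.integer(g[1L])
        gt2[i, j] <- as.integer(g[2L])
      }
      if (!is.na(dp_i) && length(parts) >= dp_i && parts[dp_i] != ".") {
        dp[i, j] <- as.integer(parts[dp_i])
      }
    }
  }
  hy_vcf(samples, sites, gt1, gt2, dp, n_skipped)
}

#' Write a multi-sample VCF (v4.2, GT:DP)
#'
#' @param vcf an [hy_vcf()] object.
#' @param path output path.
#' @param contig_lengths optional named integer vector; when supplied,
#'   `##contig` header lines are emitted.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path, contig_lengths = NULL) {
  validate_hy_vcf(vcf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hybridly",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
  ), con)
  if (!is.null(contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), as.integer(contig_lengths)),
               con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vcf$samples), collapse = "\t"), con)
  n <- nrow(vcf$sites)
  if (n > 0L) {
    gt_str <- matrix("./.", n, length(vcf$samples))
    ok <- !is.na(vcf$gt1)
    a <- pmin(vcf$gt1, vcf$gt2)
    b <- pmax(vcf$gt1, vcf$gt2)
    gt_str[ok] <- paste0(a[ok], "/", b[ok])
    dp_str <- ifelse(is.na(vcf$dp), ".", as.character(vcf$dp))
    cells <- matrix(paste0(gt_str, ":", dp_str), n)
    rows <- paste(vcf$sites$contig, vcf$sites$pos + 1L, ".", vcf$sites$ref,
                  vcf$sites$alts, ".", ".", ".", "GT:DP",
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

## ---- Newick ------------------------------------------------------------

quote_newick_label <- function(x) {
  needs <- grepl("[][(){}:;,'\"[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs], fixed = TRUE), "'")
  x
}

newick_string <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  labs <- quote_newick_label(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  fmt_len <- function(e) {
    if (!has_len) "" else paste0(":", format(tree$edge.length[e],
                                             digits = 10, trim = TRUE,
                                             scientific = FALSE))
  }
  rec <- function(node) {
    if (node <= ntip) return(labs[node])
    es <- kids[[as.character(node)]]
    paste0("(", paste0(vapply(es, function(e) {
      paste0(rec(tree$edge[e, 2L]), fmt_len(e))
    }, ""), collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Write a tree in Newick format
#'
#' Serializes an [ape::read.tree()]-compatible `phylo` object, quoting
#' labels that contain spaces or Newick metacharacters.
#'
#' @param tree a `phylo` object (rooted or unrooted), with or without
#'   branch lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}
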