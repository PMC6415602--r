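DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized over its input; `N` maps to `N`.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAN"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  revcomp_cpp(x)
}

## Evaluate `code` under a fixed RNG seed, restoring caller RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Derive a sub-seed for an operation from a master seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset)
}

## Random uniform-composition DNA string of length n (uses current RNG).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Substitute bases of a sequence (as character string) at Poisson(rate * L)
## uniformly chosen distinct positions; new base drawn from the 3 others.
## Returns list(seq, pos (1-based), from, to).
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rpois(1L, rate * n)
  k <- min(k, n)
  if (k == 0L) {
    return(list(seq = seq, pos = integer(0), from = character(0),
                to = character(0)))
  }
  pos <- sort(sample.int(n, k))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  from <- chars[pos]
  to <- vapply(from, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  chars[pos] <- to
  list(seq = paste(chars, collapse = ""), pos = pos, from = from, to = to)
}

## Cyclic base shift used by deterministic ITS allele specs: shift 1 maps
## A->C->G->T->A; always yields a base different from the input for 1..3.
shift_base <- function(base, shift) {
  i <- match(base, DNA_BASES)
  DNA_BASES[((i - 1L + shift) %% 4L) + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
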