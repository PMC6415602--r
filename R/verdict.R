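## Integration of the evidence lines into a single parentage verdict:
## heterozygosity fold-elevation establishes hybridity; the half-sharing
## confidence interval plus a corroborating line (maternal organelle,
## alt-allele sharing, or a shared ITS allele) supports a candidate as a
## parent; a candidate that is neither supported nor plausibly the donor
## of the hybrid's non-reference alleles (g below threshold) is excluded.
##
## Why the corroboration clause: at the hybrid's heterozygous sites every
## candidate carries the reference allele, so the sharing fraction f sits
## near 0.5 for parents and non-parents alike; f alone cannot name the
## parent. The organellar assignment, the alt-sharing fraction g, and the
## ITS allele table are exactly the lines that break that symmetry.

#' Verdict thresholds
#'
#' @param fold_min minimal hybrid/candidate heterozygosity fold to call
#'   genome-wide SNP elevation.
#' @param g_min minimal alt-sharing fraction for a candidate to remain a
#'   plausible second parent.
#' @param tie_ratio maternal-assignment margin below which the organelle
#'   call is ambiguous.
#' @param conf_level confidence level of the half-sharing interval.
#' @return object of class `verdict_params`.
#' @export
verdict_params <- function(fold_min = 10, g_min = 0.2, tie_ratio = 1.1,
                           conf_level = 0.95) {
  stopifnot(fold_min > 1, g_min > 0, g_min < 1)
  structure(list(fold_min = fold_min, g_min = g_min, tie_ratio = tie_ratio,
                 conf_level = conf_level), class = "verdict_params")
}

## does the hybrid share >= 1 supported ITS allele with `sample`?
its_shares_allele <- function(its_tables, hybrid, sample) {
  any(vapply(its_tables, function(tb) {
    if (!all(c(hybrid, sample) %in% colnames(tb$support))) return(FALSE)
    any(tb$support[, hybrid] >= tb$min_support &
          tb$support[, sample] >= tb$min_support)
  }, logical(1L)))
}

#' Decide the hybrid-origin verdict
#'
#' @param density_report a [density_report()] (or
#'   [density_from_totals()]) result; its fold ratios drive the
#'   is-hybrid call.
#' @param sharing_tests named list of [half_sharing_test()] results, one
#'   per candidate.
#' @param partition the [partition_alleles()] result the tests came from.
#' @param maternal_result an [assign_maternal()] result.
#' @param its_tables optional named list of [cluster_alleles()] results;
#'   enables the ITS-consistency check.
#' @param params a [verdict_params()].
#' @return object of class `hybrid_verdict`: `is_hybrid` (+ `folds`),
#'   `maternal` (+ `margin`), `supported_parents`, `excluded_candidates`,
#'   `indeterminate`, `its_consistent`, `narrative`, `notes`.
#' @export
decide <- function(density_report, sharing_tests, partition,
                   maternal_result, its_tables = NULL,
                   params = verdict_params()) {
  stopifnot(inherits(density_report, "density_report"),
            inherits(partition, "allele_partition"),
            inherits(params, "verdict_params"))
  hybrid <- partition$hybrid
  candidates <- partition$candidates
  ## sample-name consistency across the evidence lines
  mism <- c(
    if (!setequal(names(density_report$fold_vs), candidates))
      paste0("density report folds name {",
             paste(names(density_report$fold_vs), collapse = ","), "}"),
    if (!setequal(names(sharing_tests), candidates))
      paste0("sharing tests name {",
             paste(names(sharing_tests), collapse = ","), "}"),
    if (!setequal(names(maternal_result$distances), candidates))
      paste0("maternal distances name {",
             paste(names(maternal_result$distances), collapse = ","), "}")
  )
  if (length(mism) > 0L) {
    stop("evidence lines disagree on candidate names (expected {",
         paste(candidates, collapse = ","), "}): ",
         paste(mism, collapse = "; "), call. = FALSE)
  }
  folds <- density_report$fold_vs[candidates]
  is_hybrid <- all(is.finite(folds)) && all(folds >= params$fold_min)
  maternal <- maternal_result$maternal
  g <- partition$alt_shared_fraction[candidates]
  ci_pass <- vapply(candidates, function(cd) {
    ci <- sharing_tests[[cd]]$conf_int
    ci[1L] <= 0.5 && 0.5 <= ci[2L]
  }, logical(1L))
  its_share <- if (is.null(its_tables)) {
    setNames(rep(NA, length(candidates)), candidates)
  } else {
    vapply(candidates, function(cd)
      its_shares_allele(its_tables, hybrid, cd), logical(1L))
  }
  corroborated <- candidates == maternal | g >= params$g_min |
    (!is.na(its_share) & its_share)
  supported <- if (is_hybrid) candidates[ci_pass & corroborated] else
    character(0)
  excluded <- setdiff(candidates[g < params$g_min], supported)
  indeterminate <- setdiff(candidates, c(supported, excluded))
  its_consistent <- if (is.null(its_tables)) NA else {
    all(its_share[supported]) &&
      !any(its_share[setdiff(excluded, supported)])
  }
  notes <- character(0)
  if (is_hybrid && length(candidates) > 0L &&
      all(g < params$g_min, na.rm = TRUE)) {
    notes <- c(notes, paste0(
      "second parent not among sampled candidates: no candidate's ",
      "non-reference alleles account for the hybrid's non-reference ",
      "alleles (all g < ", params$g_min, ")"))
  }
  v <- structure(list(
    hybrid = hybrid, is_hybrid = is_hybrid, folds = folds,
    maternal = if (is_hybrid) maternal else NA_character_,
    maternal_margin = if (is_hybrid) maternal_result$margin else NA_real_,
    inheritance = maternal_result$inheritance %||% "maternal",
    supported_parents = lapply(
      setNames(supported, supported), function(cd) list(
        f = sharing_tests[[cd]]$point_estimate,
        conf_int = sharing_tests[[cd]]$conf_int,
        p_value = sharing_tests[[cd]]$p_value)),
    excluded_candidates = lapply(
      setNames(excluded, excluded), function(cd) list(g = unname(g[[cd]]))),
    indeterminate = indeterminate,
    its_consistent = its_consistent,
    notes = notes,
    params = unclass(params)
  ), class = "hybrid_verdict")
  v$narrative <- verdict_narrative(v)
  v
}

verdict_narrative <- function(v) {
  if (!v$is_hybrid) {
    return(paste0(
      "Sample '", v$hybrid, "' shows no genome-wide SNP elevation ",
      "relative to the candidate parents (folds: ",
      paste(sprintf("%.1f vs %s", v$folds, names(v$folds)),
            collapse = ", "),
      "); the data do not support a hybrid origin."))
  }
  genitor_word <- if (identical(v$inheritance, "paternal")) {
    "male genitor"
  } else "female genitor"
  parts <- c(
    paste0("Sample '", v$hybrid, "' shows strong genome-wide SNP ",
           "elevation (folds: ",
           paste(sprintf("%.1f vs %s", v$folds, names(v$folds)),
                 collapse = ", "),
           "), supporting a hybrid origin."),
    if (!identical(v$maternal, "ambiguous"))
      paste0("Organellar distances put '", v$maternal, "' as the ",
             genitor_word, " (margin ", sprintf("%.2f", v$maternal_margin),
             ")."),
    if (length(v$supported_parents) > 0L)
      paste0("Allele sharing consistent with parenthood for: ",
             paste(names(v$supported_parents), collapse = ", "), "."),
    if (length(v$excluded_candidates) > 0L)
      paste0("Excluded as a genitor: ",
             paste(names(v$excluded_candidates), collapse = ", "), "."),
    v$notes
  )
  paste(parts, collapse = " ")
}

#' @export
print.hybrid_verdict <- function(x, ...) {
  cat("<hybrid_verdict>\n", x$narrative, "\n", sep = "")
  invisible(x)
}

#' Write a verdict report
#'
#' Emits a versioned JSON document and, optionally, a plain-text summary.
#'
#' @param verdict a [decide()] result.
#' @param path JSON output path.
#' @param txt_path optional text output path.
#' @return `path`, invisibly.
#' @export
render_report <- function(verdict, path, txt_path = NULL) {
  stopifnot(inherits(verdict, "hybrid_verdict"))
  doc <- list(
    schema = "hybridly/verdict/v1",
    hybrid = verdict$hybrid,
    is_hybrid = verdict$is_hybrid,
    folds = as.list(verdict$folds),
    maternal = verdict$maternal,
    maternal_margin = verdict$maternal_margin,
    inheritance = verdict$inheritance,
    supported_parents = verdict$supported_parents,
    excluded_candidates = verdict$excluded_candidates,
    indeterminate = verdict$indeterminate,
    its_consistent = verdict$its_consistent,
    notes = verdict$notes,
    narrative = verdict$narrative
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  if (!is.null(txt_path)) writeLines(verdict$narrative, txt_path)
  invisible(path)
}
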