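#' Call RNA-RNA interactions end to end
#'
#' Orchestrates the whole interactome analysis: load the annotation, append
#' UA features so every position is assignable, classify each replicate's
#' chimeric alignments, sum replicate interaction matrices, test every pair
#' with the one-sided hypergeometric test, BH-adjust, and extract the
#' significant sets.
#'
#' @param sam_files Character vector of per-replicate SAM/BAM files, *or*
#'   `NULL` when `alignments` is given.
#' @param gff Path to the GFF3 annotation, *or* a ready [feature_table()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param alignments Optional list of in-memory `read_alignments` tables (one
#'   per replicate), bypassing SAM parsing.
#' @param distance_threshold,junction_gap,circular See [assign_reads()].
#' @param min_ua_length See [make_ua_features()].
#' @param min_count See [test_all_pairs()].
#' @param raw_alpha,fdr See [extract_significant()].
#' @param label Condition label attached to the merged matrix.
#' @return A `ligr_run` list: `results` (all tested pairs), `significant`
#'   (list `raw` / `fdr`), `matrix` (merged `interaction_matrix`),
#'   `class_tally` (reads per classification class), `features` (universe
#'   incl. UA).
#' @export
call_interactions_end_to_end <- function(sam_files = NULL, gff, chrom_lengths,
                                         alignments = NULL,
                                         distance_threshold = 2000L,
                                         junction_gap = 50L,
                                         circular = FALSE,
                                         min_ua_length = 30L,
                                         min_count = 1L,
                                         raw_alpha = 0.05, fdr = 0.05,
                                         label = NULL) {
  ft <- if (inherits(gff, "feature_table")) gff else load_annotation(gff)
  ft <- make_ua_features(ft, chrom_lengths, min_ua_length = min_ua_length)
  if (is.null(alignments)) {
    if (is.null(sam_files)) stop("need sam_files or alignments", call. = FALSE)
    alignments <- lapply(sam_files, read_sam_alignments)
  }
  mats <- lapply(seq_along(alignments), function(r) {
    calls <- assign_reads(alignments[[r]], ft,
                          distance_threshold = distance_threshold,
                          junction_gap = junction_gap, circular = circular,
                          chrom_lengths = chrom_lengths)
    build_interaction_matrix(calls, feature_universe = ft$id,
                             label = sprintf("replicate_%d", r))
  })
  merged <- merge_replicates(mats, label = label)
  results <- test_all_pairs(merged, min_count = min_count)
  sig <- extract_significant(results, raw_alpha = raw_alpha, fdr = fdr)
  structure(list(results = results, significant = sig, matrix = merged,
                 class_tally = merged$class_tally, features = ft),
            class = "ligr_run")
}

#' @export
print.ligr_run <- function(x, ...) {
  cat("<ligr_run>\n  reads per class:\n")
  tl <- x$class_tally
  for (cl in sort(names(tl))) cat(sprintf("    %-18s %d\n", cl, tl[[cl]]))
  cat(sprintf("  tested pairs: %d;  p_raw < 0.05: %d;  FDR < 0.05: %d\n",
              nrow(x$results), nrow(x$significant$raw), nrow(x$significant$fdr)))
  invisible(x)
}

#' Write chimera calls / interaction results as TSV
#'
#' @param x A `chimera_calls` or `interaction_results` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}
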