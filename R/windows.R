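#' Link UTR features to their genes
#'
#' Convenience constructor for the mapping used by [prediction_window()]:
#' a named list, one entry per gene id, each a character vector of UTR
#' feature ids belonging to that gene's transcript.
#'
#' @param ... Named arguments, e.g. `utr_links(gene_001 = c("utr5_001",
#'   "utr3_001"))`.
#' @return A named list.
#' @export
utr_links <- function(...) {
  out <- list(...)
  stopifnot(length(out) == 0L || !is.null(names(out)))
  out
}

#' Sequence window for hybridization prediction
#'
#' Builds the input window handed to pairwise hybridization predictors
#' (IntaRNA-style tools) for one partner of a candidate interaction. If UTR
#' features are linked to the gene, the window is the UTR-extended transcript
#' span (transcription start to stop); otherwise the gene span extended by
#' `flank` nt (default 50) on each side, clipped at the chromosome ends. The
#' sequence is taken from the feature strand (reverse-complemented for `-`).
#'
#' @param feature_id Feature to build the window for.
#' @param features A [feature_table()].
#' @param links UTR mapping from [utr_links()] (may be empty).
#' @param genome A `syn_genome`, named [Biostrings::DNAStringSet], or single
#'   [Biostrings::DNAString] for the feature's chromosome.
#' @param flank Flank size in nt when no UTR is linked.
#' @return A `prediction_window` list: `feature_id`, `chrom`, `start`, `end`,
#'   `strand`, `window_rule` (`annotated_utr` or `flank50`), `sequence`
#'   (character).
#' @export
prediction_window <- function(feature_id, features, links = utr_links(),
                              genome, flank = 50L) {
  ft <- as.data.table(features)
  i <- match(feature_id, ft$id)
  if (is.na(i)) stop("unknown feature: ", feature_id, call. = FALSE)
  chrom <- ft$chrom[i]

  seqs <- if (inherits(genome, "syn_genome")) {
    setNames(Biostrings::DNAStringSet(genome$genome), names(genome$chrom_lengths))
  } else if (inherits(genome, "DNAString")) {
    setNames(Biostrings::DNAStringSet(genome), chrom)
  } else Biostrings::DNAStringSet(genome)
  if (!chrom %in% names(seqs)) stop("genome lacks chromosome ", chrom, call. = FALSE)
  chrom_len <- Biostrings::width(seqs[chrom])

  linked <- links[[feature_id]]
  if (!is.null(linked) && length(linked)) {
    j <- match(linked, ft$id)
    if (anyNA(j)) stop("utr link references unknown feature: ",
                       paste(linked[is.na(j)], collapse = ", "), call. = FALSE)
    ws <- min(ft$start[c(i, j)]); we <- max(ft$end[c(i, j)])
    rule <- "annotated_utr"
  } else {
    ws <- max(1L, ft$start[i] - as.integer(flank))
    we <- min(chrom_len, ft$end[i] + as.integer(flank))
    rule <- "flank50"
  }
  sq <- Biostrings::subseq(seqs[[chrom]], ws, we)
  if (ft$strand[i] == "-") sq <- Biostrings::reverseComplement(sq)
  structure(list(feature_id = feature_id, chrom = chrom, start = ws, end = we,
                 strand = ft$strand[i], window_rule = rule,
                 sequence = as.character(sq)),
            class = "prediction_window")
}

#' Write prediction windows as FASTA
#'
#' Headers are the feature ids, ready to feed a hybridization predictor.
#'
#' @param windows A list of `prediction_window` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_prediction_windows <- function(windows, path) {
  dss <- Biostrings::DNAStringSet(vapply(windows, `[[`, character(1), "sequence"))
  names(dss) <- vapply(windows, `[[`, character(1), "feature_id")
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}
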