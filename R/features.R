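#' Feature tables
#'
#' A feature table is the universe of assignable genomic features: annotated
#' transcripts/elements plus, after [make_ua_features()], the auto-generated
#' unannotated-region (`UA`) intervals that tile the rest of the genome so
#' that every chimera fragment lands in *some* feature.
#'
#' Columns: `id` (unique), `chrom`, `start`, `end` (1-based inclusive),
#' `strand` (`+`, `-`, or `.`), `ftype` (one of `CDS`, `5UTR`, `3UTR`,
#' `sRNA`, `rRNA`, `tRNA`, `other_ncRNA`, `UA`), `length` (nt).
#'
#' @param id,chrom,start,end,strand,ftype Vectors of equal length (recycled
#'   where scalar) describing one feature per element.
#' @return A `feature_table` (a `data.table`).
#' @export
feature_table <- function(id, chrom, start, end, strand = "+", ftype = "CDS") {
  ft <- data.table(
    id = as.character(id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), ftype = as.character(ftype)
  )
  ft[, length := end - start + 1L]
  validate_feature_table(ft)
}

FEATURE_TYPES <- c("CDS", "5UTR", "3UTR", "sRNA", "rRNA", "tRNA", "other_ncRNA", "UA")

validate_feature_table <- function(ft) {
  ft <- as.data.table(ft)
  if (nrow(ft)) {
    if (anyDuplicated(ft$id)) stop("feature ids must be unique", call. = FALSE)
    if (any(ft$start > ft$end)) stop("feature start must be <= end", call. = FALSE)
    if (!all(ft$strand %in% c("+", "-", "."))) stop("strand must be +, - or .", call. = FALSE)
    if (!all(ft$ftype %in% FEATURE_TYPES))
      stop("unknown ftype; expected one of: ", paste(FEATURE_TYPES, collapse = ", "),
           call. = FALSE)
    if (any(ft$ftype == "UA" & ft$strand != "."))
      stop("UA features must be unstranded ('.')", call. = FALSE)
  }
  setattr(ft, "class", c("feature_table", class(data.table())))
  ft[]
}

features_as_granges <- function(ft) {
  GenomicRanges::GRanges(
    seqnames = ft$chrom,
    ranges = IRanges::IRanges(start = ft$start, end = ft$end),
    strand = ifelse(ft$strand == ".", "*", ft$strand),
    id = ft$id, ftype = ft$ftype
  )
}
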