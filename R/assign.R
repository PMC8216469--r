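#' Add unannotated-region (UA) features
#'
#' Many chimera fragments fall outside the annotation. To keep them
#' assignable, the complement of the annotated interval union on each
#' chromosome is turned into features named `UA-<start>-<stop>` (unstranded),
#' so that annotated plus UA intervals tile the genome. Complement intervals
#' shorter than `min_ua_length` are left out: they are below typical fragment
#' size and could never win a maximal-overlap assignment.
#'
#' @param features A [feature_table()] of annotated features.
#' @param chrom_lengths Named integer vector covering every chromosome in
#'   `features`.
#' @param min_ua_length Minimum UA interval length in nt (default 30). Use 1
#'   to obtain an exact tiling.
#' @return A [feature_table()]: the input with UA rows appended.
#' @export
make_ua_features <- function(features, chrom_lengths, min_ua_length = 30L) {
  ft <- as.data.table(features)
  if (nrow(ft) && !all(ft$chrom %in% names(chrom_lengths)))
    stop("chrom_lengths must cover every chromosome in the annotation", call. = FALSE)
  ua <- list()
  for (ch in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[ch]])
    sub <- ft[chrom == ch]
    gaps_ir <- if (nrow(sub)) {
      IRanges::gaps(IRanges::reduce(IRanges::IRanges(sub$start, sub$end)),
                    start = 1L, end = len)
    } else IRanges::IRanges(1L, len)
    gaps_ir <- gaps_ir[IRanges::width(gaps_ir) >= min_ua_length]
    if (length(gaps_ir)) {
      ua[[ch]] <- data.table(
        id = sprintf("UA-%d-%d", IRanges::start(gaps_ir), IRanges::end(gaps_ir)),
        chrom = ch, start = IRanges::start(gaps_ir), end = IRanges::end(gaps_ir),
        strand = ".", ftype = "UA"
      )
    }
  }
  ua <- rbindlist(ua)
  if (nrow(ua)) {
    ua[, length := end - start + 1L]
    out <- rbind(ft, ua)
  } else out <- ft
  validate_feature_table(out)
}

# closest-edge separation between two features; 0 when overlapping/adjacent.
# On a circular chromosome the wrap-around gap is also considered.
feature_gap <- function(s1, e1, s2, e2, circular = FALSE, chrom_length = NA_integer_) {
  lin <- pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
  if (!circular) return(lin)
  wrap <- pmax(0L, chrom_length - pmax(e1, e2) + pmin(s1, s2) - 1L)
  pmin(lin, wrap)
}

#' Classify chimeric reads against the feature universe
#'
#' Every aligned segment is assigned to the feature with maximal overlap
#' (ties broken towards the smaller feature, then lexicographically by id).
#' Reads are then classified into exactly one class:
#'
#' * `repeat_ambiguous` — any segment flagged ambiguous (repeat-derived /
#'   unmapped placements are discarded rather than guessed);
#' * `intramolecular` — both segments in one feature (counted toward that
#'   feature's expression, not interaction);
#' * `junction_artifact` — two features overlapping or nearly adjacent
#'   (closest-edge gap <= `junction_gap`): indistinguishable from a read
#'   spanning a junction between neighbouring transcripts;
#' * `proximal_excluded` — distinct features closer than
#'   `distance_threshold` (the assay cannot separate genuine contacts from
#'   local proximity below ~2 kb);
#' * `interaction` — two features separated by more than
#'   `distance_threshold`;
#' * `unassigned` — reads without a chimeric junction (a single aligned
#'   segment) or with more than two segments.
#'
#' Segment order within a read never affects the outcome, and strand is
#' ignored in overlap assignment (the recovered orientation of a
#' psoralen-crosslinked duplex is not informative).
#'
#' @param alignments A `read_alignments` table ([toy_align()],
#'   [emit_truth_alignments()] or [read_sam_alignments()]).
#' @param features [feature_table()] *including* UA features, so that every
#'   genomic position is covered.
#' @param distance_threshold Minimum closest-edge separation (nt) between two
#'   features for an `interaction` call (default 2000).
#' @param junction_gap Maximum gap (nt) for the `junction_artifact` call
#'   (default 50).
#' @param circular Logical: compute separations on a circular chromosome.
#' @param chrom_lengths Named lengths, required when `circular = TRUE`.
#' @return A `chimera_calls` `data.table`: `read_id`, `featureA`, `featureB`
#'   (canonically ordered, `NA` for single-feature reads), `class`.
#' @export
assign_reads <- function(alignments, features, distance_threshold = 2000L,
                         junction_gap = 50L, circular = FALSE,
                         chrom_lengths = NULL) {
  aln <- as.data.table(alignments)
  ft <- as.data.table(features)
  if (circular && is.null(chrom_lengths))
    stop("chrom_lengths required for circular distance computation", call. = FALSE)
  if (!nrow(aln)) {
    return(data.table(read_id = character(0), featureA = character(0),
                      featureB = character(0), class = character(0)))
  }
  aln[, seg_id := seq_len(.N)]
  mapped <- aln[ambiguous == FALSE]

  feat_of <- rep(NA_character_, nrow(aln))
  if (nrow(mapped)) {
    if (!all(mapped$chrom %in% ft$chrom))
      stop("alignment segment on unknown chromosome: ",
           paste(setdiff(mapped$chrom, ft$chrom), collapse = ", "), call. = FALSE)
    seg_gr <- GenomicRanges::GRanges(mapped$chrom,
                                     IRanges::IRanges(mapped$start, mapped$end))
    ft_gr <- GenomicRanges::GRanges(ft$chrom, IRanges::IRanges(ft$start, ft$end))
    hits <- GenomicRanges::findOverlaps(seg_gr, ft_gr, ignore.strand = TRUE)
    if (length(hits)) {
      hdt <- data.table(seg = S4Vectors::queryHits(hits),
                        feat = S4Vectors::subjectHits(hits))
      hdt[, ov := pmin(mapped$end[seg], ft$end[feat]) -
            pmax(mapped$start[seg], ft$start[feat]) + 1L]
      hdt[, feat_len := ft$length[feat]]
      hdt[, feat_id := ft$id[feat]]
      setorder(hdt, seg, -ov, feat_len, feat_id)
      best <- hdt[!duplicated(seg)]
      feat_of[mapped$seg_id[best$seg]] <- best$feat_id
    }
  }
  aln[, feat_id := feat_of]

  aln[, amb_seg := ambiguous | is.na(feat_id)]
  setorder(aln, read_id, feat_id, na.last = TRUE)
  aln[, rk := rowid(read_id)]
  per_read <- aln[, .(n_seg = .N, n_amb = sum(amb_seg)), by = read_id]
  per_read[aln[rk == 1L], fA := i.feat_id, on = "read_id"]
  per_read[aln[rk == 2L], fB := i.feat_id, on = "read_id"]
  if (!"fB" %in% names(per_read)) per_read[, fB := NA_character_]
  per_read[, any_amb := n_amb > 0L]

  fidx_A <- match(per_read$fA, ft$id)
  fidx_B <- match(per_read$fB, ft$id)
  gap <- rep(NA_integer_, nrow(per_read))
  both <- !is.na(fidx_A) & !is.na(fidx_B)
  if (any(both)) {
    clen <- if (circular) as.integer(chrom_lengths[ft$chrom[fidx_A[both]]]) else NA_integer_
    gap[both] <- feature_gap(ft$start[fidx_A[both]], ft$end[fidx_A[both]],
                             ft$start[fidx_B[both]], ft$end[fidx_B[both]],
                             circular = circular, chrom_length = clen)
    # different chromosomes: always distal
    diffchrom <- ft$chrom[fidx_A[both]] != ft$chrom[fidx_B[both]]
    gap[which(both)[diffchrom]] <- .Machine$integer.max
  }

  cls <- rep("unassigned", nrow(per_read))
  cls[per_read$any_amb] <- "repeat_ambiguous"
  two <- !per_read$any_amb & per_read$n_seg == 2L
  same <- two & per_read$fA == per_read$fB
  cls[same] <- "intramolecular"
  diff2 <- two & !same
  cls[diff2 & gap <= junction_gap] <- "junction_artifact"
  cls[diff2 & gap > junction_gap & gap <= distance_threshold] <- "proximal_excluded"
  cls[diff2 & gap > distance_threshold] <- "interaction"

  out <- data.table(read_id = per_read$read_id,
                    featureA = per_read$fA,
                    featureB = fifelse(two, per_read$fB, NA_character_),
                    class = cls)
  out[class == "repeat_ambiguous", `:=`(featureA = NA_character_,
                                        featureB = NA_character_)]
  setkey(out, read_id)
  out[]
}

#' @rdname assign_reads
#' @param alignment A single read's alignment rows.
#' @export
assign_read <- function(alignment, features, distance_threshold = 2000L,
                        junction_gap = 50L, circular = FALSE,
                        chrom_lengths = NULL) {
  assign_reads(alignment, features, distance_threshold, junction_gap,
               circular, chrom_lengths)
}
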