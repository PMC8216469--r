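#' Toy exact-match split aligner
#'
#' Stands in for a full chimeric-aware aligner on synthetic data. For each
#' read it finds the longest exact-match *prefix* and the longest exact-match
#' *suffix* (both strands searched) by anchoring a `seed_length`-mer and
#' extending without mismatches; the prefix placement is reported as the
#' primary alignment and the suffix, when it is a distinct placement, as a
#' supplementary segment. Because the synthetic genome carries no repeated
#' seed-length k-mer outside flagged repeat blocks, any seed with more than
#' one hit means a repeat: such reads have no unique placement and are
#' reported ambiguous (unmapped in SAM).
#'
#' @param reads Named [Biostrings::DNAStringSet] (or character vector).
#' @param genome A `syn_genome`, or a [Biostrings::DNAString].
#' @param seed_length Exact-match anchor length (default 20 nt; fragments are
#'   at least this long by config invariant).
#' @param chrom Chromosome name used in the output (taken from the
#'   `syn_genome` when available).
#' @return A `read_alignments` `data.table`: one row per aligned segment with
#'   `read_id`, `chrom`, `start`, `end`, `strand`, `ambiguous`, plus the query
#'   interval (`qstart`, `qend`, `qlen`) and `is_supplementary`.
#' @export
toy_align <- function(reads, genome, seed_length = 20L, chrom = NULL) {
  if (inherits(genome, "syn_genome")) {
    if (is.null(chrom)) chrom <- names(genome$chrom_lengths)[1]
    gchr <- as.character(genome$genome)
  } else {
    gchr <- as.character(genome)
    if (is.null(chrom)) chrom <- "chr1"
  }
  if (is.null(names(reads))) stop("reads must be named", call. = FALSE)
  rchr <- setNames(as.character(reads), names(reads))
  k <- as.integer(seed_length)
  L <- nchar(gchr)
  rcg <- reverse_complement_chr(gchr)
  npos <- L - k + 1L

  km_dt <- data.table(
    km = c(substring(gchr, 1:npos, k:L), substring(rcg, 1:npos, k:L)),
    km_strand = rep(c("+", "-"), each = npos),
    km_pos = c(1:npos, 1:npos) # position within its own (fwd / rc) string
  )
  setkey(km_dt, km)

  # unique-hit lookup for a vector of seeds: NA strand when absent or repeated
  lookup_many <- function(seeds) {
    dt <- data.table(km = seeds, ord = seq_along(seeds))
    j <- km_dt[dt, on = "km", allow.cartesian = TRUE]
    j <- j[, .(nhit = sum(!is.na(km_strand)), km_strand = km_strand[1L],
               km_pos = km_pos[1L]), by = ord]
    setorder(j, ord)
    j[nhit != 1L, `:=`(km_strand = NA_character_, km_pos = NA_integer_)]
    j
  }

  nqv <- nchar(rchr)
  pre_seeds <- substring(rchr, 1L, k)
  suf_seeds <- substring(rchr, nqv - k + 1L, nqv)
  pre_hits <- lookup_many(pre_seeds)
  suf_hits <- lookup_many(suf_seeds)
  lookup <- function(hits, i) {
    if (is.na(hits$km_strand[i])) return(NULL)
    list(strand = hits$km_strand[i], pos = hits$km_pos[i])
  }

  # first mismatch position between two equal-length strings (0 if identical)
  first_mismatch <- function(x, y) {
    a <- charToRaw(x); b <- charToRaw(y)
    d <- which(a != b)
    if (length(d)) d[1L] else 0L
  }

  rows <- vector("list", length(rchr))
  for (ri in seq_along(rchr)) {
    rd <- rchr[[ri]]
    nid <- names(rchr)[ri]
    nq <- nchar(rd)
    amb_row <- data.table(read_id = nid, chrom = NA_character_,
                          start = NA_integer_, end = NA_integer_,
                          strand = NA_character_, ambiguous = TRUE,
                          qstart = NA_integer_, qend = NA_integer_,
                          qlen = nq, is_supplementary = FALSE)
    if (nq < k) { rows[[ri]] <- amb_row; next }

    pre <- lookup(pre_hits, ri)
    if (is.null(pre)) { rows[[ri]] <- amb_row; next }
    s1 <- if (pre$strand == "+") gchr else rcg
    maxext <- min(nq, L - pre$pos + 1L)
    mm <- first_mismatch(substring(rd, 1L, maxext),
                         substring(s1, pre$pos, pre$pos + maxext - 1L))
    e1 <- if (mm == 0L) maxext else mm - 1L

    seg <- function(strand, pos, qstart, qend, supp) {
      w <- qend - qstart + 1L
      if (strand == "+") {
        gs <- pos; ge <- pos + w - 1L; st <- "+"
      } else {
        ge <- L - pos + 1L; gs <- L - (pos + w - 1L) + 1L; st <- "-"
      }
      data.table(read_id = nid, chrom = chrom, start = gs, end = ge,
                 strand = st, ambiguous = FALSE,
                 qstart = qstart, qend = qend, qlen = nq,
                 is_supplementary = supp)
    }

    if (e1 == nq) { rows[[ri]] <- seg(pre$strand, pre$pos, 1L, nq, FALSE); next }

    suf <- lookup(suf_hits, ri)
    if (is.null(suf)) {
      rows[[ri]] <- rbind(seg(pre$strand, pre$pos, 1L, e1, FALSE),
                          copy(amb_row)[, is_supplementary := TRUE])
      next
    }
    # extend the suffix seed leftwards
    anchor_q <- nq - k + 1L # read position of the seed start
    s2 <- if (suf$strand == "+") gchr else rcg
    maxback <- min(anchor_q - 1L, suf$pos - 1L)
    b <- anchor_q
    if (maxback > 0L) {
      rseg <- substring(rd, anchor_q - maxback, anchor_q - 1L)
      gseg <- substring(s2, suf$pos - maxback, suf$pos - 1L)
      mmr <- first_mismatch(paste(rev(strsplit(rseg, "")[[1]]), collapse = ""),
                            paste(rev(strsplit(gseg, "")[[1]]), collapse = ""))
      back <- if (mmr == 0L) maxback else mmr - 1L
      b <- anchor_q - back
    }
    q2start <- b
    p2 <- suf$pos - (anchor_q - b)
    same_diag <- identical(pre$strand, suf$strand) &&
      (p2 - q2start) == (pre$pos - 1L)
    if (same_diag) {
      rows[[ri]] <- seg(pre$strand, pre$pos, 1L, e1, FALSE)
    } else {
      rows[[ri]] <- rbind(seg(pre$strand, pre$pos, 1L, e1, FALSE),
                          seg(suf$strand, p2, q2start, nq, TRUE))
    }
  }
  out <- rbindlist(rows)
  setkey(out, read_id)
  out[]
}

#' Alignments placed directly from the simulation truth table
#'
#' Bypasses sequence alignment: each truth fragment becomes an alignment
#' segment at its exact genomic coordinates. This is the noise-free route
#' used for end-to-end conservation checks (simulation truth in, interaction
#' matrix out, counts must match exactly).
#'
#' @param truth A truth `data.table` from [simulate_ligation()].
#' @param features The [feature_table()] the truth refers to.
#' @param chrom Chromosome name (single synthetic chromosome).
#' @return A `read_alignments` `data.table` (see [toy_align()]; no query
#'   coordinates, since no sequences are consulted).
#' @export
emit_truth_alignments <- function(truth, features, chrom = "syn1") {
  truth <- as.data.table(truth)
  if (!nrow(truth)) {
    return(data.table(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), ambiguous = logical(0),
                      is_supplementary = logical(0)))
  }
  ft <- as.data.table(features)
  check_frag <- function(feat, s, e) {
    i <- match(feat, ft$id)
    if (anyNA(i)) stop("truth references unknown feature: ",
                       paste(unique(feat[is.na(i)]), collapse = ", "), call. = FALSE)
    if (any(s < ft$start[i] | e > ft$end[i] | s > e))
      stop("truth fragment coordinates outside feature bounds", call. = FALSE)
  }
  check_frag(truth$feat1, truth$start1, truth$end1)
  two <- !is.na(truth$feat2)
  if (any(two)) check_frag(truth$feat2[two], truth$start2[two], truth$end2[two])

  seg1 <- truth[, .(read_id, chrom = chrom, start = start1, end = end1,
                    strand = strand1, ambiguous = FALSE, is_supplementary = FALSE)]
  seg2 <- truth[two, .(read_id, chrom = chrom, start = start2, end = end2,
                       strand = strand2, ambiguous = FALSE, is_supplementary = TRUE)]
  out <- rbind(seg1, seg2)
  setkey(out, read_id)
  out[]
}
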