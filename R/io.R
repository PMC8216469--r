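## File formats. Standard formats go through Bioconductor (Biostrings,
## rtracklayer, Rsamtools/GenomicAlignments); SAM *writing* is plain text
## because the synthetic aligner is the producer.

GFF_TYPE_OUT <- c(CDS = "CDS", `5UTR` = "five_prime_UTR", `3UTR` = "three_prime_UTR",
                  sRNA = "sRNA", rRNA = "rRNA", tRNA = "tRNA",
                  other_ncRNA = "ncRNA", UA = "biological_region")
GFF_TYPE_IN <- setNames(names(GFF_TYPE_OUT), GFF_TYPE_OUT)

#' Write the synthetic genome as FASTA
#'
#' @param genome A `syn_genome` (or a named [Biostrings::DNAStringSet]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- if (inherits(genome, "syn_genome")) {
    setNames(Biostrings::DNAStringSet(genome$genome), names(genome$chrom_lengths))
  } else Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Write a feature table as GFF3
#'
#' Features are written 1-based inclusive with an `ID=` attribute; `ftype`
#' is mapped onto Sequence Ontology terms (`5UTR` -> `five_prime_UTR`, ...).
#'
#' @param features A [feature_table()].
#' @param path Output file.
#' @param chrom_lengths Named integer vector of chromosome lengths (emitted as
#'   `##sequence-region` pragmas).
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path, chrom_lengths = NULL) {
  si <- if (is.null(chrom_lengths)) NULL else
    GenomeInfoDb::Seqinfo(names(chrom_lengths), unname(as.integer(chrom_lengths)))
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = ifelse(features$strand == ".", "*", features$strand),
    seqinfo = si,
    type = unname(GFF_TYPE_OUT[features$ftype]),
    # CDS records require a phase column in GFF3; synthetic CDS start in frame
    phase = ifelse(features$ftype == "CDS", 0L, NA_integer_),
    ID = features$id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation into a feature table
#'
#' One row per GFF3 feature; UTR records are retained as distinct features
#' (they get their own rows, linked to genes only via [utr_links()]).
#' GFF3 types without a known mapping are kept as `other_ncRNA` with a
#' warning.
#'
#' @param gff Path to a GFF3 file.
#' @return A [feature_table()].
#' @export
load_annotation <- function(gff) {
  gr <- rtracklayer::import(gff, format = "gff3")
  if (!length(gr)) {
    return(feature_table(character(0), character(0), integer(0), integer(0),
                         character(0), character(0)))
  }
  type <- as.character(gr$type)
  ftype <- GFF_TYPE_IN[type]
  if (anyNA(ftype)) {
    warning("unknown GFF3 feature type(s) mapped to other_ncRNA: ",
            paste(unique(type[is.na(ftype)]), collapse = ", "), call. = FALSE)
    ftype[is.na(ftype)] <- "other_ncRNA"
  }
  id <- gr$ID
  if (is.null(id) || anyNA(id)) stop("every GFF3 record needs an ID attribute", call. = FALSE)
  if (anyDuplicated(id)) stop("duplicate feature IDs in annotation", call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  feature_table(id = id, chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                strand = strand, ftype = unname(ftype))
}

#' Write reads as FASTQ
#'
#' Quality strings are constant `'I'`; qualities are unused downstream.
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

## ---- SAM -------------------------------------------------------------------

#' Write read alignments as SAM
#'
#' Each alignment segment becomes one SAM record; the second segment of a
#' chimeric read is written as a supplementary alignment (flag 2048) under the
#' same read name. Ambiguously placed reads are written unmapped (flag 4).
#' When `reads` is supplied, SEQ is filled and soft clips describe the part of
#' the read belonging to the other segment; otherwise SEQ is `*` and the CIGAR
#' is a bare match.
#'
#' @param alignments A `read_alignments` table (columns `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `ambiguous`, and optionally `qstart`, `qend`,
#'   `qlen`, `is_supplementary`).
#' @param path Output file.
#' @param chrom_lengths Named integer vector for the `@SQ` header lines.
#' @param reads Optional named [Biostrings::DNAStringSet] with the read
#'   sequences.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, chrom_lengths, reads = NULL) {
  aln <- as.data.table(alignments)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  lines <- character(0)
  if (nrow(aln)) {
    if (!"is_supplementary" %in% names(aln)) {
      aln[, is_supplementary := duplicated(read_id) & !ambiguous]
    }
    has_q <- all(c("qstart", "qend", "qlen") %in% names(aln)) && !is.null(reads)
    flag <- ifelse(aln$ambiguous, 4L,
                   ifelse(aln$strand == "-", 16L, 0L) +
                     ifelse(aln$is_supplementary, 2048L, 0L))
    rname <- ifelse(aln$ambiguous, "*", aln$chrom)
    pos <- ifelse(aln$ambiguous, 0L, aln$start)
    mapq <- ifelse(aln$ambiguous, 0L, 60L)
    m <- aln$end - aln$start + 1L
    if (has_q) {
      lead <- aln$qstart - 1L
      trail <- aln$qlen - aln$qend
      # on '-', SEQ is the reverse complement so the clips swap sides
      l <- ifelse(aln$strand == "-", trail, lead)
      t <- ifelse(aln$strand == "-", lead, trail)
      cigar <- paste0(ifelse(l > 0L, paste0(l, "S"), ""), m, "M",
                      ifelse(t > 0L, paste0(t, "S"), ""))
      sq <- as.character(reads[aln$read_id])
      mi <- aln$strand == "-"
      sq[mi] <- reverse_complement_chr(sq[mi])
      seqf <- sq
    } else {
      cigar <- paste0(m, "M")
      seqf <- "*"
    }
    cigar <- ifelse(aln$ambiguous, "*", cigar)
    if (!is.null(reads) && !has_q) seqf <- as.character(reads[aln$read_id])
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     aln$read_id, flag, rname, pos, mapq, cigar, seqf)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM/BAM file into a segment table
#'
#' Primary and supplementary records are grouped by read name into one row per
#' aligned segment; unmapped records (the toy aligner's ambiguous placements)
#' become segments with `ambiguous = TRUE`.
#'
#' @param path A SAM (or BAM) file.
#' @return A `read_alignments` `data.table` with columns `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `ambiguous`.
#' @export
read_sam_alignments <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand",
                                        "pos", "cigar"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(res$flag, 4L) > 0L
  w <- rep(NA_integer_, length(res$cigar))
  ok <- !unmapped & !is.na(res$cigar)
  if (any(ok)) w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[ok])
  dt <- data.table(
    read_id = res$qname,
    chrom = ifelse(unmapped, NA_character_, as.character(res$rname)),
    start = ifelse(unmapped, NA_integer_, res$pos),
    end = ifelse(unmapped, NA_integer_, res$pos + w - 1L),
    strand = ifelse(unmapped, NA_character_, as.character(res$strand)),
    ambiguous = unmapped
  )
  setkey(dt, read_id)
  dt[]
}
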