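#' Generate a synthetic annotated genome
#'
#' Places `n_genes` protein-coding genes and `n_srnas` sRNA features on a
#' random single-chromosome genome, non-overlapping, in random order and
#' strand, separated by intergenic gaps of at least `min_gap` nt (leftover
#' space is spread randomly over the gaps, so with the default sizing some
#' feature pairs are separated by well over 2000 bp and the downstream
#' proximity filter is exercisable). The sequence is constructed so that no
#' `seed_length`-mer occurs twice on either strand outside an explicitly
#' flagged repeat block, which makes the exact-match toy aligner unambiguous
#' by construction.
#'
#' @param config A [sim_config()].
#' @return A `syn_genome` list: `genome` (a [Biostrings::DNAString]),
#'   `features` (a [feature_table()]), `chrom_lengths` (named integer),
#'   `repeats` (`NULL`, or a `data.table` of the two flagged repeat copies),
#'   and the `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nf <- config$n_genes + config$n_srnas
    lens <- integer(0)
    types <- character(0)
    if (config$n_genes > 0L) {
      lens <- c(lens, sample(config$gene_length_range[1]:config$gene_length_range[2],
                             config$n_genes, replace = TRUE))
      types <- c(types, rep("CDS", config$n_genes))
    }
    if (config$n_srnas > 0L) {
      lens <- c(lens, sample(config$srna_length_range[1]:config$srna_length_range[2],
                             config$n_srnas, replace = TRUE))
      types <- c(types, rep("sRNA", config$n_srnas))
    }
    ord <- sample.int(nf)
    lens <- lens[ord]; types <- types[ord]

    spare <- config$genome_length - sum(lens) - (nf + 1L) * config$min_gap
    if (spare < 0L)
      stop(sprintf(paste0("cannot fit %d features (%d nt + %d nt minimum gaps) ",
                          "in a %d nt genome"),
                   nf, sum(lens), (nf + 1L) * config$min_gap, config$genome_length),
           call. = FALSE)
    gaps <- config$min_gap +
      as.integer(stats::rmultinom(1L, spare, rep(1, nf + 1L))[, 1L])
    starts <- cumsum(gaps[seq_len(nf)]) + cumsum(c(0L, lens[-nf])) + 1L
    ends <- starts + lens - 1L

    counters <- c(CDS = 0L, sRNA = 0L)
    ids <- character(nf)
    for (i in seq_len(nf)) {
      counters[types[i]] <- counters[types[i]] + 1L
      ids[i] <- sprintf("%s_%03d", ifelse(types[i] == "CDS", "gene", "srna"),
                        counters[types[i]])
    }
    strands <- sample(c("+", "-"), nf, replace = TRUE)

    seq_chr <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                            replace = TRUE), collapse = "")

    repeats <- NULL
    if (config$repeat_length > 0L) {
      rl <- config$repeat_length
      gap_starts <- c(1L, ends + 1L)
      gap_ends <- c(starts - 1L, config$genome_length)
      big <- which(gap_ends - gap_starts + 1L >= rl + 2L)
      if (length(big) < 2L)
        stop("no room for two repeat copies in intergenic space", call. = FALSE)
      slots <- sample(big, 2L)
      rs <- gap_starts[slots] + 1L
      block <- substring(seq_chr, rs[1], rs[1] + rl - 1L)
      substr(seq_chr, rs[2], rs[2] + rl - 1L) <- block
      repeats <- data.table(start = rs, end = rs + rl - 1L)
    }

    seq_chr <- fix_duplicate_kmers(seq_chr, config$seed_length, repeats)

    ft <- feature_table(id = ids, chrom = config$chrom_name,
                        start = starts, end = ends,
                        strand = strands, ftype = types)
    out <- list(genome = Biostrings::DNAString(seq_chr),
                features = ft,
                chrom_lengths = setNames(config$genome_length, config$chrom_name),
                repeats = repeats,
                config = config)
    class(out) <- "syn_genome"
    out
  })
}

# Mutate single bases until no k-mer (on either strand) occurs twice, except
# for k-mers overlapping the flagged repeat blocks.
fix_duplicate_kmers <- function(seq_chr, k, repeats = NULL) {
  L <- nchar(seq_chr)
  npos <- L - k + 1L
  exempt <- rep(FALSE, npos)
  if (!is.null(repeats)) {
    for (i in seq_len(nrow(repeats))) {
      lo <- max(1L, repeats$start[i] - k + 1L)
      hi <- min(npos, repeats$end[i])
      exempt[lo:hi] <- TRUE
    }
  }
  for (iter in 1:60) {
    fwd <- substring(seq_chr, 1:npos, k:L)
    rc_chr <- reverse_complement_chr(seq_chr)
    rev <- substring(rc_chr, 1:npos, k:L)
    # genome window start of rc k-mer at rc-position j is L - j - k + 2
    win_start <- c(1:npos, L - (1:npos) - k + 2L)
    all_km <- c(fwd, rev)
    all_exempt <- c(exempt, exempt[L - (1:npos) - k + 2L])
    dup_val <- unique(all_km[duplicated(all_km)])
    if (!length(dup_val)) return(seq_chr)
    fixed_any <- FALSE
    for (v in dup_val) {
      occ <- which(all_km == v)
      fixable <- occ[!all_exempt[occ]]
      if (length(fixable) < if (all(occ %in% fixable)) 2L else 1L) next
      # leave one occurrence (or the exempt ones) alone, mutate the rest
      keep <- if (length(fixable) == length(occ)) fixable[1L] else integer(0)
      for (o in setdiff(fixable, keep)) {
        pos <- win_start[o] + sample.int(k, 1L) - 1L
        old <- substring(seq_chr, pos, pos)
        substr(seq_chr, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        fixed_any <- TRUE
      }
    }
    if (!fixed_any) break
  }
  seq_chr
}

#' @export
print.syn_genome <- function(x, ...) {
  cat(sprintf("<syn_genome> %s: %d nt, %d features (%d CDS, %d sRNA)%s\n",
              names(x$chrom_lengths)[1], x$chrom_lengths[[1]], nrow(x$features),
              sum(x$features$ftype == "CDS"), sum(x$features$ftype == "sRNA"),
              if (is.null(x$repeats)) "" else ", 1 flagged repeat pair"))
  invisible(x)
}
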