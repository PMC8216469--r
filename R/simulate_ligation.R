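#' Log-normal per-feature transcript abundances
#'
#' Draws one positive weight per feature from the log-normal distribution in
#' the config. The heavy tail mimics bacterial expression: a few very abundant
#' transcripts dominate the background ligation.
#'
#' @param config A [sim_config()].
#' @param features A [feature_table()].
#' @return Named numeric vector of strictly positive weights.
#' @export
sim_abundances <- function(config, features) {
  with_seed(derive_seed(config$seed, 1L), {
    mu <- config$abundance_lognormal_mu_sigma[1]
    sg <- config$abundance_lognormal_mu_sigma[2]
    setNames(rlnorm(nrow(features), meanlog = mu, sdlog = sg), features$id)
  })
}

#' Choose planted interaction pairs
#'
#' Samples `n_pairs` distinct unordered feature pairs to be enriched
#' `fold`-fold in the ligation model, emulating genuine sRNA interactions:
#' partner A is an sRNA, partner B any other feature, both restricted to
#' features with at least median abundance (the assay only ever reports
#' interactions of transcripts that are actually expressed), and the partners
#' separated by more than `min_separation` nt — planted pairs stand for
#' trans-acting contacts, which is the very class the proximity filter is
#' designed to keep.
#'
#' @param features A [feature_table()].
#' @param abundances Named abundance vector (see [sim_abundances()]).
#' @param n_pairs Number of pairs to plant.
#' @param fold Enrichment factor (applied to every sampled pair).
#' @param seed RNG seed.
#' @param min_separation Minimum closest-edge genomic separation (nt) between
#'   the two partners (default 2000).
#' @return A `data.frame` with columns `featureA`, `featureB`, `fold`,
#'   suitable for `sim_config(planted_pairs = )`.
#' @export
plant_random_pairs <- function(features, abundances, n_pairs, fold, seed = 1L,
                               min_separation = 2000L) {
  with_seed(derive_seed(seed, 2L), {
    ft <- as.data.table(features)
    a <- abundances[ft$id]
    expressed <- ft$id[a >= stats::median(a)]
    srnas <- intersect(ft$id[ft$ftype == "sRNA"], expressed)
    if (!length(srnas)) srnas <- expressed
    distal <- function(x, y) {
      i <- match(x, ft$id); j <- match(y, ft$id)
      ft$chrom[i] != ft$chrom[j] ||
        feature_gap(ft$start[i], ft$end[i], ft$start[j], ft$end[j]) > min_separation
    }
    pairs <- character(0)
    out <- list()
    guard <- 0L
    while (length(out) < n_pairs) {
      A <- sample(srnas, 1L)
      B <- sample(setdiff(expressed, A), 1L)
      key <- paste(sort(c(A, B)), collapse = "|")
      if (!key %in% pairs && distal(A, B)) {
        pairs <- c(pairs, key)
        out[[length(out) + 1L]] <- data.frame(featureA = A, featureB = B,
                                              fold = fold)
      }
      guard <- guard + 1L
      if (guard > 1000L * n_pairs) stop("cannot sample enough distinct pairs",
                                        call. = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Simulate a proximity-ligation read library with planted interactions
#'
#' Generates, per replicate, `n_reads` single-end reads and a truth table.
#' Reads are non-chimeric (one fragment of one transcript), intramolecular
#' chimeras (two fragments of the same transcript), or intermolecular
#' chimeras. An intermolecular chimera joins features `(i, j)` with
#' probability proportional to `a_i * a_j * e_ij`, where `e_ij` is the
#' configured enrichment fold for planted pairs and 1 otherwise — i.e.
#' background ligation is abundance-driven and planted pairs ligate at an
#' elevated rate. Fragment coordinates are uniform within the feature and the
#' order of the two fragments in the read is randomized (ligation orientation
#' is not observable in the assay). Replicate `r` uses seed `seed + r`.
#'
#' @param genome A `syn_genome` from [generate_genome()].
#' @param abundances Named positive weights per feature; defaults to
#'   [sim_abundances()].
#' @param config A [sim_config()]; defaults to the one inside `genome`.
#' @return A `ligation_sim` list with `replicates` (each a list holding
#'   `reads`, a named [Biostrings::DNAStringSet], and `truth`, a `data.table`
#'   with `read_id`, `class` in \{`non_chimeric`, `intramolecular`,
#'   `background_pair`, `planted_pair`\} and per-fragment genomic
#'   coordinates), plus `abundances` and `config`.
#' @export
simulate_ligation <- function(genome, abundances = NULL, config = genome$config) {
  stopifnot(inherits(genome, "syn_genome"))
  ft <- genome$features
  if (is.null(abundances)) abundances <- sim_abundances(config, ft)
  a <- abundances[ft$id]
  if (anyNA(a) || any(a <= 0))
    stop("abundances must be strictly positive for every feature", call. = FALSE)

  min_frag <- config$fragment_length_range[1]
  eligible <- ft$length >= min_frag
  if (!all(eligible))
    warning(sprintf("skipping %d feature(s) shorter than the minimum fragment length (%d nt): %s",
                    sum(!eligible), min_frag,
                    paste(ft$id[!eligible], collapse = ", ")), call. = FALSE)
  fe <- ft[eligible]
  ae <- a[eligible]
  m <- nrow(fe)
  if (m < 1L) stop("no feature long enough to produce a fragment", call. = FALSE)

  gchr <- as.character(genome$genome)
  chrom <- names(genome$chrom_lengths)[1]

  ## intermolecular pair weights (upper triangle), with planted enrichment
  pair_i <- pair_j <- integer(0); pair_w <- numeric(0)
  planted_key <- character(0)
  if (m >= 2L) {
    pair_i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    pair_j <- unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m))
    pair_w <- ae[pair_i] * ae[pair_j]
    if (!is.null(config$planted_pairs)) {
      pp <- as.data.frame(config$planted_pairs)
      bad <- !(pp$featureA %in% fe$id) | !(pp$featureB %in% fe$id)
      if (any(bad))
        stop("planted pair references unknown or too-short feature: ",
             paste(unique(c(pp$featureA[bad], pp$featureB[bad])), collapse = ", "),
             call. = FALSE)
      key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "|")
      planted_key <- key(pp$featureA, pp$featureB)
      pk <- key(fe$id[pair_i], fe$id[pair_j])
      idx <- match(pk, planted_key)
      pair_w <- pair_w * ifelse(is.na(idx), 1, pp$fold[idx])
    }
  }

  draw_fragment <- function(fidx) {
    if (!length(fidx)) {
      return(list(feat = character(0), start = integer(0), end = integer(0),
                  strand = character(0), seq = character(0)))
    }
    flen <- sample(config$fragment_length_range[1]:config$fragment_length_range[2],
                   length(fidx), replace = TRUE)
    flen <- pmin(flen, fe$length[fidx])
    off <- floor(runif(length(fidx)) * (fe$length[fidx] - flen + 1))
    s <- fe$start[fidx] + as.integer(off)
    e <- s + flen - 1L
    sq <- substring(gchr, s, e)
    neg <- fe$strand[fidx] == "-"
    if (any(neg)) sq[neg] <- reverse_complement_chr(sq[neg])
    list(feat = fe$id[fidx], start = s, end = e, strand = fe$strand[fidx], seq = sq)
  }

  expand_multinom <- function(nn, w) {
    if (nn == 0L) return(integer(0))
    counts <- stats::rmultinom(1L, nn, w)[, 1L]
    rep(seq_along(w), counts)
  }

  replicates <- vector("list", config$replicate_count)
  for (r in seq_len(config$replicate_count)) {
    replicates[[r]] <- with_seed(config$seed + r, {
      nn <- config$n_reads
      n_chim <- round(nn * config$frac_chimeric)
      n_intra <- round(n_chim * config$frac_intramolecular_of_chimeric)
      n_inter <- n_chim - n_intra
      n_non <- nn - n_chim
      if (n_inter > 0L && m < 2L)
        stop("intermolecular chimeras require >= 2 eligible features", call. = FALSE)

      f_non <- expand_multinom(n_non, ae)
      f_intra <- expand_multinom(n_intra, ae^2)
      p_inter <- expand_multinom(n_inter, pair_w)

      frag_n <- draw_fragment(f_non)
      frag_i1 <- draw_fragment(f_intra)
      frag_i2 <- draw_fragment(f_intra)
      frag_p1 <- draw_fragment(pair_i[p_inter])
      frag_p2 <- draw_fragment(pair_j[p_inter])

      ## randomize fragment order within each chimeric read
      swap_i <- runif(n_intra) < 0.5
      swap_p <- runif(n_inter) < 0.5
      sw <- function(x, y, swap) list(
        feat = ifelse(swap, y$feat, x$feat), start = ifelse(swap, y$start, x$start),
        end = ifelse(swap, y$end, x$end), strand = ifelse(swap, y$strand, x$strand),
        seq = ifelse(swap, y$seq, x$seq))
      a1 <- sw(frag_i1, frag_i2, swap_i); a2 <- sw(frag_i2, frag_i1, swap_i)
      b1 <- sw(frag_p1, frag_p2, swap_p); b2 <- sw(frag_p2, frag_p1, swap_p)

      inter_class <- rep("background_pair", n_inter)
      if (n_inter > 0L && length(planted_key)) {
        pk <- paste(pmin(b1$feat, b2$feat), pmax(b1$feat, b2$feat), sep = "|")
        inter_class[pk %in% planted_key] <- "planted_pair"
      }

      ids <- sprintf("rep%d_read%06d", r, seq_len(nn))
      n_ids <- head(ids, n_non)
      i_ids <- ids[n_non + seq_len(n_intra)]
      p_ids <- ids[n_non + n_intra + seq_len(n_inter)]

      truth_block <- function(ids_, class_, f1, f2 = NULL) {
        data.table(
          read_id = as.character(ids_), class = as.character(class_),
          feat1 = as.character(f1$feat), start1 = as.integer(f1$start),
          end1 = as.integer(f1$end), strand1 = as.character(f1$strand),
          feat2 = if (is.null(f2)) rep(NA_character_, length(ids_)) else as.character(f2$feat),
          start2 = if (is.null(f2)) rep(NA_integer_, length(ids_)) else as.integer(f2$start),
          end2 = if (is.null(f2)) rep(NA_integer_, length(ids_)) else as.integer(f2$end),
          strand2 = if (is.null(f2)) rep(NA_character_, length(ids_)) else as.character(f2$strand)
        )
      }
      truth <- rbind(
        truth_block(n_ids, rep("non_chimeric", n_non), frag_n),
        truth_block(i_ids, rep("intramolecular", n_intra), a1, a2),
        truth_block(p_ids, inter_class, b1, b2)
      )
      seqs <- c(frag_n$seq, paste0(a1$seq, a2$seq), paste0(b1$seq, b2$seq))
      reads <- Biostrings::DNAStringSet(setNames(seqs, ids))
      truth[, replicate := r]
      list(reads = reads, truth = truth)
    })
  }
  structure(list(replicates = replicates, abundances = abundances,
                 config = config, chrom = chrom),
            class = "ligation_sim")
}

#' @export
print.ligation_sim <- function(x, ...) {
  tr <- rbindlist(lapply(x$replicates, `[[`, "truth"))
  cat(sprintf("<ligation_sim> %d replicate(s), %d reads total\n",
              length(x$replicates), nrow(tr)))
  print(tr[, .N, by = class][order(class)])
  invisible(x)
}
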