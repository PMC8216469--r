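## Shared fixtures and independent oracles, all built in code.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(genome_length = 30000, n_genes = 8, n_srnas = 3,
                   n_reads = 400, min_gap = 150, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, args))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

## Upper-tail hypergeometric by direct binomial-coefficient summation
## (exact in double arithmetic for small N; independent of the log-space path).
hyper_oracle_choose <- function(k, K, n, N) {
  lo <- max(k, 0, K + n - N)
  hi <- min(K, n)
  if (lo > hi) return(if (k <= max(0, K + n - N)) 1 else 0)
  if (k <= max(0, K + n - N)) return(1)
  xs <- lo:hi
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

## Literal enumeration of all C(N, n) draws (tiny N only).
hyper_oracle_enum <- function(k, K, n, N) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

## Brute-force read classification: plain loops, no interval machinery.
## Mirrors the documented rules (maximal overlap, smaller-feature then
## lexicographic tie-break, closest-edge feature gaps) independently.
brute_assign <- function(alignments, features, distance_threshold = 2000,
                         junction_gap = 50) {
  ft <- as.data.frame(features)
  aln <- as.data.frame(alignments)
  assign_seg <- function(chrom, s, e) {
    best <- NA_character_; best_ov <- 0; best_len <- Inf
    for (i in seq_len(nrow(ft))) {
      if (ft$chrom[i] != chrom) next
      ov <- min(e, ft$end[i]) - max(s, ft$start[i]) + 1
      if (ov <= 0) next
      len <- ft$length[i]
      if (ov > best_ov || (ov == best_ov && (len < best_len ||
          (len == best_len && ft$id[i] < best)))) {
        best <- ft$id[i]; best_ov <- ov; best_len <- len
      }
    }
    best
  }
  out <- list()
  for (rid in unique(aln$read_id)) {
    rows <- aln[aln$read_id == rid, ]
    if (any(rows$ambiguous)) {
      out[[rid]] <- data.frame(read_id = rid, featureA = NA, featureB = NA,
                               class = "repeat_ambiguous")
      next
    }
    feats <- vapply(seq_len(nrow(rows)), function(i)
      assign_seg(rows$chrom[i], rows$start[i], rows$end[i]), character(1))
    if (anyNA(feats)) {
      out[[rid]] <- data.frame(read_id = rid, featureA = NA, featureB = NA,
                               class = "repeat_ambiguous")
      next
    }
    feats <- sort(feats)
    if (length(feats) != 2) {
      out[[rid]] <- data.frame(read_id = rid, featureA = feats[1],
                               featureB = NA, class = "unassigned")
      next
    }
    if (feats[1] == feats[2]) {
      cls <- "intramolecular"
    } else {
      i <- match(feats[1], ft$id); j <- match(feats[2], ft$id)
      gap <- max(0, max(ft$start[i], ft$start[j]) - min(ft$end[i], ft$end[j]) - 1)
      cls <- if (gap <= junction_gap) "junction_artifact"
        else if (gap <= distance_threshold) "proximal_excluded"
        else "interaction"
    }
    out[[rid]] <- data.frame(read_id = rid, featureA = feats[1],
                             featureB = if (cls == "intramolecular") feats[2] else feats[2],
                             class = cls)
  }
  res <- do.call(rbind, out)
  res[res$class == "repeat_ambiguous", c("featureA", "featureB")] <- NA
  res[order(res$read_id), ]
}

## Random annotation on one chromosome with gaps of at least `min_gap`.
random_annotation <- function(chrom_len, n_feat, min_gap = 1, seed = 1) {
  set.seed(seed)
  repeat {
    starts <- sort(sample.int(chrom_len - 50, n_feat))
    ends <- pmin(starts + sample(20:150, n_feat, replace = TRUE), chrom_len)
    ok <- TRUE
    if (n_feat > 1) ok <- all(starts[-1] - ends[-n_feat] - 1 >= min_gap)
    if (ok) break
  }
  feature_table(id = sprintf("f%03d", seq_len(n_feat)), chrom = "c1",
                start = starts, end = ends,
                strand = sample(c("+", "-"), n_feat, TRUE), ftype = "CDS")
}

## Simulate -> truth alignments -> full interaction calling, reusing a fixed
## genome; per-seed abundances, planted pairs and reads.
run_planted_sim <- function(genome, base_cfg, seed, n_planted = 5, fold = 20) {
  cfg <- base_cfg
  cfg$seed <- seed
  ab <- sim_abundances(cfg, genome$features)
  pk <- character(0)
  if (n_planted > 0) {
    pp <- plant_random_pairs(genome$features, ab, n_planted, fold, seed = seed)
    cfg$planted_pairs <- pp
    pk <- pair_key(pp$featureA, pp$featureB)
  }
  sim <- simulate_ligation(genome, ab, cfg)
  ftu <- make_ua_features(genome$features, genome$chrom_lengths)
  aln <- lapply(sim$replicates, function(r)
    emit_truth_alignments(r$truth, ftu, chrom = names(genome$chrom_lengths)[1]))
  run <- call_interactions_end_to_end(gff = genome$features,
                                      chrom_lengths = genome$chrom_lengths,
                                      alignments = aln)
  list(run = run, planted_keys = pk, sim = sim)
}
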