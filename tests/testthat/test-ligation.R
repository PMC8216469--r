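test_that("frac_chimeric = 0 yields only non-chimeric truth rows", {
  cfg <- tiny_config(frac_chimeric = 0, n_reads = 200, seed = 2)
  g <- generate_genome(cfg)
  sim <- simulate_ligation(g, config = cfg)
  for (r in sim$replicates) {
    expect_true(all(r$truth$class == "non_chimeric"))
    expect_true(all(is.na(r$truth$feat2)))
  }
})

test_that("reads and truth rows are conserved: one row per read, n_reads each", {
  cfg <- tiny_config(n_reads = 300, seed = 4)
  g <- generate_genome(cfg)
  sim <- simulate_ligation(g, config = cfg)
  for (r in sim$replicates) {
    expect_equal(length(r$reads), 300L)
    expect_equal(nrow(r$truth), 300L)
    expect_setequal(names(r$reads), r$truth$read_id)
  }
})

test_that("identical config reproduces identical reads and truth; replicates differ", {
  cfg <- tiny_config(seed = 8, n_reads = 100)
  g <- generate_genome(cfg)
  s1 <- simulate_ligation(g, config = cfg)
  s2 <- simulate_ligation(g, config = cfg)
  expect_identical(as.character(s1$replicates[[1]]$reads),
                   as.character(s2$replicates[[1]]$reads))
  expect_identical(s1$replicates[[2]]$truth, s2$replicates[[2]]$truth)
  expect_false(identical(as.character(s1$replicates[[1]]$reads),
                         as.character(s1$replicates[[2]]$reads)))
})

test_that("read sequences are the concatenated fragment sequences", {
  cfg <- tiny_config(seed = 12, n_reads = 150)
  g <- generate_genome(cfg)
  sim <- simulate_ligation(g, config = cfg)
  tr <- sim$replicates[[1]]$truth
  rd <- sim$replicates[[1]]$reads
  gchr <- as.character(g$genome)
  frag_seq <- function(s, e, strand) {
    sq <- substring(gchr, s, e)
    if (strand == "-") as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq))) else sq
  }
  idx <- which(tr$class != "non_chimeric")[1:20]
  for (i in idx) {
    expect_identical(as.character(rd[[tr$read_id[i]]]),
                     paste0(frag_seq(tr$start1[i], tr$end1[i], tr$strand1[i]),
                            frag_seq(tr$start2[i], tr$end2[i], tr$strand2[i])))
  }
})

test_that("planted pair at 20x enrichment matches the multinomial oracle", {
  # two equal-abundance partners among equal-abundance background
  cfg <- sim_config(genome_length = 60000, n_genes = 12, n_srnas = 0,
                    n_reads = 10000, frac_chimeric = 1,
                    frac_intramolecular_of_chimeric = 0,
                    min_gap = 100, replicate_count = 1, seed = 31,
                    planted_pairs = data.frame(featureA = "gene_001",
                                               featureB = "gene_002", fold = 20))
  g <- generate_genome(cfg)
  ab <- setNames(rep(1, 12), g$features$id)
  sim <- simulate_ligation(g, ab, cfg)
  tr <- sim$replicates[[1]]$truth
  counts <- table(pair_key(tr$feat1, tr$feat2))
  npairs <- choose(12, 2)
  w <- rep(1, npairs); w[1] <- 20          # planted weight among 66 pairs
  p_planted <- 20 / (npairs - 1 + 20)
  expected <- 10000 * p_planted
  sd_mult <- sqrt(10000 * p_planted * (1 - p_planted))
  k_planted <- counts[[pair_key("gene_001", "gene_002")]]
  expect_lt(abs(k_planted - expected), 3 * sd_mult)
  bg_mean <- mean(counts[names(counts) != pair_key("gene_001", "gene_002")])
  expect_gt(k_planted / bg_mean, 20 * 0.75)
  expect_lt(k_planted / bg_mean, 20 * 1.25)
})

test_that("enrichment fold 1 is indistinguishable from background (chi-square over seeds)", {
  counts_total <- NULL
  for (s in 1:10) {
    cfg <- sim_config(genome_length = 60000, n_genes = 10, n_srnas = 0,
                      n_reads = 4000, frac_chimeric = 1,
                      frac_intramolecular_of_chimeric = 0,
                      min_gap = 100, replicate_count = 1, seed = 40 + s,
                      planted_pairs = data.frame(featureA = "gene_001",
                                                 featureB = "gene_002", fold = 1))
    g <- generate_genome(sim_config(genome_length = 60000, n_genes = 10,
                                    n_srnas = 0, n_reads = 1, min_gap = 100,
                                    seed = 40))
    ab <- setNames(rep(1, 10), g$features$id)
    sim <- simulate_ligation(g, ab, cfg)
    tr <- sim$replicates[[1]]$truth
    keys <- pair_key(tr$feat1, tr$feat2)
    all_keys <- utils::combn(g$features$id, 2)
    all_keys <- pair_key(all_keys[1, ], all_keys[2, ])
    cnt <- table(factor(keys, levels = all_keys))
    counts_total <- if (is.null(counts_total)) cnt else counts_total + cnt
  }
  gof <- suppressWarnings(stats::chisq.test(counts_total))
  expect_gt(gof$p.value, 0.05)
})

test_that("background pair frequencies converge to the a_i*a_j model", {
  cfg <- sim_config(genome_length = 80000, n_genes = 10, n_srnas = 0,
                    n_reads = 1e5, frac_chimeric = 1,
                    frac_intramolecular_of_chimeric = 0,
                    min_gap = 100, replicate_count = 1, seed = 17)
  g <- generate_genome(cfg)
  ab <- sim_abundances(cfg, g$features)
  sim <- simulate_ligation(g, ab, cfg)
  tr <- sim$replicates[[1]]$truth
  ids <- g$features$id
  cmb <- utils::combn(ids, 2)
  keys <- pair_key(cmb[1, ], cmb[2, ])
  w <- ab[cmb[1, ]] * ab[cmb[2, ]]
  cnt <- table(factor(pair_key(tr$feat1, tr$feat2), levels = keys))
  gof <- suppressWarnings(stats::chisq.test(cnt, p = w / sum(w)))
  expect_gt(gof$p.value, 0.01)
})

test_that("features shorter than the minimum fragment length are skipped with a warning", {
  ftl <- feature_table(id = c("a", "b", "tiny"), chrom = "c1",
                       start = c(1000, 9000, 20000), end = c(1500, 9400, 20010),
                       strand = "+", ftype = c("CDS", "CDS", "sRNA"))
  g <- generate_genome(tiny_config(seed = 6))
  g$features <- ftl
  g$chrom_lengths <- c(c1 = 30000L)
  names(g$chrom_lengths) <- "c1"
  cfg <- tiny_config(seed = 6, n_reads = 50)
  ab <- setNames(c(1, 1, 1), ftl$id)
  expect_warning(sim <- simulate_ligation(g, ab, cfg), "tiny")
  tr <- rbindlist(lapply(sim$replicates, `[[`, "truth"))
  expect_false("tiny" %in% c(tr$feat1, tr$feat2))
})
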