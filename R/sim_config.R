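#' Simulation configuration for the synthetic ligation library
#'
#' Bundles and validates every knob of the synthetic-data generator: a small
#' annotated genome, per-feature transcript abundances, and a single-end
#' proximity-ligation read library in which chimeric reads join two RNA
#' fragments. Background chimeras form between random transcript pairs at a
#' rate proportional to the product of the partners' abundances; a small set
#' of *planted* pairs ligates at an elevated (`fold`-enriched) rate and serves
#' as ground truth for the downstream enrichment test.
#'
#' @param genome_length Genome size in nt.
#' @param n_genes,n_srnas Number of protein-coding genes (`CDS`) and sRNAs to
#'   place. `n_genes + n_srnas >= 2`.
#' @param abundance_lognormal_mu_sigma Length-2 numeric: meanlog and sdlog of
#'   the log-normal per-feature abundance weights. Heavy-tailed expression is
#'   what structures the background ligation the hypergeometric test must
#'   absorb.
#' @param n_reads Reads per replicate.
#' @param frac_chimeric Fraction of reads that are chimeric (two ligated
#'   fragments), in `[0, 1]`.
#' @param frac_intramolecular_of_chimeric Fraction of chimeric reads whose two
#'   fragments come from the same transcript.
#' @param planted_pairs `NULL`, or a data.frame with columns `featureA`,
#'   `featureB`, `fold` (enrichment factor, `>= 1`) naming pairs whose
#'   ligation rate is multiplied by `fold`.
#' @param fragment_length_range Length-2 integer, min/max fragment length in
#'   nt; minimum `>= 20` so every fragment can seed the toy aligner.
#' @param replicate_count Number of replicate libraries (the assay design uses
#'   duplicates).
#' @param seed Integer RNG seed. Replicate `r` uses stream seed `seed + r`.
#' @param gene_length_range,srna_length_range Feature length ranges in nt.
#' @param min_gap Minimum intergenic gap in nt between placed features.
#' @param chrom_name Name of the single synthetic chromosome.
#' @param circular Logical; treat the chromosome as circular downstream.
#' @param repeat_length If `> 0`, plant one duplicated block of this length in
#'   intergenic space (flagged, so reads from it are expected to be ambiguous).
#' @param seed_length Exact-match seed length of the toy aligner; the genome
#'   is built free of repeated `seed_length`-mers (on either strand) outside
#'   the flagged repeat.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(genome_length = 20000, n_genes = 5, n_srnas = 2,
#'                   n_reads = 500, seed = 7)
#' @export
sim_config <- function(genome_length = 1e5,
                       n_genes = 40,
                       n_srnas = 10,
                       abundance_lognormal_mu_sigma = c(0, 1),
                       n_reads = 20000,
                       frac_chimeric = 0.5,
                       frac_intramolecular_of_chimeric = 0.2,
                       planted_pairs = NULL,
                       fragment_length_range = c(25L, 60L),
                       replicate_count = 2L,
                       seed = 1L,
                       gene_length_range = c(300L, 1500L),
                       srna_length_range = c(80L, 200L),
                       min_gap = 200L,
                       chrom_name = "syn1",
                       circular = FALSE,
                       repeat_length = 0L,
                       seed_length = 20L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    n_srnas = as.integer(n_srnas),
    abundance_lognormal_mu_sigma = as.numeric(abundance_lognormal_mu_sigma),
    n_reads = as.integer(n_reads),
    frac_chimeric = frac_chimeric,
    frac_intramolecular_of_chimeric = frac_intramolecular_of_chimeric,
    planted_pairs = planted_pairs,
    fragment_length_range = as.integer(fragment_length_range),
    replicate_count = as.integer(replicate_count),
    seed = as.integer(seed),
    gene_length_range = as.integer(gene_length_range),
    srna_length_range = as.integer(srna_length_range),
    min_gap = as.integer(min_gap),
    chrom_name = as.character(chrom_name),
    circular = isTRUE(circular),
    repeat_length = as.integer(repeat_length),
    seed_length = as.integer(seed_length)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 0L || n_srnas < 0L || n_genes + n_srnas < 2L)
      stop("need n_genes + n_srnas >= 2", call. = FALSE)
    if (frac_chimeric < 0 || frac_chimeric > 1 ||
        frac_intramolecular_of_chimeric < 0 || frac_intramolecular_of_chimeric > 1)
      stop("fractions must lie in [0, 1]", call. = FALSE)
    if (length(fragment_length_range) != 2L || fragment_length_range[1] < 20L ||
        diff(fragment_length_range) < 0L)
      stop("fragment lengths must be >= 20 nt with min <= max", call. = FALSE)
    if (length(abundance_lognormal_mu_sigma) != 2L ||
        abundance_lognormal_mu_sigma[2] < 0)
      stop("abundance_lognormal_mu_sigma must be c(meanlog, sdlog >= 0)", call. = FALSE)
    if (replicate_count < 1L) stop("replicate_count must be >= 1", call. = FALSE)
    if (n_reads < 0L) stop("n_reads must be >= 0", call. = FALSE)
    if (!is.null(planted_pairs)) {
      pp <- as.data.frame(planted_pairs)
      if (!all(c("featureA", "featureB", "fold") %in% names(pp)))
        stop("planted_pairs needs columns featureA, featureB, fold", call. = FALSE)
      if (any(pp$fold < 1)) stop("planted enrichment fold must be >= 1", call. = FALSE)
      if (any(pp$featureA == pp$featureB))
        stop("planted pairs must join two distinct features", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d nt genome, %d genes + %d sRNAs, %d reads x %d replicates\n",
    x$genome_length, x$n_genes, x$n_srnas, x$n_reads, x$replicate_count))
  cat(sprintf("  frac_chimeric=%.2f (intramolecular %.2f), %d planted pair(s), seed=%d\n",
              x$frac_chimeric, x$frac_intramolecular_of_chimeric,
              if (is.null(x$planted_pairs)) 0L else nrow(as.data.frame(x$planted_pairs)),
              x$seed))
  invisible(x)
}
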