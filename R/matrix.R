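#' Build an interaction count matrix from chimera calls
#'
#' Only `interaction`-class calls increment the pair counts; pairs are stored
#' canonically (`featureA <= featureB`), so the matrix is symmetric by
#' construction and permuting the two fragments of any read changes nothing.
#' Intramolecular counts are tallied separately (they contribute to a
#' feature's expression estimate, not to interactions).
#'
#' The stored marginals are the hypergeometric test's ingredients: `K_f`, the
#' total interaction count involving feature `f` (including the pair's own
#' count), and `N`, the total interaction count of the sample.
#'
#' @param calls A `chimera_calls` table from [assign_reads()].
#' @param feature_universe Optional character vector fixing the feature
#'   universe (needed to validate replicate merges); defaults to all features
#'   seen in `calls`.
#' @param label Optional sample/condition label.
#' @return An `interaction_matrix`: list with `pairs` (`featureA`, `featureB`,
#'   `count`), `marginals` (named `K_f`), `N`, `intramolecular` (per-feature
#'   counts), `class_tally`, `feature_universe`, `label`.
#' @export
build_interaction_matrix <- function(calls, feature_universe = NULL, label = NULL) {
  calls <- as.data.table(calls)
  inter <- calls[class == "interaction"]
  pairs <- if (nrow(inter)) {
    inter[, .(count = .N),
          by = .(featureA = pmin(featureA, featureB),
                 featureB = pmax(featureA, featureB))]
  } else data.table(featureA = character(0), featureB = character(0),
                    count = integer(0))
  setorder(pairs, featureA, featureB)
  intra <- calls[class == "intramolecular", .(count = .N), by = .(feature = featureA)]
  setorder(intra, feature)
  if (is.null(feature_universe)) {
    feature_universe <- sort(unique(stats::na.omit(
      c(calls$featureA, calls$featureB))))
  }
  tal <- calls[, .N, by = class]
  tally <- setNames(tal$N, tal$class)
  out <- list(pairs = pairs,
              marginals = pair_marginals(pairs),
              N = sum(pairs$count),
              intramolecular = intra,
              class_tally = tally,
              feature_universe = sort(feature_universe),
              label = label)
  class(out) <- "interaction_matrix"
  out
}

pair_marginals <- function(pairs) {
  if (!nrow(pairs)) return(setNames(integer(0), character(0)))
  long <- rbind(pairs[, .(feature = featureA, count)],
                pairs[, .(feature = featureB, count)])
  # a self pair would be double-counted here, but self pairs are
  # intramolecular by construction and never enter `pairs`
  marg <- long[, .(K = sum(count)), by = feature]
  setorder(marg, feature)
  setNames(marg$K, marg$feature)
}

#' Sum interaction matrices across replicates
#'
#' Element-wise sum of the pair counts of replicate samples of one condition;
#' marginals and the total are recomputed from the summed counts. All inputs
#' must share one feature universe.
#'
#' @param matrices A list of `interaction_matrix` objects.
#' @param label Optional label for the combined matrix.
#' @return The combined `interaction_matrix`.
#' @export
merge_replicates <- function(matrices, label = NULL) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "interaction_matrix")))
  uni <- matrices[[1L]]$feature_universe
  for (mmat in matrices[-1L]) {
    if (!identical(mmat$feature_universe, uni))
      stop("replicates have mismatched feature universes", call. = FALSE)
  }
  pairs <- rbindlist(lapply(matrices, `[[`, "pairs"))
  pairs <- if (nrow(pairs)) pairs[, .(count = sum(count)), by = .(featureA, featureB)]
    else data.table(featureA = character(0), featureB = character(0), count = integer(0))
  setorder(pairs, featureA, featureB)
  intra <- rbindlist(lapply(matrices, `[[`, "intramolecular"))
  intra <- if (nrow(intra)) intra[, .(count = sum(count)), by = feature]
    else data.table(feature = character(0), count = integer(0))
  setorder(intra, feature)
  tallies <- lapply(matrices, `[[`, "class_tally")
  all_cls <- unique(unlist(lapply(tallies, names)))
  tally <- setNames(vapply(all_cls, function(cl)
    sum(vapply(tallies, function(tt) sum(tt[names(tt) == cl]), numeric(1))),
    numeric(1)), all_cls)
  out <- list(pairs = pairs, marginals = pair_marginals(pairs),
              N = sum(pairs$count), intramolecular = intra,
              class_tally = tally, feature_universe = uni, label = label)
  class(out) <- "interaction_matrix"
  out
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix>%s %d pair(s), N = %d interaction reads\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              nrow(x$pairs), x$N))
  if (nrow(x$pairs)) print(head(x$pairs, 10L))
  invisible(x)
}

#' Write / read an interaction matrix as TSV
#'
#' Columns: `featureA`, `featureB`, `count`, `K_A`, `K_B`, `N`.
#'
#' @param x An `interaction_matrix`.
#' @param path Output (input) file.
#' @return `path` invisibly; for the reader, an `interaction_matrix`.
#' @export
write_interaction_matrix <- function(x, path) {
  dt <- copy(x$pairs)
  dt[, `:=`(K_A = unname(x$marginals[featureA]),
            K_B = unname(x$marginals[featureB]),
            N = x$N)]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = c("featureA", "featureB")))
  pairs <- dt[, .(featureA, featureB, count = as.integer(count))]
  setorder(pairs, featureA, featureB)
  out <- list(pairs = pairs, marginals = pair_marginals(pairs),
              N = sum(pairs$count),
              intramolecular = data.table(feature = character(0), count = integer(0)),
              class_tally = setNames(integer(0), character(0)),
              feature_universe = sort(unique(c(pairs$featureA, pairs$featureB))),
              label = NULL)
  class(out) <- "interaction_matrix"
  out
}
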