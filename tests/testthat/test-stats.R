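test_that("hypergeometric tail matches closed forms and enumeration oracles", {
  expect_equal(hypergeom_pvalue(0, 5, 4, 20), 1)                 # P(X >= 0)
  expect_equal(hypergeom_pvalue(3, 3, 3, 10), 1 / choose(10, 3),
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(2, 5, 4, 20), 1205 / 4845, tolerance = 1e-12)
  # literal enumeration of all C(N, n) draws for small cases
  for (cs in list(c(2, 5, 4, 10), c(1, 3, 6, 9), c(3, 4, 4, 8), c(0, 2, 2, 6))) {
    expect_equal(hypergeom_pvalue(cs[1], cs[2], cs[3], cs[4]),
                 hyper_oracle_enum(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric tail agrees with phyper at large counts", {
  set.seed(7)
  for (i in 1:100) {
    N <- sample(10:50000, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("hypergeometric p is monotone in k and symmetric in (K, n)", {
  ks <- 0:10
  p <- hypergeom_pvalue(ks, 12, 10, 60)
  expect_true(all(diff(p) <= 0))
  expect_equal(hypergeom_pvalue(4, 12, 10, 60), hypergeom_pvalue(4, 10, 12, 60))
  expect_error(hypergeom_pvalue(5, 4, 10, 20), "require")
  expect_error(hypergeom_pvalue(1, 25, 10, 20), "require")
})

test_that("BH step-up reproduces the hand computation and reference values", {
  expect_equal(bh_adjust(0.2), 0.2)                       # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))                 # hand step-up
  expect_equal(bh_adjust(rep(0.03, 7)), rep(0.03, 7))     # equal-p fixed point
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("BH is permutation-equivariant and idempotent on adjusted vectors", {
  set.seed(5)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  q <- bh_adjust(p)
  # an already-adjusted monotone vector is a fixed point up to the cap
  expect_true(all(bh_adjust(sort(q)) >= sort(q) - 1e-12))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("test_all_pairs produces per-pair oracle p-values with BH adjustment", {
  calls <- rbindlist(list(
    data.table(read_id = sprintf("ab%d", 1:6), featureA = "A", featureB = "B",
               class = "interaction"),
    data.table(read_id = sprintf("cd%d", 1:2), featureA = "C", featureB = "D",
               class = "interaction"),
    data.table(read_id = sprintf("ac%d", 1:2), featureA = "A", featureB = "C",
               class = "interaction"),
    data.table(read_id = "bd1", featureA = "B", featureB = "D",
               class = "interaction")))
  m <- build_interaction_matrix(calls)
  res <- test_all_pairs(m)
  expect_equal(nrow(res), 4L)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_raw[i],
                 hyper_oracle_choose(res$k[i], res$K[i], res$n[i], res$N[i]),
                 tolerance = 1e-10)
  }
  expect_equal(sort(res$p_adj), sort(bh_adjust(res$p_raw)))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$k <= pmin(res$K, res$n)))
})

test_that("a single pair filling the whole matrix has p = 1", {
  calls <- data.table(read_id = sprintf("r%d", 1:5), featureA = "A",
                      featureB = "B", class = "interaction")
  res <- test_all_pairs(build_interaction_matrix(calls))
  expect_equal(res$p_raw, 1)
})

test_that("relabeling features leaves the multiset of p-values unchanged", {
  calls <- rbindlist(list(
    data.table(read_id = sprintf("x%d", 1:4), featureA = "A", featureB = "B",
               class = "interaction"),
    data.table(read_id = sprintf("y%d", 1:3), featureA = "B", featureB = "C",
               class = "interaction"),
    data.table(read_id = "z1", featureA = "A", featureB = "C",
               class = "interaction")))
  relabeled <- copy(calls)
  map <- c(A = "Q", B = "R", C = "P")
  relabeled[, `:=`(featureA = map[featureA], featureB = map[featureB])]
  p1 <- sort(test_all_pairs(build_interaction_matrix(calls))$p_raw)
  p2 <- sort(test_all_pairs(build_interaction_matrix(relabeled))$p_raw)
  expect_equal(p1, p2)
})

test_that("significant sets are nested, thresholded and deterministically ordered", {
  res <- data.table(featureA = c("A", "B", "C", "D"),
                    featureB = c("X", "Y", "Z", "W"),
                    k = 1L, K = 1L, n = 1L, N = 10L,
                    p_raw = c(0.01, 0.03, 0.5, 1.0),
                    p_adj = c(0.04, 0.09, 0.8, 1.0))
  sig <- extract_significant(res)
  expect_equal(sig$raw$featureA, c("A", "B"))
  expect_equal(sig$fdr$featureA, "A")                 # p_adj 0.09 fails FDR
  expect_true(all(sig$fdr$featureA %in% sig$raw$featureA))
  all_null <- copy(res)[, `:=`(p_raw = 1, p_adj = 1)]
  sig2 <- extract_significant(all_null)
  expect_equal(nrow(sig2$raw), 0L)
  expect_equal(nrow(sig2$fdr), 0L)
})

test_that("empty matrices test to empty result tables", {
  m <- build_interaction_matrix(data.table(read_id = character(0),
                                           featureA = character(0),
                                           featureB = character(0),
                                           class = character(0)))
  expect_equal(nrow(test_all_pairs(m)), 0L)
})
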