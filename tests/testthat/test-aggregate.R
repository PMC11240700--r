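test_that("largest-lesion selection follows volume with a deterministic tie rule", {
  X <- matrix(1:6, 3, 2, dimnames = list(NULL, c("f1", "f2")))
  sel <- select_largest_lesion(X, c(3, 9, 5), c("L1", "L2", "L3"))
  expect_equal(as.numeric(sel), unname(X[2, ]))
  expect_equal(attr(sel, "lesion_id"), "L2")

  ## tie: the smaller identifier wins
  sel2 <- select_largest_lesion(X[1:2, ], c(4, 4), c("L2", "L1"))
  expect_equal(attr(sel2, "lesion_id"), "L1")

  ## permuting lesion order does not change the selection
  set.seed(4)
  X4 <- matrix(rnorm(20), 5, 4)
  vols <- c(2, 8, 8, 1, 5)
  ids <- paste0("L", 1:5)
  base <- select_largest_lesion(X4, vols, ids)
  for (r in 1:10) {
    p <- sample(5)
    perm <- select_largest_lesion(X4[p, ], vols[p], ids[p])
    expect_equal(attr(perm, "lesion_id"), attr(base, "lesion_id"))
  }
  expect_error(select_largest_lesion(X, c(1, NA, 2)), "required")
})

test_that("min/avg/max summaries reduce columnwise with the right prefixes", {
  X <- matrix(c(1, 3, 5, 3), 2, 2, dimnames = list(NULL, c("a", "b")))
  s <- summarize_min_avg_max(X)
  expect_equal(unname(s[c("min_a", "min_b")]), c(1, 3))
  expect_equal(unname(s[c("avg_a", "avg_b")]), c(2, 4))
  expect_equal(unname(s[c("max_a", "max_b")]), c(3, 5))

  ## identical lesions: min = avg = max
  Xi <- matrix(rep(c(2, -1), each = 3), 3, 2, dimnames = list(NULL, c("a", "b")))
  si <- summarize_min_avg_max(Xi)
  expect_equal(unname(si[c("min_a", "avg_a", "max_a")]), rep(2, 3))

  ## 15 random lesions match the brute-force columnwise reduction
  set.seed(9)
  Xr <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(NULL, paste0("f", 1:4)))
  sr <- summarize_min_avg_max(Xr)
  for (j in 1:4) {
    expect_equal(unname(sr[paste0("min_f", j)]), min(Xr[, j]))
    expect_equal(unname(sr[paste0("avg_f", j)]), mean(Xr[, j]))
    expect_equal(unname(sr[paste0("max_f", j)]), max(Xr[, j]))
  }
})

test_that("pairwise distances reproduce hand-computed values", {
  a <- c(1, 0); b <- c(0, 1)
  expect_equal(pairwise_lesion_distance(a, b, "canberra"), 2)
  expect_equal(pairwise_lesion_distance(a, b, "chebyshev"), 1)
  expect_equal(pairwise_lesion_distance(a, b, "euclidean"), sqrt(2))
  expect_equal(pairwise_lesion_distance(a, b, "minkowski", p = 3), 2^(1 / 3))

  ## identity: all metrics 0 (Spearman needs a non-constant vector)
  v <- c(1, 2, 3)
  for (m in ipith_metrics()) {
    expect_equal(pairwise_lesion_distance(v, v, m), 0, info = m)
  }
  ## perfect anticorrelation: Spearman distance 2
  expect_equal(pairwise_lesion_distance(c(1, 2, 3), c(3, 2, 1), "spearman"), 2)
  ## Canberra 0/0 terms contribute nothing
  expect_equal(pairwise_lesion_distance(c(0, 1), c(0, 3), "canberra"), 0.5)
  ## generalized Jaccard on all-zero vectors is 0 by convention
  expect_equal(pairwise_lesion_distance(c(0, 0), c(0, 0), "jaccard"), 0)
  expect_error(pairwise_lesion_distance(1, c(1, 2)), "dimension")
})

test_that("distance axioms hold on random pairs and triples", {
  set.seed(12)
  d <- 7
  for (r in 1:25) {
    a <- rnorm(d); b <- rnorm(d); c0 <- rnorm(d)
    for (m in ipith_metrics()) {
      ## Jaccard's documented domain is per-feature min-max rescaled [0, 1]
      if (m == "jaccard") {
        dab <- pairwise_lesion_distance(pnorm(a), pnorm(b), m)
        expect_equal(dab, pairwise_lesion_distance(pnorm(b), pnorm(a), m))
      } else {
        dab <- pairwise_lesion_distance(a, b, m)
        expect_equal(dab, pairwise_lesion_distance(b, a, m), info = m)
      }
      expect_gte(dab, 0)
    }
    ## triangle inequality for the norm-induced metrics
    for (m in c("euclidean", "chebyshev", "minkowski")) {
      expect_lte(pairwise_lesion_distance(a, c0, m),
                 pairwise_lesion_distance(a, b, m) +
                   pairwise_lesion_distance(b, c0, m) + 1e-12)
    }
    ## Chebyshev <= Euclidean <= sqrt(d) * Chebyshev; Canberra <= d
    che <- pairwise_lesion_distance(a, b, "chebyshev")
    euc <- pairwise_lesion_distance(a, b, "euclidean")
    expect_lte(che, euc + 1e-12)
    expect_lte(euc, sqrt(d) * che + 1e-12)
    expect_lte(pairwise_lesion_distance(a, b, "canberra"), d)
  }
})

test_that("IPITH summaries behave at k = 2 and match brute force at k = 4", {
  X2 <- matrix(rnorm(10), 2, 5, dimnames = list(NULL, paste0("f", 1:5)))
  s <- ipith_summaries(X2, "euclidean")
  expect_equal(unname(s["euclidean_range"]), 0)
  expect_equal(unname(s["euclidean_min"]), unname(s["euclidean_max"]))
  expect_equal(unname(s["euclidean_min"]), unname(s["euclidean_mean"]))

  set.seed(6)
  X4 <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(NULL, paste0("f", 1:6)))
  for (m in c("euclidean", "canberra", "chebyshev", "minkowski")) {
    s4 <- ipith_summaries(X4, m)
    dd <- c()
    for (i in 1:3) for (j in (i + 1):4) {
      dd <- c(dd, pairwise_lesion_distance(X4[i, ], X4[j, ], m))
    }
    expect_equal(unname(s4), c(min(dd), mean(dd), max(dd), max(dd) - min(dd)),
                 info = m)
  }

  ## lesion ordering does not change the summaries
  p <- c(3, 1, 4, 2)
  expect_equal(ipith_summaries(X4[p, ], "canberra"),
               ipith_summaries(X4, "canberra"))
})

test_that("constant lesion vectors yield Spearman distance 0 with a warning", {
  X <- rbind(rep(1, 4), c(1, 2, 3, 4))
  colnames(X) <- paste0("f", 1:4)
  expect_warning(s <- ipith_summaries(X, "spearman"), "undefined")
  expect_equal(unname(s["spearman_mean"]), 0)
})

test_that("scaling lesion deviations by c scales the norm-metric summaries by c", {
  set.seed(15)
  centroid <- rnorm(6)
  dev <- matrix(rnorm(4 * 6), 4, 6)
  X1 <- sweep(dev, 2, centroid, `+`)
  X3 <- sweep(3 * dev, 2, centroid, `+`)
  colnames(X1) <- colnames(X3) <- paste0("f", 1:6)
  for (m in c("euclidean", "chebyshev", "minkowski")) {
    expect_equal(unname(ipith_summaries(X3, m)[1:3]),
                 3 * unname(ipith_summaries(X1, m)[1:3]), info = m)
  }
})

test_that("the patient predictor table assembles all column families", {
  co <- small_cohort(n = 20, p = 5, seed = 10)
  tab <- cohort_predictor_table(co)
  expect_equal(nrow(tab), 20)
  expect_true(all(c("largest_rf_01", "min_rf_01", "avg_rf_01", "max_rf_01",
                    "canberra_mean", "jaccard_range", "who_ps") %in% names(tab)))
  ## IPITH summary columns are center scaled across the cohort
  expect_lt(abs(mean(tab$canberra_mean)), 1e-12)
  ## a zero-heterogeneity cohort has all-zero distances before scaling
  co0 <- small_cohort(n = 12, p = 5, seed = 3, heterogeneity_scale = 0)
  fc <- grep("^rf_", names(co0$lesions), value = TRUE)
  cs <- center_scale(co0$lesions[, fc])
  l2 <- co0$lesions; l2[, fc] <- cs$scaled
  pt0 <- suppressWarnings(
    patient_predictor_table(l2, fc, metrics = c("euclidean", "canberra"),
                            scale_ipith = FALSE))
  expect_equal(max(abs(pt0$euclidean_max)), 0)
  expect_equal(max(abs(pt0$canberra_mean)), 0)
})
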