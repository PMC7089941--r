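quiet <- function(expr) suppressMessages(suppressWarnings(expr))

test_that("standardize centers and scales rows by population SD", {
  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("g1", c("a", "b", "c")))
  z <- standardize(m)
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  m2 <- rbind(m, g2 = c(5, 5, 5))
  expect_warning(z2 <- standardize(m2), "zero-variance")
  expect_equal(rownames(z2), "g1")
  expect_error(suppressWarnings(standardize(m2["g2", , drop = FALSE])),
               "zero variance")

  # idempotence
  set.seed(1)
  m3 <- matrix(rnorm(50), nrow = 5,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  expect_equal(standardize(standardize(m3)), standardize(m3))
})

test_that("cluster_samples recovers a separable plant and canonicalizes ids", {
  sig <- toy_signature("fibrosis")
  sim <- gen_expression(c(20, 20), sig, shift = 10, noise_sd = 1, seed = 11)
  truth <- setNames(sim$truth$subgroup_true, sim$truth$sample)

  cl <- quiet(cluster_samples(sim$expr, sig, k = 2))
  expect_equal(ari(cl$cluster, truth[cl$sample]), 1)

  # column permutation leaves the canonical assignment unchanged
  perm <- sim$expr[, c("gene", sample(setdiff(names(sim$expr), "gene")))]
  cl2 <- quiet(cluster_samples(perm, sig, k = 2))
  expect_equal(dplyr::arrange(cl2, sample), dplyr::arrange(cl, sample))

  # duplicated samples co-cluster
  m <- as_expr_matrix(sim$expr)
  dup <- cbind(m, `dup1` = m[, 1], `dup2` = m[, 2])
  cl3 <- quiet(cluster_samples(dup, sig, k = 2))
  expect_equal(cl3$cluster[cl3$sample == "dup1"],
               cl3$cluster[cl3$sample == colnames(m)[1]])

  expect_error(quiet(cluster_samples(sim$expr, sig, k = 50)), "exceeds")
})

test_that("name_clusters maps clusters by up-gene scores, symmetrically", {
  sig <- toy_signature("fibrosis")
  sim <- gen_expression(c(15, 15), sig, shift = 8, seed = 12)
  truth <- setNames(sim$truth$subgroup_true, sim$truth$sample)
  cl <- quiet(cluster_samples(sim$expr, sig, k = 2))
  named <- quiet(name_clusters(cl, sim$expr, sig))
  expect_equal(unname(setNames(named$label, named$sample)[names(truth)]),
               unname(truth))

  # swapping the two set names swaps the labels
  swapped <- sig
  swapped$set <- ifelse(sig$set == "Fibrosis_up", "non_Fibrosis_up", "Fibrosis_up")
  named2 <- quiet(name_clusters(cl, sim$expr, swapped))
  expect_true(all(named$label != named2$label))
})

test_that("classify recovers planted 2- and 4-group structure", {
  sig2 <- toy_signature("fibrosis")
  sim2 <- gen_expression(c(25, 25), sig2, shift = 10, seed = 13)
  a2 <- quiet(classify(sim2$expr, sig2, k = 2))
  truth2 <- setNames(sim2$truth$subgroup_true, sim2$truth$sample)
  expect_equal(unname(setNames(a2$label, a2$sample)[names(truth2)]),
               unname(truth2))

  # euclidean and pearson agree on the zero-noise-equivalent plant
  a2p <- quiet(classify(sim2$expr, sig2, k = 2, distance = "pearson"))
  expect_equal(dplyr::arrange(as_tibble(a2p), sample)$label,
               dplyr::arrange(as_tibble(a2), sample)$label)

  sig4 <- toy_signature("dimp")
  sim4 <- gen_expression(c(12, 12, 12, 12), sig4, shift = 10, seed = 14)
  a4 <- quiet(classify(sim4$expr, sig4, k = 4))
  truth4 <- setNames(sim4$truth$subgroup_true, sim4$truth$sample)
  expect_equal(unname(setNames(a4$label, a4$sample)[names(truth4)]),
               unname(truth4))
})

test_that("classify is invariant to per-gene scalar shifts", {
  sig <- toy_signature("fibrosis")
  sim <- gen_expression(c(15, 15), sig, shift = 5, seed = 15)
  a <- quiet(classify(sim$expr, sig, k = 2))
  shifted <- sim$expr
  shifted[3, -1] <- shifted[3, -1] + 100  # uniform shift on one gene row
  a2 <- quiet(classify(shifted, sig, k = 2))
  expect_equal(dplyr::arrange(as_tibble(a2), sample),
               dplyr::arrange(as_tibble(a), sample))
})

test_that("ARI grows monotonically with the planted shift", {
  sig <- toy_signature("fibrosis")
  med_ari <- purrr::map_dbl(c(0.5, 2, 6), function(shift) {
    median(purrr::map_dbl(1:10, function(s) {
      sim <- gen_expression(c(20, 20), sig, shift = shift, seed = 1000 + s)
      a <- quiet(classify(sim$expr, sig, k = 2))
      truth <- setNames(sim$truth$subgroup_true, sim$truth$sample)
      ari(a$label, truth[a$sample])
    }))
  })
  expect_true(med_ari[1] <= med_ari[2] + 1e-9)
  expect_true(med_ari[2] <= med_ari[3] + 1e-9)
  expect_equal(med_ari[3], 1)
})

test_that("classify aborts when too few signature genes match", {
  sig <- toy_signature("fibrosis")
  sim <- gen_expression(c(10, 10), sig, shift = 5, seed = 16)
  m <- as_expr_matrix(sim$expr)
  few <- m[c(sprintf("FIB%02d", 1:3), sprintf("BG%04d", 1:50)), ]  # 3/38 match
  expect_error(quiet(classify(few, sig, k = 2)), "50%")
  expect_error(quiet(classify(m[sprintf("BG%04d", 1:50), ], sig, k = 2)),
               "no signature gene")
})

test_that("concordance cross-tabulates with row percentages", {
  a <- tibble::tibble(sample = c("s1", "s2", "s3"), label = c("X", "X", "Y"))
  b <- tibble::tibble(sample = c("s1", "s2", "s3"), label = c("U", "V", "V"))
  tab <- quiet(concordance(a, b))
  expect_equal(as.vector(as.matrix(tab)), c(1, 0, 1, 1))
  expect_equal(tab$row_pct[tab$label_a == "X"], c(50, 50))

  # transpose symmetry
  tba <- quiet(concordance(b, a))
  expect_equal(as.matrix(tba), t(as.matrix(tab)))

  # identical assignments give a diagonal table
  d <- quiet(concordance(a, a))
  m <- as.matrix(d)
  expect_equal(m[upper.tri(m) | lower.tri(m)], rep(0, 2))
  expect_equal(diag(m), c(X = 2, Y = 1))

  # marginals equal label frequencies
  expect_equal(rowSums(as.matrix(tab)), c(X = 2, Y = 1))
  expect_equal(colSums(as.matrix(tab)), c(U = 1, V = 2))

  expect_error(concordance(a, tibble::tibble(sample = "zz", label = "U")),
               "no samples")
})

test_that("pca_subgroup_association finds the planted axis and respects ranks", {
  sig <- toy_signature("fibrosis")
  sim <- gen_expression(c(20, 20), sig, shift = 4, seed = 17)
  a <- quiet(classify(sim$expr, sig, k = 2))
  res <- quiet(pca_subgroup_association(sim$expr, sig, a, n_components = 4))
  expect_equal(nrow(res), 4)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # the dominant component carries the group split
  expect_equal(which.min(res$p_value), 1L)
  expect_lt(res$p_value[1], 1e-6)

  bad <- a
  bad$label <- "one_level"
  expect_error(quiet(pca_subgroup_association(sim$expr, sig, bad)), "2 levels")
})

test_that("pca association p-values are null-uniform for random labels", {
  sig <- toy_signature("fibrosis")
  sim <- gen_expression(c(30, 30), sig, shift = 0, seed = 18)
  ps <- purrr::map_dbl(1:200, function(s) {
    set.seed(3000 + s)
    lab <- sample(rep(c("g1", "g2"), each = 30))
    a <- structure(tibble::tibble(sample = sim$truth$sample, label = lab),
                   scheme = "null", class = c("subgroup_assignment", "tbl_df",
                                              "tbl", "data.frame"))
    quiet(pca_subgroup_association(sim$expr, sig, a, n_components = 1))$p_value
  })
  # rank-test p-values are discrete, so identical values across seeds are
  # possible; the KS statistic itself is unaffected
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("dichotomize_by_median splits with ties to low", {
  expect_equal(unname(dichotomize_by_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(unname(dichotomize_by_median(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  # permutation equivariance
  v <- c(a = 3, b = 1, c = 4, d = 2)
  expect_equal(dichotomize_by_median(v)[c("b", "d", "a", "c")],
               dichotomize_by_median(v[c("b", "d", "a", "c")]))
  expect_error(dichotomize_by_median(c(2, 2, 2)), "identical")
  expect_error(dichotomize_by_median(3), "at least 2")
})
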