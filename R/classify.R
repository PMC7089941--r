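#' Standardize expression rows
#'
#' Centers each gene to mean zero and scales to unit variance across samples
#' (population standard deviation, so a row `(1, 2, 3)` maps to
#' `(-1.2247, 0, 1.2247)`). Zero-variance genes carry no contrast and are
#' dropped with a warning.
#'
#' @param expr Expression tibble (`gene` column) or genes x samples matrix.
#' @return Same container type as the input, standardized.
#' @export
standardize <- function(expr) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 2) abort("standardize needs at least 2 samples")
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  keep <- sd_pop > 0
  if (!any(keep)) abort("all genes have zero variance")
  if (!all(keep)) {
    warn(paste0(sum(!keep), " zero-variance gene(s) dropped: ",
                paste(head(rownames(m)[!keep], 5), collapse = ", ")))
  }
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  if (is.matrix(expr)) return(z)
  out <- tibble(gene = rownames(z))
  dplyr::bind_cols(out, as_tibble(z))
}

# restrict a matrix to the genes of a signature scheme, with match logging
signature_submatrix <- function(m, signature, scheme = NULL, force = FALSE) {
  stopifnot(is.data.frame(signature))
  if (!is.null(scheme)) signature <- filter(signature, .data$scheme == !!scheme)
  if (nrow(signature) == 0) abort("signature has no gene sets (check scheme name)")
  genes <- unique(signature$gene)
  present <- intersect(genes, rownames(m))
  frac <- length(present) / length(genes)
  inform(sprintf("signature gene match: %d/%d (%.0f%%)",
                 length(present), length(genes), 100 * frac))
  if (length(present) == 0) abort("no signature gene present in the expression matrix")
  if (frac < 0.5 && !force) {
    abort(sprintf(
      "only %.0f%% of signature genes matched (< 50%%); pass force = TRUE to proceed",
      100 * frac))
  }
  m[present, , drop = FALSE]
}

#' Cluster samples on signature genes
#'
#' Restricts the expression matrix to the genes of one signature scheme,
#' standardizes the rows, and clusters the samples agglomeratively with
#' Ward's minimum-variance criterion (the `ward.D2` convention, i.e. the
#' Lance-Williams update on squared distances), cutting the dendrogram into
#' exactly `k` groups. Distance between samples is either Euclidean or the
#' Pearson correlation distance `1 - r`. Cluster ids are canonicalized by
#' decreasing cluster size, ties by the first sample id, so the output is
#' invariant to column order.
#'
#' @param expr Expression tibble or matrix.
#' @param signature A `gene_signature` tibble.
#' @param k Number of clusters.
#' @param distance `"euclidean"` or `"pearson"`.
#' @param scheme Optional scheme name when `signature` holds several.
#' @param force Proceed below 50% signature-gene match.
#' @return A tibble with columns `sample`, `cluster` (integer in `1:k`).
#' @export
cluster_samples <- function(expr, signature, k = 2,
                            distance = c("euclidean", "pearson"),
                            scheme = NULL, force = FALSE) {
  distance <- match.arg(distance)
  m <- as_expr_matrix(expr)
  if (k > ncol(m)) abort("k exceeds the number of samples")
  m <- signature_submatrix(m, signature, scheme = scheme, force = force)
  z <- suppressWarnings(standardize(m))
  x <- t(z)  # samples in rows
  d <- switch(distance,
    euclidean = dist(x),
    pearson = stats::as.dist(1 - cor(t(x)))
  )
  raw <- cutree(hclust(d, method = "ward.D2"), k = k)
  # canonical ids: largest cluster first, first-sample id breaks ties
  sizes <- table(raw)
  first_sample <- tapply(colnames(m), raw, function(s) sort(s)[1])
  ord <- order(-as.integer(sizes), first_sample)
  relabel <- setNames(seq_len(k), names(sizes)[ord])
  tibble(sample = colnames(m),
         cluster = as.integer(relabel[as.character(raw)]))
}

#' Name clusters from up-gene set scores
#'
#' Maps raw cluster ids to subtype labels: each cluster is scored by the mean
#' standardized expression of every label's up-gene set, and labels are
#' assigned by greedy maximum-score matching (largest score first; exact ties
#' broken by set order, with a message). Labels are the signature set names
#' with a trailing `_up` stripped.
#'
#' @param clusters Tibble `sample`, `cluster` from [cluster_samples()].
#' @inheritParams cluster_samples
#' @return A tibble of class `subgroup_assignment` with columns `sample`,
#'   `label`; attribute `scheme` records the scheme name.
#' @export
name_clusters <- function(clusters, expr, signature, scheme = NULL,
                          force = FALSE) {
  m <- as_expr_matrix(expr)
  if (!is.null(scheme)) signature <- filter(signature, .data$scheme == !!scheme)
  sets <- split(signature$gene, signature$set)
  k <- length(unique(clusters$cluster))
  if (length(sets) < k) {
    abort(paste0("signature scheme has ", length(sets),
                 " gene sets but ", k, " clusters need labels"))
  }
  msub <- signature_submatrix(m, signature, force = force)
  z <- suppressWarnings(standardize(msub))
  score <- matrix(NA_real_, nrow = k, ncol = length(sets),
                  dimnames = list(seq_len(k), names(sets)))
  for (ci in seq_len(k)) {
    in_cluster <- clusters$sample[clusters$cluster == ci]
    for (si in seq_along(sets)) {
      genes <- intersect(sets[[si]], rownames(z))
      if (length(genes) == 0) next
      score[ci, si] <- mean(z[genes, in_cluster, drop = FALSE])
    }
  }
  if (any(apply(score, 1, function(r) length(unique(r[is.finite(r)])) <= 1))) {
    abort("cluster scores tie across all labels; map clusters to labels manually")
  }
  # greedy matching, largest score first
  assignment <- rep(NA_character_, k)
  sc <- score
  for (step in seq_len(k)) {
    best <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)
    if (nrow(best) > 1) {
      best <- best[order(best[, "col"]), , drop = FALSE]
      inform("score tie during cluster naming; broken by gene-set order")
    }
    ci <- best[1, "row"]; si <- best[1, "col"]
    assignment[ci] <- colnames(sc)[si]
    sc[ci, ] <- -Inf; sc[, si] <- -Inf
  }
  labels <- sub("_up$", "", assignment)
  out <- tibble(sample = clusters$sample,
                label = labels[clusters$cluster])
  scheme_name <- unique(signature$scheme)[1]
  structure(out, scheme = scheme_name,
            class = c("subgroup_assignment", class(out)))
}

#' Classify samples under a gene-signature scheme
#'
#' End-to-end subtype assignment: [standardize()] the signature-gene
#' submatrix, [cluster_samples()] with Ward agglomeration, and
#' [name_clusters()] by up-gene scores. `k = 2` fits two-group schemes
#' (Fibrosis/non-Fibrosis, C1/C2-C6, M1/M2-M4); `k = 4` the D-I-M-P scheme.
#'
#' @inheritParams cluster_samples
#' @return A `subgroup_assignment` tibble (`sample`, `label`).
#' @examples
#' sig <- toy_signature("fibrosis")
#' sim <- gen_expression(c(20, 20), sig, shift = 10, seed = 1)
#' classify(sim$expr, sig, k = 2)
#' @export
classify <- function(expr, signature, k = 2,
                     distance = c("euclidean", "pearson"),
                     scheme = NULL, force = FALSE) {
  distance <- match.arg(distance)
  cl <- cluster_samples(expr, signature, k = k, distance = distance,
                        scheme = scheme, force = force)
  name_clusters(cl, expr, signature, scheme = scheme, force = force)
}

#' Cross-tabulate two subgroup assignments
#'
#' Counts label combinations over the intersection of the two sample sets and
#' adds row percentages (share of each `label_a` falling in each `label_b`).
#'
#' @param a,b `subgroup_assignment` tibbles (or any tibble with `sample`,
#'   `label`).
#' @return A tibble of class `concordance` with columns `label_a`, `label_b`,
#'   `n`, `row_pct`.
#' @export
concordance <- function(a, b) {
  common <- intersect(a$sample, b$sample)
  if (length(common) == 0) abort("assignments share no samples")
  inform(paste0("concordance over ", length(common), " shared samples"))
  la <- setNames(a$label, a$sample)[common]
  lb <- setNames(b$label, b$sample)[common]
  out <- tidyr::expand_grid(label_a = sort(unique(la)),
                            label_b = sort(unique(lb))) %>%
    mutate(n = purrr::map2_int(.data$label_a, .data$label_b,
                               ~ sum(la == .x & lb == .y))) %>%
    group_by(.data$label_a) %>%
    mutate(row_pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
  structure(out, class = c("concordance", class(out)))
}

#' @export
as.matrix.concordance <- function(x, ...) {
  tidyr::pivot_wider(as_tibble(x)[, c("label_a", "label_b", "n")],
                     names_from = "label_b", values_from = "n") %>%
    tibble::column_to_rownames("label_a") %>%
    as.matrix()
}

#' Associate principal components with a two-group assignment
#'
#' Runs PCA on the standardized signature-gene submatrix (samples as
#' observations) and, for each of the first `n_components` components, tests
#' whether the component scores differ between the two groups — by default a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test, optionally Welch's t.
#' P-values are reported per component, unadjusted.
#'
#' @inheritParams cluster_samples
#' @param assignment A two-level `subgroup_assignment`.
#' @param n_components Number of leading components to test.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return A tibble with columns `component`, `p_value`, `group_factor`,
#'   `var_explained`.
#' @export
pca_subgroup_association <- function(expr, signature, assignment,
                                     n_components = 5,
                                     test = c("wilcox", "t"),
                                     scheme = NULL, force = FALSE) {
  test <- match.arg(test)
  m <- as_expr_matrix(expr)
  m <- m[, intersect(colnames(m), assignment$sample), drop = FALSE]
  lab <- setNames(assignment$label, assignment$sample)[colnames(m)]
  levs <- unique(lab)
  if (length(levs) != 2) abort("assignment must have exactly 2 levels")
  if (min(table(lab)) < 3) abort("each group needs at least 3 samples")
  msub <- signature_submatrix(m, signature, scheme = scheme, force = force)
  z <- suppressWarnings(standardize(msub))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  purrr::map_dfr(seq_len(n_components), function(i) {
    s <- pc$x[, i]
    p <- if (test == "wilcox") {
      wilcox.test(s[lab == levs[1]], s[lab == levs[2]], exact = FALSE)$p.value
    } else {
      stats::t.test(s[lab == levs[1]], s[lab == levs[2]])$p.value
    }
    tibble(component = i, p_value = p,
           group_factor = attr(assignment, "scheme") %||% "group",
           var_explained = ve[i])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dichotomize a measurement at its median
#'
#' Splits samples into `high` (strictly above the median) and `low` (at or
#' below — ties go to `low`). Used e.g. for miR-200 family expression groups.
#'
#' @param values Numeric vector, optionally named by sample.
#' @return Character vector of `"high"`/`"low"`, same names as input.
#' @examples
#' dichotomize_by_median(c(a = 1, b = 2, c = 3, d = 4))
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) < 2) abort("need at least 2 values")
  if (any(!is.finite(values))) abort("values must be finite")
  if (length(unique(values)) == 1) abort("all values identical; no median split possible")
  med <- median(values)
  setNames(ifelse(values > med, "high", "low"), names(values))
}
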