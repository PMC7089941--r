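#' Published TCGA HGSOC association counts
#'
#' Cross-tabulated counts, transcribed from published association tables for
#' the TCGA high-grade serous ovarian carcinoma cohort, between each of the
#' three classifications — Fibrosis/non-Fibrosis (`"fibrosis"`), the four
#' D-I-M-P subtypes (`"dimp"`), and the LST/HRD genomic signature (`"lst"`) —
#' and ten clinical or molecular variables (grade, stage, debulking, platinum
#' resistance, primary therapy outcome, BRCA1/2 mutation, BRCA1 and RAD51C
#' promoter methylation, the other signature, ploidy). Denominators vary by
#' variable because missing values were dropped pairwise.
#'
#' These counts let the per-variable Fisher's exact tests of the published
#' analysis be recomputed from scratch; see [association_fisher()].
#'
#' @return A tibble: `classification`, `variable`, `level`, `group`, `count`.
#' @examples
#' counts <- tcga_association_counts()
#' association_fisher(counts, "fibrosis", "stage")
#' @export
tcga_association_counts <- function() {
  path <- system.file("extdata", "tcga_association_counts.csv",
                      package = "hgsocstrat", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccccd", progress = FALSE)
}

#' Fisher's exact test on one published association table
#'
#' Rebuilds the level x group contingency table for one classification and
#' variable from [tcga_association_counts()] (or any tibble of the same
#' shape) and runs [fisher_exact()] on it.
#'
#' @param counts Tibble with columns `classification`, `variable`, `level`,
#'   `group`, `count`.
#' @param classification,variable Which table to test.
#' @return A one-row tibble: `classification`, `variable`, `n`, `p_value`,
#'   `odds_ratio`, `method`.
#' @export
association_fisher <- function(counts, classification, variable) {
  sub <- filter(counts, .data$classification == !!classification,
                .data$variable == !!variable)
  if (nrow(sub) == 0) {
    abort(paste0("no counts for classification '", classification,
                 "', variable '", variable, "'"))
  }
  tab <- tidyr::pivot_wider(sub[, c("level", "group", "count")],
                            names_from = "group", values_from = "count") %>%
    tibble::column_to_rownames("level") %>%
    as.matrix()
  ft <- fisher_exact(tab)
  tibble(classification = classification, variable = variable,
         n = sum(tab), p_value = ft$p_value, odds_ratio = ft$odds_ratio,
         method = ft$method)
}
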