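#' Combine genomic and transcriptomic calls into four strata
#'
#' Crosses the HRD call (`LST_high`/`LST_low`) with a two-group subtype
#' assignment into the four prognostic strata, e.g. `LST_high/non_Fibrosis`.
#' Samples missing either call are excluded with a message reporting the
#' count; stratum sizes always sum to the size of the intersection.
#'
#' @param lst_calls An `hrd_calls` tibble ([call_hrd()]) or any tibble with
#'   `sample`, `lst_class`.
#' @param assignment A `subgroup_assignment` tibble (`sample`, `label`).
#' @return A tibble of class `combined_strata`: `sample`, `lst_class`,
#'   `label`, `stratum`.
#' @export
combine_strata <- function(lst_calls, assignment) {
  both <- inner_join(select(as_tibble(lst_calls), "sample", "lst_class"),
                     select(as_tibble(assignment), "sample", "label"),
                     by = "sample")
  if (nrow(both) == 0) abort("no sample has both an LST call and a subtype label")
  dropped <- length(union(lst_calls$sample, assignment$sample)) - nrow(both)
  if (dropped > 0) {
    inform(paste0(dropped, " sample(s) missing one of the two calls were excluded"))
  }
  out <- mutate(both, stratum = paste(.data$lst_class, .data$label, sep = "/"))
  sizes <- count(out, .data$stratum)
  inform(paste0("strata: ",
                paste(sizes$stratum, sizes$n, sep = "=", collapse = ", ")))
  structure(out, class = c("combined_strata", class(out)))
}

#' Association report between an assignment and clinical variables
#'
#' For each declared categorical variable, cross-tabulates subtype labels
#' against variable levels (missing values dropped per variable, so
#' denominators vary as in published cohort tables), computes per-group
#' percentages, and runs [fisher_exact()]. Variables with a single observed
#' level are skipped with a warning.
#'
#' @param assignment A `subgroup_assignment` (or tibble with `sample`,
#'   `label`).
#' @param clinical Clinical tibble ([read_clinical()]).
#' @param variables Character vector of clinical column names to test.
#' @return A tibble with one row per variable: `variable`, `n`, `p_value`,
#'   `method` and `counts` (list column of level x group counts with
#'   `group_pct`).
#' @export
association_report <- function(assignment, clinical, variables) {
  data <- inner_join(select(as_tibble(assignment), "sample", "label"),
                     as_tibble(clinical), by = "sample")
  if (nrow(data) == 0) abort("assignment and clinical table share no samples")
  rows <- purrr::map(variables, function(v) {
    if (!v %in% names(data)) abort(paste0("no clinical column '", v, "'"))
    d <- filter(data, !is.na(.data[[v]]) & .data[[v]] != "")
    tab <- table(d[[v]], d$label)
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      warn(paste0("variable '", v, "' has a single observed level; skipped"))
      return(NULL)
    }
    ft <- fisher_exact(unclass(tab))
    counts <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE)) %>%
      rename(level = "Var1", group = "Var2", n = "Freq") %>%
      group_by(.data$group) %>%
      mutate(group_pct = 100 * .data$n / sum(.data$n)) %>%
      ungroup()
    tibble(variable = v, n = sum(tab), p_value = ft$p_value,
           method = ft$method, counts = list(counts))
  })
  bind_rows(rows)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", stage, "] ", conditionMessage(e)))
  })
}

#' Run the full stratification pipeline
#'
#' Orchestrates the whole analysis on one cohort: LST/HRD calling from
#' segments, transcriptomic classification, combination into four strata,
#' per-variable association report, Kaplan-Meier curves, global and pairwise
#' log-rank (Benjamini-Hochberg adjusted over the 6 stratum pairs), and
#' univariate plus multivariate Cox models. Deterministic given its inputs.
#'
#' @param config Named list (or path to a JSON file holding one):
#'   \describe{
#'     \item{segments, expr, signatures, clinical}{inputs — file paths or
#'       in-memory objects ([read_seg()]/[read_expression()]/[read_gmt()]/
#'       [read_clinical()] forms)}
#'     \item{scheme}{signature scheme name (default the single scheme
#'       present)}
#'     \item{k}{number of transcriptomic subgroups (default 2)}
#'     \item{distance}{`"euclidean"` (default) or `"pearson"`}
#'     \item{horizon_months}{survival truncation, months (default 120)}
#'     \item{covariates}{clinical variables for the association report and
#'       the multivariate Cox model (default `c("stage", "debulking")`,
#'       intersected with available columns)}
#'     \item{outdir}{optional output directory for TSV/JSON artifacts}
#'   }
#' @return A report bundle (list, class `strat_report`): `hrd_calls`,
#'   `assignment`, `strata`, `association`, `km`, `logrank`,
#'   `pairwise_logrank`, `cox_univariate`, `cox_multivariate`.
#' @examples
#' cohort <- gen_cohort(list(n = 40), seed = 2)
#' rep <- run_pipeline(list(segments = cohort$segments, expr = cohort$expr,
#'                          signatures = cohort$signature,
#'                          clinical = cohort$clinical))
#' rep$logrank
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (key in c("segments", "expr", "signatures", "clinical")) {
    if (is.null(config[[key]])) {
      abort(paste0("[config] missing required input '", key, "'"))
    }
  }
  k <- config$k %||% 2
  distance <- config$distance %||% "euclidean"
  horizon <- config$horizon_months %||% 120

  segments <- stage_try("read_segments",
    if (is.character(config$segments)) read_seg(config$segments)
    else as_segments(config$segments))
  expr <- stage_try("read_expression",
    if (is.character(config$expr)) read_expression(config$expr)
    else config$expr)
  signature <- stage_try("read_signatures",
    if (is.character(config$signatures)) read_gmt(config$signatures)
    else new_signature(config$signatures))
  clinical <- stage_try("read_clinical",
    if (is.character(config$clinical)) read_clinical(config$clinical)
    else validate_survival(config$clinical))
  scheme <- config$scheme %||% unique(signature$scheme)[1]

  hrd <- stage_try("lst_calling", call_hrd(segments))
  assignment <- stage_try("classification",
    classify(expr, signature, k = k, distance = distance, scheme = scheme))
  strata <- stage_try("combination", combine_strata(hrd, assignment))

  covariates <- config$covariates %||% c("stage", "debulking")
  covariates <- intersect(covariates, names(clinical))
  records <- inner_join(clinical, select(strata, "sample", "stratum"),
                        by = "sample")
  assoc <- stage_try("association",
    association_report(tibble(sample = strata$sample, label = strata$stratum),
                       clinical, covariates))

  km <- stage_try("kaplan_meier",
    km_curve(records, group = "stratum", horizon_months = horizon))
  lr <- stage_try("logrank",
    logrank(records, group = "stratum", horizon_months = horizon))
  plr <- stage_try("pairwise_logrank",
    pairwise_logrank_bh(records, group = "stratum", horizon_months = horizon))
  cox_uni <- stage_try("cox_univariate",
    cox_fit(records, covariates = "stratum",
            reference_levels = list(stratum = "LST_high/non_Fibrosis"),
            horizon_months = horizon))
  cox_multi <- stage_try("cox_multivariate",
    cox_fit(records, covariates = c("stratum", covariates),
            reference_levels = list(stratum = "LST_high/non_Fibrosis"),
            horizon_months = horizon))

  report <- structure(list(
    hrd_calls = hrd, assignment = assignment, strata = strata,
    association = assoc, km = km, logrank = lr, pairwise_logrank = plr,
    cox_univariate = cox_uni, cox_multivariate = cox_multi,
    config = config
  ), class = "strat_report")

  if (!is.null(config$outdir)) {
    stage_try("write_outputs", write_report(report, config$outdir))
  }
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(report$hrd_calls),
                   file.path(outdir, "hrd_calls.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(report$assignment),
                   file.path(outdir, "assignment.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(report$strata),
                   file.path(outdir, "strata.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(report$km), file.path(outdir, "km.tsv"),
                   progress = FALSE)
  jsonlite::write_json(list(
    logrank = report$logrank,
    pairwise_logrank = as_tibble(report$pairwise_logrank),
    association = select(report$association, -"counts"),
    association_counts = setNames(report$association$counts,
                                  report$association$variable),
    cox_univariate = tidy(report$cox_univariate),
    cox_multivariate = tidy(report$cox_multivariate)
  ), file.path(outdir, "stats.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.strat_report <- function(x, ...) {
  cat("HGSOC stratification report\n")
  cat("  samples stratified:", nrow(x$strata), "\n")
  sizes <- count(as_tibble(x$strata), .data$stratum)
  cat(paste0("  ", sizes$stratum, ": ", sizes$n, collapse = "\n"), "\n")
  cat(sprintf("  4-stratum log-rank: chi2 = %.2f (df %d), p = %.3g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  invisible(x)
}
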