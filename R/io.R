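#' Read and write gene signatures in GMT format
#'
#' Each GMT line is a gene set: set name, description, then gene ids,
#' tab-separated. Set names encode the classification scheme by a separator
#' convention (default `"."`), e.g. `fibrosis.Fibrosis_up` and
#' `fibrosis.non_Fibrosis_up` form the two up-gene sets of scheme `fibrosis`.
#' A set name without the separator forms a single-set scheme of its own name.
#' Within a scheme, sets must be non-empty and pairwise disjoint.
#'
#' @param path File path.
#' @param scheme_sep Separator between scheme and set name (first occurrence
#'   splits; default `"."`).
#' @return A tibble with columns `scheme`, `set`, `gene` (long format), class
#'   `gene_signature`.
#' @export
read_gmt <- function(path, scheme_sep = ".") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("'", path, "': empty GMT file"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- purrr::map(parts, function(p) {
    name <- p[[1]]
    genes <- unique(p[-(1:2)][nzchar(p[-(1:2)])])
    if (length(genes) == 0) {
      abort(paste0("'", path, "': gene set '", name, "' is empty"))
    }
    list(name = name, genes = genes)
  })
  names_all <- purrr::map_chr(sets, "name")
  if (anyDuplicated(names_all)) {
    abort(paste0("'", path, "': duplicate gene-set name '",
                 names_all[duplicated(names_all)][1], "'"))
  }
  out <- purrr::map_dfr(sets, function(s) {
    split_at <- regexpr(scheme_sep, s$name, fixed = TRUE)
    if (split_at > 0) {
      scheme <- substr(s$name, 1, split_at - 1)
      set <- substr(s$name, split_at + nchar(scheme_sep), nchar(s$name))
    } else {
      scheme <- s$name
      set <- s$name
    }
    tibble(scheme = scheme, set = set, gene = s$genes)
  })
  new_signature(out)
}

new_signature <- function(x) {
  x <- as_tibble(x)[, c("scheme", "set", "gene")]
  # pairwise disjointness within each scheme
  dup <- x %>% distinct(.data$scheme, .data$set, .data$gene) %>%
    count(.data$scheme, .data$gene) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("gene '", dup$gene[1], "' appears in more than one set of scheme '",
                 dup$scheme[1], "' (sets within a scheme must be disjoint)"))
  }
  class(x) <- c("gene_signature", class(x))
  x
}

#' @rdname read_gmt
#' @param signature A `gene_signature` tibble (columns `scheme`, `set`, `gene`).
#' @export
write_gmt <- function(signature, path, scheme_sep = ".") {
  stopifnot(is.data.frame(signature))
  lines <- signature %>%
    group_by(.data$scheme, .data$set) %>%
    summarise(line = paste(c(paste0(.data$scheme[1], scheme_sep, .data$set[1]),
                             "na", .data$gene), collapse = "\t"),
              .groups = "drop") %>%
    pull(.data$line)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a gene-expression matrix from TSV
#'
#' Expects log-scale expression, first column the gene identifier, remaining
#' columns one per sample. Gene and sample identifiers must be unique and the
#' values finite.
#'
#' @param path File path.
#' @return A tibble with first column `gene` and one numeric column per
#'   sample.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (names(x)[1] != "gene") names(x)[1] <- "gene"
  if (ncol(x) < 2) abort(paste0("'", path, "': no sample columns"))
  if (anyDuplicated(x$gene)) {
    abort(paste0("'", path, "': duplicate gene id '",
                 x$gene[duplicated(x$gene)][1], "'"))
  }
  if (anyDuplicated(names(x)[-1])) abort(paste0("'", path, "': duplicate sample id"))
  vals <- as.matrix(x[, -1])
  if (any(!is.finite(vals))) abort(paste0("'", path, "': non-finite expression value"))
  x
}

#' @rdname read_expression
#' @param expr Expression data: tibble with `gene` column, or genes x samples
#'   matrix with rownames.
#' @export
write_expression <- function(expr, path) {
  m <- as_expr_matrix(expr)
  out <- tibble(gene = rownames(m))
  out <- dplyr::bind_cols(out, as_tibble(m))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Convert expression data to a genes x samples matrix
#'
#' Accepts either a tibble whose first column `gene` carries identifiers
#' (the form returned by [read_expression()]) or an already-formed numeric
#' matrix with gene rownames, which is validated and passed through.
#'
#' @inheritParams write_expression
#' @return A numeric matrix, genes in rows (rownames), samples in columns.
#' @export
as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr)) || is.null(colnames(expr))) {
      abort("expression matrix needs gene rownames and sample colnames")
    }
    m <- expr
  } else if (is.data.frame(expr)) {
    if (!"gene" %in% names(expr)) {
      abort("expression tibble needs a 'gene' column")
    }
    m <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
    rownames(m) <- expr$gene
  } else {
    abort("expression must be a data frame or a matrix")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate gene ids in expression data")
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in expression data")
  storage.mode(m) <- "double"
  m
}

#' Read a clinical table from CSV
#'
#' Parses survival records: a sample identifier, follow-up time (months,
#' strictly positive), an event indicator (0 = censored, 1 = event) and any
#' number of categorical covariates. Unknown levels are preserved verbatim
#' and missing covariate values stay `NA`; downstream analyses drop them
#' pairwise, so denominators may differ per variable as in real cohort
#' tables.
#'
#' @param path File path.
#' @param sample_col,time_col,event_col Column names in the file mapped onto
#'   `sample`, `time`, `event`.
#' @param covariates Character vector of covariate columns to keep
#'   (default: every other column).
#' @return A tibble with columns `sample`, `time`, `event`, then covariates.
#' @export
read_clinical <- function(path, sample_col = "sample", time_col = "time",
                          event_col = "event", covariates = NULL) {
  x <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  for (col in c(sample_col, time_col, event_col)) {
    if (!col %in% names(x)) abort(paste0("'", path, "': missing column '", col, "'"))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(x), c(sample_col, time_col, event_col))
  }
  out <- tibble(
    sample = as.character(x[[sample_col]]),
    time = as.numeric(x[[time_col]]),
    event = as.numeric(x[[event_col]])
  )
  for (cv in covariates) out[[cv]] <- as.character(x[[cv]])
  validate_survival(out)
}

validate_survival <- function(x) {
  if (!all(c("sample", "time", "event") %in% names(x))) {
    abort("survival records need columns sample, time, event")
  }
  if (anyNA(x$time) || any(x$time <= 0)) {
    i <- which(is.na(x$time) | x$time <= 0)[1]
    abort(paste0("non-positive or missing follow-up time for sample '",
                 x$sample[i], "'"))
  }
  if (!all(x$event %in% c(0, 1))) {
    i <- which(!x$event %in% c(0, 1))[1]
    abort(paste0("event indicator must be 0 or 1 (sample '", x$sample[i],
                 "' has ", x$event[i], ")"))
  }
  if (anyDuplicated(x$sample)) abort("duplicate sample ids in clinical table")
  as_tibble(x)
}

#' @rdname read_clinical
#' @param clinical A clinical tibble as returned by [read_clinical()].
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(validate_survival(clinical), path, progress = FALSE)
  invisible(path)
}
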