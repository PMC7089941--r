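#' Fisher's exact test on a contingency table
#'
#' Two-sided exact test of independence for an r x c table of counts. For
#' 2 x 2 tables the two-sided p-value is the sum of hypergeometric point
#' probabilities no larger than that of the observed table (the point-
#' probability convention, not tail doubling), and the conditional
#' maximum-likelihood odds ratio is reported. Larger tables use the exact
#' network algorithm when the total count is at most `exact_limit`, and a
#' seeded Monte-Carlo estimate (`b` draws) beyond it.
#'
#' @param counts A matrix/table of non-negative integer counts (at least
#'   2 x 2), or a data frame of counts.
#' @param exact_limit Largest table total for the exact r x c algorithm.
#' @param b Monte-Carlo replicates for large r x c tables.
#' @param mc_seed Seed for the Monte-Carlo fallback (recorded in `method`).
#' @return A one-row tibble: `p_value`, `odds_ratio` (2 x 2 only), `method`.
#' @examples
#' fisher_exact(matrix(c(20, 4, 260, 195), nrow = 2))
#' @export
fisher_exact <- function(counts, exact_limit = 1000, b = 1e6, mc_seed = 1L) {
  m <- if (is.data.frame(counts)) as.matrix(counts) else as.matrix(counts)
  if (!is.numeric(m)) abort("counts must be numeric")
  if (any(m < 0) || any(m %% 1 != 0)) abort("counts must be non-negative integers")
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least a 2 x 2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero row or column margin: test undefined")
  }
  two_by_two <- nrow(m) == 2 && ncol(m) == 2
  if (two_by_two || sum(m) <= exact_limit) {
    ft <- fisher.test(m, workspace = 2e7)
    method <- "fisher_exact"
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(mc_seed)
    ft <- fisher.test(m, simulate.p.value = TRUE, B = b)
    method <- sprintf("fisher_monte_carlo(B=%g,seed=%d)", b, mc_seed)
  }
  tibble(
    p_value = ft$p.value,
    odds_ratio = if (two_by_two) unname(ft$estimate) else NA_real_,
    method = method
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

apply_horizon <- function(records, horizon_months) {
  if (is.null(horizon_months) || !is.finite(horizon_months) || horizon_months <= 0) {
    return(records)
  }
  over <- records$time > horizon_months
  records$event[over] <- 0
  records$time[over] <- horizon_months
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, overall or per group.
#' Follow-up is administratively censored at `horizon_months` first (120 by
#' default, matching 10-year analyses; `horizon_months = Inf` or `0`
#' disables). Censoring at tied event times is handled events-first, the
#' product-limit convention.
#'
#' @param records Survival tibble with columns `sample`, `time`, `event`
#'   (see [read_clinical()]).
#' @param group Optional name of a grouping column in `records`.
#' @param horizon_months Administrative censoring horizon in months.
#' @return A tibble of class `km_curve`: `group` (if any), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_curve <- function(records, group = NULL, horizon_months = 120) {
  records <- validate_survival_loose(records)
  if (nrow(records) == 0) abort("no survival records")
  records <- apply_horizon(records, horizon_months)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
    out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, survival = fit$surv)
  } else {
    if (!group %in% names(records)) abort(paste0("no column '", group, "'"))
    records$..g <- records[[group]]
    records <- filter(records, !is.na(.data$..g))
    fit <- survival::survfit(survival::Surv(time, event) ~ ..g, data = records)
    gl <- sub("^\\.\\.g=", "", rep(names(fit$strata), fit$strata))
    out <- tibble(group = gl, time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  survival = fit$surv)
  }
  structure(out, horizon = horizon_months,
            class = c("km_curve", class(out)))
}

validate_survival_loose <- function(records) {
  if (!all(c("time", "event") %in% names(records))) {
    abort("survival records need columns time and event")
  }
  if (!"sample" %in% names(records)) {
    records$sample <- paste0("r", seq_len(nrow(records)))
  }
  validate_survival(as_tibble(records))
}

#' Log-rank test
#'
#' Standard k-group log-rank chi-square test of equal survival, with k - 1
#' degrees of freedom. Follow-up is censored at `horizon_months` first
#' (disable with `Inf`), matching the Kaplan-Meier horizon.
#'
#' @inheritParams km_curve
#' @param group Name of the grouping column.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
logrank <- function(records, group = "group", horizon_months = 120) {
  records <- validate_survival_loose(records)
  if (!group %in% names(records)) abort(paste0("no column '", group, "'"))
  records$..g <- records[[group]]
  records <- filter(records, !is.na(.data$..g))
  if (length(unique(records$..g)) < 2) abort("log-rank needs at least 2 groups")
  records <- apply_horizon(records, horizon_months)
  sd <- survival::survdiff(survival::Surv(time, event) ~ ..g, data = records)
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df = df, lower.tail = FALSE),
         method = "logrank")
}

#' Pairwise log-rank tests with Benjamini-Hochberg adjustment
#'
#' All pairwise two-group log-rank tests among k >= 3 groups; p-values are
#' adjusted by [bh_adjust()] over the set of pairs of this one analysis only
#' (6 pairs for 4 strata), matching the `pairwise_survdiff` convention.
#'
#' @inheritParams logrank
#' @return A tibble of class `pairwise_logrank`: `group1`, `group2`,
#'   `p_value`, `p_adj`; `as.matrix()` yields the symmetric adjusted-p matrix
#'   with an empty diagonal.
#' @export
pairwise_logrank_bh <- function(records, group = "group", horizon_months = 120) {
  records <- validate_survival_loose(records)
  if (!group %in% names(records)) abort(paste0("no column '", group, "'"))
  records <- filter(records, !is.na(.data[[group]]))
  levs <- sort(unique(records[[group]]))
  if (length(levs) < 3) abort("pairwise comparison needs at least 3 groups")
  pairs <- utils::combn(levs, 2)
  raw <- purrr::map_dbl(seq_len(ncol(pairs)), function(j) {
    sub <- records[records[[group]] %in% pairs[, j], ]
    logrank(sub, group = group, horizon_months = horizon_months)$p_value
  })
  out <- tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                p_value = raw, p_adj = bh_adjust(raw))
  structure(out, groups = levs, class = c("pairwise_logrank", class(out)))
}

#' @export
as.matrix.pairwise_logrank <- function(x, ...) {
  levs <- attr(x, "groups")
  m <- matrix(NA_real_, length(levs), length(levs), dimnames = list(levs, levs))
  for (i in seq_len(nrow(x))) {
    m[x$group1[i], x$group2[i]] <- m[x$group2[i], x$group1[i]] <- x$p_adj[i]
  }
  m
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: order the m raw p-values increasingly, form
#' `p(i) * m / i`, take the cumulative minimum from the largest rank down,
#' clip at 1, and return in the original order. Ties are handled stably.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  adj <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(m)))))
  adj[order(o)]
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (the R `survival`
#' default). Covariates are categorical; reference levels may be fixed
#' explicitly, otherwise the first sorted level is the reference. Supplying
#' one covariate gives the univariate model, several gives the joint
#' (multivariate) model. Wald 95% intervals are `exp(beta +/- 1.96 se)`.
#'
#' @inheritParams km_curve
#' @param covariates Character vector of covariate column names.
#' @param reference_levels Optional named list/vector, covariate -> reference
#'   level.
#' @param horizon_months Administrative censoring horizon (`Inf` disables).
#' @return An object of class `cox_result`; use [tidy()] for the per-level
#'   hazard-ratio table and [glance()] for the model summary.
#' @examples
#' cohort <- gen_cohort(list(n = 60), seed = 4)
#' fit <- cox_fit(cohort$clinical, covariates = "stage")
#' tidy(fit)
#' @export
cox_fit <- function(records, covariates, reference_levels = NULL,
                    horizon_months = 120) {
  records <- validate_survival_loose(records)
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov) > 0) {
    abort(paste0("missing covariate column(s): ", paste(missing_cov, collapse = ", ")))
  }
  records <- apply_horizon(records, horizon_months)
  data <- records[complete.cases(records[, covariates, drop = FALSE]), ]
  if (sum(data$event) == 0) abort("no events after filtering; cannot fit")
  refs <- character(0)
  for (cv in covariates) {
    levs <- sort(unique(data[[cv]]))
    if (length(levs) < 2) abort(paste0("covariate '", cv, "' has a single level"))
    ref <- if (!is.null(reference_levels) && cv %in% names(reference_levels)) {
      as.character(reference_levels[[cv]])
    } else levs[1]
    if (!ref %in% levs) abort(paste0("reference level '", ref,
                                     "' absent from '", cv, "'"))
    data[[cv]] <- stats::relevel(factor(data[[cv]], levels = levs), ref = ref)
    refs[cv] <- ref
  }
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w))) {
        abort(paste0("Cox fit failed: ", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (any(!is.finite(stats::coef(fit)))) abort("Cox fit produced non-finite coefficients")
  structure(list(fit = fit, covariates = covariates, references = refs,
                 n = nrow(data), n_event = sum(data$event)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  cat("  n =", x$n, ", events =", x$n_event, "\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `cox_result` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cox_result <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  terms <- rownames(co)
  cov_of_term <- purrr::map_chr(terms, function(t) {
    hit <- x$covariates[startsWith(t, x$covariates)]
    hit[which.max(nchar(hit))]
  })
  tibble(
    term = cov_of_term,
    level = substr(terms, nchar(cov_of_term) + 1, nchar(terms)),
    reference_level = unname(x$references[cov_of_term]),
    hazard_ratio = unname(exp(co[, "coef"])),
    ci95_low = unname(exp(co[, "coef"] - 1.96 * co[, "se(coef)"])),
    ci95_high = unname(exp(co[, "coef"] + 1.96 * co[, "se(coef)"])),
    p_value = unname(co[, "Pr(>|z|)"])
  )
}

#' @rdname cox_fit
#' @exportS3Method generics::glance
glance.cox_result <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n, n_event = x$n_event,
    concordance = unname(s$concordance["C"]),
    logtest_p = unname(s$logtest["pvalue"]),
    waldtest_p = unname(s$waldtest["pvalue"])
  )
}
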