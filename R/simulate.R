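# seeded evaluation that never leaks RNG state to the caller; seed = NULL
# leaves the current stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  force(code)
}

# deterministic small sub-seed derived from a master seed (kept < 2^31)
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483629)
}

#' Generate a copy-number segment profile with planted LST breakpoints
#'
#' Builds one synthetic absolute copy-number profile: a flat baseline at
#' `ploidy_base` copies, exactly `n_lst` planted state transitions whose
#' flanking regions are all at least 10 Mb (so [count_lst()] recovers
#' `n_lst` exactly), plus `n_small_variants` sub-3 Mb variant segments that
#' the smoothing/filtering step must remove without disturbing the planted
#' breakpoints. Variants are placed at least 3 Mb inside a host segment, so
#' no filtering order can erode a planted flank.
#'
#' @param sample_id Sample identifier.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_mb Chromosome length in Mb (scalar or per chromosome).
#' @param ploidy_base Baseline total copy number, 2 (diploid) or 4
#'   (tetraploid).
#' @param n_lst Planted breakpoint count.
#' @param n_small_variants Planted sub-3 Mb variant count.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list: `segments` (a `cn_segments` tibble) and `truth` (one-row
#'   tibble `sample`, `lst_count_true`, `ploidy_true`).
#' @examples
#' p <- gen_cn_profile(n_lst = 17, seed = 1)
#' count_lst(p$segments)  # 17
#' @export
gen_cn_profile <- function(sample_id = "S1", n_chromosomes = 22,
                           chrom_length_mb = 130, ploidy_base = 2,
                           n_lst = 0, n_small_variants = 0, seed = NULL) {
  stopifnot(ploidy_base %in% c(2, 4), n_lst >= 0, n_small_variants >= 0)
  len_mb <- rep(chrom_length_mb, length.out = n_chromosomes)
  # capacity: b breakpoints need b+1 segments of >= 10 Mb each
  cap <- pmax(0, floor(len_mb / 10) - 1)
  if (n_lst > sum(cap)) {
    abort(paste0("cannot place ", n_lst, " breakpoints: capacity is ",
                 sum(cap), " for ", n_chromosomes, " chromosome(s) of ",
                 paste(unique(len_mb), collapse = "/"), " Mb"))
  }
  with_seed(seed, {
    # spread breakpoints over chromosomes, respecting per-chromosome capacity
    b <- integer(n_chromosomes)
    for (i in seq_len(n_lst)) {
      open <- which(b < cap)
      pick <- if (length(open) == 1) open else sample(open, 1)
      b[pick] <- b[pick] + 1
    }
    segs <- vector("list", n_chromosomes)
    for (ci in seq_len(n_chromosomes)) {
      L <- len_mb[ci] * MB
      k <- b[ci]
      # k+1 segment lengths, each >= 10 Mb: 10 Mb floor + random split of slack
      slack <- L - (k + 1) * 10 * MB
      cuts <- sort(runif(k, 0, slack))
      lens <- diff(c(0, cuts, slack)) + 10 * MB
      ends <- round(cumsum(lens)); ends[k + 1] <- L
      starts <- c(1, head(ends, -1) + 1)
      cn <- ploidy_base + (seq_len(k + 1) - 1) %% 2  # alternate base, base+1
      segs[[ci]] <- tibble(
        sample = sample_id, chrom = as.character(ci),
        start = starts, end = ends, total_cn = cn,
        major_cn = ceiling(cn / 2)
      )
    }
    df <- bind_rows(segs)
    # sub-3 Mb variants strictly inside host segments: both residual flanks
    # stay >= 3 Mb so the filter always deletes the variant first and the
    # host re-merges exactly
    for (v in seq_len(n_small_variants)) {
      vlen <- round(runif(1, 0.2, 2.9) * MB)
      host_len <- df$end - df$start + 1
      hosts <- which(host_len >= vlen + 6 * MB)
      if (length(hosts) == 0) {
        abort(paste0("cannot place small variant ", v,
                     ": no host segment long enough"))
      }
      h <- if (length(hosts) == 1) hosts else sample(hosts, 1)
      off <- round(runif(1, 3 * MB, host_len[h] - vlen - 3 * MB))
      v_start <- df$start[h] + off
      v_end <- v_start + vlen - 1
      vcn <- max(0, df$total_cn[h] + sample(c(-1, 1), 1))
      left <- df[h, ]; right <- df[h, ]; varseg <- df[h, ]
      left$end <- v_start - 1
      varseg$start <- v_start; varseg$end <- v_end
      varseg$total_cn <- vcn; varseg$major_cn <- ceiling(vcn / 2)
      right$start <- v_end + 1
      df <- bind_rows(df[-h, ], left, varseg, right)
    }
    list(
      segments = as_segments(df),
      truth = tibble(sample = sample_id, lst_count_true = as.integer(n_lst),
                     ploidy_true = if (ploidy_base == 2) "near_diploid"
                                   else "near_tetraploid")
    )
  })
}

#' Generate an expression matrix with planted group structure
#'
#' Each group's samples have the up-genes of the corresponding signature set
#' elevated by `shift * noise_sd` over a zero baseline; all values carry
#' i.i.d. Gaussian noise of SD `noise_sd`. Background genes are pure noise.
#' Group order follows the signature's set order.
#'
#' @param n_per_group Integer vector of group sizes (length = number of sets
#'   in the scheme; a scalar is recycled).
#' @param signature A `gene_signature` tibble holding one scheme.
#' @param shift Mean shift of up-genes in units of `noise_sd`.
#' @param noise_sd Gaussian noise SD (log-expression units).
#' @param n_background_genes Unstructured noise genes added to the matrix.
#' @param seed Integer seed.
#' @param sample_prefix Prefix for generated sample ids.
#' @return A list: `expr` (tibble, `gene` column + samples) and `truth`
#'   (tibble `sample`, `subgroup_true`).
#' @export
gen_expression <- function(n_per_group, signature, shift = 3, noise_sd = 1,
                           n_background_genes = 200, seed = NULL,
                           sample_prefix = "S") {
  stopifnot(shift >= 0, noise_sd > 0)
  sets <- split(signature$gene, signature$set)
  sets <- sets[unique(signature$set)]  # keep file order
  n_groups <- length(sets)
  n_per_group <- rep(n_per_group, length.out = n_groups)
  if (any(n_per_group < 2)) abort("each group needs at least 2 samples")
  labels <- sub("_up$", "", names(sets))
  with_seed(seed, {
    n <- sum(n_per_group)
    group_of <- rep(seq_len(n_groups), n_per_group)
    # interleave group memberships so sample ids carry no positional hint
    group_of <- sample(group_of)
    samples <- sprintf("%s%03d", sample_prefix, seq_len(n))
    genes <- c(unique(signature$gene),
               if (n_background_genes > 0)
                 sprintf("BG%04d", seq_len(n_background_genes)))
    m <- matrix(rnorm(length(genes) * n, sd = noise_sd),
                nrow = length(genes), dimnames = list(genes, samples))
    for (g in seq_len(n_groups)) {
      up <- sets[[g]]
      m[up, group_of == g] <- m[up, group_of == g] + shift * noise_sd
    }
    expr <- dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
    list(expr = expr,
         truth = tibble(sample = samples, subgroup_true = labels[group_of]))
  })
}

#' Generate survival records under proportional hazards
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(log_hr[label])`; censoring is an independent
#' exponential clock calibrated so that, before the administrative horizon, a
#' fraction `censor_rate` of subjects are censored
#' (`mu = lambda * c / (1 - c)`), plus administrative censoring at
#' `horizon_months`.
#'
#' @param truth Tibble with columns `sample` and a label column (default
#'   `subgroup_true`), or a named character vector of labels.
#' @param label_col Name of the label column in `truth`.
#' @param baseline_hazard Events per month for the reference label.
#' @param log_hr Named numeric: log hazard ratio per label (missing labels
#'   get 0).
#' @param censor_rate Target pre-horizon censoring fraction in `[0, 1)`.
#' @param horizon_months Administrative censoring horizon (`Inf` disables).
#' @param seed Integer seed.
#' @return A survival tibble: `sample`, `time`, `event`, plus the label
#'   column.
#' @export
gen_survival <- function(truth, label_col = "subgroup_true",
                         baseline_hazard = 0.0154, log_hr = NULL,
                         censor_rate = 0.3, horizon_months = 120,
                         seed = NULL) {
  if (!is.data.frame(truth)) {
    truth <- tibble(sample = names(truth), subgroup_true = unname(truth))
    label_col <- "subgroup_true"
  }
  if (baseline_hazard <= 0) abort("baseline_hazard must be positive")
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate must be in [0, 1)")
  labels <- truth[[label_col]]
  lhr <- setNames(rep(0, length(unique(labels))), sort(unique(labels)))
  if (!is.null(log_hr)) lhr[names(log_hr)] <- log_hr
  lambda <- baseline_hazard * exp(lhr[labels])
  if (any(!is.finite(lambda)) || any(lambda <= 0)) abort("degenerate hazards")
  with_seed(seed, {
    t_event <- rexp(length(lambda), rate = lambda)
    t_cens <- if (censor_rate > 0) {
      rexp(length(lambda), rate = lambda * censor_rate / (1 - censor_rate))
    } else rep(Inf, length(lambda))
    time <- pmin(t_event, t_cens, horizon_months)
    out <- tibble(
      sample = truth$sample,
      time = pmax(time, .Machine$double.eps),
      event = as.numeric(t_event <= t_cens & t_event <= horizon_months)
    )
    out[[label_col]] <- labels
    out
  })
}

#' Built-in toy gene signatures
#'
#' Small synthetic stand-ins for published signature gene lists (which are
#' user-supplied in real analyses): scheme `"fibrosis"` has a 16-gene
#' `Fibrosis_up` set and a 22-gene `non_Fibrosis_up` set (the published
#' signature sizes); scheme `"dimp"` has four 12-gene up-sets `D_up`, `I_up`,
#' `M_up`, `P_up`.
#'
#' @param scheme `"fibrosis"` or `"dimp"`.
#' @return A `gene_signature` tibble.
#' @export
toy_signature <- function(scheme = c("fibrosis", "dimp")) {
  scheme <- match.arg(scheme)
  sig <- switch(scheme,
    fibrosis = bind_rows(
      tibble(scheme = "fibrosis", set = "Fibrosis_up",
             gene = sprintf("FIB%02d", 1:16)),
      tibble(scheme = "fibrosis", set = "non_Fibrosis_up",
             gene = sprintf("STR%02d", 1:22))
    ),
    dimp = purrr::map_dfr(c("D", "I", "M", "P"), function(s) {
      tibble(scheme = "dimp", set = paste0(s, "_up"),
             gene = sprintf("%s%02d", s, 1:12))
    })
  )
  new_signature(sig)
}

default_cohort_config <- function() {
  list(
    n = 200,
    # equal four-way split over the combined strata, best to worst survival:
    strata = c("LST_high/non_Fibrosis", "LST_high/Fibrosis",
               "LST_low/non_Fibrosis", "LST_low/Fibrosis"),
    ploidy_base = 2,
    lst_mean_high = 22, lst_mean_low = 5,
    n_chromosomes = 22, chrom_length_mb = 130,
    n_small_variants = 5,
    shift = 3, noise_sd = 1, n_background_genes = 200,
    baseline_hazard = 0.0154,  # median OS ~ 45 months
    log_hr = c("LST_high/non_Fibrosis" = 0,
               "LST_high/Fibrosis" = log(1.5),
               "LST_low/non_Fibrosis" = log(2),
               "LST_low/Fibrosis" = log(3)),
    censor_rate = 0.3, horizon_months = 120,
    # clinical covariate frequencies by Fibrosis status (advanced stage,
    # partial debulking), mirroring published association tables
    p_stage_advanced = c(Fibrosis = 0.98, non_Fibrosis = 0.93),
    p_debulking_partial = c(Fibrosis = 0.84, non_Fibrosis = 0.76)
  )
}

#' Generate a full synthetic cohort
#'
#' Composes the three generators with consistent sample ids: copy-number
#' profiles whose planted LST counts put each sample on its assigned side of
#' the HRD cut-off, an expression matrix with Fibrosis/non-Fibrosis group
#' structure on the toy signature, clinical covariates with group-dependent
#' frequencies, and survival with stratum-specific proportional hazards
#' (default ordering: `LST_high/non_Fibrosis` best to `LST_low/Fibrosis`
#' worst). Optionally writes all pipeline input files plus a `truth.json`
#' sidecar.
#'
#' @param config Named list overriding the defaults (see
#'   `hgsocstrat:::default_cohort_config()`): `n`, `lst_mean_high/low`,
#'   `shift`, `noise_sd`, `baseline_hazard`, `log_hr`, `censor_rate`,
#'   `horizon_months`, ...
#' @param seed Integer master seed; every generator draws from a sub-seed of
#'   it.
#' @param outdir Optional directory: writes `segments.seg`,
#'   `expression.tsv`, `signatures.gmt`, `clinical.csv`, `truth.json`.
#' @return A list: `segments`, `expr`, `signature`, `clinical`, `truth`
#'   (per-sample planted values), `config`.
#' @examples
#' cohort <- gen_cohort(list(n = 20), seed = 1)
#' names(cohort)
#' @export
gen_cohort <- function(config = list(), seed = 1L, outdir = NULL) {
  cfg <- modifyList(default_cohort_config(), config)
  n <- cfg$n
  if (n < 8) abort("cohort needs at least 8 samples (2 per stratum)")
  sig <- toy_signature("fibrosis")
  stratum <- sort(rep(cfg$strata, length.out = n))
  samples <- sprintf("S%03d", seq_len(n))
  lst_side <- ifelse(grepl("^LST_high", stratum), "LST_high", "LST_low")
  fib_side <- ifelse(grepl("Fibrosis$", stratum) &
                       !grepl("non_Fibrosis$", stratum),
                     "Fibrosis", "non_Fibrosis")
  cutoff <- if (cfg$ploidy_base == 2) 15L else 20L

  # planted LST counts: clearly above / below the ploidy cut-off
  counts <- with_seed(sub_seed(seed, 1), {
    hi <- cutoff + rpois(n, cfg$lst_mean_high - cutoff)
    lo <- pmin(rpois(n, cfg$lst_mean_low), cutoff - 1L)
    ifelse(lst_side == "LST_high", hi, lo)
  })

  profiles <- purrr::map(seq_len(n), function(i) {
    gen_cn_profile(sample_id = samples[i], n_chromosomes = cfg$n_chromosomes,
                   chrom_length_mb = cfg$chrom_length_mb,
                   ploidy_base = cfg$ploidy_base, n_lst = counts[i],
                   n_small_variants = cfg$n_small_variants,
                   seed = sub_seed(seed, 100 + i))
  })
  segments <- as_segments(bind_rows(purrr::map(profiles, "segments")))

  # expression: 2-group structure by Fibrosis status; regenerate ids to match
  n_fib <- sum(fib_side == "Fibrosis")
  ex <- gen_expression(c(n_fib, n - n_fib), sig, shift = cfg$shift,
                       noise_sd = cfg$noise_sd,
                       n_background_genes = cfg$n_background_genes,
                       seed = sub_seed(seed, 2))
  # remap generated sample ids onto cohort ids, matching planted groups
  map <- character(0)
  map[ex$truth$sample[ex$truth$subgroup_true == "Fibrosis"]] <-
    samples[fib_side == "Fibrosis"]
  map[ex$truth$sample[ex$truth$subgroup_true == "non_Fibrosis"]] <-
    samples[fib_side == "non_Fibrosis"]
  expr <- ex$expr
  names(expr)[-1] <- unname(map[names(expr)[-1]])
  expr <- expr[, c("gene", sort(names(expr)[-1]))]

  truth <- tibble(
    sample = samples, stratum_true = stratum, lst_class_true = lst_side,
    subgroup_true = fib_side, lst_count_true = as.integer(counts),
    ploidy_true = if (cfg$ploidy_base == 2) "near_diploid" else "near_tetraploid",
    log_hr_true = unname(cfg$log_hr[stratum])
  )

  surv <- gen_survival(tibble(sample = samples, subgroup_true = stratum),
                       baseline_hazard = cfg$baseline_hazard,
                       log_hr = cfg$log_hr, censor_rate = cfg$censor_rate,
                       horizon_months = cfg$horizon_months,
                       seed = sub_seed(seed, 3))
  clinical <- with_seed(sub_seed(seed, 4), {
    p_adv <- cfg$p_stage_advanced[fib_side]
    p_part <- cfg$p_debulking_partial[fib_side]
    tibble(
      sample = samples, time = surv$time, event = surv$event,
      stage = ifelse(runif(n) < p_adv, "III-IV", "II"),
      debulking = ifelse(runif(n) < p_part, "Partial", "Full")
    )
  })

  out <- list(segments = segments, expr = expr, signature = sig,
              clinical = clinical, truth = truth, config = cfg, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_seg(segments, file.path(outdir, "segments.seg"))
    write_expression(expr, file.path(outdir, "expression.tsv"))
    write_gmt(sig, file.path(outdir, "signatures.gmt"))
    write_clinical(clinical, file.path(outdir, "clinical.csv"))
    jsonlite::write_json(
      list(seed = seed, config = cfg[setdiff(names(cfg), "log_hr")],
           log_hr = as.list(cfg$log_hr), truth = truth),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}
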