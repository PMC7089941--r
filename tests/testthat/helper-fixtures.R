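# Builders and independent oracles shared across the test files.
# Oracles are deliberately naive (enumeration, hand formulas) and never call
# the implementation paths they check.

mb <- 1e6

# quick segment-row builder: coordinates in Mb, converted to bp (1-based closed)
seg_mb <- function(sample, chrom, start_mb, end_mb, total_cn, major_cn = NA) {
  tibble::tibble(
    sample = sample, chrom = as.character(chrom),
    start = round(start_mb * mb) + 1, end = round(end_mb * mb),
    total_cn = total_cn, major_cn = major_cn
  )
}

# ---- Fisher 2x2 oracle: full hypergeometric enumeration --------------------
# two-sided p = sum of point probabilities <= observed point probability
fisher2x2_enum <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- Kaplan-Meier oracle: hand product-limit -------------------------------
km_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  tibble::tibble(time = ut, survival = out)
}

# ---- log-rank oracle: brute-force at-risk table (2 groups, O-E/V) ----------
logrank_hand <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# ---- Cox oracle: Efron partial log-likelihood for one binary covariate -----
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - l / d * sum_d)
    }
  }
  ll
}

# ---- adjusted Rand index ----------------------------------------------------
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# small deterministic 2-group survival fixture used by the log-rank and Cox
# hand-oracle tests (n = 8, two tied event times)
toy_surv <- function() {
  tibble::tibble(
    sample = paste0("p", 1:8),
    time = c(2, 4, 4, 6, 1, 3, 5, 8),
    event = c(1, 1, 0, 1, 1, 1, 1, 0),
    group = rep(c("a", "b"), each = 4)
  )
}

# count_lst silencing the one-per-call major_cn fallback warning, for
# fixtures that deliberately omit major allele counts
count_lst_q <- function(...) suppressWarnings(hgsocstrat::count_lst(...))
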