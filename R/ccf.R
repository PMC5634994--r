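# Cancer cell fraction estimation: the expected-VAF model, its closed-form
# inversion with exact binomial confidence intervals, the clonal-status rule,
# and a lightweight binomial-mixture oligoclonality assessment.

#' Expected variant allele fraction given a cancer cell fraction
#'
#' For a mutation carried on one copy in the fraction `ccf` of tumor cells,
#' in a sample of purity `p` with local tumor copy number `cpn_mut` and
#' matched-normal copy number `cpn_norm`, the expected VAF is
#' \deqn{f(\mathrm{CCF}) = \frac{p \cdot \mathrm{CCF}}
#'   {\mathrm{CPN}_{mut} \cdot p + \mathrm{CPN}_{norm} (1 - p)}}
#' The model assumes mutation multiplicity 1 (one mutated copy per carrying
#' cell).
#'
#' @param ccf cancer cell fraction in `[0, 1]`.
#' @param p tumor purity in `(0, 1]`.
#' @param cpn_mut local total copy number in the tumor (>= 0).
#' @param cpn_norm local copy number in the matched normal (default 2).
#' @return expected VAF (vectorized).
#' @export
expected_vaf <- function(ccf, p, cpn_mut, cpn_norm = 2) {
  if (any(ccf < 0 | ccf > 1)) stopf("ccf must lie in [0, 1]")
  if (any(p <= 0 | p > 1)) stopf("purity must lie in (0, 1]")
  denom <- cpn_mut * p + cpn_norm * (1 - p)
  if (any(denom <= 0)) stopf("copy-number/purity combination gives zero allele denominator")
  p * ccf / denom
}

# Inverse of expected_vaf in ccf; linear, so exact.
invert_vaf <- function(vaf, p, cpn_mut, cpn_norm = 2) {
  vaf * (cpn_mut * p + cpn_norm * (1 - p)) / p
}

#' Estimate a per-variant cancer cell fraction with confidence interval
#'
#' Inverts [expected_vaf()] at the observed VAF (closed form: the model is
#' linear in CCF) and transforms an exact Clopper-Pearson binomial interval
#' on the VAF through the same inversion.  Estimates and bounds are clipped
#' to `[0, 1]`; the pre-clip estimate is retained in `ccf_raw`.
#'
#' @param alt_reads,ref_reads allele read counts (alt + ref > 0).
#' @param p tumor purity in `(0, 1]`.
#' @param cpn_mut,cpn_norm local copy numbers (defaults 2, 2).
#' @param ci_level confidence level (default 0.95).
#' @return one-row `data.frame` (class `ccf_record` rows): `vaf_obs, ccf_hat,
#'   ccf_raw, ci_low, ci_high, depth, p, cpn_mut, cpn_norm, status` (status
#'   filled by [classify_clonal()], initialised to `NA`).  Vectorized over
#'   counts.
#' @export
estimate_ccf <- function(alt_reads, ref_reads, p, cpn_mut = 2, cpn_norm = 2,
                         ci_level = 0.95) {
  n <- alt_reads + ref_reads
  if (any(n <= 0)) stopf("alt_reads + ref_reads must be positive")
  if (any(p <= 0 | p > 1)) stopf("purity must lie in (0, 1]")
  k <- length(n)
  p <- rep_len(p, k); cpn_mut <- rep_len(cpn_mut, k); cpn_norm <- rep_len(cpn_norm, k)
  vaf <- alt_reads / n
  alpha <- 1 - ci_level
  lo <- ifelse(alt_reads == 0, 0, stats::qbeta(alpha / 2, alt_reads, ref_reads + 1))
  hi <- ifelse(ref_reads == 0, 1, stats::qbeta(1 - alpha / 2, alt_reads + 1, ref_reads))
  raw <- invert_vaf(vaf, p, cpn_mut, cpn_norm)
  clip <- function(x) pmin(pmax(x, 0), 1)
  # Degenerate geometry: a clonal mutation would be invisible (f(1) == 0).
  degenerate <- expected_vaf(rep(1, k), p, cpn_mut, cpn_norm) <= 0
  out <- data.frame(
    vaf_obs = vaf, ccf_hat = clip(raw), ccf_raw = raw,
    ci_low = clip(invert_vaf(lo, p, cpn_mut, cpn_norm)),
    ci_high = clip(invert_vaf(hi, p, cpn_mut, cpn_norm)),
    depth = n, p = p, cpn_mut = cpn_mut, cpn_norm = cpn_norm,
    status = NA_character_, stringsAsFactors = FALSE)
  if (any(degenerate)) out$status[degenerate] <- "indeterminate"
  out
}

#' Classify clonal status from a CCF confidence interval
#'
#' A mutation is called clonal when the upper bound of its CCF confidence
#' interval reaches `clonal_cut` (default 0.95), i.e. the data cannot exclude
#' presence in essentially all tumor cells; otherwise subclonal.  Records
#' with depth below `min_depth` are indeterminate regardless of the interval.
#'
#' @param records output of [estimate_ccf()].
#' @param clonal_cut CI-upper threshold for a clonal call (default 0.95).
#' @param min_depth minimum depth for a determinate call (default 10).
#' @return `records` with `status` filled (`clonal`/`subclonal`/`indeterminate`).
#' @export
classify_clonal <- function(records, clonal_cut = 0.95, min_depth = 10) {
  status <- ifelse(records$ci_high >= clonal_cut, "clonal", "subclonal")
  status[records$depth < min_depth] <- "indeterminate"
  keep <- !is.na(records$status) & records$status == "indeterminate"
  status[keep] <- "indeterminate"
  records$status <- status
  records
}

#' Assess oligoclonality of one region by a binomial mixture
#'
#' A deliberately lightweight single-sample clonality assessment: alternate
#' read counts are modelled as a K-component binomial mixture whose component
#' success probabilities are tied to candidate CCF centres through the
#' expected-VAF model (`p_ik = expected_vaf(ccf_k, p_i, cpn_i, cpn_norm_i)`).
#' Components `K = 1..k_max` are fitted by EM with seeded restarts and K is
#' selected by BIC; the region is called oligoclonal when `K >= 2`.  This is
#' a stand-in for full Bayesian clonality machinery, adequate for detecting
#' well-separated CCF clusters.
#'
#' @param records output of [estimate_ccf()] joined with read counts: needs
#'   columns `alt_reads` is reconstructed as `round(vaf_obs * depth)`.
#' @param k_max maximum number of components (default 5).
#' @param min_variants minimum usable variants (default 10).
#' @param min_depth minimum depth for a variant to enter the fit (default 10).
#' @param n_restarts EM restarts per K (default 3).
#' @param seed RNG seed for restarts (default 1).
#' @param max_iter,tol EM controls.
#' @return list with `k` (chosen number of clusters, or `NA`), `oligoclonal`
#'   flag, `assignment` (component index per usable variant), `ccf_centers`,
#'   `weights`, `bic` (vector over K), `loglik`, and `message`
#'   (`"ok"` or `"insufficient data"`).
#' @export
assess_oligoclonality <- function(records, k_max = 5, min_variants = 10,
                                  min_depth = 10, n_restarts = 3, seed = 1,
                                  max_iter = 200, tol = 1e-8) {
  use <- records$depth >= min_depth
  rec <- records[use, , drop = FALSE]
  if (nrow(rec) < min_variants) {
    return(list(k = NA_integer_, oligoclonal = NA, assignment = NULL,
                ccf_centers = NULL, weights = NULL, bic = NULL, loglik = NULL,
                message = "insufficient data"))
  }
  alt <- round(rec$vaf_obs * rec$depth)
  n <- rec$depth
  # VAF produced by a fully clonal mutation, per variant: scales CCF to
  # success probability under each variant's purity/copy-number geometry.
  g <- expected_vaf(rep(1, nrow(rec)), rec$p, rec$cpn_mut, rec$cpn_norm)

  fit_k <- function(K, restart) {
    set.seed(child_seed(seed, K * 100 + restart))
    centers <- sort(stats::runif(K, 0.05, 1))
    weights <- rep(1 / K, K)
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      pm <- outer(g, centers)               # n x K success probabilities
      pm <- pmin(pmax(pm, 1e-9), 1 - 1e-9)
      logd <- sapply(seq_len(K), function(k2)
        stats::dbinom(alt, n, pm[, k2], log = TRUE) + log(weights[k2]))
      logd <- matrix(logd, ncol = K)
      m <- apply(logd, 1, max)
      ll <- sum(m + log(rowSums(exp(logd - m))))
      r <- exp(logd - m - log(rowSums(exp(logd - m))))
      weights <- colMeans(r)
      centers <- vapply(seq_len(K), function(k2) {
        num <- sum(r[, k2] * alt)
        den <- sum(r[, k2] * n * g)
        if (den <= 0) centers[k2] else min(max(num / den, 1e-4), 1)
      }, 0)
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(loglik = ll, centers = centers, weights = weights, resp = r)
  }

  best <- vector("list", k_max)
  bic <- rep(NA_real_, k_max)
  for (K in seq_len(k_max)) {
    fits <- lapply(seq_len(n_restarts), function(rs) fit_k(K, rs))
    fk <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
    best[[K]] <- fk
    bic[K] <- -2 * fk$loglik + (2 * K - 1) * log(nrow(rec))
  }
  kstar <- which.min(bic)
  fk <- best[[kstar]]
  # Drop empty components (weight ~ 0) from the reported cluster count.
  occupied <- fk$weights > 1e-3
  assignment <- apply(fk$resp, 1, which.max)
  k_eff <- length(unique(assignment[occupied[assignment]]))
  list(k = k_eff, oligoclonal = k_eff >= 2, assignment = assignment,
       ccf_centers = fk$centers, weights = fk$weights, bic = bic,
       loglik = fk$loglik, message = "ok")
}
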