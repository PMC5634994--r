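# Trinucleotide mutation spectra: the fixed 96-channel layout, spectrum
# construction with pyrimidine-strand collapse, signature refitting by
# non-negative least squares with iterative pruning, sample clustering on
# cosine distance, and trunk-vs-branch exposure comparison.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
CONTEXT_BASES <- c("A", "C", "G", "T")

#' The fixed 96-channel ordering
#'
#' Channels are ordered substitution-class major (`C>A, C>G, C>T, T>A, T>C,
#' T>G`), then 5' base, then 3' base, each alphabetical; names follow the
#' conventional `A[C>A]A` notation.  The ordering is fixed so spectra and
#' signature catalogs are comparable across runs.
#'
#' @return character vector of length 96.
#' @export
channel_names_96 <- function() {
  out <- character(0)
  for (sub in SUBSTITUTION_CLASSES) {
    ref <- substr(sub, 1, 1)
    for (p5 in CONTEXT_BASES) for (p3 in CONTEXT_BASES) {
      out <- c(out, paste0(p5, "[", sub, "]", p3))
    }
  }
  out
}

# Map (ref, alt, context3) -> channel name, collapsing purine-reference
# substitutions onto the pyrimidine strand by reverse complement.
snv_channel <- function(ref, alt, context3) {
  flip <- ref %in% c("A", "G")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref2 <- ifelse(flip, comp[ref], ref)
  alt2 <- ifelse(flip, comp[alt], alt)
  ctx2 <- ifelse(flip, revcomp(context3), context3)
  paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]", substr(ctx2, 3, 3))
}

#' Compute a 96-channel trinucleotide mutation spectrum
#'
#' Counts somatic SNVs into 6 substitution classes x 16 trinucleotide
#' contexts (the flanking 5' and 3' reference bases).  Purine-reference
#' SNVs are reverse-complemented to the pyrimidine strand before binning.
#' Indels are skipped; SNVs lacking a context (no `context3` and no
#' reference) are skipped with a warning.
#'
#' @param calls `VariantCall` rows.
#' @param reference optional named `Biostrings::DNAStringSet` (or path to a
#'   FASTA) used to extract contexts for calls without `context3`.
#' @param sample_id label stored on the spectrum.
#' @return object of class `spectrum96`: named integer vector of length 96
#'   with attributes `sample_id`, `n_snv`, `n_skipped`.
#' @export
compute_spectrum <- function(calls, reference = NULL, sample_id = "sample") {
  channels <- channel_names_96()
  counts <- stats::setNames(integer(96), channels)
  if (nrow(calls) > 0) {
    snv <- is_snv(calls$ref, calls$alt)
    calls <- calls[snv, , drop = FALSE]
    ctx <- calls$context3
    need <- is.na(ctx) | ctx == ""
    if (any(need) && !is.null(reference)) {
      if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
      ctx[need] <- extract_context3(reference, calls$chrom[need], calls$pos[need])
    }
    usable <- !is.na(ctx) & nchar(ctx) == 3
    if (any(!usable)) {
      warnf("%d SNV(s) lack a trinucleotide context and were skipped", sum(!usable))
    }
    mid <- substr(ctx[usable], 2, 2)
    if (any(mid != calls$ref[usable])) {
      stopf("context middle base disagrees with ref allele")
    }
    ch <- snv_channel(calls$ref[usable], calls$alt[usable], ctx[usable])
    tab <- table(factor(ch, levels = channels))
    counts <- counts + as.integer(tab)
    names(counts) <- channels
    attr(counts, "n_skipped") <- sum(!usable) + sum(!snv)
  } else {
    attr(counts, "n_skipped") <- 0L
  }
  attr(counts, "sample_id") <- sample_id
  attr(counts, "n_snv") <- sum(counts)
  class(counts) <- "spectrum96"
  counts
}

extract_context3 <- function(reference, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    if (!chrom[i] %in% names(reference)) return(NA_character_)
    seq <- reference[[chrom[i]]]
    if (pos[i] < 2 || pos[i] > length(seq) - 1) return(NA_character_)
    as.character(Biostrings::subseq(seq, pos[i] - 1, pos[i] + 1))
  }, "")
}

#' @export
print.spectrum96 <- function(x, ...) {
  cat(sprintf("spectrum96 '%s': %d SNVs over 96 channels\n",
              attr(x, "sample_id"), sum(x)))
  invisible(x)
}

#' Read a signature catalog from TSV
#'
#' Rows are signatures, columns the 96 ordered channels (header must match
#' [channel_names_96()]; a leading `signature` column carries the names).
#' Each row must sum to 1.
#'
#' @param path file path.
#' @return matrix signatures x 96 with signature row names.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "signature") stopf("catalog must start with a 'signature' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$signature
  validate_catalog(m)
}

validate_catalog <- function(m) {
  if (ncol(m) != 96) stopf("catalog must have 96 channel columns")
  if (!isTRUE(all.equal(colnames(m), channel_names_96()))) {
    stopf("catalog channel columns must follow the fixed 96-channel ordering")
  }
  if (any(m < 0)) stopf("catalog probabilities must be non-negative")
  if (any(abs(rowSums(m) - 1) > 1e-6)) stopf("catalog rows must sum to 1")
  m
}

#' Refit signature exposures by non-negative least squares with pruning
#'
#' The normalized spectrum is regressed onto the catalog rows under
#' non-negativity, then signatures whose normalized weight falls below
#' `min_weight` (default 0.06) are dropped and the remainder refitted,
#' iterating until the active set is stable.  Weights are reported
#' normalized to sum 1 over retained signatures, together with the cosine
#' similarity between the reconstruction and the observed spectrum.
#'
#' @param spectrum a `spectrum96` (or plain 96-vector of counts), sum > 0.
#' @param catalog signatures x 96 matrix (rows sum to 1).
#' @param min_weight pruning threshold on normalized weights (default 0.06).
#' @return list of class `exposure_fit`: `weights` (named, full catalog,
#'   zeros for pruned), `residual_cosine`, `n_iter`, `reconstruction`.
#' @export
fit_signatures <- function(spectrum, catalog, min_weight = 0.06) {
  if (nrow(catalog) == 0) stopf("empty signature catalog")
  b <- as.numeric(spectrum)
  if (length(b) != 96) stopf("spectrum must have 96 channels")
  if (sum(b) <= 0) stopf("spectrum has zero mutations")
  b <- b / sum(b)
  active <- rownames(catalog)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    A <- t(catalog[active, , drop = FALSE])   # 96 x S
    w <- pracma::lsqnonneg(A, b)$x
    wn <- if (sum(w) > 0) w / sum(w) else w
    drop_idx <- wn < min_weight & wn > 0
    zero_idx <- wn == 0
    if (!any(drop_idx) && !any(zero_idx)) break
    keep <- active[wn >= min_weight]
    if (length(keep) == 0) keep <- active[which.max(wn)]
    if (identical(keep, active)) break
    active <- keep
  }
  weights <- stats::setNames(numeric(nrow(catalog)), rownames(catalog))
  weights[active] <- if (sum(w) > 0) w / sum(w) else w
  recon <- as.numeric(t(catalog) %*% weights)
  structure(list(weights = weights,
                 residual_cosine = cosine_sim(recon, b),
                 n_iter = n_iter, reconstruction = recon),
            class = "exposure_fit")
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' @export
print.exposure_fit <- function(x, ...) {
  nz <- x$weights[x$weights > 0]
  cat("exposure_fit:", paste(sprintf("%s=%.3f", names(nz), nz), collapse = ", "),
      sprintf("(cosine %.4f)\n", x$residual_cosine))
  invisible(x)
}

#' Cluster sample spectra by cosine distance
#'
#' Average-linkage hierarchical clustering of normalized spectra on cosine
#' distance, cut into `k` clusters (default 2, the typical major split of a
#' cohort by dominant mutational process).  Zero spectra are excluded with a
#' warning.
#'
#' @param spectra list of `spectrum96` objects.
#' @param k number of clusters to cut (default 2).
#' @param method linkage (default `"average"`).
#' @return list: `labels` (named cluster index per retained sample),
#'   `hclust` (the tree), `excluded` (names of zero spectra).
#' @export
cluster_samples <- function(spectra, k = 2, method = "average") {
  ids <- vapply(spectra, function(s) attr(s, "sample_id") %||% "sample", "")
  sums <- vapply(spectra, sum, 0)
  if (any(sums == 0)) warnf("excluding %d zero spectrum(s)", sum(sums == 0))
  keep <- sums > 0
  spectra <- spectra[keep]; ids <- ids[keep]
  if (length(spectra) < 2) stopf("need at least 2 non-zero spectra")
  m <- t(vapply(spectra, function(s) as.numeric(s) / sum(s), numeric(96)))
  rownames(m) <- make.unique(ids)
  d <- cosine_dist(m)
  hc <- stats::hclust(stats::as.dist(d), method = method)
  k <- min(k, nrow(m))
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, hclust = hc, excluded = names(sums)[!keep])
}

cosine_dist <- function(m) {
  norms <- sqrt(rowSums(m^2))
  sim <- (m %*% t(m)) / outer(norms, norms)
  d <- 1 - sim
  d[d < 0] <- 0
  d
}

#' Compare trunk and branch signature exposures with bootstrap intervals
#'
#' Fits exposures separately to the truncal and branched spectra of one
#' tumor and reports the branch-minus-trunk weight difference per signature
#' with a percentile bootstrap interval obtained by resampling mutations
#' (multinomial over channels) within each spectrum.
#'
#' @param trunk_spectrum,branch_spectrum `spectrum96` objects, both non-zero.
#' @param catalog signature catalog matrix.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed (default 1).
#' @param conf interval level (default 0.95).
#' @param min_weight passed to [fit_signatures()].
#' @return `data.frame`: signature, trunk/branch weights, `diff`
#'   (branch - trunk), `ci_low`, `ci_high`.
#' @export
compare_trunk_branch <- function(trunk_spectrum, branch_spectrum, catalog,
                                 n_boot = 1000, seed = 1, conf = 0.95,
                                 min_weight = 0.06) {
  if (sum(trunk_spectrum) == 0 || sum(branch_spectrum) == 0) {
    stopf("both spectra must contain mutations")
  }
  fit_t <- fit_signatures(trunk_spectrum, catalog, min_weight)
  fit_b <- fit_signatures(branch_spectrum, catalog, min_weight)
  set.seed(child_seed(seed, 0))
  boot_diff <- matrix(NA_real_, n_boot, nrow(catalog),
                      dimnames = list(NULL, rownames(catalog)))
  resample <- function(sp) {
    n <- sum(sp)
    as.numeric(stats::rmultinom(1, n, as.numeric(sp) / n))
  }
  for (i in seq_len(n_boot)) {
    wt <- fit_signatures(resample(trunk_spectrum), catalog, min_weight)$weights
    wb <- fit_signatures(resample(branch_spectrum), catalog, min_weight)$weights
    boot_diff[i, ] <- wb - wt
  }
  a <- (1 - conf) / 2
  data.frame(signature = rownames(catalog),
             trunk = unname(fit_t$weights), branch = unname(fit_b$weights),
             diff = unname(fit_b$weights - fit_t$weights),
             ci_low = apply(boot_diff, 2, stats::quantile, probs = a),
             ci_high = apply(boot_diff, 2, stats::quantile, probs = 1 - a),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' A synthetic signature catalog for simulation and tests
#'
#' Builds `k` well-separated 96-channel probability profiles: signature `j`
#' concentrates most of its mass on its own block of channels with a small
#' uniform background, loosely mimicking the sparsity of real mutational
#' signatures.  Purely synthetic — not derived from any published catalog.
#'
#' @param k number of signatures (default 4).
#' @param sharpness fraction of mass on the signature's own channel block
#'   (default 0.9).
#' @param seed RNG seed shaping the within-block profile (default 1).
#' @return matrix k x 96, rows summing to 1, named `SynSig1..k`.
#' @export
synthetic_signature_catalog <- function(k = 4, sharpness = 0.9, seed = 1) {
  set.seed(child_seed(seed, 42))
  channels <- channel_names_96()
  m <- matrix(0, k, 96, dimnames = list(paste0("SynSig", seq_len(k)), channels))
  block <- split(seq_len(96), rep_len(seq_len(k), 96))
  for (j in seq_len(k)) {
    prof <- rep((1 - sharpness) / 96, 96)
    own <- block[[j]]
    w <- stats::rgamma(length(own), shape = 0.5)
    prof[own] <- prof[own] + sharpness * w / sum(w)
    m[j, ] <- prof / sum(prof)
  }
  m
}

#' Write a spectrum (or several) to TSV
#' @param spectra list of `spectrum96` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  m <- t(vapply(spectra, as.numeric, numeric(96)))
  colnames(m) <- channel_names_96()
  df <- data.frame(sample_id = vapply(spectra, function(s) attr(s, "sample_id"), ""),
                   m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
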