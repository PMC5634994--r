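# Neoantigen candidate screen: enumerate every 9-11-mer window that covers
# a missense-mutated residue, pair each mutant peptide with its wild-type
# counterpart, and apply the affinity filter (mutant < 500 nM and stronger
# binding than wild type, both strict).

#' Enumerate mutant/wild-type peptide pairs around a missense residue
#'
#' For each length L in 9, 10, 11, every window of the protein that contains
#' the mutated residue and lies fully inside the sequence yields one pair:
#' the mutant window (with `mut_aa` substituted) and the same window of the
#' unmutated protein.  An interior residue therefore yields 9 + 10 + 11 = 30
#' pairs.
#'
#' @param protein_seq wild-type protein sequence (single string, or a
#'   `Biostrings::AAString`).
#' @param mut_position 1-based residue position of the substitution.
#' @param mut_aa mutant amino acid (single letter).
#' @param lengths peptide lengths to enumerate (default `9:11`).
#' @return `data.frame`: length, offset (1-based position of the mutated
#'   residue within the peptide), mut_seq, wt_seq.  Zero rows (with a
#'   warning) when no window fits.
#' @export
enumerate_peptides <- function(protein_seq, mut_position, mut_aa,
                               lengths = 9:11) {
  seq <- as.character(protein_seq)
  n <- nchar(seq)
  if (mut_position < 1 || mut_position > n) {
    stopf("mut_position %d outside protein of length %d", mut_position, n)
  }
  wt_aa <- substr(seq, mut_position, mut_position)
  mut_protein <- paste0(substr(seq, 1, mut_position - 1), mut_aa,
                        substr(seq, mut_position + 1, n))
  out <- list()
  for (L in lengths) {
    starts <- max(1L, mut_position - L + 1L):min(mut_position, n - L + 1L)
    starts <- starts[starts >= 1 & starts + L - 1 <= n]
    for (s in starts) {
      out[[length(out) + 1L]] <- data.frame(
        length = L, offset = mut_position - s + 1L,
        mut_seq = substr(mut_protein, s, s + L - 1L),
        wt_seq = substr(seq, s, s + L - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    warnf("protein too short for any %d-%dmer window", min(lengths), max(lengths))
    return(data.frame(length = integer(0), offset = integer(0),
                      mut_seq = character(0), wt_seq = character(0)))
  }
  res <- do.call(rbind, out)
  res$wt_aa <- wt_aa
  res$mut_aa <- mut_aa
  res
}

#' Filter peptide pairs to candidate neoantigens
#'
#' A pair is a candidate iff the mutant peptide's predicted affinity is
#' strictly below 500 nM and strictly below the wild-type peptide's affinity
#' (lower nM = stronger binding).  Exactly 500 nM is rejected, as is a tie
#' with wild type.  Pairs lacking either affinity are skipped and counted.
#'
#' @param pairs `data.frame` with columns `aff_mut`, `aff_wt` (nM).
#' @param affinity_cut mutant affinity threshold in nM (default 500).
#' @return the candidate subset, with attributes `n_skipped` (pairs missing
#'   an affinity) and `n_rejected`.
#' @export
filter_candidates <- function(pairs, affinity_cut = 500) {
  if (!all(c("aff_mut", "aff_wt") %in% names(pairs))) {
    stopf("pairs need aff_mut and aff_wt columns")
  }
  if (any(pairs$aff_mut < 0 | pairs$aff_wt < 0, na.rm = TRUE)) {
    stopf("negative affinity: malformed table")
  }
  has <- !is.na(pairs$aff_mut) & !is.na(pairs$aff_wt)
  keep <- has & pairs$aff_mut < affinity_cut & pairs$aff_mut < pairs$aff_wt
  out <- pairs[keep, , drop = FALSE]
  attr(out, "n_skipped") <- sum(!has)
  attr(out, "n_rejected") <- sum(has & !keep)
  out
}

#' Read a peptide-affinity table
#'
#' Tab-separated with columns `peptide, hla_allele, affinity_nM`, e.g. an
#' export from an external MHC-binding predictor.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_affinities <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "hla_allele", "affinity_nM")
  if (!all(need %in% names(df))) {
    stopf("affinity table needs columns: %s", paste(need, collapse = ", "))
  }
  df$affinity_nM <- as.numeric(df$affinity_nM)
  df
}

#' Deterministic mock affinity provider
#'
#' Assigns each (peptide, allele) pair a reproducible pseudo-affinity in
#' roughly (0, 5000] nM from a seeded polynomial hash of the strings.
#' Useful for exercising the filter and computing per-tumor neoantigen
#' loads without an external predictor; carries no biology.
#'
#' @param peptide,hla_allele character vectors (recycled).
#' @param seed integer mixed into the hash (default 1).
#' @return numeric affinities in nM.
#' @export
mock_affinity <- function(peptide, hla_allele = "HLA-A*02:01", seed = 1) {
  n <- max(length(peptide), length(hla_allele))
  peptide <- rep_len(peptide, n); hla_allele <- rep_len(hla_allele, n)
  vapply(seq_len(n), function(i) {
    codes <- utf8ToInt(paste0(peptide[i], "|", hla_allele[i]))
    h <- as.numeric(seed %% 2147483647)
    for (c in codes) h <- (h * 131 + c) %% 2147483647
    # map hash to (0, 5000]
    (h %% 500000) / 100 + 0.01
  }, 0)
}

#' Per-tumor neoantigen load from missense calls
#'
#' Enumerates peptide pairs for each missense call with a known protein
#' context, attaches affinities via `affinity_fun` (default the
#' deterministic mock provider) and counts filter-passing candidates per
#' tumor.
#'
#' @param calls `VariantCall` rows (missense with `protein_change` parsed
#'   for the residue; calls without protein context are skipped).
#' @param proteins named character vector (or `AAStringSet`) of wild-type
#'   protein sequences keyed by gene.
#' @param tumor_of named region -> tumor map.
#' @param hla_alleles alleles to score against (default one allele).
#' @param affinity_fun function(peptide, allele) -> nM (default
#'   [mock_affinity()]).
#' @return list: `candidates` (per-pair table), `load` (named candidate
#'   count per tumor), `n_skipped_calls`.
#' @export
neoantigen_load <- function(calls, proteins, tumor_of,
                            hla_alleles = "HLA-A*02:01",
                            affinity_fun = mock_affinity) {
  proteins <- stats::setNames(as.character(proteins), names(proteins))
  keys <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  uniq <- !duplicated(keys)
  skipped <- 0L
  out <- list()
  for (i in which(uniq)) {
    v <- calls[i, ]
    posn <- protein_position(v$protein_change)
    aa <- sub("^[A-Za-z*]*[0-9]+", "", v$protein_change %||% NA_character_)
    if (v$effect != "missense" || is.na(posn) || !nzchar(aa %na% "") ||
        !v$gene %in% names(proteins)) {
      skipped <- skipped + 1L
      next
    }
    if (posn > nchar(proteins[[v$gene]])) { skipped <- skipped + 1L; next }
    pep <- enumerate_peptides(proteins[[v$gene]], posn, aa)
    if (nrow(pep) == 0) { skipped <- skipped + 1L; next }
    for (allele in hla_alleles) {
      p2 <- pep
      p2$hla_allele <- allele
      p2$aff_mut <- affinity_fun(p2$mut_seq, allele)
      p2$aff_wt <- affinity_fun(p2$wt_seq, allele)
      p2$key <- keys[i]
      p2$tumor <- unique(tumor_of[calls$region_id[keys == keys[i]]])[1]
      out[[length(out) + 1L]] <- p2
    }
  }
  tumors <- unique(tumor_of)
  if (length(out) == 0) {
    return(list(candidates = NULL,
                load = stats::setNames(rep(0L, length(tumors)), tumors),
                n_skipped_calls = skipped))
  }
  pairs <- do.call(rbind, out)
  cand <- filter_candidates(pairs)
  load <- vapply(tumors, function(t) sum(cand$tumor == t), 0L)
  list(candidates = cand, load = load, n_skipped_calls = skipped)
}
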