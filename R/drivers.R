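# Putative-driver rule engine: candidate-gene gate, then either COSMIC-style
# evidence (exact match / same site / >=3 known mutations within 15 bp) or
# recessive-gene deleteriousness with score support.

#' Read a cancer-gene census table
#'
#' Tab-separated with columns `gene`, `recessive` (0/1 or TRUE/FALSE),
#' `candidate` (membership of the frequently-mutated candidate-driver gene
#' lists).  Gene symbols must be unique.
#'
#' @param path file path.
#' @return `data.frame` keyed by gene.
#' @export
read_census <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "recessive", "candidate")
  if (!all(need %in% names(df))) {
    stopf("census table needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene)) stopf("duplicate gene symbols in census")
  df$recessive <- as.logical(as.integer(df$recessive) | df$recessive %in% c("TRUE", "true"))
  df$candidate <- as.logical(as.integer(df$candidate) | df$candidate %in% c("TRUE", "true"))
  df
}

#' Read a known-somatic-variant table
#'
#' Tab-separated with columns `gene, chrom, pos, ref, alt, protein_change`
#' (a COSMIC-like export; the real COSMIC table is license-restricted and is
#' supplied by the user).
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_known_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "pos", "ref", "alt", "protein_change")
  if (!all(need %in% names(df))) {
    stopf("known-variant table needs columns: %s", paste(need, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df
}

# Protein residue number from a change string like "G12D" / "E746K";
# NA when unparseable.
protein_position <- function(x) {
  suppressWarnings(as.integer(sub("^[A-Za-z*]+([0-9]+).*$", "\\1", x)))
}

#' Match one variant against a known-somatic-variant table
#'
#' `exact` requires the same (chrom, pos, ref, alt) or the same protein
#' change in the same gene; `same_site` the same genomic position or the
#' same protein residue in the same gene; `window_count` counts known
#' variants of the same gene within 15 bp (inclusive) of the variant.
#'
#' @param variant one `VariantCall` row.
#' @param known table from [read_known_variants()].
#' @param window window half-width in bp (default 15).
#' @return list `exact`, `same_site`, `window_count`.
#' @export
match_known <- function(variant, known, window = 15) {
  if (is.null(known) || nrow(known) == 0) {
    return(list(exact = FALSE, same_site = FALSE, window_count = 0L))
  }
  same_gene <- known$gene == variant$gene
  exact_genomic <- known$chrom == variant$chrom & known$pos == variant$pos &
    known$ref == variant$ref & known$alt == variant$alt
  exact_protein <- same_gene & !is.na(known$protein_change) &
    !is.na(variant$protein_change) &
    known$protein_change == variant$protein_change
  site_genomic <- known$chrom == variant$chrom & known$pos == variant$pos
  vp <- protein_position(variant$protein_change)
  site_protein <- same_gene & !is.na(vp) &
    !is.na(protein_position(known$protein_change)) &
    protein_position(known$protein_change) == vp
  window_count <- sum(same_gene & abs(known$pos - variant$pos) <= window,
                      na.rm = TRUE)
  list(exact = any(exact_genomic | exact_protein),
       same_site = any(site_genomic | site_protein),
       window_count = as.integer(window_count))
}

#' Decide whether a variant is a putative driver
#'
#' Gate: the gene must sit on the candidate-driver list (disable with
#' `require_candidate = FALSE`).  Then a variant is a putative driver if
#' (1) the exact mutation, the same mutation site, or at least three known
#' mutations within 15 bp are found in the known-somatic table, or (2) the
#' gene is recessive in the census, the effect is stop-gain / frameshift /
#' splicing, and SIFT < 0.05 or PolyPhen > 0.995.  Absent scores fail the
#' score clause (conservative).  `rule_fired` records the first satisfied
#' branch in the order exact_match, same_site, window_15bp,
#' recessive_deleterious.
#'
#' @param variant one `VariantCall` row.
#' @param census table from [read_census()].
#' @param match result of [match_known()] (computed if `NULL`).
#' @param known known-variant table, used when `match` is `NULL`.
#' @param require_candidate apply the candidate-list gate (default `TRUE`).
#' @param sift_cut,polyphen_cut score thresholds (defaults 0.05, 0.995).
#' @return list of class `driver_verdict`: `key`, `gene`, `is_driver`,
#'   `rule_fired`, `evidence`.
#' @export
is_putative_driver <- function(variant, census, match = NULL, known = NULL,
                               require_candidate = TRUE,
                               sift_cut = 0.05, polyphen_cut = 0.995) {
  key <- variant_key(variant$chrom, variant$pos, variant$ref, variant$alt)
  verdict <- function(rule, evidence) {
    structure(list(key = key, gene = variant$gene,
                   is_driver = rule != "none", rule_fired = rule,
                   evidence = evidence), class = "driver_verdict")
  }
  entry <- census[census$gene == variant$gene, , drop = FALSE]
  if (require_candidate && (nrow(entry) == 0 || !entry$candidate[1])) {
    return(verdict("none", "gene not in candidate list"))
  }
  if (is.null(match)) match <- match_known(variant, known)
  if (isTRUE(match$exact)) return(verdict("exact_match", "exact known mutation"))
  if (isTRUE(match$same_site)) return(verdict("same_site", "known mutation at same site"))
  if (match$window_count >= 3) {
    return(verdict("window_15bp",
                   sprintf("%d known mutations within 15 bp", match$window_count)))
  }
  recessive <- nrow(entry) > 0 && isTRUE(entry$recessive[1])
  deleterious <- variant$effect %in% c("stop_gain", "frameshift", "splicing")
  score_ok <- (!is.na(variant$sift) && variant$sift < sift_cut) ||
    (!is.na(variant$polyphen) && variant$polyphen > polyphen_cut)
  if (recessive && deleterious && score_ok) {
    return(verdict("recessive_deleterious",
                   sprintf("recessive gene, %s, sift=%s polyphen=%s",
                           variant$effect, format(variant$sift),
                           format(variant$polyphen))))
  }
  verdict("none", "no rule satisfied")
}

#' Screen a table of variant calls for putative drivers
#'
#' Applies [is_putative_driver()] to every row; deterministic and
#' independent of input order.
#'
#' @param calls `VariantCall` rows.
#' @param census census table.
#' @param known known-variant table.
#' @param ... passed to [is_putative_driver()].
#' @return `data.frame`: key, region_id, gene, effect, is_driver,
#'   rule_fired, evidence.
#' @export
screen_drivers <- function(calls, census, known, ...) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, , drop = FALSE]
    res <- is_putative_driver(v, census, known = known, ...)
    data.frame(key = res$key, region_id = v$region_id, gene = v$gene,
               effect = v$effect, protein_change = v$protein_change,
               sift = v$sift,
               is_driver = res$is_driver, rule_fired = res$rule_fired,
               evidence = res$evidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.driver_verdict <- function(x, ...) {
  cat(sprintf("%s (%s): %s [%s]\n", x$key, x$gene,
              if (x$is_driver) "putative driver" else "not a driver",
              x$rule_fired))
  invisible(x)
}
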