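# Reading and writing the tabular formats the pipeline touches, and the
# per-patient binary mutation matrix everything downstream consumes.

VARIANT_EFFECTS <- c("missense", "stop_gain", "frameshift", "splicing",
                     "inframe_indel", "synonymous", "other")
NONSILENT_EFFECTS <- c("missense", "stop_gain", "frameshift", "splicing",
                       "inframe_indel")

# Canonical column set of the MAF-like TSV dialect (written by
# write_variants(), read by read_variants(format = "tsv")).
VARIANT_COLUMNS <- c("patient_id", "region_id", "chrom", "pos", "ref", "alt",
                     "gene", "effect", "alt_reads", "ref_reads", "context3",
                     "protein_change", "sift", "polyphen")

#' Construct a table of somatic variant calls
#'
#' A `VariantCall` table is a plain `data.frame` with one row per somatic
#' variant per tumor region: the atom of every downstream stage.  Positions
#' are 1-based; `ref`/`alt` follow VCF conventions (indels carry the shared
#' anchor base and are left-trimmed to a minimal representation).
#'
#' @param patient_id,region_id identifiers (region = tumor + region label).
#' @param chrom,pos,ref,alt variant coordinates, 1-based.
#' @param gene gene symbol or `""`.
#' @param effect one of `r paste(VARIANT_EFFECTS, collapse = ", ")`; unknown
#'   strings are mapped to `"other"` with a warning.
#' @param alt_reads,ref_reads supporting read counts (`NA` when absent).
#' @param context3 3-mer reference context centred on `pos` (optional).
#' @param protein_change e.g. `"G12D"` (optional).
#' @param sift,polyphen deleteriousness scores in `[0, 1]` (optional).
#' @return `data.frame` with the columns listed above.
#' @export
variant_calls <- function(patient_id, region_id, chrom, pos, ref, alt,
                          gene = "", effect = "other",
                          alt_reads = NA_integer_, ref_reads = NA_integer_,
                          context3 = NA_character_,
                          protein_change = NA_character_,
                          sift = NA_real_, polyphen = NA_real_) {
  df <- data.frame(
    patient_id = as.character(patient_id), region_id = as.character(region_id),
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene), effect = as.character(effect),
    alt_reads = as.integer(alt_reads), ref_reads = as.integer(ref_reads),
    context3 = as.character(context3),
    protein_change = as.character(protein_change),
    sift = as.numeric(sift), polyphen = as.numeric(polyphen),
    stringsAsFactors = FALSE
  )
  validate_variant_calls(df)
}

validate_variant_calls <- function(df) {
  bad <- !df$effect %in% VARIANT_EFFECTS
  if (any(bad)) {
    warnf("unknown effect string(s) %s mapped to 'other'",
          paste(unique(df$effect[bad]), collapse = ", "))
    df$effect[bad] <- "other"
  }
  if (any(df$ref == df$alt)) stopf("ref must differ from alt")
  has_reads <- !is.na(df$alt_reads) & !is.na(df$ref_reads)
  if (any(has_reads & (df$alt_reads + df$ref_reads) <= 0)) {
    stopf("variant with read support must have alt_reads + ref_reads > 0")
  }
  has_ctx <- !is.na(df$context3) & df$context3 != ""
  mid <- substr(df$context3[has_ctx], 2, 2)
  snv <- is_snv(df$ref[has_ctx], df$alt[has_ctx])
  if (any(snv & mid != df$ref[has_ctx])) {
    stopf("context3 middle base must equal ref for SNVs")
  }
  df
}

#' Read somatic variant calls from TSV or VCF
#'
#' The TSV dialect is the tab-separated table written by [write_variants()]
#' (columns `patient_id, region_id, chrom, pos, ref, alt, gene, effect,
#' alt_reads, ref_reads, context3, protein_change, sift, polyphen`; optional
#' annotation columns may be empty).  VCF input (4.x) is parsed with
#' \pkg{vcfR}; sample columns become regions, allelic depths are taken from
#' the `AD` FORMAT field, and multi-allelic records are split into one call
#' per alternate allele.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param patient_id patient identifier to stamp on VCF-derived calls
#'   (TSV carries its own column).
#' @return a `VariantCall` `data.frame` (possibly 0-row).
#' @export
read_variants <- function(path, format = c("tsv", "vcf"), patient_id = "P1") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path, patient_id)
}

read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c("patient_id", "region_id", "chrom", "pos", "ref", "alt"),
                          names(df))
  if (length(missing_cols)) {
    stopf("variant TSV lacks required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(empty_variant_calls())
  num <- function(col) if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else NA_real_
  chr <- function(col) if (col %in% names(df)) df[[col]] else NA_character_
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) {
    stopf("malformed pos at line %d of %s", which(is.na(pos))[1] + 1L, path)
  }
  if (!all(c("alt_reads", "ref_reads") %in% names(df))) {
    warnf("read-depth columns missing in %s; counts recorded as absent", path)
  }
  blank_na <- function(x) { x[!is.na(x) & x == ""] <- NA; x }
  variant_calls(df$patient_id, df$region_id, df$chrom, pos, df$ref, df$alt,
                gene = chr("gene") %na% "", effect = chr("effect") %na% "other",
                alt_reads = num("alt_reads"), ref_reads = num("ref_reads"),
                context3 = blank_na(chr("context3")),
                protein_change = blank_na(chr("protein_change")),
                sift = num("sift"), polyphen = num("polyphen"))
}

empty_variant_calls <- function() {
  variant_calls(character(), character(), character(), integer(),
                character(), character(), gene = character(),
                effect = character(), alt_reads = integer(),
                ref_reads = integer(), context3 = character(),
                protein_change = character(), sift = numeric(),
                polyphen = numeric())
}

`%na%` <- function(x, default) { x[is.na(x)] <- default; x }

read_variants_vcf <- function(path, patient_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(empty_variant_calls())
  samples <- colnames(v@gt)[-1]
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  out <- list()
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      for (s in samples) {
        alt_r <- ref_r <- NA_integer_
        if (!is.null(ad) && !is.na(ad[i, s])) {
          depths <- suppressWarnings(as.integer(strsplit(ad[i, s], ",")[[1]]))
          if (length(depths) >= k + 1) { ref_r <- depths[1]; alt_r <- depths[k + 1] }
        }
        out[[length(out) + 1L]] <- data.frame(
          patient_id = patient_id, region_id = s,
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[k], gene = "", effect = "other",
          alt_reads = alt_r, ref_reads = ref_r,
          context3 = NA_character_, protein_change = NA_character_,
          sift = NA_real_, polyphen = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- do.call(rbind, out)
  if (is.null(ad)) warnf("no AD field in %s; read counts recorded as absent", path)
  # Drop sample rows without any read evidence of the allele (uncalled): keep
  # all rows — presence thresholds are applied later by build_mutation_matrix.
  validate_variant_calls(calls)
}

#' Write variant calls to the package's TSV dialect
#'
#' @param calls a `VariantCall` `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(calls, path) {
  utils::write.table(calls[, VARIANT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Build the per-patient binary mutation matrix
#'
#' A variant is marked present in a region iff its alternate-read count and
#' variant allele fraction there pass the detection thresholds.  Variants
#' passing in no region are dropped; with `nonsilent_only` the synonymous and
#' `other` effect classes are excluded, matching the convention of non-silent
#' presence/absence heat maps from multi-focal studies.
#'
#' @param calls `VariantCall` rows for one patient.
#' @param min_alt_reads minimum alternate reads for presence (default 3).
#' @param min_vaf minimum variant allele fraction for presence (default 0.02).
#' @param nonsilent_only restrict to non-silent effects (default `TRUE`).
#' @return object of class `mutation_matrix`: list with `present`
#'   (binary variants x regions matrix), `variants` (key strings), `regions`,
#'   and `info` (per-variant annotation rows).
#' @export
build_mutation_matrix <- function(calls, min_alt_reads = 3, min_vaf = 0.02,
                                  nonsilent_only = TRUE) {
  if (length(unique(calls$patient_id)) > 1) {
    stopf("all calls must share one patient_id")
  }
  regions <- sort(unique(calls$region_id))
  if (length(regions) == 0) stopf("no regions in input calls")
  if (nonsilent_only) calls <- calls[calls$effect %in% NONSILENT_EFFECTS, , drop = FALSE]
  keys <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  uniq <- sort(unique(keys))
  m <- matrix(0L, nrow = length(uniq), ncol = length(regions),
              dimnames = list(uniq, regions))
  depth <- calls$alt_reads + calls$ref_reads
  vaf <- ifelse(depth > 0, calls$alt_reads / depth, 0)
  pass <- !is.na(calls$alt_reads) & calls$alt_reads >= min_alt_reads &
    !is.na(vaf) & vaf >= min_vaf
  if (any(pass)) {
    m[cbind(match(keys[pass], uniq), match(calls$region_id[pass], regions))] <- 1L
  }
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  info <- calls[!duplicated(keys) & keys %in% rownames(m), , drop = FALSE]
  info <- info[match(rownames(m), variant_key(info$chrom, info$pos, info$ref, info$alt)), ,
               drop = FALSE]
  structure(list(present = m, variants = rownames(m), regions = regions,
                 info = info),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d variants x %d regions (%s)\n",
              nrow(x$present), length(x$regions),
              paste(x$regions, collapse = ", ")))
  invisible(x)
}

#' Read a copy-number segment table
#'
#' SEG/BED-like tab-separated table with columns `region_id, chrom, start,
#' end, cn_total`.  Coordinates are interpreted as 1-based inclusive unless
#' `bed = TRUE`, in which case the 0-based half-open BED start is converted
#' on read.  Overlapping segments within one region are rejected.
#'
#' @param path file path.
#' @param bed input uses BED coordinate conventions (default `FALSE`).
#' @return `data.frame` of segments.
#' @export
read_copy_number <- function(path, bed = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "chrom", "start", "end", "cn_total")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("copy-number table lacks column(s): %s", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$cn_total <- as.integer(df$cn_total)
  if (bed) df$start <- df$start + 1L
  validate_segments(df)
}

validate_segments <- function(df) {
  if (any(df$start > df$end)) stopf("segment with start > end")
  if (any(df$cn_total < 0)) stopf("negative copy number")
  for (key in unique(paste(df$region_id, df$chrom))) {
    seg <- df[paste(df$region_id, df$chrom) == key, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stopf("overlapping copy-number segments in %s", key)
    }
  }
  df
}

#' Look up local total copy number at a position
#'
#' Returns the covering segment's `cn_total` for the region, or `default`
#' (2, the diploid assumption) when no segment covers the position.  Segment
#' boundaries are inclusive.
#'
#' @param segments table from [read_copy_number()] (may be `NULL`).
#' @param region_id,chrom,pos query locus.
#' @param default copy number outside all segments (default 2).
#' @return integer copy number.
#' @export
lookup_cn <- function(segments, region_id, chrom, pos, default = 2L) {
  if (is.null(segments) || nrow(segments) == 0) return(as.integer(default))
  hit <- segments$region_id == region_id & segments$chrom == chrom &
    segments$start <= pos & segments$end >= pos
  if (!any(hit)) return(as.integer(default))
  as.integer(segments$cn_total[which(hit)[1]])
}

#' Read a per-region tumor purity table
#'
#' Tab-separated with columns `region_id, purity`; purity in (0, 1].
#'
#' @param path file path.
#' @return named numeric vector of purities keyed by region_id.
#' @export
read_purity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region_id", "purity") %in% names(df))) {
    stopf("purity table needs columns region_id, purity")
  }
  p <- as.numeric(df$purity)
  if (any(p <= 0 | p > 1)) stopf("purity values must lie in (0, 1]")
  stats::setNames(p, df$region_id)
}

#' Restrict a mutation matrix to a subset of regions
#'
#' Keeps the given regions and drops variants absent from all of them —
#' e.g. to isolate one tumor's regions before tree building.
#'
#' @param matrix a `mutation_matrix`.
#' @param regions region ids to keep (must exist in the matrix).
#' @return a `mutation_matrix` over the requested regions.
#' @export
subset_regions <- function(matrix, regions) {
  missing_regions <- setdiff(regions, matrix$regions)
  if (length(missing_regions)) {
    stopf("unknown region(s): %s", paste(missing_regions, collapse = ", "))
  }
  m <- matrix$present[, regions, drop = FALSE]
  keep <- rowSums(m) > 0
  info <- matrix$info
  if (!is.null(info)) info <- info[keep, , drop = FALSE]
  structure(list(present = m[keep, , drop = FALSE],
                 variants = matrix$variants[keep], regions = regions,
                 info = info),
            class = "mutation_matrix")
}
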