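# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Reverse complement of an A/C/G/T string vector (no ambiguity codes needed:
# somatic SNV contexts are plain bases).
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(b) paste(rev(unname(comp[b])), collapse = ""), "")
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
}

# Variant key shared across the whole package.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Fan a master seed out to reproducible child seeds.  Adding a stream never
# perturbs earlier streams; all results stay below 2^31.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
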