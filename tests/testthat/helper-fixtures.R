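# Shared fixtures, built in code.

ext_path <- function(f) system.file("extdata", f, package = "mfclone")

fixture_census <- function() read_census(ext_path("census.tsv"))
fixture_known <- function() read_known_variants(ext_path("known_variants.tsv"))
fixture_pathways <- function() {
  utils::read.delim(ext_path("pathways.tsv"), stringsAsFactors = FALSE)
}

# A small deterministic call set: two tumors x two regions, hand-chosen
# presence patterns.
toy_calls <- function() {
  rows <- list(
    # variant A: clonal in both regions of T1 only
    c("T1_R1", "chr1", 1000, "C", "T", "GENE1", "missense", 40, 60),
    c("T1_R2", "chr1", 1000, "C", "T", "GENE1", "missense", 35, 65),
    # variant B: private to T1_R1
    c("T1_R1", "chr2", 2000, "A", "G", "GENE2", "missense", 20, 80),
    # variant C: shared across tumors
    c("T1_R1", "chr3", 3000, "G", "A", "GENE3", "stop_gain", 30, 70),
    c("T2_R1", "chr3", 3000, "G", "A", "GENE3", "stop_gain", 25, 75),
    # variant D: T2 only, below alt-read floor in T2_R2
    c("T2_R1", "chr4", 4000, "T", "C", "GENE4", "missense", 15, 85),
    c("T2_R2", "chr4", 4000, "T", "C", "GENE4", "missense", 2, 98),
    # variant E: synonymous (dropped by nonsilent filter)
    c("T2_R2", "chr5", 5000, "C", "G", "GENE5", "synonymous", 50, 50)
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("region_id", "chrom", "pos", "ref", "alt", "gene", "effect",
                 "alt_reads", "ref_reads")
  variant_calls("P1", df$region_id, df$chrom, as.integer(df$pos), df$ref,
                df$alt, gene = df$gene, effect = df$effect,
                alt_reads = as.integer(df$alt_reads),
                ref_reads = as.integer(df$ref_reads))
}

toy_tumor_of <- c(T1_R1 = "T1", T1_R2 = "T1", T2_R1 = "T2", T2_R2 = "T2")

# Random binary mutation matrix for parsimony checks.
random_matrix <- function(n_var, n_reg, seed) {
  set.seed(seed)
  m <- matrix(rbinom(n_var * n_reg, 1, 0.5), n_var, n_reg)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  regions <- paste0("R", seq_len(n_reg))
  dimnames(m) <- list(paste0("v", seq_len(nrow(m))), regions)
  structure(list(present = m, variants = rownames(m), regions = regions,
                 info = NULL), class = "mutation_matrix")
}

# Independent exhaustive-parsimony oracle via phangorn: minimum Fitch score
# over all unrooted topologies on the regions plus an all-absent outgroup.
oracle_parsimony <- function(mat) {
  m <- rbind(t(mat$present), normal = 0L)
  dat <- phangorn::phyDat(m, type = "USER", levels = c(0, 1))
  trees <- phangorn::allTrees(nrow(m), rooted = FALSE,
                              tip.label = rownames(m))
  min(phangorn::parsimony(trees, dat))
}

# Spectrum synthesized directly from catalog rows (multinomial draw).
spectrum_from_weights <- function(catalog, weights, n, seed,
                                  sample_id = "synth") {
  set.seed(seed)
  probs <- as.numeric(weights %*% catalog)
  counts <- as.integer(stats::rmultinom(1, n, probs))
  names(counts) <- channel_names_96()
  attr(counts, "sample_id") <- sample_id
  attr(counts, "n_snv") <- n
  class(counts) <- "spectrum96"
  counts
}
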