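# Synthetic multifocal-patient simulator.  Generates cohorts with known
# clonal architecture (independent primaries vs. metastatic pairs), branched
# subclonal structure under multi-region sampling, trinucleotide contexts
# drawn from signature mixtures, whole-arm copy-number events, purity and
# binomial read sampling — with complete ground truth for recovery tests.

SIM_CHROMS <- paste0("chr", 1:22)
SIM_CHROM_LEN <- 1e8L

#' Default driver-mutation menu for simulations
#'
#' A small table of recurrent lung-cancer driver lesions (gene, protein
#' change, pathway, synthetic genomic coordinates) used to plant truncal
#' drivers.  Coordinates are synthetic but stable, and match the bundled
#' known-somatic-variant fixture so planted drivers are recoverable by the
#' exact-match rule.
#'
#' @return `data.frame` with columns gene, protein_change, pathway, chrom,
#'   pos, ref, alt, effect.
#' @export
driver_menu_default <- function() {
  data.frame(
    gene = c("EGFR", "EGFR", "KRAS", "KRAS", "BRAF", "MAP2K1", "MET", "ARAF",
             "ERBB2", "TP53"),
    protein_change = c("L858R", "E746K", "G12D", "G12C", "D594G", "E102K",
                       "D1010H", "S214C", "V777L", "R175H"),
    pathway = c("EGFR_family", "EGFR_family", "MAPK", "MAPK", "MAPK", "MAPK",
                "MAPK", "MAPK", "EGFR_family", "TP53"),
    chrom = c("chr7", "chr7", "chr12", "chr12", "chr7", "chr15", "chr7",
              "chr20", "chr17", "chr17"),
    pos = c(55259515L, 55242465L, 25398284L, 25398285L, 40453193L, 66729181L,
            16411990L, 47426121L, 37880220L, 7578406L),
    ref = c("T", "G", "C", "C", "T", "G", "G", "C", "G", "C"),
    alt = c("G", "A", "T", "A", "C", "A", "C", "G", "T", "T"),
    effect = rep("missense", 10),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Defaults emulate a small multifocal lung-cancer study: two tumors of two
#' sampled regions each, roughly 150 truncal plus 40-per-branch somatic
#' mutations per tumor (a few hundred alterations per tumor overall), mean
#' coverage 244x, purity 0.6, and two subclones per tumor at cancer cell
#' fractions 0.6 and 0.3.
#'
#' @param n_tumors number of tumors in the patient (default 2).
#' @param regions_per_tumor sampled regions per tumor (scalar or vector).
#' @param scenario `"independent_primaries"` (tumors share zero variants by
#'   construction) or `"metastatic"` (all tumors carry one identical truncal
#'   set with true CCF 1 everywhere).
#' @param n_truncal_per_tumor truncal mutations per tumor (default 150).
#' @param n_branch_per_clone mutations per branch clone (default 40).
#' @param n_subclones_per_tumor subclones confined to single regions
#'   (default 2).
#' @param n_mut_per_subclone mutations per subclone (default 30).
#' @param subclone_ccf_values CCFs cycled over subclones, each in (0, 1].
#' @param purity per-region purity in (0, 1] (recycled).
#' @param depth mean sequencing coverage (default 244).
#' @param catalog signature catalog used to draw trinucleotide channels
#'   (default [synthetic_signature_catalog()] with 4 signatures).
#' @param signature_weights matrix tumors x signatures (rows sum to 1);
#'   default gives each tumor one dominant signature (weight 0.8) plus a
#'   uniform remainder, rotating through the catalog.
#' @param driver_menu table as [driver_menu_default()].
#' @param n_drivers_per_tumor planted truncal drivers per tumor (default 1).
#' @param synonymous_frac fraction of passenger SNVs emitted as synonymous
#'   (default 0.2).
#' @param cn_levels,cn_props whole-arm copy-number levels and their sampling
#'   proportions (defaults `1:4`, `c(0.05, 0.85, 0.05, 0.05)`).
#' @param seed master RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_tumors = 2, regions_per_tumor = 2,
                       scenario = c("independent_primaries", "metastatic"),
                       n_truncal_per_tumor = 150, n_branch_per_clone = 40,
                       n_subclones_per_tumor = 2, n_mut_per_subclone = 30,
                       subclone_ccf_values = c(0.6, 0.3),
                       purity = 0.6, depth = 244,
                       catalog = synthetic_signature_catalog(4),
                       signature_weights = NULL,
                       driver_menu = driver_menu_default(),
                       n_drivers_per_tumor = 1,
                       synonymous_frac = 0.2,
                       cn_levels = 1:4, cn_props = c(0.05, 0.85, 0.05, 0.05),
                       seed = 1) {
  scenario <- match.arg(scenario)
  regions_per_tumor <- rep_len(regions_per_tumor, n_tumors)
  if (n_tumors < 1) stopf("need at least one tumor")
  if (any(c(n_truncal_per_tumor, n_branch_per_clone, n_subclones_per_tumor,
            n_mut_per_subclone) < 0)) stopf("mutation counts must be >= 0")
  if (any(subclone_ccf_values <= 0 | subclone_ccf_values > 1)) {
    stopf("subclone CCF values must lie in (0, 1]")
  }
  if (any(purity <= 0 | purity > 1)) stopf("purity must lie in (0, 1]")
  if (depth <= 0) stopf("depth must be positive")
  if (is.null(signature_weights)) {
    k <- nrow(catalog)
    signature_weights <- t(vapply(seq_len(n_tumors), function(t) {
      w <- rep(0.2 / (k - 1), k)
      w[(t - 1) %% k + 1] <- 0.8
      w
    }, numeric(k)))
    colnames(signature_weights) <- rownames(catalog)
  }
  if (any(abs(rowSums(signature_weights) - 1) > 1e-9)) {
    stopf("signature weights must sum to 1 per tumor")
  }
  if (abs(sum(cn_props) - 1) > 1e-9) stopf("cn_props must sum to 1")
  if (n_tumors * n_drivers_per_tumor > nrow(driver_menu) &&
      scenario == "independent_primaries") {
    stopf("driver menu too small to give each tumor distinct drivers")
  }
  structure(list(
    n_tumors = n_tumors, regions_per_tumor = regions_per_tumor,
    scenario = scenario, n_truncal_per_tumor = n_truncal_per_tumor,
    n_branch_per_clone = n_branch_per_clone,
    n_subclones_per_tumor = n_subclones_per_tumor,
    n_mut_per_subclone = n_mut_per_subclone,
    subclone_ccf_values = subclone_ccf_values, purity = purity,
    depth = depth, catalog = catalog, signature_weights = signature_weights,
    driver_menu = driver_menu, n_drivers_per_tumor = n_drivers_per_tumor,
    synonymous_frac = synonymous_frac,
    cn_levels = cn_levels, cn_props = cn_props, seed = seed
  ), class = "sim_config")
}

#' Sample read counts for one variant under the expected-VAF model
#'
#' Total depth is Poisson around `depth`; alternate reads are binomial with
#' success probability [expected_vaf()]`(true_ccf, purity, cn_mut, cn_norm)`.
#' This is the forward model whose inversion [estimate_ccf()] implements.
#'
#' @param true_ccf cancer cell fraction in `[0, 1]` (vectorized).
#' @param purity tumor purity in (0, 1].
#' @param cn_mut,cn_norm local copy numbers.
#' @param depth mean coverage.
#' @return `data.frame` with `alt_reads`, `ref_reads`.
#' @export
sample_read_counts <- function(true_ccf, purity, cn_mut, cn_norm = 2, depth = 244) {
  if (depth <= 0) stopf("depth must be positive")
  f <- expected_vaf(true_ccf, purity, cn_mut, cn_norm)
  if (any(f < 0 | f > 1)) stopf("expected VAF outside [0, 1]: inconsistent cn/purity")
  n <- length(f)
  total <- stats::rpois(n, depth)
  alt <- stats::rbinom(n, total, f)
  data.frame(alt_reads = alt, ref_reads = total - alt)
}

# Random rooted binary topology over n leaves (uniform via leaf insertion).
random_topology <- function(n) {
  tree <- 1L
  if (n >= 2) {
    for (leaf in 2:n) {
      options <- insert_leaf_everywhere(tree, leaf)
      tree <- options[[sample.int(length(options), 1)]]
    }
  }
  tree
}

# Clade membership per edge of a nested topology, named by the same edge-id
# scheme build_phylogeny() uses (trunk, clade_*, leaf names).
topology_clades <- function(topo, regions) {
  clades <- list()
  counter <- 0L
  leafset <- function(node) if (!is.list(node)) node else
    c(leafset(node[[1]]), leafset(node[[2]]))
  walk <- function(node, edge_id) {
    clades[[edge_id]] <<- sort(leafset(node))
    if (is.list(node)) {
      for (side in 1:2) {
        child <- node[[side]]
        if (!is.list(child)) {
          cid <- regions[child]
        } else {
          counter <<- counter + 1L
          cid <- sprintf("clade_%02d", counter)
        }
        walk(child, cid)
      }
    }
  }
  walk(topo, "trunk")
  clades
}

# Draw channel indices from a signature mixture and decode to alleles,
# flipping half onto the purine strand to exercise strand collapse.
draw_snv_alleles <- function(n, probs) {
  channels <- channel_names_96()
  idx <- sample.int(96, n, replace = TRUE, prob = probs)
  ch <- channels[idx]
  ref <- substr(ch, 3, 3)
  alt <- substr(ch, 5, 5)
  ctx <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
  flip <- stats::runif(n) < 0.5
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  ctx[flip] <- revcomp(ctx[flip])
  data.frame(channel = ch, ref = ref, alt = alt, context3 = ctx,
             stringsAsFactors = FALSE)
}

#' Simulate one multifocal patient with full ground truth
#'
#' Under `independent_primaries` the tumors share zero somatic variants by
#' construction (all loci are drawn without replacement from one pool).
#' Under `metastatic` a single truncal clone spanning every region of every
#' tumor is emitted once, so all tumors carry the identical truncal keys at
#' true CCF 1.  Each tumor additionally receives a random branched topology
#' over its regions with clone-private mutations, plus single-region
#' subclones at the configured CCFs.  Trinucleotide channels are drawn from
#' the tumor's signature mixture; read counts follow [sample_read_counts()]
#' under per-region purity and local (whole-arm) copy number.  Output is
#' deterministic under the config seed; per-tumor child seeds mean adding a
#' tumor never perturbs earlier tumors.
#'
#' @param config a [sim_config()].
#' @param patient_id identifier stamped on all outputs (default `"SIM1"`).
#' @return list of class `sim_patient`: `calls` (`VariantCall` rows),
#'   `cn` (segment table), `purity` (named vector), `tumor_of` (region ->
#'   tumor map) and `truth` (per-variant truth incl. clone, channel, driver
#'   flag and true CCF per region; per-tumor topology/newick/signature
#'   weights; per-pair related flag; the config).
#' @export
simulate_patient <- function(config, patient_id = "SIM1") {
  stopifnot(inherits(config, "sim_config"))
  regions <- unlist(lapply(seq_len(config$n_tumors), function(t)
    paste0("T", t, "_R", seq_len(config$regions_per_tumor[t]))))
  tumor_of <- stats::setNames(sub("_R\\d+$", "", regions), regions)
  purity <- stats::setNames(rep_len(config$purity, length(regions)), regions)

  set.seed(child_seed(config$seed, 0))
  n_max <- config$n_tumors * (config$n_truncal_per_tumor +
    8 * config$n_branch_per_clone +
    config$n_subclones_per_tumor * config$n_mut_per_subclone) + 1000L
  pos_pool <- sample.int(SIM_CHROM_LEN - 2L, n_max) + 1L
  chrom_pool <- sample(SIM_CHROMS, n_max, replace = TRUE)
  pool_next <- 1L
  take_loci <- function(n) {
    idx <- seq.int(pool_next, length.out = n)
    pool_next <<- pool_next + n
    data.frame(chrom = chrom_pool[idx], pos = pos_pool[idx],
               stringsAsFactors = FALSE)
  }
  gene_counter <- 0L
  new_genes <- function(n) {
    out <- sprintf("GENE%05d", gene_counter + seq_len(n))
    gene_counter <<- gene_counter + n
    out
  }

  truth_rows <- list(); clone_rows <- list(); tumor_meta <- list()
  cn_rows <- list()

  make_truth <- function(tumor, clone_id, member_regions, ccf, loci, alle,
                         gene, effect, protein_change, driver) {
    df <- data.frame(
      key = variant_key(loci$chrom, loci$pos, alle$ref, alle$alt),
      tumor = tumor, clone = clone_id,
      chrom = loci$chrom, pos = loci$pos, ref = alle$ref, alt = alle$alt,
      gene = gene, effect = effect, protein_change = protein_change,
      channel = alle$channel, context3 = alle$context3,
      driver = driver, ccf = ccf,
      member_regions = paste(member_regions, collapse = ","),
      stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <<- df
    clone_rows[[length(clone_rows) + 1L]] <<- data.frame(
      tumor = tumor, clone = clone_id, ccf = ccf,
      regions = paste(member_regions, collapse = ","),
      n_mutations = nrow(df), stringsAsFactors = FALSE)
    invisible(df)
  }

  emit_passengers <- function(tumor, clone_id, member_regions, ccf, n_mut, probs) {
    if (n_mut == 0) return(invisible(NULL))
    loci <- take_loci(n_mut)
    alle <- draw_snv_alleles(n_mut, probs)
    eff <- ifelse(stats::runif(n_mut) < config$synonymous_frac,
                  "synonymous", "missense")
    make_truth(tumor, clone_id, member_regions, ccf, loci, alle,
               new_genes(n_mut), eff, NA_character_, FALSE)
  }

  emit_drivers <- function(tumor, clone_id, member_regions, ccf, menu_rows) {
    if (is.null(menu_rows) || nrow(menu_rows) == 0) return(invisible(NULL))
    ctx <- paste0("A", menu_rows$ref, "A")   # minimal context consistent with ref
    loci <- data.frame(chrom = menu_rows$chrom, pos = menu_rows$pos,
                       stringsAsFactors = FALSE)
    alle <- data.frame(channel = snv_channel(menu_rows$ref, menu_rows$alt, ctx),
                       ref = menu_rows$ref, alt = menu_rows$alt,
                       context3 = ctx, stringsAsFactors = FALSE)
    make_truth(tumor, clone_id, member_regions, ccf, loci, alle,
               menu_rows$gene, menu_rows$effect, menu_rows$protein_change, TRUE)
  }

  tumor_probs <- function(t) as.numeric(config$signature_weights[t, ] %*% config$catalog)

  # Metastatic: one shared truncal clone spanning every region, drawn from
  # the founding tumor's signature mixture, carrying one shared driver.
  if (config$scenario == "metastatic") {
    set.seed(child_seed(config$seed, 500))
    emit_passengers("shared", "trunk", regions, 1,
                    config$n_truncal_per_tumor, tumor_probs(1))
    if (config$n_drivers_per_tumor > 0) {
      emit_drivers("shared", "trunk", regions, 1,
                   config$driver_menu[1, , drop = FALSE])
    }
  }

  menu_used <- 0L
  for (t in seq_len(config$n_tumors)) {
    set.seed(child_seed(config$seed, t))
    tumor <- paste0("T", t)
    t_regions <- regions[tumor_of == tumor]
    nr <- length(t_regions)
    probs <- tumor_probs(t)

    topo <- random_topology(nr)
    clades <- topology_clades(topo, t_regions)

    # whole-arm copy-number events shared by all regions of the tumor
    arms <- expand.grid(chrom = SIM_CHROMS, arm = c("p", "q"),
                        stringsAsFactors = FALSE)
    arm_cn <- sample(config$cn_levels, nrow(arms), replace = TRUE,
                     prob = config$cn_props)
    half <- SIM_CHROM_LEN %/% 2L
    for (r in t_regions) {
      cn_rows[[length(cn_rows) + 1L]] <- data.frame(
        region_id = r, chrom = arms$chrom,
        start = ifelse(arms$arm == "p", 1L, half + 1L),
        end = ifelse(arms$arm == "p", half, SIM_CHROM_LEN),
        cn_total = arm_cn, stringsAsFactors = FALSE)
    }

    if (config$scenario == "independent_primaries") {
      emit_passengers(tumor, "trunk", t_regions, 1,
                      config$n_truncal_per_tumor, probs)
      if (config$n_drivers_per_tumor > 0) {
        idx <- menu_used + seq_len(config$n_drivers_per_tumor)
        emit_drivers(tumor, "trunk", t_regions, 1,
                     config$driver_menu[idx, , drop = FALSE])
        menu_used <- menu_used + config$n_drivers_per_tumor
      }
    }

    for (edge_id in names(clades)) {
      if (edge_id == "trunk" || nr < 2) next
      emit_passengers(tumor, edge_id, t_regions[clades[[edge_id]]], 1,
                      config$n_branch_per_clone, probs)
    }
    if (config$n_subclones_per_tumor > 0) {
      for (s in seq_len(config$n_subclones_per_tumor)) {
        host <- t_regions[((s - 1L) %% nr) + 1L]
        ccf <- config$subclone_ccf_values[
          ((s - 1L) %% length(config$subclone_ccf_values)) + 1L]
        emit_passengers(tumor, sprintf("subclone_%02d", s), host, ccf,
                        config$n_mut_per_subclone, probs)
      }
    }
    tumor_meta[[tumor]] <- list(
      topology = topo, regions = t_regions,
      newick = if (nr >= 2) paste0(encode_topology(topo, t_regions), ";") else
        paste0("(", t_regions, ");"),
      signature_weights = config$signature_weights[t, ])
  }

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (anyDuplicated(truth$key)) stopf("internal error: duplicate variant keys")
  cn <- do.call(rbind, cn_rows)

  ccf_mat <- matrix(0, nrow(truth), length(regions),
                    dimnames = list(truth$key, regions))
  for (i in seq_len(nrow(truth))) {
    mr <- strsplit(truth$member_regions[i], ",", fixed = TRUE)[[1]]
    ccf_mat[i, mr] <- truth$ccf[i]
  }

  set.seed(child_seed(config$seed, 9999))
  calls <- list()
  for (r in regions) {
    cn_r <- cn[cn$region_id == r, , drop = FALSE]
    cn_at <- vapply(seq_len(nrow(truth)), function(i)
      lookup_cn(cn_r, r, truth$chrom[i], truth$pos[i]), 0L)
    rc <- sample_read_counts(ccf_mat[, r], purity[[r]], cn_at, 2, config$depth)
    calls[[r]] <- data.frame(
      patient_id = patient_id, region_id = r,
      chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
      gene = truth$gene, effect = truth$effect,
      alt_reads = rc$alt_reads, ref_reads = rc$ref_reads,
      context3 = truth$context3, protein_change = truth$protein_change,
      sift = NA_real_, polyphen = NA_real_,
      true_ccf = ccf_mat[, r], stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  # a caller would not report loci without any alternate evidence
  calls <- calls[!(calls$alt_reads == 0 & calls$true_ccf == 0), , drop = FALSE]
  calls$true_ccf <- NULL

  pairs <- NULL
  if (config$n_tumors >= 2) {
    cmb <- utils::combn(paste0("T", seq_len(config$n_tumors)), 2)
    pairs <- data.frame(tumor_a = cmb[1, ], tumor_b = cmb[2, ],
                        related = config$scenario == "metastatic",
                        stringsAsFactors = FALSE)
  }

  structure(list(
    calls = validate_variant_calls(calls), cn = cn, purity = purity,
    tumor_of = tumor_of,
    truth = list(variants = truth, ccf = ccf_mat,
                 clones = do.call(rbind, clone_rows),
                 tumors = tumor_meta, pairs = pairs, config = config)
  ), class = "sim_patient")
}

#' @export
print.sim_patient <- function(x, ...) {
  cat(sprintf("sim_patient: %d tumors, %d regions, %d variants (%s)\n",
              x$truth$config$n_tumors, length(x$purity),
              nrow(x$truth$variants), x$truth$config$scenario))
  invisible(x)
}

#' Write a simulated patient to disk in the pipeline's input dialects
#'
#' Produces `variants.tsv`, `copy_number.seg`, `purity.tsv` and
#' `truth.json` under `dir`.
#'
#' @param sim a `sim_patient`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_patient <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_variants(sim$calls, file.path(dir, "variants.tsv"))
  utils::write.table(sim$cn, file.path(dir, "copy_number.seg"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(region_id = names(sim$purity),
                                purity = unname(sim$purity)),
                     file.path(dir, "purity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(variants = truth$variants, clones = truth$clones,
         pairs = truth$pairs,
         tumors = lapply(truth$tumors, function(x) x[c("regions", "newick")])),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Synthetic wild-type protein sequences for a driver menu
#'
#' Deterministic pseudo-protein sequences, one per menu gene, long enough to
#' contain the menu's mutated residue and carrying the wild-type amino acid
#' at that position.  Purely synthetic stand-ins for real proteome entries,
#' intended for exercising the neoantigen stage without external data.
#'
#' @param menu a driver menu as [driver_menu_default()].
#' @param seed RNG seed (default 1).
#' @param tail_len residues appended beyond the mutated position (default 20).
#' @return named character vector of protein sequences keyed by gene.
#' @export
synthetic_proteins <- function(menu = driver_menu_default(), seed = 1,
                               tail_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- character(0)
  for (i in seq_len(nrow(menu))) {
    g <- menu$gene[i]
    if (g %in% names(out)) next
    posn <- protein_position(menu$protein_change[i])
    wt <- substr(menu$protein_change[i], 1, 1)
    set.seed(child_seed(seed, 1000 + i))
    s <- sample(aa, posn + tail_len, replace = TRUE)
    s[posn] <- wt
    out[g] <- paste(s, collapse = "")
  }
  out
}

#' Write protein sequences to FASTA
#' @param proteins named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteins_fasta <- function(proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(proteins)) {
    writeLines(c(paste0(">", g), proteins[[g]]), con)
  }
  invisible(path)
}
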