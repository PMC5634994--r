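# Per-patient orchestration: ingest -> clonal architecture -> spectra and
# signatures -> CCF/clonality -> drivers -> neoantigens, plus the pathway
# convergence summary.  Stage artifacts are written as TSV/Newick/JSON; the
# report is a JSON-serializable list.

#' Run the full per-patient analysis pipeline
#'
#' `config` is a YAML file (or an equivalent named list) with keys:
#' \describe{
#'   \item{variants}{path to the variant TSV (or `vcf:` path).}
#'   \item{copy_number}{optional segment table path.}
#'   \item{purity}{purity TSV path (or a single number applied everywhere).}
#'   \item{tumor_of}{optional named map region -> tumor; by default the
#'     region prefix before `_R` is the tumor.}
#'   \item{census, known_variants, pathways}{optional driver inputs.}
#'   \item{catalog}{optional signature catalog TSV.}
#'   \item{proteins}{optional protein FASTA for the neoantigen stage.}
#'   \item{params}{optional overrides: min_alt_reads, min_vaf, alpha,
#'     max_shared_frac, exome_positions, min_weight, clonal_cut, min_depth,
#'     k_max, n_permutations.}
#'   \item{seed}{RNG seed for the seeded stages (default 1).}
#' }
#' Stages run in dependency order; a failure halts with the stage name while
#' earlier artifacts remain on disk.  Unknown config keys are rejected.
#'
#' @param config path to a YAML config, or a named list.
#' @param out_dir directory for stage artifacts (default: `report` only,
#'   no files, when `NULL`).
#' @return a `patient_report` list: `relatedness`, `trees`, `itb`,
#'   `spectra`, `exposures`, `clusters`, `ccf`, `drivers`, `neoantigen_load`,
#'   `convergence`, `meta`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known_keys <- c("variants", "vcf", "copy_number", "purity", "tumor_of",
                  "census", "known_variants", "pathways", "catalog",
                  "proteins", "params", "seed", "patient_id")
  unknown <- setdiff(names(config), known_keys)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  params <- config$params %||% list()
  seed <- config$seed %||% 1

  # pre-flight: report all missing inputs at once
  paths <- unlist(config[intersect(names(config),
                                   c("variants", "vcf", "copy_number", "census",
                                     "known_variants", "pathways", "catalog",
                                     "proteins"))])
  if (is.character(config$purity)) paths <- c(paths, config$purity)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) if (!is.null(out_dir)) writer(file.path(out_dir, name))

  stage <- "ingest"
  report <- list()
  tryCatch({
    calls <- if (!is.null(config$vcf)) {
      read_variants(config$vcf, "vcf", patient_id = config$patient_id %||% "P1")
    } else read_variants(config$variants, "tsv")
    cn <- if (!is.null(config$copy_number)) read_copy_number(config$copy_number) else NULL
    purity <- if (is.character(config$purity)) read_purity(config$purity) else {
      regions <- unique(calls$region_id)
      stats::setNames(rep(as.numeric(config$purity %||% 1), length(regions)), regions)
    }
    tumor_of <- if (!is.null(config$tumor_of)) unlist(config$tumor_of) else {
      regions <- unique(calls$region_id)
      stats::setNames(sub("_R\\d+$", "", regions), regions)
    }
    mm <- build_mutation_matrix(calls,
                                min_alt_reads = params$min_alt_reads %||% 3,
                                min_vaf = params$min_vaf %||% 0.02)

    stage <- "architecture"
    tumors <- unique(tumor_of[mm$regions])
    relatedness <- list()
    if (length(tumors) >= 2) {
      cmb <- utils::combn(tumors, 2)
      for (j in seq_len(ncol(cmb))) {
        r <- test_pair_overlap(mm, tumor_of, cmb[1, j], cmb[2, j],
                               exome_positions = params$exome_positions %||% 3e7,
                               alpha = params$alpha %||% 0.01,
                               max_shared_frac = params$max_shared_frac %||% 0.05)
        relatedness[[paste(cmb[, j], collapse = "_vs_")]] <- unclass(r)
      }
    }
    trees <- list(); itb <- list()
    for (t in tumors) {
      t_regions <- mm$regions[tumor_of[mm$regions] == t]
      if (length(t_regions) < 2) next
      sub <- subset_regions(mm, t_regions)
      tree <- build_phylogeny(sub)
      labels <- assign_trunk_branch(sub)
      trees[[t]] <- tree
      itb[[t]] <- compute_itb(labels)
      emit(sprintf("tree_%s.nwk", t), function(p) writeLines(tree$newick, p))
    }

    stage <- "spectra_signatures"
    spectra <- lapply(split(calls, calls$region_id), compute_spectrum)
    for (r in names(spectra)) attr(spectra[[r]], "sample_id") <- r
    catalog <- if (!is.null(config$catalog)) read_signature_catalog(config$catalog) else
      synthetic_signature_catalog(4)
    exposures <- lapply(spectra, function(s)
      if (sum(s) > 0) fit_signatures(s, catalog,
                                     min_weight = params$min_weight %||% 0.06) else NULL)
    clusters <- if (sum(vapply(spectra, sum, 0) > 0) >= 2) {
      cluster_samples(spectra, k = params$k %||% 2)
    } else NULL
    emit("spectra.tsv", function(p) write_spectra(spectra, p))

    stage <- "ccf"
    ccf_tab <- lapply(unique(calls$region_id), function(r) {
      cr <- calls[calls$region_id == r & !is.na(calls$alt_reads), , drop = FALSE]
      if (nrow(cr) == 0) return(NULL)
      cn_mut <- vapply(seq_len(nrow(cr)), function(i)
        lookup_cn(cn, r, cr$chrom[i], cr$pos[i]), 0L)
      rec <- estimate_ccf(cr$alt_reads, cr$ref_reads, purity[[r]], cn_mut, 2)
      rec <- classify_clonal(rec, clonal_cut = params$clonal_cut %||% 0.95,
                             min_depth = params$min_depth %||% 10)
      cbind(data.frame(key = variant_key(cr$chrom, cr$pos, cr$ref, cr$alt),
                       region_id = r, gene = cr$gene, stringsAsFactors = FALSE),
            rec)
    })
    ccf_tab <- do.call(rbind, ccf_tab)
    emit("ccf.tsv", function(p) utils::write.table(ccf_tab, p, sep = "\t",
                                                   quote = FALSE, row.names = FALSE))
    oligo <- lapply(unique(calls$region_id), function(r) {
      assess_oligoclonality(ccf_tab[ccf_tab$region_id == r, , drop = FALSE],
                            k_max = params$k_max %||% 5, seed = seed)
    })
    names(oligo) <- unique(calls$region_id)

    stage <- "drivers"
    drivers <- NULL
    if (!is.null(config$census) && !is.null(config$known_variants)) {
      census <- read_census(config$census)
      known <- read_known_variants(config$known_variants)
      drivers <- screen_drivers(calls, census, known)
      emit("drivers.tsv", function(p) utils::write.table(drivers, p, sep = "\t",
                                                         quote = FALSE, row.names = FALSE))
    }

    stage <- "neoantigen"
    neo <- NULL
    if (!is.null(config$proteins)) {
      prot <- Biostrings::readAAStringSet(config$proteins)
      names(prot) <- sub("\\s.*$", "", names(prot))
      neo <- neoantigen_load(calls, prot, tumor_of)
    }

    stage <- "convergence"
    convergence <- NULL
    if (!is.null(drivers) && !is.null(config$pathways)) {
      pathways <- utils::read.delim(config$pathways, stringsAsFactors = FALSE)
      convergence <- summarize_convergence(drivers, pathways, tumor_of,
                                           n_permutations = params$n_permutations %||% 1e4,
                                           seed = seed)
    }

    report <- list(
      relatedness = relatedness,
      trees = lapply(trees, function(tr) list(newick = tr$newick, score = tr$score)),
      itb = itb,
      spectra = lapply(spectra, as.numeric),
      exposures = lapply(exposures, function(e) if (!is.null(e)) as.list(e$weights)),
      clusters = if (!is.null(clusters)) as.list(clusters$labels),
      ccf = ccf_tab,
      oligoclonality = lapply(oligo, function(o) o[c("k", "oligoclonal", "message")]),
      drivers = drivers,
      neoantigen_load = if (!is.null(neo)) as.list(neo$load),
      convergence = convergence,
      meta = list(seed = seed, n_variants = nrow(mm$present),
                  regions = mm$regions,
                  package_version = as.character(utils::packageVersion("mfclone")))
    )
    class(report) <- "patient_report"
    if (!is.null(out_dir)) {
      json <- report
      json$ccf <- NULL  # full table already on disk
      jsonlite::write_json(unclass(json), file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = 10, force = TRUE)
    }
    report
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Summarize pathway convergence of per-tumor driver mutations
#'
#' Each tumor contributes its most prominent driver (rule priority
#' exact_match > same_site > window_15bp > recessive_deleterious, ties by
#' lowest SIFT then gene name); the statistic is the number of tumors whose
#' driver hits the modal pathway.  Significance is the fraction of at least
#' as extreme statistics when pathways are reassigned uniformly at random
#' (seeded permutations), i.e. the chance that independent tumors converge
#' this strongly by luck.
#'
#' @param drivers output of [screen_drivers()].
#' @param pathways `data.frame` with columns `gene`, `pathway`.
#' @param tumor_of named region -> tumor map.
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param seed RNG seed.
#' @return list: `per_tumor` (gene/pathway per tumor), `statistic`,
#'   `modal_pathway`, `p_value`, `n_tumors_with_driver`, `excluded`.
#' @export
summarize_convergence <- function(drivers, pathways, tumor_of,
                                  n_permutations = 1e4, seed = 1) {
  rule_rank <- c(exact_match = 1, same_site = 2, window_15bp = 3,
                 recessive_deleterious = 4)
  hits <- drivers[drivers$is_driver, , drop = FALSE]
  hits$tumor <- tumor_of[hits$region_id]
  per_tumor <- list()
  for (t in unique(stats::na.omit(hits$tumor))) {
    h <- hits[hits$tumor == t, , drop = FALSE]
    h <- h[order(rule_rank[h$rule_fired], h$sift %na% 1, h$gene), , drop = FALSE]
    per_tumor[[t]] <- h[1, c("gene", "rule_fired"), drop = FALSE]
  }
  excluded <- setdiff(unique(tumor_of), names(per_tumor))
  if (length(per_tumor) == 0) {
    return(list(per_tumor = NULL, statistic = 0L, modal_pathway = NA,
                p_value = 1, n_tumors_with_driver = 0L, excluded = excluded))
  }
  pw_of <- stats::setNames(pathways$pathway, pathways$gene)
  genes <- vapply(per_tumor, function(x) x$gene, "")
  pw <- unname(pw_of[genes])
  pw[is.na(pw)] <- "unmapped"
  tab <- table(pw)
  statistic <- max(tab)
  modal <- names(tab)[which.max(tab)]
  n_foci <- length(pw)
  n_pw <- length(unique(pathways$pathway))
  if (n_foci == 1 || n_pw <= 1) {
    p <- 1
  } else {
    set.seed(child_seed(seed, 7))
    perm <- stats::rmultinom(n_permutations, n_foci, rep(1 / n_pw, n_pw))
    p <- mean(apply(perm, 2, max) >= statistic)
  }
  list(per_tumor = lapply(per_tumor, function(x)
         list(gene = x$gene, pathway = unname(pw_of[x$gene]) %na% "unmapped",
              rule = x$rule_fired)),
       statistic = as.integer(statistic), modal_pathway = modal,
       p_value = p, n_tumors_with_driver = n_foci, excluded = excluded)
}

#' @export
print.patient_report <- function(x, ...) {
  cat("patient_report\n")
  for (nm in names(x$relatedness)) {
    r <- x$relatedness[[nm]]
    cat(sprintf("  %s: %d shared, p = %.3g -> %s\n", nm, r$shared_count,
                r$overlap_p, r$verdict))
  }
  for (t in names(x$itb)) cat(sprintf("  %s ITB = %.2f\n", t, x$itb[[t]]))
  if (!is.null(x$convergence)) {
    cat(sprintf("  convergence: %d/%d tumors on %s (p = %.3g)\n",
                x$convergence$statistic, x$convergence$n_tumors_with_driver,
                x$convergence$modal_pathway, x$convergence$p_value))
  }
  invisible(x)
}
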