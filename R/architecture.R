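# Clonal architecture: shared/private classification, the tumor-pair
# relatedness test, maximum-parsimony phylogeny reconstruction on binary
# presence/absence matrices (exhaustive Fitch for small region counts,
# neighbor-joining seed beyond), trunk/branch assignment and the
# branched-to-truncal index.

#' Classify variants as shared or private across tumors
#'
#' A variant is shared when present in at least one region of two or more
#' distinct tumors; presence in several regions of a single tumor is still
#' private at the tumor level.
#'
#' @param matrix a `mutation_matrix`.
#' @param tumor_of named character vector mapping region_id -> tumor id.
#' @return named character vector (`"shared"`/`"private"`) per variant key.
#' @export
classify_shared_private <- function(matrix, tumor_of) {
  missing_regions <- setdiff(matrix$regions, names(tumor_of))
  if (length(missing_regions)) {
    stopf("region(s) missing from tumor map: %s", paste(missing_regions, collapse = ", "))
  }
  tumors <- unique(tumor_of[matrix$regions])
  if (length(tumors) < 2) stopf("shared/private classification needs >= 2 tumors")
  m <- matrix$present
  n_tumors_hit <- vapply(seq_len(nrow(m)), function(i) {
    length(unique(tumor_of[matrix$regions[m[i, ] > 0]]))
  }, 0L)
  stats::setNames(ifelse(n_tumors_hit >= 2, "shared", "private"), matrix$variants)
}

#' Test whether two tumors' variant sets overlap more than chance
#'
#' Under the null that the two tumors accumulated mutations independently
#' across a universe of `exome_positions` callable sites, the number of
#' shared variants follows a hypergeometric distribution; `overlap_p` is the
#' upper tail `P(X >= shared_count)`.  The verdict is `independent` iff the
#' overlap is non-significant (`overlap_p >= alpha`) AND the shared fraction
#' `shared / min(|A|, |B|)` stays below `max_shared_frac` — the guard keeps a
#' single coincidental hotspot from forcing a related call while a large
#' shared truncal set cannot be explained away.
#'
#' @param matrix a `mutation_matrix` covering both tumors.
#' @param tumor_of named region -> tumor map.
#' @param tumor_a,tumor_b tumor ids to compare.
#' @param exome_positions size of the callable-site universe
#'   (default 3e7).
#' @param alpha significance cut on the overlap tail (default 0.01).
#' @param max_shared_frac shared-fraction guard (default 0.05).
#' @return list of class `relatedness_result`: `tumor_a`, `tumor_b`,
#'   `n_a`, `n_b`, `shared_count`, `shared_frac`, `overlap_p`, `verdict`.
#' @export
test_pair_overlap <- function(matrix, tumor_of, tumor_a, tumor_b,
                              exome_positions = 3e7, alpha = 0.01,
                              max_shared_frac = 0.05) {
  m <- matrix$present
  in_tumor <- function(t) rowSums(m[, tumor_of[matrix$regions] == t, drop = FALSE]) > 0
  a <- in_tumor(tumor_a); b <- in_tumor(tumor_b)
  n_a <- sum(a); n_b <- sum(b)
  if (n_a == 0 || n_b == 0) stopf("both tumors need at least one variant")
  if (exome_positions < n_a + n_b) {
    stopf("exome_positions smaller than combined variant sets")
  }
  shared <- sum(a & b)
  overlap_p <- stats::phyper(shared - 1, n_a, exome_positions - n_a, n_b,
                             lower.tail = FALSE)
  shared_frac <- shared / min(n_a, n_b)
  verdict <- if (overlap_p >= alpha && shared_frac < max_shared_frac) {
    "independent"
  } else "related"
  structure(list(tumor_a = tumor_a, tumor_b = tumor_b, n_a = n_a, n_b = n_b,
                 shared_count = shared, shared_frac = shared_frac,
                 overlap_p = overlap_p, verdict = verdict),
            class = "relatedness_result")
}

#' @export
print.relatedness_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %d/%d variants, %d shared (p = %.3g) -> %s\n",
              x$tumor_a, x$tumor_b, x$n_a, x$n_b, x$shared_count,
              x$overlap_p, x$verdict))
  invisible(x)
}

# ---- maximum parsimony ----------------------------------------------------

# Rooted binary topologies over leaves 1..n (rooted by the implicit normal
# outgroup on the stem): classic leaf-insertion enumeration, (2n-3)!! trees.
# A tree is a nested list; a leaf is an integer.
enumerate_topologies <- function(n) {
  trees <- list(1L)
  if (n == 1) return(trees)
  for (leaf in 2:n) {
    trees <- unlist(lapply(trees, insert_leaf_everywhere, leaf = leaf),
                    recursive = FALSE)
  }
  trees
}

insert_leaf_everywhere <- function(tree, leaf) {
  out <- list(list(tree, leaf))           # insertion on the stem above `tree`
  if (is.list(tree)) {
    for (side in 1:2) {
      for (sub in insert_leaf_everywhere(tree[[side]], leaf)) {
        nt <- tree
        nt[[side]] <- sub
        out[[length(out) + 1L]] <- nt
      }
    }
  }
  out
}

# Fitch small-parsimony pass, vectorized over variants.  Leaf states are
# codes 1 ({absent}) / 2 ({present}); internal sets 1, 2 or 3 ({0,1}).
# Returns prelim state codes per node (as a list mirroring the topology)
# plus the change count per variant (including the stem to the all-absent
# normal outgroup).
fitch_post <- function(tree, leaf_codes) {
  changes <- integer(ncol(leaf_codes) * 0 + nrow(leaf_codes) * 0)  # placeholder
  nvar <- nrow(leaf_codes)
  changes <- integer(nvar)
  rec <- function(node) {
    if (!is.list(node)) return(leaf_codes[, node])
    a <- rec(node[[1]]); b <- rec(node[[2]])
    inter <- bitwAnd(a, b)
    miss <- inter == 0L
    changes <<- changes + as.integer(miss)
    ifelse(miss, bitwOr(a, b), inter)
  }
  root_prelim <- rec(tree)
  # stem to the normal outgroup (state {absent} = 1)
  changes <- changes + as.integer(bitwAnd(root_prelim, 1L) == 0L)
  list(root_prelim = root_prelim, changes = changes)
}

fitch_score <- function(tree, leaf_codes) sum(fitch_post(tree, leaf_codes)$changes)

# Canonical encoding for deterministic tie-breaking between equally
# parsimonious topologies.
encode_topology <- function(tree, labels) {
  if (!is.list(tree)) return(labels[tree])
  e <- sort(c(encode_topology(tree[[1]], labels), encode_topology(tree[[2]], labels)))
  paste0("(", e[1], ",", e[2], ")")
}

#' Reconstruct a maximum-parsimony phylogeny from a mutation matrix
#'
#' Builds the most parsimonious tree over the sampled regions with an
#' all-absent normal outgroup as root.  For up to `max_exhaustive` regions
#' every rooted topology is scored exhaustively with the Fitch algorithm
#' (exact); beyond that a neighbor-joining tree on Hamming distance supplies
#' the topology and Fitch is used for scoring and placement.  Ties between
#' equally parsimonious topologies are broken by a lexicographic canonical
#' encoding, so results are deterministic.  Each variant is placed on the
#' edge where its presence state is gained (first gain in preorder when
#' homoplasy forces several changes; such variants are flagged).
#'
#' @param matrix a `mutation_matrix` with >= 2 regions.
#' @param max_exhaustive largest region count solved exhaustively
#'   (default 8).
#' @return object of class `phylo_mp`: `regions`, `score`, `edges`
#'   (`data.frame` edge_id/parent/child/n_mutations/is_trunk), `placement`
#'   (edge_id per variant), `homoplasy` (flag per variant), `newick`, and
#'   the underlying topology.
#' @export
build_phylogeny <- function(matrix, max_exhaustive = 8) {
  regions <- matrix$regions
  n <- length(regions)
  if (n < 2) stopf("phylogeny needs >= 2 regions")
  m <- matrix$present
  leaf_codes <- ifelse(m > 0, 2L, 1L)       # variants x regions
  if (n <= max_exhaustive) {
    topos <- enumerate_topologies(n)
    scores <- vapply(topos, fitch_score, 0L, leaf_codes = leaf_codes)
    best <- which(scores == min(scores))
    if (length(best) > 1) {
      enc <- vapply(topos[best], encode_topology, "", labels = regions)
      best <- best[order(enc)[1]]
    }
    topo <- topos[[best]]
    score <- min(scores)
  } else {
    topo <- nj_topology(m, regions)
    score <- fitch_score(topo, leaf_codes)
  }
  placement <- place_variants(topo, leaf_codes, regions)
  edges <- placement$edges
  edges$n_mutations <- vapply(edges$edge_id, function(e) sum(placement$edge_of == e), 0L)
  structure(list(regions = regions, score = score, topology = topo,
                 edges = edges,
                 placement = stats::setNames(placement$edge_of, matrix$variants),
                 homoplasy = stats::setNames(placement$homoplasy, matrix$variants),
                 newick = phylo_mp_newick(placement$annotated, regions,
                                          stats::setNames(edges$n_mutations,
                                                          edges$edge_id))),
            class = "phylo_mp")
}

# Neighbor-joining topology (regions + normal outgroup) converted to the
# nested representation rooted at the normal stem.
nj_topology <- function(m, regions) {
  mat <- rbind(t(m), normal = 0L)
  d <- stats::dist(mat, method = "manhattan")
  tr <- ape::nj(d)
  tr <- ape::root(tr, outgroup = "normal", resolve.root = TRUE)
  tr <- ape::drop.tip(tr, "normal")
  ape_to_nested(tr, regions)
}

ape_to_nested <- function(tr, regions) {
  rec <- function(node) {
    if (node <= length(tr$tip.label)) return(match(tr$tip.label[node], regions))
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    # resolve any multifurcation left-to-right
    sub <- lapply(kids, rec)
    while (length(sub) > 2) sub <- c(list(list(sub[[1]], sub[[2]])), sub[-(1:2)])
    list(sub[[1]], sub[[2]])
  }
  rec(length(tr$tip.label) + 1L)
}

# Final-state assignment and per-variant edge placement.  Every edge is
# identified by the node below it: leaf edges carry the region name,
# internal edges stable preorder ids, and the stem from the normal root to
# the MRCA of all regions is "trunk".
place_variants <- function(topo, leaf_codes, regions) {
  nvar <- nrow(leaf_codes)
  post <- function(node) {
    if (!is.list(node)) return(list(code = leaf_codes[, node], leaf = node))
    a <- post(node[[1]]); b <- post(node[[2]])
    inter <- bitwAnd(a$code, b$code)
    list(code = ifelse(inter == 0L, bitwOr(a$code, b$code), inter),
         left = a, right = b)
  }
  annotated <- post(topo)
  edges <- list()
  n_gain <- integer(nvar); n_loss <- integer(nvar)
  first_gain <- rep(NA_character_, nvar)
  counter <- 0L
  walk <- function(node, parent_final, parent_id, edge_id) {
    final <- ifelse(bitwAnd(node$code, parent_final) > 0L, parent_final, node$code)
    gain <- parent_final == 1L & final == 2L
    loss <- parent_final == 2L & final == 1L
    n_gain <<- n_gain + as.integer(gain)
    n_loss <<- n_loss + as.integer(loss)
    first_gain[gain & is.na(first_gain)] <<- edge_id
    edges[[length(edges) + 1L]] <<- data.frame(
      edge_id = edge_id, parent = parent_id, stringsAsFactors = FALSE)
    node$edge_id <- edge_id
    if (!is.null(node$left)) {
      for (side in c("left", "right")) {
        child <- node[[side]]
        if (is.null(child$left)) {
          cid <- regions[child$leaf]
        } else {
          counter <<- counter + 1L
          cid <- sprintf("clade_%02d", counter)
        }
        node[[side]] <- walk(child, final, edge_id, cid)
      }
    }
    node
  }
  annotated <- walk(annotated, rep(1L, nvar), "normal", "trunk")
  if (anyNA(first_gain)) stopf("internal error: variant without a gain edge")
  edges <- do.call(rbind, edges)
  edges$is_trunk <- edges$edge_id == "trunk"
  list(edges = edges, edge_of = first_gain,
       homoplasy = n_gain > 1L | n_loss > 0L, annotated = annotated)
}

# Newick string with edge lengths equal to mutation counts; the normal
# outgroup sits on a zero-length edge next to the trunk.
phylo_mp_newick <- function(annotated, regions, edge_len) {
  rec <- function(node) {
    body <- if (is.null(node$left)) {
      regions[node$leaf]
    } else {
      sprintf("(%s,%s)", rec(node$left), rec(node$right))
    }
    sprintf("%s:%d", body, edge_len[[node$edge_id]] %||% 0L)
  }
  sprintf("(normal:0,%s);", rec(annotated))
}

#' @export
print.phylo_mp <- function(x, ...) {
  cat(sprintf("phylo_mp: %d regions, parsimony score %d\n",
              length(x$regions), x$score))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Assign variants to trunk or branch
#'
#' A variant is truncal when present in every sampled region of the tumor
#' (the multi-region-sequencing convention for early mutations); everything
#' else is branched.
#'
#' @param matrix a `mutation_matrix` restricted to one tumor's regions, or a
#'   `phylo_mp` built from such a matrix together with its matrix via the
#'   `matrix` argument.
#' @return named character vector `"truncal"`/`"branched"` per variant.
#' @export
assign_trunk_branch <- function(matrix) {
  m <- matrix$present
  stats::setNames(ifelse(rowSums(m > 0) == ncol(m), "truncal", "branched"),
                  matrix$variants)
}

#' Index of branched to truncal mutations (ITB)
#'
#' The ratio of branched to truncal mutation counts in one multi-region
#' sequenced tumor; higher values indicate proportionally more late,
#' subclonal diversification.
#'
#' @param labels output of [assign_trunk_branch()] (or a named vector with
#'   values `"truncal"`/`"branched"`).
#' @return numeric ratio; `Inf` with a warning when no truncal mutations.
#' @export
compute_itb <- function(labels) {
  n_trunk <- sum(labels == "truncal")
  n_branch <- sum(labels == "branched")
  if (n_trunk == 0) {
    warnf("no truncal mutations: ITB undefined, returning Inf")
    return(Inf)
  }
  n_branch / n_trunk
}
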