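test_that("shared/private classification follows the tumor-level definition", {
  mm <- build_mutation_matrix(toy_calls())
  lab <- classify_shared_private(mm, toy_tumor_of)
  expect_equal(unname(lab["chr3:3000:G:A"]), "shared")   # T1 + T2
  expect_equal(unname(lab["chr1:1000:C:T"]), "private")  # both T1 regions only
  expect_equal(sum(lab == "shared") + sum(lab == "private"), nrow(mm$present))
  expect_error(classify_shared_private(mm, toy_tumor_of[-1]), "missing")
})

test_that("pair overlap test: empty intersection is independent, identity is related", {
  mm <- build_mutation_matrix(toy_calls())
  # drop the single shared variant to get an empty intersection
  mm0 <- mm
  keep <- mm0$variants != "chr3:3000:G:A"
  mm0$present <- mm0$present[keep, , drop = FALSE]
  mm0$variants <- mm0$variants[keep]
  r0 <- test_pair_overlap(mm0, toy_tumor_of, "T1", "T2")
  expect_equal(r0$shared_count, 0)
  expect_equal(r0$overlap_p, 1)
  expect_equal(r0$verdict, "independent")

  # identical 100-variant sets in a 3e7 universe
  m <- matrix(1L, 100, 2, dimnames = list(paste0("v", 1:100), c("A_R1", "B_R1")))
  mmI <- structure(list(present = m, variants = rownames(m),
                        regions = colnames(m), info = NULL),
                   class = "mutation_matrix")
  rI <- test_pair_overlap(mmI, c(A_R1 = "A", B_R1 = "B"), "A", "B")
  expect_lt(rI$overlap_p, 1e-100)
  expect_equal(rI$verdict, "related")
  # independent tail oracle: explicit hypergeometric mass summation
  tail_mass <- sum(stats::dhyper(100:100, 100, 3e7 - 100, 100))
  expect_equal(rI$overlap_p, tail_mass, tolerance = 1e-12)
})

test_that("overlap p-value equals an explicit hypergeometric mass sum", {
  # 12 shared of |A|=60, |B|=80 in a universe of 1e5
  n_a <- 60; n_b <- 80; shared <- 12; N <- 1e5
  m <- matrix(0L, n_a + n_b - shared, 2)
  m[1:n_a, 1] <- 1L
  m[(n_a - shared + 1):(n_a + n_b - shared), 2] <- 1L
  dimnames(m) <- list(paste0("v", seq_len(nrow(m))), c("A_R1", "B_R1"))
  mm <- structure(list(present = m, variants = rownames(m),
                       regions = colnames(m), info = NULL),
                  class = "mutation_matrix")
  r <- test_pair_overlap(mm, c(A_R1 = "A", B_R1 = "B"), "A", "B",
                         exome_positions = N)
  oracle <- sum(stats::dhyper(shared:n_a, n_a, N - n_a, n_b))
  expect_equal(r$overlap_p, oracle, tolerance = 1e-12)
  expect_equal(r$verdict, "related")  # 12/60 shared trips the fraction guard
})

test_that("two-region phylogeny splits shared trunk from private branches", {
  m <- matrix(0L, 11, 2, dimnames = list(NULL, c("R1", "R2")))
  m[1:5, ] <- 1L          # 5 shared
  m[6:8, 1] <- 1L         # 3 private to R1
  m[9:11, 2] <- 1L        # 3 private to R2
  rownames(m) <- paste0("v", 1:11)
  mm <- structure(list(present = m, variants = rownames(m),
                       regions = colnames(m), info = NULL),
                  class = "mutation_matrix")
  tree <- build_phylogeny(mm)
  expect_equal(tree$score, 11)
  lens <- setNames(tree$edges$n_mutations, tree$edges$edge_id)
  expect_equal(unname(lens["trunk"]), 5)
  expect_equal(unname(lens[c("R1", "R2")]), c(3, 3))
  # every variant placed exactly once; placements sum to matrix rows
  expect_equal(sum(tree$edges$n_mutations), nrow(m))
})

test_that("Fitch score matches the exhaustive phangorn oracle on random matrices", {
  skip_if_not_installed("phangorn")
  for (seed in 1:20) {
    mm <- random_matrix(40, 5, seed)
    tree <- build_phylogeny(mm)
    expect_equal(tree$score, oracle_parsimony(mm),
                 info = sprintf("seed %d", seed))
  }
})

test_that("simulated 4-region topologies are recovered when branches are informative", {
  for (seed in c(2, 4, 6)) {
    cfg <- sim_config(n_tumors = 1, regions_per_tumor = 4,
                      n_truncal_per_tumor = 30, n_branch_per_clone = 10,
                      n_subclones_per_tumor = 0, synonymous_frac = 0,
                      seed = seed)
    sim <- simulate_patient(cfg)
    mm <- build_mutation_matrix(sim$calls)
    tree <- build_phylogeny(mm)
    truth_tree <- ape::read.tree(text = sim$truth$tumors$T1$newick)
    est_tree <- ape::read.tree(text = tree$newick)
    est_tree <- ape::drop.tip(est_tree, "normal")
    expect_equal(ape::dist.topo(ape::unroot(est_tree), ape::unroot(truth_tree)),
                 structure(0, class = NULL), ignore_attr = TRUE,
                 info = sprintf("seed %d", seed))
  }
})

test_that("trunk/branch assignment and ITB follow their definitions", {
  m <- matrix(0L, 30, 3, dimnames = list(paste0("v", 1:30), c("R1", "R2", "R3")))
  m[1:10, ] <- 1L                       # 10 truncal
  m[11:25, 1] <- 1L                     # 15 branched
  m[26:30, c(2, 3)] <- 1L               # 5 branched
  mm <- structure(list(present = m, variants = rownames(m),
                       regions = colnames(m), info = NULL),
                  class = "mutation_matrix")
  lab <- assign_trunk_branch(mm)
  expect_equal(sum(lab == "truncal"), 10)
  expect_equal(compute_itb(lab), 2.0)
  # relabeling regions does not change ITB
  mm2 <- mm
  colnames(mm2$present) <- c("X", "Y", "Z")
  mm2$regions <- c("X", "Y", "Z")
  expect_equal(compute_itb(assign_trunk_branch(mm2)), 2.0)
  # all-ubiquitous matrix has no branches
  mall <- mm
  mall$present[] <- 1L
  expect_equal(compute_itb(assign_trunk_branch(mall)), 0)
  # no trunk -> Inf with warning
  mnone <- mm
  mnone$present[, 1] <- 0L
  mnone$present[1:10, 1] <- 1L
  mnone$present[1:10, 2:3] <- 0L
  expect_warning(itb <- compute_itb(assign_trunk_branch(mnone)), "undefined")
  expect_equal(itb, Inf)
})

test_that("simulated cohorts are discriminated by scenario", {
  for (seed in 1:5) {
    ind <- simulate_patient(sim_config(seed = seed))
    mm <- build_mutation_matrix(ind$calls)
    expect_equal(test_pair_overlap(mm, ind$tumor_of, "T1", "T2")$verdict,
                 "independent")
    met <- simulate_patient(sim_config(scenario = "metastatic", seed = seed))
    mmm <- build_mutation_matrix(met$calls)
    expect_equal(test_pair_overlap(mmm, met$tumor_of, "T1", "T2")$verdict,
                 "related")
  }
})
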