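test_that("independent primaries share zero variants; metastatic share the trunk", {
  sim <- simulate_patient(sim_config(seed = 11))
  tv <- sim$truth$variants
  keys_by_tumor <- split(tv$key, tv$tumor)
  expect_length(intersect(keys_by_tumor$T1, keys_by_tumor$T2), 0)

  simm <- simulate_patient(sim_config(scenario = "metastatic", seed = 11))
  tvm <- simm$truth$variants
  trunk <- tvm[tvm$clone == "trunk", ]
  expect_equal(unique(trunk$member_regions),
               paste(names(simm$purity), collapse = ","))
  # truncal true CCF 1 in every region
  expect_true(all(simm$truth$ccf[trunk$key, ] == 1))
})

test_that("same seed gives identical simulated output", {
  s1 <- simulate_patient(sim_config(seed = 42))
  s2 <- simulate_patient(sim_config(seed = 42))
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$truth$variants, s2$truth$variants)
  s3 <- simulate_patient(sim_config(seed = 43))
  expect_false(identical(s1$calls, s3$calls))
})

test_that("read sampling follows the expected-VAF forward model", {
  set.seed(1)
  # zero CCF never yields alternate reads
  rc0 <- sample_read_counts(rep(0, 200), 0.8, 2, 2, 100)
  expect_true(all(rc0$alt_reads == 0))
  # clonal diploid pure-tumor limit: VAF -> 0.5
  rc1 <- sample_read_counts(rep(1, 2000), 1, 2, 2, 500)
  vaf <- rc1$alt_reads / (rc1$alt_reads + rc1$ref_reads)
  expect_equal(mean(vaf), 0.5, tolerance = 0.01)
  # hand-derived mean VAF 0.09375 at (ccf .5, p .6, cn 4/2), Monte Carlo
  rc2 <- sample_read_counts(rep(0.5, 1e5), 0.6, 4, 2, 100)
  expect_equal(mean(rc2$alt_reads / (rc2$alt_reads + rc2$ref_reads)),
               0.09375, tolerance = 0.002)
  # inconsistent geometry (zero tumor copies at high purity) is rejected
  expect_error(sample_read_counts(1, 0.9, 0, 2, 100), "outside")
})

test_that("empirical VAF of simulated clonal diploid variants approaches p/2", {
  sim <- simulate_patient(sim_config(seed = 5, purity = 0.7,
                                     cn_props = c(0, 1, 0, 0)))
  tv <- sim$truth$variants
  trunk_keys <- tv$key[tv$clone == "trunk" & tv$tumor == "T1"]
  calls <- sim$calls[sim$calls$region_id == "T1_R1", ]
  calls <- calls[variant_key(calls$chrom, calls$pos, calls$ref, calls$alt) %in%
                   trunk_keys, ]
  vaf <- calls$alt_reads / (calls$alt_reads + calls$ref_reads)
  expect_equal(mean(vaf), 0.35, tolerance = 0.01)
})

test_that("simulated trinucleotide channels follow the signature mixture", {
  catalog <- synthetic_signature_catalog(4)
  w <- c(0.5, 0.3, 0.15, 0.05)
  cfg <- sim_config(n_tumors = 1, regions_per_tumor = 1,
                    n_truncal_per_tumor = 5000, n_branch_per_clone = 0,
                    n_subclones_per_tumor = 0, catalog = catalog,
                    signature_weights = matrix(w, 1), seed = 9)
  sim <- simulate_patient(cfg)
  probs <- as.numeric(w %*% catalog)
  counts <- table(factor(sim$truth$variants$channel, levels = channel_names_96()))
  gof <- suppressWarnings(stats::chisq.test(as.integer(counts), p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(sim_config(subclone_ccf_values = c(0.5, 1.2)), "CCF")
  expect_error(sim_config(purity = 0), "purity")
  expect_error(sim_config(depth = -1), "depth")
  expect_error(sim_config(n_truncal_per_tumor = -5), "counts")
})

test_that("simulated patients round-trip through the on-disk dialects", {
  sim <- simulate_patient(sim_config(seed = 3))
  dir <- withr::local_tempdir()
  write_sim_patient(sim, dir)
  back <- read_variants(file.path(dir, "variants.tsv"), "tsv")
  expect_equal(nrow(back), nrow(sim$calls))
  expect_equal(sort(back$pos), sort(sim$calls$pos))
  seg <- read_copy_number(file.path(dir, "copy_number.seg"))
  expect_equal(nrow(seg), nrow(sim$cn))
  pur <- read_purity(file.path(dir, "purity.tsv"))
  expect_equal(pur, sim$purity)
})
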