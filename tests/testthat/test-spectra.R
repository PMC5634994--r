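test_that("spectrum has exactly 96 channels and bins by pyrimidine strand", {
  expect_length(channel_names_96(), 96)
  # C>T at ACG
  s1 <- compute_spectrum(variant_calls("P", "R", "chr1", 10, "C", "T",
                                       context3 = "ACG"))
  expect_length(s1, 96)
  expect_equal(sum(s1), 1)
  expect_equal(s1[["A[C>T]G"]], 1)
  # G>A at CGT reverse-complements to the same channel
  s2 <- compute_spectrum(variant_calls("P", "R", "chr1", 10, "G", "A",
                                       context3 = "CGT"))
  expect_equal(s2[["A[C>T]G"]], 1)
  # empty input: all zero, still 96 channels
  s0 <- compute_spectrum(toy_calls()[0, ])
  expect_length(s0, 96)
  expect_equal(sum(s0), 0)
})

test_that("spectrum is invariant under full reverse-complement mirroring", {
  sim <- simulate_patient(sim_config(seed = 21))
  calls <- sim$calls[sim$calls$region_id == "T1_R1", ][1:50, ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mirror <- calls
  mirror$ref <- unname(comp[calls$ref])
  mirror$alt <- unname(comp[calls$alt])
  mirror$context3 <- mfclone:::revcomp(calls$context3)
  expect_equal(as.numeric(compute_spectrum(calls)),
               as.numeric(compute_spectrum(mirror)))
})

test_that("contexts can be extracted from a reference FASTA", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "AAACGTTT"), fa)
  calls <- variant_calls("P", "R", "chr1", 4, "C", "A")
  s <- compute_spectrum(calls, reference = fa)
  expect_equal(s[["A[C>A]G"]], 1)
  # middle-base mismatch is an error
  bad <- variant_calls("P", "R", "chr1", 5, "C", "A")  # ref base there is G
  expect_error(compute_spectrum(bad, reference = fa), "disagrees")
})

test_that("single-source spectra are attributed to the generating signature", {
  catalog <- synthetic_signature_catalog(4)
  for (j in 1:4) {
    sp <- spectrum_from_weights(catalog, diag(4)[j, ], 10000, seed = j)
    fit <- fit_signatures(sp, catalog)
    expect_gte(fit$weights[j], 0.99)
    expect_equal(sum(fit$weights[-j]), 0, tolerance = 0.01)
  }
})

test_that("two-signature mixtures are recovered within 0.05", {
  catalog <- synthetic_signature_catalog(4)
  truth <- c(0.7, 0.3, 0, 0)
  for (seed in 1:5) {
    sp <- spectrum_from_weights(catalog, truth, 2000, seed = seed)
    fit <- fit_signatures(sp, catalog)
    expect_lt(max(abs(fit$weights - truth)), 0.05)
  }
})

test_that("pruning drops sub-threshold signatures and the fit reports cosine", {
  catalog <- synthetic_signature_catalog(4)
  sp <- spectrum_from_weights(catalog, c(0.97, 0.03, 0, 0), 5000, seed = 1)
  fit <- fit_signatures(sp, catalog, min_weight = 0.06)
  expect_equal(unname(fit$weights[2]), 0)        # pruned, below 0.06
  expect_gte(fit$weights[1], 0.99)
  expect_gt(fit$residual_cosine, 0.95)
  # uniform-noise spectrum fits worse than any pure catalog spectrum fits itself
  set.seed(2)
  noise <- as.integer(rmultinom(1, 2000, rep(1 / 96, 96)))
  class(noise) <- "spectrum96"
  noise_fit <- fit_signatures(noise, catalog)
  pure_cos <- vapply(1:4, function(j)
    fit_signatures(spectrum_from_weights(catalog, diag(4)[j, ], 2000, j),
                   catalog)$residual_cosine, 0)
  expect_lt(noise_fit$residual_cosine, min(pure_cos))
})

test_that("samples generated from two signatures split into two clean clusters", {
  catalog <- synthetic_signature_catalog(4)
  spectra <- c(
    lapply(1:4, function(i) spectrum_from_weights(catalog, c(1, 0, 0, 0), 500,
                                                  i, sprintf("a%d", i))),
    lapply(1:4, function(i) spectrum_from_weights(catalog, c(0, 0, 1, 0), 500,
                                                  10 + i, sprintf("b%d", i))))
  cl <- cluster_samples(spectra, k = 2)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_false(cl$labels[1] == cl$labels[5])
  # k = n puts every sample in its own cluster
  cln <- cluster_samples(spectra, k = 8)
  expect_equal(length(unique(cln$labels)), 8)
})

test_that("identical spectra merge at height zero", {
  catalog <- synthetic_signature_catalog(4)
  sp <- spectrum_from_weights(catalog, c(1, 0, 0, 0), 500, 1)
  cl <- cluster_samples(list(sp, sp, sp), k = 2)
  expect_equal(max(cl$hclust$height), 0, tolerance = 1e-12)
})

test_that("trunk/branch exposure comparison brackets the planted shift", {
  catalog <- synthetic_signature_catalog(4)
  trunk <- spectrum_from_weights(catalog, c(0.8, 0.2, 0, 0), 1000, 1, "trunk")
  branch <- spectrum_from_weights(catalog, c(0.4, 0.2, 0.4, 0), 1000, 2, "branch")
  cmp <- compare_trunk_branch(trunk, branch, catalog, n_boot = 200, seed = 3)
  sig3 <- cmp[cmp$signature == "SynSig3", ]
  expect_gt(sig3$ci_low, 0)           # +0.4 shift detected
  expect_equal(sig3$diff, 0.4, tolerance = 0.1)
  # identical spectra: zero differences, CIs cover 0
  same <- compare_trunk_branch(trunk, trunk, catalog, n_boot = 100, seed = 4)
  expect_true(all(same$diff == 0))
  expect_true(all(same$ci_low <= 0 & same$ci_high >= 0))
  # tiny spectra do not crash and give wide intervals
  tiny_t <- spectrum_from_weights(catalog, c(1, 0, 0, 0), 10, 5, "t")
  tiny_b <- spectrum_from_weights(catalog, c(0, 1, 0, 0), 10, 6, "b")
  tiny <- compare_trunk_branch(tiny_t, tiny_b, catalog, n_boot = 100, seed = 7)
  expect_true(all(is.finite(tiny$ci_low)))
})

test_that("catalog TSV round trip validates structure", {
  catalog <- synthetic_signature_catalog(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(signature = rownames(catalog), catalog, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_signature_catalog(path)
  expect_equal(unname(back), unname(catalog), tolerance = 1e-12)
  expect_equal(rownames(back), rownames(catalog))
})
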