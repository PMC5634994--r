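driver_call <- function(chrom, pos, ref, alt, gene, effect = "missense",
                        protein_change = NA, sift = NA, polyphen = NA) {
  variant_calls("P", "R1", chrom, pos, ref, alt, gene = gene, effect = effect,
                alt_reads = 30L, ref_reads = 70L,
                protein_change = protein_change, sift = sift,
                polyphen = polyphen)
}

test_that("every rule branch fires on its designed case", {
  census <- fixture_census(); known <- fixture_known()
  # exact genomic + protein match
  v <- driver_call("chr12", 25398284, "C", "T", "KRAS", protein_change = "G12D")
  d <- is_putative_driver(v, census, known = known)
  expect_true(d$is_driver); expect_equal(d$rule_fired, "exact_match")
  # same residue, different substitution -> same_site
  v2 <- driver_call("chr12", 25398290, "G", "T", "KRAS", protein_change = "G12V")
  m2 <- match_known(v2, known)
  expect_false(m2$exact); expect_true(m2$same_site)
  expect_equal(is_putative_driver(v2, census, known = known)$rule_fired,
               "same_site")
  # >= 3 known mutations within 15 bp (TP53 cluster), inclusive boundary
  v3 <- driver_call("chr17", 7578409, "G", "A", "TP53")
  m3 <- match_known(v3, known)
  expect_gte(m3$window_count, 3)
  expect_equal(is_putative_driver(v3, census, known = known)$rule_fired,
               "window_15bp")
  # recessive + deleterious + score
  v4 <- driver_call("chr19", 1221320, "C", "T", "STK11", effect = "stop_gain",
                    sift = 0.01)
  expect_equal(is_putative_driver(v4, census, known = known)$rule_fired,
               "recessive_deleterious")
  # polyphen route
  v5 <- driver_call("chr19", 1221320, "C", "T", "STK11", effect = "frameshift",
                    polyphen = 0.999)
  expect_true(is_putative_driver(v5, census, known = known)$is_driver)
})

test_that("the 15 bp window boundary is inclusive on genomic coordinates", {
  known <- data.frame(gene = "G1", chrom = "chr1",
                      pos = c(1000 - 15, 1000 + 15, 1000 + 3),
                      ref = "A", alt = "T",
                      protein_change = c("A5T", "A6T", "A7T"))
  v <- driver_call("chr1", 1000, "C", "G", "G1")
  expect_equal(match_known(v, known)$window_count, 3)
  known$pos[1] <- 1000 - 16
  expect_equal(match_known(v, known)$window_count, 2)
})

test_that("negative cases fail: no evidence, missing scores, gate", {
  census <- fixture_census(); known <- fixture_known()
  # candidate-list gene, missense, no match, mediocre SIFT
  v <- driver_call("chr7", 99, "A", "C", "EGFR", sift = 0.3)
  expect_false(is_putative_driver(v, census, known = known)$is_driver)
  # recessive + deleterious but absent scores: conservative fail
  v2 <- driver_call("chr19", 5, "C", "T", "STK11", effect = "stop_gain")
  expect_false(is_putative_driver(v2, census, known = known)$is_driver)
  # exact match on a gene outside the candidate list: gate wins
  known2 <- rbind(known, data.frame(gene = "TTN", chrom = "chr2", pos = 179e6,
                                    ref = "A", alt = "G", protein_change = "I100V"))
  v3 <- driver_call("chr2", 1.79e8, "A", "G", "TTN", protein_change = "I100V")
  d3 <- is_putative_driver(v3, census, known = known2)
  expect_false(d3$is_driver)
  expect_match(d3$evidence, "candidate")
  # gate can be disabled
  expect_true(is_putative_driver(v3, census, known = known2,
                                 require_candidate = FALSE)$is_driver)
})

test_that("verdicts are order-independent and monotone in evidence", {
  census <- fixture_census(); known <- fixture_known()
  v <- driver_call("chr12", 25398284, "C", "T", "KRAS", protein_change = "G12D")
  set.seed(1)
  shuffled <- known[sample(nrow(known)), ]
  expect_equal(is_putative_driver(v, census, known = known)$rule_fired,
               is_putative_driver(v, census, known = shuffled)$rule_fired)
  # adding an unrelated known record never removes a driver verdict
  more <- rbind(known, data.frame(gene = "EGFR", chrom = "chr7", pos = 1,
                                  ref = "A", alt = "C", protein_change = "M1L"))
  expect_true(is_putative_driver(v, census, known = more)$is_driver)
})

test_that("planted simulator drivers are recovered and passengers never flagged", {
  census <- fixture_census(); known <- fixture_known()
  sim <- simulate_patient(sim_config(seed = 17))
  verdicts <- screen_drivers(sim$calls, census, known)
  truth <- sim$truth$variants
  driver_keys <- truth$key[truth$driver]
  expect_true(all(driver_keys %in% verdicts$key[verdicts$is_driver]))
  flagged <- unique(verdicts$key[verdicts$is_driver])
  expect_true(all(flagged %in% driver_keys))
})
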