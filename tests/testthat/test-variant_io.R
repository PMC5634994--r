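test_that("TSV round trip preserves all variant fields", {
  calls <- toy_calls()
  calls$sift[1] <- 0.02
  calls$protein_change[1] <- "G12D"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(calls, path)
  back <- read_variants(path, "tsv")
  expect_equal(back$pos, calls$pos)
  expect_equal(back$alt_reads, calls$alt_reads)
  expect_equal(back$sift, calls$sift)
  expect_equal(back$protein_change, calls$protein_change)
  expect_equal(back[, c("chrom", "ref", "alt", "gene", "effect")],
               calls[, c("chrom", "ref", "alt", "gene", "effect")])
})

test_that("header-only TSV yields an empty call set without error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(mfclone:::VARIANT_COLUMNS, collapse = "\t"), path)
  expect_equal(nrow(read_variants(path, "tsv")), 0)
})

test_that("VCF reading splits multi-allelic records and maps AD depths", {
  calls <- read_variants(ext_path("example.vcf"), "vcf", patient_id = "P1")
  # 3 records, one with two alts, two samples
  expect_equal(nrow(calls), (2 + 2) * 2)
  kras <- calls[calls$chrom == "chr12" & calls$region_id == "T1_R1", ]
  expect_setequal(kras$alt, c("T", "A"))
  expect_equal(kras$alt_reads[kras$alt == "T"], 20)
  expect_equal(kras$alt_reads[kras$alt == "A"], 5)
  expect_equal(kras$ref_reads, c(80, 80))
  egfr <- calls[calls$pos == 55259515 & calls$region_id == "T1_R2", ]
  expect_equal(egfr$alt_reads, 30)
})

test_that("unknown effect strings downgrade to 'other' with a warning", {
  expect_warning(
    v <- variant_calls("P", "R", "chr1", 1, "A", "C", effect = "nonsense_mediated"),
    "other")
  expect_equal(v$effect, "other")
})

test_that("mutation matrix applies presence thresholds and drops failures", {
  mm <- build_mutation_matrix(toy_calls())
  # variant D passes only in T2_R1 (2 alt reads in T2_R2 fails the floor)
  expect_equal(unname(mm$present["chr4:4000:T:C", ]), c(0, 0, 1, 0))
  # variant A present in both T1 regions
  expect_equal(unname(mm$present["chr1:1000:C:T", ]), c(1, 1, 0, 0))
  # synonymous variant excluded entirely
  expect_false("chr5:5000:C:G" %in% mm$variants)
  # no all-zero rows
  expect_true(all(rowSums(mm$present) > 0))
})

test_that("variant failing the alt-read floor everywhere is dropped", {
  calls <- variant_calls("P", c("R1", "R2"), "chr1", 100, "A", "G",
                         effect = "missense",
                         alt_reads = c(2L, 2L), ref_reads = c(98L, 98L))
  mm <- build_mutation_matrix(calls)
  expect_equal(nrow(mm$present), 0)
})

test_that("mutation matrix is invariant to call order and idempotent", {
  calls <- toy_calls()
  mm1 <- build_mutation_matrix(calls)
  mm2 <- build_mutation_matrix(calls[rev(seq_len(nrow(calls))), ])
  expect_equal(mm1$present, mm2$present)
  expect_equal(mm1$variants, mm2$variants)
})

test_that("copy-number lookup honours coverage, boundaries and the default", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("region_id\tchrom\tstart\tend\tcn_total",
               "R1\tchr1\t100\t200\t4",
               "R1\tchr1\t300\t400\t1"), path)
  seg <- read_copy_number(path)
  expect_equal(lookup_cn(seg, "R1", "chr1", 150), 4)
  expect_equal(lookup_cn(seg, "R1", "chr1", 200), 4)   # inclusive end
  expect_equal(lookup_cn(seg, "R1", "chr1", 250), 2)   # default
  expect_equal(lookup_cn(seg, "R2", "chr1", 150), 2)   # other region
})

test_that("overlapping segments within one region are rejected", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("region_id\tchrom\tstart\tend\tcn_total",
               "R1\tchr1\t100\t200\t4",
               "R1\tchr1\t150\t400\t1"), path)
  expect_error(read_copy_number(path), "overlapping")
})
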