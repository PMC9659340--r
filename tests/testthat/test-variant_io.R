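test_that("variant tokens parse, validate and round-trip", {
  v <- parse_variant_token("m.13708G>A")
  expect_equal(v$position, 13708L)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "A")
  expect_equal(format(v), "m.13708G>A")

  # boundary: last rCRS position parses; position 0 and beyond-range reject
  expect_equal(parse_variant_token("m.16569T>C")$position, 16569L)
  expect_error(parse_variant_token("m.0A>G"), "range")
  expect_error(parse_variant_token("m.16570A>G"), "range")

  expect_error(parse_variant_token("13708G>A"), "malformed")
  expect_error(parse_variant_token("m.13708G>G"), "identical")
  expect_error(parse_variant_token("m.13708G>N"), "malformed")
  # indels get their own rejection, distinct from malformed
  expect_error(parse_variant_token("m.513_514del"), "indel")
  expect_error(parse_variant_token("m.960insC"), "indel")
})

test_that("catalog TSV round-trips and rejects bad input with locations", {
  cat0 <- variant_catalog(
    c("s1", "s2", "s3"), c("H7", "J", NA),
    list(c("m.4793A>G", "m.13708G>A"), "m.10398A>G", character(0))
  )
  expect_equal(nrow(cat0), 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat0, path)
  cat1 <- read_catalog(path)
  expect_true(catalogs_equal(cat0, cat1))

  # simulated catalog round-trips too
  sim <- patient_catalog(seed = 7, n_h7 = 20, n_j = 10, n_inject = 2,
                         private_rate = 1)
  write_catalog(sim, path)
  expect_true(catalogs_equal(sim, read_catalog(path)))

  # duplicate ids named in the error
  writeLines(c("sample_id\thaplogroup\tvariants",
               "dup1\tH7\tm.4793A>G", "dup1\tJ\t."), path)
  expect_error(read_catalog(path), "dup1")

  # missing header
  writeLines(c("id\thg\tvars", "s1\tH7\t."), path)
  expect_error(read_catalog(path), "header")

  # bad token reported with line number
  writeLines(c("sample_id\thaplogroup\tvariants",
               "s1\tH7\tm.4793A>G", "s2\tH7\tm.0A>G"), path)
  expect_error(read_catalog(path), "line 3")

  expect_error(variant_catalog(c("a", "a")), "duplicate sample_id")
})

test_that("VCF reader extracts chrM SNVs per sample and skips indels", {
  path <- withr::local_tempfile(fileext = ".vcf")

  write_toy_vcf(path, records = list(
    list(pos = 13708, ref = "G", alt = "A", gts = "1")
  ))
  cat1 <- read_vcf_chrm(path)
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$variants[[1]], "m.13708G>A")

  # indel-only VCF: empty variant sets, skip counter 1
  write_toy_vcf(path, records = list(
    list(pos = 513, ref = "GCA", alt = "G", gts = "1")
  ))
  cat2 <- read_vcf_chrm(path)
  expect_equal(cat2$variants[[1]], character(0))
  expect_equal(unname(attr(cat2, "skipped")["indel"]), 1L)

  # multi-sample: one record per sample, genotype-specific presence
  write_toy_vcf(path, records = list(
    list(pos = 13708, ref = "G", alt = "A", gts = c("1", "0", "1")),
    list(pos = 10398, ref = "A", alt = "G", gts = c("0", "1", "1"))
  ))
  cat3 <- read_vcf_chrm(path)
  expect_equal(nrow(cat3), 3L)
  expect_equal(cat3$variants[[1]], "m.13708G>A")
  expect_equal(cat3$variants[[2]], "m.10398A>G")
  expect_equal(cat3$variants[[3]], c("m.10398A>G", "m.13708G>A"))

  # MT also accepted as the mitochondrial contig; other contigs are not
  write_toy_vcf(path, chrom = "MT", records = list(
    list(pos = 100, ref = "A", alt = "G", gts = "1")
  ))
  expect_equal(read_vcf_chrm(path)$variants[[1]], "m.100A>G")
  write_toy_vcf(path, chrom = "chr1", records = list(
    list(pos = 100, ref = "A", alt = "G", gts = "1")
  ))
  expect_error(read_vcf_chrm(path), "chrM/MT")
})

test_that("haplogroup tree JSON validates structure and round-trips", {
  tr <- toy_tree()
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, path)
  tr2 <- read_tree(path)
  expect_equal(haplogroup_names(tr2), haplogroup_names(tr))
  expect_equal(haplogroup_path_variants(tr2, "J"),
               haplogroup_path_variants(tr, "J"))
  expect_equal(haplogroup_path(tr2, "H7"), c("root", "H", "H7"))

  nodes <- function(...) data.frame(..., stringsAsFactors = FALSE)
  expect_error(haplogroup_tree(nodes(name = c("a", "b"), parent = c(NA, "zz")),
                               defining = list(character(0), character(0))),
               "unknown parent")
  expect_error(haplogroup_tree(nodes(name = c("a", "b"), parent = c(NA, NA)),
                               defining = list(character(0), character(0))),
               "exactly one root")
  expect_error(haplogroup_tree(nodes(name = c("r", "a", "b"),
                                     parent = c(NA, "b", "a")),
                               defining = rep(list(character(0)), 3)),
               "cycle")
  # a variant gained twice on one root path violates the linkage invariant
  expect_error(haplogroup_tree(nodes(name = c("r", "a"), parent = c(NA, "r")),
                               defining = list("m.100A>G", "m.100A>G")),
               "more than once")
})

test_that("pedigree TSV round-trips and validates", {
  ped <- family_pedigree()
  expect_equal(nrow(ped), 17L)  # 2 parents + 8 children + 7 miscarriages
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, path)
  ped2 <- read_pedigree(path)
  expect_equal(as.data.frame(ped2), as.data.frame(ped))

  writeLines(c("id\tgeneration\tstatus\tcarrier\tmtdna",
               "x\t2\tzombie\tcarrier\tmutant"), path)
  expect_error(read_pedigree(path), "invalid status")
  expect_error(mt_pedigree(c("a", "a"), 1, "alive", "carrier"), "duplicate")
})
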