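# Shared fixtures, all built in code at test time.

# two-haplogroup tree: H7 and J diverge from a common root; J carries the
# ND5 m.13708G>A defining variant
toy_tree <- function() {
  haplogroup_tree(
    data.frame(name = c("root", "H", "H7", "J"),
               parent = c(NA, "root", "H", "root"),
               stringsAsFactors = FALSE),
    defining = list(character(0),
                    "m.2706A>G",
                    c("m.4793A>G", "m.6365T>C"),
                    c("m.13708G>A", "m.10398A>G", "m.4216T>C"))
  )
}

# population catalog emulating the H7 conditional-frequency situation:
# 348 H7 records and 348 J records, with the J-defining m.13708G>A injected
# into exactly 3 H7 records
patient_catalog <- function(seed = 42, n_h7 = 348, n_j = 348, n_inject = 3,
                            private_rate = 0) {
  cfg <- sim_catalog_config(
    seed = seed,
    counts_per_haplogroup = c(H7 = n_h7, J = n_j),
    private_rate = private_rate,
    injections = list(list(variant = "m.13708G>A", haplogroup = "H7",
                           count = n_inject))
  )
  simulate_catalog(cfg, toy_tree())
}

# the proband-like variant set: full H7 path plus the out-of-context variant
patient_record <- function() {
  c("m.2706A>G", "m.4793A>G", "m.6365T>C", "m.13708G>A")
}

# pedigree shaped like the study family: 8 surviving carrier offspring,
# 7 miscarriages of unknown genotype
family_pedigree <- function() {
  mt_pedigree(
    id = c("I1", "I2", sprintf("II%d", 1:15)),
    generation = c(1L, 1L, rep(2L, 15)),
    status = c("alive", "alive", rep("alive", 8), rep("miscarriage", 7)),
    carrier = c("carrier", "noncarrier", rep("carrier", 8), rep("unknown", 7)),
    mtdna = c("control", "mutant", rep("mutant", 15))
  )
}

# minimal VCF writer for reader tests
write_toy_vcf <- function(path, chrom = "chrM",
                          records = list(list(pos = 13708, ref = "G", alt = "A",
                                              gts = "1")),
                          samples = paste0("S", seq_along(records[[1]]$gts))) {
  n_samp <- length(records[[1]]$gts)
  samples <- paste0("S", seq_len(n_samp))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=16569>", chrom),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(records, function(r) {
    paste(c(chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT", r$gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# single-pixel noiseless biexponential curve on the default timebase
noiseless_curve <- function(a1, amplitude = 5000, n_channels = 256,
                            period = 12500, tau_free = 400, tau_bound = 2500,
                            background = 0) {
  tm <- (seq_len(n_channels) - 0.5) * (period / n_channels)
  amplitude * (a1 * exp(-tm / tau_free) + (1 - a1) * exp(-tm / tau_bound)) + background
}
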