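test_that("noise-free catalogs carry exactly the haplogroup-defining sets", {
  tr <- toy_tree()
  cfg <- sim_catalog_config(seed = 1, counts_per_haplogroup = c(H7 = 50, J = 50))
  cat <- simulate_catalog(cfg, tr)
  expect_equal(nrow(cat), 100L)
  for (h in c("H7", "J")) {
    expected <- haplogroup_path_variants(tr, h)
    sets <- cat$variants[cat$haplogroup == h]
    expect_true(all(vapply(sets, identical, logical(1), y = expected)))
  }
})

test_that("injection places a variant at the configured conditional frequency", {
  cat <- patient_catalog(seed = 11)
  f <- conditional_allele_frequency(cat, "m.13708G>A", "H7")
  expect_equal(f$count, 3L)
  expect_equal(f$total, 348L)
  expect_equal(f$frequency, 3 / 348)
})

test_that("catalog generation is deterministic in config + seed", {
  a <- patient_catalog(seed = 5, private_rate = 2)
  b <- patient_catalog(seed = 5, private_rate = 2)
  c <- patient_catalog(seed = 6, private_rate = 2)
  expect_true(catalogs_equal(a, b))
  expect_false(catalogs_equal(a, c))
})

test_that("generator bookkeeping matches a brute-force recount of emitted records", {
  tr <- haplogroup_tree(data.frame(name = "root", parent = NA),
                        defining = list(character(0)))
  cfg <- sim_catalog_config(seed = 3, counts_per_haplogroup = c(root = 5000),
                            homoplasy_rate = 0.1,
                            homoplasy_variants = c("m.100A>G", "m.200C>T"))
  cat <- simulate_catalog(cfg, tr)
  truth <- attr(cat, "truth")
  # quadratic oracle: nested loop over records
  n1 <- n2 <- n12 <- 0L
  for (i in seq_len(nrow(cat))) {
    h1 <- "m.100A>G" %in% cat$variants[[i]]
    h2 <- "m.200C>T" %in% cat$variants[[i]]
    n1 <- n1 + h1; n2 <- n2 + h2; n12 <- n12 + (h1 && h2)
  }
  pc <- pair_counts(cat, c("m.100A>G", "m.200C>T"))
  expect_equal(unname(pc$n[["m.100A>G"]]), n1)
  expect_equal(unname(pc$n[["m.200C>T"]]), n2)
  expect_equal(unname(pc$n_ij["m.100A>G", "m.200C>T"]), n12)
  expect_equal(length(truth$homoplasy_ids[["m.100A>G"]]), n1)
  expect_equal(length(truth$homoplasy_ids[["m.200C>T"]]), n2)
})

test_that("catalog config rejects invalid structure", {
  tr <- toy_tree()
  cfg <- sim_catalog_config(seed = 1, counts_per_haplogroup = c(Q9 = 10))
  expect_error(simulate_catalog(cfg, tr), "unknown haplogroup")
  # injection colliding with a defining variant of the target background
  cfg2 <- sim_catalog_config(seed = 1, counts_per_haplogroup = c(J = 10),
                             injections = list(list(variant = "m.13708G>A",
                                                    haplogroup = "J", count = 1)))
  expect_error(simulate_catalog(cfg2, tr), "collides")
  expect_error(sim_catalog_config(seed = 1, counts_per_haplogroup = c(H7 = 5),
                                  injections = list(list(variant = "m.100A>G",
                                                         haplogroup = "H7",
                                                         count = 6))),
               "exceeds")
  expect_error(sim_catalog_config(seed = 1, counts_per_haplogroup = c(H7 = -1)),
               ">= 0")
})

test_that("pedigree generator honours lethality model and Mendelian ratios", {
  # full-penetrance noncarrier lethality: every survivor is a carrier
  cfg <- sim_pedigree_config(seed = 2, n_conceptions = 15,
                             lethality_model = "lethal_if_noncarrier",
                             lethality_penetrance = 1)
  ped <- simulate_pedigree(cfg)
  off <- ped[ped$generation == 2L, ]
  expect_equal(nrow(off), 15L)
  surv <- off[off$status == "alive", ]
  expect_true(all(surv$carrier == "carrier"))
  expect_equal(sum(off$status == "alive") + sum(off$status == "miscarriage"), 15L)

  # no lethality at n = 10,000: carrier fraction within 3 binomial SE of 1/2
  big <- simulate_pedigree(sim_pedigree_config(seed = 9, n_conceptions = 10000))
  frac <- mean(big$carrier[big$generation == 2L] == "carrier")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))

  # determinism
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
  expect_error(sim_pedigree_config(seed = 1, n_conceptions = 0), ">= 1")
  expect_error(sim_pedigree_config(seed = 1, n_conceptions = 5,
                                   paternal_carrier_prob = 1.5), "\\[0, 1\\]")
})

test_that("decay-stack generator is seeded and flags empty stacks", {
  cfg <- sim_decay_config(seed = 4, image_shape = c(2, 2), a1_map = 0.5,
                          photons_per_pixel = 1000)
  s1 <- simulate_decay_stack(cfg)
  s2 <- simulate_decay_stack(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_equal(dim(s1$counts), c(2L, 2L, 256L))

  empty <- simulate_decay_stack(sim_decay_config(seed = 1, image_shape = c(2, 2),
                                                 a1_map = 0.5, photons_per_pixel = 0))
  expect_true(all(empty$counts == 0))
  expect_true(isTRUE(attr(empty, "empty")))

  expect_error(sim_decay_config(seed = 1, image_shape = c(2, 2), a1_map = 1.2,
                                photons_per_pixel = 10), "\\[0, 1\\]")
  expect_error(sim_decay_config(seed = 1, image_shape = c(2, 2), a1_map = 0.5,
                                photons_per_pixel = 10, tau1 = 3000), "tau1")
})

test_that("respirometry trace generator produces exact plateaus at zero noise", {
  tr <- simulate_respirometry_trace(
    list(Routine = 50, Leak = 10, ETS = c(80, 100, 95), background = 5),
    noise_sd = 0, seed = 1
  )
  st <- respirometry_states(tr, "intact")
  expect_equal(unname(st$raw[c("Routine", "Leak", "ETS", "background")]),
               c(50, 10, 100, 5))
  # background self-subtraction: the antimycin state is exactly 0
  expect_equal(unname(st$subtracted[["background"]]), 0)
  expect_equal(unname(st$subtracted[c("Routine", "Leak", "ETS")]), c(45, 5, 95))
  expect_error(simulate_respirometry_trace(list()), "empty")
  expect_error(simulate_respirometry_trace(list(Routine = -1, Leak = 1,
                                                ETS = 2, background = 0)),
               ">= 0")
})

test_that("noisy respirometry state estimates are unbiased", {
  true <- list(Routine = 50, Leak = 10, ETS = c(80, 100, 95), background = 5)
  n_rep <- 500
  est <- matrix(NA_real_, n_rep, 4,
                dimnames = list(NULL, c("Routine", "Leak", "ETS", "background")))
  for (r in seq_len(n_rep)) {
    tr <- simulate_respirometry_trace(true, noise_sd = 2, seed = 1000 + r)
    est[r, ] <- respirometry_states(tr, "intact")$raw[colnames(est)]
  }
  # per-replicate plateau = median of 30 noisy samples; ETS = max of 3 such
  # medians, slightly upward biased, so allow a small systematic allowance
  se <- 2 / sqrt(30) / sqrt(n_rep) * 1.253  # approx SE of a median, averaged
  expect_lt(abs(mean(est[, "Routine"]) - 50), 5 * se)
  expect_lt(abs(mean(est[, "Leak"]) - 10), 5 * se)
  expect_lt(abs(mean(est[, "background"]) - 5), 5 * se)
  expect_lt(abs(mean(est[, "ETS"]) - 100), 5 * se + 0.4)
})
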