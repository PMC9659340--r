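test_that("pair counts come out of a single pass over records", {
  # N=100: two variants in 10 records each, sharing exactly 1
  vars <- rep(list(character(0)), 100)
  for (i in 1:10) vars[[i]] <- "m.100A>G"
  for (i in 10:19) vars[[i]] <- c(vars[[i]], "m.200C>T")
  cat <- variant_catalog(sprintf("s%03d", 1:100), "H", vars)
  pc <- pair_counts(cat, c("m.100A>G", "m.200C>T", "m.300G>A"))
  expect_equal(unname(pc$n), c(10L, 10L, 0L))
  expect_equal(unname(pc$n_ij["m.100A>G", "m.200C>T"]), 1L)
  expect_equal(unname(pc$n_ij["m.100A>G", "m.300G>A"]), 0L)
  expect_equal(pc$N, 100L)
})

test_that("normalized cooccurrence hits its closed-form anchors", {
  expect_equal(normalized_cooccurrence(10, 10, 1, 100), 1)    # independence
  expect_equal(normalized_cooccurrence(10, 10, 10, 100), 10)  # full linkage: 1/freq
  expect_equal(normalized_cooccurrence(10, 10, 0, 100), 0)    # exclusion
  expect_true(is.na(normalized_cooccurrence(0, 10, 0, 100)))  # undefined margin
  expect_error(normalized_cooccurrence(10, 10, 1, 0), "N")
  expect_error(normalized_cooccurrence(5, 5, 6, 100), "inconsistent")
})

test_that("the under-cooccurrence p equals exhaustive enumeration", {
  # N=10, both margins 5, zero overlap: enumerate all C(10,5) placements
  sets <- combn(10, 5)
  overlap <- colSums(sets <= 5)
  expect_equal(under_cooccurrence_test(5, 5, 0, 10), mean(overlap <= 0))
  expect_equal(mean(overlap <= 0), 1 / 252)
  # and across the whole support
  for (k in 0:5) {
    expect_equal(under_cooccurrence_test(5, 5, k, 10), mean(overlap <= k))
  }
  # full lower tail
  expect_equal(under_cooccurrence_test(7, 3, 3, 20), 1)
})

test_that("p is monotone in the overlap and symmetric in the margins", {
  p <- vapply(0:8, function(k) under_cooccurrence_test(8, 12, k, 40), numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_equal(under_cooccurrence_test(8, 12, 3, 40),
               under_cooccurrence_test(12, 8, 3, 40))
})

test_that("p matches a permutation oracle within Monte-Carlo error", {
  set.seed(7)
  for (trial in 1:4) {
    N <- sample(20:50, 1)
    n_i <- sample(3:(N - 3), 1)
    n_j <- sample(3:(N - 3), 1)
    draws <- vapply(seq_len(20000),
                    function(d) sum(sample.int(N, n_j) <= n_i), integer(1))
    n_ij <- sample(max(0, n_i + n_j - N):min(n_i, n_j), 1)
    p_hat <- mean(draws <= n_ij)
    p <- under_cooccurrence_test(n_i, n_j, n_ij, N)
    expect_lt(abs(p_hat - p), 4 * sqrt(p * (1 - p) / 20000) + 1e-9)
  }
})

test_that("the cooccurrence matrix is symmetric and self-consistent", {
  cat <- patient_catalog(seed = 13)
  vars <- c("m.4793A>G", "m.13708G>A", "m.10398A>G")
  cm <- cooccurrence_matrix(cat, vars)
  expect_equal(nrow(cm$pairs), 3L)  # C(3,2)
  expect_equal(cm$ratio, t(cm$ratio))
  # ratio recomputed from the pair counts equals the matrix entry
  for (r in seq_len(nrow(cm$pairs))) {
    row <- cm$pairs[r, ]
    expect_equal(row$ratio,
                 normalized_cooccurrence(row$n_i, row$n_j, row$n_ij, row$N))
  }
  expect_error(cooccurrence_matrix(cat, "m.4793A>G"), ">= 2")
})

test_that("zero-carrier pairs are flagged undefined, never dropped", {
  cat <- variant_catalog(c("a", "b"), "H", list("m.100A>G", "m.100A>G"))
  cm <- cooccurrence_matrix(cat, c("m.100A>G", "m.200C>T"))
  expect_equal(nrow(cm$pairs), 1L)
  expect_equal(cm$pairs$flag, "undefined")
  expect_true(is.na(cm$pairs$ratio))
})

test_that("mean ratio is near 1 under independent simulation", {
  tr <- haplogroup_tree(data.frame(name = "root", parent = NA),
                        defining = list(character(0)))
  toks <- variant_token(seq(500, 500 + 19 * 700, by = 700), "A", "G")
  cfg <- sim_catalog_config(seed = 21, counts_per_haplogroup = c(root = 2000),
                            homoplasy_rate = 0.15, homoplasy_variants = toks)
  cm <- cooccurrence_matrix(simulate_catalog(cfg, tr), toks)
  r <- cm$pairs$ratio
  expect_lt(abs(mean(r) - 1), 3 * stats::sd(r) / sqrt(length(r)))
})

test_that("linked haplogroup blocks give depressed cross-background ratios", {
  cat <- patient_catalog(seed = 17)
  h7 <- haplogroup_path_variants(toy_tree(), "H7")
  jv <- setdiff(haplogroup_path_variants(toy_tree(), "J"), "m.2706A>G")
  cm <- cooccurrence_matrix(cat, c(h7, jv))
  cross <- cm$pairs$variant_i %in% h7 != cm$pairs$variant_j %in% h7
  # m.2706A>G is shared upstream of H7 only; pure H7-vs-J pairs are near-exclusive
  pure <- cross & cm$pairs$variant_i != "m.2706A>G" & cm$pairs$variant_j != "m.2706A>G"
  expect_true(all(cm$pairs$ratio[pure] < 1))
  expect_true(all(cm$pairs$q[pure] < 0.05))
  within <- !cross
  expect_true(all(cm$pairs$ratio[within] >= 1))
})

test_that("out-of-context screening flags the injected variant only", {
  cat <- patient_catalog(seed = 19)
  flags <- flag_out_of_context(cat, patient_record())
  expect_gt(nrow(flags), 0)
  expect_true(all(flags$variant_i == "m.13708G>A" | flags$variant_j == "m.13708G>A"))
  expect_true(all(flags$ratio < 1))
  expect_true(all(flags$q < 0.05))
  expect_false(is.unsorted(flags$q))

  # a clean record of its own background: nothing flagged
  clean <- flag_out_of_context(cat, haplogroup_path_variants(toy_tree(), "H7"))
  expect_equal(nrow(clean), 0L)

  # empty record: empty result; unknown variants skipped with a note
  expect_equal(nrow(flag_out_of_context(cat, character(0))), 0L)
  sk <- flag_out_of_context(cat, c("m.9999A>G"))
  expect_equal(attr(sk, "skipped"), "m.9999A>G")
})
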