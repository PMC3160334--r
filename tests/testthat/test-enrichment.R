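# Exhaustive-null values for the 5-gene universe {1..5}, module size 2,
# enumerated by hand: medians of the C(5,2) = 10 pairs.
HAND_MEDIANS <- c(1.5, 2, 2.5, 2.5, 3, 3, 3.5, 3.5, 4, 4.5)

test_that("exact_null reproduces hand enumerations", {
  nm <- exact_null(c(1, 2, 3), 2)
  expect_equal(nm$null_mean, 2)
  expect_equal(nm$n_sets, 3)

  nm <- exact_null(c(1, 2, 3, 4, 5), 2)
  expect_equal(nm$null_mean, mean(HAND_MEDIANS))           # 3.0
  expect_equal(nm$null_sd, sqrt(mean((HAND_MEDIANS - 3)^2)))  # population s.d.

  nm <- exact_null(c(1, 2, 3), 3)   # size = universe: degenerate null
  expect_equal(nm$null_sd, 0)

  expect_error(exact_null(rnorm(40), 10, cap = 1000), "cap")
})

test_that("Monte-Carlo z converges to the exhaustive-null z", {
  vals <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
  ex <- exact_null(vals, 2)
  z_exact <- (4.5 - ex$null_mean) / ex$null_sd
  mz <- module_zscore(vals, c("d", "e"), n_draws = 50000, seed = 7)
  expect_equal(mz$observed_median, 4.5)
  expect_lt(abs(mz$z - z_exact), 0.1)
  # and the exact path matches the oracle identically
  mz_ex <- module_zscore(vals, c("d", "e"), exact = TRUE)
  expect_equal(mz_ex$z, z_exact)
})

test_that("module equal to the whole universe has z = 0", {
  vals <- setNames(c(0.3, -1, 2, 0.7), paste0("g", 1:4))
  mz <- module_zscore(vals, names(vals), n_draws = 100, seed = 1)
  expect_equal(mz$z, 0)
  expect_true(mz$degenerate)
  expect_equal(mz$call, "ns")
})

test_that("z is deterministic under a fixed seed and shift-invariant", {
  set.seed(12)
  vals <- setNames(rnorm(60), paste0("g", 1:60))
  mod <- paste0("g", 1:10)
  a <- module_zscore(vals, mod, n_draws = 2000, seed = 42)
  b <- module_zscore(vals, mod, n_draws = 2000, seed = 42)
  expect_identical(a$z, b$z)
  shifted <- module_zscore(vals + 11.5, mod, n_draws = 2000, seed = 42)
  expect_equal(shifted$z, a$z, tolerance = 1e-9)
})

test_that("z depends only on values and membership, not gene labels", {
  set.seed(13)
  vals <- setNames(rnorm(40), paste0("g", 1:40))
  mod <- paste0("g", 5:12)
  relabeled <- setNames(vals, paste0("X_", toupper(names(vals))))
  a <- module_zscore(vals, mod, n_draws = 1000, seed = 3)
  b <- module_zscore(relabeled, paste0("X_", toupper(mod)),
                     n_draws = 1000, seed = 3)
  expect_identical(a$z, b$z)
})

test_that("mirror modules of a value-symmetric universe have opposite z", {
  vals <- setNames(c(-2, -1, -0.5, 0.5, 1, 2), paste0("g", 1:6))
  up <- module_zscore(vals, c("g5", "g6"), exact = TRUE)
  down <- module_zscore(vals, c("g1", "g2"), exact = TRUE)
  expect_equal(up$z, -down$z)
})

test_that("absent module genes are dropped with effective size recorded", {
  vals <- setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  expect_warning(mz <- module_zscore(vals, c("g3", "g4", "nope"),
                                     n_draws = 200, seed = 1),
                 "absent")
  expect_equal(mz$effective_size, 2L)
  expect_error(suppressWarnings(module_zscore(vals, c("x", "y"), seed = 1)),
               "effective module size 0")
})

test_that("enrichment_matrix is independent of module iteration order", {
  sim <- simulate_expression(small_scenario(seed = 5, n_genes = 120,
                                            module_size = 15))
  nm <- gene_normalize(collapse_probes(sim$probes))
  mods <- truth_modules(sim$truth)
  fwd <- enrichment_matrix(nm, mods, n_draws = 300, seed = 8)
  # reversing list order must not change any (module, sample) z
  rev_prof <- enrichment_matrix(nm, rev(mods), n_draws = 300, seed = 8)
  expect_equal(fwd$z, rev_prof$z[rownames(fwd$z), ])
  # calls follow the 1.96 thresholds
  expect_true(all((fwd$call == "over") == (fwd$z > 1.96), na.rm = TRUE))
  expect_true(all((fwd$call == "under") == (fwd$z < -1.96), na.rm = TRUE))
})

test_that("a one-gene module at the sample maximum scores positive", {
  vals <- named_matrix(c(0.1, 0.5, 3, -1, 0.2), paste0("g", 1:5), "s1")
  em <- expr_matrix(vals, scale = "gene_normalized")
  prof <- enrichment_matrix(em, list(gene_module("top", "g3")),
                            n_draws = 500, seed = 2)
  expect_gt(prof$z["top", "s1"], 0)
})

test_that("planted over-expressed module is called over in the active group", {
  sim <- simulate_expression(small_scenario(seed = 6, noise_sd = 0.2))
  nm <- gene_normalize(collapse_probes(sim$probes))
  prof <- enrichment_matrix(nm, truth_modules(sim$truth),
                            n_draws = 500, seed = 3)
  grp <- sim$truth$group_assignment[colnames(prof$z)]
  expect_gt(mean(prof$z["modA", grp == "hi"]), 1.96)
  expect_gt(mean(prof$call["modA", grp == "hi"] == "over"), 0.5)
  expect_lt(mean(prof$z["modA", grp == "lo"]), -1.96)
})

test_that("optional BH adjustment matches a direct p.adjust computation", {
  sim <- simulate_expression(small_scenario(seed = 7, n_genes = 120,
                                            module_size = 15))
  nm <- gene_normalize(collapse_probes(sim$probes))
  mods <- truth_modules(sim$truth)
  raw <- enrichment_matrix(nm, mods, n_draws = 300, seed = 5)
  adj <- enrichment_matrix(nm, mods, n_draws = 300, seed = 5, bh_adjust = TRUE)
  expect_equal(adj$z, raw$z)
  for (m in rownames(raw$z)) {
    padj <- p.adjust(2 * pnorm(-abs(raw$z[m, ])), method = "BH")
    expect_equal(unname(adj$call[m, ] != "ns"), unname(padj < 0.05))
  }
})
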