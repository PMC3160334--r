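test_that("well QC applies the cap and melt rules literally", {
  wells <- data.frame(plate_id = "p1", sample_id = paste0("s", 1:4),
                      gene = "KDM5A",
                      ct = c(36, 35, NA, 20),
                      melt_ok = c(TRUE, TRUE, TRUE, FALSE))
  qc <- apply_well_qc(wells)
  expect_equal(qc$ct_used[1], 40)              # Ct 36 > 35 -> assigned 40
  expect_equal(qc$qc_status[1], "assigned_40")
  expect_equal(qc$ct_used[2], 35)              # exactly 35: rule is strict
  expect_equal(qc$qc_status[2], "ok")
  expect_equal(qc$ct_used[3], 40)              # no product -> assigned 40
  expect_equal(qc$qc_status[4], "removed_melt")
  expect_true(is.na(qc$ct_used[4]))
})

test_that("ddCt centering: mean-dCt samples get fold 1, and 2^-ddCt is exact", {
  dct <- matrix(c(2, 4, 6,      # geneA: mean dCt = 4
                  5, 5, 5),     # geneB: constant
                2, 3, byrow = TRUE,
                dimnames = list(c("geneA", "geneB"), paste0("s", 1:3)))
  res <- relative_quantification(apply_well_qc(manual_plate(dct)), "B2M")
  a <- res[res$gene == "geneA", ]
  expect_equal(a$delta_delta_ct, c(-2, 0, 2))
  expect_equal(a$fold_change, c(4, 1, 0.25))
  b <- res[res$gene == "geneB", ]
  expect_equal(b$fold_change, rep(1, 3))
  # mean ddCt per gene is zero by construction
  for (g in unique(res$gene))
    expect_lt(abs(mean(res$delta_delta_ct[res$gene == g])), 1e-12)
  # geometric mean of folds is 1 when nothing was filtered
  expect_equal(exp(mean(log(a$fold_change))), 1, tolerance = 1e-12)
})

test_that("noise-free synthetic plates round-trip the planted folds exactly", {
  set.seed(71)
  folds <- matrix(2^rnorm(3 * 8), 3, 8,
                  dimnames = list(c("KDM5A", "KDM5B", "BRD8"), NULL))
  folds["KDM5A", 1] <- 8; folds["KDM5A", 2:8] <- 8^(-1/7)  # geomean 1, fold 8 planted
  pl <- simulate_qpcr_plate(8, c("B2M", rownames(folds)), fold_changes = folds,
                            seed = 72)
  truth <- attr(pl, "truth")
  res <- relative_quantification(apply_well_qc(pl), "B2M")
  expect_equal(res$fold_change, truth[cbind(res$gene, res$sample_id)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$fold_change[res$gene == "KDM5A" & res$sample_id == "S001"],
               8, tolerance = 1e-12)
})

test_that("a +c shift to one gene well rescales its fold by 2^(-c (n-1)/n)", {
  dct <- matrix(c(1, 2, 3, 4), 1, 4,
                dimnames = list("geneA", paste0("s", 1:4)))
  base <- relative_quantification(apply_well_qc(manual_plate(dct)), "B2M")
  shifted_dct <- dct; shifted_dct["geneA", "s2"] <- dct["geneA", "s2"] + 3
  shifted <- relative_quantification(apply_well_qc(manual_plate(shifted_dct)),
                                     "B2M")
  ratio <- shifted$fold_change[shifted$sample_id == "s2"] /
           base$fold_change[base$sample_id == "s2"]
  expect_equal(ratio, 2^(-3 * (4 - 1) / 4), tolerance = 1e-12)
})

test_that("a global per-sample shift leaves dCt and folds unchanged", {
  dct <- matrix(c(1, 2, 3), 1, 3, dimnames = list("geneA", paste0("s", 1:3)))
  pl <- manual_plate(dct)
  pl_shift <- pl
  pl_shift$ct[pl_shift$sample_id == "s2"] <- pl_shift$ct[pl_shift$sample_id == "s2"] + 5
  a <- relative_quantification(apply_well_qc(pl), "B2M")
  b <- relative_quantification(apply_well_qc(pl_shift), "B2M")
  expect_equal(a$delta_ct, b$delta_ct, tolerance = 1e-12)
  expect_equal(a$fold_change, b$fold_change, tolerance = 1e-12)
})

test_that("reference handling: missing per sample vs absent entirely", {
  dct <- matrix(c(1, 2, 3), 1, 3, dimnames = list("geneA", paste0("s", 1:3)))
  pl <- manual_plate(dct)
  pl$melt_ok[pl$gene == "B2M" & pl$sample_id == "s1"] <- FALSE
  res <- relative_quantification(apply_well_qc(pl), "B2M")
  expect_equal(res$qc_status[res$sample_id == "s1"], "missing_reference")
  expect_true(is.na(res$fold_change[res$sample_id == "s1"]))
  expect_false(anyNA(res$fold_change[res$sample_id != "s1"]))

  expect_error(relative_quantification(apply_well_qc(manual_plate(dct)), "GAPDH"),
               "absent from the plate")

  # a dropped-out reference well (assigned 40) cannot normalize its sample
  pl2 <- manual_plate(dct)
  pl2$ct[pl2$gene == "B2M" & pl2$sample_id == "s2"] <- NA
  res2 <- relative_quantification(apply_well_qc(pl2), "B2M")
  expect_equal(res2$qc_status[res2$sample_id == "s2"], "missing_reference")
  expect_true(is.na(res2$fold_change[res2$sample_id == "s2"]))
})

test_that("technical replicates are averaged on the Ct scale", {
  dct <- matrix(c(2, 4), 1, 2, dimnames = list("geneA", c("s1", "s2")))
  pl <- manual_plate(dct)
  dup <- pl[pl$gene == "geneA" & pl$sample_id == "s1", ]
  dup$ct <- dup$ct + 2    # replicate well two cycles higher
  res <- relative_quantification(apply_well_qc(rbind(pl, dup)), "B2M")
  expect_equal(res$delta_ct[res$sample_id == "s1"], 3)   # mean(2, 4)
})

test_that("an all-melt-failed plate yields an empty, explained result", {
  dct <- matrix(c(1, 2), 1, 2, dimnames = list("geneA", c("s1", "s2")))
  pl <- manual_plate(dct)
  pl$melt_ok <- FALSE
  res <- relative_quantification(apply_well_qc(pl), "B2M")
  expect_equal(nrow(res), 0L)
})

test_that("assigned-40 wells can be excluded from the centering mean", {
  dct <- matrix(c(2, 4, 24), 1, 3, dimnames = list("geneA", paste0("s", 1:3)))
  pl <- manual_plate(dct)  # s3 has Ct 18 + 24 = 42 > 35 -> assigned 40
  qc <- apply_well_qc(pl)
  incl <- relative_quantification(qc, "B2M", exclude_assigned = FALSE)
  excl <- relative_quantification(qc, "B2M", exclude_assigned = TRUE)
  # inclusive mean dCt: mean(2, 4, 22) = 28/3; exclusive: mean(2, 4) = 3
  expect_equal(incl$delta_delta_ct[incl$sample_id == "s1"], 2 - 28 / 3)
  expect_equal(excl$delta_delta_ct[excl$sample_id == "s1"], -1)
  expect_equal(excl$qc_status[excl$sample_id == "s3"], "assigned_40")
})

test_that("heatmap scale clips to [0, 10] around the neutral fold of 1", {
  expect_equal(heatmap_scale(1), 1)
  expect_equal(heatmap_scale(25), 10)
  expect_equal(heatmap_scale(0.3), 0.3)
  expect_equal(heatmap_scale(c(0.01, 2, 100)), c(0.01, 2, 10))
  expect_error(heatmap_scale(-1))
})

test_that("plate TSV write/read round trip preserves wells and flags", {
  pl <- simulate_qpcr_plate(4, c("B2M", "KDM5A"), dropout_rate = 0.3,
                            melt_fail_rate = 0.3, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qpcr_plate(pl, path)
  back <- read_qpcr_plate(path)
  expect_equal(back$ct, pl$ct, tolerance = 1e-12)
  expect_equal(back$melt_ok, pl$melt_ok)
  expect_equal(back$sample_id, pl$sample_id)
})
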