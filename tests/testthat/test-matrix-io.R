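test_that("matrix TSV write/read round trip is identity (incl. groups and NA)", {
  vals <- named_matrix(c(1.5, 2, NA, 4.25, -1, 0), c("G1", "G2", "G3"),
                       c("s1", "s2"))
  em <- expr_matrix(vals, scale = "log2_absolute",
                    groups = c(s1 = "colon", s2 = "lung"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(em, path)
  back <- read_matrix(path)
  expect_equal(back$values, em$values)
  expect_equal(back$groups, em$groups)

  pm <- probe_matrix(vals, c(G1 = "A", G2 = "A", G3 = "B"), scale = "log2")
  write_matrix(pm, path)
  back <- read_matrix(path)
  expect_s3_class(back, "probe_matrix")
  expect_equal(back$values, pm$values)
  expect_equal(back$probe_to_gene, pm$probe_to_gene)
})

test_that("malformed matrix files give parse errors, not silent matrices", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts1", "G1\t1\t2"), path)
  expect_error(read_matrix(path), "duplicate sample ids")
  writeLines(c("id\ts1\ts2", "G1\t1"), path)
  expect_error(read_matrix(path), "line 2")
  writeLines(character(), path)
  expect_error(read_matrix(path), "empty")
  writeLines(c("gene\ts1", "G1\t1"), path)
  expect_error(read_matrix(path), "first header field")
})

test_that("missing cells are read as missing, never zero", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "G1\tNA\t2", "G2\t3\t"), path)
  m <- read_matrix(path)
  expect_true(is.na(m$values["G1", "s1"]))
  expect_true(is.na(m$values["G2", "s2"]))
  expect_equal(m$values["G1", "s2"], 2)
})

test_that("GMT round trip, de-duplication and degenerate files", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("M1\tsrc\tA\tB\tC", "M2\tother\tD\tE"), path)
  mods <- read_gmt(path)
  expect_named(mods, c("M1", "M2"))
  expect_equal(mods$M1$genes, c("A", "B", "C"))
  expect_equal(length(mods$M2$genes), 2L)

  write_gmt(mods, path)
  expect_equal(read_gmt(path)$M1$genes, c("A", "B", "C"))

  writeLines("M1\tsrc\ta\tb\ta", path)
  expect_warning(mods <- read_gmt(path), "duplicate")
  expect_equal(mods$M1$genes, c("A", "B"))  # upper-cased set semantics

  writeLines(character(), path)
  expect_warning(out <- read_gmt(path), "no modules")
  expect_length(out, 0L)
})

test_that("probes expressed nowhere are dropped; singletons survive the PCC filter", {
  vals <- named_matrix(c(2, 2, 2, 2,       # flat at the matrix floor
                         5, 6, 7, 8),
                       c("p_floor", "p_live"), paste0("s", 1:4))
  pm <- probe_matrix(vals, c(p_floor = "G1", p_live = "G2"), scale = "log2")
  kept <- filter_probes(pm, min_interprobe_pcc = 0.99)
  expect_equal(rownames(kept$values), "p_live")  # singleton kept at any threshold
})

test_that("iterative interprobe filter drops the anti-tracking probe only", {
  s <- paste0("s", 1:6)
  vals <- rbind(p1 = c(1, 2, 3, 4, 5, 6),
                p2 = c(2, 3, 4, 5, 6, 7),    # PCC 1 with p1
                p3 = c(6, 5, 4, 3, 2, 1))    # PCC -1 with both
  colnames(vals) <- s
  pm <- probe_matrix(vals, setNames(rep("G", 3), rownames(vals)), scale = "log2")
  kept <- filter_probes(pm, min_interprobe_pcc = 0.5, drop_unexpressed = FALSE)
  expect_setequal(rownames(kept$values), c("p1", "p2"))
})

test_that("collapse_probes averages probe rows per gene on the log2 scale", {
  vals <- named_matrix(c(2, 4, 4, 6), c("p1", "p2"), c("s1", "s2"))
  pm <- probe_matrix(vals, c(p1 = "G", p2 = "G"), scale = "log2")
  em <- collapse_probes(pm)
  expect_equal(unname(em$values["G", ]), c(3, 5))
  expect_equal(em$scale, "log2_absolute")

  single <- probe_matrix(vals[1, , drop = FALSE], c(p1 = "G"), scale = "log2")
  expect_equal(unname(collapse_probes(single)$values["G", ]), c(2, 4))

  lin <- probe_matrix(named_matrix(c(8, 16), "p1", c("s1", "s2")),
                      c(p1 = "G"), scale = "linear")
  expect_equal(unname(collapse_probes(lin)$values["G", ]), c(3, 4))
})

test_that("gene_normalize standardizes rows under the n-1 s.d. convention", {
  em <- make_em(named_matrix(c(1, 2, 3), "G1", paste0("s", 1:3)))
  nm <- gene_normalize(em)
  expect_equal(unname(nm$values["G1", ]), c(-1, 0, 1))
  expect_equal(nm$scale, "gene_normalized")

  em <- make_em(named_matrix(c(5, 5, 5), "G1", paste0("s", 1:3)))
  nm <- gene_normalize(em)
  expect_equal(unname(nm$values["G1", ]), c(0, 0, 0))
  expect_true("G1" %in% nm$constant_genes)

  em <- make_em(named_matrix(c(0, 0, 4, 4), "G1", paste0("s", 1:4)))
  nm <- gene_normalize(em)
  expect_equal(unname(nm$values["G1", ]), c(-1, -1, 1, 1) * 0.8660254,
               tolerance = 1e-7)

  expect_error(gene_normalize(make_em(named_matrix(1, "G1", "s1"))),
               "at least 2 samples")
})

test_that("gene_normalize is idempotent and commutes with column permutation", {
  set.seed(31)
  vals <- matrix(rnorm(60, 7, 2), 10, 6,
                 dimnames = list(paste0("G", 1:10), paste0("s", 1:6)))
  vals[3, ] <- 2  # constant row
  nm <- gene_normalize(make_em(vals))
  nm2 <- gene_normalize(nm)
  expect_equal(nm2$values, nm$values, tolerance = 1e-12)

  perm <- c(4, 1, 6, 2, 5, 3)
  nm_perm <- gene_normalize(make_em(vals[, perm]))
  expect_equal(nm_perm$values, nm$values[, perm], tolerance = 1e-12)
})

test_that("rows with fewer than two observations become missing and flagged", {
  vals <- named_matrix(c(1, NA, NA, 2, 3, 4), c("G1", "G2"), paste0("s", 1:3))
  expect_warning(nm <- gene_normalize(make_em(vals)), "observed")
  expect_true(all(is.na(nm$values["G1", ])))
  expect_true("G1" %in% nm$constant_genes)
  expect_equal(unname(nm$values["G2", ]), c(-1, 0, 1))
})
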