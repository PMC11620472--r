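# Activity ingestion, pIC50 conversion and descriptor-matrix plumbing.

test_that("pIC50 conversion matches the negative log-molar definition", {
  expect_equal(ic50_to_pic50(1), 9)
  expect_equal(ic50_to_pic50(1000), 6)
  expect_equal(ic50_to_pic50(50), 7.30103, tolerance = 1e-6)
  expect_error(ic50_to_pic50(0), "positive")
  expect_error(ic50_to_pic50(-3), "positive")

  set.seed(42)
  act <- 10^runif(100, -1, 6)
  expect_equal(pic50_to_ic50(ic50_to_pic50(act)), act, tolerance = 1e-6)
})

test_that("activity tables are filtered with counted drops", {
  txt <- paste("id,smiles,activity_nM",
               "a,CCO,100", "b,CCC,", "c,CCN,250", sep = "\n")
  out <- read_activity_table(txt)
  expect_equal(nrow(out), 2L)
  expect_equal(out$id, c("a", "c"))
  expect_equal(nrow(attr(out, "drops")), 1L)
  expect_equal(attr(out, "drops")$reason, "missing activity")
  expect_equal(out$pic50, 9 - log10(c(100, 250)))

  all_ok <- read_activity_table(
    paste("id,smiles,activity_nM", "a,CCO,1", "b,CCC,2", sep = "\n"))
  expect_equal(nrow(all_ok), 2L)
  expect_equal(nrow(attr(all_ok, "drops")), 0L)

  neg <- read_activity_table(
    paste("id,smiles,activity_nM", "a,CCO,-5", sep = "\n"))
  expect_equal(nrow(neg), 0L)
  expect_equal(attr(neg, "drops")$reason, "non-positive activity")

  expect_error(read_activity_table("id,smiles\na,CCO"), "activity_nM")
})

test_that("activity units are normalised to nM and unknown units dropped", {
  txt <- paste("id,smiles,activity_nM,units",
               "a,CCO,1,uM", "b,CCC,1000,nM", "c,CCN,5,parsec",
               sep = "\n")
  out <- read_activity_table(txt)
  expect_equal(out$activity_nM, c(1000, 1000))
  expect_equal(attr(out, "drops")$reason, "unknown units")
})

test_that("canonical dedupe merges spellings and aggregates by median", {
  rec <- data.frame(id = c("x", "y"), smiles = c("CCO", "OCC"),
                    pic50 = c(6, 8), stringsAsFactors = FALSE)
  out <- canonical_dedupe(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pic50, 7)

  uni <- data.frame(id = c("x", "y"), smiles = c("CCO", "CCC"),
                    pic50 = c(6, 8), stringsAsFactors = FALSE)
  expect_equal(nrow(canonical_dedupe(uni)), 2L)

  bad <- data.frame(id = c("x", "y", "z"),
                    smiles = c("CCO", "C1CC", "CCC"),
                    pic50 = c(6, 7, 8), stringsAsFactors = FALSE)
  out2 <- canonical_dedupe(bad)
  expect_equal(nrow(out2), 2L)
  expect_equal(attr(out2, "drops"), "y")

  # three duplicates, aggregate selectable
  tri <- data.frame(id = c("a", "b", "c"),
                    smiles = c("CCO", "OCC", "C(C)O"),
                    pic50 = c(5, 6, 10), stringsAsFactors = FALSE)
  expect_equal(canonical_dedupe(tri)$pic50, 6)
  expect_equal(canonical_dedupe(tri, "mean")$pic50, 7)
  expect_equal(canonical_dedupe(tri, "first")$pic50, 5)
})

test_that("DUD-E .smi parsing is line-based with blank lines ignored", {
  out <- read_dude_smi("CCO mol1\nCCC mol2\n")
  expect_equal(nrow(out), 2L)
  expect_equal(out$smiles[1], "CCO")
  expect_equal(out$id[1], "mol1")
  expect_equal(nrow(read_dude_smi("CCO mol1\n\n\nCCC mol2\n")), 2L)
  expect_error(read_dude_smi("CCO mol1\nCCN\n"), "line 2")
})

test_that("PaDEL fingerprint tables load with binary validation", {
  set.seed(7)
  vals <- matrix(rbinom(2 * 881, 1, 0.3), 2, 881)
  txt <- paste(c(paste(c("Name", paste0("PubchemFP", 1:881)),
                       collapse = ","),
                 paste(c("cpd1", vals[1, ]), collapse = ","),
                 paste(c("cpd2", vals[2, ]), collapse = ",")),
               collapse = "\n")
  fp <- read_padel_fingerprints(txt)
  expect_equal(dim(fp), c(2L, 881L))
  expect_equal(rownames(fp), c("cpd1", "cpd2"))
  expect_false(attr(fp, "width_mismatch"))

  txt_bad <- "Name,F1,F2\ncpd1,0,2\n"
  expect_error(read_padel_fingerprints(txt_bad), "row 1.*F2")

  txt880 <- paste(c(paste(c("Name", paste0("F", 1:880)), collapse = ","),
                    paste(c("cpd1", rep(0, 880)), collapse = ",")),
                  collapse = "\n")
  expect_warning(fp880 <- read_padel_fingerprints(txt880), "880")
  expect_true(attr(fp880, "width_mismatch"))
})

test_that("variance filter applies the p(1-p) rule and is monotone", {
  mat <- cbind(const = rep(1L, 10),
               half = rep(c(0L, 1L), 5),     # p = 0.5, var 0.25
               rare = c(1L, rep(0L, 9)))     # p = 0.1, var 0.09
  sch <- variance_filter(mat, 0.16)
  expect_equal(sch$names, "half")
  expect_false("const" %in% variance_filter(mat, 1e-9)$names)

  # monotone: raising the threshold never adds a descriptor
  set.seed(3)
  m <- matrix(rbinom(50 * 40, 1, runif(40)), 50, 40, byrow = TRUE,
              dimnames = list(NULL, paste0("D", 1:40)))
  prev <- variance_filter(m, 0)$names
  for (thr in c(0.05, 0.1, 0.16, 0.2, 0.24)) {
    cur <- variance_filter(m, thr)$names
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("schema merging satisfies inclusion-exclusion", {
  shared <- sprintf("S%03d", 1:144)
  a <- descriptor_schema(c(sprintf("A%03d", 1:91), shared))   # 235
  b <- descriptor_schema(c(shared, sprintf("B%03d", 1:107)))  # 251
  m <- merge_schemas(a, b)
  expect_equal(length(m), 342L)
  expect_equal(m$provenance, "merged")

  expect_equal(length(merge_schemas(c("x", "y"), "z")), 3L)
  expect_equal(length(merge_schemas(a, a)), length(a))

  # membership commutativity + size identity vs set-union oracle
  set.seed(11)
  for (rep in 1:20) {
    pool <- sprintf("P%02d", 1:30)
    na <- sample(pool, sample(5:20, 1))
    nb <- sample(pool, sample(5:20, 1))
    ab <- merge_schemas(na, nb)
    ba <- merge_schemas(nb, na)
    expect_setequal(ab$names, union(na, nb))
    expect_setequal(ab$names, ba$names)
    expect_equal(length(ab), length(na) + length(nb) -
                   length(intersect(na, nb)))
  }
  expect_setequal(merge_schemas(a, b, mode = "intersection")$names, shared)
})

test_that("projection fills, drops and preserves shared columns", {
  set.seed(5)
  mat <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4,
                dimnames = list(paste0("r", 1:6), c("a", "b", "c", "d")))
  out <- project_descriptors(mat, c("c", "a"))
  expect_equal(colnames(out), c("c", "a"))
  expect_equal(out[, "a"], mat[, "a"])

  out2 <- project_descriptors(mat, c("a", "new"))
  expect_equal(unname(out2[, "new"]), rep(0L, 6))

  sch <- descriptor_schema(c("b", "zz", "d"))
  expect_identical(project_descriptors(project_descriptors(mat, sch), sch),
                   project_descriptors(mat, sch))

  # shared-column values never change (cell-wise, random schemas)
  for (rep in 1:10) {
    nm <- sample(c("a", "b", "c", "d", "x", "y"), sample(2:6, 1))
    pr <- project_descriptors(mat, nm)
    for (cn in intersect(nm, colnames(mat)))
      expect_identical(pr[, cn], mat[, cn])
  }
})
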