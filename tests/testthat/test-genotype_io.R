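# PLINK 1 binary codec, phenotype typing, covariates and result output.

test_that("hand-assembled .bed block decodes to the expected dosages", {
  # 4 individuals x 1 SNP; two-bit codes low-to-high within the byte:
  # 11 (hom allele2 = dosage 0), 10 (het = 1), 00 (hom allele1 = 2),
  # 01 (missing) -> byte 0b01001011 = 0x4B
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x4b)), paste0(prefix, ".bed"))
  writeLines("1\trs1\t0\t100\tA\tB", paste0(prefix, ".bim"))
  writeLines(paste0("f", 1:4, " i", 1:4, " 0 0 1 ", c(1, 1, 2, 2)),
             paste0(prefix, ".fam"))
  ds <- read_plink_binary(paste0(prefix, ".bed"))
  expect_equal(as.vector(ds$genotypes), c(0L, 1L, 2L, NA))
  expect_identical(ds$phenotype_type, "binary")
  expect_equal(ds$phenotype, c(0, 0, 1, 1))
})

test_that("bad magic bytes, individual-major mode and truncation error out", {
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "bad")
  writeLines("1\trs1\t0\t100\tA\tB", paste0(prefix, ".bim"))
  writeLines("f1 i1 0 0 1 1", paste0(prefix, ".fam"))
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink_binary(paste0(prefix, ".bed")), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink_binary(paste0(prefix, ".bed")), "individual-major")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), paste0(prefix, ".bed"))
  expect_error(read_plink_binary(paste0(prefix, ".bed")), "truncated|size")
})

test_that("write/read round trip is the identity and re-orients minor alleles", {
  set.seed(11)
  for (rep in 1:3) {
    n <- sample(5:23, 1)
    m <- sample(2:8, 1)
    g <- random_geno(n, m, miss = 0.1)
    # orient input to minor allele so round trip is exactly comparable
    freq <- colMeans(g, na.rm = TRUE) / 2
    flip <- !is.na(freq) & freq > 0.5
    g[, flip] <- 2L - g[, flip]
    ds <- make_dataset(g, rbinom(n, 1, 0.5))
    prefix <- file.path(withr::local_tempdir(), "rt")
    write_plink_fixture(ds, prefix)
    back <- read_plink_binary(paste0(prefix, ".bed"))
    expect_equal(unname(back$genotypes), unname(ds$genotypes))
    # minor-allele orientation invariant: frequency <= 0.5 everywhere
    expect_true(all(colMeans(back$genotypes, na.rm = TRUE) / 2 <= 0.5 + 1e-12))
  }
})

test_that("fam phenotype typing follows the 1/2-vs-other rule", {
  tmp <- withr::local_tempdir()
  g <- matrix(c(0L, 1L, 2L, 1L), ncol = 1)
  ds <- make_dataset(g, c(1, 0, 1, NA))
  prefix <- file.path(tmp, "ph")
  write_plink_fixture(ds, prefix)

  # all 1/2 (with -9 missing) -> binary
  b <- read_plink_binary(paste0(prefix, ".bed"))
  expect_identical(b$phenotype_type, "binary")
  expect_equal(b$phenotype, c(1, 0, 1, NA))

  # a non-integer value makes the trait quantitative
  fam <- read.table(paste0(prefix, ".fam"))
  fam$V6 <- c(3.7, 1.2, -0.5, -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  q <- read_plink_binary(paste0(prefix, ".bed"))
  expect_identical(q$phenotype_type, "quantitative")
  expect_equal(q$phenotype, c(3.7, 1.2, -0.5, NA))
})

test_that("unsorted bp positions within a chromosome are rejected", {
  g <- matrix(rbinom(8, 2, 0.3), ncol = 2)
  expect_error(make_dataset(g, rep(0:1, 2), bp = c(2000L, 1000L)),
               "non-decreasing")
})

test_that("covariate files parse, match by ID and flag absent individuals", {
  set.seed(4)
  n <- 6
  ds <- make_dataset(random_geno(n, 2), rbinom(n, 1, 0.5))
  tmp <- withr::local_tempdir()
  cpath <- file.path(tmp, "covar.txt")

  # full table with header
  writeLines(c("FID IID PC1 PC2 PC3",
               paste(ds$fam$fid, ds$fam$iid, round(rnorm(n), 3),
                     round(rnorm(n), 3), round(rnorm(n), 3))), cpath)
  ct <- read_covariates(cpath, ds)
  expect_equal(dim(ct$values), c(n, 3))
  expect_false(any(ct$excluded))
  expect_equal(ct$names, c("PC1", "PC2", "PC3"))

  # one individual absent -> flagged excluded
  lines <- readLines(cpath)
  writeLines(lines[-3], cpath)
  ct2 <- read_covariates(cpath, ds)
  expect_equal(sum(ct2$excluded), 1)
  expect_true(all(is.na(ct2$values[ct2$excluded, ])))

  # IDs only -> zero columns, nobody excluded
  writeLines(paste(ds$fam$fid, ds$fam$iid), cpath)
  ct3 <- read_covariates(cpath, ds)
  expect_equal(ncol(ct3$values), 0)
  expect_false(any(ct3$excluded))

  # non-numeric covariate cell -> parse error naming row and column
  writeLines(c(paste(ds$fam$fid, ds$fam$iid, 1.0),
               paste(ds$fam$fid[1], "zzz", "abc")), cpath)
  expect_error(read_covariates(cpath, ds), "non-numeric")
})

test_that("results files have a header, one row per anchor and NA markers", {
  res <- data.frame(chrom = "1", anchor_id = c("rs1", "rs2"),
                    anchor_bp = c(100L, 200L),
                    partner_id = c("rs2", NA), partner_bp = c(200L, NA),
                    r2 = c(0.31, NA), score = c(99.2, 0),
                    ai_stat = c(5.1, NA), ai_p = c(0.0239, NA),
                    single_stat = c(3.3, NA), single_p = c(0.069, NA),
                    status = c("ok", "no_partner"), n_used = c(100L, 100L),
                    stringsAsFactors = FALSE)
  path <- file.path(withr::local_tempdir(), "out.tsv")
  write_results(res, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  expect_match(lines[1], "^chrom\tanchor_id")
  expect_match(lines[3], "\tNA\t")
  back <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$ai_p, c(0.0239, NA))
})
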