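# PLINK 1 binary I/O and the in-memory genotype container.
#
# Genotypes are stored as an n_individuals x n_snps integer matrix of minor
# allele dosages (0/1/2, NA = missing). allele1 in the SNP map is the counted
# (minor) allele after orientation; allele2 is the other allele.

#' Construct a genotype dataset
#'
#' Low-level constructor for the container used by the scan. Most users will
#' obtain one from [read_plink_binary()] or [generate_panel()].
#'
#' @param genotypes integer matrix, individuals x SNPs, entries in
#'   `{0, 1, 2, NA}` counting minor alleles.
#' @param snps data frame with columns `chrom`, `snp_id`, `cm`, `bp`,
#'   `allele1`, `allele2`; rows must be in non-decreasing `bp` order within
#'   each chromosome.
#' @param phenotype numeric vector, one value per individual. For a binary
#'   trait use 0 = control, 1 = case, NA = missing.
#' @param phenotype_type `"binary"` or `"quantitative"`.
#' @param fam optional data frame of family metadata (columns `fid`, `iid`,
#'   `pid`, `mid`, `sex`, `pheno`); generated when omitted.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, snps, phenotype,
                             phenotype_type = c("binary", "quantitative"),
                             fam = NULL) {
  phenotype_type <- match.arg(phenotype_type)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(is.data.frame(snps),
            all(c("chrom", "snp_id", "bp", "allele1", "allele2") %in%
                  names(snps)))
  if (!"cm" %in% names(snps)) snps$cm <- 0
  snps$chrom <- as.character(snps$chrom)
  snps$snp_id <- as.character(snps$snp_id)
  if (any(!is.na(genotypes) & (genotypes < 0L | genotypes > 2L)))
    stop("genotype entries must be in {0, 1, 2, NA}")
  if (nrow(snps) != ncol(genotypes))
    stop("snps rows must match genotype columns")
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length must match number of individuals")
  if (any(snps$bp < 0) || any(!nzchar(snps$snp_id)))
    stop("SNP records need non-negative bp and non-empty ids")
  for (ch in unique(snps$chrom)) {
    bp <- snps$bp[snps$chrom == ch]
    if (is.unsorted(bp))
      stop("SNPs on chromosome ", ch, " are not in non-decreasing bp order")
  }
  if (is.null(fam)) {
    ids <- rownames(genotypes)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(genotypes)))
    fam <- data.frame(fid = ids, iid = ids, pid = "0", mid = "0",
                      sex = 0L, pheno = NA_real_,
                      stringsAsFactors = FALSE)
  }
  rownames(genotypes) <- fam$iid
  colnames(genotypes) <- snps$snp_id
  structure(list(genotypes = genotypes, snps = snps,
                 phenotype = as.numeric(phenotype),
                 phenotype_type = phenotype_type, fam = fam),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "SNPs\n")
  cat("  phenotype:", x$phenotype_type, "(",
      sum(!is.na(x$phenotype)), "non-missing )\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

# 4 x 256 lookup: PLINK 1 two-bit codes, low bits first within each byte.
# 00 = homozygous allele1 (dosage 2), 01 = missing, 10 = het, 11 = hom allele2.
.bed_decode_lut <- local({
  lut <- matrix(NA_integer_, nrow = 4, ncol = 256)
  for (b in 0:255) {
    v <- b
    for (s in 1:4) {
      code <- v %% 4L
      lut[s, b + 1L] <- switch(code + 1L, 2L, NA_integer_, 1L, 0L)
      v <- v %/% 4L
    }
  }
  lut
})

.bed_encode_codes <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # dosage -> 2-bit code

#' Read a PLINK 1 binary fileset
#'
#' Decodes SNP-major PLINK 1 `.bed`/`.bim`/`.fam` files into a
#' [genotype_dataset]. Dosages are re-oriented so that they count the
#' dataset-wide minor allele of each SNP (ties at frequency 0.5 keep the file
#' allele order); minor-allele determination uses all individuals regardless
#' of phenotype. A `.fam` phenotype column coded 1/2 (with 0/-9 missing) is
#' read as control/case; any other numeric column is read as a quantitative
#' trait with -9 treated as missing.
#'
#' @param bed_path,bim_path,fam_path paths to the three files. `bim_path` and
#'   `fam_path` default to the `.bed` path with swapped extensions.
#' @return A [genotype_dataset].
#' @export
read_plink_binary <- function(bed_path,
                              bim_path = sub("\\.bed$", ".bim", bed_path),
                              fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)

  bim <- read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "bp",
                                  "allele1", "allele2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK 1 .bed file (bad magic bytes)")
  if (raw[3] == as.raw(0x00))
    stop("individual-major .bed files are not supported")
  if (raw[3] != as.raw(0x01))
    stop("unrecognized .bed mode byte")
  bps <- ceiling(n / 4)
  if (length(raw) - 3L != m * bps)
    stop(".bed size inconsistent with .bim/.fam (expected ", m * bps,
         " data bytes, found ", length(raw) - 3L, "): truncated or mismatched")

  codes <- .bed_decode_lut[, as.integer(raw[-(1:3)]) + 1L]
  geno <- matrix(codes, nrow = 4L * bps, ncol = m)[seq_len(n), , drop = FALSE]

  # orient to the dataset-wide minor allele
  a1 <- bim$allele1
  a2 <- bim$allele2
  freq <- colMeans(geno, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    geno[, flip] <- 2L - geno[, flip]
    tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
  }
  bim$allele1 <- a1
  bim$allele2 <- a2

  ph <- suppressWarnings(as.numeric(fam$pheno))
  missing_codes <- !is.na(ph) & (ph == 0 | ph == -9)
  nonmiss <- ph[!is.na(ph) & !missing_codes]
  if (length(nonmiss) > 0 && all(nonmiss %in% c(1, 2))) {
    phenotype <- ifelse(is.na(ph) | missing_codes, NA_real_, ph - 1)
    ptype <- "binary"
  } else {
    phenotype <- ifelse(is.na(ph) | (!is.na(ph) & ph == -9), NA_real_, ph)
    ptype <- "quantitative"
  }

  genotype_dataset(geno, bim, phenotype, ptype, fam = fam)
}

#' Write a genotype dataset as a PLINK 1 binary fileset
#'
#' Emits SNP-major `.bed` (magic `0x6c 0x1b 0x01`), `.bim` and `.fam` files
#' that round-trip through [read_plink_binary()]. Missing genotypes are
#' encoded with the `01` two-bit code per the PLINK 1 format.
#'
#' @param dataset a [genotype_dataset].
#' @param prefix output path prefix; `<prefix>.bed` etc. are written.
#' @return Invisibly, the three file paths.
#' @export
write_plink_fixture <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  geno <- dataset$genotypes
  n <- nrow(geno)
  m <- ncol(geno)
  bps <- ceiling(n / 4)

  code <- matrix(1L, nrow = 4L * bps, ncol = m)  # 01 = missing padding
  gcode <- ifelse(is.na(geno), 1L, .bed_encode_codes[as.character(geno)])
  code[seq_len(n), ] <- gcode
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- integer(bps * m)
  dim(code) <- c(4L, bps * m)
  for (s in 1:4) bytes <- bytes + code[s, ] * shift[s]

  bed_path <- paste0(prefix, ".bed")
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)

  bim <- dataset$snps[, c("chrom", "snp_id", "cm", "bp", "allele1", "allele2")]
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- dataset$fam
  if (dataset$phenotype_type == "binary") {
    fam$pheno <- ifelse(is.na(dataset$phenotype), -9, dataset$phenotype + 1)
  } else {
    fam$pheno <- ifelse(is.na(dataset$phenotype), -9, dataset$phenotype)
  }
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a covariate table in PLINK --covar layout
#'
#' Whitespace-delimited text with family and individual ID columns followed
#' by numeric covariate columns (an optional `FID IID ...` header line is
#' detected). Rows are matched to dataset individuals by FID+IID; individuals
#' absent from the file are flagged for exclusion from regression.
#'
#' @param path covariate file path.
#' @param dataset the [genotype_dataset] the covariates accompany.
#' @return An object of class `covariate_table`: a list with `values`
#'   (individuals x covariates numeric matrix, rows aligned to the dataset,
#'   NA rows for absent individuals), `names`, `individual_ids` and
#'   `excluded` (logical, TRUE where the individual was absent).
#' @export
read_covariates <- function(path, dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty covariate file: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  ncol_file <- length(fields[[1]])
  if (ncol_file < 2) stop("covariate file needs FID and IID columns")
  has_header <- toupper(fields[[1]][1]) %in% c("FID", "#FID") &&
    toupper(fields[[1]][2]) == "IID"
  cov_names <- if (has_header && ncol_file > 2) {
    fields[[1]][-(1:2)]
  } else if (ncol_file > 2) {
    paste0("COV", seq_len(ncol_file - 2))
  } else character(0)
  rows <- if (has_header) fields[-1] else fields
  if (any(lengths(rows) != ncol_file))
    stop("ragged covariate file: rows have differing field counts")

  file_key <- vapply(rows, function(f) paste(f[1], f[2], sep = "\r"), "")
  nc <- ncol_file - 2L
  vals <- matrix(NA_real_, nrow = length(rows), ncol = nc)
  for (j in seq_len(nc)) {
    raw <- vapply(rows, function(f) f[j + 2L], "")
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(raw %in% c("NA", "na")))
    if (length(bad) > 0)
      stop("non-numeric covariate value '", raw[bad[1]], "' at row ",
           bad[1] + has_header, ", column ", j + 2L)
    vals[, j] <- num
  }

  key <- paste(dataset$fam$fid, dataset$fam$iid, sep = "\r")
  idx <- match(key, file_key)
  out <- matrix(NA_real_, nrow = nrow(dataset$genotypes), ncol = nc,
                dimnames = list(dataset$fam$iid, cov_names))
  out[!is.na(idx), ] <- vals[idx[!is.na(idx)], , drop = FALSE]
  structure(list(values = out, names = cov_names,
                 individual_ids = dataset$fam$iid,
                 excluded = is.na(idx)),
            class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("covariate_table:", length(x$individual_ids), "individuals x",
      length(x$names), "covariates;", sum(x$excluded), "excluded\n")
  invisible(x)
}

#' Write scan results to a tab-separated file
#'
#' One row per anchor SNP with header; missing values are written as `NA`.
#'
#' @param results a results data frame from [run_scan()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
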