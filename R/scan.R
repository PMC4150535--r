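# Genome-wide driver: iterate anchors, select partners, run the AI and
# companion single-SNP tests, and collect results. SNPs failing QC are
# excluded both as anchors and as partner candidates, so a bad SNP cannot
# silently drive its neighbours' tests.

#' Scan configuration
#'
#' @param window_size candidate window size in SNPs (default 10).
#' @param window_bp candidate window half-width in base pairs; mutually
#'   exclusive with `window_size`.
#' @param metric metric curve variant used to score candidate partners.
#' @param min_maf minimum minor allele frequency for a SNP to be tested or
#'   used as a candidate (default 0, no filtering).
#' @param max_missing maximum per-SNP missing genotype rate (default 1).
#' @param force_type `NULL` to use the dataset's phenotype type, or
#'   `"binary"` / `"quantitative"` to override.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_size = 10, window_bp = NULL,
                        metric = c("multiplicative", "dominant", "recessive"),
                        min_maf = 0, max_missing = 1, force_type = NULL) {
  metric <- match.arg(metric)
  stopifnot(min_maf >= 0, min_maf <= 1, max_missing >= 0, max_missing <= 1)
  if (!is.null(window_bp)) window_size <- NULL
  if (!is.null(force_type))
    force_type <- match.arg(force_type, c("binary", "quantitative"))
  structure(list(window_size = window_size, window_bp = window_bp,
                 metric = metric, min_maf = min_maf,
                 max_missing = max_missing, force_type = force_type),
            class = "scan_config")
}

#' Run the AI scan over all anchor SNPs
#'
#' For every SNP passing quality-control filters, selects a partner SNP from
#' the local window with [select_partner()] and runs the AI conditional test
#' together with the companion single-SNP test. Each result row equals the
#' composition of [candidate_window()], [select_partner()] and
#' [ai_test_binary()] / [ai_test_quantitative()] on that anchor; the scan is
#' deterministic given its inputs.
#'
#' @param dataset a [genotype_dataset].
#' @param covariates optional `covariate_table` (or numeric matrix).
#' @param config a [scan_config()].
#' @param curve metric curve; defaults to the bundled curve named by
#'   `config$metric`.
#' @return A data frame with one row per QC-passing anchor SNP: chromosome,
#'   anchor/partner ids and positions, anchor-partner `r2` and `score`, the
#'   AI statistic and p-value, the single-SNP statistic and p-value, a
#'   status flag, and the number of individuals used.
#' @export
run_scan <- function(dataset, covariates = NULL, config = scan_config(),
                     curve = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "scan_config"))
  if (is.null(curve)) curve <- default_metric_curve(config$metric)
  geno <- dataset$genotypes
  snps <- dataset$snps
  ptype <- config$force_type %||% dataset$phenotype_type
  y <- dataset$phenotype

  miss <- colMeans(is.na(geno))
  maf <- colMeans(geno, na.rm = TRUE) / 2
  maf[is.nan(maf)] <- 0
  keep <- which(miss <= config$max_missing & maf >= config$min_maf)
  if (length(keep) == 0) {
    warning("no SNPs pass the QC filters; empty result")
    return(.empty_scan_result())
  }
  ksnps <- snps[keep, , drop = FALSE]

  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    j <- keep[i]
    cand_k <- candidate_window(i, ksnps, window_size = config$window_size,
                               window_bp = config$window_bp)
    choice <- select_partner(j, keep[cand_k], geno, curve)
    pj <- choice$partner_index

    if (is.na(pj)) {
      sing <- single_snp_test(geno[, j], y, covariates,
                              type = if (ptype == "binary") "binary"
                                     else "quantitative")
      res <- .ai_result(snps$snp_id[j], NA_character_, NA_real_, 1L,
                        NA_real_,
                        if (ptype == "binary") "logistic_LRT" else "linear_F",
                        sing$statistic, sing$p_value, "no_partner",
                        sing$n_used)
    } else if (ptype == "binary") {
      res <- ai_test_binary(geno[, j], geno[, pj], y, covariates,
                            anchor_id = snps$snp_id[j],
                            partner_id = snps$snp_id[pj])
    } else {
      res <- ai_test_quantitative(geno[, j], geno[, pj], y, covariates,
                                  anchor_id = snps$snp_id[j],
                                  partner_id = snps$snp_id[pj])
    }

    rows[[i]] <- data.frame(
      chrom = snps$chrom[j], anchor_id = snps$snp_id[j], anchor_bp = snps$bp[j],
      partner_id = if (is.na(pj)) NA_character_ else snps$snp_id[pj],
      partner_bp = if (is.na(pj)) NA_integer_ else snps$bp[pj],
      r2 = choice$r2, score = choice$score,
      ai_stat = res$statistic, ai_p = res$p_value,
      single_stat = res$single_snp_statistic, single_p = res$single_snp_p,
      status = res$status, n_used = res$n_used,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("snipscan_results", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_scan_result <- function() {
  out <- data.frame(chrom = character(0), anchor_id = character(0),
                    anchor_bp = integer(0), partner_id = character(0),
                    partner_bp = integer(0), r2 = numeric(0),
                    score = numeric(0), ai_stat = numeric(0),
                    ai_p = numeric(0), single_stat = numeric(0),
                    single_p = numeric(0), status = character(0),
                    n_used = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("snipscan_results", "data.frame")
  out
}

#' Detection power / type-I error of the AI and single-SNP tests
#'
#' Replicated evaluation harness: each replicate generates a panel from the
#' scenario, scans it, and records — for the AI test and for single-SNP
#' testing separately — whether any SNP within `detection_window_bp` of the
#' causal position passes each p-value threshold. Under a null scenario
#' (unit relative risks) the detection proportion is the type-I proportion,
#' to be compared with the Bonferroni reference `a * threshold` where `a` is
#' the number of tested anchors in the window.
#'
#' @param scenario a [multi_snp_scenario()] (its causal position defines the
#'   detection window even when the causal SNP is untyped).
#' @param thresholds numeric vector of nominal p-value thresholds.
#' @param detection_window_bp half-width of the detection window around the
#'   causal position (default 110,000 bp).
#' @param n_replicates number of replicates.
#' @param config a [scan_config()] used for each scan.
#' @param curve metric curve (defaults to the bundled multiplicative curve).
#' @return A data frame with one row per method x threshold: `method`
#'   (`"ai"` or `"single_snp"`), `threshold`, `n_detected`, `n_replicates`,
#'   `power` (the detection proportion) and `n_anchors_window` (`a`).
#' @export
evaluate_power <- function(scenario, thresholds = c(1e-4, 1e-3),
                           detection_window_bp = 110000,
                           n_replicates = 100,
                           config = scan_config(), curve = NULL) {
  stopifnot(inherits(scenario, "multi_snp_scenario"))
  if (is.null(curve)) curve <- default_metric_curve(config$metric)
  hits_ai <- matrix(FALSE, n_replicates, length(thresholds))
  hits_ss <- matrix(FALSE, n_replicates, length(thresholds))
  n_anchors <- NA_integer_

  causal_bp <- scenario$positions[scenario$causal_index]
  for (r in seq_len(n_replicates)) {
    panel <- generate_panel(scenario)
    res <- run_scan(panel, config = config, curve = curve)
    inwin <- abs(res$anchor_bp - causal_bp) <= detection_window_bp
    if (is.na(n_anchors)) n_anchors <- sum(inwin)
    for (t in seq_along(thresholds)) {
      hits_ai[r, t] <- any(inwin & !is.na(res$ai_p) &
                             res$ai_p < thresholds[t])
      hits_ss[r, t] <- any(inwin & !is.na(res$single_p) &
                             res$single_p < thresholds[t])
    }
  }
  data.frame(
    method = rep(c("ai", "single_snp"), each = length(thresholds)),
    threshold = rep(thresholds, 2),
    n_detected = c(colSums(hits_ai), colSums(hits_ss)),
    n_replicates = n_replicates,
    power = c(colMeans(hits_ai), colMeans(hits_ss)),
    n_anchors_window = n_anchors,
    stringsAsFactors = FALSE)
}
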