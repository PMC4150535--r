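# Synthetic-data generators: multi-SNP haplotype-pool scenarios with a
# designated (typed or untyped) causal SNP, plus the printed expected
# haplotype counts from the malaria case/control worked example.

#' Define a multi-SNP simulation scenario
#'
#' A haplotype pool over `m` SNPs with frequencies, one SNP designated as
#' causal (optionally untyped, i.e. dropped from the emitted panel), genotype
#' relative risks, and case/control sample sizes. The disease model is
#' penetrance `f0 * rr[g]` for `g` copies of the causal allele, with baseline
#' `f0` chosen so that the population prevalence matches `prevalence`.
#'
#' @param haplotypes matrix (`n_hap x m`) of 0/1 alleles; allele 1 at the
#'   causal SNP is the risk allele.
#' @param hap_freqs haplotype frequencies summing to 1.
#' @param positions base-pair positions (non-decreasing), length `m`.
#' @param causal_index column index of the causal SNP.
#' @param causal_typed keep the causal SNP in the emitted panel?
#' @param relative_risks genotype relative risks `(g = 1, g = 2)` vs 0
#'   copies, e.g. `c(1.5, 2.25)`; use `c(1, 1)` for a null scenario.
#' @param prevalence population disease prevalence (default 0.01).
#' @param n_cases,n_controls sample sizes.
#' @param chrom chromosome label for the emitted SNP map.
#' @param snp_ids optional SNP ids (defaults to `snp1..snpm`).
#' @return A list of class `multi_snp_scenario`.
#' @export
multi_snp_scenario <- function(haplotypes, hap_freqs, positions,
                               causal_index, causal_typed = FALSE,
                               relative_risks = c(1.5, 2.25),
                               prevalence = 0.01,
                               n_cases = 1000, n_controls = 1000,
                               chrom = "1", snp_ids = NULL) {
  haplotypes <- as.matrix(haplotypes)
  m <- ncol(haplotypes)
  stopifnot(all(haplotypes %in% c(0, 1)),
            length(hap_freqs) == nrow(haplotypes),
            length(positions) == m,
            causal_index >= 1, causal_index <= m,
            length(relative_risks) == 2, all(relative_risks >= 0),
            prevalence > 0, prevalence < 1)
  if (any(hap_freqs < 0) || abs(sum(hap_freqs) - 1) > 1e-9)
    stop("haplotype frequencies must be non-negative and sum to 1")
  if (is.unsorted(positions))
    stop("positions must be non-decreasing")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  structure(list(haplotypes = haplotypes, hap_freqs = as.numeric(hap_freqs),
                 positions = as.integer(positions),
                 causal_index = as.integer(causal_index),
                 causal_typed = causal_typed,
                 relative_risks = relative_risks, prevalence = prevalence,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 chrom = chrom, snp_ids = snp_ids),
            class = "multi_snp_scenario")
}

#' Generate a case/control genotype panel from a scenario
#'
#' Diploid individuals are pairs of independent haplotype draws; disease is
#' assigned with penetrance `f0 * rr(g)` for `g` causal alleles, `f0` solved
#' from the scenario prevalence. Sampling is from the exact conditional
#' haplotype-pair distributions given affection status, so exactly `n_cases`
#' cases and `n_controls` controls are produced. The causal column is dropped
#' from the emitted panel when the scenario flags it untyped.
#'
#' @param scenario a [multi_snp_scenario()].
#' @return A [genotype_dataset] with a binary phenotype.
#' @export
generate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "multi_snp_scenario"))
  H <- scenario$haplotypes
  fr <- scenario$hap_freqs
  nh <- nrow(H)
  rr <- c(1, scenario$relative_risks)

  # causal dosage per ordered haplotype pair and its probability
  i <- rep(seq_len(nh), times = nh)
  j <- rep(seq_len(nh), each = nh)
  pr <- fr[i] * fr[j]
  gd <- H[i, scenario$causal_index] + H[j, scenario$causal_index]

  f0 <- scenario$prevalence / sum(pr * rr[gd + 1])
  pen <- f0 * rr[gd + 1]
  if (any(pen > 1))
    stop("unattainable prevalence: implied penetrance exceeds 1")
  pcase <- sum(pr * pen)
  if (pcase <= 0 || pcase >= 1)
    stop("degenerate scenario: disease probability is ", signif(pcase, 4))

  pc <- pr * pen / pcase
  pt <- pr * (1 - pen) / (1 - pcase)
  ncse <- as.vector(rmultinom(1, scenario$n_cases, pc))
  nctl <- as.vector(rmultinom(1, scenario$n_controls, pt))

  expand <- function(counts) {
    idx <- rep.int(seq_along(counts), counts)
    H[i[idx], , drop = FALSE] + H[j[idx], , drop = FALSE]
  }
  geno <- rbind(expand(ncse), expand(nctl))
  phen <- rep(c(1, 0), c(scenario$n_cases, scenario$n_controls))

  keep <- if (scenario$causal_typed) seq_len(ncol(H)) else
    setdiff(seq_len(ncol(H)), scenario$causal_index)
  geno <- geno[, keep, drop = FALSE]

  # orient dosages to count the dataset-wide minor allele
  freq <- colMeans(geno) / 2
  flip <- freq > 0.5
  geno[, flip] <- 2 - geno[, flip]
  a1 <- ifelse(flip, "A", "B")
  a2 <- ifelse(flip, "B", "A")

  snps <- data.frame(chrom = scenario$chrom,
                     snp_id = scenario$snp_ids[keep], cm = 0,
                     bp = scenario$positions[keep],
                     allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  genotype_dataset(geno, snps, phen, "binary")
}

#' Expected haplotype counts from the malaria worked example
#'
#' The published expected haplotype counts (estimated separately within
#' cases and controls) for the eight haplotypes over the causal SNP (rs334),
#' the selected partner SNP and the selected anchor SNP in the Gambian
#' severe-malaria case/control study. Allele indicator columns are included
#' for use with [haplotype_r2_from_counts()]; the `causal` indicator marks
#' the protective A allele at rs334 and the `partner`/`anchor` indicators
#' mark the C alleles.
#'
#' @return A data frame with columns `haplotype`, `case_freq`,
#'   `control_freq`, `case_count`, `control_count`, `causal`, `partner`,
#'   `anchor`.
#' @export
table1_fixture <- function() {
  data.frame(
    haplotype = c("A-C-C", "A-C-T", "A-T-C", "A-T-T",
                  "T-C-C", "T-C-T", "T-T-C", "T-T-T"),
    case_freq = c(0.005611, 0.001889, 0, 0, 0.026310, 0.922400,
                  0.043080, 0.000671),
    control_freq = c(0.053530, 0.021680, 0, 0, 0.026960, 0.853100,
                     0.044720, 0),
    case_count = c(8.978, 3.022, 0, 0, 42.100, 1476.000, 68.930, 1.074),
    control_count = c(131.700, 53.330, 0, 0, 66.330, 2099.000, 110.000, 0),
    causal = c(1, 1, 1, 1, 0, 0, 0, 0),
    partner = c(1, 1, 0, 0, 1, 1, 0, 0),
    anchor = c(1, 0, 1, 0, 1, 0, 1, 0),
    stringsAsFactors = FALSE)
}

#' Bundled demonstration scenarios
#'
#' Three ready-made [multi_snp_scenario()] objects used throughout the tests
#' and documentation. All use genotype relative risks 1.5/2.25 (except the
#' null panel), 1,000 cases and 1,000 controls, and prevalence 0.01.
#'
#' * `"weak_tagging"`: an untyped causal SNP whose protective-style coupling
#'   mirrors the malaria worked example — the anchor SNP tags the causal SNP
#'   only weakly (haplotype r2 about 0.26), the partner SNP barely at all,
#'   but the anchor-partner correlation (about 0.33) sits near the metric
#'   optimum and the additive anchor+partner combination tags the causal SNP
#'   much better (r2 about 0.44). The AI test is expected to beat single-SNP
#'   testing here.
#' * `"strong_tagging"`: the anchor tags the untyped causal SNP at r2 about
#'   0.9 with an independent partner; AI and single-SNP power should be
#'   indistinguishable.
#' * `"null_panel"`: six typed SNPs in strong LD, unit relative risks; used
#'   for type-I error evaluation.
#'
#' @param name scenario name.
#' @param n_cases,n_controls sample sizes (default 1,000 each).
#' @return A `multi_snp_scenario`.
#' @export
demo_scenario <- function(name = c("weak_tagging", "strong_tagging",
                                   "null_panel"),
                          n_cases = 1000, n_controls = 1000) {
  name <- match.arg(name)
  if (name == "weak_tagging") {
    # columns: causal, partner, anchor (allele 1 = risk / minor allele)
    H <- rbind(c(1, 0, 1),
               c(1, 0, 0),
               c(0, 0, 1),
               c(0, 0, 0),
               c(0, 1, 1))
    fr <- c(0.0535, 0.0217, 0.0270, 0.8531, 0.0447)
    multi_snp_scenario(H, fr, positions = c(5200000, 5230000, 5245000),
                       causal_index = 1, causal_typed = FALSE,
                       relative_risks = c(1.5, 2.25),
                       n_cases = n_cases, n_controls = n_controls,
                       snp_ids = c("causal", "partner", "anchor"))
  } else if (name == "strong_tagging") {
    # causal and anchor near-duplicated (r2 ~ 0.9); partner independent
    da <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
    dafr <- c(0.0954, 0.0046, 0.0046, 0.8954)
    H <- cbind(da[rep(1:4, each = 2), 1],
               rep(c(1, 0), times = 4),
               da[rep(1:4, each = 2), 2])
    fr <- rep(dafr, each = 2) * rep(c(0.3, 0.7), times = 4)
    multi_snp_scenario(H, fr, positions = c(5200000, 5230000, 5245000),
                       causal_index = 1, causal_typed = FALSE,
                       relative_risks = c(1.5, 2.25),
                       n_cases = n_cases, n_controls = n_controls,
                       snp_ids = c("causal", "partner", "anchor"))
  } else {
    # six SNPs carried by four haplotypes: strong LD, no disease effect
    H <- rbind(c(0, 0, 0, 0, 0, 0),
               c(1, 1, 0, 0, 1, 0),
               c(0, 1, 1, 1, 0, 0),
               c(1, 0, 1, 0, 1, 1))
    fr <- c(0.4, 0.3, 0.2, 0.1)
    multi_snp_scenario(H, fr,
                       positions = 5200000 + (0:5) * 18000,
                       causal_index = 3, causal_typed = TRUE,
                       relative_risks = c(1, 1),
                       n_cases = n_cases, n_controls = n_controls)
  }
}

#' Write a scenario definition to a JSON file
#'
#' @param scenario a [multi_snp_scenario()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "multi_snp_scenario"))
  obj <- unclass(scenario)
  obj$haplotypes <- apply(scenario$haplotypes, 1, paste0, collapse = "")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scenario definition from a JSON file
#'
#' @param path path written by [write_scenario()].
#' @return A `multi_snp_scenario`.
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- do.call(rbind, lapply(strsplit(obj$haplotypes, ""), as.integer))
  multi_snp_scenario(H, obj$hap_freqs, obj$positions, obj$causal_index,
                     obj$causal_typed, obj$relative_risks, obj$prevalence,
                     obj$n_cases, obj$n_controls, obj$chrom, obj$snp_ids)
}
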