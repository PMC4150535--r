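# Candidate-window definition around an anchor SNP and score-based choice of
# its partner. Selection uses genotypes only (all individuals, regardless of
# phenotype), which keeps it statistically independent of the AI test.

#' Candidate partner window around an anchor SNP
#'
#' In SNP-count mode a window of total size `w` takes `floor(w/2)` SNPs to
#' the left and `ceiling(w/2)` to the right of the anchor; near a chromosome
#' end the window extends to the opposite side so that the total is
#' `min(w, available same-chromosome SNPs)`. In base-pair mode all
#' same-chromosome SNPs within `window_bp` of the anchor position are taken
#' (boundary inclusive). Candidates never cross chromosome boundaries and the
#' anchor itself is excluded.
#'
#' @param anchor_index column index of the anchor SNP.
#' @param snps SNP map data frame (`chrom`, `bp`, ... as in a
#'   [genotype_dataset]), sorted by position within chromosome.
#' @param window_size total number of candidate SNPs (default 10); ignored
#'   when `window_bp` is given.
#' @param window_bp base-pair half-width of the window; mutually exclusive
#'   with `window_size`.
#' @return Integer vector of candidate indices in chromosome order (possibly
#'   empty).
#' @export
candidate_window <- function(anchor_index, snps, window_size = 10,
                             window_bp = NULL) {
  chrom <- snps$chrom[anchor_index]
  chrom_idx <- which(snps$chrom == chrom)
  if (!is.null(window_bp)) {
    stopifnot(window_bp >= 1)
    keep <- chrom_idx[abs(snps$bp[chrom_idx] - snps$bp[anchor_index]) <=
                        window_bp]
    return(setdiff(keep, anchor_index))
  }
  stopifnot(window_size >= 1)
  k <- match(anchor_index, chrom_idx)
  n <- length(chrom_idx)
  total <- min(window_size, n - 1)
  if (total <= 0) return(integer(0))
  nl <- min(floor(window_size / 2), k - 1)
  nr <- min(ceiling(window_size / 2), n - k)
  # extend toward the side with spare SNPs near a chromosome end
  short <- total - (nl + nr)
  if (short > 0) {
    nl <- min(nl + max(0, short - (n - k - nr)), k - 1)
    nr <- min(total - nl, n - k)
  }
  left <- if (nl > 0) seq.int(k - nl, k - 1) else integer(0)
  right <- if (nr > 0) seq.int(k + 1, k + nr) else integer(0)
  chrom_idx[c(left, right)]
}

#' Select the partner SNP for an anchor
#'
#' Computes the anchor-candidate squared correlation on all individuals
#' (regardless of phenotype, pairwise-complete), maps each to a score with
#' the metric curve, and picks the highest-scoring candidate; ties are broken
#' in favour of the candidate appearing first in the window. Monomorphic
#' candidates (undefined r2) score 0 and can never win against a candidate
#' with a defined correlation; if every candidate is undefined (or there are
#' none) no partner is chosen.
#'
#' @param anchor_index column index of the anchor SNP.
#' @param candidates candidate indices from [candidate_window()].
#' @param genotypes dosage matrix (individuals x SNPs).
#' @param curve a `metric_curve` used to score correlations.
#' @return An object of class `partner_choice`: a list with `anchor_index`,
#'   `partner_index` (`NA` if none), `r2`, `score` and `n_candidates`.
#' @export
select_partner <- function(anchor_index, candidates, genotypes, curve) {
  anchor <- genotypes[, anchor_index]
  if (length(candidates) == 0) {
    return(structure(list(anchor_index = anchor_index,
                          partner_index = NA_integer_, r2 = NA_real_,
                          score = 0, n_candidates = 0L),
                     class = "partner_choice"))
  }
  r2 <- vapply(candidates,
               function(j) genotype_r2(anchor, genotypes[, j]), numeric(1))
  if (all(is.na(r2))) {
    return(structure(list(anchor_index = anchor_index,
                          partner_index = NA_integer_, r2 = NA_real_,
                          score = 0, n_candidates = length(candidates)),
                     class = "partner_choice"))
  }
  sc <- score(curve, r2)
  sc[is.na(r2)] <- -Inf  # undefined r2 never beats a defined one
  best <- which.max(sc)  # first maximum wins ties (window order)
  structure(list(anchor_index = anchor_index,
                 partner_index = candidates[best], r2 = r2[best],
                 score = max(sc[best], 0), n_candidates = length(candidates)),
            class = "partner_choice")
}

#' @export
print.partner_choice <- function(x, ...) {
  if (is.na(x$partner_index)) {
    cat("partner_choice: anchor", x$anchor_index, "-> no partner (",
        x$n_candidates, "candidates )\n")
  } else {
    cat("partner_choice: anchor", x$anchor_index, "-> partner",
        x$partner_index, " r2 =", format(x$r2, digits = 4),
        " score =", format(x$score, digits = 4), "\n")
  }
  invisible(x)
}
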