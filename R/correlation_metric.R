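# Anchor-partner correlation, the simulation-derived correlation-to-score
# metric, and the three-SNP haplotype disease model that drives it.

#' Squared Pearson correlation of two dosage vectors
#'
#' Computed over pairwise-complete observations on the unphased genotype
#' dosages (no phasing required). Returns `NA` (undefined) when fewer than two
#' complete pairs remain or either vector is constant on the complete pairs.
#'
#' @param g1,g2 numeric dosage vectors of equal length (0/1/2, NA missing).
#' @return Squared Pearson correlation in `[0, 1]`, or `NA_real_`.
#' @export
genotype_r2 <- function(g1, g2) {
  if (length(g1) != length(g2))
    stop("dosage vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  vx <- sum((x - mean(x))^2)
  vy <- sum((y - mean(y))^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cxy <- sum((x - mean(x)) * (y - mean(y)))
  (cxy * cxy) / (vx * vy)
}

#' Squared correlation between haplotype-coded variables
#'
#' Squared Pearson correlation between two variables defined on haplotypes,
#' under the discrete distribution given by non-negative haplotype weights
#' (e.g. expected haplotype counts). Used for haplotype-based r2 such as the
#' causal-SNP tagging correlations in the malaria worked example.
#'
#' @param counts non-negative haplotype weights (need not sum to 1).
#' @param x,y numeric values of the two variables on each haplotype (e.g.
#'   allele indicators, or a sum of indicators for a combination variable).
#' @return Squared Pearson correlation, or `NA_real_` if either variable has
#'   zero variance under the weights.
#' @export
haplotype_r2_from_counts <- function(counts, x, y) {
  stopifnot(length(counts) == length(x), length(counts) == length(y))
  if (any(counts < 0)) stop("haplotype counts must be non-negative")
  W <- sum(counts)
  if (W <= 0) stop("haplotype counts must not be all zero")
  w <- counts / W
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * x^2) - mx^2
  vy <- sum(w * y^2) - my^2
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cxy <- sum(w * x * y) - mx * my
  (cxy * cxy) / (vx * vy)
}

#' Sample a random haplotype-frequency partition
#'
#' Draws 8 haplotype frequencies by sequential uniform stick breaking: a
#' haplotype is picked uniformly at random from those still undefined, its
#' frequency is drawn uniformly on `[0, 1 - S]` where `S` is the frequency
#' already assigned, and the last haplotype receives the remainder.
#'
#' @param n number of independent partitions to draw.
#' @param n_haplotypes number of haplotype classes (default 8, i.e. three
#'   biallelic SNPs).
#' @return An `n x n_haplotypes` matrix of frequencies, each row summing to 1.
#' @export
sample_haplotype_partition <- function(n = 1, n_haplotypes = 8) {
  out <- matrix(0, nrow = n, ncol = n_haplotypes)
  for (i in seq_len(n)) {
    remaining <- seq_len(n_haplotypes)
    S <- 0
    while (length(remaining) > 1) {
      j <- remaining[sample.int(length(remaining), 1)]
      u <- runif(1, 0, 1 - S)
      out[i, j] <- u
      S <- S + u
      remaining <- setdiff(remaining, j)
    }
    out[i, remaining] <- 1 - S
  }
  out
}

#' Three-SNP haplotype disease model
#'
#' Eight haplotype frequencies over (anchor, causal, partner) alleles plus
#' three penetrances (disease probability given 0/1/2 copies of the causal
#' allele). Haplotypes are indexed in binary order `anchor*4 + causal*2 +
#' partner`, allele 1 being the counted allele at each SNP.
#'
#' @param hap_freqs 8 non-negative frequencies summing to 1.
#' @param penetrances numeric length 3, each in `[0, 1]`; monotonicity is not
#'   required.
#' @return An object of class `haplotype_disease_model`.
#' @export
haplotype_disease_model <- function(hap_freqs, penetrances) {
  hap_freqs <- as.numeric(hap_freqs)
  penetrances <- as.numeric(penetrances)
  stopifnot(length(hap_freqs) == 8, length(penetrances) == 3)
  if (any(hap_freqs < 0)) stop("haplotype frequencies must be non-negative")
  if (abs(sum(hap_freqs) - 1) > 1e-12)
    stop("haplotype frequencies must sum to 1")
  if (any(penetrances < 0 | penetrances > 1))
    stop("penetrances must lie in [0, 1]")
  structure(list(hap_freqs = hap_freqs, penetrances = penetrances),
            class = "haplotype_disease_model")
}

# Joint genotype distribution over (anchor, causal, partner) dosages under
# random mating: returns a 27-vector indexed x1*9 + xd*3 + x2 + 1.
.genotype_joint <- function(hap_freqs) {
  i <- rep(0:7, times = 8)
  j <- rep(0:7, each = 8)
  pr <- hap_freqs[i + 1] * hap_freqs[j + 1]
  x1 <- (i %/% 4) + (j %/% 4)
  xd <- ((i %/% 2) %% 2) + ((j %/% 2) %% 2)
  x2 <- (i %% 2) + (j %% 2)
  cell <- numeric(27)
  idx <- x1 * 9 + xd * 3 + x2 + 1
  for (k in seq_along(pr)) cell[idx[k]] <- cell[idx[k]] + pr[k]
  cell
}

#' Simulate a case/control sample from a haplotype disease model
#'
#' Individuals are pairs of haplotypes drawn independently from the model
#' frequencies (random mating); disease is assigned with the penetrance for
#' the individual's causal-allele dosage. Sampling is from the exact
#' conditional genotype distributions given affection status (analytically
#' normalized multinomials), so exactly `n_cases` cases and `n_controls`
#' controls are returned.
#'
#' @param model a [haplotype_disease_model].
#' @param n_cases,n_controls sample sizes.
#' @return A list with `genotypes` (matrix, `n_cases + n_controls` rows,
#'   columns `anchor`, `causal`, `partner` of dosages) and `phenotype`
#'   (1 = case, 0 = control).
#' @export
simulate_case_control <- function(model, n_cases = 1000, n_controls = 1000) {
  stopifnot(inherits(model, "haplotype_disease_model"))
  cell <- .genotype_joint(model$hap_freqs)
  xd <- rep(rep(0:2, each = 3), times = 3)  # causal dosage per 27-cell index
  pen <- model$penetrances[xd + 1]
  pcase <- sum(cell * pen)
  if (pcase <= 1e-12 || pcase >= 1 - 1e-12)
    stop("degenerate model: disease probability is ", signif(pcase, 4))
  pc <- cell * pen / pcase
  pt <- cell * (1 - pen) / (1 - pcase)
  ncse <- as.vector(rmultinom(1, n_cases, pc))
  nctl <- as.vector(rmultinom(1, n_controls, pt))

  x1 <- rep(0:2, each = 9)
  x2 <- rep(0:2, times = 9)
  expand <- function(counts) {
    idx <- rep.int(seq_len(27), counts)
    cbind(anchor = x1[idx], causal = xd[idx], partner = x2[idx])
  }
  g <- rbind(expand(ncse), expand(nctl))
  list(genotypes = g,
       phenotype = rep(c(1, 0), c(n_cases, n_controls)))
}

#' Metric-construction configuration
#'
#' Parameters of the simulation that maps anchor-partner correlation to a
#' partner-usefulness score. Defaults reproduce the published construction:
#' one million replicates of 1,000 cases and 1,000 controls with
#' multiplicative penetrances 0.01/0.015/0.0225, top 1% of AI-minus-single-SNP
#' statistic differences, correlation bins of width 0.05, a degree-5
#' polynomial anchored at (0,0) and (1,0) with the three lowest and highest
#' populated bins fitted separately as tails.
#'
#' @param n_replicates number of simulation replicates.
#' @param n_cases,n_controls per-replicate sample sizes.
#' @param penetrances disease probabilities for 0/1/2 causal alleles.
#' @param top_fraction fraction of largest statistic differences marked "top".
#' @param bin_width correlation bin width (must divide 1 evenly).
#' @param poly_degree degree of the fitted core polynomial.
#' @param n_tail_bins_excluded populated bins per side excluded from the core
#'   polynomial fit and covered by linear tail segments.
#' @param seed RNG seed applied by [run_metric_construction()]; `NULL` leaves
#'   the RNG state alone.
#' @return A list of class `metric_construction_config`.
#' @export
metric_construction_config <- function(n_replicates = 1e6,
                                       n_cases = 1000, n_controls = 1000,
                                       penetrances = c(0.01, 0.015, 0.0225),
                                       top_fraction = 0.01,
                                       bin_width = 0.05,
                                       poly_degree = 5,
                                       n_tail_bins_excluded = 3,
                                       seed = NULL) {
  stopifnot(n_replicates >= 1, top_fraction > 0, top_fraction < 1,
            length(penetrances) == 3, poly_degree >= 3,
            n_tail_bins_excluded >= 0)
  nbins <- 1 / bin_width
  if (abs(nbins - round(nbins)) > 1e-9)
    stop("bin_width must divide (0, 1] into equal bins")
  structure(list(n_replicates = as.integer(n_replicates),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 penetrances = penetrances, top_fraction = top_fraction,
                 bin_width = bin_width, poly_degree = as.integer(poly_degree),
                 n_tail_bins_excluded = as.integer(n_tail_bins_excluded),
                 seed = seed),
            class = "metric_construction_config")
}

# Penetrance sets for the three metric variants. The multiplicative set is
# the published one; the dominant and recessive sets keep its baseline and
# maximum (the originals are not printed).
.metric_penetrances <- list(
  multiplicative = c(0.01, 0.015, 0.0225),
  dominant       = c(0.01, 0.0225, 0.0225),
  recessive      = c(0.01, 0.01, 0.0225))

#' Construct a correlation-score metric curve by simulation
#'
#' Runs the metric-construction simulation: each replicate draws a random
#' three-SNP haplotype-frequency partition, simulates a case/control sample,
#' and records the all-sample anchor-partner r2 together with the AI
#' (anchor-given-partner) and single-SNP logistic LRT statistics at the
#' anchor. Replicates whose AI-minus-single-SNP difference falls in the top
#' `top_fraction` are marked; r2 values are binned and the per-bin proportion
#' marked is fitted with a degree-`poly_degree` polynomial constrained to
#' vanish at r2 = 0 and r2 = 1, with the excluded low/high tail bins covered
#' by linear segments. The curve is scaled so its maximum over `[0, 1]` is
#' 100.
#'
#' @param config a [metric_construction_config()].
#' @param model one of `"multiplicative"`, `"dominant"`, `"recessive"`;
#'   selects the penetrance set when `config` is omitted, and labels the
#'   curve.
#' @return An object of class `metric_curve`; see [score()].
#' @export
run_metric_construction <- function(config = NULL,
                                    model = c("multiplicative", "dominant",
                                              "recessive")) {
  model <- match.arg(model)
  if (is.null(config))
    config <- metric_construction_config(
      penetrances = .metric_penetrances[[model]])
  stopifnot(inherits(config, "metric_construction_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  sim <- metric_sim_cpp(config$n_replicates, config$n_cases,
                        config$n_controls, config$penetrances[1],
                        config$penetrances[2], config$penetrances[3])
  sim <- sim[stats::complete.cases(sim), , drop = FALSE]
  if (nrow(sim) < 100)
    stop("too few usable replicates to construct a metric curve")

  diffs <- sim[, "ai_stat"] - sim[, "single_stat"]
  thr <- quantile(diffs, 1 - config$top_fraction, names = FALSE)
  top <- diffs >= thr

  nbins <- as.integer(round(1 / config$bin_width))
  bin <- pmin(floor(sim[, "r2"] / config$bin_width), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins)
  tops <- vapply(seq_len(nbins) - 1L,
                 function(b) sum(top[bin == b]), numeric(1))
  mids <- (seq_len(nbins) - 0.5) * config$bin_width
  populated <- counts > 0
  prob <- ifelse(populated, tops / pmax(counts, 1), NA_real_)

  pop_idx <- which(populated)
  k <- config$n_tail_bins_excluded
  if (length(pop_idx) <= 2 * k + config$poly_degree)
    stop("not enough populated bins to fit the core polynomial")
  core_idx <- pop_idx[(k + 1):(length(pop_idx) - k)]

  # Core fit: p(x) = x (1 - x) q(x) with q of degree poly_degree - 2, so the
  # curve is exactly anchored at (0, 0) and (1, 0).
  x <- mids[core_idx]
  yv <- prob[core_idx]
  qdeg <- config$poly_degree - 2L
  B <- outer(x, 0:qdeg, function(xx, j) xx^(j + 1) * (1 - xx))
  qcoef <- as.vector(qr.solve(qr(B, LAPACK = TRUE), yv))

  # Tails: straight lines from the anchor points (0,0) and (1,0) to the core
  # polynomial's value at the first/last included bin midpoint, so the score
  # map is continuous across the tail joints.
  lo_mid <- mids[core_idx[1]]
  hi_mid <- mids[core_idx[length(core_idx)]]
  polyval <- function(xx)
    xx * (1 - xx) * sum(qcoef * xx^(seq_along(qcoef) - 1))
  lo_val <- max(polyval(lo_mid), 0)
  hi_val <- max(polyval(hi_mid), 0)

  curve <- structure(list(model = model, q_coef = qcoef,
                          tail_lo = lo_mid, tail_lo_val = lo_val,
                          tail_hi = hi_mid, tail_hi_val = hi_val,
                          scale = 1,
                          bins = data.frame(mid = mids, n = counts,
                                            prob = prob,
                                            in_core = seq_len(nbins) %in%
                                              core_idx),
                          config = config[c("n_replicates", "n_cases",
                                            "n_controls", "penetrances",
                                            "top_fraction", "bin_width",
                                            "poly_degree",
                                            "n_tail_bins_excluded", "seed")]),
                     class = "metric_curve")
  grid <- seq(0, 1, by = 1e-3)
  mx <- max(.curve_raw(curve, grid))
  if (mx <= 0) stop("degenerate metric curve: no positive values")
  curve$scale <- 100 / mx
  curve
}

# Unscaled piecewise curve value, clamped below at zero.
.curve_raw <- function(curve, r2) {
  qv <- numeric(length(r2))
  for (j in seq_along(curve$q_coef))
    qv <- qv + curve$q_coef[j] * r2^(j - 1)
  val <- r2 * (1 - r2) * qv
  lo <- r2 < curve$tail_lo
  hi <- r2 > curve$tail_hi
  if (curve$tail_lo > 0)
    val[lo] <- r2[lo] * (curve$tail_lo_val / curve$tail_lo)
  if (curve$tail_hi < 1)
    val[hi] <- (1 - r2[hi]) * (curve$tail_hi_val / (1 - curve$tail_hi))
  pmax(val, 0)
}

#' Evaluate a metric curve
#'
#' Maps anchor-partner r2 values to partner-usefulness scores in `[0, 100]`.
#' Undefined correlations (`NA`, e.g. a monomorphic candidate) score 0.
#'
#' @param curve a `metric_curve` from [run_metric_construction()] or
#'   [default_metric_curve()].
#' @param r2 numeric vector of squared correlations in `[0, 1]` (NA allowed).
#' @return Scores in `[0, 100]`, same length as `r2`.
#' @export
score <- function(curve, r2) {
  stopifnot(inherits(curve, "metric_curve"))
  out <- numeric(length(r2))
  ok <- !is.na(r2)
  if (any(ok))
    out[ok] <- pmin(pmax(.curve_raw(curve, r2[ok]) * curve$scale, 0), 100)
  out
}

#' Location of a metric curve's maximum
#'
#' @param curve a `metric_curve`.
#' @param grid_step spacing of the evaluation grid on `[0, 1]`.
#' @return The r2 at which the curve attains its maximum score.
#' @export
curve_argmax <- function(curve, grid_step = 1e-3) {
  grid <- seq(0, 1, by = grid_step)
  grid[which.max(score(curve, grid))]
}

#' @export
print.metric_curve <- function(x, ...) {
  cat("metric_curve (", x$model, "): peak score 100 at r2 = ",
      format(curve_argmax(x)), "\n", sep = "")
  cat("  built from", x$config$n_replicates, "replicates,",
      x$config$n_cases, "cases /", x$config$n_controls, "controls\n")
  invisible(x)
}

#' Serialize a metric curve to JSON
#'
#' @param curve a `metric_curve`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_metric_curve <- function(curve, path) {
  stopifnot(inherits(curve, "metric_curve"))
  obj <- curve
  class(obj) <- NULL
  obj$bins <- as.list(obj$bins)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized metric curve
#'
#' @param path path to a JSON file written by [write_metric_curve()].
#' @return A `metric_curve`.
#' @export
read_metric_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$bins <- as.data.frame(obj$bins)
  structure(obj, class = "metric_curve")
}

.curve_cache <- new.env(parent = emptyenv())

#' Load a bundled default metric curve
#'
#' The package ships three precomputed curves (multiplicative, dominant,
#' recessive), each built by [run_metric_construction()] from one million
#' replicates with seed 1. Curves can be regenerated with the `build-metric`
#' subcommand of the command-line driver.
#'
#' @param model metric variant.
#' @return A `metric_curve`.
#' @export
default_metric_curve <- function(model = c("multiplicative", "dominant",
                                           "recessive")) {
  model <- match.arg(model)
  if (is.null(.curve_cache[[model]])) {
    path <- system.file("extdata", paste0("metric_", model, ".json"),
                        package = "snipscan", mustWork = TRUE)
    .curve_cache[[model]] <- read_metric_curve(path)
  }
  .curve_cache[[model]]
}
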