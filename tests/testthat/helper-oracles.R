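# Independent oracles and small fixture builders used across the suite.

# Maximized logistic log-likelihood by a general-purpose optimizer (BFGS on
# the written-out likelihood with analytic gradient), independent of the
# IRLS route used by the package.
oracle_logistic_ll <- function(y, X) {
  X <- as.matrix(X)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  gr <- function(b) {
    mu <- plogis(drop(X %*% b))
    -drop(crossprod(X, y - mu))
  }
  opt <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  -opt$value
}

# Closed-form OLS residual sum of squares via the normal equations.
oracle_rss <- function(y, X) {
  X <- as.matrix(X)
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - drop(X %*% beta))^2)
}

# Random correlated case/control dataset free of separation: anchor and
# partner dosages from a two-SNP haplotype model, modest logistic effects.
random_cc_data <- function(n = 120, b = NULL) {
  H <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  fr <- c(0.2, 0.15, 0.15, 0.5)
  i <- sample.int(4, n, TRUE, fr)
  j <- sample.int(4, n, TRUE, fr)
  g <- H[i, ] + H[j, ]
  if (is.null(b)) b <- runif(3, -0.6, 0.6)
  eta <- b[1] + b[2] * g[, 1] + b[3] * g[, 2]
  y <- rbinom(n, 1, plogis(eta))
  # guard against one-class draws and monomorphic columns
  if (length(unique(y)) < 2 || var(g[, 1]) == 0 || var(g[, 2]) == 0)
    return(random_cc_data(n, b))
  list(anchor = g[, 1], partner = g[, 2], y = y)
}

# Small in-memory genotype dataset on one chromosome, equally spaced SNPs.
make_dataset <- function(geno, phenotype, ptype = "binary", chrom = "1",
                         bp = NULL) {
  m <- ncol(geno)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  snps <- data.frame(chrom = chrom, snp_id = paste0("rs", seq_len(m)),
                     cm = 0, bp = bp, allele1 = "A", allele2 = "B",
                     stringsAsFactors = FALSE)
  genotype_dataset(geno, snps, phenotype, ptype)
}

# Random dosage matrix with the requested missing rate.
random_geno <- function(n, m, miss = 0) {
  g <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(seq_len(m), each = n)]),
              nrow = n)
  if (miss > 0) g[runif(n * m) < miss] <- NA
  g
}
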