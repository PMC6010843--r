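# Fixtures built in code, shared across test files.

## a small feature table with known group structure:
## f1/f2 co-eluting correlated pair, f3 isolated
tiny_feature_table <- function() {
  inten <- rbind(
    f1 = c(100, 200, 300, 400),
    f2 = c(10, 20, 30, 40),
    f3 = c(5, 50, 7, 80))
  feature_table(rownames(inten), mz = c(435.1, 436.1, 227.2),
                rt = c(576, 576.5, 630), intensity = inten,
                sample_ids = paste0("s", 1:4))
}

## toy genotype matrix: 2 tags x 2 SNPs, 6 individuals, no missingness
toy_genotypes <- function(dosage = NULL) {
  if (is.null(dosage)) {
    dosage <- rbind(
      c(0, 1, 2, 0), c(1, 1, 0, 0), c(2, 0, 1, 1),
      c(0, 2, 2, 1), c(1, 0, 0, 2), c(2, 1, 1, 0))
  }
  rownames(dosage) <- paste0("i", seq_len(nrow(dosage)))
  meta <- data.frame(
    id = paste0("snp", seq_len(ncol(dosage))),
    tag_id = rep(c("T1", "T2"), each = 2)[seq_len(ncol(dosage))],
    pos_in_tag = c(10L, 40L, 5L, 60L)[seq_len(ncol(dosage))],
    selection_class = "neutral",
    fst = NA_real_, stringsAsFactors = FALSE)
  genotype_matrix(dosage, meta)
}

## memoized demo cohort so expensive stages are generated once per run
demo_cohort <- local({
  cache <- NULL
  function(seed = 42L) {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_config(preset = "demo", seed = seed))
    cache
  }
})

## dosage matrix drawn from given allele freqs under HWE (helper for
## estimator-recovery tests)
hwe_dosage <- function(n, p) {
  L <- length(p)
  matrix(stats::rbinom(n * L, 2, rep(p, each = n)), n, L,
         dimnames = list(paste0("i", 1:n), paste0("s", 1:L)))
}

## independently coded scalar Weir-Cockerham (1984) theta for one locus,
## two or more populations; direct textbook transcription used as oracle
wc_theta_oracle <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

## naive REML log-likelihood for y = Xb + u + e via direct V inversion;
## generic-optimizer oracle independent of the eigendecomposition route
naive_reml_loglik <- function(delta, y, X, K) {
  n <- length(y)
  V <- K + delta * diag(n)
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  q <- qr(X)$rank
  m <- n - q
  sg2 <- drop(t(y) %*% P %*% y) / m
  -0.5 * (m * log(2 * pi * sg2) + m +
            determinant(V)$modulus +
            determinant(t(X) %*% Vi %*% X)$modulus -
            determinant(crossprod(X))$modulus)
}

naive_reml_h2 <- function(y, X, K) {
  opt <- stats::optimize(function(ld)
    naive_reml_loglik(exp(ld), y, X, K), c(-10, 10), maximum = TRUE,
    tol = 1e-10)
  1 / (1 + exp(opt$maximum))
}
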