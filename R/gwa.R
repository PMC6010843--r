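# EMMA-style REML variance components and EMMAX-approximation association
# scans of SNPs against metabolite traits under environmental covariate
# configurations, with Bonferroni control, Q-Q screening, and
# cross-configuration overlap summaries.

## eigendecomposition of K with PSD repair (symmetrize, floor at 0)
.k_eigen <- function(K) {
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  ## IBS similarity is often marginally indefinite; only warn when the
  ## negative part is non-trivial relative to the spectrum
  if (min(e$values) < -1e-3 * max(abs(e$values)))
    warning("kinship matrix not PSD; negative eigenvalues floored at 0")
  e$values <- pmax(e$values, 0)
  e
}

#' REML variance components by the EMMA algorithm
#'
#' Fits y = X beta + u + e with u ~ N(0, sigma_g^2 K), e ~ N(0,
#' sigma_e^2 I), maximizing the REML profile likelihood in delta =
#' sigma_e^2 / sigma_g^2. The likelihood uses a one-time
#' eigendecomposition of the projected kinship; the profile is evaluated
#' on a 100-point grid of ln(delta) in \[-10, 10\] and refined by Brent
#' search within every derivative sign-change interval, returning the
#' global optimum.
#'
#' @param y trait vector.
#' @param X covariate matrix including the intercept column.
#' @param K kinship matrix (symmetrized, eigenvalues floored at 0 with a
#'   warning if needed).
#' @return list of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `delta`, `reml_loglik`, `pseudo_heritability`
#'   (= sigma_g2/(sigma_g2+sigma_e2)), `boundary` flag.
#' @export
emma_reml <- function(y, X, K) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  q <- qr(X)$rank
  if (q < ncol(X)) abort("covariate matrix X is rank-deficient")
  if (n <= q) abort("need n > rank(X)")
  ek <- .k_eigen(K)
  Ksym <- ek$vectors %*% (ek$values * t(ek$vectors))
  ## projected kinship: eigenvectors spanning the residual space of X.
  ## Decomposing S(K + I)S and subtracting 1 keeps the q projected-out
  ## directions (eigenvalue exactly 0) strictly below every residual
  ## direction (eigenvalue >= 1) even when K is rank-deficient.
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% (Ksym + diag(n)) %*% S, symmetric = TRUE)
  m <- n - q
  xi <- pmax(es$values[seq_len(m)] - 1, 0)
  U <- es$vectors[, seq_len(m), drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2

  loglik <- function(delta) {
    w <- xi + delta
    0.5 * (m * (log(m / (2 * pi)) - 1 - log(sum(eta2 / w))) - sum(log(w)))
  }
  dloglik <- function(delta) {
    w <- xi + delta
    0.5 * (m * sum(eta2 / w^2) / sum(eta2 / w) - sum(1 / w))
  }
  grid <- exp(seq(-10, 10, length.out = 100L))
  dvals <- vapply(grid, dloglik, numeric(1))
  cand <- c(grid[1], grid[length(grid)])
  sign_change <- which(dvals[-length(dvals)] > 0 & dvals[-1] < 0)
  for (i in sign_change) {
    opt <- stats::optimize(loglik, c(grid[i], grid[i + 1]), maximum = TRUE,
                           tol = 1e-10)
    cand <- c(cand, opt$maximum)
  }
  lls <- vapply(cand, loglik, numeric(1))
  delta <- cand[which.max(lls)]
  boundary <- delta %in% c(grid[1], grid[length(grid)])
  sigma_g2 <- sum(eta2 / (xi + delta)) / m
  sigma_e2 <- delta * sigma_g2
  res <- list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, delta = delta,
              reml_loglik = loglik(delta),
              pseudo_heritability = 1 / (1 + delta),
              boundary = boundary)
  class(res) <- "variance_components"
  res
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance_components: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f%s\n",
    x$sigma_g2, x$sigma_e2, x$pseudo_heritability,
    if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Q-Q screen of a p-value set
#'
#' Computes the genomic-control inflation factor lambda_gc (median of the
#' chi-square(1) quantiles of the p-values divided by 0.4549) and a
#' Kolmogorov-Smirnov test of the p-values (excluding those at or below
#' the significance threshold) against the uniform distribution. The set
#' passes when lambda_gc lies in \[0.8, 1.2\] and the KS test is not
#' rejected at 0.01.
#'
#' @param pvalues numeric p-values for one trait/configuration.
#' @param threshold significance threshold whose hits are excluded from
#'   the KS comparison; default 0.05 / length(pvalues).
#' @return list with `lambda_gc`, `qq_ok`, `ks_p`, `reason`.
#' @export
qq_screen <- function(pvalues, threshold = NULL) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 100)
    return(list(lambda_gc = NA_real_, qq_ok = FALSE, ks_p = NA_real_,
                reason = "fewer than 100 p-values"))
  if (is.null(threshold)) threshold <- 0.05 / length(pvalues)
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, 1, lower.tail = FALSE)
  keep <- pvalues > threshold
  ks_p <- if (sum(keep) >= 10) {
    suppressWarnings(stats::ks.test(pvalues[keep], "punif")$p.value)
  } else 0
  ok <- lambda >= 0.8 && lambda <= 1.2 && ks_p >= 0.01
  reason <- if (ok) "" else if (lambda < 0.8) "deflated (lambda_gc < 0.8)"
    else if (lambda > 1.2) "inflated (lambda_gc > 1.2)"
    else "non-uniform p-value distribution"
  list(lambda_gc = lambda, qq_ok = ok, ks_p = ks_p, reason = reason)
}

#' EMMAX association scan of SNPs against traits
#'
#' For each trait the null mixed model (covariates only) is fit once by
#' [emma_reml()]; the resulting V = sigma_g^2 K + sigma_e^2 I is then
#' reused for generalized least squares of the trait on
#' \[intercept, covariates, dosage\] per SNP (the EMMAX approximation).
#' p-values come from the t statistic on the dosage coefficient. Missing
#' dosages are mean-imputed per SNP; SNPs monomorphic after imputation
#' are skipped. Per trait, the Bonferroni threshold is `alpha` divided by
#' the number of SNPs tested, and a Q-Q screen decides whether the
#' trait's results are interpretable; `significant` requires both.
#'
#' @param traits sample-by-trait matrix (log metabolite abundances and/or
#'   a richness vector), or a single numeric trait vector.
#' @param genotypes a [genotype_matrix()] or a sample-by-SNP dosage
#'   matrix, sample-aligned with `traits`.
#' @param K kinship matrix.
#' @param covariates optional sample-by-covariate matrix (no intercept
#'   column; it is added internally).
#' @param config label recorded in the output (e.g. "none", "Tcol").
#' @param alpha family-wise alpha for the Bonferroni rule (default 0.05).
#' @return data.frame of class `association_result` with columns snp,
#'   trait, config, beta, se, p, significant; per-trait Q-Q diagnostics
#'   in `attr(, "qq")`, the Bonferroni threshold in
#'   `attr(, "bonferroni")`, skipped SNPs in `attr(, "skipped")`.
#' @export
gwa_scan <- function(traits, genotypes, K, covariates = NULL,
                     config = "none", alpha = 0.05) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
    else as.matrix(genotypes)
  traits <- as.matrix(traits)
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  if (nrow(traits) != nrow(G))
    abort("traits and genotypes must be sample-aligned")
  n <- nrow(G)
  ## mean-impute missing dosages per SNP
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  sd_g <- apply(G, 2, stats::sd)
  skipped <- colnames(G)[sd_g == 0]
  use <- sd_g > 0
  G <- G[, use, drop = FALSE]
  n_snps <- ncol(G)
  bonf <- alpha / n_snps
  X0 <- cbind(`(Intercept)` = rep(1, n),
              if (!is.null(covariates)) as.matrix(covariates))
  ek <- .k_eigen(K)
  out <- vector("list", ncol(traits))
  qq_tab <- vector("list", ncol(traits))
  for (t_i in seq_len(ncol(traits))) {
    y <- traits[, t_i]
    vc <- emma_reml(y, X0, K)
    w <- 1 / sqrt(vc$sigma_g2 * ek$values + vc$sigma_e2)
    Tm <- w * t(ek$vectors)          # V^{-1/2}
    ys <- drop(Tm %*% y)
    X0s <- Tm %*% X0
    Gs <- Tm %*% G
    qx <- qr(X0s)
    My <- qr.resid(qx, ys)
    MG <- qr.resid(qx, Gs)
    gg <- colSums(MG^2)
    beta <- colSums(MG * My) / gg
    df <- n - ncol(X0) - 1L
    ss_res <- sum(My^2) - beta^2 * gg
    se <- sqrt(pmax(ss_res, 0) / df / gg)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    qq <- qq_screen(p, threshold = bonf)
    out[[t_i]] <- data.frame(
      snp = colnames(G), trait = colnames(traits)[t_i], config = config,
      beta = beta, se = se, p = p,
      significant = p <= bonf & qq$qq_ok,
      stringsAsFactors = FALSE, row.names = NULL)
    qq_tab[[t_i]] <- data.frame(
      trait = colnames(traits)[t_i], config = config,
      lambda_gc = qq$lambda_gc, qq_ok = qq$qq_ok, ks_p = qq$ks_p,
      pseudo_heritability = vc$pseudo_heritability,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "qq") <- do.call(rbind, qq_tab)
  attr(res, "bonferroni") <- bonf
  attr(res, "skipped") <- skipped
  class(res) <- c("association_result", class(res))
  res
}

#' Run the association scan under the four covariate configurations
#'
#' Scans with (1) no covariates, (2) Bio14, (3) Tcol, (4) both, and
#' returns the stacked long-format results.
#'
#' @param traits sample-by-trait matrix.
#' @param genotypes a [genotype_matrix()] or dosage matrix.
#' @param K kinship matrix.
#' @param metadata data.frame carrying `Tcol` and `Bio14`, row-aligned
#'   with the samples.
#' @param alpha family-wise alpha.
#' @return `association_result` data.frame over all four configs; Q-Q
#'   diagnostics stacked in `attr(, "qq")`.
#' @export
gwa_all_configs <- function(traits, genotypes, K, metadata, alpha = 0.05) {
  covs <- list(none = NULL,
               Bio14 = cbind(Bio14 = metadata$Bio14),
               Tcol = cbind(Tcol = metadata$Tcol),
               both = cbind(Tcol = metadata$Tcol, Bio14 = metadata$Bio14))
  res <- lapply(names(covs), function(cfg)
    gwa_scan(traits, genotypes, K, covariates = covs[[cfg]],
             config = cfg, alpha = alpha))
  out <- do.call(rbind, res)
  attr(out, "qq") <- do.call(rbind, lapply(res, attr, "qq"))
  attr(out, "bonferroni") <- attr(res[[1]], "bonferroni")
  class(out) <- c("association_result", "data.frame")
  out
}

#' Venn-style overlap summary of significant results across configurations
#'
#' For chemical features (traits) and SNPs separately: the count of unique
#' significant items per configuration, the exclusive counts of every
#' nonempty configuration-set intersection cell, and the union count.
#' Exclusive cell counts sum to each configuration's total.
#'
#' @param results an `association_result` covering the configurations.
#' @return list with elements `features` and `snps`, each a list with
#'   `per_config`, `cells` (named by the "+"-joined config set), `union`.
#' @export
overlap_summary <- function(results) {
  configs <- unique(results$config)
  sig <- results[results$significant, , drop = FALSE]
  summarize <- function(col) {
    sets <- lapply(configs, function(cfg)
      unique(sig[[col]][sig$config == cfg]))
    names(sets) <- configs
    items <- unique(unlist(sets))
    membership <- vapply(items, function(it)
      paste(sort(configs[vapply(sets, function(s) it %in% s, logical(1))]),
            collapse = "+"), character(1))
    cells <- table(membership)
    list(per_config = vapply(sets, length, integer(1)),
         cells = stats::setNames(as.integer(cells), names(cells)),
         union = length(items))
  }
  list(features = summarize("trait"), snps = summarize("snp"))
}
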