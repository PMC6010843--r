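# Distance-based congruence analyses: DAPC with and without group priors,
# pairwise ANOSIM R between subpopulations, full/partial Mantel permutation
# tests with bootstrap support, and construction of the aligned
# subpopulation-level distance matrices.

#' Discriminant analysis of principal components (DAPC)
#'
#' Variables are autoscaled, a PCA is fit, and the retained PC scores are
#' passed to a linear discriminant analysis. With `groups` given, the DA
#' discriminates those groups. Without groups, k-means is run on the PC
#' scores for candidate K = 1..`k_max`, the cluster number is chosen by
#' BIC(K) = n ln(WSS_K / n) + K ln(n), and the DA is fit on the inferred
#' clusters.
#'
#' @param data entity-by-variable numeric matrix.
#' @param groups optional group labels (length = rows of `data`).
#' @param n_pcs PCs to retain; default is the smallest number explaining
#'   at least `var_target` of the variance, capped at n/3.
#' @param var_target variance fraction for the default retention rule.
#' @param k_max largest candidate K in prior-free mode
#'   (default min(20, n/3)).
#' @param n_start random k-means restarts per K.
#' @return list of class `dapc_result`: `retained_pcs`, `coords`
#'   (discriminant coordinates), `assignments`, `posterior` (membership
#'   probabilities), `bic` (K-by-BIC table, prior-free mode), `chosen_k`,
#'   `pc_scores`.
#' @export
dapc <- function(data, groups = NULL, n_pcs = NULL, var_target = 0.9,
                 k_max = NULL, n_start = 10L) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 2) abort("need >= 2 entities")
  sds <- apply(data, 2, stats::sd)
  X <- scale(data[, sds > 0, drop = FALSE])
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  var_frac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  if (is.null(n_pcs)) {
    n_pcs <- which(var_frac >= var_target)[1]
    n_pcs <- max(1L, min(n_pcs, floor(n / 3)))
  }
  if (n_pcs >= n) abort("n_pcs must be smaller than the number of entities")
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  bic_tab <- NULL
  chosen_k <- NULL
  if (is.null(groups)) {
    ## cluster identification uses (nearly) all PCs: with few dimensions
    ## k-means splits of pure noise remove a large WSS fraction and the
    ## BIC penalty cannot compensate, whereas on full-rank scores noise
    ## splits are negligible
    full <- pc$x[, seq_len(min(ncol(pc$x), n - 2L)), drop = FALSE]
    if (is.null(k_max)) k_max <- max(1L, min(20L, floor(n / 3)))
    ## penalty counts the K * d cluster-mean parameters; a K-only penalty
    ## is always beaten by the WSS removed when k-means splits pure noise
    d_eff <- ncol(full)
    bic <- vapply(seq_len(k_max), function(k) {
      wss <- if (k == 1) sum(scale(full, scale = FALSE)^2) else {
        km <- stats::kmeans(full, centers = k, nstart = n_start,
                            iter.max = 50)
        km$tot.withinss
      }
      n * log(wss / n) + k * d_eff * log(n)
    }, numeric(1))
    bic_tab <- data.frame(K = seq_len(k_max), BIC = bic)
    chosen_k <- which.min(bic)
    groups <- if (chosen_k == 1) rep(1L, n) else
      stats::kmeans(full, centers = chosen_k, nstart = n_start,
                    iter.max = 50)$cluster
  } else {
    chosen_k <- length(unique(groups))
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    res <- list(retained_pcs = n_pcs, coords = NULL,
                assignments = groups,
                posterior = matrix(1, n, 1,
                                   dimnames = list(rownames(data),
                                                   levels(groups))),
                bic = bic_tab, chosen_k = chosen_k, pc_scores = scores)
    class(res) <- "dapc_result"
    return(res)
  }
  ld <- MASS::lda(scores, grouping = groups)
  pred <- stats::predict(ld, as.data.frame(scores))
  res <- list(retained_pcs = n_pcs, coords = pred$x,
              assignments = pred$class, posterior = pred$posterior,
              bic = bic_tab, chosen_k = chosen_k, pc_scores = scores)
  class(res) <- "dapc_result"
  res
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("dapc_result: %d PCs retained, K = %d\n",
              x$retained_pcs, x$chosen_k))
  invisible(x)
}

## ANOSIM R for one two-group comparison given a pooled distance submatrix
## and a logical same-group indicator per pair; ranks are over all pooled
## pairs with mean ranks for ties.
.anosim_r <- function(rank_d, within) {
  m <- length(rank_d)
  (mean(rank_d[!within]) - mean(rank_d[within])) / (m / 2)
}

#' Pairwise ANOSIM R matrix between subpopulations
#'
#' For each pair of subpopulations the analysis is restricted to their
#' samples; pooled pairwise distances are ranked (mean ranks for ties) and
#' R = (mean between-group rank - mean within-group rank) / (M/4), with M
#' the number of pooled pairs. Significance is by label permutation.
#'
#' @param d square symmetric distance matrix over samples (with dimnames),
#'   or a `dist` object.
#' @param grouping subpopulation label per sample.
#' @param n_perm label permutations (default 9999).
#' @return list with `R` (subpopulation-by-subpopulation matrix of ANOSIM
#'   R, diagonal 0) and `p` (one-tailed permutation p-values,
#'   (count + 1)/(n_perm + 1)).
#' @export
anosim_pairwise <- function(d, grouping, n_perm = 9999L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (n_perm < 99) warning("fewer than 99 permutations is unreliable")
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(d))
    abort("grouping must assign every sample a subpopulation")
  tab <- table(grouping)
  if (any(tab < 2)) abort("each subpopulation needs >= 2 samples")
  nm <- names(tab)
  k <- length(nm)
  R <- matrix(0, k, k, dimnames = list(nm, nm))
  P <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    idx <- which(grouping %in% c(nm[i], nm[j]))
    sub <- d[idx, idx]
    labs <- grouping[idx]
    pair_d <- sub[upper.tri(sub)]
    rank_d <- rank(pair_d)  # mean ranks for ties
    same <- outer(labs, labs, "==")[upper.tri(sub)]
    r_obs <- .anosim_r(rank_d, same)
    count <- 0L
    for (b in seq_len(n_perm)) {
      labs_p <- sample(labs)
      same_p <- outer(labs_p, labs_p, "==")[upper.tri(sub)]
      if (.anosim_r(rank_d, same_p) >= r_obs) count <- count + 1L
    }
    R[i, j] <- R[j, i] <- r_obs
    P[i, j] <- P[j, i] <- (count + 1) / (n_perm + 1)
  }
  list(R = R, p = P)
}

#' Full and partial Mantel tests
#'
#' Pearson correlation r between the off-diagonal upper-triangle vectors
#' of two distance matrices, with one-tailed significance by simultaneous
#' row/column permutation of `a` (p = (count(r_perm >= r_obs) + 1) /
#' (n_perm + 1)) and a bootstrap confidence interval over entities. In the
#' partial form both vectors are replaced by their residuals after linear
#' regression on the conditioning matrix's vector.
#'
#' @param a,b square symmetric distance matrices with matching dimnames
#'   (or `dist` objects).
#' @param n_perm permutations (default 9999).
#' @param n_boot bootstrap draws over entities (default 500); 0 disables
#'   the interval.
#' @param conditioning optional third matrix for the partial test.
#' @param conf confidence level of the bootstrap interval.
#' @return list with `r`, `p` (one-tailed), `ci` (bootstrap percentile
#'   interval or NULL), `n_perm`, `partial`.
#' @export
mantel <- function(a, b, n_perm = 9999L, n_boot = 500L,
                   conditioning = NULL, conf = 0.95) {
  to_m <- function(x) if (inherits(x, "dist")) as.matrix(x) else as.matrix(x)
  a <- to_m(a); b <- to_m(b)
  if (!identical(dim(a), dim(b))) abort("matrices must be conformable")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!identical(rownames(a), rownames(b)))
      abort("entity ids of the two matrices differ")
  }
  cmat <- if (!is.null(conditioning)) to_m(conditioning) else NULL
  if (!is.null(cmat) && !identical(dim(cmat), dim(a)))
    abort("conditioning matrix must be conformable")
  n <- nrow(a)
  ut <- upper.tri(a)
  stat <- function(av, bv, cv) {
    if (stats::sd(av) == 0 || stats::sd(bv) == 0)
      abort("constant distance vector: correlation undefined")
    if (is.null(cv)) return(stats::cor(av, bv))
    ra <- stats::residuals(stats::lm(av ~ cv))
    rb <- stats::residuals(stats::lm(bv ~ cv))
    if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
      abort("constant residual distance vector")
    stats::cor(ra, rb)
  }
  cv <- if (is.null(cmat)) NULL else cmat[ut]
  r_obs <- stat(a[ut], b[ut], cv)
  count <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    ap <- a[perm, perm][ut]
    r_p <- tryCatch(stat(ap, b[ut], cv), error = function(e) NA_real_)
    if (!is.na(r_p) && r_p >= r_obs) count <- count + 1L
  }
  p <- (count + 1) / (n_perm + 1)
  ci <- NULL
  if (n_boot > 0) {
    rs <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      ab <- a[idx, idx]; bb <- b[idx, idx]
      keep <- upper.tri(ab) & outer(idx, idx, "!=")  # drop self-pairs
      cb <- if (is.null(cmat)) NULL else cmat[idx, idx][keep]
      tryCatch(stat(ab[keep], bb[keep], cb), error = function(e) NA_real_)
    }, numeric(1))
    rs <- rs[!is.na(rs)]
    if (length(rs) >= 10)
      ci <- unname(stats::quantile(rs, c((1 - conf) / 2, (1 + conf) / 2)))
  }
  list(r = r_obs, p = p, ci = ci, n_perm = n_perm,
       partial = !is.null(cmat))
}

#' Subpopulation-level distance matrices for congruence tests
#'
#' Builds the aligned set of subpopulation distance matrices: geographic
#' (Euclidean on planar site coordinates), Tcol and Bio14 (Euclidean on
#' site means), genetic (linearized Weir-Cockerham F_ST from the neutral
#' panel), and metabolic (pairwise ANOSIM R from intersample Euclidean
#' distances of log metabolite abundances, shifted to be nonnegative if
#' any R is negative).
#'
#' @param metadata data.frame with columns `sample_id`, `subpop`, `x`,
#'   `y`, `Tcol`, `Bio14`.
#' @param log_abundance metabolite-by-sample log-abundance matrix.
#' @param genotypes neutral-panel [genotype_matrix()].
#' @param n_perm permutations for the ANOSIM step.
#' @return named list of square matrices (`geographic`, `Tcol`, `Bio14`,
#'   `genetic`, `metabolic`) with identical subpopulation ids; the ANOSIM
#'   p-value matrix rides along as `attr(metabolic, "p")`.
#' @export
subpop_distance_matrices <- function(metadata, log_abundance, genotypes,
                                     n_perm = 999L) {
  need <- c("sample_id", "subpop", "x", "y", "Tcol", "Bio14")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) abort("metadata missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(is.na(metadata[need])))
    abort("missing covariate or coordinate for some site")
  subs <- sort(unique(metadata$subpop))
  site_mean <- function(v) {
    vapply(subs, function(s) mean(v[metadata$subpop == s]), numeric(1))
  }
  euclid <- function(m) as.matrix(stats::dist(m))
  geographic <- euclid(cbind(site_mean(metadata$x), site_mean(metadata$y)))
  tcol <- euclid(cbind(site_mean(metadata$Tcol)))
  bio14 <- euclid(cbind(site_mean(metadata$Bio14)))
  dimnames(geographic) <- dimnames(tcol) <- dimnames(bio14) <-
    list(subs, subs)
  genetic <- pairwise_fst(genotypes,
                          metadata$subpop[match(genotypes$sample_ids,
                                                metadata$sample_id)])
  genetic <- genetic[subs, subs]
  common <- intersect(colnames(log_abundance), metadata$sample_id)
  dsamp <- as.matrix(stats::dist(t(log_abundance[, common, drop = FALSE])))
  an <- anosim_pairwise(dsamp,
                        metadata$subpop[match(common, metadata$sample_id)],
                        n_perm = n_perm)
  metabolic <- an$R[subs, subs]
  if (min(metabolic) < 0) metabolic <- metabolic - min(metabolic)
  diag(metabolic) <- 0
  attr(metabolic, "p") <- an$p[subs, subs]
  list(geographic = geographic, Tcol = tcol, Bio14 = bio14,
       genetic = genetic, metabolic = metabolic)
}
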