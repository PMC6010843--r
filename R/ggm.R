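# Gaussian graphical model of the metabolome by shrinkage partial
# correlations, and fusion with association results into an integrated
# SNP-metabolite network.

#' Shrinkage partial-correlation graph of metabolites
#'
#' The sample correlation matrix is shrunk toward the identity with the
#' analytically chosen intensity of Ledoit-Wolf/Schafer-Strimmer form,
#' lambda* = sum of estimated variances of the off-diagonal correlations
#' divided by the sum of their squares, clamped to \[0, 1\]. Full-order
#' partial correlations follow from the inverse: pcor_ij =
#' -omega_ij / sqrt(omega_ii omega_jj). Edge significance uses an
#' empirical null fitted to the Fisher-z-transformed partial correlations
#' (robust scale via the median absolute deviation), with
#' Benjamini-Hochberg q-values; edges are retained at q <= `q_max`.
#'
#' This estimator is the central methodological choice of the module: with
#' more metabolites than samples the sample covariance is singular and the
#' classical full-order partial correlation does not exist, while the
#' shrunk correlation matrix is always invertible.
#'
#' @param log_abundance sample-by-metabolite matrix of log abundances.
#' @param q_max BH q-value threshold for edge retention (default 0.05).
#' @param pcor_min optional fixed threshold: when non-NULL, edges are
#'   instead retained at |pcor| >= `pcor_min`.
#' @return list of class `pcor_graph`: `pcor` (symmetric matrix, unit
#'   diagonal), `lambda`, `edges` (data.frame a, b, pcor, z, p, q),
#'   `dropped` (zero-variance metabolites removed with a warning).
#' @export
shrinkage_pcor <- function(log_abundance, q_max = 0.05, pcor_min = NULL) {
  X <- as.matrix(log_abundance)
  n <- nrow(X)
  if (n < 3) abort("need at least 3 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  v <- apply(X, 2, stats::var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped))
    warning(sprintf("dropping %d zero-variance metabolites", length(dropped)))
  X <- X[, v > 0, drop = FALSE]
  p <- ncol(X)
  Xs <- scale(X)
  R <- crossprod(Xs) / (n - 1)
  ## var-hat of each off-diagonal r_ij from the products of standardized
  ## observations (Schafer & Strimmer 2005)
  var_r <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    wi <- Xs[, i] * Xs[, (i + 1):p, drop = FALSE]
    var_r[i, (i + 1):p] <-
      n / ((n - 1)^3) * colSums((wi - rep(colMeans(wi), each = n))^2)
  }
  off <- upper.tri(R)
  lambda <- sum(var_r[off]) / sum(R[off]^2)
  lambda <- min(1, max(0, lambda))
  Rstar <- (1 - lambda) * R
  diag(Rstar) <- 1
  omega <- solve(Rstar)
  denom <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(denom)
  diag(pcor) <- 1
  dimnames(pcor) <- list(colnames(X), colnames(X))
  pv <- pcor[off]
  z <- atanh(pmin(pmax(pv, -1 + 1e-12), 1 - 1e-12))
  ## null scale: empirical (MAD of the mostly-null z's) when enough pairs
  ## exist, otherwise the analytic Fisher-z SE of a full-order partial
  ## correlation, 1/sqrt(n - (p-2) - 3)
  s_analytic <- 1 / sqrt(max(n - (p - 2) - 3, 3))
  s_emp <- stats::mad(z, center = 0)
  s0 <- if (length(z) >= 50 && s_emp > 0) s_emp else s_analytic
  pval <- if (all(z == 0)) rep(1, length(z)) else
    2 * stats::pnorm(-abs(z) / s0)
  qval <- stats::p.adjust(pval, method = "BH")
  idx <- which(off, arr.ind = TRUE)
  edges <- data.frame(a = colnames(X)[idx[, 1]], b = colnames(X)[idx[, 2]],
                      pcor = pv, z = z, p = pval, q = qval,
                      stringsAsFactors = FALSE)
  keep <- if (is.null(pcor_min)) edges$q <= q_max else
    abs(edges$pcor) >= pcor_min
  res <- list(pcor = pcor, lambda = lambda,
              edges = edges[keep, , drop = FALSE],
              all_pairs = edges, dropped = dropped)
  class(res) <- "pcor_graph"
  res
}

#' @export
print.pcor_graph <- function(x, ...) {
  cat(sprintf("pcor_graph: %d metabolites, lambda = %.3f, %d edges\n",
              nrow(x$pcor), x$lambda, nrow(x$edges)))
  invisible(x)
}

#' Integrate the metabolite GGM with SNP association results
#'
#' Builds the typed network of Figure-style summaries: metabolite nodes
#' with at least one retained GGM edge, plus SNP nodes with at least one
#' significant association to those metabolites. GGM edges
#' (metabolite-metabolite) carry the partial correlation; GWA edges
#' (SNP-metabolite) carry -log10(p) and the set of covariate
#' configurations under which they are significant. SNPs associated with
#' two or more distinct metabolites are flagged multi-associated.
#'
#' @param ggm a `pcor_graph` from [shrinkage_pcor()].
#' @param gwa an `association_result` from [gwa_scan()] /
#'   [gwa_all_configs()].
#' @param feature_map optional named vector mapping GWA trait
#'   (feature/group) ids to the GGM metabolite ids; NULL when they share
#'   an id space. Unmappable traits are logged and skipped.
#' @param snp_meta optional per-SNP annotation data.frame (columns `id`,
#'   `tag_id`, `selection_class`) copied onto SNP nodes.
#' @return an igraph graph with vertex attributes `type`
#'   ("metabolite"/"SNP") and `multi_associated`, and edge attributes
#'   `kind` ("GGM"/"GWA"), `weight` (pcor or -log10 p), `configs`.
#' @export
integrate_network <- function(ggm, gwa, feature_map = NULL,
                              snp_meta = NULL) {
  stopifnot(inherits(ggm, "pcor_graph"))
  ggm_edges <- ggm$edges
  mets <- unique(c(ggm_edges$a, ggm_edges$b))
  sig <- gwa[gwa$significant, , drop = FALSE]
  if (nrow(sig)) {
    mapped <- if (is.null(feature_map)) sig$trait else
      unname(feature_map[sig$trait])
    unmappable <- is.na(mapped) | !(mapped %in% rownames(ggm$pcor))
    if (any(unmappable))
      message(sprintf("integrate_network: %d GWA results skipped (no metabolite mapping)",
                      sum(unmappable)))
    sig <- sig[!unmappable, , drop = FALSE]
    sig$metabolite <- mapped[!unmappable]
    sig <- sig[sig$metabolite %in% mets, , drop = FALSE]
  } else sig$metabolite <- character(0)
  ## one GWA edge per SNP-metabolite pair: best p, set of configs
  gwa_edges <- NULL
  if (nrow(sig)) {
    key <- paste(sig$snp, sig$metabolite, sep = "\r")
    gwa_edges <- do.call(rbind, lapply(split(sig, key), function(df) {
      data.frame(snp = df$snp[1], metabolite = df$metabolite[1],
                 neg_log10_p = -log10(min(df$p)),
                 configs = paste(sort(unique(df$config)), collapse = "+"),
                 stringsAsFactors = FALSE)
    }))
    rownames(gwa_edges) <- NULL
  }
  snps <- if (is.null(gwa_edges)) character(0) else unique(gwa_edges$snp)
  multi <- if (is.null(gwa_edges)) character(0) else
    names(which(tapply(gwa_edges$metabolite, gwa_edges$snp,
                       function(x) length(unique(x))) >= 2))
  vertices <- data.frame(
    name = c(mets, snps),
    type = c(rep("metabolite", length(mets)), rep("SNP", length(snps))),
    multi_associated = c(rep(FALSE, length(mets)), snps %in% multi),
    stringsAsFactors = FALSE)
  if (!is.null(snp_meta)) {
    m <- match(vertices$name, snp_meta$id)
    vertices$tag_id <- snp_meta$tag_id[m]
    vertices$selection_class <- snp_meta$selection_class[m]
  }
  e1 <- if (nrow(ggm_edges)) {
    data.frame(from = ggm_edges$a, to = ggm_edges$b, kind = "GGM",
               weight = ggm_edges$pcor, configs = NA_character_,
               stringsAsFactors = FALSE)
  } else NULL
  e2 <- if (is.null(gwa_edges)) NULL else
    data.frame(from = gwa_edges$snp, to = gwa_edges$metabolite,
               kind = "GWA", weight = gwa_edges$neg_log10_p,
               configs = gwa_edges$configs, stringsAsFactors = FALSE)
  edges <- rbind(e1, e2)
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0), weight = numeric(0),
                        configs = character(0), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Write an integrated network to GraphML and edge-list TSVs
#'
#' @param network igraph graph from [integrate_network()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(graphml = file.path(dir, "network.graphml"),
             ggm = file.path(dir, "ggm_edges.tsv"),
             gwa = file.path(dir, "gwa_edges.tsv"))
  igraph::write_graph(network, paths[["graphml"]], format = "graphml")
  ed <- igraph::as_data_frame(network, what = "edges")
  utils::write.table(ed[ed$kind == "GGM", ], paths[["ggm"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ed[ed$kind == "GWA", ], paths[["gwa"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
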