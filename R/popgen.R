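# Genotype container, I/O, QC filters, and population-genetic statistics:
# exact Hardy-Weinberg tests, one-SNP-per-tag selection, heterozygosities,
# nucleotide diversity, rarefied allelic richness, individual inbreeding F,
# identity-by-state kinship, and Weir-Cockerham F_ST with linearization.

#' Construct a genotype matrix
#'
#' @param dosage individuals-by-SNPs matrix over \{0, 1, 2, NA\} (count of
#'   the alternate/minor allele), with row and column names.
#' @param snp_meta per-SNP data.frame with columns `id`, `tag_id`,
#'   `pos_in_tag` (0-based base offset within the tag), `selection_class`
#'   ("neutral" or "outlier"), `fst` (may be NA for neutral tags).
#' @param tag_length assembled tag length in bases (default 90).
#' @return an object of class `genotype_matrix` with fields `dosage`,
#'   `snp_meta`, `sample_ids`, `tag_length`.
#' @export
genotype_matrix <- function(dosage, snp_meta, tag_length = 90L) {
  dosage <- as.matrix(dosage)
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) abort("dosage values must be 0, 1, 2, or NA")
  need <- c("id", "tag_id", "pos_in_tag", "selection_class")
  if (!all(need %in% names(snp_meta)))
    abort("snp_meta must have columns %s", paste(need, collapse = ", "))
  if (!"fst" %in% names(snp_meta)) snp_meta$fst <- NA_real_
  if (nrow(snp_meta) != ncol(dosage))
    abort("snp_meta rows must match dosage columns")
  if (any(!nzchar(snp_meta$tag_id))) abort("tag ids must be nonempty")
  if (any(snp_meta$pos_in_tag < 0 | snp_meta$pos_in_tag >= tag_length))
    abort("pos_in_tag must lie in [0, tag_length)")
  if (is.null(colnames(dosage))) colnames(dosage) <- snp_meta$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, snp_meta = snp_meta,
                 sample_ids = rownames(dosage),
                 tag_length = as.integer(tag_length)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d tags (%d bp)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$snp_meta$tag_id)), x$tag_length))
  invisible(x)
}

#' Write genotypes as a dosage TSV with tag metadata
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- cbind(g$snp_meta,
               as.data.frame(t(g$dosage), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a dosage TSV (as written by [write_genotypes()])
#' @param path input path.
#' @param tag_length tag length in bases.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, tag_length = 90L) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_cols <- c("id", "tag_id", "pos_in_tag", "selection_class", "fst")
  have <- intersect(meta_cols, names(raw))
  dosage <- t(as.matrix(raw[setdiff(names(raw), meta_cols)]))
  colnames(dosage) <- raw$id
  genotype_matrix(dosage, raw[have], tag_length = tag_length)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Uses the VCF CHROM as the tag id and POS - 1 as the position within the
#' tag; the INFO keys `SEL` (neutral/outlier) and `FST` populate the
#' selection class and per-SNP differentiation when present.
#'
#' @param path VCF path (plain text).
#' @param tag_length tag length in bases.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path, tag_length = 90L) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    ifelse(is.na(x), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"), function(a)
             sum(a == "1"), integer(1)))
  }
  dosage <- t(apply(gt, 1, alt_count))  # snps x samples
  dimnames(dosage) <- dimnames(gt)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, element = "SEL")
  fst <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "FST")))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  snp_meta <- data.frame(
    id = ids, tag_id = fix$CHROM,
    pos_in_tag = as.integer(fix$POS) - 1L,
    selection_class = ifelse(is.na(info), "neutral", info),
    fst = fst, stringsAsFactors = FALSE)
  genotype_matrix(t(dosage), snp_meta, tag_length = tag_length)
}

#' Exact Hardy-Weinberg test (Levene-Haldane)
#'
#' Two-sided exact p-value from the conditional distribution of the
#' heterozygote count given the allele counts in a diploid sample: all
#' outcomes with probability at most that of the observed table are
#' summed.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value; 1 for a monomorphic locus.
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) abort("need at least one genotype")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

## per-SNP genotype counts within a sample subset
.geno_counts <- function(dosage_col) {
  c(n_AA = sum(dosage_col == 0, na.rm = TRUE),
    n_Aa = sum(dosage_col == 1, na.rm = TRUE),
    n_aa = sum(dosage_col == 2, na.rm = TRUE))
}

#' Filter SNPs by minor allele frequency, call rate, and Hardy-Weinberg
#'
#' A SNP is kept iff its minor allele frequency (over non-missing calls)
#' is at least `maf_min`, its call rate at least `call_rate_min`, and its
#' exact Hardy-Weinberg p-value is at least `hwe_alpha` in strictly more
#' than half of the subpopulations having at least `hwe_min_n` genotyped
#' individuals (a SNP with no such subpopulation passes the HWE rule).
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minor-allele-frequency floor (default 0.05).
#' @param call_rate_min genotyping-rate floor (default 0.80).
#' @param hwe_alpha per-test Hardy-Weinberg alpha (default 0.05).
#' @param grouping subpopulation label per individual.
#' @param hwe_min_n minimum genotyped individuals for a subpopulation to
#'   enter the HWE rule (default 5).
#' @return the filtered `genotype_matrix`; `attr(, "filter_report")` holds
#'   per-filter removal counts.
#' @export
filter_snps <- function(g, maf_min = 0.05, call_rate_min = 0.80,
                        hwe_alpha = 0.05, grouping, hwe_min_n = 5L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(grouping) != nrow(g$dosage))
    abort("grouping must assign every individual a subpopulation")
  d <- g$dosage
  n_called <- colSums(!is.na(d))
  call_rate <- n_called / nrow(d)
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  pass_maf <- !is.na(maf) & maf >= maf_min
  pass_cr <- call_rate >= call_rate_min
  groups <- split(seq_len(nrow(d)), grouping)
  pass_hwe <- vapply(seq_len(ncol(d)), function(j) {
    ps <- vapply(groups, function(idx) {
      col <- d[idx, j]
      if (sum(!is.na(col)) < hwe_min_n) return(NA_real_)
      cnt <- .geno_counts(col)
      hwe_exact(cnt[1], cnt[2], cnt[3])
    }, numeric(1))
    ps <- ps[!is.na(ps)]
    if (!length(ps)) return(TRUE)
    sum(ps >= hwe_alpha) > length(ps) / 2
  }, logical(1))
  keep <- pass_maf & pass_cr & pass_hwe
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         g$snp_meta[keep, , drop = FALSE],
                         tag_length = g$tag_length)
  attr(out, "filter_report") <- c(
    input = ncol(d), removed_maf = sum(!pass_maf),
    removed_call_rate = sum(!pass_cr), removed_hwe = sum(!pass_hwe),
    kept = sum(keep))
  out
}

#' Select one SNP per GBS tag
#'
#' For neutral tags the SNP closest to the restriction cut site (minimal
#' position in the tag, ties by lexicographic id) is kept; for outlier
#' tags the SNP with the highest per-SNP F_ST (ties by minimal position).
#' A tag carrying both classes is treated as outlier.
#'
#' @param g a [genotype_matrix()] with `fst` populated for outlier tags.
#' @return list with `association` (one SNP per tag, all tags) and
#'   `neutral` (the subset on purely neutral tags), both
#'   `genotype_matrix` objects.
#' @export
select_one_snp_per_tag <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  meta <- g$snp_meta
  tags <- split(seq_len(nrow(meta)), meta$tag_id)
  picked <- vapply(tags, function(idx) {
    cls <- unique(meta$selection_class[idx])
    is_outlier <- "outlier" %in% cls
    if (is_outlier) {
      if (any(is.na(meta$fst[idx])))
        abort("fst missing for outlier tag %s", meta$tag_id[idx[1]])
      o <- order(-meta$fst[idx], meta$pos_in_tag[idx])
    } else {
      o <- order(meta$pos_in_tag[idx], meta$id[idx])
    }
    idx[o[1]]
  }, integer(1))
  picked <- sort(picked)
  assoc <- genotype_matrix(g$dosage[, picked, drop = FALSE],
                           meta[picked, , drop = FALSE], g$tag_length)
  tag_class <- vapply(tags, function(idx)
    if ("outlier" %in% meta$selection_class[idx]) "outlier" else "neutral",
    character(1))
  neutral_idx <- picked[tag_class[match(meta$tag_id[picked],
                                        names(tags))] == "neutral"]
  neutral <- genotype_matrix(g$dosage[, neutral_idx, drop = FALSE],
                             meta[neutral_idx, , drop = FALSE],
                             g$tag_length)
  list(association = assoc, neutral = neutral)
}

## per-locus allele freq, observed het freq, and sample size in a subset
.locus_stats <- function(d) {
  n <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  h <- colMeans(d == 1, na.rm = TRUE)
  list(n = n, p = p, h = h)
}

#' Observed and expected heterozygosity per subpopulation
#'
#' Per locus, Ho is the heterozygote fraction and He the unbiased
#' (sample-size-corrected) expected heterozygosity 2p(1-p) * 2n/(2n-1);
#' the subpopulation value is the mean over loci, with a 95% nonparametric
#' bootstrap interval over loci.
#'
#' @param g a [genotype_matrix()].
#' @param grouping subpopulation label per individual.
#' @param n_boot bootstrap draws over loci (default 1000).
#' @return data.frame with columns subpop, Ho, Ho_lo, Ho_hi, He, He_lo,
#'   He_hi.
#' @export
heterozygosity <- function(g, grouping, n_boot = 1000L) {
  stopifnot(inherits(g, "genotype_matrix"))
  groups <- split(seq_len(nrow(g$dosage)), grouping)
  out <- lapply(names(groups), function(gp) {
    d <- g$dosage[groups[[gp]], , drop = FALSE]
    st <- .locus_stats(d)
    ok <- st$n >= 2
    ho <- st$h[ok]
    he <- 2 * st$p[ok] * (1 - st$p[ok]) * 2 * st$n[ok] / (2 * st$n[ok] - 1)
    boot <- replicate(n_boot, {
      idx <- sample.int(length(ho), replace = TRUE)
      c(mean(ho[idx]), mean(he[idx]))
    })
    data.frame(subpop = gp, Ho = mean(ho),
               Ho_lo = stats::quantile(boot[1, ], 0.025),
               Ho_hi = stats::quantile(boot[1, ], 0.975),
               He = mean(he),
               He_lo = stats::quantile(boot[2, ], 0.025),
               He_hi = stats::quantile(boot[2, ], 0.975),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Nucleotide diversity per subpopulation from GBS tags
#'
#' pi = sum over variable sites of the unbiased heterozygosity
#' 2*p*q*2n/(2n-1), divided by the total assembled sequence length
#' (number of tags times tag length).
#'
#' @param g a [genotype_matrix()].
#' @param grouping subpopulation label per individual.
#' @return data.frame with columns subpop, pi.
#' @export
nucleotide_diversity <- function(g, grouping) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_tags <- length(unique(g$snp_meta$tag_id))
  total_bp <- n_tags * g$tag_length
  groups <- split(seq_len(nrow(g$dosage)), grouping)
  out <- lapply(names(groups), function(gp) {
    d <- g$dosage[groups[[gp]], , drop = FALSE]
    st <- .locus_stats(d)
    ok <- st$n >= 2 & st$p > 0 & st$p < 1
    he <- 2 * st$p[ok] * (1 - st$p[ok]) * 2 * st$n[ok] / (2 * st$n[ok] - 1)
    data.frame(subpop = gp, pi = sum(he) / total_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rarefied allelic richness from allele counts at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g_size`
#' gene copies: A_r = sum over alleles of 1 - C(N - N_i, g)/C(N, g).
#'
#' @param counts vector of allele counts (one entry per allele).
#' @param g_size rarefaction size in gene copies (>= 2).
#' @return expected allele count.
#' @export
rarefied_richness_counts <- function(counts, g_size) {
  if (g_size < 2) abort("rarefaction size must be >= 2")
  N <- sum(counts)
  if (g_size > N) abort("rarefaction size exceeds available gene copies")
  sum(1 - exp(lchoose(N - counts, g_size) - lchoose(N, g_size)))
}

#' Rarefied allelic richness per subpopulation
#'
#' Mean over loci of the expected allele count in a subsample of `g_size`
#' gene copies. The default `g_size` is the minimum, over subpopulations
#' and loci, of twice the number of genotyped individuals.
#'
#' @param g a [genotype_matrix()].
#' @param grouping subpopulation label per individual.
#' @param g_size rarefaction size in gene copies; NULL for the default.
#' @return data.frame with columns subpop, Ar, g_size.
#' @export
rarefied_allelic_richness <- function(g, grouping, g_size = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  groups <- split(seq_len(nrow(g$dosage)), grouping)
  copies <- sapply(groups, function(idx)
    colSums(!is.na(g$dosage[idx, , drop = FALSE])) * 2)
  if (is.null(g_size)) g_size <- min(copies)
  if (g_size < 2) abort("rarefaction size must be >= 2")
  if (g_size > min(copies))
    abort("rarefaction size exceeds gene copies at some locus")
  out <- lapply(names(groups), function(gp) {
    d <- g$dosage[groups[[gp]], , drop = FALSE]
    ar <- vapply(seq_len(ncol(d)), function(j) {
      alt <- sum(d[, j], na.rm = TRUE)
      tot <- 2 * sum(!is.na(d[, j]))
      cnt <- c(tot - alt, alt)
      rarefied_richness_counts(cnt[cnt > 0], g_size)
    }, numeric(1))
    data.frame(subpop = gp, Ar = mean(ar), g_size = g_size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Method-of-moments inbreeding coefficient per individual
#'
#' F = (O_hom - E_hom) / (L - E_hom), where over an individual's
#' non-missing loci O_hom is the observed homozygote count, E_hom the
#' expected homozygote count under Hardy-Weinberg using total-sample
#' allele frequencies with the unbiased correction 2pq * 2N/(2N-1), and L
#' the non-missing locus count.
#'
#' @param g a [genotype_matrix()].
#' @param min_loci individuals with fewer non-missing loci are flagged
#'   unreliable (default 20).
#' @return data.frame with columns sample_id, F, n_loci, reliable.
#' @export
inbreeding_F <- function(g, min_loci = 20L) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  N <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  e_het <- 2 * p * (1 - p) * 2 * N / (2 * N - 1)
  hom <- d == 0 | d == 2
  f <- vapply(seq_len(nrow(d)), function(i) {
    ok <- !is.na(d[i, ])
    L <- sum(ok)
    e_hom <- sum(1 - e_het[ok])
    o_hom <- sum(hom[i, ok])
    if (L - e_hom == 0) return(NA_real_)
    (o_hom - e_hom) / (L - e_hom)
  }, numeric(1))
  n_loci <- rowSums(!is.na(d))
  data.frame(sample_id = rownames(d), F = f, n_loci = n_loci,
             reliable = n_loci >= min_loci, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Identity-by-state kinship matrix
#'
#' Pairwise similarity = mean over shared non-missing loci of
#' (2 - |d_i - d_j|)/2, with unit diagonal.
#'
#' @param g a [genotype_matrix()].
#' @return symmetric sample-by-sample matrix in \[0, 1\].
#' @export
ibs_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  M <- !is.na(d)
  I0 <- M & d == 0; I1 <- M & d == 1; I2 <- M & d == 2
  I0[is.na(I0)] <- FALSE; I1[is.na(I1)] <- FALSE; I2[is.na(I2)] <- FALSE
  storage.mode(I0) <- "numeric"; storage.mode(I1) <- "numeric"
  storage.mode(I2) <- "numeric"; storage.mode(M) <- "numeric"
  shared <- M %*% t(M)
  diff1 <- I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1)
  diff2 <- I0 %*% t(I2) + I2 %*% t(I0)
  absdiff <- diff1 + 2 * diff2
  off <- shared == 0 & row(shared) != col(shared)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    abort("no shared non-missing locus for pair %s, %s",
          rownames(d)[bad[1]], rownames(d)[bad[2]])
  }
  sim <- (shared - absdiff / 2) / shared
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(d), rownames(d))
  sim
}

## Weir & Cockerham (1984) variance components a, b, c per locus, over the
## populations listed in `groups` (list of row-index vectors).
.wc_components <- function(dosage, groups) {
  r <- length(groups)
  stats_by_pop <- lapply(groups, function(idx)
    .locus_stats(dosage[idx, , drop = FALSE]))
  as_mat <- function(field) {
    m <- sapply(stats_by_pop, `[[`, field)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)  # single-locus case
    m
  }
  n_mat <- as_mat("n")    # loci x pops
  p_mat <- as_mat("p")
  h_mat <- as_mat("h")
  nbar <- rowMeans(n_mat)
  nc <- (r * nbar - rowSums(n_mat^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_mat * p_mat) / (r * nbar)
  s2 <- rowSums(n_mat * (p_mat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_mat * h_mat) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- is.finite(a) & is.finite(b) & is.finite(cc) & nbar > 1 &
    pbar > 0 & pbar < 1
  list(a = a, b = b, c = cc, ok = ok)
}

#' Multilocus Weir-Cockerham F_ST
#'
#' Ratio-of-sums estimator theta = sum(a) / sum(a + b + c) over loci, using
#' the Weir & Cockerham (1984) variance components.
#'
#' @param g a [genotype_matrix()].
#' @param grouping subpopulation label per individual.
#' @return scalar theta; per-locus components attached as attribute
#'   `components`.
#' @export
wc_fst <- function(g, grouping) {
  stopifnot(inherits(g, "genotype_matrix"))
  groups <- split(seq_len(nrow(g$dosage)), grouping)
  if (length(groups) < 2) abort("need >= 2 subpopulations")
  comp <- .wc_components(g$dosage, groups)
  num <- sum(comp$a[comp$ok])
  den <- sum((comp$a + comp$b + comp$c)[comp$ok])
  structure(num / den, components = comp)
}

#' Pairwise linearized F_ST between subpopulations
#'
#' For every subpopulation pair, the multilocus Weir-Cockerham theta is
#' computed and linearized as theta / (1 - theta). Negative multilocus
#' estimates are truncated to 0 before linearization; theta = 1 maps to
#' `cap` with a warning. Subpopulations with fewer than 2 individuals are
#' excluded with a warning.
#'
#' @param g a [genotype_matrix()] (typically the neutral panel).
#' @param grouping subpopulation label per individual.
#' @param cap linearized value standing in for complete fixation
#'   (default 100).
#' @return symmetric matrix of linearized F_ST with zero diagonal; the raw
#'   theta matrix is attached as attribute `theta`.
#' @export
pairwise_fst <- function(g, grouping, cap = 100) {
  stopifnot(inherits(g, "genotype_matrix"))
  groups <- split(seq_len(nrow(g$dosage)), as.character(grouping))
  small <- names(groups)[lengths(groups) < 2]
  if (length(small)) {
    warning(sprintf("excluding subpopulations with < 2 individuals: %s",
                    paste(small, collapse = ", ")))
    groups <- groups[lengths(groups) >= 2]
  }
  if (length(groups) < 2) abort("need >= 2 subpopulations")
  nm <- names(groups)
  k <- length(nm)
  theta <- matrix(0, k, k, dimnames = list(nm, nm))
  lin <- theta
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    comp <- .wc_components(g$dosage, groups[c(i, j)])
    th <- sum(comp$a[comp$ok]) / sum((comp$a + comp$b + comp$c)[comp$ok])
    theta[i, j] <- theta[j, i] <- th
    th0 <- max(th, 0)
    if (th0 >= 1) {
      warning(sprintf("theta = 1 between %s and %s; capped at %g",
                      nm[i], nm[j], cap))
      lv <- cap
    } else lv <- th0 / (1 - th0)
    lin[i, j] <- lin[j, i] <- lv
  }
  structure(lin, theta = theta)
}
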