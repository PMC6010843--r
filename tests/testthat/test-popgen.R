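# Population-genetic statistics against enumeration and closed-form oracles.

test_that("hwe_exact matches full enumeration of the conditional distribution", {
  ## enumeration oracle: list all diploid genotype assignments compatible
  ## with the allele counts, weight by multinomial coefficients
  enum_hwe <- function(n_AA, n_Aa, n_aa) {
    n <- n_AA + n_Aa + n_aa
    nA <- 2 * n_AA + n_Aa
    hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    w <- vapply(hets, function(h) {
      aa <- (nA - h) / 2
      exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) -
            lfactorial(n - aa - h) + h * log(2))
    }, numeric(1))
    p <- w / sum(w)
    obs <- p[match(n_Aa, hets)]
    sum(p[p <= obs * (1 + 1e-9)])
  }
  expect_equal(hwe_exact(1, 0, 1), 1 / 3, tolerance = 1e-12)
  ## exhaustively over all genotype tables with up to 10 individuals
  for (n in 1:10) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      expect_equal(hwe_exact(n_AA, n_Aa, n_aa),
                   enum_hwe(n_AA, n_Aa, n_aa), tolerance = 1e-10)
    }
  }
})

test_that("hwe_exact handles extreme-heterozygote and monomorphic tables", {
  for (n in c(1, 3, 7)) {
    # all-heterozygote table: p equals the enumerated tail mass
    p <- hwe_exact(0, n, 0)
    expect_gte(p, 0); expect_lte(p, 1)
  }
  expect_identical(hwe_exact(5, 0, 0), 1)
  expect_identical(hwe_exact(0, 0, 8), 1)
  expect_error(hwe_exact(-1, 0, 1), "counts")
})

test_that("filter_snps applies MAF, call-rate, and HWE rules", {
  set.seed(1)
  n <- 60
  grp <- rep(c("A", "B"), each = n / 2)
  d <- hwe_dosage(n, rep(0.4, 5))
  d[, 1] <- rep(c(0L, 1L, 1L, 2L), 15)    # exact HWE proportions
  d[, 5] <- rep(c(0L, 1L, 1L, 2L), 15)
  d[, 2] <- 0L; d[1:2, 2] <- 1L           # MAF 1/60 -> removed
  d[1:20, 3] <- NA                        # call rate 2/3 -> removed
  d[, 4] <- rep(c(0, 2), n / 2)           # no hets anywhere -> HWE fail
  meta <- data.frame(id = paste0("s", 1:5), tag_id = paste0("T", 1:5),
                     pos_in_tag = 0L, selection_class = "neutral",
                     fst = NA_real_)
  g <- genotype_matrix(d, meta)
  out <- filter_snps(g, grouping = grp)
  kept <- out$snp_meta$id
  expect_false("s2" %in% kept)
  expect_false("s3" %in% kept)
  expect_false("s4" %in% kept)
  expect_true(all(c("s1", "s5") %in% kept))
  rep_tab <- attr(out, "filter_report")
  expect_identical(unname(rep_tab["input"]), 5L)
})

test_that("HWE-rule rejection rate is near nominal under equilibrium", {
  ## cohorts generated under HWE: the fraction of SNPs failing the
  ## majority-of-subpopulations rule should be small, consistent with the
  ## nominal per-test alpha (binomial check over replicates)
  set.seed(11)
  fails <- replicate(20, {
    n <- 60
    grp <- rep(c("A", "B"), each = 30)
    d <- hwe_dosage(n, runif(50, 0.2, 0.8))
    meta <- data.frame(id = paste0("s", 1:50), tag_id = paste0("T", 1:50),
                       pos_in_tag = 0L, selection_class = "neutral",
                       fst = NA_real_)
    g <- genotype_matrix(d, meta)
    out <- filter_snps(g, maf_min = 0, call_rate_min = 0, grouping = grp)
    unname(attr(out, "filter_report")["removed_hwe"]) / 50
  })
  ## exact tests are conservative; both subpops must fail (p < alpha in
  ## >= half of 2 subpops means: fails unless both are in equilibrium)
  expect_lt(mean(fails), 0.10)
})

test_that("one SNP per tag follows the cut-site / highest-Fst rules", {
  d <- hwe_dosage(10, rep(0.5, 5))
  meta <- data.frame(
    id = c("a1", "a2", "b1", "b2", "c1"),
    tag_id = c("T1", "T1", "T2", "T2", "T3"),
    pos_in_tag = c(40L, 10L, 5L, 60L, 0L),
    selection_class = c("neutral", "neutral", "outlier", "outlier",
                        "neutral"),
    fst = c(NA, NA, 0.1, 0.3, NA))
  colnames(d) <- meta$id
  g <- genotype_matrix(d, meta)
  panels <- select_one_snp_per_tag(g)
  expect_setequal(panels$association$snp_meta$id, c("a2", "b2", "c1"))
  expect_setequal(panels$neutral$snp_meta$id, c("a2", "c1"))
  ## mixed-class tag is treated as outlier
  meta$selection_class <- c("neutral", "outlier", "neutral", "neutral",
                            "neutral")
  meta$fst <- c(0.05, 0.2, NA, NA, NA)
  g2 <- genotype_matrix(d, meta)
  p2 <- select_one_snp_per_tag(g2)
  expect_true("a2" %in% p2$association$snp_meta$id)  # highest fst on T1
  expect_false("T1" %in% p2$neutral$snp_meta$tag_id)
})

test_that("heterozygosity: closed forms and Balding-Nichols expectation", {
  d <- matrix(1L, 10, 4, dimnames = list(paste0("i", 1:10), paste0("s", 1:4)))
  meta <- data.frame(id = paste0("s", 1:4), tag_id = paste0("T", 1:4),
                     pos_in_tag = 0L, selection_class = "neutral",
                     fst = NA_real_)
  het <- heterozygosity(genotype_matrix(d, meta), rep("A", 10),
                        n_boot = 50)
  expect_equal(het$Ho, 1)
  ## p = 0.5, large n: unbiased He -> 0.5
  set.seed(2)
  d2 <- hwe_dosage(2000, rep(0.5, 20))
  het2 <- heterozygosity(toy_like <- genotype_matrix(
    d2, data.frame(id = paste0("s", 1:20), tag_id = paste0("T", 1:20),
                   pos_in_tag = 0L, selection_class = "neutral",
                   fst = NA_real_)), rep("A", 2000), n_boot = 50)
  expect_equal(het2$He, 0.5, tolerance = 0.01)
  ## Balding-Nichols cohort: mean He ~ 2 E[p(1-p)] = 2 pbar qbar (1 - F)
  cfg <- cohort_config(preset = "demo", n_tags = 300, fst_target = 0.2,
                       region_share = 0, missing_rate = 0, inbreeding = 0,
                       seed = 5)
  g <- simulate_genotypes(cfg)
  md <- chemodivgwa:::simulate_metadata(cfg)
  p_sub <- attr(g, "subpop_freq")
  het3 <- heterozygosity(g, md$subpop, n_boot = 50)
  expect_equal(mean(het3$He), mean(2 * p_sub * (1 - p_sub)),
               tolerance = 0.02)
})

test_that("nucleotide diversity uses tag-length denominators", {
  ## one tag (90 bp), one SNP with unbiased He = 0.45 -> pi = 0.005
  ## construct: 10 individuals, p = 0.5, Ho chosen freely; use closed form
  d <- matrix(c(rep(0L, 5), rep(2L, 5)), ncol = 1,
              dimnames = list(paste0("i", 1:10), "s1"))
  meta <- data.frame(id = "s1", tag_id = "T1", pos_in_tag = 0L,
                     selection_class = "neutral", fst = NA_real_)
  g <- genotype_matrix(d, meta)
  ## p = 0.5, n = 10: He = 2*0.25*20/19 = 0.5263; pi = He/90
  pi1 <- nucleotide_diversity(g, rep("A", 10))
  expect_equal(pi1$pi, (2 * 0.25 * 20 / 19) / 90, tolerance = 1e-12)
  ## doubling tag count with no new SNPs halves pi
  meta2 <- rbind(meta, data.frame(id = "s2", tag_id = "T2",
                                  pos_in_tag = 0L,
                                  selection_class = "neutral",
                                  fst = NA_real_))
  d2 <- cbind(d, s2 = 0L)  # monomorphic second tag
  g2 <- genotype_matrix(d2, meta2)
  expect_equal(nucleotide_diversity(g2, rep("A", 10))$pi, pi1$pi / 2)
})

test_that("rarefied allelic richness equals subsample enumeration", {
  ## counts (3,1), g = 2: all C(4,2)=6 subsamples -> mean distinct = 1.5
  expect_equal(rarefied_richness_counts(c(3, 1), 2), 1.5)
  ## brute-force enumeration oracle on a second case
  counts <- c(5, 2, 1); g_size <- 3
  pool <- rep(seq_along(counts), counts)
  combos <- utils::combn(length(pool), g_size)
  brute <- mean(apply(combos, 2, function(i) length(unique(pool[i]))))
  expect_equal(rarefied_richness_counts(counts, g_size), brute,
               tolerance = 1e-12)
  expect_equal(rarefied_richness_counts(8, 5), 1)      # monomorphic
  expect_equal(rarefied_richness_counts(c(3, 1), 4), 2) # g = N identity
  expect_error(rarefied_richness_counts(c(3, 1), 1), ">= 2")
})

test_that("rarefied richness matches Monte-Carlo subsampling within 3 SE", {
  set.seed(3)
  counts <- c(11, 6, 2, 1); g_size <- 8
  pool <- rep(seq_along(counts), counts)
  draws <- replicate(10000, length(unique(sample(pool, g_size))))
  mc <- mean(draws); se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(rarefied_richness_counts(counts, g_size) - mc), 3 * se)
})

test_that("inbreeding F: boundary identities and selfing recovery", {
  set.seed(4)
  d <- hwe_dosage(30, runif(60, 0.2, 0.8))
  meta <- data.frame(id = colnames(d), tag_id = colnames(d),
                     pos_in_tag = 0L, selection_class = "neutral",
                     fst = NA_real_)
  ## an individual homozygous at every locus has F = 1
  d[1, ] <- ifelse(d[1, ] == 1, 0L, d[1, ])
  g <- genotype_matrix(d, meta)
  f <- inbreeding_F(g)
  expect_equal(f$F[1], 1, tolerance = 1e-12)
  expect_true(all(f$reliable))
  ## selfed individuals (true f = 0.5): mean estimate near 0.5
  est <- replicate(20, {
    p <- runif(200, 0.2, 0.8)
    n <- 50
    u1 <- matrix(rbinom(n * 200, 1, rep(p, each = n)), n, 200)
    ibd <- matrix(runif(n * 200) < 0.5, n, 200)
    u2 <- ifelse(ibd, u1, matrix(rbinom(n * 200, 1, rep(p, each = n)),
                                 n, 200))
    dd <- u1 + u2
    dimnames(dd) <- list(paste0("i", 1:n), paste0("s", 1:200))
    gg <- genotype_matrix(dd, data.frame(
      id = colnames(dd), tag_id = colnames(dd), pos_in_tag = 0L,
      selection_class = "neutral", fst = NA_real_))
    mean(inbreeding_F(gg)$F)
  })
  expect_equal(mean(est), 0.5, tolerance = 0.03)
})

test_that("IBS matrix: identities, arithmetic, and permutation equivariance", {
  d <- rbind(i1 = c(0, 1, 2, 1, 0, 2, 1, 0, 2, 1),
             i2 = c(0, 1, 2, 1, 0, 2, 1, 0, 2, 1),
             i3 = 2 - c(0, 1, 2, 1, 0, 2, 1, 0, 2, 1))
  d3 <- d; d3["i3", ] <- d["i1", ]; d3["i3", 1] <- 1  # one-het difference
  mk <- function(dd) genotype_matrix(dd, data.frame(
    id = paste0("s", 1:10), tag_id = paste0("T", 1:10), pos_in_tag = 0L,
    selection_class = "neutral", fst = NA_real_))
  K <- ibs_matrix(mk(d))
  expect_equal(K["i1", "i2"], 1)
  ## i3 is the complement: IBS = mean (2-|d_i-d_j|)/2; het positions match
  expect_equal(K["i1", "i3"],
               mean((2 - abs(d["i1", ] - d["i3", ])) / 2))
  K3 <- ibs_matrix(mk(d3))
  expect_equal(K3["i1", "i3"], 0.95)
  expect_true(isSymmetric(K))
  expect_equal(unname(diag(K)), rep(1, 3))
  ## permuting individuals permutes rows/columns consistently
  perm <- c(3, 1, 2)
  Kp <- ibs_matrix(mk(d3[perm, ]))
  expect_equal(Kp, K3[perm, perm])
  ## opposite homozygotes at all loci -> 0
  d0 <- rbind(i1 = rep(0L, 10), i2 = rep(2L, 10))
  expect_equal(ibs_matrix(mk(d0))["i1", "i2"], 0)
})

test_that("Weir-Cockerham theta matches an independently coded oracle", {
  ## two-population toy with explicit genotype construction
  set.seed(6)
  mk_pop <- function(n, p) {
    g <- rbinom(n, 2, p)
    g
  }
  d <- c(mk_pop(20, 0.2), mk_pop(20, 0.8))
  dos <- matrix(as.integer(d), ncol = 1,
                dimnames = list(paste0("i", 1:40), "s1"))
  g <- genotype_matrix(dos, data.frame(
    id = "s1", tag_id = "T1", pos_in_tag = 0L,
    selection_class = "neutral", fst = NA_real_))
  grp <- rep(c("A", "B"), each = 20)
  th <- wc_fst(g, grp)
  orc <- wc_theta_oracle(
    n_i = c(20, 20),
    p_i = c(mean(d[1:20]) / 2, mean(d[21:40]) / 2),
    h_i = c(mean(d[1:20] == 1), mean(d[21:40] == 1)))
  expect_equal(as.numeric(th), unname(orc["theta"]), tolerance = 1e-10)
  ## multilocus ratio-of-sums against the oracle components
  set.seed(7)
  dos2 <- cbind(s1 = as.integer(c(mk_pop(15, 0.3), mk_pop(25, 0.6))),
                s2 = as.integer(c(mk_pop(15, 0.5), mk_pop(25, 0.5))),
                s3 = as.integer(c(mk_pop(15, 0.1), mk_pop(25, 0.9))))
  rownames(dos2) <- paste0("i", 1:40)
  g2 <- genotype_matrix(dos2, data.frame(
    id = paste0("s", 1:3), tag_id = paste0("T", 1:3), pos_in_tag = 0L,
    selection_class = "neutral", fst = NA_real_))
  grp2 <- rep(c("A", "B"), c(15, 25))
  comps <- sapply(1:3, function(j) {
    x <- dos2[, j]
    wc_theta_oracle(c(15, 25),
                    c(mean(x[1:15]) / 2, mean(x[16:40]) / 2),
                    c(mean(x[1:15] == 1), mean(x[16:40] == 1)))
  })
  expect_equal(as.numeric(wc_fst(g2, grp2)),
               sum(comps["a", ]) / sum(colSums(comps[c("a", "b", "c"), ])),
               tolerance = 1e-10)
})

test_that("pairwise linearized F_ST: identical tables give 0, fixation caps", {
  set.seed(8)
  half <- hwe_dosage(20, runif(30, 0.3, 0.7))
  d <- rbind(half, half)
  rownames(d) <- paste0("i", 1:40)
  meta <- data.frame(id = colnames(half), tag_id = colnames(half),
                     pos_in_tag = 0L, selection_class = "neutral",
                     fst = NA_real_)
  g <- genotype_matrix(d, meta)
  lin <- pairwise_fst(g, rep(c("A", "B"), each = 20))
  expect_equal(lin["A", "B"], 0)          # negative theta truncated to 0
  expect_lt(abs(attr(lin, "theta")["A", "B"]), 0.05)
  ## fixed alternative alleles at all loci -> theta = 1 -> capped
  dfix <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))
  dimnames(dfix) <- list(paste0("i", 1:20), paste0("s", 1:5))
  gfix <- genotype_matrix(dfix, data.frame(
    id = paste0("s", 1:5), tag_id = paste0("T", 1:5), pos_in_tag = 0L,
    selection_class = "neutral", fst = NA_real_))
  expect_warning(linf <- pairwise_fst(gfix, rep(c("A", "B"), each = 10)),
                 "capped")
  expect_equal(linf["A", "B"], 100)
})

test_that("genotype TSV round-trip preserves dosage and metadata", {
  g <- toy_genotypes()
  path <- tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path)
  expect_equal(g2$dosage, g$dosage)
  expect_equal(g2$snp_meta$tag_id, g$snp_meta$tag_id)
})

test_that("VCF input yields the same dosage matrix as the TSV path", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SEL,Number=1,Type=String,Description=\"class\">",
    "##INFO=<ID=FST,Number=1,Type=Float,Description=\"fst\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2\ti3",
    "T1\t11\tsnp1\tA\tG\t.\tPASS\tSEL=neutral\tGT\t0/0\t0/1\t1/1",
    "T1\t41\tsnp2\tC\tT\t.\tPASS\tSEL=outlier;FST=0.3\tGT\t0/1\t./.\t1|1")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes_vcf(path)
  expect_equal(unname(g$dosage[, "snp1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$dosage[, "snp2"]), c(1L, NA_integer_, 2L))
  expect_equal(g$snp_meta$selection_class, c("neutral", "outlier"))
  expect_equal(g$snp_meta$pos_in_tag, c(10L, 40L))
  expect_equal(g$snp_meta$fst[2], 0.3)
})
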