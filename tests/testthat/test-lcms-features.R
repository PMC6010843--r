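# Feature-table I/O, DModX outlier screening, redundant-peak grouping,
# exact-mass annotation, and log transformation.

test_that("feature-table TSV round-trip and validation", {
  ft <- tiny_feature_table()
  expect_equal(dim(ft$intensity), c(3L, 4L))
  path <- tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  ft2 <- read_feature_table(path)
  expect_equal(ft2$intensity, ft$intensity)
  expect_equal(ft2$mz, ft$mz)
  ## duplicated feature id is a hard error naming the id
  tab <- read.delim(path, check.names = FALSE)
  tab$feature_id[2] <- tab$feature_id[1]
  bad <- tempfile(fileext = ".tsv")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(bad), "f1")
  ## missing intensities read as 0 with a message
  tab2 <- read.delim(path, check.names = FALSE)
  tab2$s1[1] <- NA
  miss <- tempfile(fileext = ".tsv")
  write.table(tab2, miss, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ftm <- read_feature_table(miss), "1 missing")
  expect_equal(unname(ftm$intensity["f1", "s1"]), 0)
  ## non-numeric intensity names the cell
  tab3 <- read.delim(path, check.names = FALSE)
  tab3$s2 <- as.character(tab3$s2); tab3$s2[3] <- "oops"
  badnum <- tempfile(fileext = ".tsv")
  write.table(tab3, badnum, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(badnum), "f3.*s2")
})

test_that("constructor enforces the container invariants", {
  expect_error(feature_table(c("a", "a"), c(100, 200), c(10, 20),
                             matrix(1, 2, 2)), "duplicate")
  expect_error(feature_table(c("a", "b"), c(-1, 200), c(10, 20),
                             matrix(1, 2, 2)), "mz")
  expect_error(feature_table(c("a", "b"), c(100, 200), c(10, 20),
                             matrix(-1, 2, 2)), "nonnegative")
})

test_that("DModX does not flag a duplicated sample but catches planted noise", {
  set.seed(41)
  ## clean cohort with correlated structure + one duplicated sample
  n <- 60; k <- 80
  scores <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(rnorm(3 * k), 3, k)
  X <- scores %*% load + matrix(rnorm(n * k, 0, 0.3), n, k)
  X[n, ] <- X[1, ]  # duplicate
  ft <- feature_table(paste0("f", 1:k), mz = runif(k, 100, 1600),
                      rt = runif(k, 60, 1200),
                      intensity = t(X - min(X)),
                      sample_ids = paste0("s", 1:n))
  out <- dmodx_outliers(ft, n_components = 3, alpha = 0.05)
  expect_false("s60" %in% out)
  ## planted outlier: heavy independent noise in half the features,
  ## detection rate >= 95% over replicates at alpha = 0.05
  hits <- replicate(20, {
    Xr <- scores %*% load + matrix(rnorm(n * k, 0, 0.3), n, k)
    bad <- sample(k, k / 2)
    Xr[7, bad] <- Xr[7, bad] + rnorm(length(bad), 0, 4)
    ftr <- feature_table(paste0("f", 1:k), runif(k, 100, 1600),
                         runif(k, 60, 1200), t(Xr - min(Xr)),
                         paste0("s", 1:n))
    "s7" %in% dmodx_outliers(ftr, n_components = 3, alpha = 0.05)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("grouping applies the RT window and correlation gate", {
  ft <- tiny_feature_table()
  ## f1/f2 perfectly correlated at the same RT, f3 apart
  mt <- group_features(ft, rt_tol = 5, cor_min = 0.9)
  expect_equal(unname(mt$group_of[["f1"]]), unname(mt$group_of[["f2"]]))
  expect_false(mt$group_of[["f3"]] == mt$group_of[["f1"]])
  ## representative is the largest-median member
  g1 <- mt$group_of[["f1"]]
  expect_equal(unname(mt$representative[[g1]]), "f1")
  ## same RT but uncorrelated -> singletons
  inten <- rbind(f1 = c(1, 2, 3, 4), f2 = c(2, -0 + 4, 1, 3))
  ft2 <- feature_table(c("f1", "f2"), c(100, 101), c(300, 300), inten)
  mt2 <- group_features(ft2, rt_tol = 5, cor_min = 0.9)
  expect_equal(length(unique(mt2$group_of)), 2L)
  ## parameter validation
  expect_error(group_features(ft, rt_tol = -1), "rt_tol")
  expect_error(group_features(ft, cor_min = -2), "cor_min")
})

test_that("grouping edge regimes: all singletons vs one component", {
  ft <- tiny_feature_table()
  singles <- group_features(ft, rt_tol = 1e6, cor_min = 1 + 1e-9)
  expect_equal(length(unique(singles$group_of)), 3L)
  one <- group_features(ft, rt_tol = 1e6, cor_min = -1)
  expect_equal(length(unique(one$group_of)), 1L)
  ## partition property: group sizes sum to the feature count
  expect_equal(sum(table(one$group_of)), length(ft$feature_id))
  expect_equal(sum(table(singles$group_of)), length(ft$feature_id))
})

test_that("grouping is invariant to feature and sample order", {
  set.seed(42)
  cfg <- cohort_config(preset = "demo", n_metabolites = 15, n_tags = 10,
                       rt_jitter = 0.05, redundancy_noise_sd = 0.02,
                       dropout_rate = 0, seed = 43)
  met <- simulate_metabolome(cfg, simulate_genotypes(cfg))
  ft <- met$features
  mt <- group_features(ft)
  fperm <- sample(length(ft$feature_id))
  sperm <- sample(length(ft$sample_ids))
  ftp <- feature_table(ft$feature_id[fperm], ft$mz[fperm], ft$rt[fperm],
                       ft$intensity[fperm, sperm],
                       ft$sample_ids[sperm])
  mtp <- group_features(ftp)
  ## same partition (group labels may differ)
  expect_equal(adjusted_rand_index(mt$group_of[ft$feature_id],
                                   mtp$group_of[ft$feature_id]), 1)
  expect_setequal(unname(mt$representative), unname(mtp$representative))
})

test_that("near-zero jitter regroups the synthetic truth exactly (ARI = 1)", {
  ## identifiable truth: only one small pathway, so no two distinct
  ## metabolites are both co-eluting and correlated above the gate
  cfg <- cohort_config(preset = "demo", n_metabolites = 30, n_tags = 10,
                       n_latent_pathways = 1, pathway_size_range = c(3, 3),
                       rt_jitter = 0.05, redundancy_noise_sd = 0.02,
                       dropout_rate = 0, seed = 44)
  met <- simulate_metabolome(cfg, simulate_genotypes(cfg))
  mt <- group_features(met$features)
  truth <- met$truth$group_of[met$features$feature_id]
  found <- mt$group_of[met$features$feature_id]
  expect_equal(adjusted_rand_index(truth, found), 1)
  ## cross-check the ARI utility itself on this nontrivial partition
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(adjusted_rand_index(truth, found),
                 mclust::adjustedRandIndex(truth, found))
})

test_that("exact-mass annotation honors the ppm threshold inclusively", {
  proton <- 1.007276
  db <- data.frame(name = c("compoundA", "compoundB"),
                   mass = c(435.1, 500))
  ft <- feature_table("f1", mz = 435.1 - proton, rt = 100,
                      intensity = matrix(c(5, 6), 1, 2,
                                         dimnames = list("f1", c("s1", "s2"))))
  mt <- group_features(ft, rt_tol = 5, cor_min = -1)
  ann <- annotate_by_mass(mt, db, ppm_max = 10)
  hit <- ann$annotation[[1]]
  expect_equal(hit$name, "compoundA")
  expect_equal(hit$ppm, 0, tolerance = 1e-9)
  ## 25 ppm away -> no match at 10 ppm
  ft2 <- feature_table("f1", mz = 435.1 * (1 + 25e-6) - proton, rt = 100,
                       intensity = matrix(c(5, 6), 1, 2,
                                          dimnames = list("f1", c("s1", "s2"))))
  ann2 <- annotate_by_mass(group_features(ft2, cor_min = -1), db, 10)
  expect_equal(nrow(ann2$annotation[[1]]), 0L)
  ## boundary constructed at exactly 10.0 ppm is retained (<=)
  mz10 <- 435.1 * (1 + 10e-6) - proton
  ft3 <- feature_table("f1", mz = mz10, rt = 100,
                       intensity = matrix(c(5, 6), 1, 2,
                                          dimnames = list("f1", c("s1", "s2"))))
  ann3 <- annotate_by_mass(group_features(ft3, cor_min = -1), db, 10)
  expect_equal(ann3$annotation[[1]]$name, "compoundA")
  expect_equal(ann3$annotation[[1]]$ppm, 10, tolerance = 1e-6)
})

test_that("log transform: anchors, monotonicity, and zero handling", {
  expect_equal(log_transform(matrix(0), offset = 1)[1], 0)
  expect_equal(log_transform(matrix(exp(1) - 1), offset = 1)[1], 1)
  x <- matrix(sort(runif(20, 0, 100)), 4)
  lx <- log_transform(x)
  expect_true(all(diff(as.vector(lx)) >= 0))
  expect_error(log_transform(matrix(-1)), "negative")
  expect_error(log_transform(matrix(0), offset = 0), "offset")
})
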