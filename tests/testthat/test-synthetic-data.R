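# The cohort generator: determinism, emulation targets, and construction
# invariants that downstream modules rely on.

test_that("same seed gives bit-identical cohorts; config is validated", {
  cfg <- cohort_config(preset = "demo", n_tags = 40, n_metabolites = 12,
                       seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$features$intensity, b$features$intensity)
  expect_identical(a$metadata$health_score, b$metadata$health_score)
  expect_error(cohort_config(fst_target = 0), "fst_target")
  expect_error(cohort_config(fst_target = 1.2), "fst_target")
  expect_error(cohort_config(dropout_rate = 1), "dropout_rate")
  expect_error(cohort_config(redundancy_factor = 0.5), "redundancy")
  expect_error(cohort_config(n_subpops = 0), "count")
})

test_that("near-zero differentiation yields pairwise F_ST centered on 0", {
  cfg <- cohort_config(preset = "demo", n_subpops = 2, n_regions = 1,
                       n_tags = 150, fst_target = 1e-6, region_share = 0,
                       missing_rate = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  md <- chemodivgwa:::simulate_metadata(cfg)
  lin <- pairwise_fst(g, md$subpop)
  expect_lt(abs(attr(lin, "theta")[1, 2]), 0.01)
})

test_that("feature count emulates ~2,785 peaks from 377 metabolites", {
  cfg <- cohort_config(individuals_per_subpop = 5, n_tags = 10, seed = 2)
  met <- simulate_metabolome(cfg, simulate_genotypes(cfg))
  nf <- length(met$features$feature_id)
  expect_gt(nf, 2785 * 0.9)
  expect_lt(nf, 2785 * 1.1)
  expect_equal(length(met$truth$metabolite_ids), 377L)
  ## ranges respect the acquisition window
  expect_true(all(met$features$mz >= 100 & met$features$mz <= 1600))
  expect_true(all(met$features$rt >= 60 & met$features$rt <= 1200))
})

test_that("zero noise, zero effects, no dropout makes redundant peaks exact multiples", {
  cfg <- cohort_config(preset = "demo", n_metabolites = 8, n_tags = 10,
                       n_latent_pathways = 1, pathway_size_range = c(3, 3),
                       pathway_noise_sd = 0, baseline_noise_sd = 0,
                       planted_snp_effects = data.frame(
                         snp = character(0), metabolite = character(0),
                         beta = numeric(0)),
                       env_effect_sizes = c(Tcol = 0, Bio14 = 0),
                       dropout_rate = 0, rt_jitter = 0,
                       redundancy_noise_sd = 0, seed = 30)
  met <- simulate_metabolome(cfg, simulate_genotypes(cfg))
  ## within a metabolite group every peak is a fixed multiple of the
  ## representative, so inter-sample correlations are exactly 1
  grp <- met$truth$group_of
  one_group <- names(grp)[grp == grp[[1]]]
  if (length(one_group) > 1) {
    inten <- met$features$intensity[one_group, , drop = FALSE]
    ratios <- inten / rep(inten[1, ], each = nrow(inten))
    expect_equal(apply(ratios, 1, stats::sd), rep(0, nrow(inten)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  ## non-pathway metabolites with all effects off are constant across
  ## samples up to dropout (none here)
  iso <- setdiff(met$truth$metabolite_ids,
                 unlist(met$truth$pathways))
  rep_feat <- met$truth$representative_feature[iso[1]]
  expect_equal(stats::sd(met$features$intensity[rep_feat, ]), 0)
})

test_that("planted pathway X3 = X1 + X2 yields negative partial correlation", {
  ## closed-form sign: conditioning on the sum induces pcor(X1,X2|X3) < 0
  set.seed(31)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- x1 + x2 + rnorm(n, 0, 0.1)
  pc <- solve(stats::cor(cbind(x1, x2, x3)))
  pcor12 <- -pc[1, 2] / sqrt(pc[1, 1] * pc[2, 2])
  expect_lt(pcor12, 0)
  ## generator pathway members share a factor: their conditional
  ## dependence given the rest is positive by construction
  cfg <- cohort_config(preset = "demo", n_metabolites = 10, n_tags = 10,
                       n_latent_pathways = 1, pathway_size_range = c(3, 3),
                       dropout_rate = 0, seed = 32)
  co <- simulate_cohort(cfg)
  pw <- co$truth$pathways[[1]]
  la <- co$truth$log_abundance[, pw]
  om <- solve(stats::cov(la))
  expect_gt(-om[1, 2] / sqrt(om[1, 1] * om[2, 2]), 0)
})

test_that("health generation: null model, planted slope sign, recode identity", {
  cfg0 <- cohort_config(preset = "demo", n_metabolites = 10, n_tags = 10,
                        individuals_per_subpop = 200,
                        disease_model = list(intercept = 0,
                                             f_slope = 0, tcol_slope = 0,
                                             site_sd = 0,
                                             biomarker_slopes = c(met001 = 0)),
                        seed = 33)
  md0 <- chemodivgwa:::simulate_metadata(cfg0)
  met0 <- simulate_metabolome(cfg0, simulate_genotypes(cfg0), md0)
  h0 <- simulate_health(cfg0, met0, md0)
  expect_equal(mean(h0$health_binary), 0.5, tolerance = 0.05)
  ## large positive slope on one biomarker: point-biserial correlation
  ## between that biomarker and health is positive
  cfg1 <- cohort_config(preset = "demo", n_metabolites = 10, n_tags = 10,
                        individuals_per_subpop = 100,
                        disease_model = list(
                          biomarker_slopes = c(met002 = 3),
                          f_slope = 0, tcol_slope = 0, site_sd = 0),
                        seed = 34)
  md1 <- chemodivgwa:::simulate_metadata(cfg1)
  met1 <- simulate_metabolome(cfg1, simulate_genotypes(cfg1), md1)
  h1 <- simulate_health(cfg1, met1, md1)
  r_pb <- stats::cor(met1$truth$log_abundance[, "met002"],
                     h1$health_binary)
  expect_gt(r_pb, 0.2)
  ## construction invariant: recode(score) == generated binary, always
  for (h in list(h0, h1))
    expect_identical(recode_health(h$health_score), h$health_binary)
})

test_that("written cohort round-trips through the real-data readers", {
  cfg <- cohort_config(preset = "demo", n_metabolites = 10, n_tags = 15,
                       seed = 35)
  co <- simulate_cohort(cfg)
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  ft <- read_feature_table(paths[["features"]])
  expect_equal(ft$intensity, co$features$intensity, tolerance = 1e-6)
  g <- read_genotypes(paths[["genotypes"]])
  expect_equal(g$dosage, co$genotypes$dosage)
  md <- read.delim(paths[["metadata"]], stringsAsFactors = FALSE)
  expect_equal(md$health_score, co$metadata$health_score)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_true(all(unlist(truth$snp_effects$snp) %in%
                    co$genotypes$snp_meta$id))
})

test_that("planted effects referencing unknown ids are rejected", {
  cfg <- cohort_config(preset = "demo", n_metabolites = 10, n_tags = 10,
                       planted_snp_effects = data.frame(
                         snp = "nope_1", metabolite = "met001",
                         beta = 1), seed = 36)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_metabolome(cfg, g), "unknown ids")
})
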