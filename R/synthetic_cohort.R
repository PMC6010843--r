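# Synthetic cohort generator: genotypes, metabolome, environment, and health
# with recorded ground truth, emulating a multi-subpopulation tree cohort
# (6 collection sites in 3 ecoregions, ~30 trees each) profiled by untargeted
# LC-MS and genotyped at biallelic SNPs on short GBS tags.

#' Configuration for a synthetic cohort
#'
#' Builds the parameter set controlling every stage of cohort simulation:
#' population structure, SNP panel layout, metabolome covariance (latent
#' biosynthetic pathways), planted SNP and environment effects, and the
#' disease model. Defaults emulate the field-study design this package
#' targets: 6 subpopulations in 3 ecoregions, 30 trees per subpopulation,
#' 377 metabolites expanding to roughly 2,785 redundant LC-MS features.
#'
#' @param n_subpops number of subpopulations (collection sites).
#' @param n_regions number of ecoregions; subpopulations are split evenly
#'   across regions and share a regional allele-frequency draw, so genetic
#'   structure mirrors geography.
#' @param individuals_per_subpop trees sampled per subpopulation.
#' @param n_tags number of GBS tags.
#' @param snps_per_tag SNPs simulated on each tag.
#' @param fst_target total Balding-Nichols differentiation among
#'   subpopulations, in (0,1). A fraction `region_share` of it acts between
#'   regions, the rest between subpopulations within a region.
#' @param region_share fraction of `fst_target` attributed to the
#'   between-region level (0 disables the hierarchy).
#' @param n_metabolites number of true metabolites.
#' @param redundancy_factor mean number of redundant peaks (isotopes,
#'   adducts, fragments) per metabolite; 7.39 reproduces ~2,785 features
#'   from 377 metabolites.
#' @param n_latent_pathways number of latent biosynthetic pathways; each
#'   pathway's member metabolites share a latent factor, which defines the
#'   true partial-correlation (GGM) support as within-pathway cliques.
#' @param pathway_size_range inclusive range of pathway sizes (metabolites).
#' @param pathway_noise_sd residual log-abundance SD of pathway members
#'   (controls within-pathway correlation; 0.3 gives marginal r near 0.9).
#' @param baseline_noise_sd residual log-abundance SD of non-pathway
#'   metabolites.
#' @param planted_snp_effects data.frame with columns `snp`, `metabolite`,
#'   `beta` (effect on log abundance per dosage unit), or NULL for the
#'   default planting (one outlier-tag SNP hitting two metabolites of the
#'   first pathway, plus one further SNP-metabolite pair).
#' @param env_effect_sizes named vector of slopes on log abundance for the
#'   environmental covariates `Tcol` (deg C) and `Bio14` (mm).
#' @param env_affected_frac named vector: fraction of metabolites affected
#'   by each covariate.
#' @param disease_model list with `intercept` (log-odds of health at the
#'   cohort mean), `biomarker_slopes` (named by metabolite id; NULL for the
#'   default trio whose dominant member drives health), `f_slope`,
#'   `tcol_slope`, `site_sd` (random-intercept SD).
#' @param dropout_rate probability a metabolite is undetected (zero) in a
#'   sample, in \[0,1).
#' @param missing_rate genotype missingness rate.
#' @param outlier_tag_fraction fraction of tags labeled "outlier"
#'   (putatively under selection).
#' @param inbreeding either a length-2 Beta(a,b) parameter vector for
#'   per-individual inbreeding coefficients, or a single constant value.
#' @param rt_jitter SD (seconds) of retention-time scatter of redundant
#'   peaks around their metabolite's RT.
#' @param redundancy_noise_sd log-scale intensity noise of redundant peaks
#'   relative to the representative peak (near 0 makes peaks within a group
#'   near-perfectly correlated).
#' @param tag_length GBS tag length in bases.
#' @param seed integer seed; per-stage substreams are derived from it.
#' @param preset "paper" (the defaults) or "demo", a scaled-down cohort
#'   (50 metabolites, 200 tags x 2 SNPs) used for fast end-to-end runs.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subpops = 6L,
                          n_regions = 3L,
                          individuals_per_subpop = 30L,
                          n_tags = 1000L,
                          snps_per_tag = 2L,
                          fst_target = 0.05,
                          region_share = 0.5,
                          n_metabolites = 377L,
                          redundancy_factor = 7.39,
                          n_latent_pathways = 25L,
                          pathway_size_range = c(3L, 6L),
                          pathway_noise_sd = 0.3,
                          baseline_noise_sd = 0.5,
                          planted_snp_effects = NULL,
                          env_effect_sizes = c(Tcol = 0.05, Bio14 = 0.01),
                          env_affected_frac = c(Tcol = 0.3, Bio14 = 0.2),
                          disease_model = list(),
                          dropout_rate = 0.05,
                          missing_rate = 0.05,
                          outlier_tag_fraction = 0.1,
                          inbreeding = c(1, 19),
                          rt_jitter = 1,
                          redundancy_noise_sd = 0.05,
                          tag_length = 90L,
                          seed = 1L,
                          preset = c("paper", "demo")) {
  preset <- match.arg(preset)
  if (preset == "demo") {
    if (missing(n_metabolites)) n_metabolites <- 50L
    if (missing(n_tags)) n_tags <- 200L
    if (missing(n_latent_pathways)) n_latent_pathways <- 10L
  }
  counts <- c(n_subpops = n_subpops, n_regions = n_regions,
              individuals_per_subpop = individuals_per_subpop,
              n_tags = n_tags, snps_per_tag = snps_per_tag,
              n_metabolites = n_metabolites,
              n_latent_pathways = n_latent_pathways)
  if (any(counts < 1)) abort("all counts must be positive")
  if (!(fst_target > 0 && fst_target < 1))
    abort("fst_target must lie in (0,1)")
  check_prob(region_share, "region_share")
  if (!(dropout_rate >= 0 && dropout_rate < 1))
    abort("dropout_rate must lie in [0,1)")
  if (redundancy_factor < 1) abort("redundancy_factor must be >= 1")
  dm <- utils::modifyList(
    list(intercept = stats::qlogis(0.81), biomarker_slopes = NULL,
         f_slope = -4, tcol_slope = 0.15, site_sd = 0.5),
    disease_model)
  cfg <- list(
    n_subpops = as.integer(n_subpops), n_regions = as.integer(n_regions),
    individuals_per_subpop = as.integer(individuals_per_subpop),
    n_tags = as.integer(n_tags), snps_per_tag = as.integer(snps_per_tag),
    fst_target = fst_target, region_share = region_share,
    n_metabolites = as.integer(n_metabolites),
    redundancy_factor = redundancy_factor,
    n_latent_pathways = as.integer(n_latent_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    pathway_noise_sd = pathway_noise_sd,
    baseline_noise_sd = baseline_noise_sd,
    planted_snp_effects = planted_snp_effects,
    env_effect_sizes = env_effect_sizes,
    env_affected_frac = env_affected_frac,
    disease_model = dm,
    dropout_rate = dropout_rate, missing_rate = missing_rate,
    outlier_tag_fraction = outlier_tag_fraction,
    inbreeding = inbreeding,
    rt_jitter = rt_jitter, redundancy_noise_sd = redundancy_noise_sd,
    tag_length = as.integer(tag_length),
    seed = as.integer(seed), preset = preset)
  class(cfg) <- "cohort_config"
  cfg
}

## Sample metadata: subpopulation/region layout, planar site coordinates,
## and site-level environmental covariates.  Region centers are spread along
## a transect (mountain -> piedmont -> coast); Tcol increases and Bio14
## decreases along it, so environment correlates with geography and with
## genetic structure, as in the field design.
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(stage_seed(config$seed, "metadata"), {
    ns <- config$n_subpops
    n_per <- config$individuals_per_subpop
    region_of <- ceiling(seq_len(ns) / (ns / config$n_regions))
    region_of <- pmin(region_of, config$n_regions)
    centers_x <- seq(0, 100, length.out = config$n_regions)
    site_x <- centers_x[region_of] + stats::runif(ns, -8, 8)
    site_y <- stats::runif(ns, -10, 10)
    ## environmental gradients along the transect + site-level noise
    tcol_site <- 18 + 0.08 * site_x + stats::rnorm(ns, 0, 1)
    bio14_site <- 55 - 0.25 * site_x + stats::rnorm(ns, 0, 3)
    fb <- config$inbreeding
    n <- ns * n_per
    f_true <- if (length(fb) == 1L) rep(fb, n) else stats::rbeta(n, fb[1], fb[2])
    subpop <- rep(paste0("S", seq_len(ns)), each = n_per)
    data.frame(
      sample_id = sprintf("S%d_%02d", rep(seq_len(ns), each = n_per),
                          rep(seq_len(n_per), ns)),
      subpop = subpop,
      region = paste0("R", rep(region_of, each = n_per)),
      x = rep(site_x, each = n_per), y = rep(site_y, each = n_per),
      Tcol = rep(tcol_site, each = n_per),
      Bio14 = rep(bio14_site, each = n_per),
      F_true = f_true,
      stringsAsFactors = FALSE)
  })
}

#' Simulate genotypes under a (hierarchical) Balding-Nichols model
#'
#' Subpopulation allele frequencies are drawn around an ancestral frequency
#' `p` as Beta((1-F)/F * p, (1-F)/F * (1-p)). When the configuration has
#' more than one region and `region_share > 0`, the draw is hierarchical:
#' regional frequencies first, then subpopulation frequencies within each
#' region, with the two levels composing to the total `fst_target`.
#' Individual genotypes allow a per-individual inbreeding coefficient f
#' (the second gamete is identical by descent with probability f).
#'
#' @param config a [cohort_config()].
#' @param metadata optional metadata as from the internal metadata stage;
#'   regenerated from `config` when omitted.
#' @return a `genotype_matrix` (see [genotype_matrix()]) with true per-SNP
#'   differentiation stored in `snp_meta$fst` and the true subpopulation
#'   allele frequencies in `attr(, "subpop_freq")`.
#' @export
simulate_genotypes <- function(config, metadata = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(metadata)) metadata <- simulate_metadata(config)
  with_seed(stage_seed(config$seed, "genotypes"), {
    L <- config$n_tags * config$snps_per_tag
    ns <- config$n_subpops
    p_anc <- stats::runif(L, 0.1, 0.9)
    f_a <- config$fst_target * config$region_share
    f_b <- (config$fst_target - f_a) / (1 - f_a)
    bn_draw <- function(p, f) {
      if (f <= 0) return(p)
      a <- (1 - f) / f
      stats::rbeta(length(p), a * p, a * (1 - p))
    }
    region_of_sub <- ceiling(seq_len(ns) / (ns / config$n_regions))
    region_of_sub <- pmin(region_of_sub, config$n_regions)
    if (config$n_regions > 1 && f_a > 0) {
      p_region <- vapply(seq_len(config$n_regions),
                         function(r) bn_draw(p_anc, f_a), numeric(L))
      p_sub <- vapply(seq_len(ns),
                      function(s) bn_draw(p_region[, region_of_sub[s]], f_b),
                      numeric(L))
    } else {
      p_sub <- vapply(seq_len(ns),
                      function(s) bn_draw(p_anc, config$fst_target),
                      numeric(L))
    }
    p_sub <- pmin(pmax(p_sub, 1e-6), 1 - 1e-6)  # guard Beta boundary draws
    n <- nrow(metadata)
    sub_idx <- as.integer(factor(metadata$subpop,
                                 levels = paste0("S", seq_len(ns))))
    dosage <- matrix(NA_integer_, n, L)
    for (i in seq_len(n)) {
      p_i <- p_sub[, sub_idx[i]]
      u1 <- stats::rbinom(L, 1L, p_i)
      ibd <- stats::runif(L) < metadata$F_true[i]
      u2 <- ifelse(ibd, u1, stats::rbinom(L, 1L, p_i))
      dosage[i, ] <- u1 + u2
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * L) < config$missing_rate
      dosage[matrix(miss, n, L)] <- NA_integer_
    }
    snp_ids <- sprintf("B%d_%d", rep(seq_len(config$n_tags),
                                     each = config$snps_per_tag),
                       seq_len(config$snps_per_tag))
    tag_id <- sprintf("B%d", rep(seq_len(config$n_tags),
                                 each = config$snps_per_tag))
    pos <- unlist(lapply(seq_len(config$n_tags), function(t)
      sort(sample.int(config$tag_length, config$snps_per_tag) - 1L)))
    outlier_tags <- sample.int(config$n_tags,
                               round(config$outlier_tag_fraction *
                                       config$n_tags))
    sel_class <- ifelse(rep(seq_len(config$n_tags),
                            each = config$snps_per_tag) %in% outlier_tags,
                        "outlier", "neutral")
    ## true per-SNP differentiation from the generating frequencies
    pbar <- rowMeans(p_sub)
    fst_true <- apply(p_sub, 1, stats::var) * (ns - 1) / ns /
      (pbar * (1 - pbar))
    dimnames(dosage) <- list(metadata$sample_id, snp_ids)
    g <- genotype_matrix(
      dosage = dosage,
      snp_meta = data.frame(id = snp_ids, tag_id = tag_id, pos_in_tag = pos,
                            selection_class = sel_class, fst = fst_true,
                            stringsAsFactors = FALSE),
      tag_length = config$tag_length)
    attr(g, "subpop_freq") <- p_sub
    g
  })
}

default_planted_effects <- function(config, genotypes, pathways) {
  out_snps <- genotypes$snp_meta$id[
    genotypes$snp_meta$selection_class == "outlier"]
  if (length(out_snps) < 2L) out_snps <- genotypes$snp_meta$id
  mets <- sprintf("met%03d", seq_len(config$n_metabolites))
  pw1 <- pathways[[1]]
  third <- setdiff(seq_len(config$n_metabolites), unlist(pathways))[1]
  if (is.na(third)) third <- setdiff(seq_len(config$n_metabolites), pw1)[1]
  data.frame(
    snp = c(out_snps[1], out_snps[1], out_snps[2]),
    metabolite = c(mets[pw1[1]], mets[pw1[2]], mets[third]),
    beta = c(0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

#' Simulate an untargeted LC-MS metabolome with known structure
#'
#' Log abundance of each metabolite is baseline + latent-pathway loadings
#' (the pathways define the true partial-correlation graph as within-pathway
#' cliques) + planted SNP effects + environmental covariate effects +
#' Gaussian noise. Intensities are exponentiated, per-sample dropout zeros
#' applied, and each metabolite expanded into 1..k redundant peaks sharing
#' its retention time (plus jitter) with near-perfectly correlated
#' intensities and distinct m/z offsets (isotopes/adducts), within the
#' instrument ranges 100-1,600 m/z and 60-1,200 s RT.
#'
#' @param config a [cohort_config()].
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param metadata metadata data.frame; regenerated when omitted.
#' @return list with `features` (a [feature_table()]) and `truth`, the
#'   recorded ground truth: the feature-to-metabolite map, the planted GGM
#'   adjacency, the planted SNP effect map, per-sample latent pathway
#'   scores, the true metabolite log-abundance matrix, and metabolite m/z
#'   and RT assignments.
#' @export
simulate_metabolome <- function(config, genotypes, metadata = NULL) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(genotypes, "genotype_matrix"))
  if (is.null(metadata)) metadata <- simulate_metadata(config)
  with_seed(stage_seed(config$seed, "metabolome"), {
    n <- nrow(metadata)
    m <- config$n_metabolites
    mets <- sprintf("met%03d", seq_len(m))

    ## latent pathways: disjoint member sets
    sz <- seq(config$pathway_size_range[1], config$pathway_size_range[2])
    sizes <- sz[sample.int(length(sz), config$n_latent_pathways,
                           replace = TRUE)]
    avail <- sample.int(m)
    pathways <- list(); used <- 0L
    for (k in seq_len(config$n_latent_pathways)) {
      if (used + sizes[k] > m) break
      pathways[[k]] <- sort(avail[(used + 1L):(used + sizes[k])])
      used <- used + sizes[k]
    }

    planted <- config$planted_snp_effects
    if (is.null(planted))
      planted <- default_planted_effects(config, genotypes, pathways)
    if (nrow(planted) > 0) {
      bad_snp <- setdiff(planted$snp, genotypes$snp_meta$id)
      bad_met <- setdiff(planted$metabolite, mets)
      if (length(bad_snp) || length(bad_met))
        abort("planted effect references unknown ids: %s",
              paste(c(bad_snp, bad_met), collapse = ", "))
    }

    baseline <- stats::runif(m, 8, 14)
    noise_sd <- rep(config$baseline_noise_sd, m)
    in_pathway <- sort(unlist(pathways))
    noise_sd[in_pathway] <- config$pathway_noise_sd

    Z <- matrix(stats::rnorm(n * length(pathways)), n, length(pathways))
    logab <- matrix(rep(baseline, each = n), n, m,
                    dimnames = list(metadata$sample_id, mets))
    for (k in seq_along(pathways)) {
      load_k <- stats::runif(length(pathways[[k]]), 0.9, 1.1)
      logab[, pathways[[k]]] <- logab[, pathways[[k]]] +
        Z[, k] %*% t(load_k)
    }

    ## environmental effects on centered covariates
    env_idx <- list()
    for (cv in names(config$env_effect_sizes)) {
      frac <- config$env_affected_frac[[cv]]
      idx <- sample.int(m, round(frac * m))
      env_idx[[cv]] <- idx
      x <- metadata[[cv]] - mean(metadata[[cv]])
      logab[, idx] <- logab[, idx] + config$env_effect_sizes[[cv]] * x
    }

    ## planted SNP effects (missing dosages act through the mean)
    if (nrow(planted) > 0) {
      for (r in seq_len(nrow(planted))) {
        d <- genotypes$dosage[, planted$snp[r]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        logab[, planted$metabolite[r]] <-
          logab[, planted$metabolite[r]] + planted$beta[r] * (d - mean(d))
      }
    }

    if (any(noise_sd > 0))
      logab <- logab + matrix(stats::rnorm(n * m), n, m) %*% diag(noise_sd)

    intensity_met <- exp(logab)
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * m) < config$dropout_rate, n, m)
      intensity_met[drop] <- 0
    }

    ## metabolite m/z and RT, then expansion into redundant peaks
    mz_met <- stats::runif(m, 110, 1500)
    rt_met <- stats::runif(m, 70, 1190)
    k_m <- 1L + stats::rpois(m, max(config$redundancy_factor - 1, 0))
    offsets <- c(1.00336, 2.00671, -18.0106, 46.0055, 21.9819, 67.9874,
                 -46.0055, 35.9767, 112.9856, 132.0423)
    feat_met <- integer(0); feat_mz <- numeric(0); feat_rt <- numeric(0)
    feat_scale <- numeric(0)
    for (j in seq_len(m)) {
      k <- k_m[j]
      off <- if (k > 1) {
        ## isotope/adduct offsets; repeats shifted by further isotope
        ## spacings so m/z values stay distinct
        base_off <- sample(offsets, k - 1L, replace = k - 1L > length(offsets))
        base_off + 1.00336 * (seq_len(k - 1L) - 1L) %/% length(offsets)
      } else numeric(0)
      mzs <- c(mz_met[j], mz_met[j] + off)
      rts <- c(rt_met[j],
               rt_met[j] + stats::rnorm(k - 1L, 0, config$rt_jitter))
      feat_met <- c(feat_met, rep(j, k))
      feat_mz <- c(feat_mz, pmin(pmax(mzs, 100), 1600))
      feat_rt <- c(feat_rt, pmin(pmax(rts, 60), 1200))
      feat_scale <- c(feat_scale,
                      1, if (k > 1) stats::runif(k - 1L, 0.1, 0.85))
    }
    nf <- length(feat_met)
    noise_f <- if (config$redundancy_noise_sd > 0) {
      matrix(exp(stats::rnorm(nf * n, 0, config$redundancy_noise_sd)), nf, n)
    } else matrix(1, nf, n)
    intensity <- t(intensity_met)[feat_met, , drop = FALSE] *
      feat_scale * noise_f
    feat_ids <- sprintf("M%dT%d", round(feat_mz), round(feat_rt))
    feat_ids <- make.unique(feat_ids, sep = "_")
    dimnames(intensity) <- list(feat_ids, metadata$sample_id)

    adjacency <- matrix(0L, m, m, dimnames = list(mets, mets))
    for (pw in pathways) adjacency[pw, pw] <- 1L
    diag(adjacency) <- 0L

    features <- feature_table(feature_id = feat_ids, mz = feat_mz,
                              rt = feat_rt, intensity = intensity)
    truth <- list(
      group_of = stats::setNames(mets[feat_met], feat_ids),
      metabolite_ids = mets,
      representative_feature = stats::setNames(
        feat_ids[!duplicated(feat_met)], mets),
      log_abundance = logab,
      pathways = lapply(pathways, function(p) mets[p]),
      pathway_scores = Z,
      ggm_adjacency = adjacency,
      snp_effects = planted,
      env_affected = lapply(env_idx, function(i) mets[i]),
      mz = stats::setNames(mz_met, mets),
      rt = stats::setNames(rt_met, mets),
      subpop_freq = attr(genotypes, "subpop_freq"))
    list(features = features, truth = truth)
  })
}

#' Simulate health states from biomarker abundances and covariates
#'
#' Binary health is drawn from a logistic model on the true biomarker log
#' abundances, the individual inbreeding coefficient F, temperature at
#' collection (Tcol), and a site random intercept. The non-intercept part
#' of the linear predictor is centered over the cohort so the intercept
#' sets the healthy fraction directly. A 1-5 ordinal canopy score is then
#' derived by quantile-binning the linear predictor within each binary
#' class (diseased -> 1-3, healthy -> 4-5), so that recoding the score
#' reproduces the generated binary state exactly.
#'
#' @param config a [cohort_config()].
#' @param metabolome output of [simulate_metabolome()].
#' @param metadata metadata data.frame (must carry `F_true`, `Tcol`,
#'   `subpop`).
#' @return `metadata` with columns `health_binary` (1 = healthy) and
#'   `health_score` (1-5) appended; the realized disease-model
#'   coefficients (including biomarker choice and site effects) are in
#'   `attr(, "disease_truth")`.
#' @export
simulate_health <- function(config, metabolome, metadata) {
  stopifnot(inherits(config, "cohort_config"))
  dm <- config$disease_model
  truth <- metabolome$truth
  with_seed(stage_seed(config$seed, "health"), {
    slopes <- dm$biomarker_slopes
    if (is.null(slopes)) {
      ## default biomarker trio: the first pathway's members, with the
      ## dominant (highest-baseline) member driving health
      pw <- truth$pathways[[1]][1:3]
      dom <- pw[which.max(colMeans(truth$log_abundance[, pw, drop = FALSE]))]
      slopes <- stats::setNames(rep(0, 3), pw)
      slopes[dom] <- 1.5
    }
    X <- truth$log_abundance[, names(slopes), drop = FALSE]
    site <- factor(metadata$subpop)
    u_site <- stats::rnorm(nlevels(site), 0, dm$site_sd)
    eta_raw <- drop(X %*% slopes) + dm$f_slope * metadata$F_true +
      dm$tcol_slope * metadata$Tcol + u_site[as.integer(site)]
    eta <- dm$intercept + eta_raw - mean(eta_raw)
    healthy <- stats::rbinom(length(eta), 1L, stats::plogis(eta))
    score <- integer(length(eta))
    for (cls in c(0L, 1L)) {
      idx <- which(healthy == cls)
      if (!length(idx)) next
      k <- if (cls == 0L) 3L else 2L
      q <- stats::quantile(eta[idx], probs = seq_len(k - 1L) / k, type = 1)
      bins <- findInterval(eta[idx], q, left.open = TRUE) + 1L
      score[idx] <- bins + if (cls == 1L) 3L else 0L
    }
    metadata$health_binary <- healthy
    metadata$health_score <- score
    attr(metadata, "disease_truth") <- list(
      intercept = dm$intercept, biomarker_slopes = slopes,
      f_slope = dm$f_slope, tcol_slope = dm$tcol_slope,
      site_sd = dm$site_sd, site_effects = u_site,
      centering = mean(eta_raw))
    metadata
  })
}

#' Simulate a complete cohort
#'
#' Runs metadata, genotype, metabolome, and health generation in order and
#' bundles the results with the recorded ground truth.
#'
#' @param config a [cohort_config()].
#' @return list with elements `config`, `metadata`, `genotypes`,
#'   `features`, `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  metadata <- simulate_metadata(config)
  genotypes <- simulate_genotypes(config, metadata)
  metab <- simulate_metabolome(config, genotypes, metadata)
  metadata <- simulate_health(config, metab, metadata)
  truth <- metab$truth
  truth$disease <- attr(metadata, "disease_truth")
  list(config = config, metadata = metadata, genotypes = genotypes,
       features = metab$features, truth = truth)
}

#' Write a synthetic cohort to disk in the real-data input formats
#'
#' Emits the same formats the analysis path reads: an XCMS-dialect
#' feature-table TSV, a genotype dosage TSV with tag metadata columns, a
#' sample metadata TSV, and a ground-truth JSON.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    features = file.path(dir, "feature_table.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json"))
  write_feature_table(cohort$features, paths[["features"]])
  write_genotypes(cohort$genotypes, paths[["genotypes"]])
  utils::write.table(cohort$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$log_abundance <- NULL  # matrices regenerable from config + seed
  truth$pathway_scores <- NULL
  truth$subpop_freq <- NULL
  truth$ggm_adjacency <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
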