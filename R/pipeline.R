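# End-to-end orchestration: fixed stage order, JSON manifests with input
# hashes, and hash-based resumability.

#' Pipeline configuration
#'
#' Bundles input paths (or a simulate block), per-stage parameters, the
#' output directory, and the global seed. In simulate mode the cohort is
#' generated first and written in the same formats the real-data path
#' reads.
#'
#' @param out_dir output directory.
#' @param seed global seed; stages derive independent substreams.
#' @param simulate a [cohort_config()] for simulate mode, or NULL.
#' @param features,genotypes,metadata input paths (ignored in simulate
#'   mode).
#' @param params named list of stage-parameter overrides; recognised
#'   entries (with defaults): dmodx_components 2, dmodx_alpha 0.05,
#'   rt_tol 5, cor_min 0.75, maf_min 0.05, call_rate_min 0.8,
#'   hwe_alpha 0.05, mantel_perm 9999, mantel_boot 500, anosim_perm 999,
#'   gwa_alpha 0.05, ggm_q 0.05, rf_trees 1000, rf_top_k 12,
#'   log_offset 1.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            features = NULL, genotypes = NULL,
                            metadata = NULL, params = list()) {
  defaults <- list(dmodx_components = 2L, dmodx_alpha = 0.05, rt_tol = 5,
                   cor_min = 0.75, maf_min = 0.05, call_rate_min = 0.8,
                   hwe_alpha = 0.05, mantel_perm = 9999L,
                   mantel_boot = 500L, anosim_perm = 999L,
                   gwa_alpha = 0.05, ggm_q = 0.05, rf_trees = 1000L,
                   rf_top_k = 12L, log_offset = 1)
  params <- utils::modifyList(defaults, params)
  if (is.null(simulate)) {
    for (p in c(features, genotypes, metadata))
      if (!file.exists(p)) abort("input file not found: %s", p)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, features = features,
                 genotypes = genotypes, metadata = metadata,
                 params = params),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognises top-level keys `out_dir`, `seed`, `inputs`
#' (features/genotypes/metadata paths), `simulate` (cohort_config
#' arguments, or `preset: demo`), and `params`.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(cohort_config, y$simulate)
  pipeline_config(out_dir = y$out_dir %||% ".",
                  seed = y$seed %||% 1L,
                  simulate = sim,
                  features = y$inputs$features,
                  genotypes = y$inputs$genotypes,
                  metadata = y$inputs$metadata,
                  params = y$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.param_string <- function(params) {
  as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

.stage_fresh <- function(manifest_path, inputs, outputs, params) {
  if (!file.exists(manifest_path)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  man <- tryCatch(jsonlite::read_json(manifest_path),
                  error = function(e) NULL)
  if (is.null(man)) return(FALSE)
  cur <- .hash_files(inputs)
  old <- man$input_hashes
  if (length(old) != length(cur)) return(FALSE)
  if (!identical(old[sort(names(old))], cur[sort(names(cur))]))
    return(FALSE)
  identical(man$param_string, .param_string(params))
}

.write_manifest <- function(manifest_path, stage, inputs, outputs, params,
                            seed) {
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         version = as.character(utils::packageVersion("chemodivgwa")),
         executed_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         param_string = .param_string(params),
         input_hashes = .hash_files(inputs),
         outputs = outputs),
    manifest_path, auto_unbox = TRUE, digits = NA)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (optional) -> features -> diversity ->
#' popgen -> structure -> gwa (four covariate configurations) -> network
#' -> biomarkers. Every stage writes its outputs plus a JSON manifest
#' with input hashes, parameters, and the seed; a stage is skipped when
#' its outputs exist and its recorded input hashes and parameters still
#' match (so corrupting an intermediate re-executes exactly the
#' downstream stages). A stage failure halts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns stage, status ("executed" or
#'   "skipped"), invisible attribute `outputs` listing key result paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  man_dir <- file.path(out, "manifests")
  dir.create(man_dir, showWarnings = FALSE)
  P <- config$params
  status <- list()

  paths <- list(
    features = config$features, genotypes = config$genotypes,
    metadata = config$metadata)

  run_stage <- function(name, inputs, outputs, params, fun) {
    mp <- file.path(man_dir, paste0(name, ".json"))
    if (.stage_fresh(mp, unlist(inputs), unlist(outputs), params)) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      abort("stage '%s' failed: %s (log: %s)", name, conditionMessage(e), mp)
    })
    .write_manifest(mp, name, unlist(inputs), unlist(outputs), params,
                    config$seed)
    status[[name]] <<- "executed"
  }

  ## ---- simulate -------------------------------------------------------
  if (!is.null(config$simulate)) {
    in_dir <- file.path(out, "input")
    sim_out <- file.path(in_dir, c("feature_table.tsv", "genotypes.tsv",
                                   "metadata.tsv", "truth.json"))
    sim_params <- config$simulate[setdiff(names(config$simulate),
                                          "planted_snp_effects")]
    run_stage("simulate", character(0), sim_out, sim_params, function() {
      cfg <- config$simulate
      cfg$seed <- stage_seed(config$seed, "cohort")
      write_cohort(simulate_cohort(cfg), in_dir)
    })
    paths$features <- sim_out[1]
    paths$genotypes <- sim_out[2]
    paths$metadata <- sim_out[3]
  }

  meta <- utils::read.delim(paths$metadata, stringsAsFactors = FALSE)

  ## ---- features -------------------------------------------------------
  f_out <- file.path(out, c("metabolites.tsv", "group_map.json",
                            "outlier_samples.txt"))
  run_stage("features", paths$features, f_out,
            P[c("dmodx_components", "dmodx_alpha", "rt_tol", "cor_min")],
            function() {
    ft <- read_feature_table(paths$features)
    outl <- dmodx_outliers(ft, P$dmodx_components, P$dmodx_alpha)
    writeLines(as.character(outl), f_out[3])
    keep <- setdiff(ft$sample_ids, outl)
    ft2 <- feature_table(ft$feature_id, ft$mz, ft$rt,
                         ft$intensity[, keep, drop = FALSE], keep)
    mt <- group_features(ft2, rt_tol = P$rt_tol, cor_min = P$cor_min)
    tab <- data.frame(group = rownames(mt$intensity),
                      representative = mt$representative,
                      mz = mt$mz, rt = mt$rt, check.names = FALSE)
    utils::write.table(cbind(tab, as.data.frame(mt$intensity)), f_out[1],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(mt$group_of), f_out[2], auto_unbox = TRUE)
  })

  read_metab <- function() {
    raw <- utils::read.delim(f_out[1], check.names = FALSE,
                             stringsAsFactors = FALSE)
    inten <- as.matrix(raw[setdiff(names(raw),
                                   c("group", "representative", "mz", "rt"))])
    rownames(inten) <- raw$group
    list(intensity = inten, info = raw[c("group", "representative",
                                         "mz", "rt")])
  }

  ## ---- diversity ------------------------------------------------------
  d_out <- file.path(out, c("diversity_profiles.tsv",
                            "alpha_gamma_richness.tsv"))
  run_stage("diversity", f_out[1], d_out, list(), function() {
    mt <- read_metab()
    prof <- diversity_profiles(mt$intensity)
    utils::write.table(prof, d_out[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    grp <- meta$subpop[match(colnames(mt$intensity), meta$sample_id)]
    utils::write.table(alpha_gamma_richness(mt$intensity, grp), d_out[2],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  ## ---- popgen ---------------------------------------------------------
  g_out <- file.path(out, c("kinship.tsv", "inbreeding.tsv",
                            "diversity_genetic.tsv", "fst_linearized.tsv",
                            "panel_association.tsv", "panel_neutral.tsv",
                            "filter_report.tsv"))
  run_stage("popgen", paths$genotypes, g_out,
            P[c("maf_min", "call_rate_min", "hwe_alpha")], function() {
    g <- read_genotypes(paths$genotypes)
    grp <- meta$subpop[match(g$sample_ids, meta$sample_id)]
    gf <- filter_snps(g, P$maf_min, P$call_rate_min, P$hwe_alpha, grp)
    rep_tab <- attr(gf, "filter_report")
    utils::write.table(data.frame(filter = names(rep_tab),
                                  count = as.integer(rep_tab)),
                       g_out[7], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    panels <- select_one_snp_per_tag(gf)
    write_genotypes(panels$association, g_out[5])
    write_genotypes(panels$neutral, g_out[6])
    K <- ibs_matrix(panels$neutral)
    utils::write.table(K, g_out[1], sep = "\t", quote = FALSE)
    utils::write.table(inbreeding_F(panels$neutral), g_out[2], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    het <- heterozygosity(panels$neutral, grp, n_boot = 200L)
    pi <- nucleotide_diversity(panels$neutral, grp)
    ar <- rarefied_allelic_richness(panels$neutral, grp)
    gd <- Reduce(function(a, b) merge(a, b, by = "subpop"),
                 list(het, pi, ar))
    utils::write.table(gd, g_out[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(pairwise_fst(panels$neutral, grp), g_out[4],
                       sep = "\t", quote = FALSE)
  })

  ## ---- structure ------------------------------------------------------
  s_out <- file.path(out, c("mantel_tests.tsv", "dapc_genetic.tsv",
                            "dapc_metabolic.tsv"))
  run_stage("structure", c(f_out[1], g_out[6]), s_out,
            P[c("mantel_perm", "mantel_boot", "anosim_perm")], function() {
    with_seed(stage_seed(config$seed, "structure"), {
      mt <- read_metab()
      la <- log_transform(mt$intensity, P$log_offset)
      gn <- read_genotypes(g_out[6])
      dm <- subpop_distance_matrices(meta, la, gn,
                                     n_perm = P$anosim_perm)
      formulas <- list(
        c("metabolic", "geographic", NA), c("genetic", "geographic", NA),
        c("metabolic", "genetic", NA), c("metabolic", "Tcol", NA),
        c("metabolic", "Bio14", NA),
        c("metabolic", "genetic", "geographic"),
        c("metabolic", "genetic", "Tcol"),
        c("metabolic", "genetic", "Bio14"))
      rows <- lapply(formulas, function(f) {
        mt_res <- mantel(dm[[f[1]]], dm[[f[2]]],
                         n_perm = P$mantel_perm, n_boot = P$mantel_boot,
                         conditioning = if (is.na(f[3])) NULL else
                           dm[[f[3]]])
        data.frame(a = f[1], b = f[2],
                   conditioning = ifelse(is.na(f[3]), "", f[3]),
                   r = mt_res$r, p = mt_res$p,
                   ci_lo = if (is.null(mt_res$ci)) NA else mt_res$ci[1],
                   ci_hi = if (is.null(mt_res$ci)) NA else mt_res$ci[2])
      })
      utils::write.table(do.call(rbind, rows), s_out[1], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      grp_g <- meta$subpop[match(gn$sample_ids, meta$sample_id)]
      dg <- gn$dosage
      dg[is.na(dg)] <- rep(colMeans(dg, na.rm = TRUE),
                           each = nrow(dg))[is.na(dg)]
      dp_g <- dapc(dg, groups = grp_g)
      write_dapc <- function(dp, path, ids) {
        co <- if (is.null(dp$coords)) dp$pc_scores else dp$coords
        utils::write.table(
          data.frame(sample_id = ids, assignment = dp$assignments, co),
          path, sep = "\t", quote = FALSE, row.names = FALSE)
      }
      write_dapc(dp_g, s_out[2], gn$sample_ids)
      grp_m <- meta$subpop[match(colnames(la), meta$sample_id)]
      dp_m <- dapc(t(la), groups = grp_m)
      write_dapc(dp_m, s_out[3], colnames(la))
    })
  })

  ## ---- gwa ------------------------------------------------------------
  w_out <- file.path(out, c("gwa_results.tsv", "gwa_qq.tsv",
                            "gwa_overlap.json"))
  run_stage("gwa", c(f_out[1], g_out[5], g_out[1], d_out[1]), w_out,
            P["gwa_alpha"], function() {
    mt <- read_metab()
    la <- log_transform(mt$intensity, P$log_offset)
    ga <- read_genotypes(g_out[5])
    K <- as.matrix(utils::read.delim(g_out[1], check.names = FALSE))
    prof <- utils::read.delim(d_out[1], stringsAsFactors = FALSE)
    samples <- intersect(colnames(la), ga$sample_ids)
    traits <- cbind(t(la[, samples, drop = FALSE]),
                    richness = prof$S[match(samples, prof$sample_id)])
    mmeta <- meta[match(samples, meta$sample_id), ]
    res <- gwa_all_configs(traits, ga$dosage[samples, , drop = FALSE],
                           K[samples, samples], mmeta,
                           alpha = P$gwa_alpha)
    utils::write.table(res, w_out[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(attr(res, "qq"), w_out[2], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(overlap_summary(res), w_out[3],
                         auto_unbox = TRUE)
  })

  ## ---- network --------------------------------------------------------
  n_out <- file.path(out, c("network.graphml", "ggm_edges.tsv",
                            "gwa_edges.tsv"))
  run_stage("network", c(f_out[1], w_out[1]), n_out, P["ggm_q"],
            function() {
    mt <- read_metab()
    la <- log_transform(mt$intensity, P$log_offset)
    ggm <- shrinkage_pcor(t(la), q_max = P$ggm_q)
    res <- utils::read.delim(w_out[1], stringsAsFactors = FALSE)
    ga <- read_genotypes(g_out[5])
    net <- integrate_network(ggm, res, snp_meta = ga$snp_meta)
    write_network(net, out)
  })

  ## ---- biomarkers -----------------------------------------------------
  b_out <- file.path(out, c("rf_ranking.tsv", "logistic_fits.tsv",
                            "subset_chemodiv_fits.tsv"))
  run_stage("biomarkers", c(f_out[1], n_out[2]), b_out,
            P[c("rf_trees", "rf_top_k")], function() {
    mt <- read_metab()
    la <- log_transform(mt$intensity, P$log_offset)
    samples <- colnames(la)
    mmeta <- meta[match(samples, meta$sample_id), ]
    y <- recode_health(mmeta$health_score)
    rf <- rf_biomarkers(t(la), y, n_trees = P$rf_trees,
                        top_k = P$rf_top_k,
                        seed = stage_seed(config$seed, "rf"))
    utils::write.table(rf$ranking, b_out[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    covs <- data.frame(F = if ("F_true" %in% names(mmeta)) mmeta$F_true
                       else mmeta$F, Tcol = mmeta$Tcol)
    fits <- lapply(rownames(la), function(m) {
      ft <- tryCatch(suppressWarnings(
        logistic_mixed(y, mt$intensity[m, samples], covs, mmeta$subpop)),
        error = function(e) NULL)
      if (is.null(ft)) return(NULL)
      foc <- ft$coefficients[ft$coefficients$term == "focal", ]
      data.frame(metabolite = m, estimate = foc$estimate, se = foc$se,
                 z = foc$z, p = foc$p, converged = ft$converged)
    })
    utils::write.table(do.call(rbind, fits), b_out[2], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ## chemodiversity of the GGM group around the top biomarker
    edges <- utils::read.delim(n_out[2], stringsAsFactors = FALSE)
    top <- rf$ranking$metabolite[1]
    subset_ids <- unique(c(top, edges$to[edges$from == top],
                           edges$from[edges$to == top]))
    if (length(subset_ids) < 2)
      subset_ids <- rf$ranking$metabolite[1:3]
    sub_fits <- subset_chemodiv_models(mt$intensity[, samples], subset_ids,
                                       y, covs, mmeta$subpop)
    rows <- lapply(names(sub_fits), function(ix) {
      f <- sub_fits[[ix]]
      if (is.character(f))
        return(data.frame(index = ix, estimate = NA, se = NA, z = NA,
                          p = NA, note = f))
      foc <- f$coefficients[f$coefficients$term == "focal", ]
      data.frame(index = ix, estimate = foc$estimate, se = foc$se,
                 z = foc$z, p = foc$p, note = "")
    })
    out_tab <- do.call(rbind, rows)
    attr(out_tab, "subset") <- subset_ids
    utils::write.table(cbind(out_tab,
                             subset = paste(subset_ids, collapse = ",")),
                       b_out[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  res <- data.frame(stage = names(status),
                    status = unlist(status), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "outputs") <- list(
    input = paths, features = f_out, diversity = d_out, popgen = g_out,
    structure = s_out, gwa = w_out, network = n_out, biomarkers = b_out)
  res
}
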