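# Health-state recoding, logistic mixed models for single metabolites and
# chemodiversity indices, and random-forest biomarker ranking.

#' Recode a 1-5 canopy health score to the binary state
#'
#' Scores 4 and 5 are healthy; 1, 2, 3 are diseased.
#'
#' @param score integer vector with values in 1..5.
#' @return integer vector, 1 = healthy, 0 = diseased.
#' @export
recode_health <- function(score) {
  if (any(!score %in% 1:5)) abort("health scores must be integers in 1..5")
  as.integer(score >= 4)
}

#' Logistic mixed model for a focal predictor of health
#'
#' Random-intercept logistic regression of binary health on a focal
#' predictor (a metabolite log abundance or a chemodiversity index),
#' controlling for the inbreeding coefficient F and temperature at
#' collection Tcol, with a random intercept per collection site, fit by
#' Laplace-approximate maximum likelihood (lme4). Interaction terms are
#' deliberately not included. Significance of the focal coefficient is a
#' Wald z test.
#'
#' @param y binary health (1 = healthy).
#' @param focal numeric focal predictor.
#' @param covariates data.frame or matrix with columns `F` and `Tcol`
#'   (further columns are included as additional fixed effects).
#' @param site collection-site grouping factor.
#' @return list of class `mixed_logistic_fit`: `coefficients` (data.frame
#'   term, estimate, se, z, p), `site_sd`, `converged`, `n`, `messages`.
#' @export
logistic_mixed <- function(y, focal, covariates, site) {
  if (length(unique(stats::na.omit(focal))) < 2)
    abort("focal predictor is constant: no information")
  site <- factor(site)
  if (nlevels(site) < 2) abort("need >= 2 sites for a random intercept")
  y <- as.integer(y)
  ## complete-separation screen on the focal predictor
  if (length(unique(y)) == 2) {
    r0 <- range(focal[y == 0], na.rm = TRUE)
    r1 <- range(focal[y == 1], na.rm = TRUE)
    if (r0[2] < r1[1] || r1[2] < r0[1])
      abort("complete separation on the focal predictor")
  }
  dat <- data.frame(y = y, focal = focal, as.data.frame(covariates),
                    site = site)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  covs <- setdiff(names(dat), c("y", "focal", "site"))
  form <- stats::reformulate(c("focal", covs, "(1 | site)"), response = "y")
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = dat, family = stats::binomial()),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    !any(grepl("failed to converge", msgs))
  res <- list(
    coefficients = data.frame(
      term = rownames(sm), estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"], z = sm[, "z value"],
      p = sm[, "Pr(>|z|)"], stringsAsFactors = FALSE, row.names = NULL),
    site_sd = sqrt(unlist(lme4::VarCorr(fit))[["site"]]),
    converged = converged, n = nrow(dat), messages = msgs)
  class(res) <- "mixed_logistic_fit"
  res
}

#' @export
print.mixed_logistic_fit <- function(x, ...) {
  cat(sprintf("mixed_logistic_fit (n = %d, site SD = %.3f%s)\n", x$n,
              x$site_sd, if (x$converged) "" else ", NOT converged"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Random-forest biomarker ranking
#'
#' Classifies binary health from log metabolite abundances with a random
#' forest and ranks metabolites by out-of-bag permutation importance
#' (mean decrease in accuracy). The direction of each biomarker is the
#' sign of the healthy-minus-diseased mean log abundance.
#'
#' @param log_abundance sample-by-metabolite matrix.
#' @param y binary health (1 = healthy).
#' @param n_trees trees in the forest (default 1000).
#' @param top_k size of the selected biomarker set (default 12).
#' @param seed integer seed for the forest.
#' @return list of class `biomarker_ranking`: `ranking` (data.frame
#'   metabolite, importance, rank, direction, selected), `oob_error`,
#'   `forest`.
#' @export
rf_biomarkers <- function(log_abundance, y, n_trees = 1000L, top_k = 12L,
                          seed = 1L) {
  X <- as.matrix(log_abundance)
  if (length(unique(y)) < 2) abort("both health classes must be present")
  yf <- factor(y, levels = c(0, 1), labels = c("diseased", "healthy"))
  rf <- with_seed(seed,
    randomForest::randomForest(x = X, y = yf, ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  direction <- sign(colMeans(X[y == 1, , drop = FALSE]) -
                      colMeans(X[y == 0, , drop = FALSE]))
  rk <- rank(-imp, ties.method = "first")
  ranking <- data.frame(
    metabolite = colnames(X), importance = unname(imp),
    rank = unname(rk), direction = unname(direction),
    selected = unname(rk) <= top_k, stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$rank), ]
  rownames(ranking) <- NULL
  res <- list(ranking = ranking,
              oob_error = unname(rf$err.rate[n_trees, "OOB"]),
              forest = rf)
  class(res) <- "biomarker_ranking"
  res
}

#' @export
print.biomarker_ranking <- function(x, ...) {
  cat(sprintf("biomarker_ranking: OOB error %.3f; top metabolites:\n",
              x$oob_error))
  print(utils::head(x$ranking, 5), digits = 3)
  invisible(x)
}

#' Logistic mixed models with subset chemodiversity as the predictor
#'
#' Recomputes the six chemodiversity indices (S, H, D1, D2, E, BP) from a
#' metabolite subset (e.g. a GGM-associated compound group) and fits
#' [logistic_mixed()] with each index as the focal predictor. An index
#' constant across samples (e.g. richness with no dropout) is skipped
#' with a reason.
#'
#' @param abundance metabolite-by-sample raw intensity matrix.
#' @param subset metabolite ids (>= 2) defining the group.
#' @param y binary health per sample.
#' @param covariates data.frame with columns `F` and `Tcol`.
#' @param site collection-site factor.
#' @return list of class `subset_chemodiv_fits`: per index either a
#'   `mixed_logistic_fit` or a character reason for skipping; the index
#'   table is in `attr(, "indices")`.
#' @export
subset_chemodiv_models <- function(abundance, subset, y, covariates,
                                   site) {
  if (length(subset) < 2) abort("subset needs >= 2 metabolites")
  prof <- subset_diversity(as.matrix(abundance), subset)
  fits <- list()
  for (idx in c("S", "H", "D1", "D2", "E", "BP")) {
    v <- prof[[idx]]
    ok <- !is.na(v)
    if (length(unique(v[ok])) < 2) {
      fits[[idx]] <- sprintf("skipped: %s constant across samples", idx)
      next
    }
    fits[[idx]] <- tryCatch(
      logistic_mixed(y[ok], v[ok],
                     as.data.frame(covariates)[ok, , drop = FALSE],
                     site[ok]),
      error = function(e) sprintf("skipped: %s", conditionMessage(e)))
  }
  attr(fits, "indices") <- prof
  class(fits) <- "subset_chemodiv_fits"
  fits
}
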