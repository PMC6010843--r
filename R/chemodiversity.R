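# Per-sample chemodiversity indices on metabolite relative abundances, with
# alpha/gamma richness decomposition over subpopulations and subset-restricted
# recalculation.

#' Chemodiversity profile of one sample
#'
#' Community-ecology diversity indices applied to a sample's metabolite
#' abundances. The detected set is the entries strictly above
#' `detection_threshold`; relative abundances p_i are normalized over it.
#' Indices: richness S, Shannon entropy H = -sum p_i ln p_i (nats), Hill
#' number D1 = exp(H), inverse Simpson D2 = 1 / sum p_i^2, Pielou evenness
#' E = H / ln S (NA when S <= 1), and Berger-Parker dominance BP = max p_i.
#'
#' @param abundances nonnegative numeric vector over metabolites (raw
#'   intensities, not log).
#' @param detection_threshold intensity above which a metabolite counts as
#'   detected (default 0: any positive aligned peak).
#' @return one-row data.frame with columns S, H, D1, D2, E, BP.
#' @export
diversity_profile <- function(abundances, detection_threshold = 0) {
  x <- as.numeric(abundances)
  if (any(!is.finite(x)) || any(x < 0)) abort("abundances must be >= 0")
  detected <- x > detection_threshold
  if (!any(detected)) abort("empty metabolome: no metabolite detected")
  p <- x[detected] / sum(x[detected])
  S <- sum(detected)
  H <- -sum(p * log(p))
  data.frame(S = S, H = H, D1 = exp(H), D2 = 1 / sum(p^2),
             E = if (S > 1) H / log(S) else NA_real_, BP = max(p))
}

#' Chemodiversity profiles for all samples of a matrix
#'
#' @param abundance metabolite-by-sample nonnegative matrix.
#' @param detection_threshold see [diversity_profile()].
#' @return data.frame with one row per sample (column `sample_id` first).
#' @export
diversity_profiles <- function(abundance, detection_threshold = 0) {
  abundance <- as.matrix(abundance)
  ids <- colnames(abundance)
  if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(abundance)))
  out <- do.call(rbind, lapply(seq_len(ncol(abundance)), function(j)
    diversity_profile(abundance[, j], detection_threshold)))
  cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), out)
}

#' Alpha and gamma richness per subpopulation
#'
#' Alpha richness is the mean per-sample metabolite count within a
#' subpopulation (with a 95% t-interval over samples); gamma richness is
#' the number of metabolites detected in at least one sample of the
#' subpopulation.
#'
#' @param abundance metabolite-by-sample nonnegative matrix.
#' @param grouping vector of subpopulation labels, one per sample.
#' @param detection_threshold see [diversity_profile()].
#' @return data.frame with columns subpop, n, alpha, alpha_lo, alpha_hi,
#'   gamma (CI columns NA when a subpopulation has fewer than 2 samples).
#' @export
alpha_gamma_richness <- function(abundance, grouping,
                                 detection_threshold = 0) {
  abundance <- as.matrix(abundance)
  if (length(grouping) != ncol(abundance))
    abort("grouping must assign every sample to a subpopulation")
  detected <- abundance > detection_threshold
  S <- colSums(detected)
  groups <- unique(as.character(grouping))
  out <- lapply(groups, function(gp) {
    idx <- which(grouping == gp)
    a <- mean(S[idx])
    if (length(idx) >= 2 && stats::sd(S[idx]) > 0) {
      ci <- stats::t.test(S[idx])$conf.int
    } else ci <- c(NA_real_, NA_real_)
    data.frame(subpop = gp, n = length(idx), alpha = a,
               alpha_lo = ci[1], alpha_hi = ci[2],
               gamma = sum(rowSums(detected[, idx, drop = FALSE]) > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chemodiversity profile restricted to a metabolite subset
#'
#' Recomputes the indices after restricting to `subset` and renormalizing
#' relative abundances within it; used e.g. to quantify dominance within a
#' biosynthetically related compound group.
#'
#' @param abundances named nonnegative vector over metabolites, or a
#'   metabolite-by-sample matrix with rownames (then one profile per
#'   sample is returned).
#' @param subset metabolite ids to keep (must exist).
#' @param detection_threshold see [diversity_profile()].
#' @return as [diversity_profile()] / [diversity_profiles()]; a sample in
#'   which no subset metabolite is detected yields S = 0 and NA indices.
#' @export
subset_diversity <- function(abundances, subset, detection_threshold = 0) {
  if (!length(subset)) abort("subset must be nonempty")
  if (is.matrix(abundances)) {
    missing_ids <- setdiff(subset, rownames(abundances))
    if (length(missing_ids))
      abort("unknown metabolite ids: %s", paste(missing_ids, collapse = ", "))
    sub <- abundances[subset, , drop = FALSE]
    rows <- lapply(seq_len(ncol(sub)), function(j) {
      x <- sub[, j]
      if (!any(x > detection_threshold)) {
        data.frame(S = 0L, H = NA_real_, D1 = NA_real_, D2 = NA_real_,
                   E = NA_real_, BP = NA_real_)
      } else diversity_profile(x, detection_threshold)
    })
    ids <- colnames(sub)
    if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(sub)))
    return(cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE),
                 do.call(rbind, rows)))
  }
  missing_ids <- setdiff(subset, names(abundances))
  if (length(missing_ids))
    abort("unknown metabolite ids: %s", paste(missing_ids, collapse = ", "))
  x <- abundances[subset]
  if (!any(x > detection_threshold))
    return(data.frame(S = 0L, H = NA_real_, D1 = NA_real_, D2 = NA_real_,
                      E = NA_real_, BP = NA_real_))
  diversity_profile(x, detection_threshold)
}
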