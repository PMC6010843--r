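# Aligned LC-MS peak tables: construction, I/O, multivariate sample-outlier
# screening (DModX), redundant-peak grouping, exact-mass annotation, and log
# transformation.

#' Construct a feature table
#'
#' Container for an aligned untargeted LC-MS peak table: features (peaks
#' defined by m/z, retention time, and intensity) by samples.
#'
#' @param feature_id unique feature identifiers.
#' @param mz mass-to-charge ratios (Da/e), positive.
#' @param rt retention times in seconds, nonnegative.
#' @param intensity nonnegative feature-by-sample matrix of peak areas.
#' @param sample_ids sample identifiers; defaults to `colnames(intensity)`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(feature_id, mz, rt, intensity,
                          sample_ids = colnames(intensity)) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    abort("duplicate feature ids: %s",
          paste(unique(feature_id[duplicated(feature_id)]), collapse = ", "))
  intensity <- as.matrix(intensity)
  if (length(feature_id) != nrow(intensity) ||
      length(mz) != nrow(intensity) || length(rt) != nrow(intensity))
    abort("feature_id, mz, rt must match the intensity row count")
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(intensity)))
  if (length(sample_ids) != ncol(intensity))
    abort("sample_ids must match the intensity column count")
  if (any(!is.finite(mz)) || any(mz <= 0)) abort("mz must be positive")
  if (any(!is.finite(rt)) || any(rt < 0)) abort("rt must be nonnegative")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    abort("intensities must be finite and nonnegative")
  dimnames(intensity) <- list(feature_id, sample_ids)
  structure(list(feature_id = feature_id, mz = as.numeric(mz),
                 rt = as.numeric(rt), intensity = intensity,
                 sample_ids = as.character(sample_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples\n",
              nrow(x$intensity), ncol(x$intensity)))
  cat(sprintf("  m/z %.1f-%.1f, RT %.0f-%.0fs\n",
              min(x$mz), max(x$mz), min(x$rt), max(x$rt)))
  invisible(x)
}

#' Read an aligned peak table from a tab-separated export
#'
#' Expects the XCMS-export dialect: a header line with columns
#' `feature_id` (or the first column as row id), `mz`, `rt`, then one
#' intensity column per sample. Missing intensities are read as 0 (counted
#' in a message); non-numeric intensities are a hard error naming the cell.
#'
#' @param path path to the TSV file.
#' @param dialect table dialect; only `"xcms"` is supported.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, dialect = "xcms") {
  dialect <- match.arg(dialect, "xcms")
  if (!file.exists(path)) abort("file not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- names(raw)
  id_col <- if ("feature_id" %in% cols) "feature_id" else cols[1]
  for (need in c("mz", "rt"))
    if (!need %in% cols) abort("column '%s' missing from %s", need, path)
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids))
    abort("duplicate feature id in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sample_cols <- setdiff(cols, c(id_col, "mz", "rt"))
  if (!length(sample_cols)) abort("no sample columns in %s", path)
  inten <- as.matrix(raw[sample_cols])
  if (!is.numeric(inten)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(inten), nrow(inten)))) & !is.na(inten),
      arr.ind = TRUE)[1, , drop = TRUE]
    abort("non-numeric intensity at feature '%s', sample '%s'",
          ids[bad[1]], sample_cols[bad[2]])
  }
  n_missing <- sum(is.na(inten))
  if (n_missing > 0) {
    message(sprintf("read_feature_table: %d missing intensities set to 0",
                    n_missing))
    inten[is.na(inten)] <- 0
  }
  feature_table(ids, raw$mz, raw$rt, inten, sample_cols)
}

#' Write a feature table as an XCMS-dialect TSV
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  out <- data.frame(feature_id = table$feature_id, mz = table$mz,
                    rt = table$rt, check.names = FALSE)
  out <- cbind(out, as.data.frame(table$intensity, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Flag multivariate outlier samples by distance to a PCA model (DModX)
#'
#' Features are autoscaled (zero mean, unit variance per feature), a PCA
#' model with `n_components` components is fit, and each sample's
#' normalized orthogonal residual distance is computed as
#' DModX_i = sqrt(SS_i / (K - A)) / s0, where K is the feature count, A the
#' number of components, and s0 the pooled residual standard deviation.
#' Samples whose squared DModX exceeds the upper `alpha` critical value of
#' the F distribution with (K - A) and (n - A - 1)(K - A) degrees of
#' freedom are flagged.
#'
#' @param table a [feature_table()].
#' @param n_components PCA components retained (default 2).
#' @param alpha significance level of the F screen (default 0.05).
#' @return character vector of flagged sample ids; per-sample DModX values
#'   and the critical value are attached as attributes `dmodx` and
#'   `critical`.
#' @export
dmodx_outliers <- function(table, n_components = 2L, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  X <- t(table$intensity)  # samples x features
  n <- nrow(X)
  A <- as.integer(n_components)
  if (A < 1L || n <= A) abort("need n_samples > n_components >= 1")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep))
    warning(sprintf("dmodx_outliers: %d constant features excluded",
                    sum(!keep)))
  X <- scale(X[, keep, drop = FALSE])
  K <- ncol(X)
  if (K <= A) abort("need more variable features than components")
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(A), drop = FALSE]
  load <- pc$rotation[, seq_len(A), drop = FALSE]
  resid <- X - scores %*% t(load)
  ss <- rowSums(resid^2)
  s0 <- sqrt(sum(ss) / ((n - A - 1) * (K - A)))
  dmodx <- sqrt(ss / (K - A)) / s0
  crit <- stats::qf(1 - alpha, K - A, (n - A - 1) * (K - A))
  flagged <- table$sample_ids[dmodx^2 > crit]
  structure(flagged, dmodx = stats::setNames(dmodx, table$sample_ids),
            critical = sqrt(crit))
}

#' Collapse redundant peaks into metabolite groups
#'
#' One metabolite typically yields several aligned peaks (isotopes,
#' adducts, in-source fragments) sharing retention time and showing highly
#' correlated intensities. Features are connected by an edge when their RT
#' difference is at most `rt_tol` seconds and the Pearson correlation of
#' their intensities across samples is at least `cor_min`; groups are the
#' connected components, and each group is represented by its member with
#' the largest median intensity across samples (ties: larger mean, then
#' lexicographic feature id).
#'
#' @param table a [feature_table()].
#' @param rt_tol retention-time tolerance in seconds (default 5).
#' @param cor_min minimum Pearson correlation (default 0.75).
#' @return a `metabolite_table`: list with `group_of` (feature -> group),
#'   `representative` (group -> feature), `intensity` (group-by-sample
#'   matrix of representative-peak intensities), `mz`, `rt` of
#'   representatives, `sample_ids`, and empty `annotation`.
#' @export
group_features <- function(table, rt_tol = 5, cor_min = 0.75) {
  stopifnot(inherits(table, "feature_table"))
  if (rt_tol < 0) abort("rt_tol must be >= 0")
  if (cor_min < -1) abort("cor_min must be >= -1")  # > 1 => all singletons
  if (ncol(table$intensity) < 2) abort("need >= 2 samples for correlation")
  nf <- length(table$feature_id)
  ## candidate pairs within the RT window, then the correlation gate
  ord <- order(table$rt)
  edges_from <- integer(0); edges_to <- integer(0)
  rt_s <- table$rt[ord]
  suppressWarnings(cors <- stats::cor(t(table$intensity)))
  for (a in seq_len(nf)) {
    b <- a + 1L
    while (b <= nf && rt_s[b] - rt_s[a] <= rt_tol) {
      i <- ord[a]; j <- ord[b]
      cc <- cors[i, j]
      if (!is.na(cc) && cc >= cor_min) {
        edges_from <- c(edges_from, i); edges_to <- c(edges_to, j)
      }
      b <- b + 1L
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = table$feature_id[edges_from],
               to = table$feature_id[edges_to]),
    directed = FALSE,
    vertices = data.frame(name = table$feature_id))
  comp <- igraph::components(g)$membership[table$feature_id]
  ## stable group ids ordered by first member's position in the table
  first <- tapply(seq_len(nf), comp, min)
  relabel <- stats::setNames(rank(first, ties.method = "first"),
                             names(first))
  group_idx <- relabel[as.character(comp)]
  group_ids <- sprintf("G%04d", group_idx)
  meds <- apply(table$intensity, 1, stats::median)
  means <- rowMeans(table$intensity)
  rep_of <- vapply(split(seq_len(nf), group_ids), function(members) {
    o <- order(-meds[members], -means[members], table$feature_id[members])
    table$feature_id[members[o[1]]]
  }, character(1))
  groups <- sort(unique(group_ids))
  rep_idx <- match(rep_of[groups], table$feature_id)
  inten <- table$intensity[rep_idx, , drop = FALSE]
  rownames(inten) <- groups
  structure(list(
    group_of = stats::setNames(group_ids, table$feature_id),
    representative = rep_of[groups],
    intensity = inten,
    mz = stats::setNames(table$mz[rep_idx], groups),
    rt = stats::setNames(table$rt[rep_idx], groups),
    sample_ids = table$sample_ids,
    annotation = NULL), class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d groups from %d features, %d samples\n",
              nrow(x$intensity), length(x$group_of), ncol(x$intensity)))
  invisible(x)
}

#' Annotate metabolite groups by exact mass
#'
#' Assuming negative-ion mode with deprotonated molecules, the candidate
#' neutral mass of each representative peak is m/z + 1.007276. All
#' compounds in the database whose monoisotopic neutral mass is within
#' `ppm_max` parts per million are reported, sorted by ppm error.
#'
#' @param metabolites a `metabolite_table` from [group_features()].
#' @param compound_db data.frame with columns `name` and `mass`
#'   (monoisotopic neutral mass, Da).
#' @param ppm_max mass tolerance in ppm (default 10).
#' @return the `metabolite_table` with `annotation` set: a named list of
#'   data.frames (name, mass, ppm) per group; empty match lists are valid.
#' @export
annotate_by_mass <- function(metabolites, compound_db, ppm_max = 10) {
  stopifnot(inherits(metabolites, "metabolite_table"))
  if (!all(c("name", "mass") %in% names(compound_db)) ||
      nrow(compound_db) == 0)
    abort("compound_db must be a nonempty table with columns name, mass")
  proton <- 1.007276
  ann <- lapply(names(metabolites$mz), function(gid) {
    neutral <- metabolites$mz[[gid]] + proton
    ppm <- abs(compound_db$mass - neutral) / compound_db$mass * 1e6
    hit <- which(ppm <= ppm_max + 1e-9)  # inclusive, float-safe
    hit <- hit[order(ppm[hit])]
    data.frame(name = compound_db$name[hit], mass = compound_db$mass[hit],
               ppm = ppm[hit], stringsAsFactors = FALSE)
  })
  metabolites$annotation <- stats::setNames(ann, names(metabolites$mz))
  metabolites
}

#' Log-transform metabolite intensities
#'
#' Elementwise natural log of intensity + offset. Zeros (not-detected
#' metabolites) require a positive offset.
#'
#' @param metabolites a `metabolite_table`, or a nonnegative matrix.
#' @param offset additive offset in intensity units (default 1).
#' @return metabolite-by-sample matrix of log abundances (natural-log
#'   units).
#' @export
log_transform <- function(metabolites, offset = 1) {
  inten <- if (inherits(metabolites, "metabolite_table"))
    metabolites$intensity else as.matrix(metabolites)
  if (any(inten < 0)) abort("negative intensity")
  if (any(inten == 0) && offset <= 0)
    abort("offset must be > 0 when zeros are present")
  log(inten + offset)
}
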