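#' Default Biolog GEN III plate layout
#'
#' Role of each of the 96 wells (1-based, row-major, A1 = 1 ... H12 = 96):
#' one negative-control well anchoring the 70 metabolic assays, one
#' positive-control well anchoring the 22 chemical-sensitivity assays, and
#' the two tetrazolium-dye wells 86 and 94, which develop color in every
#' sample and are excluded from analysis. The default places the negative
#' control at well 1 and the positive control at well 72; any layout with the
#' same role partition (70 + 1 + 22 + 1 + 2 = 96) can be supplied instead.
#'
#' @param negative_control,positive_control,dye_wells well indices.
#' @return data frame with columns `well` (1..96) and `role` (one of
#'   `"metabolic"`, `"negative_control"`, `"chemical"`, `"positive_control"`,
#'   `"dye"`).
#' @export
gen3_layout <- function(negative_control = 1, positive_control = 72,
                        dye_wells = c(86, 94)) {
  role <- rep("", 96)
  role[negative_control] <- "negative_control"
  role[positive_control] <- "positive_control"
  role[dye_wells] <- "dye"
  block1 <- setdiff(seq_len(71), c(negative_control, positive_control, dye_wells))
  block2 <- setdiff(72:96, c(negative_control, positive_control, dye_wells))
  role[block1] <- "metabolic"
  role[block2] <- "chemical"
  layout <- data.frame(well = 1:96, role = role)
  validate_layout(layout)
}

validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout), all(c("well", "role") %in% names(layout)))
  if (!setequal(layout$well, 1:96)) stop_config("layout must cover wells 1..96")
  tab <- table(layout$role)
  want <- c(metabolic = 70L, negative_control = 1L, chemical = 22L,
            positive_control = 1L, dye = 2L)
  got <- suppressWarnings(as.integer(tab[names(want)]))
  if (anyNA(got) || !all(got == want))
    stop_config("layout roles must partition 96 wells as 70+1+22+1+2")
  layout[order(layout$well), ]
}

feature_names <- function(layout) {
  met <- layout$well[layout$role == "metabolic"]
  chem <- layout$well[layout$role == "chemical"]
  c(sprintf("met_W%02d", met), sprintf("chem_W%02d", chem))
}

#' Normalize one Biolog plate to its 92-feature phenotype vector
#'
#' Metabolic features are the well minus the plate's negative control;
#' chemical-sensitivity features are the positive control minus the well (so
#' larger values mean stronger inhibition). The two control wells and the two
#' dye wells are dropped, leaving exactly 92 named features in a fixed order.
#' Both normalizations are within-plate differences, so a constant offset on
#' all 96 wells cancels.
#'
#' @param od numeric vector of 96 well OD590 readings (well order 1..96).
#' @param layout a [gen3_layout()]-style layout.
#' @return named numeric vector of 92 features.
#' @export
normalize_plate <- function(od, layout = gen3_layout()) {
  layout <- validate_layout(layout)
  if (length(od) != 96 || any(!is.finite(od)))
    stop_config("a plate must have 96 finite well values")
  nc <- od[layout$well[layout$role == "negative_control"]]
  pc <- od[layout$well[layout$role == "positive_control"]]
  met <- od[layout$well[layout$role == "metabolic"]] - nc
  chem <- pc - od[layout$well[layout$role == "chemical"]]
  stats::setNames(c(met, chem), feature_names(layout))
}

#' Normalize every plate of a plate set
#'
#' @param plates a `biolog_plates` object (see [generate_biolog_plates()]) or
#'   a list with `od` (n x 96 matrix, rownames = plate ids) and `meta`.
#' @param layout plate layout.
#' @return n x 92 feature matrix with plate ids as rownames.
#' @export
normalize_plates <- function(plates, layout = gen3_layout()) {
  od <- plates$od
  out <- t(apply(od, 1, normalize_plate, layout = layout))
  colnames(out) <- feature_names(validate_layout(layout))
  out
}

#' Flag and impute inconsistent replicate wells
#'
#' Within each (strain, temperature) replicate set, a well reading is flagged
#' as inconsistent when its deviation from the leave-one-out mean of its
#' replicates (standardized by `sqrt(n/(n-1))` so it is on the noise-SD
#' scale) exceeds `threshold` times the set's typical replicate noise (the
#' larger of that well's leave-one-out SD and the median leave-one-out SD
#' across all wells). The default threshold of 5 makes false flags on clean
#' Gaussian replicates essentially impossible across a whole plate set while
#' still catching gross well failures instantly.
#' Flagged readings are replaced by the mean of the remaining replicates and
#' the imputation is recorded. Automatic flagging needs at least 3
#' replicates (with 2 the deviant one is unidentifiable); for 2 replicates an
#' explicit `flags` table must be supplied. If every replicate of a well is
#' flagged the set is unusable and an error is raised.
#'
#' @param plates a `biolog_plates`-style object (`od` matrix + `meta`).
#' @param threshold multiple of the noise scale that triggers a flag.
#' @param flags optional data frame (`plate_id`, `well`) of manually flagged
#'   readings, bypassing automatic detection.
#' @return the plate set with corrected `od` and an `imputed` data frame
#'   (`plate_id`, `well`, `original`, `imputed`) recording every change.
#' @export
qc_impute <- function(plates, threshold = 5, flags = NULL) {
  od <- plates$od
  meta <- plates$meta
  key <- interaction(meta$strain_id, meta$temperature_C, drop = TRUE)
  log <- list()
  for (grp in levels(key)) {
    rows <- which(key == grp)
    if (length(rows) < 2)
      stop_config("replicate set %s has fewer than 2 plates", grp)
    sub <- od[rows, , drop = FALSE]
    n <- nrow(sub)
    if (is.null(flags)) {
      if (n < 3) stop_config(
        "automatic flagging needs >= 3 replicates (set %s has %d); supply flags",
        grp, n)
      loo_mean <- (matrix(colSums(sub), n, 96, byrow = TRUE) - sub) / (n - 1)
      dev <- abs(sub - loo_mean) / sqrt(n / (n - 1))
      loo_sd <- sqrt(pmax(
        (matrix(colSums(sub^2), n, 96, byrow = TRUE) - sub^2 -
           (n - 1) * loo_mean^2) / (n - 2), 0))
      # the median of an SD from n-1 replicates underestimates sigma; undo
      # the chi-square median bias so the threshold is on the sigma scale
      consistency <- sqrt(stats::qchisq(0.5, n - 2) / (n - 2))
      scale0 <- stats::median(loo_sd[loo_sd > 0]) / consistency
      if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1e-8
      bad <- dev > threshold * pmax(loo_sd, scale0)
    } else {
      bad <- matrix(FALSE, n, 96)
      ids <- meta$plate_id[rows]
      hit <- flags[flags$plate_id %in% ids, , drop = FALSE]
      for (j in seq_len(nrow(hit)))
        bad[match(hit$plate_id[j], ids), hit$well[j]] <- TRUE
    }
    if (any(colSums(bad) == n))
      stop_config("all replicates flagged for well(s) %s in set %s",
                  paste(which(colSums(bad) == n), collapse = ", "), grp)
    if (any(bad)) {
      keep_sum <- colSums(sub * !bad)
      keep_n <- colSums(!bad)
      repl <- matrix(keep_sum / keep_n, n, 96, byrow = TRUE)
      log[[grp]] <- data.frame(
        plate_id = meta$plate_id[rows][row(bad)[bad]],
        well = col(bad)[bad],
        original = sub[bad], imputed = repl[bad])
      sub[bad] <- repl[bad]
      od[rows, ] <- sub
    }
  }
  plates$od <- od
  plates$imputed <- if (length(log)) {
    out <- do.call(rbind, log); rownames(out) <- NULL; out
  } else data.frame(plate_id = character(), well = integer(),
                    original = numeric(), imputed = numeric())
  plates
}

#' Column-center a feature matrix
#'
#' @param vectors n x 92 feature matrix (or list of identically named
#'   feature vectors).
#' @return centered matrix with the subtracted means in attribute
#'   `"feature_means"`.
#' @export
assemble_and_center <- function(vectors) {
  if (is.list(vectors) && !is.data.frame(vectors) && !is.matrix(vectors)) {
    nm <- names(vectors[[1]])
    for (v in vectors) if (!identical(names(v), nm))
      stop_config("feature vectors have inconsistent feature names")
    vectors <- do.call(rbind, vectors)
  }
  m <- as.matrix(vectors)
  mu <- colMeans(m)
  out <- sweep(m, 2, mu)
  attr(out, "feature_means") <- mu
  out
}

#' Broken-stick reference proportions
#'
#' Expected ordered variance shares of random partitions of unit variance
#' over `p` components: `b_k = (1/p) * sum_{i=k..p} 1/i`. A component is
#' "better than random" when its observed variance proportion exceeds `b_k`.
#'
#' @param p number of components.
#' @return numeric vector of length `p`.
#' @export
broken_stick <- function(p) {
  stopifnot(p >= 1)
  vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, 0)
}

#' Principal component analysis with broken-stick component selection
#'
#' PCA of the centered (unscaled) feature matrix. With
#' `n_components = "auto"` the retained count is the number of leading
#' components whose variance proportion exceeds the broken-stick reference;
#' the talus heuristic (the count of leading log-eigenvalue gaps that stand
#' clear of the flat tail of the spectrum) is computed as a second opinion,
#' and when the two rules disagree the retained count falls back to a default
#' of 3 -- the dimensionality this assay family typically supports. Both
#' diagnostics are reported regardless.
#'
#' @param mat centered n x p feature matrix (n >= 3).
#' @param n_components `"auto"` or a positive integer (must not exceed the
#'   matrix rank).
#' @param scale_features scale columns to unit variance first (off by
#'   default: the features are already on one OD scale).
#' @param fallback retained count used when broken-stick and talus disagree.
#' @return object of class `pca_model`: list with `scores`, `loadings`,
#'   `eigenvalues`, `prop_var`, `broken_stick`, `talus_k`, `broken_stick_k`,
#'   `retained`.
#' @export
fit_pca <- function(mat, n_components = "auto", scale_features = FALSE,
                    fallback = 3) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop_config("PCA needs at least 3 samples")
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale_features)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  prop <- ev / sum(ev)
  p <- length(ev)
  bs <- broken_stick(p)
  k_bs <- 0L
  while (k_bs < p && prop[k_bs + 1] > bs[k_bs + 1]) k_bs <- k_bs + 1L
  k_bs <- max(k_bs, 1L)
  k_talus <- talus_count(ev[seq_len(rank)])
  if (identical(n_components, "auto")) {
    retained <- if (k_bs == k_talus) k_bs else as.integer(fallback)
    retained <- max(1L, min(retained, rank))
  } else {
    retained <- as.integer(n_components)
    if (retained < 1) stop_config("n_components must be >= 1")
    if (retained > rank)
      stop_config("n_components (%d) exceeds the matrix rank (%d)",
                  retained, rank)
  }
  structure(list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
                 prop_var = prop, broken_stick = bs, broken_stick_k = k_bs,
                 talus_k = k_talus, retained = retained,
                 center = pc$center),
            class = "pca_model")
}

# Talus heuristic: gaps of the log-eigenvalue spectrum. Noise components
# produce a flat tail of small, similar gaps; informative components stand
# clear of it. Counts the leading gaps larger than the tail's typical gap by
# a wide margin.
talus_count <- function(ev, margin = 4) {
  p <- length(ev)
  if (p < 4) return(1L)
  d <- diff(-log(ev))
  tail_gap <- stats::median(d[max(2, floor(p / 2)):(p - 1)])
  k <- 0L
  while (k < p - 1 && d[k + 1] > margin * max(tail_gap, 1e-12)) k <- k + 1L
  max(k, 1L)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d samples x %d features; retained %d components (%.1f%% variance; broken-stick %d, talus %d)\n",
              nrow(x$scores), nrow(x$loadings), x$retained,
              100 * sum(x$prop_var[seq_len(x$retained)]),
              x$broken_stick_k, x$talus_k))
  invisible(x)
}

#' Ancestor centroids on the retained principal components
#'
#' Locates each ancestor group's phenotype at each assay temperature as the
#' k-means (k = 1) centroid of its replicate scores -- which is exactly the
#' arithmetic mean, the k = 1 objective's optimum -- and records per-component
#' replicate dispersions.
#'
#' @param model a [fit_pca()] model whose scores cover all plates.
#' @param meta plate metadata aligned with the score rows (`plate_id`,
#'   `strain_id`, `lineage`, `temperature_C`, `role`).
#' @param by `"lineage"` for one centroid set per ancestor lineage, or
#'   `"pooled"` to merge ancestor replicates across lineages.
#' @return object of class `centroid_set`: data frame of centroids
#'   (`group`, `temperature_C`, `n`, one column per retained component) with
#'   the matching replicate score matrices in attribute `"replicates"`.
#' @export
ancestor_centroids <- function(model, meta, by = c("lineage", "pooled")) {
  by <- match.arg(by)
  stopifnot(inherits(model, "pca_model"))
  k <- model$retained
  anc <- meta$role == "ancestor"
  if (!any(anc)) stop_config("no ancestor plates in metadata")
  grp <- if (by == "pooled") rep("pooled", sum(anc)) else meta$lineage[anc]
  temp <- meta$temperature_C[anc]
  scores <- model$scores[anc, seq_len(k), drop = FALSE]
  keys <- unique(data.frame(group = grp, temperature_C = temp))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- grp == keys$group[i] & temp == keys$temperature_C[i]
    if (sum(sel) < 2)
      stop_config("ancestor group %s at %g C has a single replicate",
                  keys$group[i], keys$temperature_C[i])
    km <- stats::kmeans(scores[sel, , drop = FALSE], centers = 1)
    c(n = sum(sel), km$centers[1, ], disp = apply(scores[sel, , drop = FALSE], 2,
                                                  stats::sd))
  })
  num <- do.call(rbind, rows)
  out <- cbind(keys, as.data.frame(num))
  names(out)[3:(2 + 1 + k)] <- c("n", paste0("PC", seq_len(k)))
  reps <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- grp == keys$group[i] & temp == keys$temperature_C[i]
    scores[sel, , drop = FALSE]
  })
  names(reps) <- paste(keys$group, keys$temperature_C, sep = "|")
  attr(out, "replicates") <- reps
  class(out) <- c("centroid_set", class(out))
  out
}

#' Hierarchical clustering of phenotype vectors
#'
#' Ward linkage on Euclidean distances of the centered feature matrix, with
#' the dendrogram also serialized to Newick.
#'
#' @param mat centered n x p feature matrix with unique rownames.
#' @param k optional number of clusters to cut at.
#' @return list with `hclust`, `newick`, and (if `k` given) `labels`.
#' @export
cluster_samples <- function(mat, k = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop_config("clustering needs at least 2 samples")
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  if (anyDuplicated(ids)) stop_config("duplicate sample ids")
  rownames(mat) <- ids
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  out <- list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}
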