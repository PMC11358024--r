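## Transcriptional alignment between a cell-line cohort and a target cohort:
## quantile normalization to a pooled reference, contrastive PCA to find
## tumor-specific (stromal) variance components, projection removal of the
## top components, and a cluster-matched shift correction. A frozen
## AlignmentTransform allows exact re-application to new samples.

#' Quantile normalize one or more expression matrices to a pooled reference
#'
#' The reference distribution is the per-rank mean of the sorted columns
#' pooled across every sample of every input matrix; each column is then
#' replaced by the reference values at its own ranks, so all columns share
#' an identical multiset of values while preserving within-column order.
#'
#' @param mats A named list of gene-by-sample matrices sharing a gene set
#'   (intersected and reordered if not identical).
#' @return List with `matrices` (normalized, same names) and `reference`
#'   (per-rank means).
#' @export
quantile_normalize <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1)
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < 2) stop("fewer than 2 shared genes", call. = FALSE)
  mats <- lapply(mats, function(m) m[shared, , drop = FALSE])
  pooled <- do.call(cbind, mats)
  reference <- rowMeans(apply(pooled, 2, sort))
  out <- lapply(mats, apply_quantile_reference, reference = reference)
  td_log("quantile_normalize", genes = length(shared),
         samples = ncol(pooled))
  list(matrices = out, reference = reference)
}

#' @rdname quantile_normalize
#' @param x Matrix to normalize against a frozen reference.
#' @param reference Per-rank reference values (length = nrow(x)).
#' @export
apply_quantile_reference <- function(x, reference) {
  stopifnot(nrow(x) == length(reference))
  out <- x
  for (j in seq_len(ncol(x))) {
    out[order(x[, j]), j] <- reference
  }
  out
}

#' Contrastive principal component analysis
#'
#' Eigendecomposition of `C_fg - alpha_c * C_bg`, the difference of
#' gene-gene covariance matrices of a foreground and a background cohort
#' (both column-centered per gene). The leading eigenvectors span the
#' variance directions specific to the foreground -- here, stromal
#' contamination present in biopsies but absent from cultured lines.
#'
#' @param foreground,background Gene-by-sample matrices on a shared gene
#'   set.
#' @param alpha_c Contrast weight (>= 0); 0 reduces to ordinary PCA of the
#'   foreground.
#' @param k Number of components to return.
#' @return List `loadings` (genes x k, orthonormal columns) and
#'   `eigenvalues` (decreasing).
#' @export
contrastive_pca <- function(foreground, background, alpha_c = 1, k = 4) {
  if (!identical(rownames(foreground), rownames(background))) {
    stop("gene sets must be aligned", call. = FALSE)
  }
  g <- nrow(foreground)
  if (k > min(g, ncol(foreground) + ncol(background))) {
    stop("k exceeds the rank of the contrast", call. = FALSE)
  }
  cf <- foreground - rowMeans(foreground)
  cb <- background - rowMeans(background)
  C <- tcrossprod(cf) / (ncol(cf) - 1) -
    alpha_c * tcrossprod(cb) / (ncol(cb) - 1)
  e <- eigen(C, symmetric = TRUE)
  loadings <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(foreground)
  list(loadings = loadings, eigenvalues = e$values[seq_len(k)])
}

#' Remove contrastive components from an expression matrix
#'
#' Projects the per-gene-centered matrix onto the orthogonal complement of
#' the loading columns (`X' = X - U U^T X`), then restores the per-gene
#' centers. Idempotent; with zero columns it is the identity.
#'
#' @param x Gene-by-sample matrix.
#' @param loadings Genes-by-k orthonormal loading matrix.
#' @return Matrix of the same shape with the components removed.
#' @export
remove_components <- function(x, loadings) {
  if (is.null(loadings) || ncol(loadings) == 0) return(x)
  if (nrow(loadings) != nrow(x)) stop("loading/gene shape mismatch", call. = FALSE)
  ctr <- rowMeans(x)
  xc <- x - ctr
  xc - loadings %*% crossprod(loadings, xc) + ctr
}

#' Cluster-matched shift correction of tumors onto cells
#'
#' Joint k-means over the pooled samples (fixed seed); each cluster's tumor
#' members are shifted by the difference between that cluster's tumor
#' centroid and the nearest cell-cluster centroid. Clusters with no cell
#' counterpart anywhere are left unshifted and logged.
#'
#' @param cells,tumors Gene-by-sample matrices (already quantile-normalized
#'   and component-removed).
#' @param n_clusters Number of joint clusters (>= 1); default the number of
#'   lineages is a sensible choice.
#' @param seed Integer seed for k-means initialization.
#' @return List `tumors` (shifted matrix) and `shifts` (per-cluster shift
#'   vectors, genes x clusters).
#' @export
cluster_match_correct <- function(cells, tumors, n_clusters = 4, seed = 1) {
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  if (!identical(rownames(cells), rownames(tumors))) {
    stop("gene sets must be aligned", call. = FALSE)
  }
  pooled <- cbind(cells, tumors)
  km <- with_seed(stream_seed(seed, "align"),
                  stats::kmeans(t(pooled), centers = n_clusters, nstart = 5,
                                iter.max = 50))
  cl <- km$cluster
  is_cell <- seq_len(ncol(pooled)) <= ncol(cells)
  cell_centroids <- lapply(seq_len(n_clusters), function(c) {
    idx <- which(cl == c & is_cell)
    if (length(idx) == 0) return(NULL)
    rowMeans(pooled[, idx, drop = FALSE])
  })
  have_cells <- which(!vapply(cell_centroids, is.null, TRUE))
  if (length(have_cells) == 0) stop("no cluster contains cell samples", call. = FALSE)
  out <- tumors
  shifts <- matrix(0, nrow(tumors), n_clusters,
                   dimnames = list(rownames(tumors), paste0("cluster", seq_len(n_clusters))))
  for (c in seq_len(n_clusters)) {
    idx <- which(cl == c & !is_cell)
    if (length(idx) == 0) next
    tc <- rowMeans(pooled[, idx, drop = FALSE])
    d <- vapply(have_cells, function(cc) sum((tc - cell_centroids[[cc]])^2),
                numeric(1))
    match_c <- have_cells[which.min(d)]
    shift <- tc - cell_centroids[[match_c]]
    shifts[, c] <- shift
    out[, idx - ncol(cells)] <- tumors[, idx - ncol(cells), drop = FALSE] - shift
  }
  td_log("cluster_match_correct", clusters = n_clusters,
         matched = sum(colSums(abs(shifts)) > 0))
  list(tumors = out, shifts = shifts)
}

#' Quantile + location-scale batch correction for a healthy cohort
#'
#' For cohorts without stromal contamination no contrastive step is needed:
#' both cohorts are quantile normalized to the pooled reference, then each
#' gene of the healthy cohort is location-scale adjusted to the cell
#' cohort's per-gene mean and SD, with the per-gene adjustment shrunk
#' toward the global (across-gene average) adjustment by weight
#' `n / (n + n0)` where n is the healthy sample count.
#'
#' @param cells,healthy Gene-by-sample matrices.
#' @param n0 Shrinkage prior weight (pseudo-samples; default 10).
#' @return List `healthy` (corrected matrix), `reference`, and the applied
#'   per-gene `location` / `scale` adjustments.
#' @export
gtex_style_correct <- function(cells, healthy, n0 = 10) {
  qn <- quantile_normalize(list(cells = cells, healthy = healthy))
  ce <- qn$matrices$cells
  he <- qn$matrices$healthy
  n <- ncol(he)
  w <- n / (n + n0)
  m_c <- rowMeans(ce); m_h <- rowMeans(he)
  s_c <- apply(ce, 1, stats::sd); s_h <- apply(he, 1, stats::sd)
  zero <- s_h < 1e-12 | s_c < 1e-12
  if (any(zero)) {
    td_log("gtex_style_correct", zero_variance_genes = sum(zero))
  }
  ratio <- ifelse(zero, 1, s_c / s_h)
  gratio <- exp(mean(log(ratio[!zero])))
  scale_adj <- exp(w * log(ratio) + (1 - w) * log(gratio))
  scale_adj[zero] <- 1
  delta <- m_c - m_h
  loc_adj <- w * delta + (1 - w) * mean(delta)
  corrected <- (he - m_h) * scale_adj + m_h + loc_adj
  list(healthy = corrected, reference = qn$reference,
       location = loc_adj, scale = scale_adj)
}

#' Per-model tumor-purity diagnostic
#'
#' R-squared of the simple linear regression of each model's predicted
#' score on tumor purity, before and after transcriptional alignment. A
#' rising purity association means the "dependency" is reading stromal
#' content, not biology.
#'
#' @param pre,post Predicted essentiality matrices (genes x tumors) from
#'   the unaligned and aligned expression.
#' @param purity Per-tumor purity in \[0,1\].
#' @return List of per-gene `r2_pre` / `r2_post`, their medians, and the
#'   two-sided Wilcoxon rank-sum P comparing the two sets.
#' @export
purity_diagnostic <- function(pre, post, purity) {
  if (stats::sd(purity) == 0) stop("constant purity: R2 undefined", call. = FALSE)
  r2 <- function(map) {
    apply(map, 1, function(s) {
      if (stats::sd(s) == 0) return(NA_real_)
      stats::cor(s, purity)^2
    })
  }
  r2_pre <- r2(pre)
  r2_post <- r2(post)
  ok <- !is.na(r2_pre) & !is.na(r2_post)
  w <- stats::wilcox.test(r2_pre[ok], r2_post[ok])
  list(r2_pre = r2_pre, r2_post = r2_post,
       median_pre = stats::median(r2_pre, na.rm = TRUE),
       median_post = stats::median(r2_post, na.rm = TRUE),
       wilcox_p = w$p.value)
}

#' Align a target cohort to the cell cohort
#'
#' The full alignment recipe: quantile normalization of both cohorts to a
#' pooled reference; contrastive PCA with the target as foreground and the
#' cells as background; removal of the top `k_removed` contrastive
#' components from both cohorts; and cluster-matched shift correction of
#' the target onto the cells. Presets: tumors remove 4 components, PDX 3
#' (lower stromal load), healthy tissue 0 (quantile + location-scale
#' correction instead).
#'
#' @param cells,target Gene-by-sample matrices.
#' @param preset `"tumor"`, `"pdx"` or `"healthy"`.
#' @param alpha_c Contrast weight.
#' @param k_removed Override the preset's component count.
#' @param n_clusters Clusters for the shift correction.
#' @param both_sides Remove components from both cohorts (default) or the
#'   target only.
#' @param seed Integer seed.
#' @return List `cells`, `target` (aligned matrices) and `transform`
#'   (`AlignmentTransform`: reference quantiles, loadings, shifts).
#' @export
align_cohorts <- function(cells, target, preset = c("tumor", "pdx", "healthy"),
                          alpha_c = 1, k_removed = NULL, n_clusters = 4,
                          both_sides = TRUE, seed = 1) {
  preset <- match.arg(preset)
  if (is.null(k_removed)) {
    k_removed <- c(tumor = 4, pdx = 3, healthy = 0)[[preset]]
  }
  if (preset == "healthy") {
    gc <- gtex_style_correct(cells, target)
    qn_cells <- apply_quantile_reference(
      cells[names(gc$location), , drop = FALSE], gc$reference)
    tr <- structure(list(preset = preset, reference = gc$reference,
                         loadings = NULL, shifts = NULL,
                         location = gc$location, scale = gc$scale,
                         k_removed = 0, alpha_c = alpha_c),
                    class = "AlignmentTransform")
    return(list(cells = qn_cells, target = gc$healthy, transform = tr))
  }
  qn <- quantile_normalize(list(cells = cells, target = target))
  ce <- qn$matrices$cells
  ta <- qn$matrices$target
  cp <- contrastive_pca(ta, ce, alpha_c = alpha_c, k = max(k_removed, 1))
  U <- if (k_removed > 0) cp$loadings[, seq_len(k_removed), drop = FALSE] else NULL
  ta2 <- remove_components(ta, U)
  ce2 <- if (both_sides) remove_components(ce, U) else ce
  cm <- cluster_match_correct(ce2, ta2, n_clusters = n_clusters, seed = seed)
  tr <- structure(list(preset = preset, reference = qn$reference,
                       loadings = U, eigenvalues = cp$eigenvalues,
                       shifts = cm$shifts, k_removed = k_removed,
                       alpha_c = alpha_c, both_sides = both_sides),
                  class = "AlignmentTransform")
  td_log("align_cohorts", preset = preset, k_removed = k_removed,
         genes = nrow(ce))
  list(cells = ce2, target = cm$tumors, transform = tr)
}
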