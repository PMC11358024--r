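## Model transposition: apply passing essentiality models to an aligned
## target transcriptome, rescale predictions back to the measured score
## scale, and assemble the cohort dependency map.

#' Tag a matrix as an essentiality map
#'
#' @param x Genes-by-samples score matrix.
#' @param provenance `"measured"`, `"predicted"` or `"predicted+rescaled"`.
#' @param modelset_id Fingerprint of the model set that produced it.
#' @return The matrix with `provenance` / `modelset_id` attributes.
#' @export
as_essentiality_map <- function(x, provenance = "measured", modelset_id = NA_character_) {
  assert_matrix(x)
  attr(x, "provenance") <- provenance
  attr(x, "modelset_id") <- modelset_id
  x
}

map_provenance <- function(x) attr(x, "provenance")

#' Predict an essentiality map from aligned expression
#'
#' `score(g, s) = intercept_g + sum_f coef_f * expr(f, s)` for every
#' passing model whose features are all present in the target matrix;
#' models with missing features are skipped (never zero-filled) and logged.
#'
#' @param models A `ModelSet`; only passing models are applied.
#' @param target Aligned gene-by-sample expression matrix.
#' @return Predicted essentiality map (modeled genes x samples).
#' @export
predict_map <- function(models, target) {
  ms <- passing_models(models)
  if (length(ms$models) == 0) stop("zero passing models", call. = FALSE)
  skipped <- character(0)
  rows <- lapply(ms$models, function(m) {
    feats <- names(m$coefficients)
    if (length(feats) && !all(feats %in% rownames(target))) {
      skipped <<- c(skipped, m$gene)
      return(NULL)
    }
    if (length(feats) == 0) {
      return(rep(m$intercept, ncol(target)))
    }
    m$intercept + colSums(target[feats, , drop = FALSE] * m$coefficients)
  })
  keep <- !vapply(rows, is.null, TRUE)
  if (length(skipped)) {
    td_log("predict_map", skipped_missing_features = length(skipped))
  }
  if (!any(keep)) stop("zero applicable models", call. = FALSE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(ms$models)[keep]
  colnames(out) <- colnames(target)
  as_essentiality_map(out, "predicted", ms$provenance$fingerprint)
}

#' Rescale predicted scores to the measured-essentiality scale
#'
#' Per gene, regresses measured scores on the model's predictions over the
#' cell cohort (`measured ~ a * predicted + b`) and applies the fitted
#' affine map to the target predictions. A monotone affine map: per-gene
#' correlations and sample rank orders are untouched.
#'
#' @param predicted Predicted map on the target cohort.
#' @param predicted_cells Predictions of the same models on the cell
#'   cohort (training representation).
#' @param measured Measured essentiality matrix for the cell cohort.
#' @return List `map` (rescaled target map, provenance
#'   `"predicted+rescaled"`) and `params` (per-gene slope/intercept;
#'   degenerate constant predictions flagged and left unscaled).
#' @export
rescale_map <- function(predicted, predicted_cells, measured) {
  genes <- intersect(rownames(predicted), intersect(rownames(predicted_cells),
                                                    rownames(measured)))
  out <- predicted[genes, , drop = FALSE]
  params <- data.frame(gene = genes, slope = NA_real_, intercept = NA_real_,
                       degenerate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    x <- predicted_cells[g, colnames(measured)]
    y <- measured[g, ]
    if (stats::sd(x) < 1e-12) {
      params$degenerate[i] <- TRUE
      next
    }
    a <- stats::cov(x, y) / stats::var(x)
    b <- mean(y) - a * mean(x)
    params$slope[i] <- a
    params$intercept[i] <- b
    out[g, ] <- a * out[g, ] + b
  }
  td_log("rescale_map", genes = length(genes),
         degenerate = sum(params$degenerate))
  list(map = as_essentiality_map(out, "predicted+rescaled",
                                 attr(predicted, "modelset_id")),
       params = params)
}

#' Hierarchical lineage clustering of a dependency map
#'
#' Ward-linkage (ward.D2) clustering of samples on Euclidean distances
#' over the dependency profiles, with the adjusted Rand index against the
#' known lineage labels at `k = nlevels(labels)`.
#'
#' @param map Essentiality map (genes x samples).
#' @param labels Per-sample lineage labels (named or ordered as columns).
#' @param k Number of clusters to cut at (default number of distinct
#'   labels).
#' @return List `hclust`, `clusters` (k-cut assignment), `ari`.
#' @export
lineage_cluster <- function(map, labels, k = NULL) {
  if (ncol(map) < 3) stop("need >= 3 samples", call. = FALSE)
  if (!is.null(names(labels))) labels <- labels[colnames(map)]
  labels <- factor(labels)
  if (is.null(k)) k <- nlevels(labels)
  hc <- stats::hclust(stats::dist(t(map)), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  list(hclust = hc, clusters = cl, ari = adjusted_rand(cl, labels))
}

## Hubert-Arabie adjusted Rand index.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Gain-of-function association with predicted dependency
#'
#' For each annotated gene, a two-sided Wilcoxon rank-sum test of its
#' predicted scores in carriers of the GOF event versus non-carriers, with
#' BH correction across genes and a direction flag set when the carrier
#' median is more negative (stronger dependency in carriers).
#'
#' @param map Essentiality map (genes x samples).
#' @param gof Binary GOF matrix (genes x samples; 1 = mutation or
#'   amplification). Only genes present in both are tested.
#' @param min_group Minimum samples per group (default 3); smaller groups
#'   are skipped and logged.
#' @return Data frame `gene`, `n_carrier`, `median_carrier`,
#'   `median_other`, `p`, `q`, `stronger_in_carriers`.
#' @export
gof_association <- function(map, gof, min_group = 3) {
  genes <- intersect(rownames(map), rownames(gof))
  samples <- intersect(colnames(map), colnames(gof))
  rows <- list()
  skipped <- 0L
  for (g in genes) {
    carrier <- gof[g, samples] == 1
    if (sum(carrier) < min_group || sum(!carrier) < min_group) {
      skipped <- skipped + 1L
      next
    }
    sc <- map[g, samples]
    w <- suppressWarnings(stats::wilcox.test(sc[carrier], sc[!carrier]))
    rows[[g]] <- data.frame(
      gene = g, n_carrier = sum(carrier),
      median_carrier = stats::median(sc[carrier]),
      median_other = stats::median(sc[!carrier]),
      p = w$p.value, stringsAsFactors = FALSE
    )
  }
  if (skipped) td_log("gof_association", skipped_small_groups = skipped)
  if (length(rows) == 0) {
    return(data.frame(gene = character(), n_carrier = integer(),
                      median_carrier = numeric(), median_other = numeric(),
                      p = numeric(), q = numeric(),
                      stronger_in_carriers = logical()))
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out$stronger_in_carriers <- out$median_carrier < out$median_other
  rownames(out) <- NULL
  out
}
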