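## Therapeutic-window ranking: contrast predicted dependency between
## malignant and matched healthy tissue. Both maps must be predictions of
## the same model set on the rescaled score scale, otherwise the t
## statistics compare apples to oranges.

#' Tumor-versus-healthy therapeutic window scan
#'
#' Per gene and tissue pairing, a Welch two-sample t statistic of the
#' tumor dependency scores against the matched healthy tissue's, with the
#' sign convention that negative t means stronger dependency in tumor
#' (the therapeutic window). BH correction within each pairing; the table
#' is ranked by most-negative t.
#'
#' @param tumor_map,healthy_map Essentiality maps with provenance
#'   `"predicted+rescaled"` from the same model set (enforced unless
#'   `check_provenance = FALSE`).
#' @param pairing Data frame `tumor_type`, `healthy_tissue` mapping tumor
#'   lineages to healthy tissues.
#' @param tumor_lineage,healthy_tissue Named per-sample labels for the two
#'   cohorts.
#' @param min_side Minimum samples per side of a pairing (default 5).
#' @param check_provenance Enforce the shared-scale precondition.
#' @return `WindowScore` data frame: `gene`, `tumor_type`,
#'   `healthy_tissue`, `t`, `p`, `q`, `mean_tumor`, `mean_healthy`,
#'   ordered by t.
#' @export
window_scan <- function(tumor_map, healthy_map, pairing, tumor_lineage,
                        healthy_tissue, min_side = 5,
                        check_provenance = TRUE) {
  if (check_provenance) {
    pa <- attr(tumor_map, "provenance")
    pb <- attr(healthy_map, "provenance")
    if (!identical(pa, "predicted+rescaled") ||
        !identical(pb, "predicted+rescaled")) {
      stop("both maps must have provenance 'predicted+rescaled'", call. = FALSE)
    }
    if (!identical(attr(tumor_map, "modelset_id"),
                   attr(healthy_map, "modelset_id"))) {
      stop("maps come from different model sets; scales not comparable",
           call. = FALSE)
    }
  }
  genes <- intersect(rownames(tumor_map), rownames(healthy_map))
  rows <- list()
  for (i in seq_len(nrow(pairing))) {
    tt <- pairing$tumor_type[i]
    ht <- pairing$healthy_tissue[i]
    ts <- colnames(tumor_map)[tumor_lineage[colnames(tumor_map)] == tt]
    hs <- colnames(healthy_map)[healthy_tissue[colnames(healthy_map)] == ht]
    if (length(ts) < min_side || length(hs) < min_side) {
      td_log("window_scan", skipped_pairing = paste(tt, ht, sep = "~"))
      next
    }
    tm <- tumor_map[genes, ts, drop = FALSE]
    hm <- healthy_map[genes, hs, drop = FALSE]
    ## vectorized Welch t over genes
    m1 <- rowMeans(tm); m2 <- rowMeans(hm)
    v1 <- apply(tm, 1, stats::var); v2 <- apply(hm, 1, stats::var)
    se2 <- v1 / length(ts) + v2 / length(hs)
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / length(ts))^2 / (length(ts) - 1) +
                   (v2 / length(hs))^2 / (length(hs) - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    rows[[i]] <- data.frame(gene = genes, tumor_type = tt,
                            healthy_tissue = ht, t = tstat, p = p,
                            q = stats::p.adjust(p, "BH"),
                            mean_tumor = m1, mean_healthy = m2,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no pairing had enough samples on both sides", call. = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$t), ]
}

#' Toxicity-annotated target-set profiles across healthy tissues
#'
#' Mean predicted essentiality of each named gene set per healthy tissue,
#' with a Wilcoxon rank-sum comparison of the set's scores against all
#' genes outside the set within the tissue.
#'
#' @param healthy_map Essentiality map over healthy samples.
#' @param target_sets Named list of gene vectors (non-empty, proper
#'   subsets of the map's genes).
#' @param tissue Named per-sample tissue labels.
#' @return Data frame `set`, `tissue`, `n_genes`, `mean_set`,
#'   `mean_complement`, `p`.
#' @export
toxicity_profile <- function(healthy_map, target_sets, tissue) {
  stopifnot(length(target_sets) >= 1)
  tissues <- unique(tissue[colnames(healthy_map)])
  rows <- list()
  for (set_name in names(target_sets)) {
    set <- intersect(target_sets[[set_name]], rownames(healthy_map))
    if (length(set) == 0) stop("empty target set: ", set_name, call. = FALSE)
    comp <- setdiff(rownames(healthy_map), set)
    if (length(comp) == 0) {
      stop("target set '", set_name,
           "' covers every gene; comparison degenerate", call. = FALSE)
    }
    for (ts in tissues) {
      cols <- colnames(healthy_map)[tissue[colnames(healthy_map)] == ts]
      mset <- rowMeans(healthy_map[set, cols, drop = FALSE])
      mcomp <- rowMeans(healthy_map[comp, cols, drop = FALSE])
      p <- if (length(set) >= 2) {
        suppressWarnings(stats::wilcox.test(mset, mcomp))$p.value
      } else NA_real_
      rows[[paste(set_name, ts)]] <- data.frame(
        set = set_name, tissue = ts, n_genes = length(set),
        mean_set = mean(mset), mean_complement = mean(mcomp), p = p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
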