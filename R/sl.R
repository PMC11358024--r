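## Synthetic-lethality discovery: per essentiality gene, a lasso of its
## dependency profile on binary LOF events proposes partners; candidates are
## confirmed by a two-group test, cross-checked against endogenous mutual
## exclusivity of the events, and finally filtered to paralogs / close
## phylogenetic neighbors.

#' Lasso screen of dependencies against LOF events
#'
#' For each essentiality gene, a lasso regression (lambda at the 5-fold CV
#' error minimum) of its scores on all LOF event columns; coefficients
#' more negative than `-coef_threshold` (carriers more essential) are
#' confirmed with a two-sided Welch t-test of carrier versus non-carrier
#' scores, BH-corrected across every tested pair. Coefficients are on the
#' original 0/1 predictor scale, so a threshold of 0.3 reads as "carriers
#' at least 0.3 score units more dependent after shrinkage".
#'
#' @param map Essentiality map (genes x samples).
#' @param lof Binary LOF matrix (genes x samples); prevalence filtered to
#'   `prev_band` before fitting.
#' @param genes Essentiality genes to screen (default all rows of `map`).
#' @param folds CV folds for the lasso (default 5).
#' @param coef_threshold Coefficient magnitude threshold (default 0.3).
#' @param q_threshold BH-FDR threshold on the confirmation test (default
#'   0.01).
#' @param prev_band Allowed LOF prevalence range (default 3--70%).
#' @param seed Integer seed (fold assignment).
#' @return Data frame of `SLCandidate` rows: `gene_a` (essentiality gene),
#'   `gene_b` (LOF partner), `coefficient`, `delta` (carrier minus
#'   non-carrier mean), `prevalence`, `p`, `q`, `pass_lasso`.
#' @export
lasso_sl <- function(map, lof, genes = NULL, folds = 5, coef_threshold = 0.3,
                     q_threshold = 0.01, prev_band = c(0.03, 0.70), seed = 1) {
  samples <- intersect(colnames(map), colnames(lof))
  if (length(samples) < 50) stop("need >= 50 shared samples", call. = FALSE)
  if (is.null(genes)) genes <- rownames(map)
  prev <- rowMeans(lof[, samples, drop = FALSE])
  keep_b <- rownames(lof)[prev >= prev_band[1] & prev <= prev_band[2]]
  td_log("lasso_sl", lof_genes = nrow(lof), in_prevalence_band = length(keep_b))
  X <- t(lof[keep_b, samples, drop = FALSE])
  rows <- list()
  skipped <- 0L
  for (g in genes) {
    y <- map[g, samples]
    if (stats::sd(y) < 1e-12) {
      skipped <- skipped + 1L
      next
    }
    cvfit <- with_seed(stream_seed(seed, "fit") + match(g, genes),
                       glmnet::cv.glmnet(X, y, alpha = 1, nfolds = folds))
    co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
    names(co) <- keep_b
    hits <- names(co)[co < -coef_threshold]
    hits <- setdiff(hits, g)
    for (b in hits) {
      carrier <- X[, b] == 1
      tt <- stats::t.test(y[carrier], y[!carrier])
      rows[[paste(g, b)]] <- data.frame(
        gene_a = g, gene_b = b, coefficient = co[[b]],
        delta = mean(y[carrier]) - mean(y[!carrier]),
        prevalence = mean(X[, b]), p = tt$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  if (skipped) td_log("lasso_sl", skipped_zero_variance = skipped)
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      coefficient = numeric(), delta = numeric(),
                      prevalence = numeric(), p = numeric(), q = numeric(),
                      pass_lasso = logical()))
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out$pass_lasso <- out$q < q_threshold
  rownames(out) <- NULL
  td_log("lasso_sl", tested_pairs = nrow(out), passing = sum(out$pass_lasso))
  out
}

## Weighted mutual-exclusivity objective: for a gene set S and sample
## weights w >= 0, each sample covered by exactly one gene of S contributes
## +w; every additional covering gene subtracts w once. With c_s genes of S
## covering sample s:  score(S) = sum_{s: c_s >= 1} w_s * (2 - c_s).
me_objective <- function(cover_counts, w) {
  covered <- cover_counts >= 1
  sum(w[covered] * (2 - cover_counts[covered]))
}

#' Greedy mutual-exclusivity search over LOF events
#'
#' Finds a set of LOF genes whose events are negatively associated
#' (mutually exclusive) and concentrated in high-weight samples. Weights
#' default to the negated essentiality profile (most dependent samples
#' weigh most; negative weights are floored at zero). The greedy search
#' adds the gene with the largest objective gain until no gain remains or
#' `max_set` is reached; significance is a permutation P (weights permuted
#' across samples, plus-one corrected, hence never zero).
#'
#' @param weights Per-sample weight vector (or raw essentiality scores via
#'   `from_scores`).
#' @param lof Binary LOF matrix (genes x samples).
#' @param from_scores If TRUE (default) `weights` are essentiality scores:
#'   the weight is the depth below the `tail_q` cohort quantile
#'   (`max(0, quantile(scores, tail_q) - score)`), so only the dependent
#'   tail carries weight and the search targets events concentrated there.
#' @param tail_q Quantile anchoring the dependent tail (default 0.25).
#' @param max_set Maximum set size (default 10).
#' @param n_perm Permutations (default 100).
#' @param seed Integer seed.
#' @return List `set`, `objective`, `p`.
#' @export
mutual_exclusivity <- function(weights, lof, from_scores = TRUE,
                               tail_q = 0.25, max_set = 10,
                               n_perm = 100, seed = 1) {
  if (all(lof == 0)) stop("all-zero LOF matrix", call. = FALSE)
  if (!is.null(names(weights))) weights <- weights[colnames(lof)]
  w <- if (from_scores) {
    pmax(stats::quantile(weights, tail_q) - weights, 0)
  } else weights
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  greedy_from <- function(w, first) {
    set <- first
    cover <- if (length(first)) as.numeric(lof[first, ]) else numeric(ncol(lof))
    obj <- me_objective(cover, w)
    pool <- setdiff(rownames(lof), first)
    while (length(set) < max_set && length(pool)) {
      gains <- vapply(pool, function(g) {
        me_objective(cover + lof[g, ], w) - obj
      }, numeric(1))
      i <- which.max(gains)
      if (gains[i] <= 0) break
      set <- c(set, pool[i])
      cover <- cover + lof[pool[i], ]
      obj <- obj + unname(gains[i])
      pool <- pool[-i]
    }
    list(set = set, objective = obj)
  }
  ## multi-start greedy: restart from each of the best single genes and keep
  ## the best completion (exact for pairs when every gene is a start)
  greedy <- function(w, n_starts = 8) {
    single <- vapply(rownames(lof), function(g) me_objective(lof[g, ], w),
                     numeric(1))
    starts <- rownames(lof)[order(-single)][seq_len(min(n_starts, nrow(lof)))]
    best <- list(set = character(0), objective = 0)
    for (s in starts) {
      cand <- greedy_from(w, s)
      if (cand$objective > best$objective) best <- cand
    }
    best
  }
  obs <- greedy(w)
  hits <- with_seed(stream_seed(seed, "perm"), {
    sum(vapply(seq_len(n_perm), function(b) {
      greedy(sample(w))$objective >= obs$objective
    }, logical(1)))
  })
  list(set = obs$set, objective = obs$objective,
       p = (hits + 1) / (n_perm + 1))
}

#' Candidate-anchored mutual-exclusivity association test
#'
#' For one SL candidate (essentiality gene A, LOF partner B): first builds
#' B's mutual-exclusivity set from the LOF matrix alone -- band genes whose
#' carrier overlap with B (and with every member already chosen) is
#' depleted below chance (one-sided hypergeometric P < `overlap_alpha`) --
#' then permutation-tests the weighted coverage objective of that frozen
#' set against A's dependent-tail weights. Because the set is chosen
#' without looking at the weights, permuting the weights gives a valid
#' null; the P value asks whether the exclusive set containing B is
#' concentrated in A's most dependent patients.
#'
#' @param scores Gene A's essentiality profile over samples.
#' @param lof Binary LOF matrix (prevalence-filtered).
#' @param anchor Partner gene B (must be a row of `lof`).
#' @param tail_q Dependent-tail quantile for the weights (default 0.25).
#' @param overlap_alpha Hypergeometric depletion threshold for set
#'   membership (default 0.05).
#' @param max_set Maximum set size including the anchor.
#' @param n_perm Weight permutations (default 100).
#' @param seed Integer seed.
#' @return List `set` (anchor first), `objective`, `p`.
#' @export
me_anchor_test <- function(scores, lof, anchor, tail_q = 0.25,
                           overlap_alpha = 0.05, max_set = 10, n_perm = 100,
                           seed = 1) {
  stopifnot(anchor %in% rownames(lof))
  if (!is.null(names(scores))) scores <- scores[colnames(lof)]
  n <- ncol(lof)
  w <- pmax(stats::quantile(scores, tail_q) - scores, 0)
  depleted <- function(a, b) {
    k <- sum(lof[a, ] & lof[b, ])
    stats::phyper(k, sum(lof[a, ]), n - sum(lof[a, ]), sum(lof[b, ])) <
      overlap_alpha
  }
  set <- anchor
  pool <- setdiff(rownames(lof), anchor)
  ## most-depleted-first greedy, requiring pairwise exclusivity with every
  ## member; uses only the LOF matrix, never the weights
  pd <- vapply(pool, function(g) {
    k <- sum(lof[g, ] & lof[anchor, ])
    stats::phyper(k, sum(lof[g, ]), n - sum(lof[g, ]), sum(lof[anchor, ]))
  }, numeric(1))
  for (g in pool[order(pd)]) {
    if (length(set) >= max_set) break
    if (all(vapply(set, function(s) depleted(g, s), logical(1)))) {
      set <- c(set, g)
    }
  }
  cover <- colSums(lof[set, , drop = FALSE])
  obj <- me_objective(cover, w)
  perm <- with_seed(stream_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(b) me_objective(cover, sample(w)),
           numeric(1))
  })
  list(set = set, objective = obj, p = (sum(perm >= obj) + 1) / (n_perm + 1))
}

#' Paralog / phylogenetic-distance filter
#'
#' Keeps candidates whose pair is an annotated paralog OR has phylogenetic
#' distance strictly below the threshold (missing distances do not fail an
#' annotated paralog).
#'
#' @param candidates SLCandidate data frame (from [lasso_sl()]).
#' @param paralog_table Data frame `gene_a`, `gene_b`, `is_paralog`
#'   (logical), `phylo_distance` (numeric, NA allowed). Pairs are matched
#'   irrespective of order.
#' @param dist_threshold Strict upper bound on distance (default 1.5).
#' @return Filtered candidates with `is_paralog` / `phylo_distance`
#'   columns populated.
#' @export
paralog_filter <- function(candidates, paralog_table, dist_threshold = 1.5) {
  need <- c("gene_a", "gene_b", "is_paralog", "phylo_distance")
  if (!all(need %in% names(paralog_table))) {
    stop("paralog table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pk <- key(paralog_table$gene_a, paralog_table$gene_b)
  idx <- match(key(candidates$gene_a, candidates$gene_b), pk)
  candidates$is_paralog <- ifelse(is.na(idx), FALSE,
                                  as.logical(paralog_table$is_paralog[idx]))
  candidates$phylo_distance <- ifelse(is.na(idx), NA_real_,
                                      paralog_table$phylo_distance[idx])
  keep <- candidates$is_paralog |
    (!is.na(candidates$phylo_distance) &
       candidates$phylo_distance < dist_threshold)
  candidates[keep, , drop = FALSE]
}

#' Full synthetic-lethality funnel
#'
#' Runs lasso -> confirmation -> mutual exclusivity -> paralog filter and
#' reports per-stage survivor counts. The mutual-exclusivity stage keeps a
#' candidate if its LOF partner belongs to the greedy set found for the
#' essentiality gene's profile with permutation P below `me_p_threshold`.
#'
#' @param map Essentiality map.
#' @param lof Binary LOF matrix.
#' @param paralog_table See [paralog_filter()]; `NULL` skips the stage.
#' @param genes Essentiality genes to screen.
#' @param coef_threshold,q_threshold,prev_band As in [lasso_sl()].
#' @param me_p_threshold,me_max_set,me_n_perm Mutual-exclusivity stage
#'   parameters.
#' @param dist_threshold Paralog stage threshold.
#' @param seed Integer seed.
#' @return List `candidates` (surviving SLCandidate rows with stage
#'   columns) and `funnel` (named stage counts, non-increasing).
#' @export
sl_funnel <- function(map, lof, paralog_table = NULL, genes = NULL,
                      coef_threshold = 0.3, q_threshold = 0.01,
                      prev_band = c(0.03, 0.70), me_p_threshold = 0.01,
                      me_max_set = 10, me_n_perm = 100, dist_threshold = 1.5,
                      seed = 1) {
  cands <- lasso_sl(map, lof, genes = genes, coef_threshold = coef_threshold,
                    q_threshold = q_threshold, prev_band = prev_band,
                    seed = seed)
  funnel <- c(lasso_tested = nrow(cands))
  cands <- cands[cands$pass_lasso, , drop = FALSE]
  funnel["lasso_q"] <- nrow(cands)
  if (nrow(cands)) {
    samples <- intersect(colnames(map), colnames(lof))
    prev <- rowMeans(lof[, samples, drop = FALSE])
    band <- rownames(lof)[prev >= prev_band[1] & prev <= prev_band[2]]
    keep <- logical(nrow(cands))
    me_p <- numeric(nrow(cands))
    for (i in seq_len(nrow(cands))) {
      me <- me_anchor_test(map[cands$gene_a[i], samples],
                           lof[band, samples, drop = FALSE],
                           anchor = cands$gene_b[i], max_set = me_max_set,
                           n_perm = me_n_perm, seed = seed + i)
      keep[i] <- me$p < me_p_threshold
      me_p[i] <- me$p
    }
    cands$me_p <- me_p
    cands <- cands[keep, , drop = FALSE]
  } else {
    cands$me_p <- numeric(0)
  }
  funnel["mutual_exclusivity"] <- nrow(cands)
  if (!is.null(paralog_table) && nrow(cands)) {
    cands <- paralog_filter(cands, paralog_table, dist_threshold)
  } else if (!is.null(paralog_table)) {
    cands$is_paralog <- logical(0)
    cands$phylo_distance <- numeric(0)
  }
  funnel["paralog"] <- nrow(cands)
  td_log("sl_funnel", coef_threshold = coef_threshold,
         q_threshold = q_threshold, me_p_threshold = me_p_threshold,
         dist_threshold = dist_threshold,
         funnel = paste(funnel, collapse = ">"))
  list(candidates = cands, funnel = funnel)
}
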