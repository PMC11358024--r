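## Survival and response association for dependency maps: maximally
## selected rank statistic dichotomization with permutation-corrected
## inference, log-rank and Cox modeling, drug-response association,
## dependency-signature subtype classification, and driver enrichment.

## Log-rank (Savage) scores: a_i = event_i - Nelson-Aalen cumulative hazard
## at the sample's time. The log-rank statistic for any binary split is the
## sum of scores in one group, with hypergeometric permutation variance.
logrank_scores <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  risk <- n - rank(t_s, ties.method = "min") + 1
  dups <- !duplicated(t_s)
  ut <- t_s[dups]
  d_at <- as.numeric(tapply(e_s, factor(t_s, levels = ut), sum))
  r_at <- risk[dups]
  cumhaz_at <- cumsum(d_at / r_at)
  a <- numeric(n)
  a[ord] <- e_s - cumhaz_at[match(t_s, ut)]
  a
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans candidate cutpoints on the score (both resulting groups kept
#' within the quantile range) and standardizes the log-rank statistic of
#' each split; the cutpoint maximizing |statistic| is returned with a
#' permutation P value of the maximum (scores permuted against the
#' survival data), which corrects for the cutpoint selection.
#'
#' @param score Per-sample score.
#' @param time,event Survival outcome.
#' @param qrange Allowed group-proportion range (default 0.1--0.9).
#' @param n_perm Permutations (default 200).
#' @param seed Integer seed.
#' @return List `cutpoint`, `statistic` (standardized, signed), `max_abs`,
#'   `p` (selection-corrected), `p_naive` (chi-square of the selected
#'   split, uncorrected).
#' @export
maxstat_cutpoint <- function(score, time, event, qrange = c(0.1, 0.9),
                             n_perm = 200, seed = 1) {
  n <- length(score)
  if (n < 10) stop("need >= 10 samples", call. = FALSE)
  if (sum(event) == 0) stop("no events", call. = FALSE)
  a <- logrank_scores(time, event)
  ssa <- sum(a^2)
  ord <- order(score)
  xs <- score[ord]
  lo <- max(2, ceiling(qrange[1] * n))
  hi <- min(n - 2, floor(qrange[2] * n))
  ms <- lo:hi
  ## skip splits inside a tie run (both sides of a tie are the same split)
  valid <- xs[ms] < xs[ms + 1]
  ms <- ms[valid]
  if (length(ms) == 0) stop("no admissible cutpoint", call. = FALSE)
  stand <- function(aa) {
    s_cum <- cumsum(aa)[ms]
    v <- ms * (n - ms) / (n * (n - 1)) * ssa
    s_cum / sqrt(v)
  }
  z <- stand(a[ord])
  i <- which.max(abs(z))
  cut <- (xs[ms[i]] + xs[ms[i] + 1]) / 2
  obs <- abs(z[i])
  perm_max <- with_seed(stream_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(b) max(abs(stand(sample(a)))), numeric(1))
  })
  list(cutpoint = cut, statistic = z[i], max_abs = obs,
       p = (sum(perm_max >= obs) + 1) / (n_perm + 1),
       p_naive = stats::pchisq(obs^2, df = 1, lower.tail = FALSE))
}

#' Two-group log-rank test
#'
#' Standard hypergeometric observed-minus-expected accumulation over
#' distinct event times (via `survival::survdiff`).
#'
#' @param time_a,event_a,time_b,event_b Group outcomes.
#' @return List `o_minus_e` (group A), `var`, `chisq`, `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop("empty group", call. = FALSE)
  }
  grp <- factor(c(rep("A", length(time_a)), rep("B", length(time_b))),
                levels = c("A", "B"))
  sd <- survival::survdiff(
    survival::Surv(c(time_a, time_b), c(event_a, event_b)) ~ grp
  )
  list(o_minus_e = unname(sd$obs[1] - sd$exp[1]),
       var = unname(sd$var[1, 1]), chisq = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio
#'
#' Partial-likelihood fit (Efron ties), optionally stratified. The hazard
#' ratio is per unit of `x` (or group-vs-reference for a binary
#' indicator).
#'
#' @param x Covariate (numeric or 0/1 group indicator).
#' @param time,event Outcome.
#' @param strata Optional stratum labels (separate baseline hazards).
#' @return List `hr`, `ci` (95%), `p_wald`, `p_score`, `converged`; an
#'   infinite or non-converged fit is flagged with `hr = NA`.
#' @export
cox_hr <- function(x, time, event, strata = NULL) {
  df <- data.frame(x = x, time = time, event = event)
  fml <- if (is.null(strata)) {
    survival::Surv(time, event) ~ x
  } else {
    df$strat <- strata
    survival::Surv(time, event) ~ x + survival::strata(strat)
  }
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) structure(list(), class = "cox_failed"),
    error = function(e) structure(list(), class = "cox_failed")
  )
  if (inherits(fit, "cox_failed") || !is.finite(stats::coef(fit)[1]) ||
      abs(stats::coef(fit)[1]) > 15) {
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), p_wald = NA_real_,
                p_score = NA_real_, converged = FALSE))
  }
  sm <- summary(fit)
  list(hr = unname(sm$conf.int[1, "exp(coef)"]),
       ci = unname(sm$conf.int[1, c("lower .95", "upper .95")]),
       p_wald = unname(sm$coefficients[1, "Pr(>|z|)"]),
       p_score = unname(sm$sctest["pvalue"]), converged = TRUE)
}

#' Scan a dependency map for progression associations
#'
#' Per gene: maxstat dichotomization of the dependency scores, log-rank at
#' the chosen cutpoint (permutation-corrected P), and a Cox hazard ratio
#' for the high-dependency group (scores below the cutpoint; HR > 1 means
#' stronger dependency goes with worse outcome). BH across genes at the
#' given FDR. Lineages on the exclusion list or below the minimum stratum
#' size are dropped before testing.
#'
#' @param map Essentiality map (genes x samples).
#' @param surv Survival data frame (`sample`, `time`, `event`).
#' @param lineage Optional named per-sample lineage labels (Cox is
#'   stratified by them).
#' @param genes Genes to scan (default all rows).
#' @param fdr BH threshold (default 0.2).
#' @param excluded_lineages Lineages excluded from the analysis.
#' @param min_stratum Minimum samples per retained lineage (default 30).
#' @param qrange,n_perm Passed to [maxstat_cutpoint()].
#' @param seed Integer seed.
#' @return `OutcomeAssociation` data frame: `gene`, `cutpoint`,
#'   `statistic`, `p`, `p_naive`, `hr`, `ci_lo`, `ci_hi`, `q`,
#'   `significant`.
#' @export
pfi_scan <- function(map, surv, lineage = NULL, genes = NULL, fdr = 0.2,
                     excluded_lineages = character(), min_stratum = 30,
                     qrange = c(0.1, 0.9), n_perm = 200, seed = 1) {
  samples <- intersect(colnames(map), surv$sample)
  if (!is.null(lineage)) {
    lin <- lineage[samples]
    keep_lin <- setdiff(names(table(lin))[table(lin) >= min_stratum],
                        excluded_lineages)
    dropped <- setdiff(unique(lin), keep_lin)
    if (length(dropped)) {
      td_log("pfi_scan", dropped_lineages = paste(dropped, collapse = ","))
    }
    samples <- samples[lin %in% keep_lin]
  }
  si <- match(samples, surv$sample)
  tt <- surv$time[si]
  ev <- surv$event[si]
  strat <- if (is.null(lineage)) NULL else lineage[samples]
  if (is.null(genes)) genes <- rownames(map)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    sc <- map[g, samples]
    mx <- tryCatch(maxstat_cutpoint(sc, tt, ev, qrange = qrange,
                                    n_perm = n_perm, seed = seed + i),
                   error = function(e) NULL)
    if (is.null(mx)) return(NULL)
    high_dep <- as.numeric(sc < mx$cutpoint)
    cx <- cox_hr(high_dep, tt, ev, strata = strat)
    data.frame(gene = g, cutpoint = mx$cutpoint, statistic = mx$statistic,
               p = mx$p, p_naive = mx$p_naive, hr = cx$hr,
               ci_lo = cx$ci[1], ci_hi = cx$ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene = character(), cutpoint = numeric(),
                      statistic = numeric(), p = numeric(),
                      p_naive = numeric(), hr = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), q = numeric(),
                      significant = logical()))
  }
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- out$q < fdr
  td_log("pfi_scan", genes = nrow(out), significant = sum(out$significant),
         fdr = fdr, n = length(samples))
  rownames(out) <- NULL
  out
}

#' Survival of predicted synthetic-lethal carriers
#'
#' Carriers are samples with a LOF event of partner B AND predicted
#' dependency of gene A in the lowest `dep_quantile` of the cohort; their
#' hazard is compared to everyone else with a lineage-stratified Cox
#' model.
#'
#' @param map Essentiality map.
#' @param lof Binary LOF matrix.
#' @param pair Character c(gene_a, gene_b).
#' @param surv Survival data frame.
#' @param lineage Optional per-sample strata.
#' @param dep_quantile Dependency quantile defining "dependent" (default
#'   0.25).
#' @return List from [cox_hr()] plus `n_carrier`, `group_rule` (the
#'   definition, logged verbatim).
#' @export
sl_survival <- function(map, lof, pair, surv, lineage = NULL,
                        dep_quantile = 0.25) {
  a <- pair[1]; b <- pair[2]
  samples <- Reduce(intersect, list(colnames(map), colnames(lof), surv$sample))
  sc <- map[a, samples]
  carrier <- lof[b, samples] == 1 &
    sc <= stats::quantile(sc, dep_quantile)
  if (sum(carrier) < 10) stop("carrier group < 10 samples", call. = FALSE)
  rule <- sprintf("carrier = LOF(%s) & %s dependency <= cohort %d%% quantile",
                  b, a, round(100 * dep_quantile))
  td_log("sl_survival", group_rule = rule, n_carrier = sum(carrier))
  si <- match(samples, surv$sample)
  cx <- cox_hr(as.numeric(carrier), surv$time[si], surv$event[si],
               strata = if (is.null(lineage)) NULL else lineage[samples])
  c(cx, list(n_carrier = sum(carrier), group_rule = rule))
}

#' Associate a dependency score with treatment response
#'
#' Binary response: two-sided Wilcoxon rank-sum plus ROC-AUC with the
#' sensitive class at low (negative) scores. Continuous response (e.g.,
#' burden change): Pearson correlation and its P.
#'
#' @param scores Per-sample essentiality scores.
#' @param response Binary (logical/0-1/2-level factor) or continuous.
#' @param min_n Minimum total samples (default 20, mirroring the
#'   at-least-20-treated-models rule).
#' @return List with `type` and either `p`, `auc` or `r`, `p`.
#' @export
response_assoc <- function(scores, response, min_n = 20) {
  if (length(scores) < min_n) {
    stop("fewer than ", min_n, " samples", call. = FALSE)
  }
  if (is.logical(response) || is.factor(response) ||
      all(response %in% c(0, 1))) {
    pos <- if (is.factor(response)) response == levels(response)[2]
           else as.logical(response)
    if (length(unique(pos)) < 2) stop("single-class response", call. = FALSE)
    w <- suppressWarnings(stats::wilcox.test(scores[pos], scores[!pos]))
    list(type = "binary", p = w$p.value,
         auc = rank_auc(scores, pos, "less"))
  } else {
    ct <- stats::cor.test(scores, response)
    list(type = "continuous", r = unname(ct$estimate), p = ct$p.value)
  }
}

#' Subtype classification from the most variable dependencies
#'
#' Selects the `k` highest-variance genes of the map (the DEP-k
#' signature), clusters samples (Ward.D2), and scores how well the
#' signature recovers known subtype labels by leave-one-out
#' linear-discriminant analysis with a one-vs-rest AUC per class.
#'
#' @param map Essentiality map (cohort subset).
#' @param labels Per-sample subtype labels.
#' @param k Signature size (default 100; clamped to available genes with a
#'   warning).
#' @param min_class Minimum samples per retained class (default 5).
#' @return List `genes` (signature), `auc` (named per-class), `hclust`,
#'   `posterior`.
#' @export
dep100_subtype <- function(map, labels, k = 100, min_class = 5) {
  if (!is.null(names(labels))) labels <- labels[colnames(map)]
  labels <- factor(labels)
  small <- names(table(labels))[table(labels) < min_class]
  if (length(small)) {
    td_log("dep100_subtype", skipped_classes = paste(small, collapse = ","))
    keep <- !(labels %in% small)
    map <- map[, keep, drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  if (k > nrow(map)) {
    warning("k clamped to ", nrow(map), " available genes")
    k <- nrow(map)
  }
  v <- apply(map, 1, stats::var)
  sig <- names(sort(v, decreasing = TRUE))[seq_len(k)]
  sub <- t(map[sig, , drop = FALSE])
  ld <- MASS::lda(sub, grouping = labels, CV = TRUE)
  auc <- vapply(levels(labels), function(cl) {
    rank_auc(ld$posterior[, cl], labels == cl, "greater")
  }, numeric(1))
  hc <- stats::hclust(stats::dist(sub), method = "ward.D2")
  list(genes = sig, auc = auc, hclust = hc, posterior = ld$posterior)
}

#' Genetic-driver enrichment in the most dependent patients
#'
#' The dependent group is the `top_frac` of samples with the lowest scores
#' for the gene; each sufficiently prevalent variant is tested for
#' enrichment in that group with a one-sided Fisher exact test, BH per
#' variant class.
#'
#' @param map Essentiality map.
#' @param variants Named list of binary variant matrices (genes x
#'   samples), e.g. `list(mutation = ..., deletion = ...,
#'   amplification = ...)`.
#' @param gene Dependency gene defining the grouping.
#' @param top_frac Dependent-group fraction (default 0.10).
#' @param prev_min Named minimum prevalences per class (defaults: mutation
#'   0.05, deletion 0.10, amplification 0.10; unnamed classes 0.05).
#' @return Data frame `class`, `variant`, `n_dep_pos`, `n_rest_pos`, `p`,
#'   `q`.
#' @export
driver_enrichment <- function(map, variants, gene, top_frac = 0.10,
                              prev_min = c(mutation = 0.05, deletion = 0.10,
                                           amplification = 0.10)) {
  sc <- map[gene, ]
  n_dep <- max(1, round(top_frac * length(sc)))
  dep <- colnames(map)[order(sc)[seq_len(n_dep)]]
  rest <- setdiff(colnames(map), dep)
  rows <- list()
  for (cls in names(variants)) {
    vm <- variants[[cls]]
    shared <- intersect(colnames(vm), colnames(map))
    pm <- if (cls %in% names(prev_min)) prev_min[[cls]] else 0.05
    prev <- rowMeans(vm[, shared, drop = FALSE])
    for (v in rownames(vm)[prev > pm]) {
      a <- sum(vm[v, dep])
      b <- sum(vm[v, rest])
      tab <- matrix(c(a, b, length(dep) - a, length(rest) - b), 2,
                    byrow = TRUE)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      rows[[paste(cls, v)]] <- data.frame(class = cls, variant = v,
                                          n_dep_pos = a, n_rest_pos = b,
                                          p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    warning("no qualifying variants")
    return(data.frame(class = character(), variant = character(),
                      n_dep_pos = integer(), n_rest_pos = integer(),
                      p = numeric(), q = numeric()))
  }
  out <- do.call(rbind, rows)
  out$q <- stats::ave(out$p, out$class,
                      FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}
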