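## Per-gene elastic-net models of essentiality from expression (or
## expression + mutation + CNV), cross-validated out of fold. glmnet does the
## regularized fitting; this module owns eligibility, the lambda path, the
## fold bookkeeping, the pass rule and the funnel accounting.

#' Genes eligible for essentiality modeling
#'
#' A gene is modeled only if it has at least `min_each` dependent lines
#' (score strictly below `dep_cutoff`) and at least `min_each` nondependent
#' lines (score at or above it).
#'
#' @param ess Measured essentiality matrix (genes x lines).
#' @param dep_cutoff Dependency cutoff (default -0.5).
#' @param min_each Minimum lines on each side (default 5).
#' @return Character vector of eligible genes (possibly empty).
#' @export
eligible_genes <- function(ess, dep_cutoff = -0.5, min_each = 5) {
  assert_matrix(ess)
  dep <- rowSums(ess < dep_cutoff)
  nondep <- rowSums(ess >= dep_cutoff)
  keep <- rownames(ess)[dep >= min_each & nondep >= min_each]
  td_log("eligible_genes", attempted = nrow(ess), eligible = length(keep))
  keep
}

lambda_path <- function(x, y, alpha, n_lambda = 100, decades = 4) {
  n <- length(y)
  ## glmnet standardizes with the biased (1/n) SD; match it so the first
  ## lambda of the path zeroes every coefficient exactly
  mu <- colMeans(x)
  sd_b <- sqrt(colMeans(x^2) - mu^2)
  sd_b[sd_b == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd_b, `/`)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(xs, yc))) / (n * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n_lambda))
}

#' Fit one cross-validated elastic-net essentiality model
#'
#' Features are standardized internally on the training folds (glmnet's
#' internal standardization); lambda is chosen to minimize mean
#' cross-validated squared error over a 100-point path log-spaced four
#' decades down from the smallest lambda that zeroes every coefficient.
#' Reported performance is the Pearson correlation between the pooled
#' out-of-fold predictions and the observed scores; final coefficients are
#' refit on all samples at the chosen lambda and reported on the original
#' feature scale (so that `intercept + sum(coef * feature)` is the
#' prediction).
#'
#' @param y Essentiality vector (one gene across lines).
#' @param X Samples-by-features matrix with feature colnames.
#' @param gene Target gene name (used for self-inclusion rank).
#' @param alpha Elastic-net mixing parameter (0.5 balances L1/L2).
#' @param folds Cross-validation folds.
#' @param mode Model flavor label.
#' @param seed Integer seed controlling fold assignment.
#' @return A `GeneModel`: intercept, sparse coefficients, chosen lambda,
#'   out-of-fold `cv_r`, two-sided P of the correlation, feature count, and
#'   `self_rank` (rank of the target's own expression among selected
#'   features by standardized coefficient magnitude; NA if unselected).
#' @export
fit_gene_model <- function(y, X, gene = "target", alpha = 0.5, folds = 10,
                           mode = "expression_only", seed = 1) {
  stopifnot(length(y) == nrow(X))
  n <- length(y)
  failed <- function() {
    structure(list(gene = gene, mode = mode, alpha = alpha, lambda = NA_real_,
                   intercept = mean(y), coefficients = numeric(0),
                   cv_r = NA_real_, p = NA_real_, q = NA_real_, pass = FALSE,
                   n_features = 0L, self_rank = NA_real_, failed = TRUE),
              class = "GeneModel")
  }
  if (stats::sd(y) == 0) return(failed())
  path <- lambda_path(X, y, alpha)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  oof <- matrix(NA_real_, n, length(path))
  for (k in seq_len(folds)) {
    test <- fold_id == k
    fit_k <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test], alpha = alpha,
                            lambda = path, standardize = TRUE)
    pr <- stats::predict(fit_k, X[test, , drop = FALSE])
    ## glmnet may drop trailing lambdas on degenerate folds; recycle last
    oof[test, seq_len(ncol(pr))] <- pr
    if (ncol(pr) < length(path)) {
      oof[test, (ncol(pr) + 1):length(path)] <- pr[, ncol(pr)]
    }
  }
  cvm <- colMeans((oof - y)^2)
  imin <- which.min(cvm)
  pred <- oof[, imin]
  cv_r <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, y)
  tstat <- cv_r * sqrt((n - 2) / max(1 - cv_r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = path, standardize = TRUE)
  cf <- stats::coef(fit, s = path[imin])
  co <- as.numeric(cf)[-1]
  names(co) <- colnames(X)
  nz <- co[co != 0]
  self_rank <- NA_real_
  if (length(nz) && gene %in% names(nz)) {
    sds <- apply(X[, names(nz), drop = FALSE], 2, stats::sd)
    self_rank <- rank(-abs(nz * sds), ties.method = "min")[[gene]]
  }
  structure(list(
    gene = gene, mode = mode, alpha = alpha, lambda = path[imin],
    intercept = as.numeric(cf)[1], coefficients = nz, cv_r = cv_r, p = p,
    q = NA_real_, pass = NA, n_features = length(nz), self_rank = self_rank,
    failed = FALSE
  ), class = "GeneModel")
}

#' Fit essentiality models for a whole cohort
#'
#' Runs the dependent-line eligibility filter, fits one elastic-net model
#' per eligible gene, computes Benjamini-Hochberg FDR across all attempted
#' genes from the per-gene correlation P values, and applies the pass rule
#' `cv_r > r_threshold AND q < q_threshold`.
#'
#' @param ess Measured essentiality matrix (genes x lines).
#' @param expr Expression matrix (genes x lines), the feature source.
#' @param mode `"expression_only"`, `"multi_omics"` (adds mutation + CNV
#'   features) or `"confounder_null"` (lineage one-hot + nuisance
#'   covariates only).
#' @param mutations,cnv Optional matrices for multi-omics mode.
#' @param metadata Per-sample metadata (needed for confounder_null).
#' @param genes Genes to attempt; default all eligible.
#' @param r_threshold,q_threshold Pass rule (defaults 0.2 and 1e-3).
#' @param dep_cutoff,min_each Eligibility filter parameters.
#' @param alpha,folds As in [fit_gene_model()].
#' @param n_nuisance Nuisance covariates for confounder_null.
#' @param seed Integer seed.
#' @return A `ModelSet`.
#' @export
fit_all <- function(ess, expr, mode = c("expression_only", "multi_omics",
                                        "confounder_null"),
                    mutations = NULL, cnv = NULL, metadata = NULL,
                    genes = NULL, r_threshold = 0.2, q_threshold = 1e-3,
                    dep_cutoff = -0.5, min_each = 5, alpha = 0.5, folds = 10,
                    n_nuisance = 5, seed = 1) {
  mode <- match.arg(mode)
  assert_matrix(ess)
  assert_matrix(expr)
  if (!identical(colnames(ess), colnames(expr))) {
    stop("essentiality and expression samples differ", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- eligible_genes(ess, dep_cutoff, min_each)
  }
  n <- ncol(expr)
  X <- switch(mode,
    expression_only = t(expr),
    multi_omics = {
      if (is.null(mutations) || is.null(cnv)) {
        stop("multi_omics mode needs mutations and cnv", call. = FALSE)
      }
      if (!identical(colnames(mutations), colnames(expr)) ||
          !identical(colnames(cnv), colnames(expr))) {
        stop("feature/sample mismatch", call. = FALSE)
      }
      mu <- t(mutations); colnames(mu) <- paste0("mut_", colnames(mu))
      cn <- t(cnv); colnames(cn) <- paste0("cnv_", colnames(cn))
      cbind(t(expr), mu, cn)
    },
    confounder_null = {
      if (is.null(metadata)) stop("confounder_null mode needs metadata", call. = FALSE)
      lin <- stats::model.matrix(~ 0 + factor(metadata$lineage))
      colnames(lin) <- paste0("lineage_", levels(factor(metadata$lineage)))
      nuis <- with_seed(stream_seed(seed, "fit"),
                        matrix(stats::rnorm(n * n_nuisance), n, n_nuisance))
      colnames(nuis) <- paste0("nuisance_", seq_len(n_nuisance))
      rownames(lin) <- rownames(nuis) <- colnames(expr)
      cbind(lin, nuis)
    }
  )
  models <- vector("list", length(genes))
  names(models) <- genes
  for (i in seq_along(genes)) {
    g <- genes[i]
    models[[i]] <- fit_gene_model(ess[g, ], X, gene = g, alpha = alpha,
                                  folds = folds, mode = mode,
                                  seed = stream_seed(seed, "fit") + i)
  }
  ps <- vapply(models, function(m) m$p, numeric(1))
  qs <- stats::p.adjust(ps, "BH")
  for (i in seq_along(models)) {
    models[[i]]$q <- qs[i]
    models[[i]]$pass <- isTRUE(!is.na(models[[i]]$cv_r) &&
                               models[[i]]$cv_r > r_threshold &&
                               !is.na(qs[i]) && qs[i] < q_threshold)
  }
  td_log("fit_all", mode = mode, attempted = length(genes),
         passed = sum(vapply(models, `[[`, TRUE, "pass")))
  structure(list(
    models = models,
    provenance = list(mode = mode, r_threshold = r_threshold,
                      q_threshold = q_threshold, alpha = alpha, folds = folds,
                      seed = seed, fingerprint = matrix_fingerprint(expr))
  ), class = "ModelSet")
}

matrix_fingerprint <- function(x) {
  sprintf("%dx%d:%.6g", nrow(x), ncol(x), sum(x))
}

#' Passing models of a set
#' @param ms A `ModelSet`.
#' @return `ModelSet` restricted to models with `pass = TRUE`.
#' @export
passing_models <- function(ms) {
  keep <- vapply(ms$models, function(m) isTRUE(m$pass), TRUE)
  structure(list(models = ms$models[keep], provenance = ms$provenance),
            class = "ModelSet")
}

#' Fit a mutation-status classifier from expression
#'
#' Logistic elastic net of a binary mutation vector on expression features,
#' with pooled out-of-fold AUC. Genes outside the prevalence band are
#' refused (too few carriers to cross-validate).
#'
#' @param mut Binary vector (one gene's mutation status across lines).
#' @param X Samples-by-features expression matrix.
#' @param gene Gene label.
#' @param min_prev Minimum carrier prevalence (default 0.02, applied on
#'   both sides).
#' @param alpha,folds,seed As in [fit_gene_model()].
#' @return A `GeneModel` with `mode = "mutation_classifier"` and `cv_r`
#'   holding the cross-validated AUC, or NULL (with a log entry) if the
#'   prevalence is out of band.
#' @export
fit_mutation_classifier <- function(mut, X, gene = "target", min_prev = 0.02,
                                    alpha = 0.5, folds = 10, seed = 1) {
  stopifnot(all(mut %in% c(0, 1)))
  prev <- mean(mut)
  if (prev <= min_prev || prev >= 1 - min_prev) {
    td_log("fit_mutation_classifier", gene = gene, skipped = "prevalence",
           prev = round(prev, 4))
    return(NULL)
  }
  n <- length(mut)
  fold_id <- with_seed(seed, {
    ## stratified folds so every training fold sees both classes
    id <- integer(n)
    id[mut == 1] <- sample(rep_len(seq_len(folds), sum(mut == 1)))
    id[mut == 0] <- sample(rep_len(seq_len(folds), sum(mut == 0)))
    id
  })
  path <- lambda_path(X, mut, alpha)
  oof <- matrix(NA_real_, n, length(path))
  for (k in seq_len(folds)) {
    test <- fold_id == k
    fit_k <- glmnet::glmnet(X[!test, , drop = FALSE], factor(mut[!test]),
                            family = "binomial", alpha = alpha, lambda = path,
                            standardize = TRUE)
    pr <- stats::predict(fit_k, X[test, , drop = FALSE], type = "response")
    oof[test, seq_len(ncol(pr))] <- pr
    if (ncol(pr) < length(path)) {
      oof[test, (ncol(pr) + 1):length(path)] <- pr[, ncol(pr)]
    }
  }
  aucs <- apply(oof, 2, function(p) rank_auc(p, mut == 1, "greater"))
  imin <- which.max(aucs)
  fit <- glmnet::glmnet(X, factor(mut), family = "binomial", alpha = alpha,
                        lambda = path, standardize = TRUE)
  cf <- stats::coef(fit, s = path[imin])
  co <- as.numeric(cf)[-1]
  names(co) <- colnames(X)
  nz <- co[co != 0]
  structure(list(
    gene = gene, mode = "mutation_classifier", alpha = alpha,
    lambda = path[imin], intercept = as.numeric(cf)[1], coefficients = nz,
    cv_r = aucs[imin], p = NA_real_, q = NA_real_, pass = NA,
    n_features = length(nz), self_rank = NA_real_, failed = FALSE
  ), class = "GeneModel")
}

#' AUC of an essentiality model at the dependency cutoff
#'
#' Classifies lines as sensitive (`observed < cutoff`) from the model's
#' predicted score; lower predictions mark the sensitive class.
#'
#' @param predicted,observed Numeric vectors.
#' @param cutoff Sensitivity cutoff on observed scores (default -0.5).
#' @return AUC in \[0,1\].
#' @export
essentiality_auc <- function(predicted, observed, cutoff = -0.5) {
  rank_auc(predicted, observed < cutoff, "less")
}

#' @export
print.ModelSet <- function(x, ...) {
  np <- sum(vapply(x$models, function(m) isTRUE(m$pass), TRUE))
  cat("ModelSet:", length(x$models), "models (", np, "pass ),",
      "mode =", x$provenance$mode, "\n")
  invisible(x)
}

#' Convert planted cohort truth into a ModelSet
#'
#' Useful for exercising transposition and downstream stages against the
#' exact generative models rather than fitted ones.
#'
#' @param truth `CohortTruth` with `model_support`.
#' @return A `ModelSet` of passing models with the planted coefficients.
#' @export
truth_modelset <- function(truth) {
  models <- lapply(names(truth$model_support), function(g) {
    sp <- truth$model_support[[g]]
    structure(list(
      gene = g, mode = "expression_only", alpha = NA_real_, lambda = NA_real_,
      intercept = sp$intercept,
      coefficients = stats::setNames(sp$coefficients, sp$features),
      cv_r = 1, p = 0, q = 0, pass = TRUE,
      n_features = length(sp$features), self_rank = NA_real_, failed = FALSE
    ), class = "GeneModel")
  })
  names(models) <- names(truth$model_support)
  structure(list(models = models,
                 provenance = list(mode = "expression_only", seed = truth$seed,
                                   fingerprint = "truth")),
            class = "ModelSet")
}
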