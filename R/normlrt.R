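## Strongly selective dependencies: a gene whose essentiality profile is
## normal across the cohort is uninteresting; a heavy left tail (a small
## subpopulation of strong dependents) is captured by a skew-t fit. The
## NormLRT statistic is twice the log-likelihood gap between the skew-t and
## normal fits.

## Azzalini-type skew-t log-density: location xi, scale omega > 0, slant
## alpha (0 = symmetric t), df nu. Density:
##   f(x) = (2/omega) t_nu(z) T_{nu+1}( alpha z sqrt((nu+1)/(nu+z^2)) ),
##   z = (x - xi)/omega.
## The normal arises in the limit nu -> Inf, alpha -> 0.
dskewt_log <- function(x, xi, omega, alpha, nu) {
  z <- (x - xi) / omega
  log(2) - log(omega) + stats::dt(z, nu, log = TRUE) +
    stats::pt(alpha * z * sqrt((nu + 1) / (nu + z^2)), nu + 1, log.p = TRUE)
}

## df kept in [2.1, 100] through a logistic transform: the lower bound keeps
## the variance finite, the upper bound is "normal-like".
.nu_bounds <- c(2.1, 100)
nu_of <- function(t) .nu_bounds[1] + diff(.nu_bounds) * stats::plogis(t)

#' Normality likelihood ratio test for one essentiality profile
#'
#' Fits a normal distribution (closed-form MLE) and a location-scale
#' skew-t (numerical MLE with three starts: symmetric-t, left-skewed,
#' right-skewed) and reports `lrt = 2 * (loglik_skewt - loglik_normal)`,
#' clamped at zero (the normal sits on the boundary of the skew-t family,
#' so small negative values are optimizer noise). Large values mark
#' strongly selective dependencies. Used for ranking only; no P value is
#' attached.
#'
#' @param x Numeric vector of essentiality scores (n >= 30).
#' @return List: `lrt`, `loglik_normal`, `loglik_skewt`, `converged`,
#'   `df`, `skew`, `location`, `scale`.
#' @export
normlrt <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 30) stop("normlrt needs >= 30 finite values", call. = FALSE)
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  ll_norm <- -n / 2 * (log(2 * pi * s2) + 1)
  negll <- function(th) {
    v <- -sum(dskewt_log(x, th[1], exp(th[2]), th[3], nu_of(th[4])))
    if (!is.finite(v)) 1e10 else v
  }
  s <- sqrt(s2)
  starts <- list(c(mu, log(s), 0, 2),
                 c(mu + s, log(s), -3, 0),
                 c(mu - s, log(s), 3, 0))
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    o <- try(stats::optim(st, negll, method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-10)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) {
    td_log("normlrt", failed = "all starts errored")
    return(list(lrt = 0, loglik_normal = ll_norm, loglik_skewt = ll_norm,
                converged = FALSE, df = NA_real_, skew = NA_real_,
                location = NA_real_, scale = NA_real_))
  }
  ll_st <- -best$value
  lrt <- max(0, 2 * (ll_st - ll_norm))
  list(lrt = lrt, loglik_normal = ll_norm, loglik_skewt = ll_st,
       converged = conv, df = nu_of(best$par[4]), skew = best$par[3],
       location = best$par[1], scale = exp(best$par[2]))
}

#' NormLRT scores for every gene of a dependency map
#'
#' @param map Essentiality map (genes x samples).
#' @param genes Genes to score (default all rows).
#' @param scaling Optional positive scaling factor applied to the raw
#'   statistics (see [bootstrap_scaling()]); rescaling never changes the
#'   ranking.
#' @return Data frame `gene`, `lrt`, `lrt_rescaled`, `df`, `skew`,
#'   `converged`.
#' @export
normlrt_scores <- function(map, genes = NULL, scaling = 1) {
  if (is.null(genes)) genes <- rownames(map)
  rows <- lapply(genes, function(g) {
    r <- normlrt(map[g, ])
    data.frame(gene = g, lrt = r$lrt, lrt_rescaled = scaling * r$lrt,
               df = r$df, skew = r$skew, converged = r$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap rescaling of NormLRT across cohort sizes
#'
#' The log-likelihood ratio grows roughly linearly with the sample count,
#' so statistics from cohorts of different sizes are not directly
#' comparable. Resamples the measured cohort's columns with replacement up
#' to the target size, recomputes the statistic per gene (averaged over
#' `n_boot` resamples), and fits the slope of the source statistics on the
#' bootstrapped target statistics by least squares through the origin. The
#' slope is the factor that brings target-cohort statistics onto the
#' source scale (a statistic of zero maps to zero).
#'
#' @param measured Measured essentiality matrix (genes x samples).
#' @param target_n Target cohort size (>= 30).
#' @param n_boot Bootstrap replicates per gene (default 50).
#' @param genes Genes to use for the fit (default all rows).
#' @param seed Integer seed.
#' @return List `scaling` (slope s), `per_gene` (source lrt, mean
#'   bootstrapped target lrt), `source_n`, `target_n`, `n_boot`.
#' @export
bootstrap_scaling <- function(measured, target_n, n_boot = 50, genes = NULL,
                              seed = 1) {
  if (target_n < 30) stop("target_n must be >= 30", call. = FALSE)
  if (is.null(genes)) genes <- rownames(measured)
  n <- ncol(measured)
  with_seed(stream_seed(seed, "boot"), {
    src <- vapply(genes, function(g) normlrt(measured[g, ])$lrt, numeric(1))
    tgt <- vapply(genes, function(g) {
      mean(vapply(seq_len(n_boot), function(b) {
        normlrt(measured[g, sample.int(n, target_n, replace = TRUE)])$lrt
      }, numeric(1)))
    }, numeric(1))
    s <- sum(src * tgt) / sum(tgt^2)
    list(scaling = s,
         per_gene = data.frame(gene = genes, lrt_source = src,
                               lrt_target_mean = tgt,
                               stringsAsFactors = FALSE),
         source_n = n, target_n = target_n, n_boot = n_boot)
  })
}

#' Cross-cohort comparison of selective dependencies
#'
#' Scores both maps with NormLRT, ranks genes within each cohort, and
#' reports the Pearson correlation of the statistics over genes exceeding
#' the selectivity threshold in either cohort.
#'
#' @param map_a,map_b Essentiality maps sharing >= 3 genes.
#' @param threshold Selectivity threshold on the (rescaled) statistic
#'   (default 100, the conventional SSD bar on consortium-scale cohorts;
#'   lower it for small cohorts).
#' @param scaling_b Scaling factor applied to map_b's statistics before
#'   comparison.
#' @return List `table` (gene, lrt_a, lrt_b, rank_a, rank_b, selective)
#'   and `r` (Pearson over selective genes).
#' @export
ssd_table <- function(map_a, map_b, threshold = 100, scaling_b = 1) {
  shared <- intersect(rownames(map_a), rownames(map_b))
  if (length(shared) < 3) stop("fewer than 3 shared genes", call. = FALSE)
  sa <- normlrt_scores(map_a, shared)
  sb <- normlrt_scores(map_b, shared, scaling = scaling_b)
  tab <- data.frame(gene = shared, lrt_a = sa$lrt,
                    lrt_b = sb$lrt_rescaled,
                    rank_a = rank(-sa$lrt, ties.method = "min"),
                    rank_b = rank(-sb$lrt_rescaled, ties.method = "min"),
                    stringsAsFactors = FALSE)
  tab$selective <- tab$lrt_a > threshold | tab$lrt_b > threshold
  sel <- tab[tab$selective, ]
  r <- if (nrow(sel) >= 3) stats::cor(sel$lrt_a, sel$lrt_b) else NA_real_
  list(table = tab[order(tab$rank_a), ], r = r)
}
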