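## Synthetic cohort generators with planted, exported ground truth.
## Expression is simulated on the log2 scale; stromal admixture is performed
## in linear space (additive contamination) and re-logged, which is exactly
## the structure the contrastive-PCA alignment step is designed to remove.

#' Generate a cell-line cohort with planted essentiality models
#'
#' Simulates a lineage-structured log2 expression matrix, a CERES-like
#' essentiality matrix in which a subset of genes follows a sparse linear
#' model of expression, plus binary mutation and continuous copy-number
#' matrices. The planted models (features, coefficients, intercepts) are
#' exported in the returned `CohortTruth`.
#'
#' @param n_lines Number of cell lines (>= 20).
#' @param n_genes Number of genes.
#' @param n_lineages Number of lineages; lines are assigned uniformly.
#' @param n_modeled Number of genes with a planted expression->essentiality
#'   model.
#' @param n_features Features per planted model.
#' @param noise_sd Residual SD of planted essentiality around the linear
#'   predictor (CERES-score units).
#' @param inert_frac Fraction of unmodeled genes that are never dependent
#'   (scores near 0), so the dependent-line eligibility filter has work to do.
#' @param self_prob Probability that a planted model includes the target
#'   gene's own expression among its features.
#' @param seed Integer seed; identical seeds reproduce the cohort
#'   bit-identically.
#' @return List with `expression`, `essentiality`, `mutations`, `cnv`
#'   (matrices, genes x lines), `metadata` (sample/cohort/lineage) and
#'   `truth` (`CohortTruth`).
#' @export
make_cell_cohort <- function(n_lines = 100, n_genes = 500, n_lineages = 4,
                             n_modeled = 20, n_features = 5, noise_sd = 0.2,
                             inert_frac = 0.2, self_prob = 0.3, seed = 1) {
  if (n_lines < 20) stop("n_lines must be >= 20", call. = FALSE)
  if (n_genes < 2 || n_lineages < 1) stop("non-positive dimensions", call. = FALSE)
  if (n_modeled * n_features >= n_genes) stop("n_informative must be < n_genes", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  genes <- sprintf("g%03d", seq_len(n_genes))
  lines <- sprintf("CL%03d", seq_len(n_lines))
  with_seed(stream_seed(seed, "cells"), {
    lineage <- sample(rep_len(sprintf("lin%d", seq_len(n_lineages)), n_lines))
    mu <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
    shifts <- matrix(stats::rnorm(n_genes * n_lineages), n_genes, n_lineages,
                     dimnames = list(genes, sprintf("lin%d", seq_len(n_lineages))))
    lin_idx <- match(lineage, colnames(shifts))
    expr <- mu + shifts[, lin_idx] + matrix(stats::rnorm(n_genes * n_lines),
                                            n_genes, n_lines)
    dimnames(expr) <- list(genes, lines)

    modeled <- sample(genes, n_modeled)
    support <- lapply(modeled, function(g) {
      feats <- sample(setdiff(genes, g), n_features)
      if (stats::runif(1) < self_prob) feats[1] <- g
      ## coefficient scale chosen so per-gene cohort spreads land in the
      ## CERES-typical 0.5-0.9 range rather than multiple score units
      coefs <- stats::runif(n_features, 0.15, 0.3) *
        sample(c(-1, 1), n_features, replace = TRUE)
      list(features = feats, coefficients = coefs,
           intercept = -0.5 - sum(coefs * (mu[match(feats, genes)])))
    })
    names(support) <- modeled

    ess <- matrix(NA_real_, n_genes, n_lines, dimnames = list(genes, lines))
    for (g in modeled) {
      sp <- support[[g]]
      lp <- sp$intercept +
        colSums(expr[sp$features, , drop = FALSE] * sp$coefficients)
      ess[g, ] <- lp + stats::rnorm(n_lines, sd = noise_sd)
    }
    others <- setdiff(genes, modeled)
    inert <- sample(others, round(inert_frac * length(others)))
    vari <- setdiff(others, inert)
    ess[vari, ] <- stats::rnorm(length(vari) * n_lines, mean = -0.5, sd = 0.5)
    ess[inert, ] <- stats::rnorm(length(inert) * n_lines, mean = 0.2, sd = 0.1)

    prev <- stats::runif(n_genes, 0.05, 0.30)
    mut <- matrix(stats::rbinom(n_genes * n_lines, 1, rep(prev, n_lines)),
                  n_genes, n_lines, dimnames = list(genes, lines))
    cnv <- matrix(stats::rnorm(n_genes * n_lines, mean = 1, sd = 0.2),
                  n_genes, n_lines, dimnames = list(genes, lines))

    truth <- structure(list(
      model_support = support,
      modeled_genes = modeled,
      noise_genes = vari,
      inert_genes = inert,
      gene_means = stats::setNames(mu, genes),
      lineage_shifts = shifts,
      lineages = stats::setNames(lineage, lines),
      hazard_gene = modeled[1],
      noise_sd = noise_sd,
      sl_pairs = NULL, gi_pairs = NULL, purity = NULL,
      seed = seed
    ), class = "CohortTruth")
    meta <- data.frame(sample = lines, cohort = "cells", lineage = lineage,
                       stringsAsFactors = FALSE)
    td_log("make_cell_cohort", n_lines = n_lines, n_genes = n_genes,
           n_modeled = n_modeled)
    list(expression = expr, essentiality = ess, mutations = mut, cnv = cnv,
         metadata = meta, truth = truth)
  })
}

#' Generate a tumor cohort by stromal admixture of the cell-line model
#'
#' Malignant expression is drawn from the same lineage-structured model as
#' the paired cell cohort; the observed biopsy signal is
#' `purity * malignant + (1 - purity) * stromal` on the linear scale,
#' re-logged. Binary LOF events are planted so that loss of partner B shifts
#' the latent essentiality of gene A by `delta`; a hazard gene's latent
#' essentiality scales the survival hazard; optional window genes get an
#' all-tumor dependency shift relative to healthy tissue.
#'
#' @param cell_truth `CohortTruth` from [make_cell_cohort()].
#' @param n_tumors Number of tumors.
#' @param purity_beta Shape parameters `c(a, b)` of the Beta purity
#'   distribution (must yield values in (0, 1]).
#' @param stromal_shift log2 mean shift of stromal genes in the stromal
#'   profile (default 4).
#' @param stromal_frac Fraction of genes that are stromal-specific.
#' @param sl_spec Data frame `gene_a`, `gene_b`, `delta` of planted
#'   synthetic-lethal effects; default plants 5 pairs at delta = -0.6.
#'   `NULL` plants none.
#' @param n_lof Number of genes carrying LOF events (prevalence drawn in
#'   3--30%).
#' @param sl_module_size Each planted partner is embedded in a redundancy
#'   module of this size whose members have mutually exclusive carriers and
#'   all sensitize gene A (exported as `truth$sl_modules`).
#' @param window_spec Data frame `gene`, `delta` of all-tumor dependency
#'   shifts (therapeutic-window truth); default one gene at -0.5.
#' @param hazard_beta Log-hazard slope on the hazard gene's centered latent
#'   essentiality (per score unit; negative scores increase hazard).
#' @param horizon Administrative censoring time; defaults give ~30-50%
#'   events.
#' @param seed Integer seed.
#' @return List with `expression`, `lof` (binary matrix), `survival`
#'   (sample/time/event), `purity`, `metadata` and updated `truth` carrying
#'   `sl_pairs`, `window_genes`, `stromal_genes`, `purity` and the tumors'
#'   `latent_essentiality` matrix.
#' @export
make_tumor_cohort <- function(cell_truth, n_tumors = 300,
                              purity_beta = c(5, 2), stromal_shift = 4,
                              stromal_frac = 0.15, sl_spec = "default",
                              n_lof = 40, sl_module_size = 3,
                              window_spec = "default",
                              hazard_beta = 0.8, horizon = 36, seed = 1) {
  stopifnot(inherits(cell_truth, "CohortTruth"))
  if (n_tumors < 2) stop("non-positive dimensions", call. = FALSE)
  if (purity_beta[1] <= 0 || purity_beta[2] < 0) {
    stop("purity_beta must yield values in (0,1]", call. = FALSE)
  }
  genes <- names(cell_truth$gene_means)
  mu <- cell_truth$gene_means
  shifts <- cell_truth$lineage_shifts
  tumors <- sprintf("T%04d", seq_len(n_tumors))

  with_seed(stream_seed(seed, "tumors"), {
    lof_genes <- sample(genes, n_lof)
    if (identical(sl_spec, "default")) {
      k <- min(5, length(cell_truth$modeled_genes), n_lof)
      sl_spec <- data.frame(
        gene_a = cell_truth$modeled_genes[seq_len(k)],
        gene_b = lof_genes[seq_len(k)],
        delta = -0.6, stringsAsFactors = FALSE
      )
    }
    if (!is.null(sl_spec)) {
      if (!all(sl_spec$gene_a %in% genes) || !all(sl_spec$gene_b %in% genes)) {
        stop("sl_spec names genes absent from the cohort", call. = FALSE)
      }
      lof_genes <- union(lof_genes, sl_spec$gene_b)
    }
    if (identical(window_spec, "default")) {
      wg <- setdiff(cell_truth$modeled_genes, if (is.null(sl_spec)) character() else sl_spec$gene_a)
      window_spec <- if (length(wg)) {
        data.frame(gene = wg[length(wg)], delta = -0.5, stringsAsFactors = FALSE)
      } else NULL
    }

    lineage <- sample(rep_len(colnames(shifts), n_tumors))
    lin_idx <- match(lineage, colnames(shifts))
    malig <- mu + shifts[, lin_idx] +
      matrix(stats::rnorm(length(genes) * n_tumors), length(genes), n_tumors)
    dimnames(malig) <- list(genes, tumors)

    stromal_genes <- sample(genes, round(stromal_frac * length(genes)))
    stromal_profile <- mu
    stromal_profile[stromal_genes] <- stromal_profile[stromal_genes] + stromal_shift
    strom <- stromal_profile +
      matrix(stats::rnorm(length(genes) * n_tumors, sd = 0.5),
             length(genes), n_tumors)
    purity <- if (purity_beta[2] == 0) {
      rep(1, n_tumors)  # shape2 = 0: degenerate at 1, no stroma
    } else {
      pmax(pmin(stats::rbeta(n_tumors, purity_beta[1], purity_beta[2]), 1), 1e-3)
    }
    expr <- log2(sweep(2^malig, 2, purity, `*`) +
                 sweep(2^strom, 2, 1 - purity, `*`))
    dimnames(expr) <- list(genes, tumors)

    prev <- stats::runif(length(lof_genes), 0.03, 0.30)
    lof <- matrix(stats::rbinom(length(lof_genes) * n_tumors, 1,
                                rep(prev, n_tumors)),
                  length(lof_genes), n_tumors,
                  dimnames = list(lof_genes, tumors))
    ## each planted pair sits inside a small redundancy module: the partner
    ## plus (sl_module_size - 1) companion LOF genes with mutually exclusive
    ## carriers, every member sensitizing gene A. This mirrors redundant-loss
    ## biology (alternative hits on the same pathway are rarely co-selected)
    ## and is the structure the mutual-exclusivity filter looks for.
    sl_modules <- NULL
    if (!is.null(sl_spec)) {
      used <- character(0)
      mods <- list()
      for (i in seq_len(nrow(sl_spec))) {
        pool <- setdiff(lof_genes, c(sl_spec$gene_b, sl_spec$gene_a, used))
        extras <- sample(pool, min(sl_module_size - 1, length(pool)))
        members <- c(sl_spec$gene_b[i], extras)
        used <- c(used, members)
        pm <- stats::runif(length(members), 0.08, 0.15)
        assign_m <- sample(0:length(members), n_tumors, replace = TRUE,
                           prob = c(1 - sum(pm), pm))
        for (m in seq_along(members)) {
          lof[members[m], ] <- as.integer(assign_m == m)
        }
        mods[[i]] <- data.frame(gene_a = sl_spec$gene_a[i], member = members,
                                delta = sl_spec$delta[i],
                                primary = members == sl_spec$gene_b[i],
                                stringsAsFactors = FALSE)
      }
      sl_modules <- do.call(rbind, mods)
    }

    ## latent essentiality: the planted models evaluated on the *malignant*
    ## component, plus SL and window shifts; this is the ground truth the
    ## transposed map is judged against.
    latent <- matrix(NA_real_, length(genes), n_tumors,
                     dimnames = list(genes, tumors))
    for (g in cell_truth$modeled_genes) {
      sp <- cell_truth$model_support[[g]]
      latent[g, ] <- sp$intercept +
        colSums(malig[sp$features, , drop = FALSE] * sp$coefficients) +
        stats::rnorm(n_tumors, sd = cell_truth$noise_sd)
    }
    nz <- c(cell_truth$noise_genes)
    latent[nz, ] <- stats::rnorm(length(nz) * n_tumors, mean = -0.5, sd = 0.5)
    latent[cell_truth$inert_genes, ] <-
      stats::rnorm(length(cell_truth$inert_genes) * n_tumors, mean = 0.2, sd = 0.1)
    if (!is.null(sl_modules)) {
      for (a in unique(sl_modules$gene_a)) {
        rows <- sl_modules[sl_modules$gene_a == a, ]
        carriers <- colSums(lof[rows$member, , drop = FALSE]) >= 1
        latent[a, carriers] <- latent[a, carriers] + rows$delta[1]
      }
    }
    if (!is.null(window_spec)) {
      for (i in seq_len(nrow(window_spec))) {
        latent[window_spec$gene[i], ] <-
          latent[window_spec$gene[i], ] + window_spec$delta[i]
      }
    }

    hz <- cell_truth$hazard_gene
    loghaz <- -hazard_beta * (latent[hz, ] - mean(latent[hz, ]))
    rate <- 0.02 * exp(loghaz)
    tt <- stats::rexp(n_tumors, rate)
    event <- as.integer(tt <= horizon)
    surv <- data.frame(sample = tumors, time = pmin(tt, horizon), event = event,
                       stringsAsFactors = FALSE)

    truth <- cell_truth
    truth$sl_pairs <- sl_spec
    truth$sl_modules <- sl_modules
    truth$window_genes <- window_spec
    truth$stromal_genes <- stromal_genes
    truth$stromal_profile <- stats::setNames(stromal_profile, genes)
    truth$purity <- stats::setNames(purity, tumors)
    truth$tumor_lineages <- stats::setNames(lineage, tumors)
    truth$latent_essentiality <- latent
    meta <- data.frame(sample = tumors, cohort = "tumors", lineage = lineage,
                       purity = purity, stringsAsFactors = FALSE)
    td_log("make_tumor_cohort", n_tumors = n_tumors, n_lof = nrow(lof),
           events = sum(event))
    list(expression = expr, lof = lof, survival = surv,
         purity = stats::setNames(purity, tumors), metadata = meta,
         truth = truth)
  })
}

#' Generate a healthy-tissue cohort paired with the cell-line model
#'
#' Tissue-structured expression with no stromal admixture (the whole sample
#' is "stroma-free" normal tissue) but a global location-scale batch
#' distortion, emulating a separately processed healthy compendium. Latent
#' essentiality follows the planted models evaluated on the undistorted
#' expression, with no tumor-specific shifts.
#'
#' @param cell_truth `CohortTruth` from [make_cell_cohort()].
#' @param n_samples Number of tissue samples.
#' @param batch_scale,batch_shift Affine distortion applied to the log2
#'   expression (`scale * x + shift`).
#' @param seed Integer seed.
#' @return List with `expression`, `metadata`, `truth` (with
#'   `latent_essentiality`).
#' @export
make_healthy_cohort <- function(cell_truth, n_samples = 120,
                                batch_scale = 1.1, batch_shift = 0.5,
                                seed = 1) {
  stopifnot(inherits(cell_truth, "CohortTruth"))
  genes <- names(cell_truth$gene_means)
  mu <- cell_truth$gene_means
  shifts <- cell_truth$lineage_shifts
  samples <- sprintf("H%04d", seq_len(n_samples))
  with_seed(stream_seed(seed, "healthy"), {
    tissue <- sample(rep_len(colnames(shifts), n_samples))
    idx <- match(tissue, colnames(shifts))
    clean <- mu + shifts[, idx] +
      matrix(stats::rnorm(length(genes) * n_samples), length(genes), n_samples)
    dimnames(clean) <- list(genes, samples)
    expr <- batch_scale * clean + batch_shift

    latent <- matrix(NA_real_, length(genes), n_samples,
                     dimnames = list(genes, samples))
    for (g in cell_truth$modeled_genes) {
      sp <- cell_truth$model_support[[g]]
      latent[g, ] <- sp$intercept +
        colSums(clean[sp$features, , drop = FALSE] * sp$coefficients) +
        stats::rnorm(n_samples, sd = cell_truth$noise_sd)
    }
    nz <- cell_truth$noise_genes
    latent[nz, ] <- stats::rnorm(length(nz) * n_samples, mean = -0.5, sd = 0.5)
    latent[cell_truth$inert_genes, ] <-
      stats::rnorm(length(cell_truth$inert_genes) * n_samples,
                   mean = 0.2, sd = 0.1)

    truth <- cell_truth
    truth$tissues <- stats::setNames(tissue, samples)
    truth$latent_essentiality <- latent
    meta <- data.frame(sample = samples, cohort = "healthy", lineage = tissue,
                       stringsAsFactors = FALSE)
    list(expression = expr, metadata = meta, truth = truth)
  })
}

#' Build a dual-knockout screen design
#'
#' Constructs carry 4 guides each (two per targeted gene, non-targeting
#' fillers otherwise): `NTxNT` negative controls, `singleKO` (one gene + NT)
#' and `DKO` (two genes). Guide sequences are unique across the library.
#'
#' @param genes Character vector of targeted genes.
#' @param pairs Data frame `gene_a`, `gene_b` of DKO pairs.
#' @param n_nt Number of NTxNT control constructs (>= 10 for GI scoring).
#' @param n_single_per_gene Single-KO constructs per gene (collapsed to the
#'   median during GI scoring).
#' @param guide_len Guide length in bases.
#' @param seed Integer seed.
#' @return Design data.frame (`construct_id`, `gene_a`, `gene_b`,
#'   `guide1..4`, `class`).
#' @export
make_screen_design <- function(genes, pairs, n_nt = 20, n_single_per_gene = 2,
                               guide_len = 21, seed = 1) {
  stopifnot(nrow(pairs) >= 1, all(c(pairs$gene_a, pairs$gene_b) %in% genes))
  with_seed(stream_seed(seed, "screen"), {
    n_constructs <- n_nt + n_single_per_gene * length(genes) + nrow(pairs)
    n_guides <- 4 * n_constructs
    guides <- character(0)
    while (length(guides) < n_guides) {
      cand <- vapply(seq_len(n_guides - length(guides)), function(i) {
        paste(sample(c("A", "C", "G", "T"), guide_len, replace = TRUE),
              collapse = "")
      }, "")
      guides <- unique(c(guides, cand))
    }
    gi <- 0L
    take <- function() {
      gi <<- gi + 4L
      guides[(gi - 3L):gi]
    }
    rows <- list()
    for (i in seq_len(n_nt)) {
      rows[[length(rows) + 1L]] <- c(sprintf("NT_%03d", i), "NT", "NT", take(), "NTxNT")
    }
    for (g in genes) {
      for (j in seq_len(n_single_per_gene)) {
        rows[[length(rows) + 1L]] <-
          c(sprintf("S_%s_%d", g, j), g, "NT", take(), "singleKO")
      }
    }
    for (i in seq_len(nrow(pairs))) {
      rows[[length(rows) + 1L]] <-
        c(sprintf("D_%s_%s", pairs$gene_a[i], pairs$gene_b[i]),
          pairs$gene_a[i], pairs$gene_b[i], take(), "DKO")
    }
    design <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(design) <- c("construct_id", "gene_a", "gene_b",
                       paste0("guide", 1:4), "class")
    validate_design(design)
    design
  })
}

validate_design <- function(design) {
  gcols <- as.matrix(design[paste0("guide", 1:4)])
  if (anyDuplicated(as.vector(gcols))) stop("guide sequences not unique", call. = FALSE)
  if (any(!grepl("^[ACGT]+$", gcols))) stop("non-ACGT guide sequence", call. = FALSE)
  n_nt <- (design$gene_a == "NT") + (design$gene_b == "NT")
  ok <- (design$class == "NTxNT" & n_nt == 2) |
        (design$class == "singleKO" & n_nt == 1) |
        (design$class == "DKO" & n_nt == 0)
  if (!all(ok)) stop("construct class inconsistent with gene columns", call. = FALSE)
  invisible(design)
}

#' Simulate plasmid and day-14 screen counts
#'
#' Day-14 expectation per construct is the plasmid proportion times
#' `2^(single effects + interaction)`, renormalized; counts are
#' negative-binomial with the given dispersion (Poisson at dispersion 0).
#' NTxNT constructs carry zero planted effect.
#'
#' @param design Screen design from [make_screen_design()].
#' @param gi_truth Data frame `gene_a`, `gene_b`, `gi` of planted
#'   interaction depletions (log2 units), or `NULL`.
#' @param single_effects Named numeric vector gene -> log2 depletion of the
#'   single knockout; missing genes get 0.
#' @param depth Mean reads per construct (> 0).
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @param n_reps Day-14 replicates.
#' @param seed Integer seed.
#' @return List `counts` (constructs x (plasmid + reps) matrix) and
#'   `effects` (per-construct total planted log2 effect).
#' @export
make_screen_counts <- function(design, gi_truth = NULL, single_effects = NULL,
                               depth = 500, dispersion = 0.1, n_reps = 3,
                               seed = 1) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  n <- nrow(design)
  eff <- numeric(n)
  se <- function(g) {
    if (g == "NT" || is.null(single_effects) || !g %in% names(single_effects)) 0
    else single_effects[[g]]
  }
  for (i in seq_len(n)) {
    eff[i] <- se(design$gene_a[i]) + se(design$gene_b[i])
  }
  if (!is.null(gi_truth)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    gk <- key(gi_truth$gene_a, gi_truth$gene_b)
    dk <- key(design$gene_a, design$gene_b)
    hit <- match(dk, gk)
    add <- ifelse(is.na(hit) | design$class != "DKO", 0, gi_truth$gi[hit])
    eff <- eff + add
  }
  with_seed(stream_seed(seed, "screen"), {
    w <- exp(stats::rnorm(n, sd = 0.3))
    p0 <- w / sum(w)
    draw <- function(mu) {
      if (dispersion == 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
    }
    libsize <- depth * n
    plasmid <- draw(p0 * libsize)
    p1 <- p0 * 2^eff
    p1 <- p1 / sum(p1)
    reps <- vapply(seq_len(n_reps), function(r) draw(p1 * libsize),
                   numeric(n))
    counts <- cbind(plasmid, reps)
    dimnames(counts) <- list(design$construct_id,
                             c("plasmid", sprintf("day14_rep%d", seq_len(n_reps))))
    list(counts = counts, effects = stats::setNames(eff, design$construct_id))
  })
}

#' Emit FASTQ reads for a screen count vector
#'
#' Each read is `flank5 + guide1..guide4 concatenated + flank3`; a construct
#' with count c contributes exactly c reads. An optional uniform per-base
#' substitution error corrupts reads (exact-match counting then loses them).
#'
#' @param design Screen design.
#' @param counts Named per-construct integer counts (names = construct_id).
#' @param flank5,flank3 Flanking vector sequences.
#' @param error_rate Per-base substitution probability.
#' @param path Optional FASTQ output path; when given the records are
#'   written (4-line records, constant quality).
#' @param seed Integer seed (read shuffling and errors).
#' @return Character vector of read sequences (invisibly if `path` given).
#' @export
make_reads <- function(design, counts, flank5 = "ACGGCTAGCTGA",
                       flank3 = "TGCATGCGATCC", error_rate = 0, path = NULL,
                       seed = 1) {
  stopifnot(!is.null(names(counts)))
  if (!all(grepl("^[ACGT]+$", c(flank5, flank3)))) {
    stop("non-ACGT flank sequence", call. = FALSE)
  }
  arrays <- apply(as.matrix(design[paste0("guide", 1:4)]), 1, paste, collapse = "")
  names(arrays) <- design$construct_id
  if (!all(names(counts) %in% names(arrays))) {
    stop("counts name constructs absent from design", call. = FALSE)
  }
  with_seed(stream_seed(seed, "reads"), {
    reads <- rep(paste0(flank5, arrays[names(counts)], flank3),
                 times = as.integer(counts))
    if (length(reads)) reads <- sample(reads)
    if (error_rate > 0 && length(reads)) {
      bases <- c("A", "C", "G", "T")
      reads <- vapply(reads, function(r) {
        ch <- strsplit(r, "")[[1]]
        flip <- stats::runif(length(ch)) < error_rate
        if (any(flip)) {
          ch[flip] <- vapply(ch[flip], function(b) sample(setdiff(bases, b), 1), "")
        }
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    if (!is.null(path)) {
      ids <- sprintf("@read%06d", seq_along(reads))
      qual <- strrep("I", nchar(reads))
      writeLines(as.vector(rbind(ids, reads, "+", qual)), path)
      return(invisible(reads))
    }
    reads
  })
}
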