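## Multiplexed dual-knockout CRISPR screen analysis: exact-match guide-array
## counting from reads, TMM library normalization, replicate log2 fold
## changes against the plasmid library, and expected-versus-observed
## genetic-interaction scores.

#' Count guide arrays from screen reads by exact match
#'
#' Extracts the sequence between the 5' and 3' flanks of each read and
#' increments the construct whose concatenated 4-guide array it matches
#' exactly; anything else (mismatched base, missing flank) lands in the
#' `unmapped` tally, mirroring perfect-match-only screen quantification.
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param design Screen design table.
#' @param flank5,flank3 Flanking vector sequences.
#' @param strict Error (rather than warn) when >90% of reads lack a flank.
#' @return List `counts` (named per-construct integer vector) and
#'   `unmapped`.
#' @export
count_guides <- function(reads, design, flank5 = "ACGGCTAGCTGA",
                         flank3 = "TGCATGCGATCC", strict = FALSE) {
  if (length(reads) == 1 && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  arrays <- apply(as.matrix(design[paste0("guide", 1:4)]), 1, paste, collapse = "")
  if (anyDuplicated(arrays)) stop("design guide arrays not unique", call. = FALSE)
  counts <- stats::setNames(integer(nrow(design)), design$construct_id)
  if (length(reads) == 0) {
    warning("empty read set: all counts zero")
    return(list(counts = counts, unmapped = 0L))
  }
  i5 <- regexpr(flank5, reads, fixed = TRUE)
  i3 <- regexpr(flank3, reads, fixed = TRUE)
  has_flanks <- i5 > 0 & i3 > i5
  if (mean(!has_flanks) > 0.9) {
    msg <- "flanks missing in >90% of reads"
    if (strict) stop(msg, call. = FALSE) else warning(msg)
  }
  inner <- substr(reads[has_flanks], i5[has_flanks] + nchar(flank5),
                  i3[has_flanks] - 1)
  hit <- match(inner, arrays)
  tab <- table(factor(hit[!is.na(hit)], levels = seq_along(arrays)))
  counts[] <- as.integer(tab)
  unmapped <- length(reads) - sum(counts)
  td_log("count_guides", reads = length(reads), mapped = sum(counts),
         unmapped = unmapped)
  list(counts = counts, unmapped = unmapped)
}

#' TMM scale factors for a screen count table
#'
#' Trimmed-mean-of-M-values normalization (edgeR's implementation): per
#' sample, the weighted trimmed mean of log2 count ratios against a
#' reference sample after trimming the most extreme 30% by M and 5% by A,
#' with inverse-variance weights; factors are normalized to geometric mean
#' one.
#'
#' @param counts Constructs-by-samples count matrix (>= 2 samples).
#' @param trim_m,trim_a Trim fractions for M and A values.
#' @param ref Reference sample name or index (default edgeR's automatic
#'   choice).
#' @return Named per-sample scale factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = NULL) {
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts", call. = FALSE)
  refCol <- if (is.null(ref)) NULL else {
    if (is.character(ref)) match(ref, colnames(counts)) else ref
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = refCol,
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(f, colnames(counts))
}

#' Per-construct log2 fold changes versus plasmid
#'
#' Counts are scaled to a common effective library size (raw library size
#' times its TMM factor), a pseudo-count is added, and each day-14
#' replicate is compared to the plasmid column:
#' `L2FC = log2((day14_norm + pseudo) / (plasmid_norm + pseudo))`.
#' Replicates are summarized by their mean and a one-sample t statistic.
#'
#' @param counts Count matrix with a `plasmid` column and day-14 replicate
#'   columns.
#' @param factors TMM factors (default computed here).
#' @param plasmid Name of the plasmid column.
#' @param pseudo Pseudo-count on the normalized scale (default 0.5).
#' @return List `l2fc` (constructs x replicates), `mean`, `t` (one-sample
#'   t across replicates), `low_confidence` (constructs with zero plasmid
#'   count).
#' @export
screen_l2fc <- function(counts, factors = NULL, plasmid = "plasmid",
                        pseudo = 0.5) {
  stopifnot(plasmid %in% colnames(counts))
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts) * factors[colnames(counts)]
  common <- exp(mean(log(eff)))
  norm <- sweep(counts, 2, eff / common, `/`)
  reps <- setdiff(colnames(counts), plasmid)
  l2fc <- log2((norm[, reps, drop = FALSE] + pseudo) /
               (norm[, plasmid] + pseudo))
  m <- rowMeans(l2fc)
  s <- apply(l2fc, 1, stats::sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(length(reps))), NA_real_)
  low <- rownames(counts)[counts[, plasmid] == 0]
  if (length(low)) td_log("screen_l2fc", low_confidence = length(low))
  list(l2fc = l2fc, mean = m, t = tstat, low_confidence = low)
}

#' Genetic-interaction scores from construct fold changes
#'
#' All construct L2FCs are z-scored against the NTxNT null distribution;
#' multiple constructs of the same target collapse to the median. Per DKO
#' pair: observed z, expected z = z_A + z_B (single-KO z values), their
#' difference, and the difference z-scored across all DKO pairs
#' (`diff_z`). Calls: `synthetic_lethal` below `-call_threshold`,
#' `buffering` above it.
#'
#' @param l2fc_mean Named per-construct mean L2FC (from [screen_l2fc()]).
#' @param design Screen design table.
#' @param call_threshold |diff_z| needed for a call (default 2).
#' @param min_nt Minimum NTxNT constructs for the null (default 10).
#' @return Data frame of `GIRecord` rows: `gene_a`, `gene_b`, `observed_z`,
#'   `expected_z`, `difference`, `diff_z`, `call`.
#' @export
gi_scores <- function(l2fc_mean, design, call_threshold = 2, min_nt = 10) {
  stopifnot(!is.null(names(l2fc_mean)))
  design <- design[match(names(l2fc_mean), design$construct_id), ]
  nt <- l2fc_mean[design$class == "NTxNT"]
  if (length(nt) < min_nt) {
    stop("need >= ", min_nt, " NTxNT constructs for the null", call. = FALSE)
  }
  z <- (l2fc_mean - mean(nt)) / stats::sd(nt)
  singles <- design$class == "singleKO"
  single_gene <- ifelse(design$gene_a[singles] == "NT",
                        design$gene_b[singles], design$gene_a[singles])
  single_z <- tapply(z[singles], single_gene, stats::median)
  dko <- design[design$class == "DKO", ]
  key <- paste(pmin(dko$gene_a, dko$gene_b), pmax(dko$gene_a, dko$gene_b))
  obs <- tapply(z[design$class == "DKO"], key, stats::median)
  pairs <- do.call(rbind, strsplit(names(obs), " "))
  missing <- !(pairs[, 1] %in% names(single_z)) |
             !(pairs[, 2] %in% names(single_z))
  if (any(missing)) {
    stop("DKO pair lacking single-KO constructs: ",
         paste(names(obs)[missing], collapse = ", "), call. = FALSE)
  }
  expected <- single_z[pairs[, 1]] + single_z[pairs[, 2]]
  diff <- as.numeric(obs) - as.numeric(expected)
  diff_z <- (diff - mean(diff)) / stats::sd(diff)
  call <- ifelse(diff_z < -call_threshold, "synthetic_lethal",
                 ifelse(diff_z > call_threshold, "buffering", "none"))
  out <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                    observed_z = as.numeric(obs),
                    expected_z = as.numeric(expected),
                    difference = diff, diff_z = diff_z, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$diff_z), ]
}

#' Run the full screen analysis from counts
#'
#' @param counts Count matrix (plasmid + replicates).
#' @param design Screen design table.
#' @param ... Passed to [gi_scores()].
#' @return GIRecord data frame.
#' @export
screen_gi <- function(counts, design, ...) {
  lf <- screen_l2fc(counts)
  gi_scores(lf$mean, design, ...)
}

#' Concordance of two screen runs
#'
#' Pearson correlation of `diff_z` over the DKO pairs shared between two
#' GI tables.
#'
#' @param gi_run1,gi_run2 GIRecord data frames.
#' @return Pearson r.
#' @export
screen_concordance <- function(gi_run1, gi_run2) {
  k1 <- paste(gi_run1$gene_a, gi_run1$gene_b)
  k2 <- paste(gi_run2$gene_a, gi_run2$gene_b)
  shared <- intersect(k1, k2)
  if (length(shared) < 3) stop("fewer than 3 shared pairs", call. = FALSE)
  stats::cor(gi_run1$diff_z[match(shared, k1)],
             gi_run2$diff_z[match(shared, k2)])
}
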