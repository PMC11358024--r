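#' Read a gene-by-sample matrix from TSV
#'
#' Canonical interchange format: tab-separated, first column `gene`, header
#' row of sample identifiers. All values must be numeric and finite;
#' `kind = "binary"` additionally requires every cell to be 0 or 1.
#'
#' @param path File path.
#' @param kind One of `"expression"`, `"essentiality"`, `"numeric"`,
#'   `"binary"`.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("expression", "essentiality", "numeric", "binary")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "gene") {
    stop("matrix TSV must have a leading 'gene' column: ", path, call. = FALSE)
  }
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene row in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric or missing cell at gene ", genes[bad[1, 1]],
         ", sample ", colnames(vals)[bad[1, 2]], " in ", path, call. = FALSE)
  }
  if (anyDuplicated(colnames(vals))) stop("duplicate sample column in ", path, call. = FALSE)
  if (kind == "binary" && !all(vals %in% c(0, 1))) {
    stop("binary matrix contains values other than 0/1 in ", path, call. = FALSE)
  }
  rownames(vals) <- genes
  vals
}

#' Write a gene-by-sample matrix as TSV
#'
#' Deterministic byte stream: fixed column order, shortest round-trip float
#' representation (R's full 15-significant-digit formatting).
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix <- function(x, path) {
  assert_matrix(x)
  df <- data.frame(gene = rownames(x),
                   format(x, trim = TRUE, digits = 15, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample metadata
#'
#' Columns: `sample`, `cohort`, `lineage`, optional `purity` in \[0,1\].
#' @param path File path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("sample", "cohort", "lineage")
  if (!all(need %in% names(df))) {
    stop("metadata TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if ("purity" %in% names(df) &&
      any(df$purity < 0 | df$purity > 1, na.rm = TRUE)) {
    stop("purity outside [0,1]", call. = FALSE)
  }
  df
}

#' @rdname read_metadata
#' @param df Metadata data.frame.
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a survival table (`sample`, `time`, `event`)
#' @param path File path.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df))) {
    stop("survival TSV needs sample/time/event columns", call. = FALSE)
  }
  if (any(df$time <= 0)) stop("non-positive survival time", call. = FALSE)
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  df
}

#' @rdname read_survival
#' @param df Survival data.frame.
#' @export
write_survival <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model set
#'
#' Two-part TSV: a JSON header line (prefixed `#`) carrying provenance
#' (format version, thresholds, folds, seed, feature fingerprint), a
#' per-model summary block and a long-format coefficient block. Round-trips
#' coefficients at full double precision.
#'
#' @param ms A `ModelSet` from [fit_all()].
#' @param path Output path.
#' @export
serialize_models <- function(ms, path) {
  stopifnot(inherits(ms, "ModelSet"))
  header <- jsonlite::toJSON(
    c(list(format_version = 1L), ms$provenance),
    auto_unbox = TRUE, digits = NA
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  summ <- model_summary(ms)
  num <- vapply(summ, is.numeric, TRUE)
  summ[num] <- lapply(summ[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(summ, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("##coefficients", con)
  co <- coef_table(ms)
  co$coefficient <- format(co$coefficient, digits = 17, trim = TRUE)
  co$intercept <- format(co$intercept, digits = 17, trim = TRUE)
  utils::write.table(co, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname serialize_models
#' @return `deserialize_models` returns a `ModelSet`.
#' @export
deserialize_models <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#")) stop("missing model file header", call. = FALSE)
  prov <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  if (is.null(prov$format_version) || prov$format_version != 1L) {
    stop("model file format version mismatch", call. = FALSE)
  }
  prov$format_version <- NULL
  cut <- which(lines == "##coefficients")
  if (length(cut) != 1) stop("malformed model file", call. = FALSE)
  summ <- utils::read.delim(text = paste(lines[2:(cut - 1)], collapse = "\n"))
  has_coef <- cut < length(lines)
  co <- if (has_coef && cut + 1 < length(lines)) {
    utils::read.delim(text = paste(lines[(cut + 1):length(lines)], collapse = "\n"))
  } else {
    data.frame(gene = character(), feature = character(),
               coefficient = numeric(), intercept = numeric())
  }
  models <- lapply(seq_len(nrow(summ)), function(i) {
    g <- summ$gene[i]
    rows <- co[co$gene == g, , drop = FALSE]
    coefs <- stats::setNames(rows$coefficient, rows$feature)
    structure(list(
      gene = g, mode = summ$mode[i], alpha = summ$alpha[i],
      lambda = summ$lambda[i],
      intercept = if (nrow(rows)) rows$intercept[1] else summ$intercept[i],
      coefficients = coefs, cv_r = summ$cv_r[i], p = summ$p[i], q = summ$q[i],
      pass = as.logical(summ$pass[i]), n_features = summ$n_features[i],
      self_rank = summ$self_rank[i]
    ), class = "GeneModel")
  })
  names(models) <- summ$gene
  structure(list(models = models, provenance = prov), class = "ModelSet")
}

#' Tabular views of a model set
#' @param ms A `ModelSet`.
#' @return `model_summary`: one row per model; `coef_table`: long format
#'   `gene`, `feature`, `coefficient`, `intercept`.
#' @export
model_summary <- function(ms) {
  if (length(ms$models) == 0) {
    return(data.frame(gene = character(), mode = character(),
                      alpha = numeric(), lambda = numeric(),
                      intercept = numeric(), cv_r = numeric(), p = numeric(),
                      q = numeric(), pass = logical(),
                      n_features = integer(), self_rank = numeric()))
  }
  do.call(rbind, lapply(ms$models, function(m) {
    data.frame(gene = m$gene, mode = m$mode, alpha = m$alpha,
               lambda = m$lambda, intercept = m$intercept, cv_r = m$cv_r,
               p = m$p, q = m$q, pass = m$pass, n_features = m$n_features,
               self_rank = if (is.null(m$self_rank)) NA_real_ else m$self_rank,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname model_summary
#' @export
coef_table <- function(ms) {
  rows <- lapply(ms$models, function(m) {
    if (length(m$coefficients) == 0) return(NULL)
    data.frame(gene = m$gene, feature = names(m$coefficients),
               coefficient = unname(m$coefficients), intercept = m$intercept,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), feature = character(),
                      coefficient = numeric(), intercept = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Read / write screen construct count tables
#' @param path File path.
#' @return Constructs-by-samples integer matrix.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "construct_id") {
    stop("counts TSV must start with construct_id", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers", call. = FALSE)
  rownames(m) <- df$construct_id
  m
}

#' @rdname read_counts
#' @param counts Constructs-by-samples matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(construct_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a screen design table
#' @param path File path.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("construct_id", "gene_a", "gene_b", paste0("guide", 1:4), "class")
  if (!all(need %in% names(df))) {
    stop("design TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  validate_design(df)
  df
}

#' @rdname read_design
#' @param design Design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export / import planted cohort truth as JSON
#' @param truth A `CohortTruth` list.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
            class = "CohortTruth")
}
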