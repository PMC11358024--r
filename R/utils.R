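#' @keywords internal
"_PACKAGE"

## Seed stream splitting: one global integer seed drives independent
## per-generator streams so cohorts can be regenerated in isolation.
## Offsets are fixed small primes; all derived seeds stay below 2^31.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  offs <- c(
    cells = 101L, tumors = 211L, healthy = 307L, screen = 401L,
    reads = 503L, fit = 601L, align = 701L, boot = 809L, perm = 907L
  )
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[stream]]
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

## Structured one-line-per-stage log. Funnel counts (attempted -> survived)
## are recoverable by grepping "stage=".
td_log <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0(
    "stage=", stage,
    if (length(kv)) paste0(" ", paste(names(kv), unlist(kv), sep = "=", collapse = " "))
  )
  message("[transdep] ", msg)
  invisible(msg)
}

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(name, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(name, " must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(name, ": duplicate gene labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(name, ": duplicate sample labels", call. = FALSE)
  }
  if (any(!is.finite(x))) stop(name, ": non-finite values", call. = FALSE)
  invisible(x)
}

## Intersect two gene x sample matrices on genes, preserving first's order.
intersect_genes <- function(a, b) {
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 2) stop("fewer than 2 shared genes", call. = FALSE)
  td_log("intersect_genes", a = nrow(a), b = nrow(b), shared = length(shared))
  list(a = a[shared, , drop = FALSE], b = b[shared, , drop = FALSE])
}

## Rank-based two-sample AUC: P(score in positive class < score in negative
## class) when direction = "less" (negative scores mark the sensitive class).
rank_auc <- function(score, positive, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  auc <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (direction == "less") 1 - auc else auc
}
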