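test_that("quantile normalization maps columns onto the pooled mean reference", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  qn <- quiet(quantile_normalize(list(x = m)))
  expect_equal(unname(qn$matrices$x[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$matrices$x[, "b"]), c(2.5, 3.5, 4.5))
})

test_that("all columns share one multiset of values after normalization", {
  set.seed(1)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  qn <- quiet(quantile_normalize(list(x = m)))
  sorted <- apply(qn$matrices$x, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # ranks are preserved within each column
  expect_identical(apply(qn$matrices$x, 2, order), apply(m, 2, order))
})

test_that("contrastive PCA reduces to PCA at zero contrast and cancels equal cohorts", {
  set.seed(2)
  fg <- matrix(rnorm(50 * 40), 50, 40, dimnames = list(sprintf("g%d", 1:50), NULL))
  bg <- matrix(rnorm(50 * 40), 50, 40, dimnames = list(sprintf("g%d", 1:50), NULL))
  cp0 <- contrastive_pca(fg, bg, alpha_c = 0, k = 3)
  pc <- stats::prcomp(t(fg), center = TRUE)
  for (j in 1:3) {
    expect_gt(abs(sum(cp0$loadings[, j] * pc$rotation[, j])), 0.999)
  }
  # identical cohorts at alpha 1: the contrast vanishes
  set.seed(3)
  shared <- matrix(rnorm(50 * 500), 50, 500, dimnames = list(rownames(fg), NULL))
  cp1 <- contrastive_pca(shared, shared, alpha_c = 1, k = 3)
  expect_lt(max(abs(cp1$eigenvalues)), 1e-6)
})

test_that("a planted foreground direction is found against an oracle", {
  set.seed(4)
  g <- 50
  v <- rnorm(g); v <- v / sqrt(sum(v^2))
  bg <- matrix(rnorm(g * 300), g, 300, dimnames = list(sprintf("g%d", 1:g), NULL))
  fg <- matrix(rnorm(g * 300), g, 300, dimnames = list(sprintf("g%d", 1:g), NULL)) +
    v %*% t(rnorm(300, sd = 3))
  cp <- contrastive_pca(fg, bg, alpha_c = 1, k = 2)
  expect_gt(abs(sum(cp$loadings[, 1] * v)), 0.95)
  # oracle: SVD of the explicitly formed contrast after a Frobenius shift
  # makes it positive definite (top singular vector = top eigenvector)
  cf <- fg - rowMeans(fg); cb <- bg - rowMeans(bg)
  M <- tcrossprod(cf) / (ncol(cf) - 1) - tcrossprod(cb) / (ncol(cb) - 1)
  Ms <- M + diag(g) * sqrt(sum(M^2))
  u <- svd(Ms)$u[, 1]
  expect_gt(abs(sum(cp$loadings[, 1] * u)), 0.999)
})

test_that("component removal is an idempotent orthogonal projection", {
  set.seed(5)
  x <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:30)))
  U <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  rownames(U) <- rownames(x)
  x1 <- remove_components(x, U)
  x2 <- remove_components(x1, U)
  expect_lt(max(abs(x1 - x2)), 1e-10)
  expect_lt(max(abs(crossprod(U, x1 - rowMeans(x1)))), 1e-8)
  expect_identical(remove_components(x, NULL), x)
})

test_that("a pure shift between cohorts is removed exactly", {
  set.seed(6)
  cells <- matrix(rnorm(30 * 20), 30, 20,
                  dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:20)))
  shift <- rnorm(30)
  tumors <- cells + shift
  colnames(tumors) <- sprintf("t%d", 1:20)
  cm <- quiet(cluster_match_correct(cells, tumors, n_clusters = 1, seed = 1))
  expect_lt(max(abs(rowMeans(cm$tumors) - rowMeans(cells))), 1e-10)
  # already aligned cohorts need essentially no shift
  cm2 <- quiet(cluster_match_correct(cells, cells + matrix(rnorm(600, sd = 1e-3), 30),
                                     n_clusters = 1, seed = 1))
  expect_lt(sqrt(sum(cm2$shifts^2)), 0.05)
  expect_error(cluster_match_correct(cells, tumors, n_clusters = 0), "n_clusters")
})

test_that("lineage-structured cohorts move onto their matched clusters", {
  cc <- fx$cc
  tc <- fx$tc
  al <- quiet(align_cohorts(cc$expression, tc$expression, "tumor", seed = 1))
  lin_t <- tc$truth$tumor_lineages[colnames(al$target)]
  lin_c <- cc$truth$lineages[colnames(al$cells)]
  pre_qn <- quiet(quantile_normalize(list(c = cc$expression, t = tc$expression)))
  dist_between <- function(cells, tumors) {
    mean(vapply(unique(lin_t), function(l) {
      sqrt(sum((rowMeans(tumors[, lin_t == l, drop = FALSE]) -
                rowMeans(cells[, lin_c == l, drop = FALSE]))^2))
    }, numeric(1)))
  }
  pre <- dist_between(pre_qn$matrices$c, pre_qn$matrices$t)
  post <- dist_between(al$cells, al$target)
  expect_lt(post, 0.5 * pre)
})

test_that("location-scale correction undoes a known affine batch effect", {
  set.seed(7)
  cells <- matrix(rnorm(40 * 25, 7, 2), 40, 25,
                  dimnames = list(sprintf("g%d", 1:40), sprintf("c%d", 1:25)))
  healthy <- 2 * cells + 3
  colnames(healthy) <- sprintf("h%d", 1:25)
  gc <- quiet(gtex_style_correct(cells, healthy, n0 = 1))
  qn_cells <- apply_quantile_reference(cells, gc$reference)
  expect_lt(max(abs(rowMeans(gc$healthy) - rowMeans(qn_cells))), 0.05)
  # identical cohorts: the adjustment is the identity up to tolerance
  gc2 <- quiet(gtex_style_correct(cells, cells))
  expect_lt(max(abs(gc2$location)), 1e-8)
  expect_lt(max(abs(gc2$scale - 1)), 1e-8)
})

test_that("tiny healthy cohorts are shrunk toward the global adjustment", {
  set.seed(8)
  cells <- matrix(rnorm(30 * 20, 5), 30, 20,
                  dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:20)))
  healthy <- matrix(rnorm(30 * 2, 8), 30, 2,
                    dimnames = list(rownames(cells), c("h1", "h2")))
  gc <- quiet(gtex_style_correct(cells, healthy, n0 = 10))
  # with n=2 and n0=10 the per-gene location adjustments hug the global mean
  expect_lt(stats::sd(gc$location), stats::sd(rowMeans(
    apply_quantile_reference(cells, gc$reference)) - rowMeans(
      apply_quantile_reference(healthy, gc$reference))))
})

test_that("purity diagnostic flags exact and null relationships", {
  set.seed(9)
  purity <- runif(200, 0.2, 1)
  exact <- matrix(2 * purity + 1, 1, dimnames = list("gA", sprintf("s%d", 1:200)))
  noise <- matrix(rnorm(200), 1, dimnames = list("gA", sprintf("s%d", 1:200)))
  pd <- purity_diagnostic(exact, noise, purity)
  expect_equal(unname(pd$r2_pre["gA"]), 1, tolerance = 1e-12)
  r2_null <- vapply(1:100, function(i) {
    stats::cor(rnorm(200), purity)^2
  }, numeric(1))
  expect_gte(mean(r2_null < 0.05), 0.95)
  expect_error(purity_diagnostic(exact, noise, rep(0.5, 200)), "constant")
})
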