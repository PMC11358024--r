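test_that("exact-match counting rejects single-base mismatches", {
  d <- fx_screen$design
  cnt <- stats::setNames(c(2L), d$construct_id[1])
  reads <- make_reads(d, cnt, seed = 1)
  mut <- reads
  substr(mut[1], 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                    substr(mut[1], 20, 20))[1]
  cg <- quiet(count_guides(mut, d))
  expect_identical(sum(cg$counts), 1L)
  expect_identical(cg$unmapped, 1L)
})

test_that("empty read sets count to zero with a warning", {
  expect_warning(cg <- count_guides(character(0), fx_screen$design), "empty")
  expect_true(all(cg$counts == 0))
})

test_that("flankless reads warn, and error under strict mode", {
  d <- fx_screen$design
  junk <- strrep("A", 80)
  expect_warning(quiet_w <- count_guides(rep(junk, 10), d), "flank")
  expect_error(count_guides(rep(junk, 10), d, strict = TRUE), "flank")
})

test_that("TMM factors: identity, geometric mean, composition bias", {
  set.seed(1)
  base <- rpois(200, 400) + 1
  m <- cbind(a = base, b = base)
  rownames(m) <- sprintf("c%d", 1:200)
  f <- tmm_factors(m)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  # 10% of constructs quadrupled in expectation in b (counts resampled, as
  # real libraries are): trimming excludes them and the factor ratio is set
  # by the unchanged constructs, analytically -log2(library-size ratio)
  mu_b <- rep(400, 200)
  mu_b[1:20] <- 1600
  b2 <- rpois(200, mu_b) + 1
  m2 <- cbind(a = base, b = b2)
  rownames(m2) <- rownames(m)
  f2 <- tmm_factors(m2, ref = "a")
  target <- 2^(-log2(sum(mu_b) / (200 * 400)))
  expect_lt(abs(f2[["b"]] / f2[["a"]] - target) / target, 0.05)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-12)
  expect_error(tmm_factors(m[, 1, drop = FALSE]), ">= 2")
  expect_error(tmm_factors(cbind(a = base, b = 0 * base)), "all-zero")
})

test_that("L2FC identities: null, halving, scale invariance", {
  set.seed(2)
  n <- 200
  base <- rpois(n, 500) + 1
  rn <- sprintf("c%d", 1:n)
  # day14 exactly proportional to plasmid: L2FC ~ 0
  m <- cbind(plasmid = base, day14_rep1 = base * 3L, day14_rep2 = base * 3L)
  rownames(m) <- rn
  lf <- quiet(screen_l2fc(m, factors = stats::setNames(c(1, 1, 1), colnames(m))))
  expect_lt(max(abs(lf$mean)), 0.01)
  # one construct at half proportion
  d14 <- base
  d14[1] <- round(base[1] / 2)
  m2 <- cbind(plasmid = base, day14_rep1 = d14)
  rownames(m2) <- rn
  lf2 <- quiet(screen_l2fc(m2, factors = stats::setNames(c(1, 1), colnames(m2))))
  expect_lt(abs(lf2$mean[1] - (-1)), 0.05)
  # doubling all counts of a sample changes nothing (proportion-based)
  m3 <- cbind(plasmid = base, day14_rep1 = d14 * 2L)
  rownames(m3) <- rn
  lf3 <- quiet(screen_l2fc(m3, factors = stats::setNames(c(1, 1), colnames(m3))))
  expect_equal(lf3$mean, lf2$mean, tolerance = 0.01)
})

test_that("GI arithmetic matches the expected-sum definition", {
  # craft construct L2FCs whose NTxNT null has mean 0, sd 1, so values read
  # directly as z-scores
  nt_vals <- as.numeric(scale(seq(-1.5, 1.5, length.out = 12)))
  design <- data.frame(
    construct_id = c(sprintf("nt%d", 1:12), "sA", "sB", "dAB"),
    gene_a = c(rep("NT", 12), "A", "B", "A"),
    gene_b = c(rep("NT", 12), "NT", "NT", "B"),
    guide1 = sprintf("AAAA%02d", 1:15), guide2 = sprintf("CCCC%02d", 1:15),
    guide3 = sprintf("GGGG%02d", 1:15), guide4 = sprintf("TTTT%02d", 1:15),
    class = c(rep("NTxNT", 12), "singleKO", "singleKO", "DKO"),
    stringsAsFactors = FALSE
  )
  l2fc <- stats::setNames(c(nt_vals, -1, -0.5, -3), design$construct_id)
  # one DKO: difference z-scoring degenerates; add a second neutral pair
  design2 <- rbind(design,
                   data.frame(construct_id = c("sC", "sD", "dCD"),
                              gene_a = c("C", "D", "C"),
                              gene_b = c("NT", "NT", "D"),
                              guide1 = sprintf("AAAA%02d", 16:18),
                              guide2 = sprintf("CCCC%02d", 16:18),
                              guide3 = sprintf("GGGG%02d", 16:18),
                              guide4 = sprintf("TTTT%02d", 16:18),
                              class = c("singleKO", "singleKO", "DKO")))
  l2fc2 <- c(l2fc, sC = 0.2, sD = -0.1, dCD = 0.1)
  gi <- gi_scores(l2fc2, design2)
  ab <- gi[gi$gene_a == "A" & gi$gene_b == "B", ]
  expect_equal(ab$observed_z, -3, tolerance = 1e-12)
  expect_equal(ab$expected_z, -1.5, tolerance = 1e-12)
  expect_equal(ab$difference, -1.5, tolerance = 1e-12)
  expect_error(gi_scores(l2fc2[-(1:6)], design2[-(1:6), ]), "NTxNT")
})

test_that("pair keys are canonical in gene order", {
  tab1 <- data.frame(gene_a = "A", gene_b = "B", diff_z = -2)
  tab2 <- data.frame(gene_a = "A", gene_b = "B", diff_z = -2.2)
  expect_equal(screen_concordance(rbind(tab1, data.frame(gene_a = c("C", "D"),
                                                         gene_b = c("E", "F"),
                                                         diff_z = c(0, 1))),
                                  rbind(tab2, data.frame(gene_a = c("C", "D"),
                                                         gene_b = c("E", "F"),
                                                         diff_z = c(0.1, 1.1)))),
               stats::cor(c(-2, 0, 1), c(-2.2, 0.1, 1.1)), tolerance = 1e-12)
})

test_that("multiple single-KO constructs collapse to the median", {
  sg <- fx_screen
  lf <- quiet(screen_l2fc(sg$counts$counts))
  gi <- gi_scores(lf$mean, sg$design)
  # the fixture has 2 single-KO constructs per gene; expected z must equal
  # the sum of the per-gene medians
  nt <- lf$mean[sg$design$class == "NTxNT"]
  z <- (lf$mean - mean(nt)) / stats::sd(nt)
  singles <- sg$design$class == "singleKO"
  sgene <- ifelse(sg$design$gene_a[singles] == "NT",
                  sg$design$gene_b[singles], sg$design$gene_a[singles])
  med <- tapply(z[singles], sgene, stats::median)
  row <- gi[gi$gene_a == "G01" & gi$gene_b == "G02", ]
  expect_equal(row$expected_z, unname(med["G01"] + med["G02"]),
               tolerance = 1e-12)
})

test_that("planted interactions surface with the most negative scores", {
  gi <- quiet(screen_gi(fx_screen$counts$counts, fx_screen$design))
  expect_identical(paste(gi$gene_a[1], gi$gene_b[1]), "G01 G02")
  expect_identical(gi$diff_z[1], min(gi$diff_z))
  # the call column is a pure function of diff_z at the +/-2 bar
  expect_identical(gi$call == "synthetic_lethal", gi$diff_z < -2)
  expect_identical(gi$call == "buffering", gi$diff_z > 2)
})

test_that("re-simulated replicate screens agree", {
  r1 <- quiet(screen_gi(make_screen_counts(fx_screen$design, fx_screen$gi_truth,
                                           fx_screen$single, seed = 21)$counts,
                        fx_screen$design))
  r2 <- quiet(screen_gi(make_screen_counts(fx_screen$design, fx_screen$gi_truth,
                                           fx_screen$single, seed = 22)$counts,
                        fx_screen$design))
  expect_gt(screen_concordance(r1, r2), 0.3)
})
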