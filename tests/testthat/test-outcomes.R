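test_that("log-rank O-E matches hand hypergeometric accumulation", {
  lr <- logrank_test(c(1, 3), c(1, 1), c(2, 4), c(1, 1))
  # E_A = 2/4 + 1/3 + 1/2 = 4/3; O_A = 2; O - E = 2/3
  expect_equal(lr$o_minus_e, 2 / 3, tolerance = 1e-4)
  # identical groups: statistic 0
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  # label swap flips the sign, same P
  lr_ab <- logrank_test(c(1, 3, 6), c(1, 1, 0), c(2, 4, 7), c(1, 1, 1))
  lr_ba <- logrank_test(c(2, 4, 7), c(1, 1, 1), c(1, 3, 6), c(1, 1, 0))
  expect_equal(lr_ab$o_minus_e, -lr_ba$o_minus_e, tolerance = 1e-10)
  expect_equal(lr_ab$p, lr_ba$p, tolerance = 1e-10)
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "empty")
})

test_that("log-rank equals the Cox score test for a binary covariate", {
  set.seed(1)
  n <- 60
  grp <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.1 * (1.6^grp)) + seq_len(n) * 1e-7  # break ties
  ev <- rep(1L, n)
  lr <- logrank_test(tt[grp == 1], ev[grp == 1], tt[grp == 0], ev[grp == 0])
  cx <- cox_hr(grp, tt, ev)
  expect_equal(lr$p, unname(cx$p_score), tolerance = 1e-6)
})

test_that("Cox fits match a grid-search partial-likelihood oracle", {
  tt <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1, 1, 0, 1, 1, 1)
  x <- c(0.3, -1.2, 0.5, 1.8, -0.7, 0.1)
  pl <- function(beta) {
    ord <- order(tt)
    s <- 0
    for (i in ord) {
      if (ev[i] == 1) {
        risk <- tt >= tt[i]
        s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
      }
    }
    s
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  cx <- cox_hr(x, tt, ev)
  expect_equal(log(cx$hr), beta_grid, tolerance = 1e-3)
})

test_that("Cox recovers a true hazard ratio of 2 and covers the null", {
  hrs <- vapply(1:20, function(s) {
    set.seed(s)
    grp <- rbinom(500, 1, 0.5)
    tt <- rexp(500, 0.05 * 2^grp)
    cox_hr(grp, tt, rep(1L, length(tt)))$hr
  }, numeric(1))
  # with full follow-up at n=500 the log-HR standard error is ~0.09, so the
  # seed-level band holds for most seeds and the median is tight
  expect_gte(sum(hrs >= 1.7 & hrs <= 2.3), 16)
  expect_gte(stats::median(hrs), 1.8)
  expect_lte(stats::median(hrs), 2.2)
  cover <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    grp <- rbinom(150, 1, 0.5)
    tt <- rexp(150, 0.1)
    ev <- as.integer(tt <= 15)
    ci <- cox_hr(grp, pmin(tt, 15), ev)$ci
    ci[1] <= 1 && ci[2] >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("maxstat finds a planted median changepoint", {
  found <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    sc <- rnorm(n)
    rate <- ifelse(sc > stats::median(sc), 0.2, 0.1)
    tt <- rexp(n, rate)
    ev <- as.integer(tt <= 15)
    mx <- maxstat_cutpoint(sc, pmin(tt, 15), ev, seed = s)
    pct <- mean(sc < mx$cutpoint)
    pct >= 0.40 && pct <= 0.60
  }, logical(1))
  expect_gte(sum(found), 18)
})

test_that("maxstat respects the admissible quantile range", {
  set.seed(2)
  n <- 100
  sc <- rnorm(n)
  tt <- rexp(n, 0.1)
  ev <- rep(1L, n)
  mx <- maxstat_cutpoint(sc, tt, ev, qrange = c(0.25, 0.75), seed = 1)
  pct <- mean(sc <= mx$cutpoint)
  expect_gte(pct, 0.2)
  expect_lte(pct, 0.8)
  expect_error(maxstat_cutpoint(sc[1:5], tt[1:5], ev[1:5]), ">= 10")
  expect_error(maxstat_cutpoint(sc, tt, rep(0L, n)), "events")
})

test_that("permutation correction keeps null maxstat calibrated", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 120
    sc <- rnorm(n)
    tt <- rexp(n, 0.1)
    ev <- as.integer(tt <= 12)
    maxstat_cutpoint(sc, pmin(tt, 12), ev, n_perm = 100, seed = s)$p < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.15)  # 1.5x nominal plus binomial noise at 40 sims
})

test_that("the hazard gene is detected and strata guards hold", {
  tc <- fx$tc
  hz <- tc$truth$hazard_gene
  map <- tc$truth$latent_essentiality
  lin <- tc$truth$tumor_lineages
  res <- quiet(pfi_scan(map, tc$survival, lineage = lin,
                        genes = c(hz, fx$cc$truth$noise_genes[1:5]),
                        n_perm = 100, seed = 1))
  hzrow <- res[res$gene == hz, ]
  expect_true(hzrow$significant)
  expect_gt(hzrow$hr, 1)  # stronger dependency, worse outcome
  # lineages below the minimum stratum size are excluded
  expect_message(
    pfi_scan(map, tc$survival, lineage = lin, genes = hz,
             min_stratum = 1e5, n_perm = 10, seed = 1),
    "dropped_lineages")
})

test_that("SL carrier survival needs >= 10 carriers and logs its rule", {
  tc <- fx$tc
  pair <- c(tc$truth$sl_pairs$gene_a[1], tc$truth$sl_pairs$gene_b[1])
  expect_message(
    res <- sl_survival(tc$truth$latent_essentiality, tc$lof, pair,
                       tc$survival, lineage = tc$truth$tumor_lineages),
    "group_rule")
  expect_true(res$n_carrier >= 10)
  expect_true(is.finite(res$hr) || is.na(res$hr))
  tiny_lof <- tc$lof
  tiny_lof[pair[2], ] <- 0
  expect_error(quiet(sl_survival(tc$truth$latent_essentiality, tiny_lof, pair,
                                 tc$survival)), "< 10")
})

test_that("response association: separation, null, guards", {
  resp <- c(rep(TRUE, 10), rep(FALSE, 10))
  sc <- c(seq(-2, -1.5, length.out = 10), seq(-0.2, 0, length.out = 10))
  r <- response_assoc(sc, resp)
  expect_identical(r$auc, 1)
  # label shuffles hover near chance
  aucs <- vapply(1:50, function(i) {
    set.seed(i)
    response_assoc(sc, sample(resp))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
  expect_error(response_assoc(sc[1:5], resp[1:5]), "fewer than")
  expect_error(response_assoc(sc, rep(TRUE, 20)), "single-class")
  # continuous response: correlation recovered
  set.seed(3)
  burden <- sc + rnorm(20, sd = 0.3)
  rc <- response_assoc(sc, burden)
  expect_identical(rc$type, "continuous")
  expect_gt(rc$r, 0.7)
})

test_that("dependency-signature LDA separates planted subtypes", {
  set.seed(4)
  k <- 3
  n_per <- 25
  centers <- matrix(rnorm(40 * k, sd = 2), 40, k)
  labs <- factor(rep(letters[1:k], each = n_per))
  map <- centers[, as.integer(labs)] + matrix(rnorm(40 * k * n_per), 40)
  dimnames(map) <- list(sprintf("g%d", 1:40), sprintf("s%d", seq_along(labs)))
  res <- quiet(dep100_subtype(map, labs, k = 30))
  expect_true(all(res$auc > 0.9))
  # permuted labels: chance-level discrimination
  aucs <- vapply(1:10, function(i) {
    set.seed(i)
    mean(quiet(dep100_subtype(map, sample(labs), k = 30))$auc)
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
  expect_warning(dep100_subtype(map, labs, k = 500), "clamped")
})

test_that("driver enrichment reproduces the hypergeometric tail", {
  # 2x2 table [[3,1],[1,5]]: one-sided P = (C(4,3)C(6,1) + C(4,4)C(6,0)) / C(10,4)
  map <- matrix(c(sort(rnorm(10))), 1, dimnames = list("gD", sprintf("s%d", 1:10)))
  variant <- matrix(0, 1, 10, dimnames = list("v1", colnames(map)))
  variant[1, colnames(map)[order(map[1, ])][c(1, 2, 3, 5)]] <- 1  # 3 of 4 dependent
  res <- driver_enrichment(map, list(mutation = variant), "gD", top_frac = 0.4)
  expect_equal(res$p, 25 / 210, tolerance = 1e-10)
  # oracle: hypergeometric tail
  expect_equal(res$p, sum(stats::dhyper(3:4, 4, 6, 4)), tolerance = 1e-12)
  # prevalence filter: 4% excluded, 6% included at the 5% mutation bar
  n <- 100
  map2 <- matrix(rnorm(n), 1, dimnames = list("gD", sprintf("s%d", 1:n)))
  vm <- rbind(rare = c(rep(1, 4), rep(0, n - 4)),
              common = c(rep(1, 6), rep(0, n - 6)))
  colnames(vm) <- colnames(map2)
  res2 <- quiet(driver_enrichment(map2, list(mutation = vm), "gD"))
  expect_identical(res2$variant, "common")
})

test_that("null genes produce BH-controlled discoveries", {
  set.seed(6)
  n <- 120
  tt <- rexp(n, 0.1)
  ev <- as.integer(tt <= 12)
  surv <- data.frame(sample = sprintf("s%d", 1:n), time = pmin(tt, 12),
                     event = ev)
  map <- matrix(rnorm(30 * n), 30, n,
                dimnames = list(sprintf("g%d", 1:30), surv$sample))
  res <- quiet(pfi_scan(map, surv, n_perm = 100, seed = 2))
  expect_lte(sum(res$significant), 2)
})
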