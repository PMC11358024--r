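# Shared synthetic fixtures, built once per test run. Everything is
# generated in code from fixed seeds; no data files.

fx <- local({
  cc <- suppressMessages(make_cell_cohort(seed = 42))
  tc <- suppressMessages(make_tumor_cohort(cc$truth, seed = 42))
  # larger cohort for the synthetic-lethality stages, which are powered at
  # patient-cohort rather than cell-panel sample sizes
  tc500 <- suppressMessages(make_tumor_cohort(cc$truth, n_tumors = 500,
                                              seed = 42))
  list(cc = cc, tc = tc, tc500 = tc500)
})

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# tiny screen fixture used by screen tests
fx_screen <- local({
  genes <- sprintf("G%02d", 1:12)
  pairs <- data.frame(gene_a = genes[seq(1, 11, 2)],
                      gene_b = genes[seq(2, 12, 2)],
                      stringsAsFactors = FALSE)
  design <- make_screen_design(genes, pairs, n_nt = 15, seed = 9)
  single <- stats::setNames(seq(-1, 0, length.out = length(genes)), genes)
  gi_truth <- data.frame(gene_a = "G01", gene_b = "G02", gi = -2,
                         stringsAsFactors = FALSE)
  counts <- make_screen_counts(design, gi_truth, single, depth = 400,
                               dispersion = 0.05, seed = 9)
  list(genes = genes, pairs = pairs, design = design, single = single,
       gi_truth = gi_truth, counts = counts)
})
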