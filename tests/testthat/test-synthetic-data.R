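test_that("design_config rejects invalid parameters", {
  expect_error(design_config(n_mirna = 0), "positive")
  expect_error(design_config(class_fractions = c(
    hs_dep_up = 0.5, hs_dep_down = 0.5, hs_indep_up = 0.1,
    hs_indep_down = 0, unclassified = 0)), "sum to 1")
  expect_error(design_config(baseline_mean = 0), "> 0")
})

test_that("planted class means follow the class definitions", {
  classes <- c("hs_dep_up", "hs_dep_down", "hs_indep_up", "hs_indep_down",
               "unclassified")
  mean_row <- function(class, baseline, effect) {
    frac <- setNames(as.numeric(classes == class), classes)
    cfg <- design_config(n_mirna = 1, baseline_mean = baseline,
                         class_fractions = frac, effect_log2fc = effect,
                         seed = 1)
    unname(generate_truth(cfg)$means[1, ])
  }
  expect_equal(mean_row("unclassified", 500, 2), c(500, 500, 500, 500))
  expect_equal(mean_row("hs_dep_up", 100, 2), c(100, 400, 100, 100))
  expect_equal(mean_row("hs_dep_down", 100, 2), c(100, 25, 100, 100))
  expect_equal(mean_row("hs_indep_down", 100, 1), c(100, 100, 200, 200))
  expect_equal(mean_row("hs_indep_up", 100, 1), c(100, 100, 50, 50))
})

test_that("count simulation is reproducible and seed-sensitive", {
  cfg <- design_config(n_mirna = 50, seed = 42)
  tr <- generate_truth(cfg)
  m1 <- simulate_counts(tr, cfg)
  m2 <- simulate_counts(tr, cfg)
  expect_identical(unclass(m1), unclass(m2))
  cfg2 <- design_config(n_mirna = 50, seed = 43)
  m3 <- simulate_counts(generate_truth(cfg2), cfg2)
  expect_false(identical(unclass(m1), unclass(m3)))
})

test_that("simulated counts recover the planted first two moments", {
  # one unclassified miRNA, many pseudo-replicates, no library jitter
  frac <- c(hs_dep_up = 0, hs_dep_down = 0, hs_indep_up = 0,
            hs_indep_down = 0, unclassified = 1)
  cfg <- design_config(n_mirna = 1, n_replicates = 2500,
                       baseline_mean = 1000, dispersion = 0.01,
                       class_fractions = frac, library_size_spread = 0,
                       seed = 5)
  x <- as.numeric(simulate_counts(generate_truth(cfg), cfg))
  n <- length(x)
  expect_equal(n, 10000L)
  se <- sqrt((1000 + 1000^2 * 0.01) / n)
  expect_lt(abs(mean(x) - 1000), 3 * se)

  # dispersion 0 degenerates to Poisson: variance ~ mean
  cfg0 <- design_config(n_mirna = 1, n_replicates = 2500,
                        baseline_mean = 1000, dispersion = 0,
                        class_fractions = frac, library_size_spread = 0,
                        seed = 6)
  y <- as.numeric(simulate_counts(generate_truth(cfg0), cfg0))
  expect_lt(abs(var(y) / mean(y) - 1), 0.1)
})

test_that("realized class counts follow the configured fractions", {
  classes <- c("hs_dep_up", "hs_dep_down", "hs_indep_up", "hs_indep_down",
               "unclassified")
  observed <- setNames(numeric(5), classes)
  n_seeds <- 50
  n_mirna <- 200
  for (s in seq_len(n_seeds)) {
    tr <- generate_truth(design_config(n_mirna = n_mirna, seed = s))
    tab <- table(factor(tr$class, levels = classes))
    observed <- observed + as.numeric(tab)
  }
  expected_p <- c(0.05, 0.05, 0.05, 0.05, 0.80)
  gof <- suppressWarnings(chisq.test(observed, p = expected_p))
  expect_gt(gof$p.value, 0.001)
})

test_that("simulated reads are mature+adapter with planted error rate", {
  ref <- c(mirA = "ACGTACGTACGTACGTACGTAC")
  counts <- matrix(3L, 1, 1, dimnames = list("mirA", "s1"))
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  reads <- simulate_reads(counts, ref, adapter, error_rate = 0, seed = 1)
  expect_length(reads$s1, 3L)
  expect_true(all(reads$s1 == paste0(ref[["mirA"]], adapter)))

  counts0 <- matrix(0L, 1, 1, dimnames = list("mirA", "s1"))
  expect_length(simulate_reads(counts0, ref, adapter, seed = 1)$s1, 0L)

  # binomial expectation: 22 nt x 0.05 = 1.1 mismatches per read
  n_reads <- 10000L
  counts_big <- matrix(n_reads, 1, 1, dimnames = list("mirA", "s1"))
  noisy <- simulate_reads(counts_big, ref, adapter, error_rate = 0.05,
                          seed = 2)$s1
  mature <- substr(noisy, 1, 22)
  ref_ch <- strsplit(ref[["mirA"]], "")[[1]]
  mm <- vapply(strsplit(mature, ""), function(ch) sum(ch != ref_ch),
               numeric(1))
  se <- sqrt(22 * 0.05 * 0.95 / n_reads)
  expect_lt(abs(mean(mm) - 1.1), 3 * se)

  # missing reference for a counted miRNA is an error
  counts2 <- matrix(1L, 2, 1, dimnames = list(c("mirA", "mirB"), "s1"))
  expect_error(simulate_reads(counts2, ref, adapter, seed = 1),
               "no reference")
})

test_that("target maps plant the stated keepable fraction", {
  cfg <- design_config(n_mirna = 250, seed = 11)
  tr <- generate_truth(cfg)
  tm1 <- simulate_target_map(tr, n_genes = 400, frac_inverse = 1, seed = 3)
  expect_true(all(tm1$truth_edges$keepable))
  tm0 <- simulate_target_map(tr, n_genes = 400, frac_inverse = 0, seed = 3)
  expect_false(any(tm0$truth_edges$keepable))

  # ~1000 planted edges at frac 0.5: binomial 3 SE band
  cfg_big <- design_config(n_mirna = 1000, seed = 12)
  tr_big <- generate_truth(cfg_big)
  tm <- simulate_target_map(tr_big, n_genes = 1500, frac_inverse = 0.5,
                            targets_per_mirna = 5, seed = 4)
  n_edges <- nrow(tm$truth_edges)
  expect_lt(abs(sum(tm$truth_edges$keepable) - 0.5 * n_edges),
            3 * sqrt(n_edges * 0.25))
  # genes serve at most one edge each
  expect_false(anyDuplicated(tm$truth_edges$gene) > 0)
})

test_that("planted annotations over-represent the target set", {
  genes <- sprintf("g%03d", 1:500)
  targets <- genes[1:50]
  ann <- simulate_annotations(genes, targets, n_terms = 20, n_planted = 2,
                              term_size = 20, enrichment_factor = 10,
                              seed = 9)
  planted_overlap <- mean(vapply(ann$planted_terms, function(tid) {
    length(intersect(ann$annotations$gene[ann$annotations$term_id == tid],
                     targets))
  }, numeric(1)))
  expect_gt(planted_overlap, 20 * 50 / 500)   # hypergeometric mean 2.0

  # factor 1 is the null: planted terms behave like background
  ann_null <- simulate_annotations(genes, targets, n_terms = 40,
                                   n_planted = 20, term_size = 20,
                                   enrichment_factor = 1, seed = 10)
  null_overlap <- mean(vapply(ann_null$planted_terms, function(tid) {
    length(intersect(
      ann_null$annotations$gene[ann_null$annotations$term_id == tid],
      targets))
  }, numeric(1)))
  expect_lt(abs(null_overlap - 2.0), 1.5)
  expect_error(simulate_annotations(genes, targets, term_size = 501),
               "universe")
})

test_that("interaction simulation respects density bounds", {
  genes <- sprintf("g%02d", 1:40)
  expect_identical(nrow(simulate_interactions(genes, 0, seed = 1)), 0L)
  e <- simulate_interactions(genes, 0.1, seed = 2)
  n_pairs <- choose(40, 2)
  expect_lt(abs(nrow(e) - 0.1 * n_pairs), 3 * sqrt(n_pairs * 0.1 * 0.9))
  expect_true(all(e$gene_a < e$gene_b))
  expect_identical(e, simulate_interactions(genes, 0.1, seed = 2))
})
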