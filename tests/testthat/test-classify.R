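# Fixture universe and helper to build the five contrasts from per-miRNA
# (log2fc, q) pairs; unspecified miRNAs default to a clean null.
fixture_contrasts <- function(ids, pattern) {
  build <- function(key) {
    lfc <- setNames(rep(0, length(ids)), ids)
    q <- setNames(rep(1, length(ids)), ids)
    if (key %in% names(pattern)) {
      for (m in names(pattern[[key]])) {
        lfc[m] <- pattern[[key]][[m]][1]
        q[m] <- pattern[[key]][[m]][2]
      }
    }
    make_contrast(ids, unname(lfc), unname(q), label = key)
  }
  keys <- c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0", "C1_vs_C2", "C2_vs_C3")
  setNames(lapply(keys, build), keys)
}

test_that("venn partition enumerates the seven disjoint regions", {
  ids <- sprintf("m%02d", 1:10)
  cons <- fixture_contrasts(ids, list(
    C1_vs_C0 = list(m01 = c(2, 0.01))))
  p <- venn_partition(cons[c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")])
  expect_identical(p$up[["C1_vs_C0"]], "m01")
  expect_true(all(lengths(p$up[-1]) == 0))
  expect_true(all(lengths(p$down) == 0))
  expect_equal(sum(p$counts$n), 1)

  # no significant miRNAs -> all regions empty
  p0 <- venn_partition(fixture_contrasts(ids, list())[1:3])
  expect_true(all(lengths(p0$up) == 0) && all(lengths(p0$down) == 0))

  # three identical significant sets -> everything in the triple overlap
  trip <- list(m01 = c(1, 0.01), m02 = c(1, 0.01), m03 = c(1, 0.01))
  p3 <- venn_partition(fixture_contrasts(
    ids, list(C1_vs_C0 = trip, C2_vs_C0 = trip, C3_vs_C0 = trip))[1:3])
  expect_setequal(p3$up[["C1_vs_C0&C2_vs_C0&C3_vs_C0"]],
                  c("m01", "m02", "m03"))
  expect_equal(sum(lengths(p3$up)), 3)

  # region counts sum to the union size and regions are disjoint
  mixed <- fixture_contrasts(ids, list(
    C1_vs_C0 = list(m01 = c(1, 0.01), m02 = c(1, 0.01)),
    C2_vs_C0 = list(m02 = c(1, 0.01), m03 = c(-1, 0.01)),
    C3_vs_C0 = list(m02 = c(1, 0.01))))
  pm <- venn_partition(mixed[1:3])
  up_members <- unlist(pm$up)
  expect_false(anyDuplicated(up_members) > 0)
  expect_equal(length(up_members), 2)  # m01, m02 (m03 is a down call)
  expect_error(venn_partition(list(C1_vs_C0 = mixed$C1_vs_C0,
                                   C2_vs_C0 = mixed$C2_vs_C0,
                                   C3_vs_C0 = make_contrast("zz", 1, 1))),
               "mismatched")
})

test_that("worked examples reproduce the reported class calls and signs", {
  ids <- c("miR-784", "miR-239b", "miR-00x")
  cons <- fixture_contrasts(ids, list(
    # miR-784: up on heat shock, difference requires HSF-1
    C1_vs_C0 = list(`miR-784` = c(1.35, 0.01)),
    C1_vs_C2 = list(`miR-784` = c(1.2, 0.02)),
    # miR-239b: rises on knockdown without heat; knockdown conditions agree
    C3_vs_C0 = list(`miR-239b` = c(5.70, 0.003)),
    C2_vs_C3 = list(`miR-239b` = c(0.1, 0.9))))
  calls <- call_classes(cons[c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")],
                        cons[c("C1_vs_C2", "C2_vs_C3")])
  r784 <- calls[calls$mirna == "miR-784", ]
  expect_identical(as.character(r784$class), "hs_dep_up")
  expect_equal(r784$reported_log2fc, 1.35)
  r239 <- calls[calls$mirna == "miR-239b", ]
  expect_identical(as.character(r239$class), "hs_indep_down")
  expect_equal(r239$reported_log2fc, -5.70)
  expect_identical(as.character(calls$class[calls$mirna == "miR-00x"]),
                   "unclassified")
})

test_that("confirmatory failures leave candidates unclassified", {
  ids <- c("mA", "mB")
  cons <- fixture_contrasts(ids, list(
    C1_vs_C0 = list(mA = c(2, 0.01)),
    C1_vs_C2 = list(mA = c(0.2, 0.4))))
  calls <- call_classes(cons[c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")],
                        cons[c("C1_vs_C2", "C2_vs_C3")])
  a <- calls[calls$mirna == "mA", ]
  expect_identical(as.character(a$class), "unclassified")
  expect_true(a$candidate)
  expect_false(calls$candidate[calls$mirna == "mB"])

  # independent candidate failing its confirmation (knockdown conditions
  # differ significantly) also stays unclassified
  cons2 <- fixture_contrasts(ids, list(
    C3_vs_C0 = list(mA = c(-2, 0.01)),
    C2_vs_C3 = list(mA = c(1, 0.01))))
  calls2 <- call_classes(cons2[c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")],
                         cons2[c("C1_vs_C2", "C2_vs_C3")])
  expect_identical(as.character(calls2$class[calls2$mirna == "mA"]),
                   "unclassified")
  expect_true(calls2$candidate[calls2$mirna == "mA"])
})

test_that("dual-eligible miRNAs keep the dependent label with provenance", {
  ids <- "miR-228"
  cons <- fixture_contrasts(ids, list(
    C1_vs_C0 = list(`miR-228` = c(-1.5, 0.01)),
    C1_vs_C2 = list(`miR-228` = c(-1.2, 0.02)),
    C3_vs_C0 = list(`miR-228` = c(2.1, 0.01)),
    C2_vs_C3 = list(`miR-228` = c(0.1, 0.8))))
  calls <- call_classes(cons[c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")],
                        cons[c("C1_vs_C2", "C2_vs_C3")])
  expect_identical(as.character(calls$class), "hs_dep_down")
  expect_identical(calls$dep_class, "hs_dep_down")
  expect_identical(calls$indep_class, "hs_indep_down")
  expect_equal(calls$reported_log2fc, -1.5)  # dependent convention
})

test_that("every miRNA receives exactly one class and signs obey the convention", {
  cfg <- design_config(n_mirna = 400, seed = 91)
  tr <- generate_truth(cfg)
  counts <- filter_detected(simulate_counts(tr, cfg))
  sheet <- attr(counts, "sample_sheet")
  fit <- ql_fit(counts, sheet)
  con <- function(a, b) mir_contrast(counts, a, b, sheet, "ql", fit)
  calls <- call_classes(
    list(C1_vs_C0 = con("C0", "C1"), C2_vs_C0 = con("C0", "C2"),
         C3_vs_C0 = con("C0", "C3")),
    list(C1_vs_C2 = con("C2", "C1"), C2_vs_C3 = con("C3", "C2")))
  expect_equal(nrow(calls), nrow(counts))
  expect_false(any(is.na(calls$class)))
  expect_false(anyDuplicated(calls$mirna) > 0)
  indep <- calls$class %in% c("hs_indep_up", "hs_indep_down")
  expect_equal(calls$reported_log2fc[indep], -calls$lfc_c3_vs_c0[indep])
  dep <- calls$class %in% c("hs_dep_up", "hs_dep_down")
  expect_equal(calls$reported_log2fc[dep], calls$lfc_c1_vs_c0[dep])
})

test_that("a fully null experiment yields few regulatory calls", {
  frac <- c(hs_dep_up = 0, hs_dep_down = 0, hs_indep_up = 0,
            hs_indep_down = 0, unclassified = 1)
  n_calls <- vapply(1:50, function(s) {
    cfg <- design_config(n_mirna = 300, baseline_mean = 200, dispersion = 0,
                         class_fractions = frac, seed = 1000 + s)
    counts <- filter_detected(simulate_counts(generate_truth(cfg), cfg))
    sheet <- attr(counts, "sample_sheet")
    con <- function(a, b) mir_contrast(counts, a, b, sheet, "exact")
    calls <- call_classes(
      list(C1_vs_C0 = con("C0", "C1"), C2_vs_C0 = con("C0", "C2"),
           C3_vs_C0 = con("C0", "C3")),
      list(C1_vs_C2 = con("C2", "C1"), C2_vs_C3 = con("C3", "C2")))
    sum(calls$class != "unclassified")
  }, numeric(1))
  expect_lte(mean(n_calls), 0.05 * 300)
})

test_that("classification report tabulates members and confusion marginals", {
  ids <- c("mA", "mB")
  cons <- fixture_contrasts(ids, list())
  empty_calls <- call_classes(cons[c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")],
                              cons[c("C1_vs_C2", "C2_vs_C3")])
  rep0 <- classification_report(empty_calls)
  expect_true(all(vapply(rep0$class_tables, nrow, integer(1)) == 0L))
  expect_equal(unname(rep0$class_counts["unclassified"]), 2L)

  cons1 <- fixture_contrasts(ids, list(
    C1_vs_C0 = list(mA = c(2, 0.01)),
    C1_vs_C2 = list(mA = c(2, 0.01)),
    C3_vs_C0 = list(mB = c(-2, 0.01))))
  calls1 <- call_classes(cons1[c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")],
                         cons1[c("C1_vs_C2", "C2_vs_C3")])
  truth <- c(mA = "hs_dep_up", mB = "hs_indep_up")
  rep1 <- classification_report(calls1, truth = truth)
  expect_equal(nrow(rep1$class_tables$hs_dep_up), 1L)
  expect_equal(unname(rowSums(rep1$confusion)[c("hs_dep_up",
                                                "hs_indep_up")]),
               c(1, 1))
  expect_equal(sum(rep1$confusion), 2)
})
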