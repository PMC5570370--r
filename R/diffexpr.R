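#' Remove miRNAs not detected in every replicate
#'
#' The strict default drops any miRNA with a zero count in *any* sample
#' (miRNAs without reads in each biological replicate are removed before
#' testing). `mode = "any_condition"` relaxes this to requiring nonzero
#' counts in every replicate of at least one condition.
#'
#' @param counts Count matrix (miRNA x sample).
#' @param sheet Sample sheet (`sample_id`, `condition`, `replicate`);
#'   required only for `mode = "any_condition"`. Defaults to the matrix's
#'   `sample_sheet` attribute.
#' @param mode `"all_samples"` (default, strict) or `"any_condition"`.
#' @return The filtered count matrix (attributes preserved).
#' @export
filter_detected <- function(counts, sheet = attr(counts, "sample_sheet"),
                            mode = c("all_samples", "any_condition")) {
  mode <- match.arg(mode)
  if (!nrow(counts)) return(counts)
  keep <- if (mode == "all_samples") {
    apply(counts >= 1, 1L, all)
  } else {
    ok <- vapply(unique(sheet$condition), function(cc) {
      cols <- sheet$sample_id[sheet$condition == cc]
      apply(counts[, cols, drop = FALSE] >= 1, 1L, all)
    }, logical(nrow(counts)))
    apply(ok, 1L, any)
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "sample_sheet") <- attr(counts, "sample_sheet")
  out
}

#' Library-size factors
#'
#' `factor_s = total_s / mean(totals)`; dividing a sample's counts by its
#' factor equalizes column totals.
#'
#' @param counts Count matrix (miRNA x sample).
#' @return Named numeric vector of positive factors.
#' @export
size_factors <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("sample with zero total count", call. = FALSE)
  totals / mean(totals)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with sorted `p(1) <= ... <= p(m)`,
#' `q(i) = min_{j >= i} p(j) * m / j`, capped at 1, returned in input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Fit the quasi-likelihood model once for reuse across contrasts
#'
#' Dispersion-aware alternative test backend (negative-binomial
#' quasi-likelihood via edgeR) for overdispersed replicate counts; fit once
#' and pass to [mir_contrast()] to avoid repeated estimation.
#'
#' @param counts Filtered count matrix.
#' @param sheet Sample sheet.
#' @return An edgeR `DGEGLM` fit with the design attached.
#' @export
ql_fit <- function(counts, sheet = attr(counts, "sample_sheet")) {
  cond <- factor(sheet$condition, levels = CONDITIONS)
  design <- stats::model.matrix(~0 + cond)
  colnames(design) <- levels(cond)
  d <- edgeR::DGEList(counts = counts, group = cond)
  d <- edgeR::calcNormFactors(d)
  d <- edgeR::estimateDisp(d, design)
  edgeR::glmQLFit(d, design)
}

#' Control-relative differential expression for one condition pair
#'
#' Orientation is `b` vs `a`: `log2FC = log2(mean_b) - log2(mean_a)` on
#' library-size-normalized counts averaged within each side (the
#' control-relative fold-change scheme, with depth normalization applied
#' first so sequencing depth does not masquerade as regulation).
#'
#' Two test backends:
#' * `"exact"` (default): two-sided exact conditional binomial test on
#'   pooled raw counts across each side's replicates, conditioning on the
#'   pooled total with success probability equal to side `b`'s effective
#'   library share. Deterministic and exact under Poisson sampling;
#'   anticonservative when counts are biologically overdispersed.
#' * `"ql"`: negative-binomial quasi-likelihood F-test (edgeR) — use for
#'   overdispersed replicate data.
#'
#' q-values are Benjamini-Hochberg adjusted over all miRNAs within this
#' contrast.
#'
#' @param counts Filtered count matrix.
#' @param condition_a,condition_b Condition labels (orientation b vs a).
#' @param sheet Sample sheet; defaults to the matrix attribute.
#' @param test `"exact"` or `"ql"`.
#' @param fit Optional prefitted [ql_fit()] object (ignored for
#'   `test = "exact"`).
#' @param pseudocount Added to normalized means before the ratio (default
#'   0; detection filtering already removes zero rows).
#' @return Data frame of class `"contrast_result"` with columns `mirna`,
#'   `mean_a`, `mean_b`, `log2fc`, `pvalue`, `qvalue`; attributes
#'   `contrast` (label `"b_vs_a"`), `conditions`, and `test`.
#' @export
mir_contrast <- function(counts, condition_a, condition_b,
                         sheet = attr(counts, "sample_sheet"),
                         test = c("exact", "ql"), fit = NULL,
                         pseudocount = 0) {
  test <- match.arg(test)
  if (!condition_a %in% sheet$condition || !condition_b %in% sheet$condition) {
    stop("unknown condition label", call. = FALSE)
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  cols_a <- sheet$sample_id[sheet$condition == condition_a]
  cols_b <- sheet$sample_id[sheet$condition == condition_b]
  mean_a <- rowMeans(norm[, cols_a, drop = FALSE]) + pseudocount
  mean_b <- rowMeans(norm[, cols_b, drop = FALSE]) + pseudocount
  log2fc <- log2(mean_b) - log2(mean_a)

  if (test == "exact") {
    pooled_a <- rowSums(counts[, cols_a, drop = FALSE])
    pooled_b <- rowSums(counts[, cols_b, drop = FALSE])
    share_b <- sum(sf[cols_b]) / (sum(sf[cols_a]) + sum(sf[cols_b]))
    pvalue <- exact_pooled_p(round(pooled_a), round(pooled_b), share_b)
  } else {
    if (is.null(fit)) fit <- ql_fit(counts, sheet)
    cmat <- setNames(numeric(ncol(fit$design)), colnames(fit$design))
    cmat[condition_b] <- 1
    cmat[condition_a] <- -1
    res <- edgeR::glmQLFTest(fit, contrast = cmat)
    pvalue <- res$table[rownames(counts), "PValue"]
  }
  out <- data.frame(mirna = rownames(counts), mean_a = unname(mean_a),
                    mean_b = unname(mean_b), log2fc = unname(log2fc),
                    pvalue = unname(pvalue),
                    qvalue = bh_adjust(unname(pvalue)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            contrast = paste0(condition_b, "_vs_", condition_a),
            conditions = c(a = condition_a, b = condition_b),
            test = test,
            class = c("contrast_result", "data.frame"))
}

# Two-sided exact binomial p-values for pooled counts, conditioning on the
# pooled total; (0, 0) pooled counts give p = 1 (no evidence).
exact_pooled_p <- function(pooled_a, pooled_b, share_b) {
  vapply(seq_along(pooled_a), function(i) {
    n <- pooled_a[i] + pooled_b[i]
    if (n == 0) return(1)
    binom.test(pooled_b[i], n, p = share_b)$p.value
  }, numeric(1))
}

#' Replicate concordance and sample clustering QC
#'
#' Per condition, the coefficient of determination of an ordinary
#' least-squares regression of replicate 2 on replicate 1 (log2 counts,
#' pseudocount 1); conditions with a single replicate yield `NA` and a
#' flag. Samples are clustered by average linkage on
#' `1 - Pearson correlation` of log2 counts.
#'
#' @param counts Count matrix.
#' @param sheet Sample sheet.
#' @return List with `r_squared` (named per condition, `NA` where
#'   undefined), `single_replicate` (conditions lacking a pair), and
#'   `dendrogram` (an `hclust` object).
#' @export
replicate_qc <- function(counts, sheet = attr(counts, "sample_sheet")) {
  lg <- log2(counts + 1)
  conds <- unique(sheet$condition)
  r2 <- setNames(rep(NA_real_, length(conds)), conds)
  for (cc in conds) {
    cols <- sheet$sample_id[sheet$condition == cc]
    if (length(cols) >= 2L) {
      # OLS R^2 of rep2 ~ rep1 equals the squared Pearson correlation
      r2[cc] <- cor(lg[, cols[1]], lg[, cols[2]])^2
    }
  }
  dend <- hclust(stats::as.dist(1 - cor(lg)), method = "average")
  list(r_squared = r2,
       single_replicate = conds[is.na(r2)],
       dendrogram = dend)
}

#' Volcano-plot table for a contrast
#'
#' One row per miRNA with the log2 fold change, `-log10` q-value (a q of 0
#' is reported as the display cap, default 300), and a strict significance
#' flag at `q < alpha`.
#'
#' @param result A [mir_contrast()] result.
#' @param alpha Significance threshold (strict `<`; default 0.05).
#' @param cap Cap for `-log10(q)` when q underflows to 0.
#' @return Data frame with columns `mirna`, `log2fc`, `neg_log10_q`,
#'   `significant`.
#' @export
volcano_table <- function(result, alpha = 0.05, cap = 300) {
  q <- result$qvalue
  y <- ifelse(q > 0, pmin(-log10(q), cap), cap)
  data.frame(mirna = result$mirna, log2fc = result$log2fc,
             neg_log10_q = y, significant = q < alpha,
             stringsAsFactors = FALSE)
}

#' Comparative Ct fold change
#'
#' `2^(-ddCt)` with
#' `ddCt = (ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c)`, i.e. the
#' target's cycle threshold normalized to a stably expressed reference
#' (miR-2-5p in the study) in the treatment relative to the calibrator.
#'
#' @param ct_target_t,ct_ref_t Target and reference Ct in the treatment.
#' @param ct_target_c,ct_ref_c Target and reference Ct in the calibrator.
#' @return Fold change(s); vectorized over inputs.
#' @export
ddct_fold_change <- function(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c) {
  stopifnot(all(is.finite(c(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c))))
  2^(-((ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c)))
}
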