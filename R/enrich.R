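#' Upper-tail hypergeometric over-representation test
#'
#' `P(X >= k)` where `k` is the overlap of the selected gene set with a
#' term's gene set, drawing `n = |selected|` genes from a universe of size
#' `N` containing `K = |term|` term members.
#'
#' @param selected Character vector of selected genes (subset of universe).
#' @param term Character vector of term member genes (subset of universe).
#' @param universe Character vector, the gene universe.
#' @return A single p-value.
#' @export
hypergeom_test <- function(selected, term, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  selected <- intersect(unique(selected), universe)
  term <- intersect(unique(term), universe)
  k <- length(intersect(selected, term))
  phyper(k - 1, length(term), length(universe) - length(term),
         length(selected), lower.tail = FALSE)
}

#' Term over-representation over an annotation table
#'
#' One hypergeometric test per term overlapping the selection, with
#' Benjamini-Hochberg adjustment across tested terms. The universe
#' defaults to all annotated genes in the table (overridable).
#'
#' @param selected Character vector of genes of interest.
#' @param annotations Data frame (`term_id`, `term_name`, `gene`).
#' @param universe Optional explicit gene universe.
#' @param alpha Threshold recorded in the `significant` column (strict
#'   `<`).
#' @return Data frame sorted by p-value: `term_id`, `term_name`,
#'   `overlap`, `term_size`, `pvalue`, `qvalue`, `significant`, and
#'   `genes` (overlapping genes, comma-separated). Carries the per-term
#'   overlap gene sets in the `overlap_genes` attribute for clustering.
#' @export
enrich_terms <- function(selected, annotations, universe = NULL,
                         alpha = 0.05) {
  if (is.null(universe)) universe <- unique(annotations$gene)
  selected <- intersect(unique(selected), universe)
  term_sets <- split(annotations$gene, annotations$term_id)
  term_names <- annotations$term_name[!duplicated(annotations$term_id)]
  names(term_names) <- annotations$term_id[!duplicated(annotations$term_id)]
  overlaps <- lapply(term_sets, intersect, selected)
  tested <- names(term_sets)[lengths(overlaps) >= 1L]
  if (!length(tested)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      overlap = integer(0), term_size = integer(0),
                      pvalue = numeric(0), qvalue = numeric(0),
                      significant = logical(0), genes = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "overlap_genes") <- list()
    return(out)
  }
  p <- vapply(tested, function(tid) {
    hypergeom_test(selected, term_sets[[tid]], universe)
  }, numeric(1))
  out <- data.frame(
    term_id = tested,
    term_name = unname(term_names[tested]),
    overlap = lengths(overlaps[tested]),
    term_size = lengths(lapply(term_sets[tested], intersect, universe)),
    pvalue = unname(p),
    qvalue = bh_adjust(unname(p)),
    stringsAsFactors = FALSE
  )
  out$significant <- out$qvalue < alpha
  out$genes <- vapply(overlaps[tested], function(g) {
    paste(sort(g), collapse = ",")
  }, character(1))
  ord <- order(out$pvalue, out$term_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overlap_genes") <- overlaps[out$term_id]
  out
}

#' Functional clustering of enriched terms with geometric-mean scoring
#'
#' Groups terms by single linkage on Jaccard similarity of their
#' overlapping-gene sets (terms with similarity at or above the threshold
#' end up in one cluster, transitively). Each cluster's enrichment score
#' is the arithmetic mean of the members' `-log10` p-values — identically,
#' the negative log10 of the geometric mean of the member p-values.
#' Clusters are returned sorted by score, descending.
#'
#' @param results An [enrich_terms()] result (its `overlap_genes`
#'   attribute supplies the per-term gene sets).
#' @param similarity_threshold Jaccard similarity at which two terms are
#'   linked (default 0.5).
#' @return List of clusters, each a list with `terms`, `pvalues`, and
#'   `score`.
#' @export
cluster_terms <- function(results, similarity_threshold = 0.5) {
  n <- nrow(results)
  if (!n) return(list())
  sets <- attr(results, "overlap_genes")
  # single linkage at a similarity threshold = connected components of the
  # graph linking term pairs with Jaccard >= threshold
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        a <- sets[[i]]; b <- sets[[j]]
        jac <- length(intersect(a, b)) / length(union(a, b))
        if (jac >= similarity_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- lapply(split(seq_len(n), roots), function(idx) {
    p <- results$pvalue[idx]
    list(terms = results$term_id[idx],
         pvalues = p,
         score = mean(-log10(p)))
  })
  clusters <- unname(clusters)
  clusters[order(vapply(clusters, `[[`, numeric(1), "score"),
                 decreasing = TRUE)]
}
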