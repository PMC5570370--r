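# Independent oracles and fixture builders used across the suite. These are
# deliberately written from the definitions (brute force / enumeration),
# not by calling the package's own code paths.

# Benjamini-Hochberg step-up, literal definition: sort p ascending,
# q(i) = min_{j >= i} p(j) * m / j capped at 1, return in input order.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n)
# selections from a universe of size N containing K term members:
# fraction of selections with overlap >= k.
brute_hyper <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  sel <- utils::combn(N, n)
  overlaps <- colSums(sel <= K)   # term members are items 1..K
  mean(overlaps >= k)
}

# Exhaustive positional (Hamming) mapping oracle: compare a read against
# every reference, counting mismatches position by position; a hit needs
# read length <= ref length + overhang, zero mismatches in the first 18
# positions, and at most two mismatches afterwards.
brute_map <- function(read, reference, max_overhang = 3L) {
  rch <- strsplit(read, "")[[1]]
  hits <- lapply(names(reference), function(id) {
    fch <- strsplit(reference[[id]], "")[[1]]
    if (length(rch) > length(fch) + max_overhang) return(NULL)
    L <- min(length(rch), length(fch))
    mm <- 0L
    for (pos in seq_len(L)) {
      if (rch[pos] != fch[pos] || rch[pos] == "N") {
        if (pos <= 18L) return(NULL)
        mm <- mm + 1L
      }
    }
    if (mm > 2L) return(NULL)
    data.frame(mirna = id, n_mismatch = mm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(mirna = character(0), n_mismatch = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$n_mismatch, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force shared-neighbor expansion: per unaffected gene, count
# affected interaction partners one edge at a time.
brute_expand_nodes <- function(affected_genes, interactions) {
  all_genes <- unique(c(interactions$gene_a, interactions$gene_b))
  recruited <- character(0)
  for (g in setdiff(all_genes, affected_genes)) {
    nb <- c(interactions$gene_b[interactions$gene_a == g],
            interactions$gene_a[interactions$gene_b == g])
    if (length(unique(intersect(nb, affected_genes))) >= 2L) {
      recruited <- c(recruited, g)
    }
  }
  sort(unique(c(affected_genes, recruited)))
}

# Fabricate a contrast_result with given fold changes and q-values (p set
# equal to q; only lfc/q drive classification).
make_contrast <- function(mirna, log2fc, qvalue, label = "X_vs_Y") {
  structure(
    data.frame(mirna = mirna, mean_a = 100, mean_b = 100 * 2^log2fc,
               log2fc = log2fc, pvalue = qvalue, qvalue = qvalue,
               stringsAsFactors = FALSE),
    contrast = label, test = "fixture",
    class = c("contrast_result", "data.frame")
  )
}

# Synthetic calls table built directly from planted truth labels (for
# stages downstream of classification).
calls_from_truth <- function(truth) {
  structure(
    data.frame(mirna = names(truth$class),
               class = factor(truth$class, levels = stressmir:::MIRNA_CLASSES),
               stringsAsFactors = FALSE),
    class = c("regulatory_calls", "data.frame")
  )
}

# Random undirected graph over n nodes with a random up/down/unaffected
# labelling; returns the pieces expand_network consumes.
random_labelled_graph <- function(n_nodes, p_edge = 0.15) {
  genes <- sprintf("g%02d", seq_len(n_nodes))
  pairs <- utils::combn(genes, 2L)
  hit <- runif(ncol(pairs)) < p_edge
  interactions <- data.frame(gene_a = pairs[1, hit], gene_b = pairs[2, hit],
                             stringsAsFactors = FALSE)
  n_aff <- max(1L, rbinom(1L, n_nodes, 0.4))
  aff <- sample(genes, n_aff)
  affected <- data.frame(
    gene = aff,
    direction = sample(c("up", "down"), n_aff, replace = TRUE),
    stringsAsFactors = FALSE)
  list(affected = affected, interactions = interactions)
}
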