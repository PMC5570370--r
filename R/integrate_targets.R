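#' Inverse-correlation integration of predicted miRNA targets
#'
#' Keeps a predicted miRNA-to-gene edge iff the miRNA carries a
#' non-`unclassified` regulatory call, the gene is significantly regulated
#' in the named mRNA contrast, and the gene's log2 fold change (on the
#' HSF-1-regulation scale) has the sign *opposite* to the miRNA's call
#' direction — a miRNA normally upregulated by HSF-1 should suppress its
#' targets, and vice versa. Sign opposition with a significance gate is the
#' operative meaning of inverse correlation here, not a correlation
#' coefficient.
#'
#' Kept edges are grouped into the four networks of the analysis:
#' dependent/independent crossed with suppressed (miRNA up, targets down)
#' and induced (miRNA down, targets up).
#'
#' @param calls A [call_classes()] result.
#' @param predictions Data frame (`mirna`, `gene`, optional `score`,
#'   `source`); (miRNA, gene) pairs must be unique.
#' @param regulation Data frame (`gene`, `contrast`, `log2fc`,
#'   `significant`).
#' @param contrast Contrast label to select from `regulation`.
#' @return Data frame of kept edges with columns `mirna`, `gene`,
#'   `mirna_class`, `gene_log2fc`, `network` (one of
#'   `"dep_suppressed"`, `"dep_induced"`, `"indep_suppressed"`,
#'   `"indep_induced"`), plus any prediction columns.
#' @export
integrate_targets <- function(calls, predictions, regulation,
                              contrast = "hsf1_regulation") {
  reg <- regulation[regulation$contrast == contrast, , drop = FALSE]
  if (!nrow(reg)) stop("contrast '", contrast, "' not in regulation table",
                       call. = FALSE)
  if (anyDuplicated(predictions[c("mirna", "gene")])) {
    stop("duplicate (mirna, gene) pairs in predictions", call. = FALSE)
  }
  classified <- calls[calls$class != "unclassified", , drop = FALSE]
  pred <- predictions[predictions$mirna %in% classified$mirna, , drop = FALSE]
  idx <- match(pred$gene, reg$gene)
  gene_lfc <- reg$log2fc[idx]
  gene_sig <- reg$significant[idx]
  cls <- as.character(classified$class[match(pred$mirna, classified$mirna)])
  mir_up <- cls %in% c("hs_dep_up", "hs_indep_up")
  keep <- !is.na(idx) & gene_sig &
    ifelse(mir_up, gene_lfc < 0, gene_lfc > 0)
  keep[is.na(keep)] <- FALSE
  out <- pred[keep, , drop = FALSE]
  out$mirna_class <- cls[keep]
  out$gene_log2fc <- gene_lfc[keep]
  dep <- out$mirna_class %in% c("hs_dep_up", "hs_dep_down")
  up <- out$mirna_class %in% c("hs_dep_up", "hs_indep_up")
  out$network <- paste0(ifelse(dep, "dep_", "indep_"),
                        ifelse(up, "suppressed", "induced"))
  rownames(out) <- NULL
  out
}

#' Expand an affected gene set with shared interaction neighbors
#'
#' Builds the displayed network: nodes are the affected genes plus every
#' unaffected gene that is an interaction partner of *at least two*
#' affected genes; edges are the interaction edges restricted to that node
#' set.
#'
#' @param affected Data frame (`gene`, `direction` with values
#'   `"up"`/`"down"`) of regulated genes (e.g. the targets kept by
#'   [integrate_targets()], with direction from the sign of
#'   `gene_log2fc`).
#' @param interactions Data frame of unique undirected edges (`gene_a`,
#'   `gene_b`).
#' @return List of class `"integrated_network"` with `nodes` (`gene`,
#'   `direction` — `"unaffected"` for recruited neighbors) and `edges`
#'   (rows of `interactions` joining two retained nodes).
#' @export
expand_network <- function(affected, interactions) {
  stopifnot(all(c("gene", "direction") %in% names(affected)))
  aff <- unique(affected$gene)
  if (nrow(interactions)) {
    und <- unique(data.frame(
      gene_a = pmin(interactions$gene_a, interactions$gene_b),
      gene_b = pmax(interactions$gene_a, interactions$gene_b),
      stringsAsFactors = FALSE
    ))
  } else {
    und <- data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
  }
  a_aff <- und$gene_a %in% aff
  b_aff <- und$gene_b %in% aff
  # affected-neighbor tally for unaffected genes
  partner <- c(und$gene_b[a_aff & !b_aff], und$gene_a[b_aff & !a_aff])
  tallied <- table(partner)
  recruited <- names(tallied)[tallied >= 2L]
  nodes <- data.frame(
    gene = c(aff, recruited),
    direction = c(affected$direction[match(aff, affected$gene)],
                  rep("unaffected", length(recruited))),
    stringsAsFactors = FALSE
  )
  keep_edge <- und$gene_a %in% nodes$gene & und$gene_b %in% nodes$gene
  structure(list(nodes = nodes,
                 edges = und[keep_edge, , drop = FALSE]),
            class = "integrated_network")
}

#' Find genes and edges linking the induced and suppressed clusters
#'
#' Returns the connections lying on a path of length at most two between an
#' up-regulated and a down-regulated node: direct up-down edges, and any
#' node adjacent to at least one node of each direction (the pattern of the
#' oxidative-stress and insulin-like-signaling factors bridging the two
#' clusters).
#'
#' @param network An [expand_network()] result.
#' @return List with `linker_genes` (character), `bridge_edges` (direct
#'   up-down edges), and `linker_edges` (edges incident to a linker gene
#'   and an up/down node).
#' @export
find_linkers <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  dir_of <- setNames(nodes$direction, nodes$gene)
  if (!nrow(edges)) {
    return(list(linker_genes = character(0),
                bridge_edges = edges, linker_edges = edges))
  }
  da <- dir_of[edges$gene_a]
  db <- dir_of[edges$gene_b]
  bridge <- (da == "up" & db == "down") | (da == "down" & db == "up")
  adj_up <- unique(c(edges$gene_a[db == "up"], edges$gene_b[da == "up"]))
  adj_dn <- unique(c(edges$gene_a[db == "down"], edges$gene_b[da == "down"]))
  linkers <- intersect(adj_up, adj_dn)
  inc <- (edges$gene_a %in% linkers & db %in% c("up", "down")) |
    (edges$gene_b %in% linkers & da %in% c("up", "down"))
  list(linker_genes = sort(linkers),
       bridge_edges = edges[bridge, , drop = FALSE],
       linker_edges = edges[inc, , drop = FALSE])
}

#' Write a network as node/edge TSVs plus a SIF-style edge list
#'
#' @param network An [expand_network()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(network, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    nodes = file.path(dir, paste0(prefix, "_nodes.tsv")),
    edges = file.path(dir, paste0(prefix, "_edges.tsv")),
    sif = file.path(dir, paste0(prefix, ".sif"))
  )
  write_tsv(network$nodes, paths[["nodes"]])
  write_tsv(network$edges, paths[["edges"]])
  sif <- data.frame(a = network$edges$gene_a, type = "interacts",
                    b = network$edges$gene_b, stringsAsFactors = FALSE)
  write.table(sif, paths[["sif"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
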