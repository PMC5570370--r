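#' Run the full synthetic-to-enrichment pipeline
#'
#' Executes the end-to-end analysis on synthetic data with planted truth:
#' simulate counts under the 2x2 design, optionally simulate and
#' re-quantify adapter-bearing reads, filter undetected miRNAs, compute
#' the five contrasts (C1 vs C0, C2 vs C0, C3 vs C0, C1 vs C2, C2 vs C3),
#' call regulatory classes, integrate predicted targets by the
#' inverse-correlation rule, expand interaction networks, and score
#' enriched annotation terms. Every produced file is recorded in a JSON
#' manifest together with the parameters in force and an MD5 checksum per
#' file, so identical configurations and seeds yield byte-identical
#' manifests.
#'
#' All randomness derives from `config$seed`; stage seeds are split
#' deterministically.
#'
#' @param out_dir Output directory (created).
#' @param config A [design_config()]; its seed is the pipeline root seed.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "quantify", "diffexp", "classify", "integrate",
#'   "enrich")`. Later stages require earlier ones. `character(0)` writes
#'   an empty manifest.
#' @param test Test backend for contrasts (`"ql"` default for the
#'   overdispersed generator defaults; `"exact"` for Poisson-scale data).
#' @param alpha Significance threshold used throughout (strict `<`).
#' @param with_reads If `TRUE`, the quantify stage simulates reads from
#'   the counts, trims, filters and re-quantifies them (slow for deep
#'   libraries); otherwise the simulated count matrix feeds the tests
#'   directly and the quantify stage is skipped.
#' @param n_genes,frac_inverse,targets_per_mirna Passed to
#'   [simulate_target_map()].
#' @param edge_density Passed to [simulate_interactions()].
#' @param n_terms,term_size,enrichment_factor Passed to
#'   [simulate_annotations()].
#' @return Invisibly, the manifest (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(out_dir,
                         config = design_config(),
                         stages = c("simulate", "diffexp", "classify",
                                    "integrate", "enrich"),
                         test = c("ql", "exact"),
                         alpha = 0.05,
                         with_reads = FALSE,
                         n_genes = 500L,
                         frac_inverse = 0.8,
                         targets_per_mirna = 2L,
                         edge_density = 0.01,
                         n_terms = 50L,
                         term_size = 20L,
                         enrichment_factor = 10) {
  test <- match.arg(test)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    parameters = list(
      n_mirna = config$n_mirna, n_replicates = config$n_replicates,
      baseline_mean = config$baseline_mean, dispersion = config$dispersion,
      effect_log2fc = config$effect_log2fc,
      library_size_spread = config$library_size_spread,
      class_fractions = as.list(config$class_fractions),
      seed = config$seed, test = test, alpha = alpha,
      n_genes = n_genes, frac_inverse = frac_inverse,
      targets_per_mirna = targets_per_mirna, edge_density = edge_density,
      n_terms = n_terms, term_size = term_size,
      enrichment_factor = enrichment_factor,
      stages = as.list(stages)
    ),
    files = list()
  )
  record <- function(manifest, stage, paths) {
    manifest$files[[stage]] <- lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(md5sum(p)))
    })
    manifest
  }
  finish <- function(manifest) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }
  if (!length(stages)) return(finish(manifest))

  message("stressmir pipeline: test=", test, ", alpha=", alpha,
          ", seed=", config$seed)

  truth <- generate_truth(config)
  counts <- simulate_counts(truth, config)
  sheet <- attr(counts, "sample_sheet")
  if ("simulate" %in% stages) {
    p1 <- file.path(out_dir, "counts.tsv")
    p2 <- file.path(out_dir, "samples.tsv")
    p3 <- file.path(out_dir, "truth_classes.tsv")
    write_counts_tsv(counts, p1)
    write_tsv(sheet, p2)
    write_tsv(data.frame(mirna = names(truth$class),
                         class = unname(truth$class),
                         stringsAsFactors = FALSE), p3)
    manifest <- record(manifest, "simulate", c(p1, p2, p3))
  }

  if ("quantify" %in% stages && with_reads) {
    ref <- simulate_reference(rownames(counts),
                              seed = derive_seed(config$seed, "reads"))
    reads <- simulate_reads(counts, ref,
                            seed = derive_seed(config$seed, "reads"))
    requant <- quantify_samples(
      lapply(reads, function(r) filter_reads(trim_adapter(r))), ref)
    counts <- structure(requant, sample_sheet = sheet)
    p <- file.path(out_dir, "counts_requant.tsv")
    write_counts_tsv(counts, p)
    manifest <- record(manifest, "quantify", p)
  }

  contrasts <- NULL
  if ("diffexp" %in% stages) {
    filtered <- filter_detected(counts, sheet)
    message("detection filter kept ", nrow(filtered), "/", nrow(counts),
            " miRNAs")
    fit <- if (test == "ql") ql_fit(filtered, sheet) else NULL
    pairs <- list(C1_vs_C0 = c("C0", "C1"), C2_vs_C0 = c("C0", "C2"),
                  C3_vs_C0 = c("C0", "C3"), C1_vs_C2 = c("C2", "C1"),
                  C2_vs_C3 = c("C3", "C2"))
    contrasts <- lapply(pairs, function(pp) {
      mir_contrast(filtered, pp[1], pp[2], sheet, test = test, fit = fit)
    })
    paths <- vapply(names(contrasts), function(nm) {
      p <- file.path(out_dir, paste0("contrast_", nm, ".tsv"))
      write_tsv(as.data.frame(contrasts[[nm]]), p)
      p
    }, character(1))
    volc <- file.path(out_dir, "volcano_C1_vs_C0.tsv")
    write_tsv(volcano_table(contrasts$C1_vs_C0, alpha = alpha), volc)
    manifest <- record(manifest, "diffexp", c(paths, volc))
  }

  calls <- NULL
  if ("classify" %in% stages) {
    if (is.null(contrasts)) stop("classify requires diffexp", call. = FALSE)
    partition <- venn_partition(contrasts[c("C1_vs_C0", "C2_vs_C0",
                                            "C3_vs_C0")], alpha = alpha)
    calls <- call_classes(contrasts[c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")],
                          contrasts[c("C1_vs_C2", "C2_vs_C3")],
                          alpha = alpha)
    p1 <- file.path(out_dir, "calls.tsv")
    p2 <- file.path(out_dir, "venn_regions.tsv")
    write_tsv(as.data.frame(calls), p1)
    write_tsv(partition$counts, p2)
    manifest <- record(manifest, "classify", c(p1, p2))
  }

  kept <- NULL
  tmap <- NULL
  if ("integrate" %in% stages) {
    if (is.null(calls)) stop("integrate requires classify", call. = FALSE)
    tmap <- simulate_target_map(truth, n_genes = n_genes,
                                frac_inverse = frac_inverse,
                                targets_per_mirna = targets_per_mirna,
                                seed = derive_seed(config$seed, "targets"))
    kept <- integrate_targets(calls, tmap$predictions, tmap$regulation)
    interactions <- simulate_interactions(
      tmap$regulation$gene, edge_density = edge_density,
      seed = derive_seed(config$seed, "interactions"))
    affected <- data.frame(
      gene = kept$gene,
      direction = ifelse(kept$gene_log2fc > 0, "up", "down"),
      stringsAsFactors = FALSE)
    affected <- affected[!duplicated(affected$gene), , drop = FALSE]
    network <- expand_network(affected, interactions)
    linkers <- find_linkers(network)
    p1 <- file.path(out_dir, "kept_edges.tsv")
    write_tsv(kept, p1)
    net_paths <- write_network(network, out_dir, "network")
    p2 <- file.path(out_dir, "linkers.tsv")
    write_tsv(data.frame(gene = linkers$linker_genes,
                         stringsAsFactors = FALSE), p2)
    manifest <- record(manifest, "integrate", c(p1, net_paths, p2))
  }

  if ("enrich" %in% stages) {
    if (is.null(kept)) stop("enrich requires integrate", call. = FALSE)
    ann <- simulate_annotations(
      genes = tmap$regulation$gene, target_genes = unique(kept$gene),
      n_terms = n_terms, term_size = term_size,
      enrichment_factor = enrichment_factor,
      seed = derive_seed(config$seed, "annotations"))
    res <- enrich_terms(unique(kept$gene), ann$annotations, alpha = alpha)
    clusters <- cluster_terms(res)
    p1 <- file.path(out_dir, "enrichment.tsv")
    write_tsv(res, p1)
    p2 <- file.path(out_dir, "enrichment_clusters.tsv")
    cl_df <- if (length(clusters)) {
      data.frame(
        cluster = seq_along(clusters),
        score = vapply(clusters, `[[`, numeric(1), "score"),
        terms = vapply(clusters, function(cl) {
          paste(cl$terms, collapse = ",")
        }, character(1)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = integer(0), score = numeric(0),
                 terms = character(0), stringsAsFactors = FALSE)
    }
    write_tsv(cl_df, p2)
    manifest <- record(manifest, "enrich", c(p1, p2))
  }

  finish(manifest)
}
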