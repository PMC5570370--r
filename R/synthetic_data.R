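#' Design configuration for the synthetic 2x2 knockdown-by-stress experiment
#'
#' Describes a simulated small-RNA-seq experiment with four conditions:
#' `C0` = hsf-1(+);-HS (empty-vector control), `C1` = hsf-1(+);+HS,
#' `C2` = hsf-1(-);+HS, `C3` = hsf-1(-);-HS. Each miRNA belongs to one of
#' five regulatory classes; classes alter the expected count in specific
#' conditions by a factor of `2^effect_log2fc`:
#'
#' * `hs_dep_up`: induced by HSF-1 only under heat shock — mean multiplied
#'   in `C1` only (the effect vanishes when hsf-1 is knocked down).
#' * `hs_dep_down`: suppressed by HSF-1 under heat shock — mean divided in
#'   `C1` only.
#' * `hs_indep_up`: maintained by HSF-1 regardless of stress — mean divided
#'   in both `C2` and `C3` (loss of HSF-1 lowers it with or without heat).
#' * `hs_indep_down`: suppressed by HSF-1 regardless of stress — mean
#'   multiplied in both `C2` and `C3`.
#' * `unclassified`: equal means everywhere.
#'
#' Defaults reproduce the reference study conditions: biological duplicates,
#' 1,000 miRNAs of which 200 are regulated (50 per class), control mean 500,
#' negative-binomial dispersion 0.05, planted |log2 fold change| of 3.
#'
#' @param n_mirna Number of miRNAs.
#' @param n_replicates Replicates per condition (study value: 2).
#' @param baseline_mean Expected control (`C0`) count per miRNA.
#' @param dispersion Negative-binomial dispersion shared across miRNAs;
#'   0 gives Poisson counts.
#' @param class_fractions Named probability vector over the five classes,
#'   summing to 1.
#' @param effect_log2fc Planted absolute log2 fold change for regulated
#'   classes.
#' @param library_size_spread Standard deviation (log scale) of the
#'   lognormal multiplicative library-size jitter across samples.
#' @param seed Integer seed; every downstream simulation derives its RNG
#'   stream from it.
#' @return A list of class `"design_config"`.
#' @examples
#' cfg <- design_config(n_mirna = 100, seed = 1)
#' truth <- generate_truth(cfg)
#' counts <- simulate_counts(truth, cfg)
#' @export
design_config <- function(n_mirna = 1000L,
                          n_replicates = 2L,
                          baseline_mean = 500,
                          dispersion = 0.05,
                          class_fractions = c(hs_dep_up = 0.05,
                                              hs_dep_down = 0.05,
                                              hs_indep_up = 0.05,
                                              hs_indep_down = 0.05,
                                              unclassified = 0.80),
                          effect_log2fc = 3,
                          library_size_spread = 0.2,
                          seed = 1L) {
  if (!is.numeric(n_mirna) || length(n_mirna) != 1L || n_mirna < 1) {
    stop("`n_mirna` must be a positive integer", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (baseline_mean <= 0) stop("`baseline_mean` must be > 0", call. = FALSE)
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)
  if (effect_log2fc <= 0) stop("`effect_log2fc` must be > 0", call. = FALSE)
  if (library_size_spread < 0) {
    stop("`library_size_spread` must be >= 0", call. = FALSE)
  }
  if (is.null(names(class_fractions)) ||
      !setequal(names(class_fractions), MIRNA_CLASSES)) {
    stop("`class_fractions` must be named with the five regulatory classes",
         call. = FALSE)
  }
  class_fractions <- class_fractions[MIRNA_CLASSES]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-12) {
    stop("`class_fractions` must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(n_mirna = as.integer(n_mirna),
                 n_replicates = as.integer(n_replicates),
                 conditions = CONDITIONS,
                 baseline_mean = baseline_mean,
                 dispersion = dispersion,
                 class_fractions = class_fractions,
                 effect_log2fc = effect_log2fc,
                 library_size_spread = library_size_spread,
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Sample sheet for a design configuration
#'
#' @param config A [design_config()].
#' @return Data frame with columns `sample_id`, `condition`, `replicate`.
#' @export
sample_sheet <- function(config) {
  data.frame(
    sample_id = paste0(rep(CONDITIONS, each = config$n_replicates), "_r",
                       rep(seq_len(config$n_replicates), times = 4L)),
    condition = rep(CONDITIONS, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = 4L),
    stringsAsFactors = FALSE
  )
}

#' Generate planted ground truth for a synthetic experiment
#'
#' Assigns each miRNA a regulatory class (multinomial draw from
#' `class_fractions`, deterministic given the config seed) and derives the
#' per-condition expected means implied by the class definitions (see
#' [design_config()]).
#'
#' @param config A [design_config()].
#' @return A list of class `"synth_truth"` with elements `class` (named
#'   character vector per miRNA), `means` (miRNA x condition matrix of
#'   expected control-scale counts), and `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "design_config"))
  n <- config$n_mirna
  ids <- sprintf("mir-%04d", seq_len(n))
  cls <- with_seed(derive_seed(config$seed, "truth"), {
    sample(MIRNA_CLASSES, n, replace = TRUE, prob = config$class_fractions)
  })
  names(cls) <- ids
  mult <- 2^config$effect_log2fc
  means <- matrix(config$baseline_mean, nrow = n, ncol = 4L,
                  dimnames = list(ids, CONDITIONS))
  means[cls == "hs_dep_up", "C1"] <- config$baseline_mean * mult
  means[cls == "hs_dep_down", "C1"] <- config$baseline_mean / mult
  means[cls == "hs_indep_up", c("C2", "C3")] <- config$baseline_mean / mult
  means[cls == "hs_indep_down", c("C2", "C3")] <- config$baseline_mean * mult
  structure(list(class = cls, means = means, config = config),
            class = "synth_truth")
}

#' Simulate a replicate count matrix from planted truth
#'
#' Draws one count per miRNA and sample from a negative binomial with mean
#' equal to the truth mean scaled by that sample's library-size factor and
#' shared dispersion `config$dispersion`; dispersion 0 degenerates to
#' Poisson. Library-size factors are lognormal,
#' `exp(rnorm(0, library_size_spread))`.
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [design_config()].
#' @param seed Optional override of the derived stage seed.
#' @return Integer matrix (miRNA x sample) with attributes
#'   `sample_sheet` and `lib_factors`.
#' @export
simulate_counts <- function(truth, config = truth$config, seed = NULL) {
  stopifnot(inherits(truth, "synth_truth"))
  if (nrow(truth$means) != config$n_mirna) {
    stop("truth and config disagree on the number of miRNAs", call. = FALSE)
  }
  sheet <- sample_sheet(config)
  n_samp <- nrow(sheet)
  if (is.null(seed)) seed <- derive_seed(config$seed, "counts")
  out <- with_seed(seed, {
    libf <- exp(rnorm(n_samp, 0, config$library_size_spread))
    mu <- truth$means[, sheet$condition, drop = FALSE] *
      rep(libf, each = nrow(truth$means))
    k <- if (config$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      rpois(length(mu), lambda = mu)
    }
    m <- matrix(k, nrow = nrow(truth$means),
                dimnames = list(rownames(truth$means), sheet$sample_id))
    list(m = m, libf = libf)
  })
  structure(out$m, sample_sheet = sheet,
            lib_factors = setNames(out$libf, sheet$sample_id))
}

#' Random mature miRNA reference sequences
#'
#' Generates mutually distant random mature sequences (uniform bases) for
#' read-level simulations; real references should be supplied as FASTA via
#' [read_mature_reference()].
#'
#' @param ids miRNA identifiers.
#' @param length_range Inclusive range of mature lengths in nt.
#' @param seed Integer seed.
#' @return Named character vector of DNA sequences.
#' @export
simulate_reference <- function(ids, length_range = c(21L, 23L), seed = 1L) {
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), length(ids),
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    setNames(seqs, ids)
  })
}

#' Simulate adapter-bearing small-RNA reads from a count matrix
#'
#' For each miRNA and sample, emits exactly `count` reads consisting of the
#' mature sequence — with independent per-base substitution errors at
#' `error_rate` — followed by the 3' adapter, with placeholder qualities.
#'
#' @param counts Integer count matrix (miRNA x sample).
#' @param reference Named character vector of mature sequences (names are
#'   miRNA ids); every counted miRNA must be present.
#' @param adapter 3' adapter sequence appended to every read; defaults to
#'   the standard Illumina small-RNA adapter.
#' @param error_rate Per-base substitution probability, in `[0, 0.25)`.
#' @param seed Integer seed.
#' @return Named list (one element per sample) of named character vectors of
#'   read sequences; read names encode the source miRNA.
#' @export
simulate_reads <- function(counts, reference,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           error_rate = 0, seed = 1L) {
  assert_prob(error_rate, "error_rate")
  if (error_rate >= 0.25) stop("`error_rate` must be < 0.25", call. = FALSE)
  missing_ref <- setdiff(rownames(counts)[rowSums(counts) > 0],
                         names(reference))
  if (length(missing_ref)) {
    stop("no reference sequence for counted miRNA(s): ",
         paste(head(missing_ref, 5), collapse = ", "), call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- lapply(colnames(counts), function(s) {
      ids <- rep(rownames(counts), counts[, s])
      if (!length(ids)) return(setNames(character(0), character(0)))
      seqs <- unname(reference[ids])
      if (error_rate > 0) {
        seqs <- vapply(seqs, function(sq) {
          ch <- strsplit(sq, "", fixed = TRUE)[[1]]
          hit <- runif(length(ch)) < error_rate
          if (any(hit)) {
            ch[hit] <- vapply(ch[hit], function(b) {
              sample(setdiff(bases, b), 1L)
            }, character(1))
          }
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      setNames(paste0(seqs, adapter),
               sprintf("%s:%s:%06d", s, ids, seq_along(ids)))
    })
    setNames(out, colnames(counts))
  })
}

#' Simulate a target-prediction table and matching mRNA regulation table
#'
#' For each classified (non-`unclassified`) miRNA, emits `targets_per_mirna`
#' predicted target edges to distinct genes (each gene serves at most one
#' edge, so planted edge outcomes never conflict). A fraction
#' `frac_inverse` of edges point to genes whose planted mRNA log2 fold
#' change has the *opposite* sign to the miRNA's regulatory direction and a
#' significance flag set — exactly the edges the inverse-correlation rule
#' keeps. The remainder are split between same-sign significant genes and
#' opposite-sign non-significant genes, both of which the rule drops.
#' Remaining genes are emitted as unaffected.
#'
#' The regulation table stores log2FC on the HSF-1-regulation scale (sign
#' already convention-adjusted), under a single contrast label.
#'
#' @param truth A [generate_truth()] result.
#' @param n_genes Size of the gene universe; must accommodate all edges.
#' @param frac_inverse Fraction of planted edges that are keepable.
#' @param targets_per_mirna Predicted targets per classified miRNA.
#' @param contrast Contrast label written to the regulation table.
#' @param seed Integer seed.
#' @return List with `predictions` (miRNA, gene, score, source),
#'   `regulation` (gene, contrast, log2fc, significant), and `truth_edges`
#'   (miRNA, gene, keepable).
#' @export
simulate_target_map <- function(truth, n_genes = 500L, frac_inverse = 0.5,
                                targets_per_mirna = 5L,
                                contrast = "hsf1_regulation", seed = 1L) {
  assert_prob(frac_inverse, "frac_inverse")
  stopifnot(inherits(truth, "synth_truth"))
  mirs <- names(truth$class)[truth$class != "unclassified"]
  n_edges <- length(mirs) * targets_per_mirna
  if (n_edges > n_genes) {
    stop("n_genes too small for ", n_edges, " planted edges", call. = FALSE)
  }
  genes <- sprintf("gene-%05d", seq_len(n_genes))
  with_seed(seed, {
    target_genes <- sample(genes, n_edges)
    pred <- data.frame(
      mirna = rep(mirs, each = targets_per_mirna),
      gene = target_genes,
      score = round(runif(n_edges, 1, 10), 3),
      source = sample(c("primary_predictor", "fallback_predictor"), n_edges,
                      replace = TRUE, prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE
    )
    mir_up <- truth$class[pred$mirna] %in% c("hs_dep_up", "hs_indep_up")
    keep <- runif(n_edges) < frac_inverse
    # keepable: opposite sign, significant; decoys: same sign significant or
    # opposite sign non-significant, half and half
    sgn <- ifelse(mir_up, -1, 1)          # inverse sign for keepable edges
    decoy_same_sign <- !keep & runif(n_edges) < 0.5
    sgn[decoy_same_sign] <- -sgn[decoy_same_sign]
    lfc <- sgn * runif(n_edges, 0.5, 3)
    sig <- keep | decoy_same_sign
    reg <- data.frame(gene = genes, contrast = contrast, log2fc = 0,
                      significant = FALSE, stringsAsFactors = FALSE)
    idx <- match(pred$gene, reg$gene)
    reg$log2fc[idx] <- round(lfc, 3)
    reg$significant[idx] <- sig
    list(predictions = pred,
         regulation = reg,
         truth_edges = data.frame(mirna = pred$mirna, gene = pred$gene,
                                  keepable = keep, stringsAsFactors = FALSE))
  })
}

#' Simulate a term-to-gene annotation table with planted enriched terms
#'
#' Background terms sample genes uniformly; planted terms sample with weight
#' `enrichment_factor` on the supplied target set, so at factor 1 planted
#' membership is independent of the target set (null case).
#'
#' @param genes Gene universe (character).
#' @param target_genes Genes the planted terms should over-represent.
#' @param n_terms Total number of terms.
#' @param n_planted Number of planted enriched terms.
#' @param term_size Genes per term.
#' @param enrichment_factor Sampling weight multiplier for target genes in
#'   planted terms (1 = null).
#' @param seed Integer seed.
#' @return List with `annotations` (term_id, term_name, gene) and
#'   `planted_terms` (character vector of planted term ids).
#' @export
simulate_annotations <- function(genes, target_genes, n_terms = 50L,
                                 n_planted = 2L, term_size = 20L,
                                 enrichment_factor = 10, seed = 1L) {
  if (term_size > length(genes)) {
    stop("`term_size` exceeds the gene universe", call. = FALSE)
  }
  if (enrichment_factor < 1) {
    stop("`enrichment_factor` must be >= 1", call. = FALSE)
  }
  with_seed(seed, {
    term_ids <- sprintf("TERM:%04d", seq_len(n_terms))
    planted <- term_ids[seq_len(min(n_planted, n_terms))]
    w <- ifelse(genes %in% target_genes, enrichment_factor, 1)
    rows <- lapply(term_ids, function(tid) {
      members <- if (tid %in% planted) {
        sample(genes, term_size, prob = w)
      } else {
        sample(genes, term_size)
      }
      data.frame(term_id = tid,
                 term_name = paste0("process_", sub("TERM:", "", tid)),
                 gene = members, stringsAsFactors = FALSE)
    })
    list(annotations = do.call(rbind, rows), planted_terms = planted)
  })
}

#' Simulate an undirected gene-gene interaction edge list
#'
#' Each unordered gene pair is included independently with probability
#' `edge_density`.
#'
#' @param genes Gene universe (character).
#' @param edge_density Per-pair inclusion probability.
#' @param seed Integer seed.
#' @return Data frame with columns `gene_a`, `gene_b` (unique undirected
#'   edges, `gene_a < gene_b`).
#' @export
simulate_interactions <- function(genes, edge_density = 0.01, seed = 1L) {
  assert_prob(edge_density, "edge_density")
  n <- length(genes)
  if (n < 2L || edge_density == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  with_seed(seed, {
    hit <- runif(nrow(pairs)) < edge_density
    data.frame(gene_a = genes[pairs[hit, 1]], gene_b = genes[pairs[hit, 2]],
               stringsAsFactors = FALSE)
  })
}

#' Write a named set of sequences as FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write simulated reads as a 4-line-record FASTQ file
#' @param reads Named character vector of read sequences (one sample's
#'   element from [simulate_reads()]).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
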