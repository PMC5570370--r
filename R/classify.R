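#' Venn partition of significant miRNAs across the control-relative contrasts
#'
#' Splits the miRNAs significant (`q < alpha`) in each of the three
#' control-relative contrasts (C1 vs C0, C2 vs C0, C3 vs C0) by fold-change
#' sign and enumerates the seven disjoint overlap regions per orientation.
#'
#' @param contrasts Named list of three [mir_contrast()] results, names
#'   `"C1_vs_C0"`, `"C2_vs_C0"`, `"C3_vs_C0"`; all must share the same
#'   miRNA universe.
#' @param alpha Significance threshold (strict `<`).
#' @return List with elements `up` and `down`, each a list of the 7 region
#'   member vectors (names like `"C1_vs_C0"`,
#'   `"C1_vs_C0&C2_vs_C0"`, ...), plus `counts`, a data frame of region
#'   sizes.
#' @export
venn_partition <- function(contrasts, alpha = 0.05) {
  need <- c("C1_vs_C0", "C2_vs_C0", "C3_vs_C0")
  if (!all(need %in% names(contrasts))) {
    stop("contrasts must be named ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  universe <- contrasts[[need[1]]]$mirna
  for (nm in need[-1]) {
    if (!setequal(contrasts[[nm]]$mirna, universe)) {
      stop("contrasts have mismatched miRNA universes", call. = FALSE)
    }
  }
  sig_set <- function(res, dir) {
    s <- if (dir == "up") res$log2fc > 0 else res$log2fc < 0
    res$mirna[res$qvalue < alpha & s]
  }
  partition <- function(dir) {
    sets <- lapply(contrasts[need], sig_set, dir = dir)
    members <- unique(unlist(sets))
    inset <- vapply(sets, function(s) members %in% s,
                    logical(length(members)))
    if (length(members) == 1L) inset <- matrix(inset, nrow = 1L)
    key <- apply(inset, 1L, function(row) paste(need[row], collapse = "&"))
    regions <- lapply(region_keys(need), function(k) {
      members[key == k]
    })
    setNames(regions, region_keys(need))
  }
  up <- partition("up")
  down <- partition("down")
  counts <- data.frame(
    region = rep(region_keys(need), 2L),
    direction = rep(c("up", "down"), each = 7L),
    n = c(lengths(up), lengths(down)),
    stringsAsFactors = FALSE
  )
  list(up = up, down = down, counts = counts)
}

region_keys <- function(sets) {
  c(sets,
    paste(sets[c(1, 1, 2)], sets[c(2, 3, 3)], sep = "&"),
    paste(sets, collapse = "&"))
}

#' Call HSF-1 regulatory classes for each miRNA
#'
#' Implements the two-stage decision logic:
#'
#' * **Heat-shock-dependent** (`hs_dep_up` / `hs_dep_down`): significantly
#'   up/down in C1 vs C0 (heat-shocked control vs untreated control),
#'   *confirmed* by a significant difference between hsf-1(+);+HS and
#'   hsf-1(-);+HS (`q(C1 vs C2) < alpha`) — the change requires HSF-1.
#' * **Heat-shock-independent** (`hs_indep_up` / `hs_indep_down`):
#'   significantly changed in C3 vs C0 (knockdown without heat vs control)
#'   with *no* significant difference between the two knockdown conditions
#'   (`q(C2 vs C3) >= alpha`) — the change persists with or without heat.
#'   Direction is reversed to report HSF-1's normal regulatory role: a
#'   miRNA that *falls* on knockdown is normally *up*regulated by HSF-1
#'   (`hs_indep_up`), and its reported log2FC is the negated C3-vs-C0
#'   value.
#'
#' A miRNA eligible for both a dependent and an independent class keeps the
#' dependent label (precedence), with both memberships preserved in the
#' provenance columns. A miRNA passing a Venn stage (the control-relative
#' significance) but failing its confirmatory test is flagged as a
#' candidate and left `unclassified`.
#'
#' @param control_contrasts Named list with `"C1_vs_C0"` and `"C3_vs_C0"`
#'   (a `"C2_vs_C0"` element, if present, is carried into provenance).
#' @param pairwise_contrasts Named list with `"C1_vs_C2"` and `"C2_vs_C3"`.
#' @param alpha Significance threshold (strict `<`).
#' @return Data frame of class `"regulatory_calls"`, one row per miRNA:
#'   `mirna`, `class`, `candidate`, `reported_log2fc`, per-contrast
#'   q-values, and eligibility flags `dep_eligible`, `indep_eligible`.
#' @export
call_classes <- function(control_contrasts, pairwise_contrasts,
                         alpha = 0.05) {
  for (nm in c("C1_vs_C0", "C3_vs_C0")) {
    if (!nm %in% names(control_contrasts)) {
      stop("missing control contrast ", nm, call. = FALSE)
    }
  }
  for (nm in c("C1_vs_C2", "C2_vs_C3")) {
    if (!nm %in% names(pairwise_contrasts)) {
      stop("missing pairwise contrast ", nm, call. = FALSE)
    }
  }
  c10 <- control_contrasts$C1_vs_C0
  c30 <- control_contrasts$C3_vs_C0
  c12 <- pairwise_contrasts$C1_vs_C2
  c23 <- pairwise_contrasts$C2_vs_C3
  ids <- c10$mirna
  if (!setequal(ids, c30$mirna) || !setequal(ids, c12$mirna) ||
      !setequal(ids, c23$mirna)) {
    stop("contrasts computed on different miRNA universes", call. = FALSE)
  }
  align <- function(res) res[match(ids, res$mirna), ]
  c30 <- align(c30); c12 <- align(c12); c23 <- align(c23)

  sig_up_c1 <- c10$qvalue < alpha & c10$log2fc > 0
  sig_dn_c1 <- c10$qvalue < alpha & c10$log2fc < 0
  sig_up_c3 <- c30$qvalue < alpha & c30$log2fc > 0
  sig_dn_c3 <- c30$qvalue < alpha & c30$log2fc < 0
  dep_confirm <- c12$qvalue < alpha
  indep_confirm <- c23$qvalue >= alpha

  dep_up <- sig_up_c1 & dep_confirm
  dep_dn <- sig_dn_c1 & dep_confirm
  indep_up <- sig_dn_c3 & indep_confirm  # reversed comparison
  indep_dn <- sig_up_c3 & indep_confirm

  cls <- rep("unclassified", length(ids))
  cls[indep_up] <- "hs_indep_up"
  cls[indep_dn] <- "hs_indep_down"
  cls[dep_up] <- "hs_dep_up"            # dependent precedence
  cls[dep_dn] <- "hs_dep_down"

  reported <- rep(NA_real_, length(ids))
  reported[cls %in% c("hs_dep_up", "hs_dep_down")] <-
    c10$log2fc[cls %in% c("hs_dep_up", "hs_dep_down")]
  is_indep <- cls %in% c("hs_indep_up", "hs_indep_down")
  reported[is_indep] <- -c30$log2fc[is_indep]

  dep_eligible <- sig_up_c1 | sig_dn_c1
  indep_eligible <- sig_up_c3 | sig_dn_c3
  candidate <- cls == "unclassified" & (dep_eligible | indep_eligible)

  out <- data.frame(
    mirna = ids,
    class = factor(cls, levels = MIRNA_CLASSES),
    candidate = candidate,
    reported_log2fc = reported,
    dep_eligible = dep_eligible,
    indep_eligible = indep_eligible,
    dep_class = ifelse(dep_up, "hs_dep_up",
                       ifelse(dep_dn, "hs_dep_down", NA_character_)),
    indep_class = ifelse(indep_up, "hs_indep_up",
                         ifelse(indep_dn, "hs_indep_down", NA_character_)),
    lfc_c1_vs_c0 = c10$log2fc,
    lfc_c3_vs_c0 = c30$log2fc,
    q_c1_vs_c0 = c10$qvalue,
    q_c3_vs_c0 = c30$qvalue,
    q_c1_vs_c2 = c12$qvalue,
    q_c2_vs_c3 = c23$qvalue,
    stringsAsFactors = FALSE
  )
  if ("C2_vs_C0" %in% names(control_contrasts)) {
    c20 <- align(control_contrasts$C2_vs_C0)
    out$q_c2_vs_c0 <- c20$qvalue
    out$lfc_c2_vs_c0 <- c20$log2fc
  }
  structure(out, alpha = alpha,
            class = c("regulatory_calls", "data.frame"))
}

#' Summary tables for a set of regulatory calls
#'
#' Emits one member table per class (miRNA and reported log2 fold change),
#' the Venn region counts when a partition is supplied, and — when planted
#' truth labels are available — a confusion matrix of called vs true
#' classes.
#'
#' @param calls A [call_classes()] result.
#' @param partition Optional [venn_partition()] result.
#' @param truth Optional named character vector of true class labels.
#' @return List with `class_tables` (named list of data frames),
#'   `class_counts`, optional `venn_counts`, and optional `confusion`.
#' @export
classification_report <- function(calls, partition = NULL, truth = NULL) {
  classes <- setdiff(MIRNA_CLASSES, "unclassified")
  class_tables <- lapply(classes, function(cc) {
    sub <- calls[calls$class == cc,
                 c("mirna", "reported_log2fc"), drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  names(class_tables) <- classes
  out <- list(
    class_tables = class_tables,
    class_counts = setNames(vapply(MIRNA_CLASSES, function(cc) {
      sum(calls$class == cc)
    }, integer(1)), MIRNA_CLASSES)
  )
  if (!is.null(partition)) out$venn_counts <- partition$counts
  if (!is.null(truth)) {
    out$confusion <- table(
      called = factor(as.character(calls$class), levels = MIRNA_CLASSES),
      truth = factor(truth[calls$mirna], levels = MIRNA_CLASSES)
    )
  }
  out
}
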