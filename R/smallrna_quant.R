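#' Read a mature miRNA reference from FASTA
#'
#' Sequences are uppercased and U is normalized to T so RNA- and DNA-style
#' references can be mixed. A `copies=N` token in a record's description
#' line is parsed as that miRNA's genome copy count (used by the
#' multimapping rule in [quantify_sample()]); the default is 1.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences with attribute
#'   `copy_number` (named integer vector).
#' @export
read_mature_reference <- function(path) {
  x <- Biostrings::readBStringSet(path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(ids)) {
    stop("duplicate ids in mature reference", call. = FALSE)
  }
  copies <- rep(1L, length(ids))
  m <- regmatches(hdr, regexpr("copies=[0-9]+", hdr))
  has <- grepl("copies=[0-9]+", hdr)
  copies[has] <- as.integer(sub("copies=", "", m))
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) stop("empty reference sequence", call. = FALSE)
  structure(setNames(unname(seqs), ids),
            copy_number = setNames(copies, ids))
}

#' Read small-RNA reads from a FASTQ file
#'
#' Transparent to gzip. Returns bare sequences; qualities are not used by
#' the quantification rules (quality filtering is the N-content surrogate
#' applied in [filter_reads()]).
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Named character vector of read sequences.
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Trim a 3' adapter from reads
#'
#' Removes the read suffix starting at the leftmost occurrence of an
#' adapter prefix of length at least `min_overlap`: either the full adapter
#' occurs inside the read, or a suffix of the read matches a prefix of the
#' adapter with at least `min_overlap` bases. Reads with no such occurrence
#' are returned unchanged.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum adapter prefix length to trigger trimming.
#' @return Character vector of trimmed reads (names preserved).
#' @export
trim_adapter <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_overlap = 5L) {
  if (min_overlap < 1L) stop("`min_overlap` must be >= 1", call. = FALSE)
  la <- nchar(adapter)
  vapply(reads, function(r) {
    lr <- nchar(r)
    if (lr == 0L) return("")
    # leftmost full-adapter occurrence wins if it precedes any partial one
    full_at <- if (lr >= la) regexpr(adapter, r, fixed = TRUE)[1] else -1L
    last_start <- lr - min_overlap + 1L
    i <- 1L
    while (i <= last_start) {
      if (full_at > 0L && i >= full_at) return(substr(r, 1L, full_at - 1L))
      L <- min(lr - i + 1L, la)
      if (L < la && substr(r, i, i + L - 1L) == substr(adapter, 1L, L)) {
        return(substr(r, 1L, i - 1L))
      }
      i <- i + 1L
    }
    if (full_at > 0L) return(substr(r, 1L, full_at - 1L))
    r
  }, character(1))
}

#' Length and quality filter for trimmed reads
#'
#' Retains reads of length at least `min_length` (the study removed reads
#' shorter than 18 nt; the boundary is inclusive). As a surrogate for the
#' unspecified low-quality-read removal, reads with more than `max_n_frac`
#' ambiguous (N) bases are also dropped. Order is preserved.
#'
#' @param reads Character vector of trimmed reads.
#' @param min_length Minimum retained length (default 18).
#' @param max_n_frac Maximum tolerated fraction of N bases (default 0.1).
#' @return Filtered character vector.
#' @export
filter_reads <- function(reads, min_length = 18L, max_n_frac = 0.1) {
  if (!length(reads)) return(reads)
  len <- nchar(reads)
  n_count <- nchar(gsub("[^N]", "", reads))
  reads[len >= min_length & n_count <= max_n_frac * pmax(len, 1L)]
}

# Positional comparison of one read against one reference sequence under
# the mapping rules. Returns mismatch count or NA if not a valid hit.
hit_mismatches <- function(read_int, ref_int, max_overhang, n_code) {
  lr <- length(read_int)
  lf <- length(ref_int)
  if (lr > lf + max_overhang) return(NA_integer_)
  cmp <- min(lr, lf)
  mm <- which(read_int[seq_len(cmp)] != ref_int[seq_len(cmp)] |
                read_int[seq_len(cmp)] == n_code)
  if (any(mm <= 18L)) return(NA_integer_)
  if (sum(mm > 18L) > 2L) return(NA_integer_)
  length(mm)
}

#' Map one read against a mature miRNA reference
#'
#' A reference record is a hit iff the read is no more than `max_overhang`
#' nt longer than it (tolerated untemplated 3' addition, not counted as
#' mismatch), there are no mismatches in the first 18 positions, and at
#' most two mismatches from position 19 onward. Comparison is positional
#' (Hamming; no indels) over the shorter of read and reference length.
#' N bases count as mismatches.
#'
#' @param read A single read sequence (length >= 18, alphabet ACGTN).
#' @param reference Named character vector of mature sequences.
#' @param max_overhang Tolerated 3' read overhang beyond the reference
#'   length, in nt (default 3).
#' @return Data frame of hits with columns `mirna` and `n_mismatch`, sorted
#'   by (mismatch count, reference id); zero rows when the read maps
#'   nowhere.
#' @export
map_read <- function(read, reference, max_overhang = 3L) {
  if (length(read) != 1L) stop("`read` must be a single sequence",
                               call. = FALSE)
  if (grepl("[^ACGTN]", read)) {
    stop("read contains non-ACGTN symbols", call. = FALSE)
  }
  if (nchar(read) < 18L) stop("read shorter than 18 nt", call. = FALSE)
  read_int <- utf8ToInt(read)
  n_code <- utf8ToInt("N")
  mm <- vapply(reference, function(rf) {
    hit_mismatches(read_int, utf8ToInt(rf), max_overhang, n_code)
  }, integer(1))
  hits <- data.frame(mirna = names(reference), n_mismatch = unname(mm),
                     stringsAsFactors = FALSE)
  hits <- hits[!is.na(hits$n_mismatch), , drop = FALSE]
  hits <- hits[order(hits$n_mismatch, hits$mirna), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Quantify one sample's reads into a miRNA count column
#'
#' Applies the multimapping rule on already trimmed and length-filtered
#' reads: a read whose total hit multiplicity (number of hit records,
#' weighted by per-record genome copy counts when the reference carries
#' them) exceeds `max_hits`, or that hits nothing, contributes 0. Otherwise
#' the read's best tier (minimum mismatch count) receives a fractional
#' count of 1/k per tied miRNA, so column totals equal the number of
#' counted reads.
#'
#' @param reads Character vector of trimmed, filtered reads.
#' @param reference Named character vector of mature sequences, optionally
#'   with a `copy_number` attribute (see [read_mature_reference()]).
#' @param max_hits Maximum tolerated hit multiplicity (default 5).
#' @param max_overhang Passed to the mapping rule.
#' @return Named numeric vector of counts over the reference ids, with
#'   attribute `n_counted` (reads that contributed).
#' @export
quantify_sample <- function(reads, reference, max_hits = 5L,
                            max_overhang = 3L) {
  if (!length(reference)) stop("empty reference", call. = FALSE)
  copies <- attr(reference, "copy_number")
  if (is.null(copies)) copies <- setNames(rep(1L, length(reference)),
                                          names(reference))
  counts <- setNames(numeric(length(reference)), names(reference))
  if (!length(reads)) return(structure(counts, n_counted = 0L))
  tab <- table(reads)
  uniq <- names(tab)
  ref_int <- lapply(reference, utf8ToInt)
  n_code <- utf8ToInt("N")
  n_counted <- 0L
  for (i in seq_along(uniq)) {
    read_int <- utf8ToInt(uniq[i])
    mm <- vapply(ref_int, function(rf) {
      hit_mismatches(read_int, rf, max_overhang, n_code)
    }, integer(1))
    hit <- which(!is.na(mm))
    if (!length(hit)) next
    if (sum(copies[names(reference)[hit]]) > max_hits) next
    best <- hit[mm[hit] == min(mm[hit])]
    w <- as.numeric(tab[[i]])
    counts[best] <- counts[best] + w / length(best)
    n_counted <- n_counted + w
  }
  structure(counts, n_counted = n_counted)
}

#' Quantify several samples into a count matrix
#'
#' @param reads_list Named list of per-sample read vectors (already trimmed
#'   and filtered), e.g. the output of [simulate_reads()] after
#'   [trim_adapter()] and [filter_reads()].
#' @param reference Mature reference as for [quantify_sample()].
#' @param ... Passed to [quantify_sample()].
#' @return Numeric matrix (miRNA x sample).
#' @export
quantify_samples <- function(reads_list, reference, ...) {
  cols <- lapply(reads_list, quantify_sample, reference = reference, ...)
  m <- do.call(cbind, lapply(cols, as.numeric))
  dimnames(m) <- list(names(reference), names(reads_list))
  m
}
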