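# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so that a given seed is reproducible regardless of the
# surrounding session state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a stage-specific seed from a root seed, kept
# within 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(truth = 11L, counts = 23L, reads = 37L, targets = 41L,
               annotations = 53L, interactions = 61L, pipeline = 71L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1000003 + off * 97) %% 2147483629)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# TSV writers/readers used for every tabular interchange format. Writing is
# deterministic (fixed column order, no quoting, no row names) so that
# manifests of repeated runs are byte-identical.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             ...)
}

write_counts_tsv <- function(counts, path) {
  df <- data.frame(mirna = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

read_counts_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
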