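# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators are pure functions of their inputs.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Fan a single seed out into `n` reproducible substream seeds (31-bit ints).
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

# Coerce a single profile (length-5 vector) or a profile matrix / items
# data frame into an n x 5 matrix of cue values in {-1, +1}.
as_profile_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- paste0("c", 1:5)
    if (!all(cols %in% names(x))) {
      stopf("expected columns %s in items table", paste(cols, collapse = ", "))
    }
    x <- as.matrix(x[, cols])
  }
  if (is.null(dim(x))) {
    if (length(x) != 5L) stopf("a cue profile must have exactly 5 entries")
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 5L) stopf("cue profiles must have 5 columns, got %d", ncol(x))
  if (!all(x %in% c(-1, 1))) stopf("cue values must all be -1 or +1")
  storage.mode(x) <- "double"
  colnames(x) <- paste0("c", 1:5)
  x
}

profile_key <- function(profiles) {
  apply(as_profile_matrix(profiles), 1L, paste, collapse = ",")
}
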