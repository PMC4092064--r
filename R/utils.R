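# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats rnorm rpois runif rexp sd pt cor rbinom
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Vectorised reverse complement on plain character vectors.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between equal-length string pairs (vectorised over pairs).
mismatch_count <- function(a, b) {
  if (length(a) == 0L) return(integer(0))
  unname(mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b))
}

# Collapse an n x k character matrix into n strings (row-wise), fast:
# one paste0 call with k vector arguments.
collapse_rows <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  if (nrow(mat) == 0L) return(character(0))
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

phred_to_int <- function(qual) {
  lapply(qual, function(s) as.integer(charToRaw(s)) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

# Per-contig cumulative offsets so (contig, pos) maps to one global index.
contig_offsets <- function(lens) {
  off <- cumsum(c(0, as.numeric(lens[-length(lens)])))
  names(off) <- names(lens)
  off
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0,1]", name), call. = FALSE)
  invisible(x)
}
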