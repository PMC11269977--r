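#' @importFrom rlang .data abort warn inform
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# utf8 code -> base index lookup (A=1, C=2, G=3, T=4; 0 marks anything else)
.base_map <- local({
  m <- integer(128L)
  m[utf8ToInt("A")] <- 1L
  m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L
  m[utf8ToInt("T")] <- 4L
  m
})

#' Encode equal-length sequences as an integer matrix
#'
#' @param seqs character vector of equal-length ACGT sequences.
#' @return integer matrix, one row per sequence, entries in 1..4.
#' @noRd
encode_seqs <- function(seqs) {
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L))
  codes <- utf8ToInt(paste(seqs, collapse = ""))
  m <- matrix(.base_map[codes], ncol = L, byrow = TRUE)
  if (anyNA(m) || any(m == 0L)) {
    abort("sequences must contain only A/C/G/T")
  }
  m
}

# which reads are pure ACGT (uppercased beforehand)
is_acgt <- function(seqs) {
  !grepl("[^ACGT]", seqs)
}

# log(exp(a) + exp(b)) elementwise, -Inf safe
logsumexp2 <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  out <- hi + log1p(exp(lo - hi))
  out[is.infinite(hi)] <- hi[is.infinite(hi)] # covers both -Inf and +Inf
  out
}

# log sum exp of a vector, -Inf safe
logsumexp <- function(x) {
  hi <- max(x)
  if (is.infinite(hi)) return(hi)
  hi + log(sum(exp(x - hi)))
}

# row-wise log-sum-exp of a matrix, -Inf safe
row_logsumexp <- function(x) {
  if (ncol(x) == 1L) return(x[, 1L])
  hi <- x[, 1L]
  for (j in 2:ncol(x)) hi <- pmax(hi, x[, j])
  acc <- numeric(nrow(x))
  fin <- is.finite(hi)
  if (any(fin)) {
    xs <- x[fin, , drop = FALSE] - hi[fin]
    acc[fin] <- rowSums(exp(xs))
  }
  out <- hi + log(acc)
  out[!fin] <- hi[!fin]
  out
}

# deterministic per-run seed derived from (base seed, lw, run index); < 2^31
derive_seed <- function(base_seed, lw, index) {
  as.integer((as.double(base_seed) * 7919 + lw * 1299709 + index * 104729) %%
               2147483629)
}
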