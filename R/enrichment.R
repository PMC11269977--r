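#' Count k-mer occurrences in a read pool
#'
#' Overlapping window counts over all reads, weighted by copy number, with
#' every one of the `4^k` possible k-mers present (zeros included). Reads
#' shorter than `k` contribute no windows (a message reports how many).
#'
#' @param reads a `read_library` or character vector of reads.
#' @param k k-mer size, `k >= 1`.
#' @return named numeric vector of length `4^k` in lexicographic (A<C<G<T)
#'   order.
#' @examples
#' count_kmers("AAAA", 2)[["AA"]] # 3
#' @export
count_kmers <- function(reads, k) {
  k <- as.integer(k)
  if (k < 1L) abort("k must be >= 1")
  if (is.data.frame(reads)) {
    assert_library(reads)
    seqs <- reads$seq
    w <- reads$count
  } else {
    seqs <- toupper(as.character(reads))
    w <- rep(1L, length(seqs))
  }
  short <- nchar(seqs) < k
  if (any(short))
    inform(sprintf("%d read(s) shorter than k contribute no windows",
                   sum(short)))
  set <- Biostrings::DNAStringSet(seqs)
  per_read <- Biostrings::oligonucleotideFrequency(set, width = k)
  counts <- as.numeric(crossprod(per_read, w))
  names(counts) <- colnames(per_read)
  counts
}

#' k-mer enrichment of a selected pool over its input pool
#'
#' The baseline motif analysis for affinity-selection data: count every
#' k-mer in the foreground (selected) and background (input) pools and take
#' the natural-log ratio of their pseudocount-smoothed frequencies,
#' `log[(n_fg + pc)/sum(n_fg + pc)] - log[(n_bg + pc)/sum(n_bg + pc)]`.
#' With `bg_mode = "model"` the background counts are replaced by the
#' expected counts under a Markov background model (the k-mer's chain
#' probability times the total number of background windows).
#'
#' @param fg_reads,bg_reads foreground and background pools
#'   (`read_library` or character vectors).
#' @param k k-mer size (default 6, the size conventionally scanned for RBP
#'   motifs).
#' @param pseudocount additive smoothing per k-mer cell.
#' @param bg_mode `"counts"` (raw background tallies) or `"model"`.
#' @param bg_model a `markov_background`, required for `bg_mode = "model"`.
#' @return an `enrichment_table` tibble with `4^k` rows: `kmer`,
#'   `fg_count`, `bg_count`, `log_enrichment`, `rank` (1 = most enriched;
#'   ties keep lexicographic order). Rows are in k-mer order; use
#'   `dplyr::arrange(rank)` for the leaderboard.
#' @export
enrichment_table <- function(fg_reads, bg_reads, k = 6, pseudocount = 1,
                             bg_mode = c("counts", "model"),
                             bg_model = NULL) {
  bg_mode <- match.arg(bg_mode)
  fg <- count_kmers(fg_reads, k)
  if (bg_mode == "counts") {
    bg <- count_kmers(bg_reads, k)
  } else {
    if (!inherits(bg_model, "markov_background"))
      abort("bg_mode = \"model\" needs a trained markov_background")
    bg_raw <- count_kmers(bg_reads, k)
    bg <- sequence_prior(bg_model, names(bg_raw)) * sum(bg_raw)
  }
  le <- (log(fg + pseudocount) - log(sum(fg + pseudocount))) -
    (log(bg + pseudocount) - log(sum(bg + pseudocount)))
  out <- tibble(
    kmer = names(fg),
    fg_count = as.numeric(fg),
    bg_count = as.numeric(bg),
    log_enrichment = as.numeric(le)
  )
  out$rank <- rank(-out$log_enrichment, ties.method = "first")
  class(out) <- c("enrichment_table", class(out))
  attr(out, "k") <- k
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Levenshtein distance between motif strings
#'
#' Unit-cost edit distance (insertions, deletions, substitutions), used to
#' compare the top enriched k-mers of an experiment: near-identical leading
#' motifs indicate one dominant specificity, while mutually distant ones
#' suggest many shallow optima.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @examples
#' levenshtein("TGCATG", "GCATGA")
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n),
         function(i) as.integer(utils::adist(a[i], b[i])[1, 1]),
         integer(1))
}

#' Pairwise Levenshtein distances among top enriched k-mers
#'
#' @param table an `enrichment_table`.
#' @param top number of leading k-mers to compare.
#' @return a long tibble `kmer_a`, `kmer_b`, `distance` over unordered
#'   pairs.
#' @export
top_motif_distances <- function(table, top = 10) {
  stopifnot(inherits(table, "enrichment_table"))
  km <- table$kmer[order(table$rank)][seq_len(min(top, nrow(table)))]
  pairs <- utils::combn(seq_along(km), 2)
  tibble(
    kmer_a = km[pairs[1, ]],
    kmer_b = km[pairs[2, ]],
    distance = levenshtein(km[pairs[1, ]], km[pairs[2, ]])
  )
}
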