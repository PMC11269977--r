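#' Read libraries
#'
#' A read library is a tibble with one row per distinct sequence, carrying the
#' copy number `count` (duplicates are collapsed at construction) and, once
#' annotated against a background model, the frequency prior columns `prior`
#' and `log_prior`. All downstream likelihood computations consume this
#' container.
#'
#' @param x a character vector of reads (A/C/G/T), or a data frame with
#'   columns `seq` and optionally `count`.
#' @param drop_invalid drop reads containing non-ACGT symbols (with a message
#'   reporting how many were removed). If `FALSE`, such reads are an error.
#' @return a `read_library` tibble with columns `seq`, `count`, `prior`,
#'   `log_prior` (priors are `NA` until [annotate_priors()] is called).
#' @examples
#' lib <- as_read_library(c("ACGTACGT", "ACGTACGT", "TTTTACGT"))
#' lib$count # 2, 1
#' @export
as_read_library <- function(x, drop_invalid = TRUE) {
  if (is.data.frame(x)) {
    if (!"seq" %in% names(x)) abort("data frame input needs a `seq` column")
    seqs <- rep(toupper(x$seq), if ("count" %in% names(x)) x$count else 1L)
  } else {
    seqs <- toupper(as.character(x))
  }
  if (length(seqs) == 0L) abort("read collection is empty")
  ok <- is_acgt(seqs)
  if (!all(ok)) {
    if (!drop_invalid) abort("reads contain non-ACGT symbols")
    inform(sprintf("dropped %d read(s) containing non-ACGT symbols",
                   sum(!ok)))
    seqs <- seqs[ok]
    if (length(seqs) == 0L) abort("all reads contained non-ACGT symbols")
  }
  tab <- table(seqs)
  out <- tibble(
    seq = names(tab),
    count = as.integer(tab),
    prior = NA_real_,
    log_prior = NA_real_
  )
  class(out) <- c("read_library", class(out))
  out
}

#' Load a read library from FASTA or FASTQ
#'
#' Files may be gzip-compressed; the format is taken from the file extension
#' (`.fastq`/`.fq` means FASTQ, anything else FASTA). FASTQ quality scores are
#' ignored: copy numbers come solely from sequence duplication.
#'
#' @param path path to a FASTA or FASTQ file (optionally `.gz`).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @inheritParams as_read_library
#' @return a `read_library` tibble (see [as_read_library()]).
#' @export
read_library <- function(path, format = c("auto", "fasta", "fastq"),
                         drop_invalid = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    stem <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fastq|fq)$", stem, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) abort(sprintf("failed to parse %s as %s: %s",
                                      path, format, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("no records in %s", path))
  as_read_library(as.character(set), drop_invalid = drop_invalid)
}

#' Write reads to FASTA
#'
#' Each distinct sequence is written `count` times so that a round trip
#' through [read_library()] reproduces the library.
#'
#' @param library a `read_library` or character vector of reads.
#' @param path output path; `.gz` suffix enables compression.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(library, path) {
  seqs <- if (is.data.frame(library)) rep(library$seq, library$count)
          else as.character(library)
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- sprintf("read_%d", seq_along(set))
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

assert_library <- function(library, annotated = FALSE) {
  if (!is.data.frame(library) || !all(c("seq", "count") %in% names(library)))
    abort("expected a read_library (tibble with `seq` and `count`)")
  if (annotated &&
      (!"log_prior" %in% names(library) || anyNA(library$log_prior)))
    abort("library must be annotated with priors first (see annotate_priors())")
  invisible(library)
}
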