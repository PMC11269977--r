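#' Position weight matrices
#'
#' A PWM here is a `length x 4` matrix of per-position nucleotide
#' probabilities \eqn{m_{i\alpha}}. Each entry is the exponential of a
#' binding energy, so rows are normalized to 1 and a small floor keeps every
#' entry positive (a zero entry would send the log-likelihood to minus
#' infinity the moment a read lacks any other binding frame).
#'
#' @param mat numeric matrix with 4 columns (A, C, G, T), one row per motif
#'   position; rows are renormalized.
#' @param floor minimum probability per entry, applied at normalization.
#' @return a `pwm`: a probability matrix with columns `A,C,G,T`.
#' @examples
#' pwm(matrix(c(9, 1, 1, 1), nrow = 1)) # A-preferring single position
#' @export
pwm <- function(mat, floor = 1e-9) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) abort("a PWM needs exactly 4 columns (A,C,G,T)")
  if (any(mat < 0) || any(!is.finite(mat))) abort("PWM entries must be finite and >= 0")
  normalize_pwm(mat, floor = floor)
}

#' @rdname pwm
#' @export
normalize_pwm <- function(mat, floor = 1e-9) {
  mat <- as.matrix(unclass(mat))
  rs <- rowSums(mat)
  if (any(rs <= 0)) abort("PWM has a position with zero total weight")
  mat <- mat / rs
  if (floor > 0) {
    mat <- pmax(mat, floor)
    mat <- mat / rowSums(mat)
  }
  dimnames(mat) <- list(NULL, BASES)
  class(mat) <- c("pwm", class(matrix()))
  mat
}

#' @rdname pwm
#' @param lw motif length.
#' @export
uniform_pwm <- function(lw) {
  pwm(matrix(0.25, nrow = lw, ncol = 4), floor = 0)
}

#' Build a PWM around a consensus motif
#'
#' The consensus base gets probability `weight` at its position and the
#' other three bases share the rest; motifs shorter than `lw` are centered
#' with uniform flanks.
#'
#' @param motif consensus string over A/C/G/T (length <= `lw`).
#' @param lw motif length; defaults to `nchar(motif)`.
#' @param weight probability of the consensus base at each motif position.
#' @inheritParams pwm
#' @return a `pwm`.
#' @export
consensus_pwm <- function(motif, lw = nchar(motif), weight = 0.7,
                          floor = 1e-9) {
  motif <- toupper(motif)
  if (!is_acgt(motif)) abort("consensus motif must be A/C/G/T")
  k <- nchar(motif)
  if (k > lw) abort("consensus motif is longer than the PWM")
  mat <- matrix(0.25, nrow = lw, ncol = 4)
  off <- (lw - k) %/% 2
  idx <- .base_map[utf8ToInt(motif)]
  for (j in seq_len(k)) {
    mat[off + j, ] <- (1 - weight) / 3
    mat[off + j, idx[j]] <- weight
  }
  pwm(mat, floor = floor)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> length %d, consensus %s\n", nrow(x), pwm_consensus(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Consensus string of a PWM (per-position argmax)
#' @param x a `pwm`.
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste0(BASES[apply(unclass(x), 1, which.max)], collapse = "")
}

#' Shift-aligned distance between two PWMs
#'
#' EM solutions for the same motif are typically related by shifts, so raw
#' positionwise comparison is meaningless. This slides one matrix against the
#' other over all offsets with at least `min_overlap` aligned positions and
#' returns the minimum over shifts of the mean per-position total-variation
#' distance on the aligned core.
#'
#' @param a,b `pwm` objects (lengths may differ).
#' @param min_overlap minimum number of aligned positions considered.
#' @return list with `distance` (mean per-position total variation, in
#'   `[0,1]`), `shift` (offset of `b` relative to `a`) and `overlap`.
#' @export
pwm_distance <- function(a, b, min_overlap = NULL) {
  a <- unclass(a); b <- unclass(b)
  la <- nrow(a); lb <- nrow(b)
  if (is.null(min_overlap)) min_overlap <- max(3L, min(la, lb) %/% 2L)
  best <- list(distance = Inf, shift = NA_integer_, overlap = 0L)
  for (s in seq.int(-(lb - 1L), la - 1L)) {
    ia <- max(1L, 1L + s):min(la, lb + s)
    if (length(ia) < min_overlap) next
    ib <- ia - s
    d <- mean(0.5 * rowSums(abs(a[ia, , drop = FALSE] -
                                  b[ib, , drop = FALSE])))
    if (d < best$distance)
      best <- list(distance = d, shift = s, overlap = length(ia))
  }
  if (!is.finite(best$distance)) abort("no alignment satisfies min_overlap")
  best
}

#' Write / read a PWM as 4-column TSV
#'
#' One row per position, columns `A`, `C`, `G`, `T`.
#'
#' @param x a `pwm`.
#' @param path file path.
#' @return the path (writer, invisibly) or a `pwm` (reader).
#' @export
write_pwm_tsv <- function(x, path) {
  df <- as.data.frame(unclass(x))
  names(df) <- BASES
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_pwm_tsv
#' @export
read_pwm_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "d"))
  if (!all(BASES %in% names(df))) abort("PWM TSV must have columns A,C,G,T")
  pwm(as.matrix(df[, BASES]), floor = 0)
}

#' Write / read PWMs in MEME minimal motif format
#'
#' Emits a minimal MEME text file (version 4 header, ACGT alphabet, uniform
#' background line, one `MOTIF` block per matrix). T is used rather than U,
#' as is conventional for Bind'n Seq reads.
#'
#' @param x a `pwm` or named list of `pwm`s.
#' @param path file path.
#' @param nsites value written in the `nsites=` field (cosmetic).
#' @return path (writer, invisibly); named list of `pwm`s (reader).
#' @export
write_pwm_meme <- function(x, path, nsites = 20) {
  motifs <- if (inherits(x, "pwm")) list(motif_1 = x) else x
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             "strands: +", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (nm in names(motifs)) {
    m <- unclass(motifs[[nm]])
    lines <- c(lines,
               sprintf("MOTIF %s", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       nrow(m), nsites),
               apply(m, 1, function(r) paste(sprintf("%.6f", r),
                                             collapse = "  ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm_meme
#' @export
read_pwm_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) abort("no MOTIF block found")
  out <- list()
  for (s in starts) {
    nm <- sub("^MOTIF\\s+", "", lines[s])
    nm <- strsplit(trimws(nm), "\\s+")[[1]][1]
    hdr <- s + 1L
    while (hdr <= length(lines) &&
           !grepl("^letter-probability matrix", lines[hdr])) hdr <- hdr + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                 as.numeric))
    out[[nm]] <- pwm(mat, floor = 0)
  }
  out
}
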