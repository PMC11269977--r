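# Independent brute-force oracles. These deliberately avoid the package's
# log-space code paths: plain products, sums and double loops.

oracle_base_idx <- function(ch) match(ch, c("A", "C", "G", "T"))

oracle_site_weight <- function(mat, site) {
  b <- oracle_base_idx(strsplit(site, "")[[1]])
  prod(mat[cbind(seq_along(b), b)])
}

oracle_read_weight <- function(mat, read) {
  lw <- nrow(mat)
  n <- nchar(read) - lw + 1
  sum(vapply(seq_len(n),
             function(j) oracle_site_weight(mat, substr(read, j, j + lw - 1)),
             numeric(1)))
}

# naive (non-log) selection likelihood, Eq 2.5 structure
oracle_total_weight <- function(mat, read, e0) {
  lw <- nrow(mat)
  oracle_read_weight(mat, read) + (nchar(read) - lw + 1) * exp(e0)
}

oracle_loglik <- function(lib, mat, e0) {
  W <- vapply(lib$seq, function(s) oracle_total_weight(mat, s, e0),
              numeric(1))
  denom <- sum(lib$prior * W)
  sum(lib$count * log(lib$prior * W / denom))
}

oracle_selection_prob <- function(lib, mat, e0) {
  W <- vapply(lib$seq, function(s) oracle_total_weight(mat, s, e0),
              numeric(1))
  p <- lib$prior * W
  unname(p / sum(p))
}

# naive double-loop PWM reweighting
oracle_update_pwm <- function(lib, mat, e0) {
  lw <- nrow(mat)
  acc <- matrix(0, nrow = lw, ncol = 4)
  for (r in seq_len(nrow(lib))) {
    S <- lib$seq[r]
    W <- oracle_total_weight(mat, S, e0)
    for (j in seq_len(nchar(S) - lw + 1)) {
      site <- substr(S, j, j + lw - 1)
      w <- lib$count[r] * oracle_site_weight(mat, site) / W
      b <- oracle_base_idx(strsplit(site, "")[[1]])
      for (i in seq_len(lw)) acc[i, b[i]] <- acc[i, b[i]] + w
    }
  }
  acc / rowSums(acc)
}

# coarse grid + local refinement maximizer of the likelihood in e0;
# specific read weights do not depend on e0, so tabulate them once
oracle_grid_e0 <- function(lib, mat, lo = -30, hi = 0) {
  rw <- vapply(lib$seq, function(s) oracle_read_weight(mat, s), numeric(1))
  nwin <- nchar(lib$seq) - nrow(mat) + 1
  ll <- function(e0) {
    W <- rw + nwin * exp(e0)
    sum(lib$count * log(lib$prior * W / sum(lib$prior * W)))
  }
  grid <- seq(lo, hi, by = 0.1)
  best <- grid[which.max(vapply(grid, ll, numeric(1)))]
  fine <- seq(max(lo, best - 0.2), min(hi, best + 0.2), by = 1e-3)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# quadratic-table edit distance
oracle_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- matrix(0L, length(av) + 1L, length(bv) + 1L)
  m[, 1] <- 0:length(av); m[1, ] <- 0:length(bv)
  for (i in seq_along(av)) for (j in seq_along(bv)) {
    m[i + 1, j + 1] <- min(m[i, j + 1] + 1L, m[i + 1, j] + 1L,
                           m[i, j] + (av[i] != bv[j]))
  }
  m[length(av) + 1L, length(bv) + 1L]
}

# seeded random fixtures ----------------------------------------------------

rand_seq <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small annotated toy library with random priors and counts
rand_library <- function(n_reads = 6, len_range = c(8, 15), seed = 1) {
  set.seed(seed)
  seqs <- character(0)
  while (length(unique(seqs)) < n_reads) {
    seqs <- c(seqs, rand_seq(sample(len_range[1]:len_range[2], 1)))
    seqs <- unique(seqs)
  }
  lib <- as_read_library(seqs)
  lib$count <- sample(1:5, nrow(lib), replace = TRUE)
  lib$prior <- stats::runif(nrow(lib), 0.1, 1)
  lib$log_prior <- log(lib$prior)
  lib
}

rand_pwm <- function(lw, seed = 1, floor = 0) {
  set.seed(seed)
  pwm(matrix(stats::rgamma(lw * 4, shape = 1) + 1e-4, nrow = lw),
      floor = floor)
}

# annotated library of equal-length reads with equal priors
flat_library <- function(seqs) {
  lib <- as_read_library(seqs)
  lib$prior <- rep(1, nrow(lib))
  lib$log_prior <- rep(0, nrow(lib))
  lib
}
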