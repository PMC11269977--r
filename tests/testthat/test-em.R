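# a small planted-motif dataset shared across EM tests
em_fixture <- local({
  fix <- NULL
  function() {
    if (is.null(fix)) {
      sim <- simulate_selection(consensus_pwm("TGCATG", weight = 0.85),
                                e0 = -8, n_background = 5000,
                                n_foreground = 5000, seed = 31)
      bgm <- train_markov(sim$background, degree = 2, pseudocount = 1)
      fix <<- list(sim = sim,
                   fg = annotate_priors(as_read_library(sim$foreground),
                                        bgm))
    }
    fix
  }
})

test_that("initialization satisfies the model invariants in both modes", {
  r <- init_model(6, mode = "random", seed = 4)
  expect_equal(unname(rowSums(unclass(r$pwm))), rep(1, 6),
               tolerance = 1e-12)
  expect_identical(unclass(init_model(6, seed = 4)$pwm), unclass(r$pwm))
  expect_false(identical(unclass(init_model(6, seed = 5)$pwm),
                         unclass(r$pwm)))
  expect_equal(r$e0, log(1 / 20))

  cns <- init_model(6, mode = "consensus", consensus = "TGCATG")
  expect_equal(pwm_consensus(cns$pwm), "TGCATG")
  expect_equal(max(unclass(cns$pwm)), 0.7, tolerance = 1e-9)

  # shorter motif is centered with uniform flanks
  cent <- init_model(7, mode = "consensus", consensus = "GCATG")
  expect_equal(unname(unclass(cent$pwm)[1, ]), rep(0.25, 4))
  expect_error(init_model(5, mode = "consensus", consensus = "TGCXTG"),
               "A/C/G/T")
  expect_error(init_model(4, mode = "consensus", consensus = "TGCATG"),
               "longer")
})

test_that("optimize_e0 agrees with a grid-scan oracle and zeroes the gradient", {
  for (s in 1:8) {
    lib <- rand_library(4, len_range = c(8, 12), seed = s + 40)
    p <- rand_pwm(4, seed = s + 80)
    res <- optimize_e0(lib, p)
    expect_equal(res$e0, oracle_grid_e0(lib, unclass(p)), tolerance = 2e-3)
    if (!res$at_edge) {
      expect_lt(abs(bindnseq:::e0_gradient(lib, p, res$e0)), 1e-6)
    }
  }
})

test_that("optimize_e0 flags the degenerate all-zero-specific-weight case", {
  # one-hot PWM matching nothing: the objective is constant in e0
  hot <- consensus_pwm("AAAAAAAA", weight = 1, floor = 0)
  lib <- flat_library(c("CCCCCCCC", "GGGGCCCC"))
  expect_warning(res <- optimize_e0(lib, hot), "unidentifiable")
  expect_true(res$degenerate)
  expect_equal(res$e0, -15)
})

test_that("update_pwm fixed points and counting oracle", {
  # one-hot PWM, e0=-Inf, one exact match per read: update returns one-hot
  hot <- consensus_pwm("ACGTA", weight = 1, floor = 0)
  lib <- flat_library(c("TTACGTATTT", "ACGTAGGGGG", "GGGGGACGTA"))
  up <- update_pwm(lib, energy_model(hot, e0 = -Inf), floor = 0)
  expect_equal(unclass(up), unclass(hot), tolerance = 1e-12,
               ignore_attr = TRUE)

  # uniform PWM, e0=-Inf: every window weighted n_S/(L-Lw+1); the update is
  # the count-weighted position-frequency matrix of all windows
  lib2 <- rand_library(5, len_range = c(9, 13), seed = 21)
  u4 <- uniform_pwm(4)
  up2 <- update_pwm(lib2, energy_model(u4, e0 = -Inf), floor = 0)
  pfm <- matrix(0, 4, 4)
  for (r in seq_len(nrow(lib2))) {
    S <- lib2$seq[r]
    nwin <- nchar(S) - 3
    for (j in seq_len(nwin)) {
      b <- oracle_base_idx(strsplit(substr(S, j, j + 3), "")[[1]])
      for (i in 1:4) pfm[i, b[i]] <- pfm[i, b[i]] + lib2$count[r] / nwin
    }
  }
  expect_equal(unclass(up2), pfm / rowSums(pfm), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("update_pwm equals the naive double-loop oracle on random models", {
  for (s in 1:15) {
    lib <- rand_library(5, seed = s + 300)
    p <- rand_pwm(4, seed = s + 600)
    e0 <- -stats::runif(1, 1, 8)
    up <- update_pwm(lib, energy_model(p, e0 = e0), floor = 0)
    expect_equal(unclass(up), oracle_update_pwm(lib, unclass(p), e0),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("EM on a planted-motif library converges, ascends net, and is deterministic", {
  fg <- em_fixture()$fg
  f <- fit_em(fg, lw = 6, seed = 9)
  expect_true(f$converged)
  expect_lte(f$iterations, 100)
  expect_true(f$final_loglik > f$initial_loglik) # convergent by definition
  expect_true(f$convergent)
  expect_identical(f$convergent, f$final_loglik > f$initial_loglik)
  if (f$specific) expect_lt(f$model$e0, 0)

  # determinism: identical inputs give identical results
  f2 <- fit_em(fg, lw = 6, seed = 9)
  expect_identical(unclass(f$model$pwm), unclass(f2$model$pwm))
  expect_identical(f$loglik_trace, f2$loglik_trace)

  # fixed-point property: one more update moves the PWM less than the
  # convergence threshold
  up <- update_pwm(fg, f$model)
  expect_lt(sum((unclass(up) - unclass(f$model$pwm))^2), 6 * 4 * 1e-6)
})

test_that("EM recovers a planted hexamer on a small simulation", {
  fix <- em_fixture()
  best <- NULL
  for (s in 1:4) {
    f <- fit_em(fix$fg, lw = 6, seed = s)
    if (is.null(best) || f$final_loglik > best$final_loglik) best <- f
  }
  al <- pwm_distance(fix$sim$truth$pwm, best$model$pwm)
  expect_lt(al$distance, 0.15)
  expect_true(best$specific)
  expect_true(grepl("GCATG|CATGC|TGCAT",
                    paste0(pwm_consensus(best$model$pwm), collapse = "")))
})

test_that("short reads are dropped before fitting and empty libraries error", {
  lib <- flat_library(c("ACGTACGTAC", "TGCATGCATG"))
  short <- rbind(lib, tibble::tibble(seq = "ACG", count = 1L, prior = 1,
                                     log_prior = 0))
  expect_message(f <- fit_em(short, lw = 6, seed = 1), "dropped 1")
  expect_equal(f$n_dropped, 1L)
  expect_error(fit_em(lib[0, ], lw = 6), "annotated|empty|at least")
})

test_that("classify_runs counts convergent and specific fractions", {
  mk <- function(conv, spec) structure(list(convergent = conv,
                                            specific = spec),
                                       class = "em_fit")
  runs <- list(mk(TRUE, TRUE), mk(TRUE, FALSE), mk(FALSE, FALSE),
               mk(TRUE, TRUE))
  s <- classify_runs(runs)
  expect_equal(s$n_runs, 4)
  expect_equal(s$frac_convergent, 0.75)
  expect_equal(s$frac_convergent_specific, 0.5)
  all_good <- classify_runs(list(mk(TRUE, TRUE), mk(TRUE, TRUE)))
  expect_equal(all_good$frac_convergent, 1)
  expect_equal(all_good$frac_convergent_specific, 1)
})

test_that("no-signal libraries yield fewer specific than convergent runs", {
  # planted uniform PWM: selection carries no sequence signal
  sim <- simulate_selection(uniform_pwm(6), e0 = -1, n_background = 1500,
                            n_foreground = 1500, seed = 77)
  bgm <- train_markov(sim$background, degree = 1, pseudocount = 1)
  fg <- annotate_priors(as_read_library(sim$foreground), bgm)
  runs <- lapply(1:8, function(s) fit_em(fg, lw = 6, seed = s,
                                         max_iter = 60))
  s <- classify_runs(runs)
  expect_lte(s$frac_convergent_specific, s$frac_convergent)
})
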