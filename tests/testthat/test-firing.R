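test_that("a duplicated G1 library retains fraction 1 everywhere", {
  spec <- default_spec("sir2", n = 30000L)
  g1 <- simulate_chec_g1(spec)
  dup <- fragment_library(g1$fragments, g1$assay, g1$genotype,
                          timepoint = 15)
  tab <- decay_table(list(g1, dup), rdna_mcm_windows(spec$model))
  expect_true(all(tab$retained == 1))
  expect_error(decay_table(list(dup), rdna_mcm_windows(spec$model)), "G1")
})

test_that("the zero-intercept exponential fit is exact on noiseless decay", {
  t <- c(15, 30, 45, 60, 90)
  tab <- data.frame(window = "w", timepoint = c(0, t),
                    raw = 1, scaled = 1,
                    retained = c(1, exp(-0.02 * t)), low_g1 = FALSE)
  fit <- fit_firing_rate(tab, "w")
  expect_equal(fit$lambda, 0.02, tolerance = 1e-12)
  expect_lt(fit$residual, 1e-12)
  flat <- transform(tab, retained = 1)
  expect_equal(fit_firing_rate(flat, "w")$lambda, 0)
  withzero <- tab; withzero$retained[3] <- 0
  expect_warning(fz <- fit_firing_rate(withzero, "w"), "zero retained")
  expect_equal(fz$timepoints_used, t[-2])
  allzero <- transform(tab, retained = c(1, rep(0, 5)))
  expect_error(suppressWarnings(fit_firing_rate(allzero, "w")), ">= 2")
})

test_that("early-late separation reproduces the pooled-variance t closed form", {
  # groups with log2 R of {1,2,3} vs {2,3,4}
  mk <- function(name, v) data.frame(window = name, timepoint = 15,
                                     raw = 100, scaled = 100,
                                     retained = 2^v, low_g1 = FALSE)
  tab <- rbind(mk("e1", 1), mk("e2", 2), mk("e3", 3),
               mk("l1", 2), mk("l2", 3), mk("l3", 4))
  catalog <- data.frame(name = c("e1", "e2", "e3", "l1", "l2", "l3"),
                        class = rep(c("early", "late"), each = 3))
  res <- early_late_separation(tab, catalog, 15)
  # closed form: means 2 and 3, pooled sd 1, n = 3 each
  t_oracle <- (2 - 3) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$p, 2 * pt(t_oracle, df = 4), tolerance = 1e-12)
  expect_equal(res$df, 4)
  # identical distributions: t = 0, p = 1
  tab2 <- rbind(mk("e1", 1), mk("e2", 2), mk("l1", 1), mk("l2", 2))
  cat2 <- data.frame(name = c("e1", "e2", "l1", "l2"),
                     class = c("early", "early", "late", "late"))
  res2 <- early_late_separation(tab2, cat2, 15)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  expect_error(early_late_separation(tab, catalog[-(1:2), ], 15), "class")
})

test_that("displaced MCMs disappear faster than nondisplaced, suppressed by fun30", {
  m <- default_genome_model()
  wins <- rdna_mcm_windows(m)
  run <- function(geno, seed = 5L) {
    spec <- simulation_spec(m, geno, n_fragments = 150000L, seed = seed)
    decay_table(simulate_chec_timecourse(spec), wins)
  }
  sir2 <- displaced_vs_nondisplaced(run(genotype_preset("sir2")))
  expect_true(all(sir2$difference[sir2$timepoint > 0] > 0))
  expect_equal(sir2$retained_displaced[sir2$timepoint == 60], exp(-1.2),
               tolerance = 0.05)
  expect_equal(sir2$retained_nondisplaced[sir2$timepoint == 60],
               exp(-0.12), tolerance = 0.05)
  sf <- displaced_vs_nondisplaced(run(genotype_preset("sir2fun30")))
  expect_equal(sf$retained_displaced[sf$timepoint == 60], exp(-0.3),
               tolerance = 0.05)
  # fun30 suppression: displaced signal persists longer at every t > 0
  expect_true(all(sf$retained_displaced[sf$timepoint > 0] >
                    sir2$retained_displaced[sir2$timepoint > 0]))
  # matched rates erase the asymmetry
  eq <- displaced_vs_nondisplaced(
    run(genotype_params(sir2_deleted = TRUE, rate_displaced = 0.005,
                        rate_nondisplaced = 0.005)))
  expect_true(all(abs(eq$difference) < 0.06))
})

test_that("MCM loss reappears as RFB-proximal gain", {
  m <- default_genome_model()
  spec <- simulation_spec(m, genotype_preset("sir2"),
                          n_fragments = 200000L, seed = 7L)
  tc <- simulate_chec_timecourse(spec)
  wins <- rdna_mcm_windows(m)
  tab <- decay_table(tc, wins)
  rfb <- rfb_accumulation(tc, m, window_width = 320L)
  expect_equal(rfb$gain[rfb$timepoint == 0], 0)
  for (t in c(30, 60, 90)) {
    sub <- tab[tab$timepoint == t, ]
    base <- tab[tab$timepoint == 0, ]
    loss <- sum(base$scaled) - sum(sub$scaled)
    gain <- rfb$gain[rfb$timepoint == t]
    se <- sqrt(sum(base$scaled) + sum(sub$scaled) +
                 rfb$scaled[rfb$timepoint == t])
    expect_lt(abs(gain - loss), 3 * se)
  }
  # sir2 fun30 accumulates less at the RFB than sir2
  spec2 <- simulation_spec(m, genotype_preset("sir2fun30"),
                           n_fragments = 200000L, seed = 7L)
  rfb2 <- rfb_accumulation(simulate_chec_timecourse(spec2), m, 320L)
  expect_lt(rfb2$gain[rfb2$timepoint == 60], rfb$gain[rfb$timepoint == 60])
})

test_that("retained fractions are invariant to uniform depth changes", {
  spec <- default_spec("sir2", n = 40000L, seed = 13L)
  tc <- simulate_chec_timecourse(spec)
  wins <- rdna_mcm_windows(spec$model)
  tab <- decay_table(tc, wins)
  doubled <- lapply(tc, function(l) {
    fr <- l$fragments[rep(seq_len(nrow(l$fragments)), 2), ]
    fragment_library(fr, l$assay, l$genotype, l$timepoint)
  })
  tab2 <- decay_table(doubled, wins)
  expect_equal(tab2$retained, tab$retained)
})
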