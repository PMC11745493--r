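test_that("identical specs yield identical libraries", {
  spec <- default_spec("sir2", n = 20000L, seed = 9L)
  expect_identical(simulate_chec_timecourse(spec),
                   simulate_chec_timecourse(spec))
  expect_identical(simulate_mnase(spec), simulate_mnase(spec))
  expect_identical(simulate_edu(spec, 60), simulate_edu(spec, 60))
  tr <- replication_track(spec$model, 5000L, f_rdna = 0.35)
  expect_identical(simulate_sseq(spec, tr), simulate_sseq(spec, tr))
  # and a different seed changes the draw
  spec2 <- default_spec("sir2", n = 20000L, seed = 10L)
  expect_false(identical(simulate_chec_g1(spec), simulate_chec_g1(spec2)))
})

test_that("MCM-site fragments are footprint-sized, dyad fragments nucleosomal", {
  spec <- default_spec("sir2", n = 100000L)
  lib <- simulate_chec_g1(spec)
  m <- spec$model
  win <- rdna_mcm_windows(m, 40L)   # tight windows isolate the MCM sites
  all_sizes <- window_signal(lib, win)
  fp <- window_signal(lib, win, c(51L, 100L))
  expect_true(sum(fp) / sum(all_sizes) >= 0.99)
  # nucleosome-adjacent emissions are all in the 151-200 bp class
  fp2 <- feature_positions(m)
  dy <- fp2[grepl("^nuc_", fp2$feature), ]
  dwin <- data.frame(name = dy$feature, chrom = dy$chrom,
                     start = dy$pos - 20L, end = dy$pos + 20L)
  in_class <- window_signal(lib, dwin, c(151L, 200L))
  any_size <- window_signal(lib, dwin)
  expect_true(sum(in_class) / sum(any_size) > 0.95)
})

test_that("licensed rDNA signal is conserved across the time course", {
  spec <- default_spec("sir2", n = 200000L, seed = 5L)
  tc <- simulate_chec_timecourse(spec)
  m <- spec$model
  win <- rbind(rdna_mcm_windows(m, 200L), rfb_windows(m, 320L))
  tot <- vapply(tc, function(l) sum(window_signal(l, win, c(51L, 100L))),
                numeric(1))
  for (i in seq_along(tot)[-1]) {
    se <- sqrt(tot[1] + tot[i])
    expect_lt(abs(tot[i] - tot[1]), 3 * se)
  }
})

test_that("footprint signal at each MCM site decays monotonically", {
  spec <- default_spec("sir2", n = 150000L, seed = 6L)
  tc <- simulate_chec_timecourse(spec)
  win <- rdna_mcm_windows(spec$model, 200L)
  counts <- vapply(tc, function(l) window_signal(l, win, c(51L, 100L)),
                   numeric(2))
  for (w in rownames(counts)) {
    x <- counts[w, ]
    slack <- 3 * sqrt(x[-length(x)] + x[-1])
    expect_true(all(diff(x) <= slack))
  }
})

test_that("S-phase depth tracks 1 + replicated fraction", {
  m <- mini_model(0L)
  g <- genotype_params()
  spec <- simulation_spec(m, g, n_fragments = 200000L, seed = 2L)
  track <- data.frame(chrom = "chrU", start = c(0L, 500L),
                      end = c(500L, 1000L), f = c(1, 0))
  ss <- simulate_sseq(spec, track)
  cnt <- function(lib, lo, hi) {
    mid <- midpoints(lib)
    sum(lib$fragments$chrom == "chrU" & mid >= lo & mid < hi)
  }
  ratio_s <- cnt(ss$s, 0, 500) / cnt(ss$s, 500, 1000)
  expect_lt(abs(ratio_s - 2), 0.06)  # (1+1)/(1+0)
  ratio_g1 <- cnt(ss$g1, 0, 500) / cnt(ss$g1, 500, 1000)
  expect_lt(abs(ratio_g1 - 1), 0.03)
  expect_error(simulate_sseq(spec, transform(track, f = c(1.5, 0))),
               "\\[0, 1\\]")
})

test_that("EdU fork geometry spans 2 * v * t around a deterministically firing origin", {
  m <- genome_model(data.frame(name = c("chrU", "chrR"),
                               length = c(50000L, 200L)),
                    mini_model(0L)$rdna)
  m$origins <- data.frame(name = "o1", chrom = "chrU", pos = 25000,
                          class = "early", weak = FALSE)
  g <- genotype_params(rate_early = 1e6)   # fires at t ~ 0
  spec <- simulation_spec(m, g, n_fragments = 50000L, seed = 3L,
                          background_fraction = 0)
  lib <- simulate_edu(spec, harvest_minutes = 60)
  mid <- midpoints(lib)
  expect_true(all(mid >= 25000 - 3000 - 1 & mid <= 25000 + 3000))
  expect_gt(diff(range(mid)), 5600)  # fills the 6 kb replicated interval
})

test_that("licensing assay recovers the licensed fraction", {
  m <- default_genome_model()
  # unlicensed limit
  g0 <- genotype_params(licensing_prob = 0)
  b0 <- simulate_licensing_assay(simulation_spec(m, g0, 1000, seed = 1), 1)
  expect_lt(abs(suppressWarnings(licensed_fraction(b0))), 0.1)
  # complete licensing and cutting eliminates the target band
  g1 <- genotype_params(licensing_prob = 1)
  b1 <- simulate_licensing_assay(simulation_spec(m, g1, 1000, seed = 1), 1)
  expect_equal(b1$target_t, 0)
  expect_equal(as.numeric(licensed_fraction(b1)), 1)
  # default L = 0.75 sits inside the observed 60-85% depletion range
  g <- genotype_params()
  est <- mean(vapply(1:5, function(i) {
    b <- simulate_licensing_assay(simulation_spec(m, g, 1000, seed = i), 1)
    as.numeric(licensed_fraction(b))
  }, numeric(1)))
  expect_gt(est, 0.60)
  expect_lt(est, 0.85)
})
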