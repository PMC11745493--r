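make_activity <- function(origins, values_by_genotype, class = "early") {
  rows <- lapply(names(values_by_genotype), function(g)
    data.frame(origin = origins, class = class, weak = FALSE, genotype = g,
               signal = values_by_genotype[[g]],
               log10_signal = ifelse(values_by_genotype[[g]] > 0,
                                     log10(values_by_genotype[[g]]),
                                     NA_real_)))
  structure(do.call(rbind, rows),
            class = c("origin_activity_table", "data.frame"))
}

test_that("median log10 activity follows the definition", {
  tab <- make_activity(paste0("o", 1:3),
                       list(wt = rep(1e6, 3), mut = c(1e5, 1e6, 1e7)))
  expect_equal(median_log10(tab, "early", "wt"), 6)
  expect_equal(median_log10(tab, "early", "mut"), 6)
  zero <- make_activity("o1", list(wt = 0))
  expect_error(median_log10(zero, "early", "wt"), "positive")
})

test_that("drop comparison has a null at identical mutants and power at huge effects", {
  tab <- make_activity(paste0("o", 1:10),
                       list(wt = rep(1e6, 10), a = rep(1e6, 10) * 0.9,
                            b = rep(1e6, 10) * 0.9))
  res <- compare_drops(tab, "wt", "a", "b")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # constructed drops 0.3 vs 0.1 with sd 0.05, n = 111
  set.seed(77)
  n <- 111
  wt <- rep(6, n)
  a <- wt - rnorm(n, 0.3, 0.05)
  b <- wt - rnorm(n, 0.1, 0.05)
  tab2 <- make_activity(paste0("o", 1:n),
                        list(wt = 10^wt, a = 10^a, b = 10^b))
  res2 <- compare_drops(tab2, "wt", "a", "b")
  expect_lt(res2$p, 1e-10)
  expect_equal(res2$mean_drop_a, 0.3, tolerance = 0.02)
  expect_error(compare_drops(tab2, "wt", "a", "nope"), "matched")
})

test_that("5 kb windows capture the expected share of a fired origin's reads", {
  m <- genome_model(data.frame(name = c("chrU", "chrR"),
                               length = c(50000L, 200L)),
                    mini_model(0L)$rdna)
  m$origins <- data.frame(name = "o1", chrom = "chrU", pos = 25000,
                          class = "early", weak = FALSE)
  spec <- simulation_spec(m, genotype_params(rate_early = 1e6),
                          n_fragments = 100000L, seed = 3L,
                          background_fraction = 0)
  lib <- simulate_edu(spec, 60)
  tab <- origin_activity(list(x = lib), m$origins, m, window = 5000L)
  # reads fill a 6 kb interval; the centered 5 kb window holds 5/6 of them
  expect_equal(tab$signal / library_size(lib), 5000 / 6000,
               tolerance = 0.02)
})

test_that("weak early origins lose activity in sir2 and recover in sir2 fun30", {
  m <- default_genome_model()
  cat_ <- rbind(m$origins, rdna_origin(m))
  for (seed in c(5L, 6L, 7L)) {
    libs <- lapply(c(wt = "wt", sir2 = "sir2", sir2fun30 = "sir2fun30"),
                   function(g) simulate_edu(
                     simulation_spec(m, genotype_preset(g),
                                     n_fragments = 200000L, seed = seed),
                     60))
    tab <- origin_activity(libs, cat_, m)
    med <- vapply(names(libs), function(g)
      median_log10(tab, "weak_early", g), numeric(1))
    expect_true(med[["wt"]] > med[["sir2fun30"]])
    expect_true(med[["sir2fun30"]] > med[["sir2"]])
    # rDNA origins gain EdU signal in sir2, partially reversed by fun30
    rd <- vapply(names(libs), function(g)
      tab$signal[tab$class == "rdna" & tab$genotype == g], numeric(1))
    expect_true(rd[["sir2"]] > rd[["wt"]])
    expect_true(rd[["sir2"]] > rd[["sir2fun30"]])
    if (seed == 5L) {
      cd <- compare_drops(tab, "wt", "sir2", "sir2fun30", "early",
                          paired = TRUE)
      expect_lt(cd$p, 1e-3)
      expect_gt(cd$mean_drop_a, cd$mean_drop_b)
    }
  }
})

test_that("scaling one input library does not change the activity table", {
  m <- default_genome_model()
  spec <- simulation_spec(m, genotype_preset("wt"), n_fragments = 50000L,
                          seed = 9L)
  a <- simulate_edu(spec, 60)
  b <- simulate_edu(simulation_spec(m, genotype_preset("sir2"),
                                    n_fragments = 50000L, seed = 9L), 60)
  tab <- origin_activity(list(wt = a, sir2 = b), m$origins, m)
  b2 <- fragment_library(b$fragments[rep(seq_len(50000L), 3), ], b$assay,
                         b$genotype, b$timepoint)
  # the tripled library raises the max total, so the whole table scales by
  # exactly 3; relative origin activity is untouched
  tab2 <- origin_activity(list(wt = a, sir2 = b2), m$origins, m)
  expect_equal(tab2$signal, 3 * tab$signal, tolerance = 1e-12)
})
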