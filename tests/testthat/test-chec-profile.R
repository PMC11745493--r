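test_that("size-coordinate matrix places one fragment in one cell", {
  lib <- lib_at(42L, len = 65L)
  mat <- size_coord_matrix(lib, "chrU", 0L, 100L, c(51L, 100L))
  expect_equal(sum(mat$counts), 1L)
  expect_equal(mat$counts[42 + 1, 65 - 51 + 1], 1L)
  expect_error(size_coord_matrix(lib, "chrU", 10L, 10L), "empty region")
  # empty region of the genome gives an all-zero matrix
  m0 <- size_coord_matrix(lib, "chrR", 0L, 50L)
  expect_equal(sum(m0$counts), 0L)
})

test_that("matrix marginals agree with the size-class tracks", {
  spec <- default_spec("sir2", n = 50000L)
  lib <- simulate_chec_g1(spec)
  mat <- size_coord_matrix(lib, "chrXII", 0L, 18200L, c(1L, 250L))
  for (cl in list(c(51L, 100L), c(151L, 200L))) {
    prof <- class_profile(mat, cl)
    tr <- midpoint_track(lib, cl, bin = 1L, model = spec$model)
    tr <- tr[tr$chrom == "chrXII", ]
    expect_equal(prof$count, tr$count[seq_len(18200)])
  }
  expect_error(class_profile(mat, c(0L, 50L)), "outside")
  full <- class_profile(mat, c(1L, 250L))
  both <- class_profile(mat, c(51L, 100L))$count +
    class_profile(mat, c(151L, 200L))$count
  expect_true(all(both <= full$count))
})

test_that("TSV round trip preserves the size-coordinate matrix", {
  lib <- lib_at(c(42L, 42L, 60L), len = 65L)
  mat <- size_coord_matrix(lib, "chrU", 0L, 100L, c(60L, 70L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_size_coord_matrix(mat, p)
  df <- utils::read.delim(p, check.names = FALSE)
  expect_equal(df$coord, 1:100)          # 1-based coordinates on disk
  expect_equal(unname(as.matrix(df[, -1])), unname(mat$counts))
})

test_that("peak calling matches a brute-force smoothing oracle", {
  # single impulse
  prof <- structure(list(chrom = "c", coord = 0:499,
                         count = as.numeric(0:499 == 250),
                         size_class = NULL, repeat_relative = FALSE),
                    class = "occupancy_profile")
  pk <- call_peaks(prof)
  expect_equal(pk$position, 250)
  # two equal impulses 40 bp apart with min separation 100: one peak,
  # at the left impulse (tie broken leftmost)
  y <- as.numeric(0:499 %in% c(200, 240))
  prof2 <- structure(list(chrom = "c", coord = 0:499, count = y,
                          size_class = NULL, repeat_relative = FALSE),
                     class = "occupancy_profile")
  pk2 <- call_peaks(prof2, smoothing_bw = 10, min_separation = 100)
  # oracle: direct kernel sum over the grid
  sm <- vapply(0:499, function(x)
    sum(y * dnorm(x - 0:499, 0, 10)), numeric(1))
  expect_equal(pk2$position, 200)
  expect_equal(which.max(sm) - 1, 200)
  expect_equal(pk2$height, max(sm), tolerance = 1e-6)
  # invariance to uniform scaling
  prof3 <- prof2; prof3$count <- prof3$count * 7
  expect_equal(call_peaks(prof3)$position, pk2$position)
  # empty profile
  prof0 <- prof; prof0$count <- prof0$count * 0
  expect_equal(nrow(call_peaks(prof0)), 0L)
})

test_that("displaced and nondisplaced MCM peaks resolve at ~150 bp", {
  spec <- default_spec("sir2", n = 100000L, seed = 21L)
  lib <- simulate_chec_g1(spec)
  prof <- repeat_class_profile(lib, spec$model, c(51L, 100L))
  pk <- call_peaks(prof, smoothing_bw = 10, min_separation = 100)
  top2 <- pk[order(-pk$height), ][1:2, ]
  expect_lt(abs(abs(diff(top2$position)) - 150), 5 + 1e-9)
  off <- spec$model$rdna$offsets
  expect_lt(min(abs(sort(top2$position) - off$mcm_nondisplaced)), 3 + 1e-9)
  # a WT G1 library is dominated by the single nondisplaced peak
  libw <- simulate_chec_g1(default_spec("wt", n = 100000L, seed = 21L))
  pw <- call_peaks(repeat_class_profile(libw, spec$model, c(51L, 100L)))
  expect_lt(abs(pw$position[which.max(pw$height)] - off$mcm_nondisplaced),
            3 + 1e-9)
})

test_that("window signal uses half-open midpoint membership and adds up", {
  lib <- lib_at(c(899L, 900L, 1099L), len = 60L)
  win <- data.frame(name = "w", chrom = "chrU", start = 900L, end = 1100L)
  expect_equal(unname(window_signal(lib, win)), 2)
  empty <- fragment_library(data.frame(chrom = character(),
                                       start = integer(), end = integer()),
                            "chec")
  expect_equal(unname(window_signal(empty, win)), 0)
  # disjoint windows partition their union
  wins <- data.frame(name = c("a", "b"), chrom = "chrU",
                     start = c(800L, 1000L), end = c(1000L, 1200L))
  lib2 <- lib_at(seq(810L, 1190L, by = 10L), len = 60L)
  parts <- window_signal(lib2, wins)
  uni <- data.frame(name = "u", chrom = "chrU", start = 800L, end = 1200L)
  expect_equal(sum(parts), unname(window_signal(lib2, uni)))
  # shared names aggregate
  wins2 <- data.frame(name = "s", chrom = "chrU",
                      start = c(800L, 1000L), end = c(1000L, 1200L))
  expect_equal(unname(window_signal(lib2, wins2)), sum(parts))
})

test_that("nucleosome occupancy normalizes to the +1 dyad", {
  m <- default_genome_model()
  g <- genotype_params(occupancy = c(0.9, 0.3, 0.45))
  spec <- simulation_spec(m, g, n_fragments = 400000L, seed = 31L)
  occ <- nucleosome_occupancy(
    repeat_class_profile(simulate_mnase(spec), m, c(151L, 200L)), m)
  expect_equal(occ[["plus1"]], 1)
  expect_equal(unname(occ[c("plus2", "plus3")]), c(1 / 3, 0.5),
               tolerance = 0.15)
  # zero +1 signal has no normalization reference
  prof0 <- structure(list(chrom = "chrXII", coord = 0:9099,
                          count = numeric(9100), size_class = c(151, 200),
                          repeat_relative = TRUE),
                     class = "occupancy_profile")
  expect_error(nucleosome_occupancy(prof0, m), "reference")
})

test_that("ChEC +2/+3 nucleosome signal requires a displaced MCM", {
  m <- default_genome_model()
  spec0 <- simulation_spec(m, genotype_preset("wt", displaced_fraction = 0),
                           n_fragments = 150000L, seed = 15L)
  lib <- simulate_chec_g1(spec0)
  prof <- repeat_class_profile(lib, m, c(151L, 200L))
  dy <- m$rdna$offsets$nucleosome_dyads
  cnt <- vapply(dy, function(d)
    sum(prof$count[prof$coord >= d - 50 & prof$coord < d + 50]),
    numeric(1))
  expect_gt(cnt[1], 50)            # +1 still emitted with nondisplaced MCM
  expect_lt(cnt[2] + cnt[3], 0.02 * cnt[1])  # +2/+3 at background
})
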