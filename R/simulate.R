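# Synthetic fragment-library generator.
#
# Fragments are sampled directly from mixture weights (equivalent in
# distribution to simulating individual cells/repeats, but vastly cheaper).
# Each assay draws from an independent substream of the master seed, so a
# given simulation_spec always yields byte-identical libraries.

clip_round <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

draw_lengths <- function(n, spec, class) {
  switch(class,
    footprint = clip_round(stats::rnorm(n, spec$footprint[["mean"]],
                                        spec$footprint[["sd"]]),
                           spec$footprint[["min"]], spec$footprint[["max"]]),
    nucleosome = clip_round(stats::rnorm(n, spec$nucleosomal[["mean"]],
                                         spec$nucleosomal[["sd"]]),
                            spec$nucleosomal[["min"]],
                            spec$nucleosomal[["max"]]),
    background = sample(40:250, n, replace = TRUE),
    sonic = sample(150:450, n, replace = TRUE),
    stop("unknown length class ", class))
}

# Assemble a fragment data.frame from midpoints + lengths, clipped to
# chromosome bounds.
build_fragments <- function(model, chrom, mid, len) {
  start <- mid - len %/% 2L
  end <- start + len
  cl <- model$chromosomes$length[match(chrom, model$chromosomes$name)]
  # clip the rare boundary cases only
  i <- which(start < 0)
  if (length(i) > 0) start[i] <- 0
  i <- which(end > cl)
  if (length(i) > 0) end[i] <- cl[i]
  i <- which(end <= start)
  if (length(i) > 0) end[i] <- start[i] + 1
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# Sample n fragments from a component table. Components have columns:
#   weight, kind (point|uniform|grid|genome), chrom, pos, u0, u1, step,
#   ngrid, len_class, jitter (logical).
sample_components <- function(spec, comp, n) {
  model <- spec$model
  idx <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
  mid <- numeric(n)
  chrom <- comp$chrom[idx]
  kind <- comp$kind[idx]
  p <- kind == "point"
  if (any(p)) {
    mid[p] <- comp$pos[idx[p]]
    jit <- p & comp$jitter[idx]
    if (any(jit))
      mid[jit] <- mid[jit] +
        round(stats::rnorm(sum(jit), 0, spec$midpoint_jitter_sd))
  }
  u <- kind == "uniform"
  if (any(u)) {
    w <- comp$u1[idx[u]] - comp$u0[idx[u]]
    mid[u] <- comp$u0[idx[u]] + floor(stats::runif(sum(u)) * w)
  }
  g <- kind == "grid"
  if (any(g)) {
    slot <- floor(stats::runif(sum(g)) * comp$ngrid[idx[g]])
    mid[g] <- comp$u0[idx[g]] + slot * comp$step[idx[g]] +
      round(stats::rnorm(sum(g), 0, spec$midpoint_jitter_sd))
  }
  gen <- kind == "genome"
  if (any(gen)) {
    lens <- model$chromosomes$length
    ci <- sample.int(length(lens), sum(gen), replace = TRUE, prob = lens)
    chrom[gen] <- model$chromosomes$name[ci]
    mid[gen] <- floor(stats::runif(sum(gen)) * lens[ci])
  }
  # keep midpoints on-chromosome after jitter
  cl <- model$chromosomes$length[match(chrom, model$chromosomes$name)]
  mid <- pmin(cl - 1, pmax(0, mid))
  len <- numeric(n)
  for (lc in unique(comp$len_class)) {
    sel <- comp$len_class[idx] == lc
    if (any(sel)) len[sel] <- draw_lengths(sum(sel), spec, lc)
  }
  build_fragments(model, chrom, mid, len)
}

component_row <- function(weight, kind, chrom = NA, pos = NA, u0 = NA,
                          u1 = NA, step = NA, ngrid = NA,
                          len_class = "footprint", jitter = TRUE) {
  data.frame(weight = weight, kind = kind, chrom = chrom, pos = pos,
             u0 = u0, u1 = u1, step = step, ngrid = ngrid,
             len_class = len_class, jitter = jitter,
             stringsAsFactors = FALSE)
}

# Per-copy point components at an rDNA feature offset, total weight w.
rdna_point_rows <- function(model, offset, w, len_class = "footprint") {
  r <- model$rdna
  cc <- r$collapsed_copies
  pos <- r$collapsed_start + (seq_len(cc) - 1L) * r$repeat_length + offset
  component_row(rep(w / cc, cc), "point", r$chrom, pos,
                len_class = len_class)
}

# -- S-seq ------------------------------------------------------------------

#' Bin-level replicated-fraction track
#'
#' Builds the per-bin replicated fraction f used by [simulate_sseq()]. Bins
#' on the unique chromosome receive a symmetric spread of f values around
#' `f_median` (an early-to-late gradient whose genome-wide median is exactly
#' `f_median`); bins inside the collapsed rDNA interval are set to `f_rdna`.
#'
#' @param model a `genome_model`.
#' @param bin_size bin width in bp.
#' @param f_rdna replicated fraction of the rDNA locus.
#' @param f_median genome-wide median replicated fraction.
#' @param f_spread half-range of the genome f gradient (values span
#'   `f_median +/- f_spread`).
#' @return data.frame `chrom`, `start`, `end`, `f`.
#' @export
replication_track <- function(model, bin_size = 1000L, f_rdna = 0.5,
                              f_median = 0.5, f_spread = 0.4) {
  if (f_median - f_spread < 0 || f_median + f_spread > 1)
    stop("f values must stay within [0, 1]")
  bins <- lapply(seq_len(nrow(model$chromosomes)), function(i) {
    len <- model$chromosomes$length[i]
    s <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = model$chromosomes$name[i], start = s,
               end = pmin(s + bin_size, len), stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, bins)
  iv <- rdna_interval(model)
  in_rdna <- bins$chrom == model$rdna$chrom & bins$start >= iv[1] &
    bins$end <= iv[2]
  f <- numeric(nrow(bins))
  ng <- sum(!in_rdna)
  f[!in_rdna] <- f_median + f_spread * seq(-1, 1, length.out = ng)
  f[in_rdna] <- f_rdna
  bins$f <- f
  bins
}

#' Simulate sorted G1 and S fragment libraries
#'
#' G1 fragment midpoints are sampled proportional to local copy number
#' (bins in the collapsed rDNA interval carry weight N/collapsed_copies per
#' bp); S midpoints proportional to copy number times `(1 + f)`, since a
#' locus replicated in a fraction f of sorted S cells is present in `1 + f`
#' copies on average. Fragment lengths follow a uniform 150-450 bp
#' sonication model.
#'
#' @param spec a `simulation_spec`.
#' @param f_track per-bin replicated fractions from [replication_track()].
#' @return named list with `g1` and `s` fragment libraries.
#' @export
simulate_sseq <- function(spec, f_track) {
  if (any(f_track$f < 0 | f_track$f > 1))
    stop("replicated fractions must lie in [0, 1]")
  model <- spec$model
  set.seed(assay_seed(spec$seed, "sseq"))
  iv <- rdna_interval(model)
  in_rdna <- f_track$chrom == model$rdna$chrom & f_track$start >= iv[1] &
    f_track$end <= iv[2]
  copy <- ifelse(in_rdna,
                 model$rdna$physical_copies / model$rdna$collapsed_copies, 1)
  blen <- f_track$end - f_track$start
  w_g1 <- blen * copy
  w_s <- w_g1 * (1 + f_track$f)
  lab <- genotype_label(spec$genotype)
  draw <- function(w, assay) {
    # multinomial bin counts then expansion: far cheaper than per-fragment
    # weighted sampling at these library sizes
    cnt <- stats::rmultinom(1, spec$n_fragments, w)[, 1]
    idx <- rep.int(seq_along(w), cnt)
    mid <- f_track$start[idx] + floor(stats::runif(spec$n_fragments) *
                                        blen[idx])
    len <- draw_lengths(spec$n_fragments, spec, "sonic")
    fragment_library(build_fragments(model, f_track$chrom[idx], mid, len),
                     assay = assay, genotype = lab, timepoint = NA_real_)
  }
  list(g1 = draw(w_g1, "sseq_g1"), s = draw(w_s, "sseq_s"))
}

# -- MCM2-ChEC --------------------------------------------------------------

# Mixture component table for a ChEC library at time t (minutes in HU).
chec_components <- function(spec, t) {
  model <- spec$model
  g <- spec$genotype
  N <- g$physical_copies
  L <- g$licensing_prob
  pd <- g$displaced_fraction
  off <- model$rdna$offsets
  w_nd <- N * L * (1 - pd) * exp(-g$rate_nondisplaced * t)
  w_d <- N * L * pd * exp(-g$rate_displaced * t)
  w_rfb <- N * L - w_nd - w_d
  rows <- list(
    rdna_point_rows(model, off$mcm_nondisplaced, w_nd),
    rdna_point_rows(model, off$mcm_displaced, w_d))
  rows[[1]]$type <- "nondisplaced"; rows[[2]]$type <- "displaced"
  if (w_rfb > 0) {
    r <- model$rdna
    cc <- r$collapsed_copies
    rfb_pos <- r$collapsed_start + (seq_len(cc) - 1L) * r$repeat_length +
      off$rfb
    rf <- component_row(rep(w_rfb / cc, cc), "uniform", r$chrom,
                        u0 = rfb_pos - 300L, u1 = rfb_pos, jitter = FALSE)
    rf$type <- "rfb"
    rows <- c(rows, list(rf))
  }
  # nucleosome-adjacent fragments, conditional on the co-located MCM
  occ <- g$occupancy
  nuc <- rbind(
    rdna_point_rows(model, off$nucleosome_dyads[1], occ[1] * w_nd,
                    "nucleosome"),
    rdna_point_rows(model, off$nucleosome_dyads[2], occ[2] * w_d,
                    "nucleosome"),
    rdna_point_rows(model, off$nucleosome_dyads[3], occ[3] * w_d,
                    "nucleosome"))
  nuc <- nuc[nuc$weight > 0, , drop = FALSE]
  if (nrow(nuc) > 0) { nuc$type <- "nucleosome"; rows <- c(rows, list(nuc)) }
  # genomic origin footprints
  cat_ <- model$origins
  if (!is.null(cat_) && nrow(cat_) > 0) {
    rate <- ifelse(cat_$class == "early",
                   g$rate_early * ifelse(cat_$weak, g$weak_early_scale, 1),
                   g$rate_late)
    go <- component_row(exp(-rate * t), "point", cat_$chrom, cat_$pos)
    go$type <- "origin"
    rows <- c(rows, list(go))
  }
  comp <- do.call(rbind, rows)
  # conserve total signal: weight lost from genomic-origin footprints and
  # MCM-conditioned nucleosome fragments disperses genome-wide
  core0 <- N * L * (1 + occ[1] * (1 - pd) + (occ[2] + occ[3]) * pd) +
    if (!is.null(cat_)) nrow(cat_) else 0
  w_disp <- core0 - sum(comp$weight)
  if (w_disp > 1e-9) {
    dr <- component_row(w_disp, "genome", len_class = "background")
    dr$type <- "dispersed"
    comp <- rbind(comp, dr)
  }
  bf <- spec$background_fraction
  if (bf > 0) {
    br <- component_row(core0 * bf / (1 - bf), "genome",
                        len_class = "background")
    br$type <- "background"
    comp <- rbind(comp, br)
  }
  comp
}

#' Simulate an MCM2-ChEC hydroxyurea time course
#'
#' One library per timepoint. At time t the mixture holds: the nondisplaced
#' footprint with weight `L(1-p_d)exp(-lambda_n t)` per repeat, the
#' displaced footprint with `L p_d exp(-lambda_d t)`, and the balance of
#' the licensed signal deposited uniformly over the 300 bp immediately left
#' of the RFB (fired rDNA helicases travel with the stalled fork).
#' Nucleosome-adjacent 151-200 bp fragments are emitted at the +1 dyad with
#' probability occ1 per nondisplaced MCM and at +2/+3 with occ2/occ3 per
#' displaced MCM. Genomic origin footprints decay at the early/late firing
#' rates (weak early origins at a scaled rate); signal lost from decayed
#' footprints disperses genome-wide, so total library composition is
#' conserved and max-total depth normalization leaves retained fractions
#' interpretable as survival probabilities.
#'
#' @param spec a `simulation_spec`.
#' @return named list of `fragment_library` objects, one per timepoint
#'   (`"t0"` is the G1 reference).
#' @export
simulate_chec_timecourse <- function(spec) {
  lab <- genotype_label(spec$genotype)
  out <- lapply(seq_along(spec$timepoints), function(i) {
    t <- spec$timepoints[i]
    set.seed((assay_seed(spec$seed, "chec") + i) %% .Machine$integer.max)
    comp <- chec_components(spec, t)
    fr <- sample_components(spec, comp, spec$n_fragments)
    fragment_library(fr, assay = "chec", genotype = lab, timepoint = t)
  })
  stats::setNames(out, paste0("t", spec$timepoints))
}

#' Simulate a G1 MCM2-ChEC library
#'
#' Convenience wrapper: the t = 0 member of [simulate_chec_timecourse()].
#'
#' @param spec a `simulation_spec`.
#' @export
simulate_chec_g1 <- function(spec) {
  lab <- genotype_label(spec$genotype)
  set.seed((assay_seed(spec$seed, "chec") + 1L) %% .Machine$integer.max)
  comp <- chec_components(spec, 0)
  fragment_library(sample_components(spec, comp, spec$n_fragments),
                   assay = "chec", genotype = lab, timepoint = 0)
}

# -- MNase-seq --------------------------------------------------------------

#' Simulate an MNase-seq nucleosome library
#'
#' Nucleosomal (151-200 bp) fragments centered on the +1/+2/+3 dyads with
#' per-dyad emission probability occ_k per repeat (unconditional on MCM:
#' MNase sees all repeats), plus phased background nucleosomes at 165 bp
#' spacing across the rest of the repeat and the whole unique chromosome
#' (occupancy 0.7), plus uniform background.
#'
#' @param spec a `simulation_spec`.
#' @export
simulate_mnase <- function(spec) {
  model <- spec$model
  g <- spec$genotype
  set.seed(assay_seed(spec$seed, "mnase"))
  r <- model$rdna
  N <- g$physical_copies
  occ <- g$occupancy
  rows <- list()
  for (k in 1:3)
    rows[[k]] <- rdna_point_rows(model, r$offsets$nucleosome_dyads[k],
                                 N * occ[k], "nucleosome")
  # phased repeat nucleosomes outside the origin-proximal region
  grid <- seq(82L, r$repeat_length - 83L, by = 165L)
  keep <- grid < r$offsets$cpro_start - 100L |
    grid > r$offsets$nucleosome_dyads[3] + 100L
  grid <- grid[keep]
  cc <- r$collapsed_copies
  for (i in seq_len(cc)) {
    pos <- r$collapsed_start + (i - 1L) * r$repeat_length + grid
    rows[[length(rows) + 1L]] <-
      component_row(rep(0.7 * N / cc, length(pos)), "point", r$chrom, pos,
                    len_class = "nucleosome")
  }
  # phased nucleosomes across the unique chromosome, as one grid component
  ulen <- model$chromosomes$length[1]
  nd <- (ulen - 165L) %/% 165L
  rows[[length(rows) + 1L]] <-
    component_row(0.7 * nd, "grid", model$chromosomes$name[1], u0 = 82L,
                  step = 165L, ngrid = nd, len_class = "nucleosome")
  comp <- do.call(rbind, rows)
  bf <- spec$background_fraction
  if (bf > 0)
    comp <- rbind(comp, component_row(sum(comp$weight) * bf / (1 - bf),
                                      "genome", len_class = "background"))
  fragment_library(sample_components(spec, comp, spec$n_fragments),
                   assay = "mnase", genotype = genotype_label(g),
                   timepoint = 0)
}

# -- EdU-seq ----------------------------------------------------------------

#' Simulate an EdU-seq library
#'
#' Each genomic origin draws an exponential firing time at its class rate
#' (weak early origins at a scaled rate; late origins effectively silent in
#' HU). Origins that fire before harvest contribute reads uniformly over
#' the replicated interval `position +/- v * (harvest - firing)`, with read
#' weight proportional to the nascent-DNA length. Each of the N rDNA
#' repeats is licensed with probability L, carries a displaced MCM with
#' probability p_d, fires at the corresponding rate, and replicates at most
#' 1.5 kb in each direction (forks stall at the RFB). A small uniform
#' background completes the mixture.
#'
#' @param spec a `simulation_spec`.
#' @param harvest_minutes harvest time after release into HU (> 0).
#' @export
simulate_edu <- function(spec, harvest_minutes = 60) {
  if (harvest_minutes <= 0) stop("harvest_minutes must be > 0")
  model <- spec$model
  g <- spec$genotype
  set.seed(assay_seed(spec$seed, "edu"))
  v <- spec$fork_speed
  rows <- list()
  cat_ <- model$origins
  if (!is.null(cat_) && nrow(cat_) > 0) {
    rate <- ifelse(cat_$class == "early",
                   g$rate_early * ifelse(cat_$weak, g$weak_early_scale, 1),
                   g$rate_late)
    tf <- ifelse(rate > 0, stats::rexp(nrow(cat_), pmax(rate, 1e-12)), Inf)
    ext <- v * pmax(0, harvest_minutes - tf)
    fired <- ext > 0
    if (any(fired)) {
      len <- model$chromosomes$length[match(cat_$chrom[fired],
                                            model$chromosomes$name)]
      u0 <- pmax(0, cat_$pos[fired] - ext[fired])
      u1 <- pmin(len, cat_$pos[fired] + ext[fired])
      rows[[1]] <- component_row(u1 - u0, "uniform", cat_$chrom[fired],
                                 u0 = u0, u1 = u1, len_class = "sonic",
                                 jitter = FALSE)
    }
  }
  # rDNA repeats: licensed w.p. L, displaced w.p. p_d, fork capped at RFB
  r <- model$rdna
  N <- r$physical_copies
  if (N > 0) {
    lic <- stats::rbinom(N, 1L, g$licensing_prob) == 1L
    disp <- stats::rbinom(N, 1L, g$displaced_fraction) == 1L
    rate <- ifelse(disp, g$rate_displaced, g$rate_nondisplaced)
    tf <- ifelse(lic & rate > 0, stats::rexp(N, pmax(rate, 1e-12)), Inf)
    ext <- pmin(1500, v * pmax(0, harvest_minutes - tf))
    fired <- ext > 0
    if (any(fired)) {
      cc <- r$collapsed_copies
      copy <- sample.int(cc, sum(fired), replace = TRUE) - 1L
      center <- r$collapsed_start + copy * r$repeat_length + r$offsets$acs
      u0 <- pmax(0, center - ext[fired])
      u1 <- pmin(cc * r$repeat_length + r$collapsed_start,
                 center + ext[fired])
      rows[[length(rows) + 1L]] <-
        component_row(u1 - u0, "uniform", r$chrom, u0 = u0, u1 = u1,
                      len_class = "sonic", jitter = FALSE)
    }
  }
  comp <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  core <- if (is.null(comp)) 0 else sum(comp$weight)
  bf <- max(spec$background_fraction, if (core == 0) 1 else 0)
  bg <- component_row(max(core * bf / (1 - bf), if (core == 0) 1 else 0),
                      "genome", len_class = "sonic")
  comp <- rbind(comp, bg)
  fragment_library(sample_components(spec, comp, spec$n_fragments),
                   assay = "edu", genotype = genotype_label(g),
                   timepoint = harvest_minutes)
}

# -- Southern licensing assay ----------------------------------------------

#' Simulate a restriction-fragment licensing assay
#'
#' Band intensities for the Southern readout of origin licensing: MCM-MNase
#' activation destroys the origin-spanning restriction fragment in licensed
#' repeats, so the target band after activation is
#' `baseline * (1 - L * cut_efficiency)`, with multiplicative lognormal
#' noise (sigma 0.05) on every band. The loading-control band is constant
#' in expectation and the uncut-band baseline is proportional to array size
#' N (100 units at N = 150).
#'
#' @param spec a `simulation_spec`.
#' @param cut_efficiency probability that MNase cuts a licensed repeat's
#'   fragment, in `[0, 1]`.
#' @return a [band_quant()] object.
#' @export
simulate_licensing_assay <- function(spec, cut_efficiency = 1) {
  if (cut_efficiency < 0 || cut_efficiency > 1)
    stop("cut_efficiency must lie in [0, 1]")
  g <- spec$genotype
  set.seed(assay_seed(spec$seed, "bands"))
  noise <- function(n) stats::rlnorm(n, -0.05^2 / 2, 0.05)
  base <- 100 * g$physical_copies / 150
  target_t0 <- base * noise(1)
  target_t <- base * (1 - g$licensing_prob * cut_efficiency) * noise(1)
  control_t0 <- 50 * noise(1)
  control_t <- 50 * noise(1)
  uncut <- base * noise(1)
  band_quant(target_t0 = target_t0, target_t = target_t,
             control_t0 = control_t0, control_t = control_t,
             uncut = uncut)
}
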