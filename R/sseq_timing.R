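#' Relative replication timing (Trel) profile
#'
#' Per genomic bin b, the S-phase read share is divided by the G1 share,
#' `r_b = (S_b/S_tot) / (G_b/G_tot)`, which cancels copy-number differences
#' (crucial at repetitive loci whose copy number varies); the ratio track is
#' then divided by its genome-wide median so that a locus replicating at the
#' average time scores Trel = 1, early regions score above 1 (up to ~1.4)
#' and late regions below (down to ~0.8). The median (not mean) is used so
#' the normalizer is robust to the rDNA's own depth. Bins with fewer than
#' `min_g1_count` G1 midpoints are left undefined.
#'
#' @param g1,s G1 and S `fragment_library` objects (non-empty).
#' @param model a `genome_model` fixing the bin grid.
#' @param bin_size bin width in bp (>= 100; default 1000).
#' @param min_g1_count minimum G1 midpoints for a bin to be covered
#'   (default 20).
#' @return object of class `timing_profile`: element `bins` is a data.frame
#'   with `chrom`, `start`, `end`, `g1`, `s`, `ratio`, `trel` (`NA` where
#'   uncovered); plus the normalization record (`median_ratio`,
#'   `min_g1_count`, library totals).
#' @export
trel_profile <- function(g1, s, model, bin_size = 1000L,
                         min_g1_count = 20L) {
  if (bin_size < 100) stop("bin_size must be >= 100")
  if (library_size(g1) == 0 || library_size(s) == 0)
    stop("both libraries must be non-empty")
  tg <- midpoint_track(g1, bin = bin_size, model = model)
  ts <- midpoint_track(s, bin = bin_size, model = model)
  stopifnot(nrow(tg) == nrow(ts))
  g_tot <- library_size(g1); s_tot <- library_size(s)
  covered <- tg$count >= min_g1_count
  if (!any(covered)) stop("no bin reaches the G1 coverage threshold")
  ratio <- rep(NA_real_, nrow(tg))
  ratio[covered] <- (ts$count[covered] / s_tot) / (tg$count[covered] / g_tot)
  med <- stats::median(ratio[covered])
  if (!is.finite(med) || med <= 0) stop("degenerate genome-wide median ratio")
  bins <- data.frame(chrom = tg$chrom, start = tg$start, end = tg$end,
                     g1 = tg$count, s = ts$count, ratio = ratio,
                     trel = ratio / med, stringsAsFactors = FALSE)
  structure(list(bins = bins, bin_size = bin_size, median_ratio = med,
                 min_g1_count = min_g1_count,
                 totals = c(g1 = g_tot, s = s_tot)),
            class = "timing_profile")
}

#' @export
print.timing_profile <- function(x, ...) {
  cov <- sum(!is.na(x$bins$trel))
  cat("timing_profile:", nrow(x$bins), "bins of", x$bin_size, "bp |",
      cov, "covered | median ratio", signif(x$median_ratio, 4), "\n")
  invisible(x)
}

#' Mean Trel over a region
#'
#' Unweighted mean of Trel across covered bins lying fully inside the
#' half-open interval; bins partially overlapping the boundary are
#' excluded.
#'
#' @param profile a `timing_profile`.
#' @param chrom,start,end the query interval (0-based half-open).
#' @export
region_trel <- function(profile, chrom, start, end) {
  b <- profile$bins
  keep <- b$chrom == chrom & b$start >= start & b$end <= end &
    !is.na(b$trel)
  if (!any(keep)) stop("no covered bins fully inside the region")
  mean(b$trel[keep])
}

#' rDNA region Trel
#'
#' [region_trel()] evaluated on the model's rDNA timing region.
#'
#' @param profile a `timing_profile`.
#' @param model a `genome_model`.
#' @export
rdna_trel <- function(profile, model) {
  tr <- model$rdna$timing_region
  region_trel(profile, model$rdna$chrom, tr[1], tr[2])
}

#' Fraction of G1 reads arising from the rDNA
#'
#' Fraction of fragment midpoints falling inside the collapsed rDNA
#' interval; the sequencing-based readout of relative array size.
#'
#' @param g1 a G1 `fragment_library` (non-empty).
#' @param model a `genome_model`.
#' @export
rdna_g1_fraction <- function(g1, model) {
  if (library_size(g1) == 0) stop("library is empty")
  iv <- rdna_interval(model)
  mid <- midpoints(g1)
  mean(g1$fragments$chrom == model$rdna$chrom & mid >= iv[1] & mid < iv[2])
}

#' rDNA copy number from the G1 read fraction
#'
#' Inverts the closed form frac = N*l / (N*l + U):
#' `N = frac * U / ((1 - frac) * l)`.
#'
#' @param frac rDNA G1 read fraction, `0 <= frac < 1`.
#' @param model a `genome_model` supplying U (unique length) and l (repeat
#'   length).
#' @export
copies_from_fraction <- function(frac, model) {
  if (any(frac < 0) || any(frac >= 1))
    stop("fraction must lie in [0, 1)")
  frac * model$unique_length / ((1 - frac) * model$rdna$repeat_length)
}

#' Export a Trel profile as bedGraph
#'
#' @param profile a `timing_profile`.
#' @param path output path.
#' @export
write_trel_bedgraph <- function(profile, path) {
  b <- profile$bins[!is.na(profile$bins$trel), ]
  write_bedgraph(b, path, value = "trel", drop_zero = FALSE)
}
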