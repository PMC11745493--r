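#' Coordinate-by-fragment-length count matrix
#'
#' The size-resolved view of a ChEC/MNase library over a region: one row
#' per coordinate, one column per fragment length, entry `[c, s]` counting
#' fragments with midpoint c and length s. Summing columns over a size
#' class reproduces the corresponding midpoint track.
#'
#' @param lib a `fragment_library`.
#' @param chrom,start,end the region (0-based half-open, non-empty).
#' @param size_range length-2 vector `c(min, max)` of fragment lengths
#'   spanned by the columns (default 1-250).
#' @return object of class `size_coord_matrix` with elements `chrom`,
#'   `coord_start`, `coord_end`, `size_min`, `size_max` and the integer
#'   `counts` matrix.
#' @export
size_coord_matrix <- function(lib, chrom, start, end,
                              size_range = c(1L, 250L)) {
  if (end <= start) stop("empty region")
  if (size_range[1] > size_range[2] || size_range[1] < 1)
    stop("invalid size range")
  mid <- midpoints(lib)
  len <- fragment_lengths(lib)
  keep <- lib$fragments$chrom == chrom & mid >= start & mid < end &
    len >= size_range[1] & len <= size_range[2]
  nr <- end - start
  nc <- size_range[2] - size_range[1] + 1L
  idx <- (mid[keep] - start) * nc + (len[keep] - size_range[1]) + 1L
  counts <- matrix(tabulate(idx, nbins = nr * nc), nrow = nr, ncol = nc,
                   byrow = TRUE)
  structure(list(chrom = chrom, coord_start = start, coord_end = end,
                 size_min = size_range[1], size_max = size_range[2],
                 counts = counts),
            class = "size_coord_matrix")
}

#' @export
print.size_coord_matrix <- function(x, ...) {
  cat("size_coord_matrix:", x$chrom, paste0("[", x$coord_start, ",",
      x$coord_end, ")"), "x lengths", x$size_min, "-", x$size_max,
      "|", sum(x$counts), "fragments\n")
  invisible(x)
}

#' Write / read a size-coordinate matrix as TSV
#'
#' First column is the 1-based coordinate; the remaining columns are the
#' fragment lengths.
#'
#' @param mat a `size_coord_matrix`.
#' @param path TSV path.
#' @export
write_size_coord_matrix <- function(mat, path) {
  df <- data.frame(coord = seq(mat$coord_start + 1L, mat$coord_end),
                   mat$counts, check.names = FALSE)
  names(df) <- c("coord", seq(mat$size_min, mat$size_max))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Per-coordinate occupancy profile for a fragment size class
#'
#' Sums the matrix columns whose lengths fall in the class; the standard
#' classes are 51-100 bp (sub-nucleosomal MCM footprints, ~65 bp under a
#' double-hexamer) and 151-200 bp (nucleosome-protected fragments).
#'
#' @param mat a `size_coord_matrix`.
#' @param size_class length-2 vector `c(min, max)` within the matrix range.
#' @return object of class `occupancy_profile` with `chrom`, `coord`
#'   (0-based positions), `count`, `size_class`.
#' @export
class_profile <- function(mat, size_class) {
  if (size_class[1] < mat$size_min || size_class[2] > mat$size_max)
    stop("size class outside matrix range")
  cols <- seq(size_class[1] - mat$size_min + 1L,
              size_class[2] - mat$size_min + 1L)
  structure(list(chrom = mat$chrom,
                 coord = seq(mat$coord_start, mat$coord_end - 1L),
                 count = rowSums(mat$counts[, cols, drop = FALSE]),
                 size_class = size_class, repeat_relative = FALSE),
            class = "occupancy_profile")
}

#' Size-class profile folded onto repeat coordinates
#'
#' Profiles over the rDNA are computed on the collapsed repeat: midpoints
#' from every collapsed copy are folded by their repeat-relative position,
#' pooling the copies to maximize signal.
#'
#' @param lib a `fragment_library`.
#' @param model a `genome_model`.
#' @param size_class length-2 `c(min, max)` fragment-length filter, or
#'   `NULL` for all.
#' @return an `occupancy_profile` with coordinates `0 ..
#'   repeat_length - 1` relative to the repeat start.
#' @export
repeat_class_profile <- function(lib, model, size_class = c(51L, 100L)) {
  r <- model$rdna
  iv <- rdna_interval(model)
  mid <- midpoints(lib)
  len <- fragment_lengths(lib)
  keep <- lib$fragments$chrom == r$chrom & mid >= iv[1] & mid < iv[2]
  if (!is.null(size_class))
    keep <- keep & len >= size_class[1] & len <= size_class[2]
  rel <- (mid[keep] - r$collapsed_start) %% r$repeat_length
  structure(list(chrom = r$chrom, coord = seq(0L, r$repeat_length - 1L),
                 count = tabulate(rel + 1L, nbins = r$repeat_length),
                 size_class = size_class, repeat_relative = TRUE),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("occupancy_profile:", length(x$coord), "coords |",
      sum(x$count), "fragments",
      if (!is.null(x$size_class)) paste0("| lengths ", x$size_class[1], "-",
                                         x$size_class[2]),
      if (isTRUE(x$repeat_relative)) "| repeat-relative", "\n")
  invisible(x)
}

#' Call peaks on a smoothed occupancy profile
#'
#' The profile is smoothed with a Gaussian kernel of bandwidth
#' `smoothing_bw`; local maxima (leftmost point of any plateau) above
#' `min_prominence` of the global maximum are accepted greedily in order of
#' decreasing height, enforcing `min_separation` between accepted peaks.
#' Ties in height break leftmost. Defaults resolve two equal peaks 150 bp
#' apart — the spacing of the displaced and nondisplaced MCM sites.
#'
#' @param profile an `occupancy_profile`.
#' @param smoothing_bw Gaussian bandwidth in bp (>= 1; default 10).
#' @param min_separation minimum distance between accepted peaks (default
#'   100 bp).
#' @param min_prominence minimum height as a fraction of the maximum
#'   smoothed height (default 0.05).
#' @return data.frame of class `peak_set` with `position` (sorted),
#'   `height` and `prominence` (height above the profile's smoothed
#'   minimum), empty for an empty profile.
#' @export
call_peaks <- function(profile, smoothing_bw = 10, min_separation = 100,
                       min_prominence = 0.05) {
  if (smoothing_bw < 1) stop("smoothing_bw must be >= 1")
  y <- profile$count
  empty <- data.frame(position = integer(), height = numeric(),
                      prominence = numeric())
  if (length(y) == 0 || sum(y) == 0)
    return(structure(empty, class = c("peak_set", "data.frame")))
  sm <- gaussian_smooth(y, smoothing_bw)
  n <- length(sm)
  left <- c(-Inf, sm[-n])
  right <- c(sm[-1], -Inf)
  cand <- which(sm > left & sm >= right & sm >= min_prominence * max(sm))
  if (length(cand) == 0)
    return(structure(empty, class = c("peak_set", "data.frame")))
  cand <- cand[order(-sm[cand], cand)]
  acc <- integer()
  for (i in cand)
    if (all(abs(i - acc) >= min_separation)) acc <- c(acc, i)
  acc <- sort(acc)
  out <- data.frame(position = profile$coord[acc], height = sm[acc],
                    prominence = sm[acc] - min(sm))
  structure(out, class = c("peak_set", "data.frame"))
}

# Discrete Gaussian smoothing with kernel support +/- 4 bandwidths.
gaussian_smooth <- function(y, bw) {
  h <- ceiling(4 * bw)
  k <- stats::dnorm(seq(-h, h), 0, bw)
  n <- length(y)
  conv <- stats::convolve(c(numeric(h), y, numeric(h)), rev(k),
                          type = "filter")
  stopifnot(length(conv) == n)
  conv
}

#' Signal per window, restricted to a size class
#'
#' Counts fragment midpoints in each half-open window; windows sharing a
#' name (e.g. one window per collapsed repeat copy) are summed.
#'
#' @param lib a `fragment_library`.
#' @param windows data.frame with `name`, `chrom`, `start`, `end`.
#' @param size_class length-2 `c(min, max)` fragment-length filter, or
#'   `NULL` for all.
#' @return named numeric vector, one entry per unique window name.
#' @export
window_signal <- function(lib, windows, size_class = NULL) {
  mid <- midpoints(lib)
  chrom <- lib$fragments$chrom
  if (!is.null(size_class)) {
    if (size_class[1] > size_class[2]) stop("inverted size class")
    len <- fragment_lengths(lib)
    keep <- len >= size_class[1] & len <= size_class[2]
    mid <- mid[keep]; chrom <- chrom[keep]
  }
  counts <- numeric(nrow(windows))
  for (cn in unique(windows$chrom)) {
    m <- sort(mid[chrom == cn])
    wi <- which(windows$chrom == cn)
    if (length(m) == 0) next
    lo <- findInterval(windows$start[wi] - 0.5, m)
    hi <- findInterval(windows$end[wi] - 0.5, m)
    counts[wi] <- hi - lo
  }
  rowsum_names <- unique(windows$name)
  out <- rowsum(counts, group = windows$name, reorder = FALSE)[, 1]
  out[rowsum_names]
}

#' Nucleosome occupancy at the +1/+2/+3 dyads, normalized to +1
#'
#' Counts midpoints in a window around each annotated dyad and divides by
#' the +1 count — the +1 nucleosome's consistently high occupancy makes it
#' the natural normalization reference across genotypes.
#'
#' @param profile a repeat-relative `occupancy_profile` (151-200 bp class).
#' @param model a `genome_model`.
#' @param dyad_window window width centered on each dyad (even, >= 20;
#'   default 100).
#' @return named numeric vector `c(plus1 = 1, plus2, plus3)` with raw
#'   counts in attribute `"counts"`.
#' @export
nucleosome_occupancy <- function(profile, model, dyad_window = 100L) {
  if (dyad_window < 20 || dyad_window %% 2 != 0)
    stop("dyad_window must be even and >= 20")
  if (!isTRUE(profile$repeat_relative))
    stop("profile must be repeat-relative (see repeat_class_profile)")
  dy <- model$rdna$offsets$nucleosome_dyads
  half <- dyad_window %/% 2
  cnt <- vapply(dy, function(d)
    sum(profile$count[profile$coord >= d - half &
                        profile$coord < d + half]), numeric(1))
  names(cnt) <- c("plus1", "plus2", "plus3")
  if (cnt[1] == 0) stop("+1 dyad count is zero: no normalization reference")
  out <- cnt / cnt[1]
  attr(out, "counts") <- cnt
  out
}
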