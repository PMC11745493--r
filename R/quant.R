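#' Band-intensity quantification record
#'
#' Intensities from a Southern licensing assay: the origin-spanning target
#' band before (`target_t0`) and after (`target_t`) MNase activation, the
#' single-copy loading-control band at the same two times, and optionally
#' the uncut array band plus the reference sample's uncut/control pair for
#' relative array-size estimation.
#'
#' @param target_t0,target_t target-band intensities (>= 0).
#' @param control_t0,control_t loading-control intensities (> 0).
#' @param uncut optional uncut-band intensity of this sample.
#' @param reference_uncut,reference_control optional uncut/control pair of
#'   the reference sample.
#' @export
band_quant <- function(target_t0, target_t, control_t0, control_t,
                       uncut = NA_real_, reference_uncut = NA_real_,
                       reference_control = NA_real_) {
  if (any(c(target_t0, target_t) < 0))
    stop("band intensities must be non-negative")
  if (any(c(control_t0, control_t) <= 0))
    stop("loading-control intensities must be strictly positive")
  structure(list(target_t0 = target_t0, target_t = target_t,
                 control_t0 = control_t0, control_t = control_t,
                 uncut = uncut, reference_uncut = reference_uncut,
                 reference_control = reference_control),
            class = "band_quant")
}

#' Licensed fraction from restriction-fragment depletion
#'
#' Control-normalized depletion of the origin-spanning band,
#' `D = 1 - (T_t/T_0) / (C_t/C_0)`, divided by the MNase cut efficiency.
#' MNase activation destroys the fragment only in repeats carrying a
#' loaded MCM, so D estimates the licensed fraction directly when cutting
#' is complete. Values are clipped to `[0, 1]`; clipping raises a warning
#' and sets the `"clipped"` attribute.
#'
#' @param b a `band_quant`.
#' @param cut_efficiency fraction of licensed repeats actually cut, in
#'   `(0, 1]` (default 1).
#' @export
licensed_fraction <- function(b, cut_efficiency = 1) {
  if (cut_efficiency <= 0 || cut_efficiency > 1)
    stop("cut_efficiency must lie in (0, 1]")
  if (b$target_t0 == 0) stop("zero time-0 target intensity")
  depletion <- 1 - (b$target_t / b$target_t0) / (b$control_t / b$control_t0)
  lic <- depletion / cut_efficiency
  clipped <- lic < 0 || lic > 1
  if (clipped) {
    warning("licensed fraction ", signif(lic, 3), " clipped to [0, 1]")
    lic <- min(1, max(0, lic))
  }
  attr(lic, "clipped") <- clipped
  lic
}

#' Relative array size from the uncut band
#'
#' Control-normalized uncut-band intensity of the sample divided by the
#' same quantity in the reference sample; proportional to the ratio of
#' repeat copy numbers.
#'
#' @param b a `band_quant` with `uncut`, `reference_uncut` and
#'   `reference_control` set.
#' @export
relative_array_size <- function(b) {
  if (is.na(b$uncut) || is.na(b$reference_uncut) ||
      is.na(b$reference_control))
    stop("uncut and reference intensities are required")
  if (b$reference_uncut <= 0 || b$reference_control <= 0)
    stop("reference intensities must be > 0")
  (b$uncut / b$control_t0) / (b$reference_uncut / b$reference_control)
}

#' Active origins per cell from 2D-gel arc signals
#'
#' Ratio of the replication-bubble arc signal to the single-copy ARS
#' fragment signal: because the single-ARS band occurs once per cell, the
#' ratio counts active array origins per cell.
#'
#' @param bubble_signal bubble-arc intensity (>= 0).
#' @param single_ars_signal single-ARS fragment intensity (> 0).
#' @export
active_origins_per_cell <- function(bubble_signal, single_ars_signal) {
  if (single_ars_signal <= 0) stop("single-ARS signal must be > 0")
  if (bubble_signal < 0) stop("bubble signal must be >= 0")
  bubble_signal / single_ars_signal
}

#' qPCR panel for copy-number calibration
#'
#' Ct values for a repeat-specific query amplicon and a single-copy
#' reference amplicon, in the unknown sample and in two calibration
#' standards of known copy number (default 180 and 35 copies).
#'
#' @param ct_query,ct_ref Ct values of the unknown sample.
#' @param std_ct_query,std_ct_ref length-2 Ct vectors for the two
#'   standards.
#' @param std_copies known copy numbers of the standards (distinct, > 0).
#' @param efficiency assumed amplification efficiency (default 2, perfect
#'   doubling).
#' @export
qpcr_panel <- function(ct_query, ct_ref, std_ct_query, std_ct_ref,
                       std_copies = c(180, 35), efficiency = 2) {
  ct <- c(ct_query, ct_ref, std_ct_query, std_ct_ref)
  if (any(!is.finite(ct))) stop("all Ct values must be finite")
  if (length(std_copies) != 2 || any(std_copies <= 0) ||
      std_copies[1] == std_copies[2])
    stop("standards must have two distinct positive copy numbers")
  if (efficiency <= 1) stop("efficiency must exceed 1")
  structure(list(ct_query = ct_query, ct_ref = ct_ref,
                 std_ct_query = std_ct_query, std_ct_ref = std_ct_ref,
                 std_copies = std_copies, efficiency = efficiency),
            class = "qpcr_panel")
}

#' Copy number from a qPCR panel
#'
#' Two-point log-linear calibration: per sample, delta-Ct = Ct_query -
#' Ct_ref; log_E(copies) is linear in delta-Ct through the two standards,
#' and the unknown's delta-Ct is inverted on that line.
#'
#' @param p a `qpcr_panel`.
#' @export
copies_from_qpcr <- function(p) {
  dct <- p$ct_query - p$ct_ref
  d <- p$std_ct_query - p$std_ct_ref
  if (d[1] == d[2])
    stop("degenerate calibration: standards have identical delta-Ct")
  lc <- log(p$std_copies, base = p$efficiency)
  slope <- (lc[2] - lc[1]) / (d[2] - d[1])
  p$efficiency^(lc[1] + (dct - d[1]) * slope)
}

#' Per-copy C-pro expression relative to a baseline sample
#'
#' Relative expression `E^(-ddCt)` (query vs reference amplicon, sample vs
#' baseline) divided by the copy-number ratio, yielding transcription per
#' rDNA repeat.
#'
#' @param ct_cpro,ct_ref Ct values of the sample.
#' @param copies rDNA copy number of the sample (> 0).
#' @param baseline_ct_cpro,baseline_ct_ref,baseline_copies the same triple
#'   for the baseline sample.
#' @param efficiency amplification efficiency (default 2).
#' @export
cpro_per_copy <- function(ct_cpro, ct_ref, copies, baseline_ct_cpro,
                          baseline_ct_ref, baseline_copies,
                          efficiency = 2) {
  if (copies <= 0 || baseline_copies <= 0)
    stop("copy numbers must be > 0")
  ddct <- (ct_cpro - ct_ref) - (baseline_ct_cpro - baseline_ct_ref)
  rel <- efficiency^(-ddct)
  rel / (copies / baseline_copies)
}

#' Write a band-quant record as TSV
#' @param b a `band_quant`.
#' @param path output path.
#' @export
write_band_quant <- function(b, path) {
  df <- data.frame(field = names(unclass(b)),
                   value = unlist(unclass(b), use.names = FALSE))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a band-quant record from TSV
#' @param path TSV written by [write_band_quant()].
#' @export
read_band_quant <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  v <- stats::setNames(as.numeric(df$value), df$field)
  band_quant(v[["target_t0"]], v[["target_t"]], v[["control_t0"]],
             v[["control_t"]], uncut = v[["uncut"]],
             reference_uncut = v[["reference_uncut"]],
             reference_control = v[["reference_control"]])
}
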