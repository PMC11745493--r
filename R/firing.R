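#' Retained MCM-ChEC signal across an HU time course
#'
#' For each window and timepoint: the raw midpoint count in the size class,
#' the depth-scaled count (max-total normalization across the time-course
#' libraries), and the retained fraction R relative to the G1 (t = 0)
#' library. Fired helicases stop protecting their footprint, so R tracks
#' the survival probability of the loaded MCM at that window.
#'
#' @param timecourse list of `fragment_library` objects sharing a genotype
#'   and including the t = 0 (G1) reference.
#' @param windows data.frame with `name`, `chrom`, `start`, `end`.
#' @param size_class fragment-length filter (default the 51-100 bp MCM
#'   footprint class).
#' @param min_g1 windows with fewer raw G1 counts than this are flagged
#'   unreliable (default 50), not dropped.
#' @return data.frame of class `decay_table`: `window`, `timepoint`,
#'   `raw`, `scaled`, `retained`, `low_g1`.
#' @export
decay_table <- function(timecourse, windows, size_class = c(51L, 100L),
                        min_g1 = 50L) {
  tps <- vapply(timecourse, function(l) l$timepoint, numeric(1))
  if (!any(tps == 0)) stop("time course must include the t = 0 G1 library")
  gts <- vapply(timecourse, function(l) l$genotype, character(1))
  if (length(unique(gts)) != 1)
    stop("all libraries in a time course must share a genotype")
  factors <- scale_to_max_total(timecourse)
  rows <- lapply(seq_along(timecourse), function(i) {
    raw <- window_signal(timecourse[[i]], windows, size_class)
    data.frame(window = names(raw), timepoint = tps[i],
               raw = unname(raw), scaled = unname(raw) * factors[i],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  g1 <- tab[tab$timepoint == 0, ]
  base <- stats::setNames(g1$scaled, g1$window)
  raw0 <- stats::setNames(g1$raw, g1$window)
  tab$retained <- ifelse(base[tab$window] > 0,
                         tab$scaled / base[tab$window], NA_real_)
  tab$low_g1 <- raw0[tab$window] < min_g1
  rownames(tab) <- NULL
  structure(tab, class = c("decay_table", "data.frame"))
}

#' Early-versus-late origin separation at one timepoint
#'
#' Two-sample two-tailed Student t-test (pooled variance) on per-origin
#' log2 retained fractions, early class versus late class. Early origins
#' fire in HU while late origins are checkpoint-inhibited, so the
#' separation grows over the time course.
#'
#' @param table a `decay_table` whose windows are named by origin.
#' @param catalog origin catalog mapping window names to classes.
#' @param t timepoint (minutes) to test.
#' @param var_equal pooled-variance Student t (default TRUE); set FALSE for
#'   Welch.
#' @return list with `mean_log2_early`, `mean_log2_late`, `t`, `p`, `df`.
#' @export
early_late_separation <- function(table, catalog, t, var_equal = TRUE) {
  sub <- table[table$timepoint == t & !is.na(table$retained) &
                 table$retained > 0, ]
  cls <- catalog$class[match(sub$window, catalog$name)]
  le <- log2(sub$retained[which(cls == "early")])
  ll <- log2(sub$retained[which(cls == "late")])
  if (length(le) < 2 || length(ll) < 2)
    stop("each origin class needs at least 2 usable windows")
  tt <- stats::t.test(le, ll, var.equal = var_equal)
  list(mean_log2_early = mean(le), mean_log2_late = mean(ll),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Displaced versus nondisplaced retained fractions
#'
#' Pairs the retained fractions of the two rDNA MCM windows at every
#' timepoint. A faster-firing displaced population shows
#' `R_displaced < R_nondisplaced` at every t > 0.
#'
#' @param table a `decay_table` containing windows named `"displaced"` and
#'   `"nondisplaced"`.
#' @return data.frame `timepoint`, `retained_displaced`,
#'   `retained_nondisplaced`, `difference` (nondisplaced minus displaced).
#' @export
displaced_vs_nondisplaced <- function(table) {
  d <- table[table$window == "displaced", ]
  n <- table[table$window == "nondisplaced", ]
  if (nrow(d) == 0 || nrow(n) == 0)
    stop("table must contain both rDNA MCM windows")
  m <- merge(d[, c("timepoint", "retained")],
             n[, c("timepoint", "retained")], by = "timepoint",
             suffixes = c("_displaced", "_nondisplaced"))
  names(m) <- c("timepoint", "retained_displaced", "retained_nondisplaced")
  m$difference <- m$retained_nondisplaced - m$retained_displaced
  m[order(m$timepoint), ]
}

#' Signal accumulation left of the replication fork barrier
#'
#' Depth-scaled counts in `[rfb - width, rfb)` (summed over collapsed
#' copies) minus the G1 baseline. Helicase signal lost from the MCM
#' windows reappears here as forks from fired rDNA origins stall at the
#' barrier.
#'
#' @param timecourse list of `fragment_library` objects including t = 0.
#' @param model a `genome_model`.
#' @param window_width width of the RFB-proximal window (default 300 bp).
#' @param size_class fragment-length filter (default 51-100 bp).
#' @return data.frame `timepoint`, `scaled`, `gain`.
#' @export
rfb_accumulation <- function(timecourse, model, window_width = 300L,
                             size_class = c(51L, 100L)) {
  win <- rfb_windows(model, window_width)
  factors <- scale_to_max_total(timecourse)
  tps <- vapply(timecourse, function(l) l$timepoint, numeric(1))
  scaled <- vapply(seq_along(timecourse), function(i)
    as.numeric(window_signal(timecourse[[i]], win, size_class)) * factors[i],
    numeric(1))
  base <- scaled[which(tps == 0)[1]]
  out <- data.frame(timepoint = tps, scaled = scaled, gain = scaled - base)
  out[order(out$timepoint), ]
}

#' Exponential firing-rate fit for one window
#'
#' Minimal kinetic summary of a decay curve: assuming first-order loss
#' with R(0) = 1 enforced (no intercept), the least-squares rate is the
#' closed form `lambda = -sum(t * ln R) / sum(t^2)` over post-G1
#' timepoints with defined positive R. Timepoints with R = 0 are dropped
#' with a warning.
#'
#' @param table a `decay_table`.
#' @param window window name to fit.
#' @return list of class `firing_estimate`: `window`, `lambda` (per
#'   minute), `residual` (RMS of ln R + lambda t), `timepoints_used`.
#' @export
fit_firing_rate <- function(table, window) {
  sub <- table[table$window == window & table$timepoint > 0 &
                 !is.na(table$retained), ]
  zero <- sub$retained <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " timepoint(s) with zero retained signal")
    sub <- sub[!zero, ]
  }
  if (nrow(sub) < 2)
    stop("need >= 2 post-G1 timepoints with positive retained fraction")
  t <- sub$timepoint
  lr <- log(sub$retained)
  lambda <- max(0, -sum(t * lr) / sum(t^2))
  structure(list(window = window, lambda = lambda,
                 residual = sqrt(mean((lr + lambda * t)^2)),
                 timepoints_used = t),
            class = "firing_estimate")
}

#' @export
print.firing_estimate <- function(x, ...) {
  cat("firing_estimate:", x$window, "| lambda =", signif(x$lambda, 4),
      "/min | rms residual", signif(x$residual, 3), "\n")
  invisible(x)
}
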