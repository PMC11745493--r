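#' Genotype parameters for the locus simulator
#'
#' Encodes, as overridable defaults, how SIR2 and FUN30 status reshape the
#' rDNA origin: sir2 loss de-represses C-pro transcription, displacing most
#' loaded MCM double-hexamers ~150 bp rightward into a nucleosome-depleted
#' region where they fire readily, while suppressing weak early origins
#' elsewhere in the genome; fun30 loss raises +2/+3 nucleosome occupancy
#' next to the displaced site, slows displaced-MCM firing, and (via further
#' increased C-pro transcription) increases displacement.
#'
#' @param sir2_deleted,fun30_deleted logical genotype flags.
#' @param licensing_prob probability L that a repeat carries a loaded MCM
#'   double-hexamer in G1 (default 0.75, within the measured 60-85% range).
#' @param displaced_fraction fraction p_d of loaded MCMs at the displaced
#'   site (WT 0.10; sir2 0.70; fun30 adds +0.10).
#' @param rate_nondisplaced,rate_displaced per-minute firing rates in HU for
#'   the two rDNA MCM populations (defaults 0.002 and 0.02; the displaced
#'   rate is quartered when FUN30 is deleted).
#' @param occupancy length-3 vector of +1/+2/+3 nucleosome emission
#'   probabilities (defaults 0.9, 0.25, 0.35; +2/+3 doubled, capped at 1,
#'   when FUN30 is deleted).
#' @param rate_early,rate_late per-minute firing rates of genomic early and
#'   late origins in HU (defaults 0.02 and 5e-4; late origins are checkpoint
#'   silenced in HU).
#' @param weak_early_scale multiplier on the firing rate of the weak early
#'   subset (0.5 when SIR2 is deleted, else 1).
#' @param cpro_level per-copy C-pro transcription relative to WT (sir2 x20,
#'   fun30 x2, multiplicative).
#' @param physical_copies array size N carried by this strain.
#' @return list of class `genotype_params`.
#' @export
genotype_params <- function(sir2_deleted = FALSE, fun30_deleted = FALSE,
                            licensing_prob = 0.75,
                            displaced_fraction = NULL,
                            rate_nondisplaced = 0.002,
                            rate_displaced = NULL,
                            occupancy = NULL,
                            rate_early = 0.02, rate_late = 5e-4,
                            weak_early_scale = NULL,
                            cpro_level = NULL,
                            physical_copies = 150L) {
  if (is.null(displaced_fraction)) {
    displaced_fraction <- if (sir2_deleted) 0.70 else 0.10
    if (fun30_deleted) displaced_fraction <- displaced_fraction + 0.10
  }
  if (is.null(rate_displaced))
    rate_displaced <- 0.02 * if (fun30_deleted) 0.25 else 1
  if (is.null(occupancy)) {
    occupancy <- c(0.9, 0.25, 0.35)
    if (fun30_deleted) occupancy[2:3] <- pmin(1, occupancy[2:3] * 2)
  }
  if (is.null(weak_early_scale)) {
    # sir2 suppresses weak early origins via competition from the early-
    # firing rDNA; removing FUN30 as well damps rDNA firing and partially
    # restores them
    weak_early_scale <- if (sir2_deleted && fun30_deleted) 0.8
      else if (sir2_deleted) 0.5 else 1
  }
  if (is.null(cpro_level)) {
    cpro_level <- 1
    if (sir2_deleted) cpro_level <- cpro_level * 20
    if (fun30_deleted) cpro_level <- cpro_level * 2
  }
  p <- list(sir2_deleted = sir2_deleted, fun30_deleted = fun30_deleted,
            licensing_prob = licensing_prob,
            displaced_fraction = displaced_fraction,
            rate_nondisplaced = rate_nondisplaced,
            rate_displaced = rate_displaced,
            occupancy = occupancy,
            rate_early = rate_early, rate_late = rate_late,
            weak_early_scale = weak_early_scale,
            cpro_level = cpro_level,
            physical_copies = as.integer(physical_copies))
  probs <- c(p$licensing_prob, p$displaced_fraction, p$occupancy,
             p$weak_early_scale)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  rates <- c(p$rate_nondisplaced, p$rate_displaced, p$rate_early, p$rate_late)
  if (any(rates < 0)) stop("firing rates must be >= 0")
  structure(p, class = "genotype_params")
}

#' Genotype presets
#'
#' @param name one of `"wt"`, `"sir2"`, `"fun30"`, `"sir2fun30"`.
#' @param ... overrides forwarded to [genotype_params()].
#' @export
genotype_preset <- function(name, ...) {
  name <- match.arg(name, c("wt", "sir2", "fun30", "sir2fun30"))
  genotype_params(sir2_deleted = name %in% c("sir2", "sir2fun30"),
                  fun30_deleted = name %in% c("fun30", "sir2fun30"), ...)
}

#' Genotype label used in sample metadata
#' @param genotype a `genotype_params` object.
#' @export
genotype_label <- function(genotype) {
  lbl <- c(if (genotype$sir2_deleted) "sir2",
           if (genotype$fun30_deleted) "fun30")
  if (length(lbl) == 0) "wt" else paste(lbl, collapse = " ")
}

#' Simulation specification
#'
#' Bundles the genome model, genotype, library size, seed, and the fragment
#' geometry of the assays: MCM footprints are ~65 bp (sd 4, clipped to
#' 51-100 bp), nucleosome-protected fragments ~165 bp (sd 10, clipped to
#' 151-200 bp), footprint midpoints jitter with sd 3 bp, and 5% of fragments
#' are uniform background. The HU time course defaults to G1 (0) plus 15,
#' 30, 45, 60 and 90 min; fork speed in 200 mM HU defaults to 50 bp/min
#' (a ~1 kb/min unperturbed fork slowed ~20-fold).
#'
#' @param model a `genome_model`.
#' @param genotype a `genotype_params`.
#' @param n_fragments fragments per simulated library (> 0).
#' @param seed integer master seed; each assay derives an independent
#'   substream from it.
#' @param timepoints minutes after release into HU; must be ascending and
#'   start at 0 (the G1 reference).
#' @param fork_speed replication fork speed in HU, bp/min.
#' @param footprint,nucleosomal length models `c(mean, sd, min, max)`.
#' @param midpoint_jitter_sd positional jitter of footprint midpoints, bp.
#' @param background_fraction fraction of uniform background fragments.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(model, genotype, n_fragments = 200000L,
                            seed = 1L,
                            timepoints = c(0, 15, 30, 45, 60, 90),
                            fork_speed = 50,
                            footprint = c(mean = 65, sd = 4, min = 51, max = 100),
                            nucleosomal = c(mean = 165, sd = 10, min = 151, max = 200),
                            midpoint_jitter_sd = 3,
                            background_fraction = 0.05) {
  if (n_fragments <= 0) stop("n_fragments must be > 0")
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly ascending and start at 0")
  structure(
    list(model = model, genotype = genotype,
         n_fragments = as.integer(n_fragments), seed = as.integer(seed),
         timepoints = timepoints, fork_speed = fork_speed,
         footprint = footprint, nucleosomal = nucleosomal,
         midpoint_jitter_sd = midpoint_jitter_sd,
         background_fraction = background_fraction),
    class = "simulation_spec")
}

# Derive a deterministic 31-bit sub-seed per assay stream.
assay_seed <- function(seed, stream) {
  offs <- c(sseq = 101L, chec = 202L, mnase = 303L, edu = 404L,
            bands = 505L)
  (as.integer(seed) * 1009L + offs[[stream]]) %% .Machine$integer.max
}
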