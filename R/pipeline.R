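#' Run configuration
#'
#' Normalizes and validates the configuration driving both simulation and
#' analysis, rejecting unknown keys. The rDNA replicated fraction used for
#' the S-seq simulation defaults per genotype to the value that anchors
#' the locus's relative timing (wt 0.35, fun30 0.365, sir2 0.815,
#' sir2 fun30 0.56 against a genome median of 0.5).
#'
#' @param config named list with any of: `genotype` (preset name), `seed`
#'   (non-negative integer), `n_fragments`, `physical_copies`, `outdir`,
#'   `timepoints`, `f_rdna`, `f_median`, `bin_size`, `min_g1_count`,
#'   `window_mcm`, `window_edu`, `harvest_minutes`.
#' @return validated config list with defaults filled in.
#' @export
run_config <- function(config = list()) {
  defaults <- list(genotype = "wt", seed = 1L, n_fragments = 200000L,
                   physical_copies = 150L, outdir = ".",
                   timepoints = c(0, 15, 30, 45, 60, 90),
                   f_rdna = NULL, f_median = 0.5, bin_size = 1000L,
                   min_g1_count = 20L, window_mcm = 200L,
                   window_edu = 5000L, harvest_minutes = 60)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  cfg$genotype <- match.arg(cfg$genotype, c("wt", "sir2", "fun30",
                                            "sir2fun30"))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed < 0 ||
      cfg$seed != round(cfg$seed))
    stop("seed must be a non-negative integer")
  if (is.null(cfg$f_rdna))
    cfg$f_rdna <- c(wt = 0.35, fun30 = 0.365, sir2 = 0.815,
                    sir2fun30 = 0.56)[[cfg$genotype]]
  cfg
}

config_spec <- function(cfg) {
  model <- default_genome_model(cfg$physical_copies)
  genotype <- genotype_preset(cfg$genotype,
                              physical_copies = cfg$physical_copies)
  simulation_spec(model, genotype, n_fragments = cfg$n_fragments,
                  seed = cfg$seed, timepoints = cfg$timepoints)
}

#' Simulate all assays for one configuration
#'
#' Writes BED libraries (with JSON sidecars) for the ChEC time course, the
#' G1/S sorted pair, an MNase library and an EdU library, a band-quant TSV
#' for the licensing assay, and a manifest recording the seed and
#' parameters. Re-running with the same config reproduces identical files.
#'
#' @param config a list accepted by [run_config()].
#' @return invisibly, the manifest list (with file paths).
#' @export
pipeline_simulate <- function(config = list()) {
  cfg <- run_config(config)
  spec <- config_spec(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(cfg$outdir, paste0(...))
  files <- character()
  chec <- simulate_chec_timecourse(spec)
  for (nm in names(chec)) {
    f <- path("chec_", cfg$genotype, "_", nm, ".bed")
    write_fragments(chec[[nm]], f)
    files <- c(files, f)
  }
  track <- replication_track(spec$model, cfg$bin_size, f_rdna = cfg$f_rdna,
                             f_median = cfg$f_median)
  ss <- simulate_sseq(spec, track)
  for (nm in names(ss)) {
    f <- path("sseq_", cfg$genotype, "_", nm, ".bed")
    write_fragments(ss[[nm]], f)
    files <- c(files, f)
  }
  f <- path("mnase_", cfg$genotype, ".bed")
  write_fragments(simulate_mnase(spec), f); files <- c(files, f)
  f <- path("edu_", cfg$genotype, ".bed")
  write_fragments(simulate_edu(spec, cfg$harvest_minutes), f)
  files <- c(files, f)
  f <- path("bands_", cfg$genotype, ".tsv")
  write_band_quant(simulate_licensing_assay(spec), f); files <- c(files, f)
  manifest <- list(config = cfg[order(names(cfg))], files = files)
  jsonlite::write_json(manifest, path("manifest_", cfg$genotype, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

read_stage_lib <- function(cfg, stem) {
  f <- file.path(cfg$outdir, stem)
  if (!file.exists(f)) stop("missing input file: ", f)
  read_fragments(f)
}

#' Analyze simulated (or imported) libraries for one configuration
#'
#' Runs one analysis stage against the files written by
#' [pipeline_simulate()] in `config$outdir` and writes TSV reports plus a
#' JSON summary of the headline numbers.
#'
#' @param config a list accepted by [run_config()].
#' @param stage one of `"timing"`, `"firing"`, `"edu"`, `"occupancy"`,
#'   `"quant"`.
#' @return invisibly, the summary list written to JSON.
#' @export
pipeline_analyze <- function(config = list(),
                             stage = c("timing", "firing", "edu",
                                       "occupancy", "quant")) {
  stage <- match.arg(stage)
  cfg <- run_config(config)
  spec <- config_spec(cfg)
  model <- spec$model
  path <- function(...) file.path(cfg$outdir, paste0(...))
  g <- cfg$genotype
  summary <- switch(stage,
    timing = {
      g1 <- read_stage_lib(cfg, paste0("sseq_", g, "_g1.bed"))
      s <- read_stage_lib(cfg, paste0("sseq_", g, "_s.bed"))
      prof <- trel_profile(g1, s, model, cfg$bin_size, cfg$min_g1_count)
      write_trel_bedgraph(prof, path("trel_", g, ".bedgraph"))
      frac <- rdna_g1_fraction(g1, model)
      list(stage = "timing", genotype = g,
           rdna_trel = rdna_trel(prof, model),
           rdna_g1_fraction = frac,
           copy_estimate = copies_from_fraction(frac, model))
    },
    firing = {
      libs <- lapply(spec$timepoints, function(t)
        read_stage_lib(cfg, paste0("chec_", g, "_t", t, ".bed")))
      wins <- rdna_mcm_windows(model, cfg$window_mcm)
      tab <- decay_table(libs, wins)
      data.table::fwrite(tab, path("decay_", g, ".tsv"), sep = "\t")
      fits <- lapply(c("nondisplaced", "displaced"), function(w)
        fit_firing_rate(tab, w))
      rfb <- rfb_accumulation(libs, model)
      data.table::fwrite(rfb, path("rfb_", g, ".tsv"), sep = "\t")
      list(stage = "firing", genotype = g,
           lambda_nondisplaced = fits[[1]]$lambda,
           lambda_displaced = fits[[2]]$lambda,
           rfb_gain_final = rfb$gain[nrow(rfb)])
    },
    edu = {
      lib <- read_stage_lib(cfg, paste0("edu_", g, ".bed"))
      cat_ <- rbind(model$origins, rdna_origin(model))
      tab <- origin_activity(stats::setNames(list(lib), g), cat_, model,
                             cfg$window_edu)
      data.table::fwrite(tab, path("edu_activity_", g, ".tsv"), sep = "\t")
      list(stage = "edu", genotype = g,
           median_log10_early = median_log10(tab, "early", g),
           median_log10_late = median_log10(tab, "late", g))
    },
    occupancy = {
      lib <- read_stage_lib(cfg, paste0("mnase_", g, ".bed"))
      prof <- repeat_class_profile(lib, model, c(151L, 200L))
      occ <- nucleosome_occupancy(prof, model)
      list(stage = "occupancy", genotype = g,
           plus2_over_plus1 = occ[["plus2"]],
           plus3_over_plus1 = occ[["plus3"]])
    },
    quant = {
      b <- read_band_quant(file.path(cfg$outdir,
                                     paste0("bands_", g, ".tsv")))
      list(stage = "quant", genotype = g,
           licensed_fraction = as.numeric(licensed_fraction(b)))
    })
  jsonlite::write_json(summary, path("summary_", stage, "_", g, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
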