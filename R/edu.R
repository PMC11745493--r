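#' The rDNA origin as a catalog entry
#'
#' A catalog row for the rARS (first collapsed copy), so that rDNA EdU
#' signal can be quantified alongside the genomic origins.
#'
#' @param model a `genome_model`.
#' @export
rdna_origin <- function(model) {
  r <- model$rdna
  data.frame(name = "rARS", chrom = r$chrom,
             pos = r$collapsed_start + r$offsets$acs, class = "rdna",
             weak = FALSE, stringsAsFactors = FALSE)
}

#' Origin activity from EdU-seq libraries
#'
#' Applies max-total depth normalization across the libraries, then sums
#' scaled fragment-midpoint counts over a window (default 5 kb) centered
#' on each origin's MCM binding site. One row per origin per library;
#' origins with zero signal get an undefined log10 and are flagged.
#'
#' @param libs named list of `fragment_library` objects (names become the
#'   genotype labels; unnamed lists use each library's own label).
#' @param catalog origin catalog (`name`, `chrom`, `pos`, `class`, `weak`).
#' @param model a `genome_model` for window clipping.
#' @param window window width in bp (default 5000).
#' @return data.frame of class `origin_activity_table`: `origin`, `class`,
#'   `weak`, `genotype`, `signal` (scaled window sum), `log10_signal`.
#' @export
origin_activity <- function(libs, catalog, model, window = 5000L) {
  if (length(libs) == 0) stop("need at least one library")
  if (is.null(names(libs)) || any(names(libs) == ""))
    names(libs) <- vapply(libs, function(l) l$genotype, character(1))
  factors <- scale_to_max_total(libs)
  win <- origin_windows(catalog, window, model)
  rows <- lapply(names(libs), function(g) {
    s <- as.numeric(window_signal(libs[[g]], win)) * factors[[g]]
    data.frame(origin = win$name, class = catalog$class, weak = catalog$weak,
               genotype = g, signal = s,
               log10_signal = ifelse(s > 0, log10(s), NA_real_),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("origin_activity_table", "data.frame"))
}

#' Median log10 origin activity for a class and genotype
#'
#' @param table an `origin_activity_table`.
#' @param class origin class: `"early"`, `"late"`, `"weak_early"` (the
#'   weak subset of the early origins), `"rdna"`, or `NULL` for all.
#' @param genotype genotype label to select.
#' @export
median_log10 <- function(table, class = "early", genotype) {
  sub <- table[table$genotype == genotype, ]
  if (!is.null(class)) {
    keep <- switch(class,
      early = sub$class == "early",
      late = sub$class == "late",
      weak_early = sub$class == "early" & sub$weak,
      rdna = sub$class == "rdna",
      stop("unknown origin class '", class, "'"))
    sub <- sub[keep, ]
  }
  vals <- sub$log10_signal[!is.na(sub$log10_signal)]
  if (length(vals) == 0) stop("no origin with positive signal in selection")
  stats::median(vals)
}

#' Compare genotype-induced drops in origin activity
#'
#' Per matched origin, the drop from the reference genotype to each mutant
#' is `d = log10(ref) - log10(mut)`; the two per-origin drop vectors are
#' compared with a two-tailed Student t-test (unpaired pooled-variance by
#' default; `paired = TRUE` pairs origins). Origins with zero signal in
#' any involved library are excluded pairwise, with the exclusion count
#' reported.
#'
#' @param table an `origin_activity_table` containing all three genotypes.
#' @param ref,mut_a,mut_b genotype labels.
#' @param class origin class to compare (default `"early"`).
#' @param paired pair drop vectors by origin (default FALSE).
#' @param var_equal pooled variance (default TRUE).
#' @return list `t`, `p`, `mean_drop_a`, `mean_drop_b`, `n`, `n_excluded`.
#' @export
compare_drops <- function(table, ref, mut_a, mut_b, class = "early",
                          paired = FALSE, var_equal = TRUE) {
  pick <- function(g) {
    sub <- table[table$genotype == g, ]
    if (!is.null(class)) {
      keep <- switch(class,
        early = sub$class == "early",
        late = sub$class == "late",
        weak_early = sub$class == "early" & sub$weak,
        rdna = sub$class == "rdna",
        stop("unknown origin class '", class, "'"))
      sub <- sub[keep, ]
    }
    stats::setNames(sub$log10_signal, sub$origin)
  }
  r <- pick(ref); a <- pick(mut_a); b <- pick(mut_b)
  common <- Reduce(intersect, list(names(r), names(a), names(b)))
  if (length(common) == 0) stop("no matched origins across genotypes")
  r <- r[common]; a <- a[common]; b <- b[common]
  ok <- !is.na(r) & !is.na(a) & !is.na(b)
  da <- (r - a)[ok]
  db <- (r - b)[ok]
  if (sum(ok) < 2) stop("fewer than 2 usable matched origins")
  if (stats::sd(da - db) == 0 && paired) {
    tt <- list(statistic = 0, p.value = 1)
  } else if (stats::sd(c(da, db)) == 0) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(da, db, paired = paired, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_drop_a = mean(da), mean_drop_b = mean(db),
       n = sum(ok), n_excluded = sum(!ok))
}
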