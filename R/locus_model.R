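#' Genome model with a collapsed rDNA repeat array
#'
#' Constructs the data model every analysis stage consumes: an ordered set of
#' chromosomes, an annotated repeat array, and an origin catalog. Reads from a
#' tandem array map onto a small number of collapsed reference repeats, so the
#' true array size (`physical_copies`, N) manifests only as read depth over
#' the collapsed interval. All coordinates are 0-based half-open internally.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param rdna repeat-array annotation as built by [rdna_annotation()].
#' @param origins optional origin catalog (see [default_origin_catalog()]).
#' @return An object of class `genome_model` with elements `chromosomes`,
#'   `rdna`, `origins` and `unique_length` (total non-rDNA sequence, bp).
#' @seealso [default_genome_model()] for the standard configuration.
#' @export
genome_model <- function(chromosomes, rdna, origins = NULL) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name) > 0L)
    stop("chromosome names must be unique")
  if (any(chromosomes$length <= 0))
    stop("all chromosome lengths must be > 0")
  if (!rdna$chrom %in% chromosomes$name)
    stop("rDNA chromosome '", rdna$chrom, "' not in chromosome list")
  chrom_len <- chromosomes$length[match(rdna$chrom, chromosomes$name)]
  array_len <- rdna$collapsed_copies * rdna$repeat_length
  if (rdna$collapsed_start < 0 || rdna$collapsed_start + array_len > chrom_len)
    stop("collapsed rDNA interval exceeds chromosome bounds")
  tr <- rdna$timing_region
  if (tr[1] < rdna$collapsed_start || tr[2] > rdna$collapsed_start + array_len)
    stop("timing_region must lie within the collapsed array interval")
  unique_length <- sum(chromosomes$length) - array_len
  m <- structure(
    list(chromosomes = chromosomes, rdna = rdna, origins = origins,
         unique_length = unique_length),
    class = "genome_model")
  m
}

#' Repeat-array annotation
#'
#' Describes the collapsed rDNA array: where it sits on its chromosome, the
#' repeat length, how many repeats the mapping reference carries
#' (`collapsed_copies`) versus how many exist physically (`physical_copies`),
#' and the within-repeat offsets of the functional elements (ACS, the
#' nondisplaced and displaced MCM positions, the +1/+2/+3 nucleosome dyads,
#' the C-pro start, and the replication fork barrier).
#'
#' @param chrom chromosome carrying the array.
#' @param collapsed_start 0-based start of the collapsed interval.
#' @param repeat_length repeat unit length in bp.
#' @param collapsed_copies repeats present in the mapping reference.
#' @param physical_copies true array size N (>= 0).
#' @param offsets named list of within-repeat offsets, each in
#'   `[0, repeat_length)`: `acs`, `mcm_nondisplaced`, `mcm_displaced`,
#'   `nucleosome_dyads` (length-3 vector for +1/+2/+3), `cpro_start`, `rfb`.
#' @param timing_region length-2 vector, the interval (on the array
#'   chromosome) used for rDNA-level reporting.
#' @export
rdna_annotation <- function(chrom, collapsed_start, repeat_length = 9100L,
                            collapsed_copies = 2L, physical_copies = 150L,
                            offsets, timing_region) {
  off <- unlist(offsets, use.names = FALSE)
  if (any(off < 0) || any(off >= repeat_length))
    stop("every offset must satisfy 0 <= offset < repeat_length")
  if (offsets$mcm_displaced <= offsets$mcm_nondisplaced)
    stop("mcm_displaced must lie to the right of mcm_nondisplaced")
  if (physical_copies < 0)
    stop("physical_copies must be >= 0")
  if (collapsed_copies < 1)
    stop("collapsed_copies must be >= 1")
  structure(
    list(chrom = chrom, collapsed_start = as.integer(collapsed_start),
         repeat_length = as.integer(repeat_length),
         collapsed_copies = as.integer(collapsed_copies),
         physical_copies = as.integer(physical_copies),
         offsets = offsets, timing_region = as.integer(timing_region)),
    class = "rdna_annotation")
}

#' Default genome model
#'
#' One 12.1 Mb chromosome of unique sequence (`chrU`) plus an array
#' chromosome (`chrXII`) that consists of exactly two collapsed 9.1 kb
#' repeats. The within-repeat layout places the ACS at 2000 bp, the
#' nondisplaced MCM site 150 bp to its left (1850), the displaced MCM site at
#' the ACS (2000, i.e. 150 bp right of the loading site), the C-pro start
#' 200 bp left of the ACS, the RFB 1.5 kb right of the loading site, the +1
#' dyad 90 bp left of the nondisplaced MCM, and the +2/+3 dyads at 165 bp
#' spacing right of the displaced site. With N physical copies the expected
#' rDNA share of G1 reads is N*9100 / (N*9100 + 12.1e6), about 10% at N = 150.
#'
#' @param physical_copies true array size N (default 150).
#' @param with_origins attach the default origin catalog (default TRUE).
#' @return A `genome_model`.
#' @examples
#' m <- default_genome_model(150)
#' expected_rdna_fraction(m)   # ~0.101
#' @export
default_genome_model <- function(physical_copies = 150L, with_origins = TRUE) {
  if (physical_copies < 0) stop("physical_copies must be >= 0")
  repeat_length <- 9100L
  offsets <- list(
    acs = 2000L,
    mcm_nondisplaced = 1850L,
    mcm_displaced = 2000L,            # 150 bp right of the loading site
    nucleosome_dyads = c(1760L, 2165L, 2330L),  # +1, +2, +3
    cpro_start = 1800L,               # ~200 bp from the rARS
    rfb = 3350L)                      # ~1.5 kb from the MCM sites
  rdna <- rdna_annotation(
    chrom = "chrXII", collapsed_start = 0L, repeat_length = repeat_length,
    collapsed_copies = 2L, physical_copies = physical_copies,
    offsets = offsets, timing_region = c(0L, 2L * repeat_length))
  chroms <- data.frame(
    name = c("chrU", "chrXII"),
    length = c(12100000L, 2L * repeat_length),
    stringsAsFactors = FALSE)
  m <- genome_model(chroms, rdna)
  if (with_origins) m$origins <- default_origin_catalog(m)
  m
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp total\n")
  cat("  rDNA:", x$rdna$collapsed_copies, "collapsed x",
      x$rdna$repeat_length, "bp on", x$rdna$chrom,
      "| physical copies N =", x$rdna$physical_copies, "\n")
  cat("  unique length U =", format(x$unique_length, big.mark = ","), "bp\n")
  if (!is.null(x$origins))
    cat("  origins:", nrow(x$origins), "(",
        sum(x$origins$class == "early"), "early /",
        sum(x$origins$class == "late"), "late )\n")
  invisible(x)
}

#' Expected rDNA G1 read fraction
#'
#' Closed form N*l / (N*l + U) for a model with N physical repeats of length
#' l and U bp of unique sequence: the probability that a uniformly sampled
#' genomic fragment originates from the array.
#'
#' @param model a `genome_model`.
#' @export
expected_rdna_fraction <- function(model) {
  n <- model$rdna$physical_copies
  l <- model$rdna$repeat_length
  (n * l) / (n * l + model$unique_length)
}

#' Map a repeat-relative offset to genome coordinates
#'
#' @param model a `genome_model`.
#' @param repeat_index collapsed repeat index, `0 <= i < collapsed_copies`.
#' @param offset within-repeat offset, `0 <= offset < repeat_length`.
#' @return list with `chrom` and `position` (0-based).
#' @export
repeat_to_genome <- function(model, repeat_index, offset) {
  r <- model$rdna
  if (any(repeat_index < 0) || any(repeat_index >= r$collapsed_copies))
    stop("repeat_index out of range [0, ", r$collapsed_copies, ")")
  if (any(offset < 0) || any(offset >= r$repeat_length))
    stop("offset out of range [0, ", r$repeat_length, ")")
  list(chrom = r$chrom,
       position = r$collapsed_start + repeat_index * r$repeat_length + offset)
}

#' Genome coordinates of annotated repeat features
#'
#' Expands the within-repeat offsets to every collapsed repeat copy.
#'
#' @param model a `genome_model`.
#' @return data.frame with columns `feature`, `copy`, `chrom`, `pos`.
#' @export
feature_positions <- function(model) {
  r <- model$rdna
  feats <- c(acs = r$offsets$acs,
             mcm_nondisplaced = r$offsets$mcm_nondisplaced,
             mcm_displaced = r$offsets$mcm_displaced,
             nuc_plus1 = r$offsets$nucleosome_dyads[1],
             nuc_plus2 = r$offsets$nucleosome_dyads[2],
             nuc_plus3 = r$offsets$nucleosome_dyads[3],
             cpro_start = r$offsets$cpro_start,
             rfb = r$offsets$rfb)
  copies <- seq_len(r$collapsed_copies) - 1L
  out <- expand.grid(feature = names(feats), copy = copies,
                     stringsAsFactors = FALSE)
  out$chrom <- r$chrom
  out$pos <- r$collapsed_start + out$copy * r$repeat_length +
    feats[out$feature]
  out
}

#' Collapsed rDNA interval
#'
#' @param model a `genome_model`.
#' @return length-2 vector `c(start, end)` (0-based half-open) on the array
#'   chromosome.
#' @export
rdna_interval <- function(model) {
  r <- model$rdna
  c(r$collapsed_start,
    r$collapsed_start + r$collapsed_copies * r$repeat_length)
}

#' Default origin catalog
#'
#' 111 early and 101 late origins placed at regular spacing along the unique
#' chromosome, alternating early/late with the surplus early origins at the
#' end. A deterministic subset of 28 early origins (every fourth) is marked
#' `weak = TRUE`: these are the weak early origins whose firing is most
#' sensitive to genome-wide competition for initiation factors.
#'
#' @param model a `genome_model`.
#' @param n_early,n_late class sizes (defaults 111 and 101).
#' @param n_weak number of early origins flagged weak (default 28).
#' @return data.frame with columns `name`, `chrom`, `pos`, `class`, `weak`.
#' @export
default_origin_catalog <- function(model, n_early = 111L, n_late = 101L,
                                   n_weak = 28L) {
  n <- n_early + n_late
  chrom <- model$chromosomes$name[1]
  len <- model$chromosomes$length[1]
  pos <- round(seq_len(n) * (as.numeric(len) / (n + 1)))
  npair <- min(n_early, n_late)
  class <- c(rep(c("early", "late"), npair),
             rep("early", n_early - npair), rep("late", n_late - npair))
  weak <- logical(n)
  early_idx <- which(class == "early")
  weak[early_idx[seq_len(n_weak) * 4L - 3L]] <- TRUE
  data.frame(name = sprintf("ARS_%04d", seq_len(n)), chrom = chrom,
             pos = pos, class = class, weak = weak, stringsAsFactors = FALSE)
}

#' Select origins by class
#'
#' `class = "weak_early"` selects the weak subset of the early origins;
#' `"early"` selects all 111 early origins including the weak ones.
#'
#' @param catalog an origin catalog.
#' @param class one of `"early"`, `"late"`, `"weak_early"`, or `NULL` (all).
#' @export
origins_of_class <- function(catalog, class = NULL) {
  if (is.null(class)) return(catalog)
  keep <- switch(class,
    early = catalog$class == "early",
    late = catalog$class == "late",
    weak_early = catalog$class == "early" & catalog$weak,
    stop("unknown origin class '", class, "'"))
  catalog[keep, , drop = FALSE]
}

#' Windows centered on origins
#'
#' Half-open intervals `[pos - width/2, pos + width/2)` around each origin,
#' clipped to chromosome bounds.
#'
#' @param catalog origin catalog (`name`, `chrom`, `pos` columns).
#' @param width window width in bp; must be even and >= 2.
#' @param model `genome_model` supplying chromosome bounds for clipping.
#' @return data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
origin_windows <- function(catalog, width, model) {
  if (width < 2 || width %% 2 != 0)
    stop("width must be even and >= 2")
  half <- width %/% 2
  len <- model$chromosomes$length[match(catalog$chrom, model$chromosomes$name)]
  if (anyNA(len)) stop("catalog contains chromosomes absent from the model")
  data.frame(name = catalog$name, chrom = catalog$chrom,
             start = pmax(0, catalog$pos - half),
             end = pmin(len, catalog$pos + half),
             stringsAsFactors = FALSE)
}

#' Quantification windows at the rDNA MCM sites
#'
#' One window per MCM position (nondisplaced and displaced), replicated over
#' every collapsed repeat copy under a shared name so that counts from all
#' copies aggregate.
#'
#' @param model a `genome_model`.
#' @param width window width in bp (default 200, even).
#' @export
rdna_mcm_windows <- function(model, width = 200L) {
  if (width < 2 || width %% 2 != 0) stop("width must be even and >= 2")
  fp <- feature_positions(model)
  fp <- fp[fp$feature %in% c("mcm_nondisplaced", "mcm_displaced"), ]
  half <- width %/% 2
  len <- model$chromosomes$length[match(fp$chrom, model$chromosomes$name)]
  data.frame(name = sub("^mcm_", "", fp$feature), chrom = fp$chrom,
             start = pmax(0, fp$pos - half), end = pmin(len, fp$pos + half),
             stringsAsFactors = FALSE)
}

#' Windows immediately left of the replication fork barrier
#'
#' `[rfb - width, rfb)` in every collapsed repeat copy, under the shared
#' name `"rfb"`.
#'
#' @param model a `genome_model`.
#' @param width window width in bp (default 300).
#' @export
rfb_windows <- function(model, width = 300L) {
  fp <- feature_positions(model)
  fp <- fp[fp$feature == "rfb", ]
  data.frame(name = "rfb", chrom = fp$chrom,
             start = pmax(0, fp$pos - width), end = fp$pos,
             stringsAsFactors = FALSE)
}
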