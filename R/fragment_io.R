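#' Fragment library
#'
#' A sequenced sample: fragment intervals (BED-style, 0-based half-open)
#' plus assay/genotype/timepoint metadata. The positional unit used
#' throughout the package is the fragment midpoint, `floor((start+end)/2)`;
#' a fragment belongs to a window iff its midpoint lies in the half-open
#' window.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`.
#' @param assay one of `"chec"`, `"mnase"`, `"sseq_g1"`, `"sseq_s"`, `"edu"`.
#' @param genotype free-text genotype label.
#' @param timepoint minutes after HU release, or `NA` for assays without a
#'   time dimension; 0 denotes the G1 reference.
#' @return object of class `fragment_library`.
#' @export
fragment_library <- function(fragments, assay, genotype = "wt",
                             timepoint = NA_real_) {
  assay <- match.arg(assay, c("chec", "mnase", "sseq_g1", "sseq_s", "edu"))
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments) > 0 && any(fragments$end <= fragments$start))
    stop("all fragments must satisfy start < end")
  structure(
    list(fragments = as.data.frame(fragments)[c("chrom", "start", "end")],
         assay = assay, genotype = genotype, timepoint = timepoint),
    class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("fragment_library:", nrow(x$fragments), "fragments |", x$assay,
      "|", x$genotype,
      if (!is.na(x$timepoint)) paste0("| t=", x$timepoint, "m"), "\n")
  invisible(x)
}

#' Number of fragments in a library
#' @param lib a `fragment_library`.
#' @export
library_size <- function(lib) nrow(lib$fragments)

#' Fragment midpoints
#'
#' Midpoint of each fragment, `floor((start + end)/2)` (even-length
#' fragments round down).
#'
#' @param lib a `fragment_library`.
#' @export
midpoints <- function(lib) {
  (lib$fragments$start + lib$fragments$end) %/% 2
}

#' Fragment lengths
#' @param lib a `fragment_library`.
#' @export
fragment_lengths <- function(lib) lib$fragments$end - lib$fragments$start

#' Write / read a fragment library
#'
#' Libraries are stored as headerless 3-column BED (`chrom`, `start`,
#' `end`, tab-separated) with a JSON sidecar `<path>.json` holding the
#' sample metadata. Writing then reading reproduces fragments and metadata
#' exactly.
#'
#' @param lib a `fragment_library`.
#' @param path BED file path; the sidecar is written next to it.
#' @return `write_fragments` returns `path` invisibly.
#' @export
write_fragments <- function(lib, path) {
  data.table::fwrite(lib$fragments, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  meta <- list(assay = lib$assay, genotype = lib$genotype,
               timepoint = lib$timepoint)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fragments
#' @param metadata optional list with `assay`, `genotype`, `timepoint`;
#'   overrides (or substitutes for) the sidecar.
#' @param model optional `genome_model`; if supplied, fragments outside
#'   chromosome bounds raise a validation error listing offenders.
#' @export
read_fragments <- function(path, metadata = NULL, model = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  fr <- if (file.size(path) == 0) data.frame() else tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1),
                      data.table = FALSE),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e)))
  if (nrow(fr) == 0) {
    fr <- data.frame(chrom = character(), start = integer(),
                     end = integer())
  } else {
    if (ncol(fr) < 3)
      stop("malformed BED file '", path, "': fewer than 3 columns")
    fr <- fr[, 1:3]
    names(fr) <- c("chrom", "start", "end")
    bad <- which(!is.finite(fr$start) | !is.finite(fr$end) |
                   fr$end <= fr$start)
    if (length(bad) > 0)
      stop("malformed interval(s) at line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  }
  if (is.null(metadata)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("no metadata: sidecar ", side, " missing and none supplied")
    metadata <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  if (!is.null(model)) {
    len <- model$chromosomes$length[match(fr$chrom, model$chromosomes$name)]
    bad <- which(is.na(len) | fr$start < 0 | fr$end > len)
    if (length(bad) > 0)
      stop("fragment(s) outside model bounds at line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  tp <- metadata$timepoint
  fragment_library(fr, assay = metadata$assay, genotype = metadata$genotype,
                   timepoint = if (is.null(tp)) NA_real_ else as.numeric(tp))
}

#' Binned midpoint coverage track
#'
#' Counts fragment midpoints per fixed-width bin, restricted to a fragment
#' length class. Bins are `[i*bin, (i+1)*bin)` per chromosome.
#'
#' @param lib a `fragment_library`.
#' @param size_class length-2 vector `c(min, max)` of fragment lengths to
#'   keep (inclusive); `NULL` keeps all.
#' @param bin bin width in bp (default 1).
#' @param model optional `genome_model` fixing chromosome extents (so empty
#'   trailing bins are present); otherwise extents come from the data.
#' @return data.frame `chrom`, `start`, `end`, `count` (a bedGraph-ready
#'   track, zero bins included).
#' @export
midpoint_track <- function(lib, size_class = NULL, bin = 1L, model = NULL) {
  if (!is.null(size_class) && size_class[1] > size_class[2])
    stop("inverted size class: min > max")
  mid <- midpoints(lib)
  chrom <- lib$fragments$chrom
  if (!is.null(size_class)) {
    len <- fragment_lengths(lib)
    keep <- len >= size_class[1] & len <= size_class[2]
    mid <- mid[keep]; chrom <- chrom[keep]
  }
  chroms <- if (!is.null(model)) model$chromosomes$name else
    sort(unique(lib$fragments$chrom))
  out <- lapply(chroms, function(cn) {
    m <- mid[chrom == cn]
    extent <- if (!is.null(model))
      model$chromosomes$length[match(cn, model$chromosomes$name)]
    else if (length(m) > 0) max(m) + 1 else 0
    nb <- ceiling(extent / bin)
    if (nb == 0) return(NULL)
    cnt <- tabulate(m %/% bin + 1L, nbins = nb)
    data.frame(chrom = cn, start = (seq_len(nb) - 1L) * bin,
               end = pmin(seq_len(nb) * bin, extent), count = cnt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Max-total scale factors across libraries
#'
#' Cross-sample depth normalization: every library is scaled up to the
#' deepest one, `factor_i = max_j(total_j) / total_i`, so multiplying each
#' library's counts by its factor equalizes totals and the deepest library
#' keeps factor 1.
#'
#' @param libs list of `fragment_library` objects (each non-empty).
#' @return numeric vector of scale factors, same order (and names) as
#'   `libs`.
#' @export
scale_to_max_total <- function(libs) {
  if (length(libs) < 1) stop("need at least one library")
  totals <- vapply(libs, library_size, numeric(1))
  if (any(totals == 0)) stop("empty library cannot be depth-normalized")
  stats::setNames(max(totals) / totals, names(libs))
}

#' Write a track as bedGraph
#'
#' @param track data.frame with `chrom`, `start`, `end` and a value column.
#' @param path output path.
#' @param value name of the value column (default `"count"`).
#' @param drop_zero omit zero-valued bins (default TRUE).
#' @export
write_bedgraph <- function(track, path, value = "count", drop_zero = TRUE) {
  out <- track[, c("chrom", "start", "end", value)]
  if (drop_zero) out <- out[out[[value]] != 0, ]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
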