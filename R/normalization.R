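#' rRNA-based library normalization factor
#'
#' Counts pairs whose read1 overlaps any rRNA interval by at least 1 nt
#' (strand-aware: antisense reads do not count) and divides by an
#' arbitrary constant (default 30,000) to obtain the library's rRNA
#' factor. Libraries with more rRNA recovery get a larger factor and are
#' scaled down by [scale_track()], equalizing recovery across timepoints.
#'
#' @param pairs deduplicated `aligned_pairs`.
#' @param rrna data.frame of rRNA intervals: `chrom`, `start`, `end`,
#'   `strand` (e.g. `annotation$rrna`).
#' @param divisor positive constant, default 30000.
#' @return list of class `normalization_factor` with `rrna_read_count`,
#'   `divisor`, `factor`.
#' @export
rrna_factor <- function(pairs, rrna, divisor = 30000L) {
  if (divisor <= 0) stop("divisor must be positive")
  count <- 0L
  if (nrow(pairs) && nrow(rrna)) {
    reads <- GenomicRanges::GRanges(
      pairs$chrom,
      IRanges::IRanges(.first_int(pairs$r1_starts) + 1L,
                       .last_int(pairs$r1_ends)),
      strand = pairs$strand)
    ref <- GenomicRanges::GRanges(
      rrna$chrom, IRanges::IRanges(rrna$start + 1L, rrna$end),
      strand = rrna$strand)
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(reads, ref, ignore.strand = FALSE))
    count <- length(unique(S4Vectors::queryHits(hits)))
  }
  if (count == 0L) {
    stop("no reads map to rRNA annotations; library cannot be normalized")
  }
  structure(list(rrna_read_count = count, divisor = divisor,
                 factor = count / divisor),
            class = "normalization_factor")
}

#' @export
print.normalization_factor <- function(x, ...) {
  cat("<normalization_factor> rRNA reads = ", x$rrna_read_count,
      ", divisor = ", x$divisor, ", factor = ", format(x$factor), "\n",
      sep = "")
  invisible(x)
}

#' Scale a site track by a normalization factor
#'
#' Every weight is divided by the factor (the default direction:
#' libraries with more rRNA are scaled down), so the scaled total equals
#' the raw total divided by the factor. `direction = "multiply"` applies
#' the reciprocal convention.
#'
#' @param track a `site_track`.
#' @param nf a `normalization_factor` or a bare positive number.
#' @param direction `"divide"` (default) or `"multiply"`.
#' @return the scaled `site_track`.
#' @export
scale_track <- function(track, nf, direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  f <- if (inherits(nf, "normalization_factor")) nf$factor else as.numeric(nf)
  if (!is.finite(f) || f <= 0) stop("scale factor must be positive")
  track$weight <- if (direction == "divide") track$weight / f
                  else track$weight * f
  track
}

#' Normalize per-TU values by gene expression
#'
#' Divides each TU's value by its expression; TUs missing from either
#' mapping, or with non-positive expression, are skipped with a warning.
#'
#' @param per_tu_values named numeric vector `TU -> value`.
#' @param expression named numeric vector `TU -> expression`, positive.
#' @return named numeric vector of normalized values for the retained TUs.
#' @export
expression_normalize <- function(per_tu_values, expression) {
  common <- intersect(names(per_tu_values), names(expression))
  n_miss <- length(per_tu_values) - length(common)
  if (n_miss > 0L) warning(n_miss, " TU(s) missing from expression table")
  expr <- expression[common]
  bad <- !is.finite(expr) | expr <= 0
  if (any(bad)) {
    warning(sum(bad), " TU(s) with non-positive expression skipped")
    common <- common[!bad]
    expr <- expr[!bad]
  }
  per_tu_values[common] / expr
}

#' Region binding density in reads per kilobase
#'
#' For each region group, the summed track weight over the group's
#' intervals divided by the group's total length in kb. Invariant under
#' region subdivision.
#'
#' @param track a `site_track`.
#' @param regions data.frame: `group`, `chrom`, `strand`, `start`, `end`.
#' @return named numeric vector of reads/kb per group.
#' @export
region_density <- function(track, regions) {
  if (!nrow(regions)) stop("regions must be non-empty")
  groups <- unique(regions$group)
  kb <- vapply(groups, function(g) {
    sum(regions$end[regions$group == g] -
          regions$start[regions$group == g]) / 1000
  }, numeric(1))
  if (any(kb <= 0)) {
    stop("region group(s) with zero total length: ",
         paste(groups[kb <= 0], collapse = ", "))
  }
  if (!nrow(track)) return(stats::setNames(rep(0, length(groups)), groups))
  sites <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$pos + 1L, track$pos + 1L),
    strand = track$strand)
  ref <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end),
    strand = regions$strand)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sites, ref, ignore.strand = FALSE))
  w <- vapply(groups, function(g) {
    sel <- regions$group[S4Vectors::subjectHits(hits)] == g
    # a site inside two overlapping regions of one group counts once
    sum(track$weight[unique(S4Vectors::queryHits(hits)[sel])])
  }, numeric(1))
  stats::setNames(w / kb, groups)
}
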