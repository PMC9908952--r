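#' Per-position weighted site track
#'
#' The universal intermediate of the pipeline: a sparse map from
#' (chromosome, strand, position) to a non-negative weight. Before scaling,
#' the total weight equals the number of contributing reads; after scaling
#' it equals reads divided by the library's normalization factor.
#'
#' @param chrom,strand,pos site coordinates (0-based positions).
#' @param weight non-negative weights, recycled; duplicated sites are summed.
#' @param library_label,timepoint_label free-text labels carried as
#'   attributes.
#' @return a data.frame of class `site_track` with columns
#'   `chrom`, `strand`, `pos`, `weight`, sorted by (chrom, strand, pos).
#' @export
site_track <- function(chrom = character(0), strand = character(0),
                       pos = integer(0), weight = 1,
                       library_label = "", timepoint_label = "") {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  weight <- rep_len(as.numeric(weight), n)
  if (n) .check_strand(strand)
  if (any(weight < 0)) stop("site_track weights must be non-negative")
  df <- data.frame(chrom = chrom, strand = strand, pos = as.integer(pos),
                   weight = weight, stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$chrom, df$strand, df$pos, sep = "\r")
    if (anyDuplicated(key)) {
      w <- rowsum(df$weight, key, reorder = FALSE)
      keep <- !duplicated(key)
      df <- df[keep, , drop = FALSE]
      df$weight <- as.numeric(w[match(key[keep], rownames(w))])
    }
    df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("site_track", "data.frame"),
            library_label = library_label, timepoint_label = timepoint_label)
}

#' @rdname site_track
#' @param track a `site_track`.
#' @export
track_total <- function(track) sum(track$weight)

#' @export
print.site_track <- function(x, ...) {
  cat("<site_track> ", nrow(x), " sites, total weight ",
      format(sum(x$weight)), sep = "")
  lab <- attr(x, "library_label")
  if (nzchar(lab)) cat("  [", lab, "]", sep = "")
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# Named weight lookup used by all window extractions. Returns a function
# mapping (chrom, strand, pos) vectors to weights (0 where absent).
.track_lookup <- function(track) {
  key <- paste(track$chrom, track$strand, track$pos, sep = "\r")
  w <- track$weight
  names(w) <- key
  function(chrom, strand, pos) {
    out <- unname(w[paste(chrom, strand, pos, sep = "\r")])
    out[is.na(out)] <- 0
    out
  }
}

#' Write a site track as a pair of strand-specific bedGraph files
#'
#' Emits `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph` (4-column
#' bedGraph, 0-based half-open). Runs of adjacent positions carrying equal
#' weight are merged into single intervals; lines are sorted by
#' (chrom, start). Values are written with up to 6 significant digits since
#' scaled tracks are real-valued.
#'
#' @param track a `site_track`.
#' @param path_prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_bedgraph <- function(track, path_prefix) {
  paths <- c(`+` = paste0(path_prefix, ".plus.bedgraph"),
             `-` = paste0(path_prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    sub <- track[track$strand == s, , drop = FALSE]
    con <- file(paths[[s]], "w")
    if (nrow(sub)) {
      sub <- sub[order(sub$chrom, sub$pos), , drop = FALSE]
      new_run <- c(TRUE, sub$chrom[-1] != sub$chrom[-nrow(sub)] |
                     sub$pos[-1] != sub$pos[-nrow(sub)] + 1L |
                     sub$weight[-1] != sub$weight[-nrow(sub)])
      run <- cumsum(new_run)
      start <- sub$pos[new_run]
      end <- sub$pos[rev(!duplicated(rev(run)))] + 1L
      writeLines(paste(sub$chrom[new_run], start, end,
                       trimws(formatC(sub$weight[new_run], digits = 6,
                                      format = "g")), sep = "\t"), con)
    }
    close(con)
  }
  invisible(unname(paths))
}

#' Read a strand pair of bedGraph files back into a site track
#'
#' Inverse of [write_bedgraph()]: intervals are expanded back to
#' per-position weights.
#'
#' @param plus_path,minus_path the two bedGraph files (either may be absent
#'   or empty).
#' @param library_label,timepoint_label labels for the resulting track.
#' @return a `site_track`.
#' @export
read_bedgraph <- function(plus_path, minus_path,
                          library_label = "", timepoint_label = "") {
  read_one <- function(path, strand) {
    if (!file.exists(path) || file.size(path) == 0) {
      return(data.frame(chrom = character(0), strand = character(0),
                        pos = integer(0), weight = numeric(0)))
    }
    gr <- rtracklayer::import(path, format = "bedGraph")
    wid <- GenomicRanges::width(gr)
    data.frame(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), wid),
      strand = strand,
      pos = unlist(lapply(seq_along(gr), function(i) {
        seq.int(GenomicRanges::start(gr)[i] - 1L, length.out = wid[i])
      })) %||% integer(0),
      weight = rep(gr$score, wid),
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(read_one(plus_path, "+"), read_one(minus_path, "-"))
  site_track(df$chrom, df$strand, df$pos, df$weight,
             library_label = library_label,
             timepoint_label = timepoint_label)
}
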