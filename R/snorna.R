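# snoRNA anchor positions: offset 0 is the snoRNA's annotated last
# nucleotide (sno_3p_end) or the host intron's last nucleotide (host_3ss);
# +1 is the first downstream flank nucleotide.
.sno_anchors <- function(annotation, anchor = c("sno_3p_end", "host_3ss")) {
  anchor <- match.arg(anchor)
  sn <- annotation$snornas
  tus <- annotation$tus
  m <- match(sn$tu_id, tus$tu_id)
  plus <- tus$strand[m] == "+"
  pos <- if (anchor == "sno_3p_end") {
    ifelse(plus, sn$end - 1L, sn$start)
  } else {
    intr <- annotation$introns[match(sn$intron_id,
                                     annotation$introns$intron_id), ,
                               drop = FALSE]
    ifelse(plus, intr$end - 1L, intr$start)
  }
  data.frame(sno_id = sn$sno_id, sno_class = sn$sno_class,
             chrom = tus$chrom[m], strand = tus$strand[m], pos = pos,
             stringsAsFactors = FALSE)
}

#' Class-stratified windowed coverage around snoRNA 3' ends
#'
#' Aggregates a site track over a strand-oriented window centred on the
#' snoRNA 3' end (or the host intron's 3' splice site), separately for
#' CD- and H/ACA-box snoRNAs. With `normalize = TRUE` (default) each
#' class profile is divided by the number of contributing snoRNAs; raw
#' sums satisfy the partition property CD + HACA = unstratified.
#'
#' @param track a `site_track` (typically 3'CLIP).
#' @param annotation a `ticlip_annotation`.
#' @param anchor `"sno_3p_end"` or `"host_3ss"`.
#' @param window odd window width (default 101).
#' @param normalize divide by the class's snoRNA count.
#' @return named list of per-class profiles (named numeric vectors by
#'   offset); classes without members are omitted with a warning.
#' @export
snorna_window_coverage <- function(track, annotation,
                                   anchor = c("sno_3p_end", "host_3ss"),
                                   window = 101L, normalize = TRUE) {
  anchor <- match.arg(anchor)
  if (window %% 2L == 0L) stop("window must be odd")
  h <- (window - 1L) %/% 2L
  a <- .sno_anchors(annotation, anchor)
  out <- list()
  for (cls in c("CD", "HACA")) {
    sel <- a$sno_class == cls
    if (!any(sel)) {
      warning("no ", cls, " snoRNAs in annotation; class omitted")
      next
    }
    prof <- .window_aggregate(track, a$chrom[sel], a$pos[sel],
                              a$strand[sel], -h, h)
    out[[cls]] <- if (normalize) prof / sum(sel) else prof
  }
  out
}

#' Detect snoRNA 3'-extension peaks
#'
#' Local maxima of a class profile within the downstream search range
#' that exceed the range mean plus 2 standard deviations (extension peaks
#' sit on an elevated flank baseline, hence the laxer threshold than for
#' truncation signatures). `max_extension` is the largest offset whose
#' signal exceeds 10 percent of the range maximum — for CD-box snoRNAs
#' with variable extensions this reports the extension limit even when no
#' sharp peak exists.
#'
#' @param profile a per-class profile from [snorna_window_coverage()]
#'   (anchored at the snoRNA 3' end).
#' @param search_range downstream offsets to search (default `1:35`).
#' @return list of class `extension_peaks`: `peak_offsets`,
#'   `peak_scores`, `max_extension`.
#' @export
extension_peaks <- function(profile, search_range = 1:35) {
  x <- profile[as.character(search_range)]
  x[is.na(x)] <- 0
  if (all(x == 0)) {
    return(structure(list(peak_offsets = integer(0),
                          peak_scores = numeric(0), max_extension = 0L),
                     class = "extension_peaks"))
  }
  thr <- mean(x) + 2 * stats::sd(x)
  n <- length(x)
  left <- c(-Inf, x[-n])
  right <- c(x[-1L], -Inf)
  is_peak <- x > left & x >= right & x > thr
  max_ext <- if (any(x > 0.1 * max(x))) {
    as.integer(search_range[max(which(x > 0.1 * max(x)))])
  } else 0L
  structure(list(peak_offsets = as.integer(search_range[is_peak]),
                 peak_scores = unname(x[is_peak]),
                 max_extension = max_ext),
            class = "extension_peaks")
}

#' @export
print.extension_peaks <- function(x, ...) {
  cat("<extension_peaks> offsets {",
      paste(x$peak_offsets, collapse = ", "), "} nt, max extension ",
      x$max_extension, " nt\n", sep = "")
  invisible(x)
}

#' Per-snoRNA heatmap of the top-N 3'CLIP downstream windows
#'
#' Ranks snoRNAs by cumulative 3'CLIP signal in the window immediately
#' downstream of their 3' end (offsets `1..window`) and returns the top
#' `n` per-snoRNA rows; ties are broken by snoRNA id lexicographically.
#'
#' @param track a 3'CLIP `site_track`.
#' @param annotation a `ticlip_annotation`.
#' @param window downstream window width (default 35).
#' @param n number of snoRNAs to keep (default 50; all if fewer).
#' @param sno_class optional class filter (`"CD"` or `"HACA"`).
#' @return matrix (snoRNAs x offsets `1..window`) ordered by descending
#'   cumulative signal; attribute `scores` gives the ranking values.
#' @export
top_n_heatmap <- function(track, annotation, window = 35L, n = 50L,
                          sno_class = NULL) {
  a <- .sno_anchors(annotation, "sno_3p_end")
  if (!is.null(sno_class)) a <- a[a$sno_class == sno_class, , drop = FALSE]
  if (!nrow(a)) stop("no snoRNAs to rank")
  m <- .window_matrix(track, a$chrom, a$pos, a$strand, 1L, window)
  rownames(m) <- a$sno_id
  score <- rowSums(m)
  ord <- order(-score, a$sno_id)
  keep <- ord[seq_len(min(n, nrow(m)))]
  out <- m[keep, , drop = FALSE]
  attr(out, "scores") <- score[keep]
  out
}
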