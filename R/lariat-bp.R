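#' Branchpoint-centred signal matrix stratified by BP-3'SS distance
#'
#' One row per branchpoint-to-3'-splice-site distance (18-38 nt); each row
#' is the mean strand-oriented windowed signal over the branchpoints at
#' that distance (offset 0 = the branch adenosine, positive = towards the
#' 3' splice site). Distances without any branchpoint yield a zero row,
#' flagged in the `n_bp` attribute.
#'
#' @param track a cross-link or 3'CLIP `site_track`.
#' @param annotation a `ticlip_annotation` (branchpoints are annotation
#'   inputs; discovery is out of scope).
#' @param window odd window width (default 101).
#' @return matrix with rownames `18..38` and offset colnames; attribute
#'   `n_bp` gives the branchpoint count per row.
#' @export
bp_window_matrix <- function(track, annotation, window = 101L) {
  if (window %% 2L == 0L) stop("window must be odd")
  h <- (window - 1L) %/% 2L
  intr <- annotation$introns[!is.na(annotation$introns$bp_pos), ,
                             drop = FALSE]
  intr <- intr[intr$bp_dist >= 18L & intr$bp_dist <= 38L, , drop = FALSE]
  tus <- annotation$tus
  m <- match(intr$tu_id, tus$tu_id)
  dists <- 18:38
  out <- matrix(0, nrow = length(dists), ncol = window,
                dimnames = list(dists, -h:h))
  n_bp <- stats::setNames(integer(length(dists)), dists)
  for (d in dists) {
    sel <- intr$bp_dist == d
    n_bp[as.character(d)] <- sum(sel)
    if (!any(sel)) next
    w <- .window_aggregate(track, tus$chrom[m][sel], intr$bp_pos[sel],
                           tus$strand[m][sel], -h, h)
    out[as.character(d), ] <- w / sum(sel)
  }
  attr(out, "n_bp") <- n_bp
  out
}

# Anchor tables in transcript orientation (offset 0 conventions:
# BP = branch adenosine; intron_5p = first intronic nucleotide;
# exon_3p = last exonic nucleotide).
.anchors_of <- function(annotation, anchor = c("bp", "intron_5p",
                                               "exon_3p")) {
  anchor <- match.arg(anchor)
  tus <- annotation$tus
  if (anchor == "bp") {
    intr <- annotation$introns[!is.na(annotation$introns$bp_pos), ,
                               drop = FALSE]
    m <- match(intr$tu_id, tus$tu_id)
    return(data.frame(chrom = tus$chrom[m], strand = tus$strand[m],
                      pos = intr$bp_pos))
  }
  if (anchor == "intron_5p") {
    intr <- annotation$introns
    m <- match(intr$tu_id, tus$tu_id)
    plus <- tus$strand[m] == "+"
    return(data.frame(chrom = tus$chrom[m], strand = tus$strand[m],
                      pos = ifelse(plus, intr$start, intr$end - 1L)))
  }
  ex <- annotation$exons
  n_ex <- stats::ave(ex$rank, ex$tu_id, FUN = max)
  ex <- ex[ex$rank < n_ex, , drop = FALSE]    # exons followed by an intron
  m <- match(ex$tu_id, tus$tu_id)
  plus <- tus$strand[m] == "+"
  data.frame(chrom = tus$chrom[m], strand = tus$strand[m],
             pos = ifelse(plus, ex$end - 1L, ex$start))
}

#' cDNA truncation signature around lariat-diagnostic anchors
#'
#' Aggregates read-5'-derived site counts (see [five_prime_sites()])
#' around an anchor class and calls peak offsets exceeding the window
#' mean plus 3 standard deviations. Reverse transcription of a cleaved
#' lariat truncates at the 2'-5' branch linkage, so circular-origin cDNA
#' 5' ends pile on the branchpoint (offset 0) and linear-origin 5' ends
#' 1 nt downstream (offset +1); first-exon 3'-end enrichments in
#' cross-link data are diagnosed at the intron 5'-end anchor the same way.
#'
#' @param track a read1 5'-end `site_track` ([five_prime_sites()]).
#' @param annotation a `ticlip_annotation`.
#' @param anchor `"bp"`, `"intron_5p"`, or `"exon_3p"`.
#' @param window odd window width (default 101).
#' @return list of class `truncation_signature`: `offsets`, `counts`,
#'   `peak_offsets`, `anchor`.
#' @export
truncation_signature <- function(track, annotation,
                                 anchor = c("bp", "intron_5p", "exon_3p"),
                                 window = 101L) {
  anchor <- match.arg(anchor)
  if (window %% 2L == 0L) stop("window must be odd")
  h <- (window - 1L) %/% 2L
  a <- .anchors_of(annotation, anchor)
  counts <- .window_aggregate(track, a$chrom, a$pos, a$strand, -h, h)
  thr <- mean(counts) + 3 * stats::sd(counts)
  peaks <- as.integer(names(counts))[counts > thr]
  structure(list(offsets = -h:h, counts = counts, peak_offsets = peaks,
                 anchor = anchor),
            class = "truncation_signature")
}

#' First-base mismatch profile around anchors
#'
#' For reads whose read1 5' end falls within the window around an anchor
#' class, counts at each transcript-oriented offset the read 5' ends and
#' the subset whose first sequenced base is a mismatch, and reports the
#' per-offset mismatch rate. Circular-origin lariat cDNAs read through
#' the 2'-5' linkage and start with a mismatched base on the branchpoint;
#' linear-origin cDNAs (offset +1) do not. Offsets without any read 5'
#' end have an undefined (`NA`) rate, not 0.
#'
#' @param pairs deduplicated `aligned_pairs` carrying mismatch records.
#' @param annotation a `ticlip_annotation`.
#' @param anchor `"bp"`, `"intron_5p"`, or `"exon_3p"`.
#' @param window odd window width (default 21).
#' @return list of class `mismatch_profile`: `offsets`, `read_5p_count`,
#'   `mismatch_count`, `rate`.
#' @export
mismatch_profile <- function(pairs, annotation,
                             anchor = c("bp", "intron_5p", "exon_3p"),
                             window = 21L) {
  anchor <- match.arg(anchor)
  if (window %% 2L == 0L) stop("window must be odd")
  h <- (window - 1L) %/% 2L
  p5 <- .r1_five_prime(pairs)
  first_mm <- mapply(function(mp, p) {
    nzchar(mp) && p %in% .unpack_ints(mp)[[1L]]
  }, pairs$mm_pos, p5, USE.NAMES = FALSE)
  all5 <- site_track(pairs$chrom, pairs$strand, p5)
  mm5 <- if (any(first_mm)) {
    site_track(pairs$chrom[first_mm], pairs$strand[first_mm], p5[first_mm])
  } else site_track()
  a <- .anchors_of(annotation, anchor)
  n5 <- .window_aggregate(all5, a$chrom, a$pos, a$strand, -h, h)
  nm <- .window_aggregate(mm5, a$chrom, a$pos, a$strand, -h, h)
  rate <- ifelse(n5 > 0, nm / n5, NA_real_)
  structure(list(offsets = -h:h, read_5p_count = n5, mismatch_count = nm,
                 rate = rate, anchor = anchor),
            class = "mismatch_profile")
}
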