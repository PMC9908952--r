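#' Demultiplex aligned pairs by in-line sample barcode
#'
#' Each pair is assigned to the unique sample whose barcode lies within
#' `max_mismatch` Hamming distance of the pair's barcode; ambiguous or
#' unmatched pairs are routed to the `undetermined` bin. Two table barcodes
#' within `2 * max_mismatch` of each other are a configuration error
#' (collision), as a read could then match both.
#'
#' @param pairs an `aligned_pairs` table.
#' @param barcode_table named character vector `barcode -> sample name`.
#' @param max_mismatch maximal Hamming distance (default 0, strict).
#' @return named list of `aligned_pairs`, one per sample plus
#'   `undetermined`.
#' @export
demultiplex <- function(pairs, barcode_table, max_mismatch = 0L) {
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  bcs <- names(barcode_table)
  if (is.null(bcs)) stop("barcode_table must be a named vector")
  if (length(unique(nchar(bcs))) > 1L) {
    stop("table barcodes must all have equal length")
  }
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  }
  if (length(bcs) > 1L) {
    for (i in seq_len(length(bcs) - 1L)) {
      for (j in (i + 1L):length(bcs)) {
        if (hamming(bcs[i], bcs[j]) <= 2L * max_mismatch) {
          stop("barcode collision: '", bcs[i], "' and '", bcs[j],
               "' are within ", 2L * max_mismatch, " mismatches")
        }
      }
    }
  }
  ubc <- unique(pairs$barcode)
  assign_of <- vapply(ubc, function(b) {
    if (nchar(b) != nchar(bcs[1L])) return("undetermined")
    d <- vapply(bcs, hamming, numeric(1), a = b)
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1L) unname(barcode_table[hit]) else "undetermined"
  }, character(1))
  dest <- assign_of[match(pairs$barcode, ubc)]
  out <- lapply(stats::setNames(nm = c(unname(barcode_table),
                                       "undetermined")),
                function(s) {
    as_aligned_pairs(pairs[dest == s, , drop = FALSE], validate = FALSE)
  })
  out
}

#' Remove PCR duplicates by UMI and first mapping coordinate
#'
#' One pair is retained per (UMI, chromosome, read1 5' genomic coordinate,
#' strand) key; the first-encountered pair wins and input order is
#' preserved. The operation is idempotent.
#'
#' @param pairs an `aligned_pairs` table from one sample.
#' @return deduplicated `aligned_pairs`; the number of removed pairs is
#'   attached as attribute `n_duplicates`.
#' @export
deduplicate <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  key <- paste(pairs$umi, pairs$chrom, .r1_five_prime(pairs), pairs$strand,
               sep = "\r")
  keep <- !duplicated(key)
  out <- as_aligned_pairs(pairs[keep, , drop = FALSE], validate = FALSE)
  attr(out, "n_duplicates") <- sum(!keep)
  out
}

#' Extract cross-link sites (read1 5' end shifted 1 nt upstream)
#'
#' The protein-RNA contact of an iCLIP read sits one nucleotide 5' (in
#' transcript orientation) of read1's first sequenced base, because cDNA
#' synthesis truncates at the cross-linked peptide: a plus-strand read1
#' starting at `p` yields a site at `p - 1` on `+`; a minus-strand read1
#' whose first sequenced base is at `p` yields `p + 1` on `-`. Sites
#' falling before position 0 are dropped (not clamped, which would create
#' a spurious position-0 peak) and counted.
#'
#' @param pairs deduplicated `aligned_pairs`.
#' @param library_label,timepoint_label labels for the resulting track.
#' @return a `site_track` with attribute `n_dropped`.
#' @export
crosslink_sites <- function(pairs, library_label = "",
                            timepoint_label = "") {
  pos <- ifelse(pairs$strand == "+",
                .first_int(pairs$r1_starts) - 1L,
                .last_int(pairs$r1_ends))
  keep <- pos >= 0L
  tr <- site_track(pairs$chrom[keep], pairs$strand[keep], pos[keep],
                   1, library_label, timepoint_label)
  attr(tr, "n_dropped") <- sum(!keep)
  tr
}

#' Extract unshifted read1 5'-end sites
#'
#' Like [crosslink_sites()] but without the 1-nt upstream shift: the site
#' is read1's first sequenced base itself. This is the natural anchor for
#' cDNA truncation analysis, where the read 5' end marks the position the
#' reverse transcriptase stopped at (e.g. on a branchpoint).
#'
#' @inheritParams crosslink_sites
#' @return a `site_track`.
#' @export
five_prime_sites <- function(pairs, library_label = "",
                             timepoint_label = "") {
  site_track(pairs$chrom, pairs$strand, .r1_five_prime(pairs), 1,
             library_label, timepoint_label)
}

#' Extract 3'CLIP sites (fragment 3' termini)
#'
#' The fragment's RNA 3' terminus is the genomic position of read2's first
#' sequenced base (read2 starts at the adapter ligated to the RNA 3' end),
#' reported on the RNA strand (read1's strand). Set
#' `convention = "coordinate_last"` to instead take read2's highest
#' genomic coordinate regardless of strand (the two differ for
#' minus-strand fragments).
#'
#' @param pairs deduplicated `aligned_pairs`.
#' @param convention `"fragment_terminus"` (default) or
#'   `"coordinate_last"`.
#' @param library_label,timepoint_label labels for the resulting track.
#' @return a `site_track`.
#' @export
three_prime_sites <- function(pairs,
                              convention = c("fragment_terminus",
                                             "coordinate_last"),
                              library_label = "", timepoint_label = "") {
  convention <- match.arg(convention)
  pos <- if (convention == "fragment_terminus") {
    .frag_three_prime(pairs)
  } else {
    .last_int(pairs$r2_ends) - 1L
  }
  site_track(pairs$chrom, pairs$strand, pos, 1,
             library_label, timepoint_label)
}

#' Whole-read coverage from read1 aligned blocks
#'
#' Unit weight at every position covered by a read1 aligned block, on
#' read1's strand; alignment gaps (spliced-out introns) contribute
#' nothing.
#'
#' @inheritParams crosslink_sites
#' @return a `site_track` whose total equals the summed read1 aligned
#'   lengths.
#' @export
whole_read_coverage <- function(pairs, library_label = "",
                                timepoint_label = "") {
  bl <- .blocks_long(pairs, 1L)
  if (!nrow(bl)) {
    return(site_track(library_label = library_label,
                      timepoint_label = timepoint_label))
  }
  w <- bl$end - bl$start
  pos <- sequence(w, from = bl$start)
  i <- rep.int(bl$pair, w)
  site_track(pairs$chrom[i], pairs$strand[i], pos, 1,
             library_label, timepoint_label)
}

#' Classify reads overlapping exon ends as spliced or non-spliced
#'
#' A read1 whose aligned blocks cover an exon's last (3'-most) nucleotide
#' is `spliced` if a block gap joins that exon's end to the annotated
#' downstream exon start, and `non_spliced` if the alignment continues
#' contiguously at least 1 nt into the intron. Reads ending exactly at the
#' exon end belong to neither class. Only read1 is used.
#'
#' @param pairs deduplicated `aligned_pairs`.
#' @param exons data.frame with columns `exon_id`, `chrom`, `strand`,
#'   `start`, `end` (the exon), and `next_start`, `next_end` (the
#'   annotated downstream exon); rows with missing downstream exons are
#'   skipped with a warning.
#' @return data.frame with per-exon `spliced` and `non_spliced` counts.
#' @export
classify_splice_status <- function(pairs, exons) {
  no_next <- is.na(exons$next_start)
  if (any(no_next)) {
    warning(sum(no_next), " exon(s) without downstream partner skipped")
    exons <- exons[!no_next, , drop = FALSE]
  }
  bl <- .blocks_long(pairs, 1L)
  bl$chrom <- pairs$chrom[bl$pair]
  bl$strand <- pairs$strand[bl$pair]
  res <- data.frame(exon_id = exons$exon_id,
                    spliced = integer(nrow(exons)),
                    non_spliced = integer(nrow(exons)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(exons))) {
    plus <- exons$strand[i] == "+"
    last_nt <- if (plus) exons$end[i] - 1L else exons$start[i]
    cand <- bl[bl$chrom == exons$chrom[i] & bl$strand == exons$strand[i] &
                 bl$start <= last_nt & bl$end > last_nt, , drop = FALSE]
    if (!nrow(cand)) next
    for (k in seq_len(nrow(cand))) {
      pb <- bl[bl$pair == cand$pair[k], , drop = FALSE]
      if (plus) {
        # spliced: this block ends at the exon boundary and the next block
        # starts at the downstream exon start
        at_boundary <- cand$end[k] == exons$end[i]
        nxt <- pb[pb$start > cand$start[k], , drop = FALSE]
        if (at_boundary && nrow(nxt) &&
            min(nxt$start) == exons$next_start[i]) {
          res$spliced[i] <- res$spliced[i] + 1L
        } else if (cand$end[k] > exons$end[i]) {
          res$non_spliced[i] <- res$non_spliced[i] + 1L
        }
      } else {
        at_boundary <- cand$start[k] == exons$start[i]
        prv <- pb[pb$end < cand$end[k], , drop = FALSE]
        if (at_boundary && nrow(prv) &&
            max(prv$end) == exons$next_end[i]) {
          res$spliced[i] <- res$spliced[i] + 1L
        } else if (cand$start[k] < exons$start[i]) {
          res$non_spliced[i] <- res$non_spliced[i] + 1L
        }
      }
    }
  }
  res
}

#' Build the exon table expected by [classify_splice_status()]
#'
#' Extracts first or internal exons from an annotation bundle together
#' with their downstream exon coordinates.
#'
#' @param annotation a `ticlip_annotation`.
#' @param which_exons `"first"` or `"internal"`.
#' @return data.frame suitable for [classify_splice_status()].
#' @export
exon_boundary_table <- function(annotation,
                                which_exons = c("first", "internal")) {
  which_exons <- match.arg(which_exons)
  ex <- annotation$exons
  tus <- annotation$tus
  n_ex <- stats::ave(ex$rank, ex$tu_id, FUN = max)
  sel <- if (which_exons == "first") {
    ex$rank == 1L & n_ex > 1L
  } else {
    ex$rank > 1L & ex$rank < n_ex
  }
  ex <- ex[sel, , drop = FALSE]
  all_ex <- annotation$exons
  key <- paste(all_ex$tu_id, all_ex$rank)
  nxt <- all_ex[match(paste(ex$tu_id, ex$rank + 1L), key), , drop = FALSE]
  m <- match(ex$tu_id, tus$tu_id)
  plus <- tus$strand[m] == "+"
  data.frame(
    exon_id = paste0(ex$tu_id, ".e", ex$rank),
    chrom = tus$chrom[m], strand = tus$strand[m],
    start = ex$start, end = ex$end,
    # in transcript orientation the downstream exon of a minus-strand TU
    # lies genomically left; classify_splice_status expects its genomic
    # start/end as annotated
    next_start = nxt$start, next_end = nxt$end,
    stringsAsFactors = FALSE)
}
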