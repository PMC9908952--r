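#' Write aligned pairs as a SAM file
#'
#' Emits one SAM record per mate with proper FLAG/CIGAR/TLEN fields so the
#' file round-trips through any SAM/BAM toolchain. The sample barcode and
#' UMI are encoded in the read name as `name#BARCODE#UMI` (in-line barcode
#' dialect shared by the simulator, demultiplexer and deduplicator).
#' Read1 mismatches are carried in a `XM:Z:` tag as
#' `pos:base` pairs (0-based genomic positions) joined by `;`.
#'
#' @param pairs an `aligned_pairs` table.
#' @param path output `.sam` path.
#' @param chrom_lengths named integer vector of chromosome lengths for the
#'   `@SQ` header lines; must cover every chromosome present.
#' @return invisibly, `path`.
#' @export
write_alignments <- function(pairs, path, chrom_lengths) {
  chroms <- unique(pairs$chrom)
  missing <- setdiff(chroms, names(chrom_lengths))
  if (length(missing)) {
    stop("chrom_lengths lacks entries for: ", paste(missing, collapse = ", "))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (!nrow(pairs)) return(invisible(path))

  cigar_of <- function(starts, ends) {
    mapply(function(s, e) {
      w <- e - s
      if (length(w) == 1L) return(sprintf("%dM", w))
      gaps <- s[-1L] - e[-length(e)]
      paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
             w[length(w)], "M")
    }, .unpack_ints(starts), .unpack_ints(ends))
  }

  qname <- paste(pairs$name, pairs$barcode, pairs$umi, sep = "#")
  r1_pos <- .first_int(pairs$r1_starts) + 1L
  r2_pos <- .first_int(pairs$r2_starts) + 1L
  minus <- pairs$strand == "-"
  f1 <- 1L + 2L + 64L + ifelse(minus, 16L, 32L)
  f2 <- 1L + 2L + 128L + ifelse(minus, 32L, 16L)
  tlen1 <- ifelse(minus, -pairs$tlen, pairs$tlen)
  xm <- ifelse(nzchar(pairs$mm_pos),
               paste0("\tXM:Z:", mapply(function(p, b) {
                 paste(p, strsplit(b, ",", fixed = TRUE)[[1L]],
                       sep = ":", collapse = ";")
               }, pairs$mm_pos, pairs$mm_base)),
               "")
  l1 <- paste0(qname, "\t", f1, "\t", pairs$chrom, "\t", r1_pos, "\t60\t",
               cigar_of(pairs$r1_starts, pairs$r1_ends), "\t=\t", r2_pos,
               "\t", tlen1, "\t*\t*", xm)
  l2 <- paste0(qname, "\t", f2, "\t", pairs$chrom, "\t", r2_pos, "\t60\t",
               cigar_of(pairs$r2_starts, pairs$r2_ends), "\t=\t", r1_pos,
               "\t", -tlen1, "\t*\t*")
  out <- character(2L * nrow(pairs))
  out[c(TRUE, FALSE)] <- l1
  out[c(FALSE, TRUE)] <- l2
  writeLines(out, con)
  invisible(path)
}

#' Read aligned CLIP pairs from a SAM or BAM file
#'
#' Keeps only mapped, primary, paired records and re-assembles mates by
#' read name. The UMI and sample barcode are parsed from the
#' `name#BARCODE#UMI` read-name suffix. Records whose mate is absent
#' (orphans) are skipped with a counted warning; output order is the file
#' order of read1 records.
#'
#' @param path a `.sam` or `.bam` file.
#' @return an `aligned_pairs` table; the number of skipped orphan mates is
#'   attached as attribute `n_orphans`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("unparseable SAM file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "isize"),
    tag = "XM")
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- res$flag
  keep <- !is.na(res$pos) &
    bitwAnd(flag, 4L) == 0L &      # mapped
    bitwAnd(flag, 256L) == 0L &    # primary
    bitwAnd(flag, 2048L) == 0L &   # not supplementary
    bitwAnd(flag, 1L) == 1L        # paired
  idx <- which(keep)
  if (!length(idx)) {
    return(aligned_pairs(character(0), character(0), character(0),
                         character(0), character(0), character(0),
                         character(0), character(0), character(0),
                         character(0), character(0), integer(0)))
  }
  flag <- flag[idx]
  qname <- res$qname[idx]
  is_r1 <- bitwAnd(flag, 64L) == 64L
  rng <- GenomicAlignments::extractAlignmentRangesOnReference(
    res$cigar[idx], pos = res$pos[idx])
  starts <- lapply(seq_along(rng), function(i) IRanges::start(rng[[i]]) - 1L)
  ends <- lapply(seq_along(rng), function(i) IRanges::end(rng[[i]]))

  i1 <- which(is_r1)
  i2 <- which(!is_r1)
  m <- match(qname[i1], qname[i2])
  n_orphans <- sum(is.na(m)) + sum(!(qname[i2] %in% qname[i1]))
  if (n_orphans > 0L) {
    warning(n_orphans, " orphan mate record(s) skipped")
  }
  ok <- !is.na(m)
  i1 <- i1[ok]
  i2 <- i2[m[ok]]

  parts <- strsplit(qname[i1], "#", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("read name lacks '#BARCODE#UMI' suffix: record '",
         qname[i1][which(bad)[1]], "'")
  }
  xm <- res$tag$XM[idx][i1] %||% rep(NA_character_, length(i1))
  mm <- .parse_xm(xm)
  pairs <- aligned_pairs(
    name = vapply(parts, `[`, character(1), 1L),
    umi = vapply(parts, `[`, character(1), 3L),
    barcode = vapply(parts, `[`, character(1), 2L),
    chrom = as.character(res$rname[idx][i1]),
    strand = ifelse(bitwAnd(flag[i1], 16L) == 16L, "-", "+"),
    r1_starts = .pack_ints(starts[i1]), r1_ends = .pack_ints(ends[i1]),
    r2_starts = .pack_ints(starts[i2]), r2_ends = .pack_ints(ends[i2]),
    mm_pos = mm$pos, mm_base = mm$base,
    tlen = abs(res$isize[idx][i1])
  )
  attr(pairs, "n_orphans") <- n_orphans
  pairs
}

.parse_xm <- function(xm) {
  pos <- character(length(xm))
  base <- character(length(xm))
  has <- !is.na(xm) & nzchar(xm)
  if (any(has)) {
    sp <- strsplit(xm[has], ";", fixed = TRUE)
    pos[has] <- vapply(sp, function(v) {
      paste(sub(":.*$", "", v), collapse = ",")
    }, character(1))
    base[has] <- vapply(sp, function(v) {
      paste(sub("^.*:", "", v), collapse = ",")
    }, character(1))
  }
  list(pos = pos, base = base)
}
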