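#' Construct a table of aligned CLIP read pairs
#'
#' An `aligned_pairs` object is the pipeline's atomic input: one row per
#' mapped, primary, properly paired CLIP fragment. Read1 carries the RNA
#' strand (FR layout, as produced by strand-specific paired-end mapping),
#' so the `strand` column is both read1's alignment strand and the strand
#' of the underlying RNA. Aligned blocks (split at spliced-out introns) are
#' stored as comma-joined 0-based half-open intervals.
#'
#' @param name read (pair) names, unique within a library.
#' @param umi unique molecular identifier parsed from the read name.
#' @param barcode in-line sample barcode parsed from the read name.
#' @param chrom chromosome of both mates.
#' @param strand RNA strand, `"+"` or `"-"` (read1's alignment strand).
#' @param r1_starts,r1_ends read1 aligned block starts/ends; either
#'   comma-joined strings or lists of integer vectors, ascending,
#'   non-overlapping, 0-based half-open.
#' @param r2_starts,r2_ends read2 aligned blocks, same conventions.
#' @param mm_pos,mm_base genomic positions (0-based) and observed bases of
#'   read1 mismatches; comma-joined strings, `""` when none.
#' @param tlen observed template (fragment) length in nucleotides, positive.
#' @return a data.frame of class `aligned_pairs`.
#' @export
aligned_pairs <- function(name, umi, barcode, chrom, strand,
                          r1_starts, r1_ends, r2_starts, r2_ends,
                          mm_pos = "", mm_base = "", tlen = NA_integer_) {
  if (is.list(r1_starts)) r1_starts <- .pack_ints(r1_starts)
  if (is.list(r1_ends))   r1_ends   <- .pack_ints(r1_ends)
  if (is.list(r2_starts)) r2_starts <- .pack_ints(r2_starts)
  if (is.list(r2_ends))   r2_ends   <- .pack_ints(r2_ends)
  df <- data.frame(
    name = as.character(name), umi = as.character(umi),
    barcode = as.character(barcode), chrom = as.character(chrom),
    strand = as.character(strand),
    r1_starts = as.character(r1_starts), r1_ends = as.character(r1_ends),
    r2_starts = as.character(r2_starts), r2_ends = as.character(r2_ends),
    mm_pos = as.character(mm_pos), mm_base = as.character(mm_base),
    tlen = as.integer(tlen),
    stringsAsFactors = FALSE
  )
  as_aligned_pairs(df)
}

#' Mark a data.frame as an aligned-pairs table
#'
#' @param df a data.frame with the `aligned_pairs` columns.
#' @param validate check strand symbols and block ordering.
#' @return `df` with class `aligned_pairs` prepended.
#' @export
as_aligned_pairs <- function(df, validate = TRUE) {
  needed <- c("name", "umi", "barcode", "chrom", "strand",
              "r1_starts", "r1_ends", "r2_starts", "r2_ends",
              "mm_pos", "mm_base", "tlen")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("aligned_pairs is missing columns: ", paste(missing, collapse = ", "))
  }
  if (validate && nrow(df)) {
    .check_strand(df$strand)
    validate_aligned_pairs(df)
  }
  class(df) <- unique(c("aligned_pairs", class(df)))
  df
}

#' @rdname as_aligned_pairs
#' @export
validate_aligned_pairs <- function(df) {
  for (rd in c("r1", "r2")) {
    s <- .unpack_ints(df[[paste0(rd, "_starts")]])
    e <- .unpack_ints(df[[paste0(rd, "_ends")]])
    ok <- mapply(function(a, b) {
      length(a) == length(b) && length(a) >= 1L && all(a < b) &&
        (length(a) == 1L || all(b[-length(b)] <= a[-1L]))
    }, s, e)
    if (!all(ok)) {
      stop(rd, " blocks malformed (unordered or overlapping) for pair '",
           df$name[which(!ok)[1]], "'")
    }
  }
  invisible(df)
}

#' @export
print.aligned_pairs <- function(x, ...) {
  cat("<aligned_pairs> ", nrow(x), " pairs on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x)[, c(
    "name", "barcode", "umi", "chrom", "strand", "r1_starts", "tlen")], 6L))
  invisible(x)
}

# Genomic coordinate of read1's first sequenced (5') base.
.r1_five_prime <- function(pairs) {
  ifelse(pairs$strand == "+",
         .first_int(pairs$r1_starts),
         .last_int(pairs$r1_ends) - 1L)
}

# Genomic coordinate of the fragment 3' terminus (read2's first sequenced
# base; read2 starts at the adapter-ligated RNA 3' end).
.frag_three_prime <- function(pairs) {
  ifelse(pairs$strand == "+",
         .last_int(pairs$r2_ends) - 1L,
         .first_int(pairs$r2_starts))
}

# Long-format blocks of one mate: data.frame(pair = row index, start, end).
.blocks_long <- function(pairs, read = 1L) {
  s <- .unpack_ints(pairs[[sprintf("r%d_starts", read)]])
  e <- .unpack_ints(pairs[[sprintf("r%d_ends", read)]])
  n <- lengths(s)
  data.frame(pair = rep.int(seq_len(nrow(pairs)), n),
             start = unlist(s, use.names = FALSE) %||% integer(0),
             end = unlist(e, use.names = FALSE) %||% integer(0))
}
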