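#' Assemble an annotation bundle from its component tables
#'
#' The coordinate model every profile is anchored to: transcription units
#' (TUs) with exon blocks, introns derived as inter-exon gaps, one
#' branchpoint (BP) per annotated intron, intron-hosted snoRNAs with their
#' box class, and rRNA units used for library normalization. All
#' coordinates are 0-based half-open; exon/intron ranks count in the
#' direction of transcription.
#'
#' @param tus data.frame: `tu_id`, `chrom`, `start`, `end`, `strand`.
#' @param exons data.frame: `tu_id`, `rank`, `start`, `end`.
#' @param introns data.frame: `intron_id`, `tu_id`, `rank`, `start`, `end`,
#'   `bp_pos` (genomic position of the branch adenosine, or `NA`),
#'   `bp_dist` (nucleotides from the BP to the downstream 3' splice site).
#' @param snornas data.frame: `sno_id`, `intron_id`, `tu_id`, `sno_class`
#'   (`"CD"`/`"HACA"`), `start`, `end`; must lie inside the host intron.
#' @param rrna data.frame: `unit_id`, `chrom`, `start`, `end`, `strand`.
#' @param chrom_lengths named integer vector.
#' @return a list of class `ticlip_annotation`.
#' @export
ticlip_annotation <- function(tus, exons, introns, snornas, rrna,
                              chrom_lengths) {
  .check_strand(tus$strand)
  if (nrow(snornas)) {
    m <- match(snornas$intron_id, introns$intron_id)
    if (anyNA(m)) {
      stop("snoRNA(s) not inside any annotated intron: ",
           paste(snornas$sno_id[is.na(m)], collapse = ", "))
    }
    inside <- snornas$start >= introns$start[m] &
      snornas$end <= introns$end[m]
    if (!all(inside)) {
      stop("snoRNA(s) extend outside their host intron: ",
           paste(snornas$sno_id[!inside], collapse = ", "))
    }
  }
  structure(list(tus = tus, exons = exons, introns = introns,
                 snornas = snornas, rrna = rrna,
                 chrom_lengths = chrom_lengths),
            class = "ticlip_annotation")
}

#' @export
print.ticlip_annotation <- function(x, ...) {
  cat("<ticlip_annotation> ", nrow(x$tus), " TUs, ", nrow(x$introns),
      " introns (", sum(!is.na(x$introns$bp_pos)), " BPs), ",
      nrow(x$snornas), " snoRNAs, ", nrow(x$rrna), " rRNA units\n", sep = "")
  invisible(x)
}

# BP distance to the downstream 3'SS in transcript orientation; d = 1 means
# the BP is the last intron nucleotide.
.bp_dist <- function(bp_pos, intron_start, intron_end, strand) {
  ifelse(strand == "+", intron_end - bp_pos, bp_pos - intron_start + 1L)
}

#' Write an annotation bundle as BED files
#'
#' Emits `<prefix>_tus.bed` (BED12, exons as blocks), `<prefix>_bp.bed`,
#' `<prefix>_snorna.bed` and `<prefix>_rrna.bed` (BED6; the snoRNA name
#' field is `CLASS_id` so the class survives the round trip), plus
#' `<prefix>.chrom.sizes`.
#'
#' @param annotation a `ticlip_annotation`.
#' @param path_prefix output prefix.
#' @return invisibly, the file paths.
#' @export
write_annotation <- function(annotation, path_prefix) {
  tus <- annotation$tus
  str_of <- function(tu_id) tus$strand[match(tu_id, tus$tu_id)]
  chr_of <- function(tu_id) tus$chrom[match(tu_id, tus$tu_id)]

  bed6 <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(df)) {
      writeLines(paste(df$chrom, df$start, df$end, df$name, 0, df$strand,
                       sep = "\t"), con)
    }
  }
  p_tu <- paste0(path_prefix, "_tus.bed")
  con <- file(p_tu, "w")
  for (i in seq_len(nrow(tus))) {
    ex <- annotation$exons[annotation$exons$tu_id == tus$tu_id[i], ,
                           drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    writeLines(paste(tus$chrom[i], tus$start[i], tus$end[i], tus$tu_id[i],
                     0, tus$strand[i], tus$start[i], tus$end[i], "0",
                     nrow(ex),
                     paste0(paste(ex$end - ex$start, collapse = ","), ","),
                     paste0(paste(ex$start - tus$start[i], collapse = ","),
                            ","),
                     sep = "\t"), con)
  }
  close(con)

  bp <- annotation$introns[!is.na(annotation$introns$bp_pos), , drop = FALSE]
  p_bp <- paste0(path_prefix, "_bp.bed")
  bed6(data.frame(chrom = chr_of(bp$tu_id), start = bp$bp_pos,
                  end = bp$bp_pos + 1L, name = bp$intron_id,
                  strand = str_of(bp$tu_id)), p_bp)
  sn <- annotation$snornas
  p_sno <- paste0(path_prefix, "_snorna.bed")
  bed6(data.frame(chrom = chr_of(sn$tu_id), start = sn$start, end = sn$end,
                  name = paste(sn$sno_class, sn$sno_id, sep = "_"),
                  strand = str_of(sn$tu_id)), p_sno)
  p_rr <- paste0(path_prefix, "_rrna.bed")
  bed6(data.frame(chrom = annotation$rrna$chrom,
                  start = annotation$rrna$start, end = annotation$rrna$end,
                  name = annotation$rrna$unit_id,
                  strand = annotation$rrna$strand), p_rr)
  p_cs <- paste0(path_prefix, ".chrom.sizes")
  utils::write.table(
    data.frame(names(annotation$chrom_lengths),
               as.integer(annotation$chrom_lengths)),
    p_cs, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(p_tu, p_bp, p_sno, p_rr, p_cs))
}

#' Read an annotation bundle from BED files
#'
#' Introns are derived as the gaps between exon blocks of each BED12
#' record; each branchpoint is assigned to its containing intron (an
#' unassignable BP is an error) and each snoRNA record must fall inside a
#' host intron, with its class parsed from the `CD`/`HACA` prefix of the
#' BED name field.
#'
#' @param tu_path BED12 file of transcription units.
#' @param bp_path BED6 file of branchpoints (1-nt intervals).
#' @param sno_path BED6 file of snoRNAs.
#' @param rrna_path optional BED6 file of rRNA units.
#' @param chrom_sizes_path optional 2-column chromosome sizes file;
#'   defaults to the largest annotated end per chromosome.
#' @return a `ticlip_annotation`.
#' @export
read_annotation <- function(tu_path, bp_path, sno_path, rrna_path = NULL,
                            chrom_sizes_path = NULL) {
  gr <- rtracklayer::import(tu_path, format = "bed")
  tus <- data.frame(
    tu_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  .check_strand(tus$strand)

  ex_list <- lapply(seq_along(gr), function(i) {
    bl <- gr$blocks[[i]]
    s <- tus$start[i] + IRanges::start(bl) - 1L
    e <- tus$start[i] + IRanges::end(bl)
    if (is.unsorted(s) || any(e[-length(e)] > s[-1L]) ||
        any(e > tus$end[i])) {
      stop("malformed exon blocks in TU '", tus$tu_id[i], "'")
    }
    n <- length(s)
    rk <- if (tus$strand[i] == "+") seq_len(n) else rev(seq_len(n))
    data.frame(tu_id = tus$tu_id[i], rank = rk, start = s, end = e)
  })
  exons <- do.call(rbind, ex_list)

  in_list <- lapply(seq_len(nrow(tus)), function(i) {
    ex <- ex_list[[i]][order(ex_list[[i]]$start), , drop = FALSE]
    n <- nrow(ex)
    if (n < 2L) return(NULL)
    s <- ex$end[-n]
    e <- ex$start[-1L]
    rk <- if (tus$strand[i] == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
    data.frame(intron_id = paste0(tus$tu_id[i], ".i", rk),
               tu_id = tus$tu_id[i], rank = rk, start = s, end = e,
               bp_pos = NA_integer_, bp_dist = NA_integer_)
  })
  introns <- do.call(rbind, c(in_list, list(
    data.frame(intron_id = character(0), tu_id = character(0),
               rank = integer(0), start = integer(0), end = integer(0),
               bp_pos = integer(0), bp_dist = integer(0)))))

  read_bed6 <- function(path) {
    g <- rtracklayer::import(path, format = "bed")
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1L,
               end = GenomicRanges::end(g),
               name = g$name %||% paste0("rec", seq_along(g)),
               strand = as.character(GenomicRanges::strand(g)),
               stringsAsFactors = FALSE)
  }

  bp <- read_bed6(bp_path)
  if (nrow(bp)) {
    chr_of <- tus$chrom[match(introns$tu_id, tus$tu_id)]
    str_of <- tus$strand[match(introns$tu_id, tus$tu_id)]
    for (j in seq_len(nrow(bp))) {
      hit <- which(chr_of == bp$chrom[j] & str_of == bp$strand[j] &
                     introns$start <= bp$start[j] &
                     introns$end > bp$start[j])
      if (!length(hit)) {
        stop("branchpoint record '", bp$name[j],
             "' falls outside every annotated intron")
      }
      hit <- hit[1L]
      introns$bp_pos[hit] <- bp$start[j]
      introns$bp_dist[hit] <- .bp_dist(bp$start[j], introns$start[hit],
                                       introns$end[hit], str_of[hit])
    }
  }

  sn <- read_bed6(sno_path)
  snornas <- data.frame(sno_id = character(0), intron_id = character(0),
                        tu_id = character(0), sno_class = character(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
  if (nrow(sn)) {
    cls <- sub("_.*$", "", sn$name)
    if (!all(cls %in% c("CD", "HACA"))) {
      stop("snoRNA name field must start with 'CD_' or 'HACA_'")
    }
    chr_of <- tus$chrom[match(introns$tu_id, tus$tu_id)]
    str_of <- tus$strand[match(introns$tu_id, tus$tu_id)]
    host <- vapply(seq_len(nrow(sn)), function(j) {
      hit <- which(chr_of == sn$chrom[j] & str_of == sn$strand[j] &
                     introns$start <= sn$start[j] &
                     introns$end >= sn$end[j])
      if (!length(hit)) {
        stop("snoRNA record '", sn$name[j], "' is not inside any intron")
      }
      hit[1L]
    }, integer(1))
    snornas <- data.frame(sno_id = sub("^(CD|HACA)_", "", sn$name),
                          intron_id = introns$intron_id[host],
                          tu_id = introns$tu_id[host], sno_class = cls,
                          start = sn$start, end = sn$end,
                          stringsAsFactors = FALSE)
  }

  rrna <- data.frame(unit_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0), stringsAsFactors = FALSE)
  if (!is.null(rrna_path) && file.exists(rrna_path) &&
      file.size(rrna_path) > 0) {
    rr <- read_bed6(rrna_path)
    rrna <- data.frame(unit_id = rr$name, chrom = rr$chrom,
                       start = rr$start, end = rr$end, strand = rr$strand,
                       stringsAsFactors = FALSE)
  }

  if (!is.null(chrom_sizes_path)) {
    cs <- utils::read.table(chrom_sizes_path, sep = "\t",
                            stringsAsFactors = FALSE)
    chrom_lengths <- stats::setNames(as.integer(cs[[2L]]), cs[[1L]])
  } else {
    ends <- c(tus$end, rrna$end)
    chr <- c(tus$chrom, rrna$chrom)
    chrom_lengths <- vapply(split(ends, chr), max, numeric(1)) + 1000L
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  ticlip_annotation(tus, exons, introns, snornas, rrna, chrom_lengths)
}

# Per-TU transcript-orientation (sense) layout used by the simulator and
# by mature-coordinate projections. Sense offset 0 is the TSS.
.sense_layout <- function(annotation) {
  tus <- annotation$tus
  out <- vector("list", nrow(tus))
  names(out) <- tus$tu_id
  for (i in seq_len(nrow(tus))) {
    id <- tus$tu_id[i]
    s0 <- tus$start[i]; e0 <- tus$end[i]; str <- tus$strand[i]
    to_sense <- function(gs, ge) {
      if (str == "+") cbind(gs - s0, ge - s0) else cbind(e0 - ge, e0 - gs)
    }
    ex <- annotation$exons[annotation$exons$tu_id == id, , drop = FALSE]
    exs <- to_sense(ex$start, ex$end)
    o <- order(exs[, 1L])
    ins <- annotation$introns[annotation$introns$tu_id == id, , drop = FALSE]
    intr <- NULL
    if (nrow(ins)) {
      is2 <- to_sense(ins$start, ins$end)
      bp_off <- ifelse(is.na(ins$bp_pos), NA_integer_,
                       if (str == "+") ins$bp_pos - s0 else e0 - 1L - ins$bp_pos)
      intr <- data.frame(intron_id = ins$intron_id, s = is2[, 1L],
                         e = is2[, 2L], bp_off = bp_off,
                         bp_dist = ins$bp_dist,
                         stringsAsFactors = FALSE)
      intr <- intr[order(intr$s), , drop = FALSE]
    }
    sno <- annotation$snornas[annotation$snornas$tu_id == id, , drop = FALSE]
    snod <- NULL
    if (nrow(sno)) {
      ss <- to_sense(sno$start, sno$end)
      snod <- data.frame(sno_id = sno$sno_id, sno_class = sno$sno_class,
                         intron_id = sno$intron_id,
                         s = ss[, 1L], e = ss[, 2L], stringsAsFactors = FALSE)
    }
    out[[i]] <- list(tu_id = id, chrom = tus$chrom[i], strand = str,
                     g_start = s0, g_end = e0, len = e0 - s0,
                     exons = data.frame(rank = ex$rank[o],
                                        s = exs[o, 1L], e = exs[o, 2L]),
                     introns = intr, snornas = snod)
  }
  out
}

# Sense offset -> genomic position (single base).
.sense_to_genomic <- function(layout, off) {
  if (layout$strand == "+") layout$g_start + off else layout$g_end - 1L - off
}

# Sense interval [s, e) -> genomic interval [start, end).
.sense_iv_to_genomic <- function(layout, s, e) {
  if (layout$strand == "+") {
    cbind(layout$g_start + s, layout$g_start + e)
  } else {
    cbind(layout$g_end - e, layout$g_end - s)
  }
}
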