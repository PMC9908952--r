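#' Generate a synthetic transcription-unit annotation
#'
#' Emits mono- and multi-exonic TUs spanning length strata from ~1 kb to
#' above 300 kb (log-uniform), on both strands across four synthetic
#' chromosomes. Every intron carries one branchpoint placed uniformly
#' 18-38 nt upstream of its 3' splice site; a configurable fraction of
#' sufficiently long introns host one snoRNA (CD- or H/ACA-box, equal
#' odds); dedicated rRNA units live on a separate chromosome. Output is
#' deterministic for a fixed seed.
#'
#' @param n_tu number of transcription units (>= 1).
#' @param seed RNG seed.
#' @param config a [sim_config()].
#' @return a `ticlip_annotation`.
#' @export
make_annotation <- function(n_tu, seed = 1L, config = sim_config()) {
  if (n_tu < 1L) stop("n_tu must be >= 1")
  set.seed(as.integer(seed))
  lr <- log10(config$tu_length_range)
  lens <- as.integer(round(10^stats::runif(n_tu, lr[1], lr[2])))
  strands <- sample(c("+", "-"), n_tu, replace = TRUE)
  chroms <- paste0("sim", (seq_len(n_tu) - 1L) %% 4L + 1L)

  min_exon <- 100L; max_exon <- 400L; min_intron <- 400L
  tu_rows <- exon_rows <- intron_rows <- sno_rows <- list()
  offsets <- c(sim1 = 1000L, sim2 = 1000L, sim3 = 1000L, sim4 = 1000L)
  sno_n <- 0L

  for (i in seq_len(n_tu)) {
    L <- lens[i]
    id <- sprintf("tu%04d", i)
    n_max <- (L + min_intron) %/% (min_exon + min_intron)
    n_ex <- if (stats::runif(1) < config$mono_exonic_fraction || n_max < 2L) {
      1L
    } else {
      sample(2L:max(2L, min(config$max_exons, n_max)), 1L)
    }
    # exon lengths, then introns fill the remainder (each >= min_intron)
    rem <- 0L
    while (n_ex > 1L) {
      ex_len <- sample(min_exon:max_exon, n_ex, replace = TRUE)
      rem <- L - sum(ex_len)
      if (rem >= min_intron * (n_ex - 1L)) break
      n_ex <- n_ex - 1L
    }
    if (n_ex == 1L) ex_len <- L
    if (n_ex == 1L) {
      ex_s <- 0L; ex_e <- L
      in_s <- integer(0); in_e <- integer(0)
    } else {
      w <- stats::runif(n_ex - 1L)
      extra <- floor((rem - min_intron * (n_ex - 1L)) * w / sum(w))
      in_len <- min_intron + extra
      in_len[n_ex - 1L] <- rem - sum(in_len[-(n_ex - 1L)])
      pos <- 0L
      ex_s <- ex_e <- integer(n_ex)
      in_s <- in_e <- integer(n_ex - 1L)
      for (k in seq_len(n_ex)) {
        ex_s[k] <- pos; ex_e[k] <- pos + ex_len[k]; pos <- ex_e[k]
        if (k < n_ex) { in_s[k] <- pos; in_e[k] <- pos + in_len[k]
                        pos <- in_e[k] }
      }
    }
    # place on chromosome
    chrom <- chroms[i]
    g0 <- offsets[[chrom]]
    offsets[[chrom]] <- g0 + L + 10000L
    str <- strands[i]
    sense2g <- function(s, e) {
      if (str == "+") cbind(g0 + s, g0 + e) else cbind(g0 + L - e, g0 + L - s)
    }
    tu_rows[[i]] <- data.frame(tu_id = id, chrom = chrom, start = g0,
                               end = g0 + L, strand = str,
                               stringsAsFactors = FALSE)
    eg <- sense2g(ex_s, ex_e)
    exon_rows[[i]] <- data.frame(tu_id = id, rank = seq_len(n_ex),
                                 start = eg[, 1L], end = eg[, 2L])
    if (n_ex > 1L) {
      d <- sample(18:38, n_ex - 1L, replace = TRUE)
      bp_off <- in_e - d          # sense offset of the branch adenosine
      ig <- sense2g(in_s, in_e)
      bp_g <- if (str == "+") g0 + bp_off else g0 + L - 1L - bp_off
      intron_rows[[i]] <- data.frame(
        intron_id = paste0(id, ".i", seq_len(n_ex - 1L)), tu_id = id,
        rank = seq_len(n_ex - 1L), start = ig[, 1L], end = ig[, 2L],
        bp_pos = bp_g, bp_dist = d, stringsAsFactors = FALSE)
      # snoRNA hosts: intron must fit snoRNA + 3' gap + margins
      for (k in seq_len(n_ex - 1L)) {
        il <- in_e[k] - in_s[k]
        if (il >= 400L && stats::runif(1) < config$sno_intron_fraction) {
          sno_len <- sample(70:140, 1L)
          gap3 <- sample(75:110, 1L)  # snoRNA 3' end to intron 3' end
          if (sno_len + gap3 + 20L > il) next
          s_e <- in_e[k] - gap3       # sense one-past-end of snoRNA
          s_s <- s_e - sno_len
          sg <- sense2g(s_s, s_e)
          sno_n <- sno_n + 1L
          sno_rows[[length(sno_rows) + 1L]] <- data.frame(
            sno_id = sprintf("sno%04d", sno_n),
            intron_id = paste0(id, ".i", k), tu_id = id,
            sno_class = sample(c("CD", "HACA"), 1L),
            start = sg[, 1L], end = sg[, 2L], stringsAsFactors = FALSE)
        }
      }
    }
  }

  rrna <- data.frame(unit_id = sprintf("rrna%02d", seq_len(config$n_rrna)),
                     chrom = "simR",
                     start = 1000L + (seq_len(config$n_rrna) - 1L) * 7000L,
                     end = 1000L + (seq_len(config$n_rrna) - 1L) * 7000L +
                       5000L,
                     strand = "+", stringsAsFactors = FALSE)
  empty_introns <- data.frame(intron_id = character(0), tu_id = character(0),
                              rank = integer(0), start = integer(0),
                              end = integer(0), bp_pos = integer(0),
                              bp_dist = integer(0), stringsAsFactors = FALSE)
  empty_sno <- data.frame(sno_id = character(0), intron_id = character(0),
                          tu_id = character(0), sno_class = character(0),
                          start = integer(0), end = integer(0),
                          stringsAsFactors = FALSE)
  chrom_lengths <- c(offsets + 1000L,
                     simR = max(rrna$end) + 1000L)
  ticlip_annotation(
    tus = do.call(rbind, tu_rows),
    exons = do.call(rbind, exon_rows),
    introns = if (length(intron_rows)) do.call(rbind, intron_rows)
              else empty_introns,
    snornas = if (length(sno_rows)) do.call(rbind, sno_rows) else empty_sno,
    rrna = rrna,
    chrom_lengths = stats::setNames(as.integer(chrom_lengths),
                                    names(chrom_lengths)))
}
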