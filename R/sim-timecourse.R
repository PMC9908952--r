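#' Simulate a DRB-release tiCLIP time course with ground truth
#'
#' For every (timepoint, replicate) library, emits `reads_per_library`
#' paired-end alignments whose latent structure follows the generator's
#' model: nascent transcripts extend
#' `min(TU length, pause_offset + velocity * t * 1000)` nt from the TSS;
#' cross-link positions are drawn from the configured factor model's
#' anchoring density restricted to transcribed sequence; each fully
#' transcribed intron undergoes the two splicing steps with probability
#' `1 - 2^(-dt/halflife)` each; excised introns persist as lariats with
#' probability `lariat_fraction`, and lariat-derived cDNAs truncate on the
#' branchpoint (circular origin, with a mismatched terminal base) or 1 nt
#' downstream of it (linear origin); snoRNA-host introns additionally emit
#' 3' termini at the snoRNA 3' end plus a class-specific extension offset;
#' a configurable fraction of reads come from rRNA units, and PCR
#' duplicates replicate a previous read's UMI and coordinates exactly.
#'
#' UMIs of independent fragments are kept distinct on the deduplication key
#' (UMI, chromosome, read1 5' coordinate, strand), so the ground-truth
#' non-duplicate count is exactly recoverable by deduplication.
#'
#' @param annotation a `ticlip_annotation` (from [make_annotation()] or
#'   [read_annotation()]).
#' @param config a [sim_config()].
#' @return a list with `libraries` (named list of `aligned_pairs`, one per
#'   timepoint x replicate, names `"<tp>.rep<i>"`) and `ground_truth`
#'   (one data.frame keyed by library and read name).
#' @export
simulate_timecourse <- function(annotation, config = sim_config()) {
  if (!nrow(annotation$tus)) stop("annotation contains no transcription units")
  layouts <- .sense_layout(annotation)
  tps <- config$timepoints
  libs <- list()
  gts <- list()
  idx <- 0L
  for (ti in seq_along(tps)) {
    for (bi in seq_along(config$barcodes)) {
      idx <- idx + 1L
      lab <- paste0(names(tps)[ti], ".rep", bi)
      sim <- .simulate_library(layouts, annotation, config,
                               minutes = unname(tps[ti]),
                               lib_seed = .sub_seed(config$seed, idx),
                               barcode = config$barcodes[bi],
                               tp_label = names(tps)[ti], lib_label = lab)
      libs[[lab]] <- sim$pairs
      gts[[lab]] <- sim$gt
    }
  }
  list(libraries = libs, ground_truth = do.call(rbind, gts))
}

# One library. All positions are generated in transcript-orientation
# ("sense") offsets and converted to genomic coordinates at the end.
.simulate_library <- function(layouts, annotation, config, minutes,
                              lib_seed, barcode, tp_label, lib_label) {
  set.seed(lib_seed)
  n <- config$reads_per_library
  pause <- config$pause_offset
  v <- config$velocity_kb_per_min * 1000
  hl <- config$splice_halflife_min
  fmin <- config$fragment_length_range[1]
  fmax <- config$fragment_length_range[2]

  n_dup <- if (n > 1L) stats::rbinom(1L, n - 1L, config$pcr_dup_rate) else 0L
  n_orig <- n - n_dup

  tu_len <- vapply(layouts, `[[`, numeric(1), "len")
  Lt <- pmin(tu_len, pause + v * minutes)

  is_rrna <- stats::runif(n_orig) < config$rrna_fraction &
    nrow(annotation$rrna) > 0L
  n_gene <- sum(!is_rrna)
  tu_of <- integer(n_orig)
  tu_of[!is_rrna] <- sample.int(length(layouts), n_gene, replace = TRUE,
                                prob = Lt)
  rr_of <- integer(n_orig)
  if (any(is_rrna)) {
    rr_of[is_rrna] <- sample.int(nrow(annotation$rrna), sum(is_rrna),
                                 replace = TRUE)
  }

  # per-read sense-space fragment description
  f1s <- f1e <- f2s <- f2e <- rep(NA_integer_, n_orig)
  state <- rep("nascent", n_orig)
  origin <- rep("none", n_orig)
  ext <- rep(NA_integer_, n_orig)
  term_mm <- rep(FALSE, n_orig)
  flen <- sample(fmin:fmax, n_orig, replace = TRUE)

  cap_fill <- function(ii, lt, scale = 50) {
    u <- stats::runif(length(ii), 0, 1 - exp(-lt / scale))
    x <- pmin(floor(-scale * log(1 - u)), lt - 2)
    f1s[ii] <<- as.integer(x + 1)
    f1e[ii] <<- as.integer(pmin(x + 1 + flen[ii], lt))
  }
  unif_fill <- function(ii, lt) {
    x <- sample.int(max(1, lt - 1), length(ii), replace = TRUE) - 1L
    f1s[ii] <<- as.integer(x + 1)
    f1e[ii] <<- as.integer(pmin(x + 1 + flen[ii], lt))
  }
  splice_p <- function(int_e) {
    if (is.infinite(minutes)) return(rep(1, length(int_e)))
    dt <- minutes - pmax(0, int_e - pause) / v
    ifelse(dt > 0, 1 - 2^(-dt / hl), 0)
  }

  if (any(is_rrna)) {
    ii <- which(is_rrna)
    ulen <- annotation$rrna$end[rr_of[ii]] - annotation$rrna$start[rr_of[ii]]
    x <- floor(stats::runif(length(ii)) * (ulen - 1))
    f1s[ii] <- as.integer(x + 1)
    f1e[ii] <- as.integer(pmin(x + 1 + flen[ii], ulen))
    state[ii] <- "rrna"
  }

  for (t in unique(tu_of[!is_rrna])) {
    ii <- which(tu_of == t & !is_rrna)
    ly <- layouts[[t]]
    lt <- Lt[t]
    model <- config$factor_model
    if (model == "CAP_ANCHORED") {
      cap_fill(ii, lt)
    } else if (model == "UNIFORM_NASCENT") {
      unif_fill(ii, lt)
    } else if (model == "EXON3P_EJC") {
      ex <- ly$exons
      elig <- which(ex$e <= lt & ex$e - ex$s >= 30)
      if (!length(elig)) { cap_fill(ii, lt); next }
      j <- elig[sample.int(length(elig), length(ii), replace = TRUE)]
      anchor <- ex$e[j]
      x <- as.integer(round(stats::rnorm(length(ii), anchor - 26, 8)))
      x <- pmax(ex$s[j], pmin(x, anchor - 2L))
      raw_end <- x + 1L + flen[ii]
      is_last <- ex$rank[j] == max(ex$rank)
      f1s[ii] <- x + 1L
      f1e[ii] <- pmin(raw_end, lt)
      # non-last exons: sample the downstream intron's splicing state
      for (q in which(!is_last)) {
        i_row <- which(ly$introns$s == anchor[q])
        if (!length(i_row)) next
        p <- splice_p(ly$introns$e[i_row])
        s1 <- stats::runif(1) < p
        s2 <- s1 && stats::runif(1) < p
        rid <- ii[q]
        if (s2) {
          state[rid] <- "post_second"
          if (raw_end[q] > anchor[q]) {
            nx <- ly$exons[ly$exons$s == ly$introns$e[i_row], , drop = FALSE]
            f1e[rid] <- anchor[q]
            if (nrow(nx)) {
              over <- raw_end[q] - anchor[q]
              f2s[rid] <- nx$s[1]
              f2e[rid] <- min(nx$s[1] + over, nx$e[1])
            }
          }
        } else if (s1) {
          state[rid] <- "post_first"
          f1e[rid] <- anchor[q]     # 3' terminus freed at the exon end
        } else {
          state[rid] <- "pre_first"
        }
      }
      state[ii[is_last]] <- "mature_end"
    } else { # INTRON3P_LARIAT_SNORNA
      if (is.null(ly$introns) || !any(ly$introns$e <= lt)) {
        cap_fill(ii, lt); next
      }
      intr <- ly$introns[ly$introns$e <= lt, , drop = FALSE]
      j <- sample.int(nrow(intr), length(ii), replace = TRUE)
      p <- splice_p(intr$e[j])
      s1 <- stats::runif(length(ii)) < p
      s2 <- s1 & stats::runif(length(ii)) < p
      lar <- s2 & stats::runif(length(ii)) < config$lariat_fraction
      circ <- lar & stats::runif(length(ii)) < config$circular_origin_fraction

      pre <- which(!s1)
      if (length(pre)) unif_fill(ii[pre], lt)
      state[ii[!s1]] <- "pre_first"

      i3 <- which(s1 & !lar)       # post-1st or debranched: intron 3' region
      if (length(i3)) {
        d <- sample(20:100, length(i3), replace = TRUE)
        x <- intr$e[j[i3]] - d
        f1s[ii[i3]] <- as.integer(x + 1)
        f1e[ii[i3]] <- as.integer(pmin(x + 1 + flen[ii[i3]], intr$e[j[i3]]))
        state[ii[i3]] <- ifelse(s2[i3], "debranched", "post_first")
      }
      lr <- which(lar)
      if (length(lr)) {
        bp <- intr$bp_off[j[lr]]
        f1s[ii[lr]] <- as.integer(ifelse(circ[lr], bp, bp + 1L))
        f1e[ii[lr]] <- as.integer(intr$e[j[lr]])
        state[ii[lr]] <- "post_second"
        origin[ii[lr]] <- ifelse(circ[lr], "circular", "linear")
        term_mm[ii[lr]] <- circ[lr]
      }
      # snoRNA-host debranched introns emit pre-snoRNA 3'-extension reads
      if (!is.null(ly$snornas) && nrow(ly$snornas)) {
        deb <- which(s1 & s2 & !lar)
        if (length(deb)) {
          host <- match(intr$intron_id[j[deb]], ly$snornas$intron_id)
          cand <- deb[!is.na(host) &
                        stats::runif(length(deb)) < config$sno_read_share]
          host <- match(intr$intron_id[j[cand]], ly$snornas$intron_id)
          if (length(cand)) {
            cls <- ly$snornas$sno_class[host]
            k_off <- integer(length(cand))
            hac <- cls == "HACA"
            k_off[hac] <- sample(config$haca_extension_offsets,
                                 sum(hac), replace = TRUE)
            k_off[!hac] <- sample.int(config$cd_extension_max,
                                      sum(!hac), replace = TRUE)
            se <- ly$snornas$e[host]
            terminus <- se - 1L + k_off
            rid <- ii[cand]
            f1e[rid] <- terminus + 1L
            f1s[rid] <- pmax(ly$snornas$s[host],
                             terminus + 1L - flen[rid])
            state[rid] <- "debranched"
            ext[rid] <- k_off
            f2s[rid] <- NA_integer_; f2e[rid] <- NA_integer_
          }
        }
      }
    }
  }

  # ---- sense fragments -> genomic paired reads --------------------------
  chrom <- character(n_orig); strand <- character(n_orig)
  g_start <- integer(n_orig); g_end <- integer(n_orig)
  unit <- character(n_orig)
  gi <- which(!is_rrna)
  tu_tab <- annotation$tus
  chrom[gi] <- vapply(layouts[tu_of[gi]], `[[`, character(1), "chrom")
  strand[gi] <- vapply(layouts[tu_of[gi]], `[[`, character(1), "strand")
  g_start[gi] <- as.integer(vapply(layouts[tu_of[gi]],
                                   function(l) l$g_start, numeric(1)))
  g_end[gi] <- as.integer(vapply(layouts[tu_of[gi]],
                                 function(l) l$g_end, numeric(1)))
  unit[gi] <- vapply(layouts[tu_of[gi]], `[[`, character(1), "tu_id")
  ri <- which(is_rrna)
  if (length(ri)) {
    chrom[ri] <- annotation$rrna$chrom[rr_of[ri]]
    strand[ri] <- annotation$rrna$strand[rr_of[ri]]
    g_start[ri] <- annotation$rrna$start[rr_of[ri]]
    g_end[ri] <- annotation$rrna$end[rr_of[ri]]
    unit[ri] <- annotation$rrna$unit_id[rr_of[ri]]
  }

  len1 <- f1e - f1s
  len2 <- ifelse(is.na(f2s), 0L, f2e - f2s)
  m <- len1 + len2
  r_eff <- pmin(config$read_length, m)
  # read1: first r_eff fragment nt; read2: last r_eff fragment nt
  a <- pmin(r_eff, len1)
  r1a_s <- f1s; r1a_e <- f1s + a
  r1b <- r_eff - a
  r1b_s <- ifelse(r1b > 0L, f2s, NA_integer_)
  r1b_e <- ifelse(r1b > 0L, f2s + r1b, NA_integer_)
  b <- pmin(r_eff, len2)
  r2b_s <- ifelse(b > 0L, f2e - b, NA_integer_)
  r2b_e <- ifelse(b > 0L, f2e, NA_integer_)
  r2a <- r_eff - b
  r2a_s <- ifelse(r2a > 0L, f1e - r2a, NA_integer_)
  r2a_e <- ifelse(r2a > 0L, f1e, NA_integer_)

  plus <- strand == "+"
  gx <- function(s, e) {   # sense interval -> genomic (start, end)
    list(s = ifelse(plus, g_start + s, g_end - e),
         e = ifelse(plus, g_start + e, g_end - s))
  }
  pack2 <- function(A, B) { # two optional sense parts -> ascending blocks
    hasB <- !is.na(B$s)
    ss <- ifelse(!hasB, as.character(A$s),
                 ifelse(plus, paste(A$s, B$s, sep = ","),
                        paste(B$s, A$s, sep = ",")))
    ee <- ifelse(!hasB, as.character(A$e),
                 ifelse(plus, paste(A$e, B$e, sep = ","),
                        paste(B$e, A$e, sep = ",")))
    list(s = ss, e = ee)
  }
  R1A <- gx(r1a_s, r1a_e)
  R1B <- list(s = ifelse(is.na(r1b_s), NA_integer_,
                         ifelse(plus, g_start + r1b_s, g_end - r1b_e)),
              e = ifelse(is.na(r1b_s), NA_integer_,
                         ifelse(plus, g_start + r1b_e, g_end - r1b_s)))
  R2A <- list(s = ifelse(is.na(r2a_s), NA_integer_,
                         ifelse(plus, g_start + r2a_s, g_end - r2a_e)),
              e = ifelse(is.na(r2a_s), NA_integer_,
                         ifelse(plus, g_start + r2a_e, g_end - r2a_s)))
  R2B <- list(s = ifelse(is.na(r2b_s), NA_integer_,
                         ifelse(plus, g_start + r2b_s, g_end - r2b_e)),
              e = ifelse(is.na(r2b_s), NA_integer_,
                         ifelse(plus, g_start + r2b_e, g_end - r2b_s)))
  r1 <- pack2(R1A, R1B)
  # read2 sense order is A then B; when only B exists it is the whole read
  hasA2 <- !is.na(R2A$s); hasB2 <- !is.na(R2B$s)
  r2s <- ifelse(hasA2 & hasB2,
                ifelse(plus, paste(R2A$s, R2B$s, sep = ","),
                       paste(R2B$s, R2A$s, sep = ",")),
                as.character(ifelse(hasA2, R2A$s, R2B$s)))
  r2e <- ifelse(hasA2 & hasB2,
                ifelse(plus, paste(R2A$e, R2B$e, sep = ","),
                       paste(R2B$e, R2A$e, sep = ",")),
                as.character(ifelse(hasA2, R2A$e, R2B$e)))

  # mismatches: planted terminal mismatch for circular-origin lariat reads,
  # plus a low background rate elsewhere in read1
  mm_pos <- rep("", n_orig); mm_base <- rep("", n_orig)
  r1_5p <- ifelse(plus, as.integer(.first_int(r1$s)),
                  as.integer(.last_int(r1$e)) - 1L)
  tm <- which(term_mm)
  if (length(tm)) {
    mm_pos[tm] <- as.character(r1_5p[tm])
    mm_base[tm] <- sample(c("A", "C", "G", "T"), length(tm), replace = TRUE)
  }
  bg <- which(!term_mm & stats::runif(n_orig) < config$bg_mismatch_rate & a > 2L)
  if (length(bg)) {
    off <- 1L + floor(stats::runif(length(bg)) * (a[bg] - 1L))
    gpos <- ifelse(plus[bg], as.integer(R1A$s[bg]) + off,
                   as.integer(R1A$e[bg]) - 1L - off)
    mm_pos[bg] <- as.character(gpos)
    mm_base[bg] <- sample(c("A", "C", "G", "T"), length(bg), replace = TRUE)
  }

  # UMIs, unique on the deduplication key among originals
  umi <- .random_seq(n_orig, config$umi_length)
  repeat {
    key <- paste(umi, chrom, r1_5p, strand, sep = "\r")
    dup <- duplicated(key)
    if (!any(dup)) break
    umi[dup] <- .random_seq(sum(dup), config$umi_length)
  }

  gt_orig <- data.frame(
    library = lib_label, timepoint = tp_label, minutes = minutes,
    barcode = barcode, unit_id = unit, chrom = chrom, strand = strand,
    crosslink_pos = ifelse(plus, as.integer(.first_int(r1$s)) - 1L,
                           as.integer(.last_int(r1$e))),
    frag3p_pos = ifelse(plus,
                        as.integer(ifelse(is.na(f2e), g_start + f1e,
                                          g_start + f2e)) - 1L,
                        as.integer(ifelse(is.na(f2e), g_end - f1e,
                                          g_end - f2e))),
    splice_state = state, lariat_origin = origin, ext_offset = ext,
    is_pcr_duplicate = FALSE, is_rrna = is_rrna,
    stringsAsFactors = FALSE)

  df <- data.frame(umi = umi, chrom = chrom, strand = strand,
                   r1_starts = r1$s, r1_ends = r1$e,
                   r2_starts = r2s, r2_ends = r2e,
                   mm_pos = mm_pos, mm_base = mm_base,
                   tlen = as.integer(m), stringsAsFactors = FALSE)
  if (n_dup > 0L) {
    src <- sample.int(n_orig, n_dup, replace = TRUE)
    df <- rbind(df, df[src, , drop = FALSE])
    gt <- rbind(gt_orig, gt_orig[src, , drop = FALSE])
    gt$is_pcr_duplicate <- c(rep(FALSE, n_orig), rep(TRUE, n_dup))
  } else {
    gt <- gt_orig
  }
  ord <- sample.int(nrow(df))
  df <- df[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  nm <- sprintf("%s.rd%06d", lib_label, seq_len(nrow(df)))
  gt$name <- nm
  rownames(df) <- rownames(gt) <- NULL
  pairs <- aligned_pairs(
    name = nm, umi = df$umi, barcode = barcode, chrom = df$chrom,
    strand = df$strand, r1_starts = df$r1_starts, r1_ends = df$r1_ends,
    r2_starts = df$r2_starts, r2_ends = df$r2_ends,
    mm_pos = df$mm_pos, mm_base = df$mm_base, tlen = df$tlen)
  attr(pairs, "timepoint") <- tp_label
  attr(pairs, "minutes") <- minutes
  attr(pairs, "barcode") <- barcode
  list(pairs = pairs, gt = gt[, c("library", "name", setdiff(names(gt),
                                                             c("library", "name")))])
}
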