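#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates the stages end-to-end: generate (or load) an annotation,
#' simulate the time-course libraries, write the alignments and
#' annotation, then per library demultiplex-check, deduplicate,
#' deconstruct into cross-link/3'CLIP tracks, normalize by the rRNA
#' factor, and write strand-split bedGraphs; finally compute the
#' spatiotemporal profiles, wave-velocity estimate, steady-state mature
#' profile clustering, lariat truncation signatures, snoRNA extension
#' calls and insert-size QC. A manifest with the config snapshot, seeds,
#' per-stage record counts and output file digests is written as JSON.
#'
#' @param config a YAML file path or a list with (at least) `out_dir`;
#'   optional entries: `seed`, `n_tu`, and any [sim_config()] argument
#'   under `sim`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) {
    stop("config validation: 'out_dir' is required")
  }
  seed <- as.integer(config$seed %||% 1L)
  n_tu <- as.integer(config$n_tu %||% 40L)
  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  log_line <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  manifest <- list(config = config, seed = seed, stages = list(),
                   files = character(0))

  ann <- make_annotation(n_tu, seed = seed, config = cfg)
  ann_files <- write_annotation(ann, file.path(out, "annotation"))
  log_line("annotation", nrow(ann$tus), " TUs, ", nrow(ann$introns),
           " introns, ", nrow(ann$snornas), " snoRNAs")
  manifest$stages$annotation <- list(n_tu = nrow(ann$tus),
                                     n_introns = nrow(ann$introns),
                                     n_snorna = nrow(ann$snornas))

  sim <- simulate_timecourse(ann, cfg)
  utils::write.table(sim$ground_truth,
                     file.path(out, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  barcode_table <- stats::setNames(
    paste0("rep", seq_along(cfg$barcodes)), cfg$barcodes)
  tracks_x <- list(); tracks_3p <- list()
  lib_stats <- list()
  for (lab in names(sim$libraries)) {
    pairs <- sim$libraries[[lab]]
    sam <- file.path(out, paste0(lab, ".sam"))
    write_alignments(pairs, sam, ann$chrom_lengths)
    dm <- demultiplex(pairs, barcode_table)
    n_und <- nrow(dm$undetermined)
    dd <- deduplicate(pairs)
    nf <- rrna_factor(dd, ann$rrna)
    tx <- scale_track(crosslink_sites(dd, lab, attr(pairs, "timepoint")),
                      nf)
    t3 <- scale_track(three_prime_sites(dd, library_label = lab,
                                        timepoint_label =
                                          attr(pairs, "timepoint")), nf)
    write_bedgraph(tx, file.path(out, paste0(lab, ".xlink")))
    write_bedgraph(t3, file.path(out, paste0(lab, ".3p")))
    tracks_x[[lab]] <- tx
    tracks_3p[[lab]] <- t3
    st <- list(reads_in = nrow(pairs), undetermined = n_und,
               deduplicated = nrow(dd),
               duplicates_removed = attr(dd, "n_duplicates"),
               rrna_reads = nf$rrna_read_count, rrna_factor = nf$factor,
               crosslink_sites = nrow(tx),
               crosslink_dropped = attr(tx, "n_dropped"))
    if (st$crosslink_sites > st$deduplicated) {
      stop("pipeline invariant violated in ", lab,
           ": more sites than deduplicated pairs")
    }
    log_line(lab, st$reads_in, " reads -> ", st$deduplicated,
             " unique; rRNA factor ", format(nf$factor, digits = 4))
    lib_stats[[lab]] <- st
  }
  manifest$stages$libraries <- lib_stats

  # profiles per timepoint (replicate tracks pooled)
  tps <- cfg$timepoints
  prof_by_tp <- list()
  for (tp in names(tps)) {
    labs <- grep(paste0("^", tp, "\\."), names(tracks_x), value = TRUE)
    pooled <- do.call(rbind, lapply(labs, function(l) {
      as.data.frame(tracks_x[[l]])
    }))
    tr <- site_track(pooled$chrom, pooled$strand, pooled$pos,
                     pooled$weight, timepoint_label = tp)
    prof_by_tp[[tp]] <- spatiotemporal_matrix(tr, ann)
  }
  wave <- tryCatch(
    estimate_wave_velocity(prof_by_tp, tps),
    error = function(e) { log_line("velocity", "skipped: ",
                                   conditionMessage(e)); NULL })
  if (!is.null(wave)) {
    manifest$stages$wave <- list(
      velocity_kb_per_min = wave$velocity_kb_per_min,
      r_squared = wave$r_squared)
    log_line("velocity", format(wave$velocity_kb_per_min, digits = 3),
             " kb/min")
  }

  # steady-state mature-profile clustering across replicates
  ss <- names(tps)[is.infinite(tps)]
  if (length(ss) && length(cfg$barcodes) >= 2L) {
    mats <- lapply(grep(paste0("^", ss[1L], "\\."), names(tracks_x),
                        value = TRUE),
                   function(l) mature_profile_matrix(tracks_x[[l]], ann))
    common <- Reduce(intersect, lapply(mats, rownames))
    if (length(common) > 3L) {
      mats <- lapply(mats, function(m) m[common, , drop = FALSE])
      cl <- kmeans_profile_groups(mats, k = 3L, seed = seed)
      cl_df <- cl$assignments
      utils::write.table(cl_df, file.path(out, "cluster_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$clustering <- lapply(cl$groups, length)
    }
  }

  # lariat & snoRNA signatures on pooled steady-state data
  if (length(ss)) {
    labs <- grep(paste0("^", ss[1L], "\\."), names(sim$libraries),
                 value = TRUE)
    dd_ss <- deduplicate(as_aligned_pairs(
      do.call(rbind, lapply(sim$libraries[labs], as.data.frame)),
      validate = FALSE))
    if (nrow(ann$introns)) {
      ts <- truncation_signature(five_prime_sites(dd_ss), ann, "bp")
      manifest$stages$truncation_peaks <- ts$peak_offsets
    }
    if (nrow(ann$snornas)) {
      prof <- snorna_window_coverage(three_prime_sites(dd_ss), ann)
      manifest$stages$snorna <- lapply(prof, function(p) {
        pk <- extension_peaks(p)
        list(peaks = pk$peak_offsets, max_extension = pk$max_extension)
      })
    }
  }
  qc <- median_insert_size(sim$libraries)
  manifest$stages$median_insert_nt <- as.list(qc$median_nt)

  files <- list.files(out, full.names = TRUE, recursive = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
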