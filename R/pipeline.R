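# End-to-end orchestration: reference -> library simulation -> splitting ->
# refinement -> collapse -> classification, with a run report that records
# every count and conservation identity.  A single master seed feeds named
# substreams so each stage is independently reproducible.

flic_config_defaults <- function() list(
  seed = 1L,
  # reference
  sirv = TRUE, long = TRUE, background_genes = 50L,
  # expression / cDNA
  total_molecules = 20000L, spikein_fraction = 0.02,
  tso_artifact_rate = 0.02, polya_len = 30L,
  # capture + size selection
  knee_bp = 2000, floor_retention = 0, steepness = 35, midpoint_bp = 8000,
  long_min = 2000, short_min = 500,
  # concatenation
  monomer = FALSE, dimer_rate = 0.777, tetramer_rate = 0.727,
  n_dimer_arrays = NA_integer_, n_tetramer_arrays = NA_integer_,
  flip_prob = 0.5,
  # errors
  per_base_error = 0.001,
  # split / refine
  max_edit = 3L, min_a_run = 20L, max_mismatch = 1L, min_len = 80L,
  # collapse / classify
  d5 = 100, d3 = 30, gap = 10, min_ccs = 2L, end_tolerance = 50,
  jitter_sd5 = 0, jitter_sd3 = 0)

#' Pipeline configuration
#'
#' All stage parameters with their defaults; unknown keys are rejected.
#'
#' @param ... overrides of the default parameters.
#' @return named list of class `flic_config`.
#' @export
flic_config <- function(...) {
  cfg <- flic_config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "flic_config")
}

#' @rdname flic_config
#' @param cfg `flic_config`.
#' @param path file path for the plain `key = value` serialization.
#' @export
write_config <- function(cfg, path) {
  writeLines(paste(names(cfg), vapply(cfg, format, character(1)),
                   sep = " = "), path)
  invisible(path)
}

#' @rdname flic_config
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    v <- p[2]
    if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else if (!is.na(suppressWarnings(as.numeric(v)))) as.numeric(v)
    else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(flic_config, vals)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  write_config(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the full in-silico workflow
#'
#' Executes reference synthesis, library simulation, deconcatenation,
#' refinement, collapse and classification under one configuration and
#' returns every intermediate plus a report with conserved-count
#' identities.  Re-running with the same configuration reproduces
#' byte-identical outputs.
#'
#' @param cfg [flic_config()].
#' @param ref optional pre-built reference (list(genome, annotation)); by
#'   default one is generated from the config seed.
#' @param expression optional pre-computed expression table (to share a
#'   profile between conditions).
#' @return list of class `flic_run` (reference, designs, molecules,
#'   fractions, sim, split, eff, flnc, aligned, clusters, classified,
#'   recall, report, ...).
#' @export
run_pipeline <- function(cfg = flic_config(), ref = NULL, expression = NULL) {
  stopifnot(inherits(cfg, "flic_config"))
  s <- function(stream) substream_seed(cfg$seed, stream)
  if (is.null(ref))
    ref <- make_reference(sirv = cfg$sirv, long = cfg$long,
                          background_genes = cfg$background_genes,
                          seed = s("ref"))
  ann <- ref$annotation

  expr <- expression %||%
    sample_expression(ann, cfg$total_molecules,
                      spikein_fraction = cfg$spikein_fraction,
                      seed = s("expression"))
  mols <- synthesize_cdna(expr, ann, ref$genome,
                          tso_artifact_rate = cfg$tso_artifact_rate,
                          polya_len = cfg$polya_len, seed = s("cdna"))
  kept <- capture_filter(mols, knee_bp = cfg$knee_bp,
                         floor_retention = cfg$floor_retention,
                         steepness = cfg$steepness,
                         midpoint_bp = cfg$midpoint_bp, seed = s("capture"))
  n_artifact <- sum(mols$artifact != "none")
  n_capture_dropped <- nrow(mols) - n_artifact - nrow(kept)
  fr <- size_select(kept, long_min = cfg$long_min, short_min = cfg$short_min)

  if (cfg$monomer) {
    designs <- list(make_array_design(1, seed = s("design")))
    pool <- rbind(fr$long, fr$short)
    sim <- concatenate(pool, designs[[1]], full_array_rate = 1,
                       seed = s("ligation"), flip_prob = cfg$flip_prob)
  } else {
    designs <- list(make_array_design(2, seed = s("design_dimer")),
                    make_array_design(4, seed = s("design_tetramer")))
    sim_d <- concatenate(fr$long, designs[[1]],
                         full_array_rate = cfg$dimer_rate,
                         seed = s("ligation_dimer"),
                         n_arrays = if (is.na(cfg$n_dimer_arrays)) NULL
                                    else cfg$n_dimer_arrays,
                         flip_prob = cfg$flip_prob)
    sim_t <- concatenate(fr$short, designs[[2]],
                         full_array_rate = cfg$tetramer_rate,
                         seed = s("ligation_tetramer"),
                         n_arrays = if (is.na(cfg$n_tetramer_arrays)) NULL
                                    else cfg$n_tetramer_arrays,
                         flip_prob = cfg$flip_prob)
    sim <- list(reads = rbind(sim_d$reads, sim_t$reads),
                truth = rbind(sim_d$truth, sim_t$truth),
                lost = c(sim_d$lost, sim_t$lost))
  }
  sim <- apply_hifi_errors(sim, per_base_error = cfg$per_base_error,
                           seed = s("errors"))

  split <- split_reads(sim$reads, designs, max_edit = cfg$max_edit)
  eff <- array_efficiency(split, designs)
  barcodes <- unique(unlist(lapply(designs, `[[`, "barcodes")))
  flnc <- refine_reads(split$sreads, barcodes = barcodes,
                       max_edit = cfg$max_edit, min_a_run = cfg$min_a_run,
                       max_mismatch = cfg$max_mismatch,
                       min_len = cfg$min_len)
  matched <- match_sreads_to_truth(split, sim$truth)
  aligned <- align_truth(flnc, matched, ann, jitter_sd5 = cfg$jitter_sd5,
                         jitter_sd3 = cfg$jitter_sd3, seed = s("jitter"))
  clusters <- collapse_flnc(
    data.frame(id = aligned$id, chain = I(aligned$chain)),
    d5 = cfg$d5, d3 = cfg$d3, gap = cfg$gap)
  clusters_pass <- filter_by_support(clusters, cfg$min_ccs)
  classified <- classify_isoforms(clusters_pass, ann,
                                  end_tolerance = cfg$end_tolerance)
  spike_ids <- ann$transcripts$transcript_id[
    ann$transcripts$class == "sirv_isoform"]
  recall <- if (length(spike_ids)) sirv_recall(classified, spike_ids)
            else NULL
  fus_cand <- fusion_candidates_from_truth(flnc, matched, sim$truth, ann)
  fusions <- fusion_filter(fus_cand)

  report <- list(
    config_hash = config_hash(cfg),
    counts = list(
      molecules = nrow(mols),
      tso_artifacts = n_artifact,
      capture_dropped = n_capture_dropped,
      size_discarded = nrow(fr$discarded),
      packed = sum(sim$reads$n_segments_true),
      ligation_lost = length(sim$lost),
      unligated = nrow(fr$long) + nrow(fr$short) -
        sum(sim$reads$n_segments_true) - length(sim$lost),
      reads = nrow(sim$reads),
      sreads = eff$n_sreads,
      flnc = sum(flnc$status == "flnc"),
      clusters = nrow(clusters),
      clusters_pass = nrow(clusters_pass)),
    full_array_fraction = eff$full_array_fraction,
    per_design = eff$per_design,
    categories = table(classified$category),
    recall = recall)
  report$conserved <- with(report$counts,
    molecules == tso_artifacts + capture_dropped + size_discarded +
      packed + ligation_lost + unligated)

  structure(list(cfg = cfg, reference = ref, designs = designs,
                 expression = expr, molecules = mols, fractions = fr,
                 sim = sim, split = split, eff = eff, flnc = flnc,
                 matched = matched, aligned = aligned, clusters = clusters,
                 clusters_pass = clusters_pass, classified = classified,
                 recall = recall, fusion_candidates = fus_cand,
                 fusions = fusions, report = report),
            class = "flic_run")
}

#' @export
print.flic_run <- function(x, ...) {
  c <- x$report$counts
  cat("flic_run:", c$molecules, "molecules ->", c$reads, "reads ->",
      c$sreads, "s-reads ->", c$flnc, "FLNC ->", c$clusters_pass,
      "HQ isoforms\n")
  if (!is.null(x$recall))
    cat("  spike-in recall:", x$recall$recall, "% (",
        x$recall$n_detected, "isoforms )\n")
  cat("  full-array fraction:",
      sprintf("%.3f", x$report$full_array_fraction),
      "| conserved counts:", x$report$conserved, "\n")
  invisible(x)
}

#' Write the main outputs of a run to a directory
#'
#' Reference FASTA/GTF, concatemer FASTQ, truth TSV, s-read FASTA, FLNC
#' status TSV, HQ isoform BED12 and the classification TSV.
#'
#' @param run `flic_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(run$reference$genome, file.path(dir, "reference.fasta"))
  write_gtf(run$reference$annotation, file.path(dir, "reference.gtf"))
  bc <- unlist(lapply(run$designs, function(d) {
    if (!length(d$barcodes)) return(NULL)
    setNames(d$barcodes, paste0(d$design_id, "_", seq_along(d$barcodes)))
  }))
  if (length(bc)) write_fasta(bc, file.path(dir, "barcodes.fasta"))
  write_fastq(setNames(run$sim$reads$sequence, run$sim$reads$read_id),
              file.path(dir, "reads.fastq"))
  write_tsv(run$sim$truth, file.path(dir, "truth.tsv"))
  write_fasta(setNames(run$split$sreads$sequence, run$split$sreads$sread_id),
              file.path(dir, "sreads.fasta"))
  write_tsv(run$flnc[, c("flnc_id", "sread_id", "status", "polya_len")],
            file.path(dir, "flnc_status.tsv"))
  write_bed12(data.frame(name = run$clusters_pass$cluster_id,
                         chain = I(run$clusters_pass$chain)),
              file.path(dir, "hq_isoforms.bed"))
  write_tsv(run$classified, file.path(dir, "classification.tsv"))
  invisible(dir)
}
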