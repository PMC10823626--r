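# Shared fixtures, all generated in code.  Heavy simulations are cached per
# session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# one contig, two multi-isoform genes (+), one mono gene (+), one gene (-)
tiny_annotation <- function() {
  tx <- data.frame(
    transcript_id = c("tA1", "tA2", "tB1", "tD1"),
    gene_id = c("gA", "gA", "gB", "gD"),
    contig_id = "c1", strand = c("+", "+", "+", "-"),
    class = "background")
  ex <- data.frame(
    transcript_id = c("tA1", "tA1", "tA1", "tA2", "tA2", "tB1",
                      "tD1", "tD1"),
    start = c(100, 300, 600, 100, 600, 5000, 8000, 8500),
    end = c(200, 400, 700, 200, 700, 5600, 8200, 8800))
  flic_annotation(tx, ex)
}

# molecule table with random inserts; no reference needed
random_molecules <- function(n, len_min = 200, len_max = 600, seed = 1) {
  withr::with_seed(seed, {
    lens <- sample(len_min:len_max, n, replace = TRUE)
    data.frame(
      molecule_id = sprintf("m%05d", seq_len(n)),
      transcript_id = sprintf("t%05d", seq_len(n)),
      artifact = "none",
      sequence = vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1)),
      length = lens)
  })
}

random_chain <- function(contig = "c1", strand = "+", n_exons = 3,
                         origin = 1000) {
  len <- sample(80:300, n_exons, replace = TRUE)
  gapw <- sample(60:200, n_exons, replace = TRUE)
  starts <- origin + cumsum(gapw) + cumsum(c(0, head(len, -1)))
  new_chain(contig, strand, starts, starts + len)
}

small_run <- function() {
  cached("small_run", run_pipeline(
    flic_config(seed = 5, total_molecules = 4000, background_genes = 10)))
}

# error-free, spike-only run whose molecules all stay in the short size
# fraction (insert lengths 600-1,900 bp)
clean_spike_run <- function() {
  cached("clean_spike_run", {
    ref <- make_sirv_like_module(7, 69, 600, 1900, seed = 21)
    run_pipeline(
      flic_config(seed = 13, total_molecules = 6000, spikein_fraction = 1,
                  background_genes = 0, long = FALSE,
                  tso_artifact_rate = 0, per_base_error = 0),
      ref = ref)
  })
}

# full-scale mixed dimer/tetramer run: 20,000 arrays at the published
# efficiencies, array mix in the proportion implied by the published
# dimer/tetramer s-read totals
mixed_run <- function() {
  cached("mixed_run", run_pipeline(
    flic_config(seed = 11, total_molecules = 100000,
                background_genes = 50,
                n_dimer_arrays = 9440, n_tetramer_arrays = 10560)))
}

# two-condition simulation: condition A overexpresses a minor gene set
# 10-fold relative to the comparator drawn from the same profile
de_sim <- function() {
  cached("de_sim", {
    ref <- make_reference(sirv = FALSE, long = FALSE,
                          background_genes = 50, seed = 72)
    ann <- ref$annotation
    expr_comp <- sample_expression(ann, 12000, spikein_fraction = 0,
                                   sdlog = 0.6, seed = 73)
    gene_w <- tapply(expr_comp$tpm, ann$transcripts$gene_id, sum)
    up <- names(sort(gene_w))[1:3]
    scale <- ifelse(ann$transcripts$gene_id %in% up, 10, 1)
    w <- expr_comp$tpm * scale
    expr_tum <- expr_comp
    expr_tum$tpm <- w / sum(w) * 1e6
    expr_tum$copies <- as.integer(withr::with_seed(74,
      rmultinom(1, 12000, w)))
    mk <- function(seed, expr) run_pipeline(
      flic_config(seed = seed, total_molecules = 12000,
                  spikein_fraction = 0, tso_artifact_rate = 0,
                  min_ccs = 1),
      ref = ref, expression = expr)
    run_t <- mk(75, expr_tum)
    run_c <- mk(76, expr_comp)
    sup_of <- function(run) {
      fsm <- run$classified[run$classified$category == "FSM", ]
      setNames(fsm$support, fsm$matched_transcript)
    }
    st <- sup_of(run_t); sc <- sup_of(run_c)
    tx <- ann$transcripts
    recs <- data.frame(
      id = tx$transcript_id, gene_id = tx$gene_id, category = "FSM",
      reads_tumor = unname(ifelse(is.na(st[tx$transcript_id]), 0,
                           st[tx$transcript_id])),
      reads_comp = unname(ifelse(is.na(sc[tx$transcript_id]), 0,
                          sc[tx$transcript_id])),
      tpm_tumor = expr_tum$tpm[match(tx$transcript_id,
                                     expr_tum$transcript_id)],
      tpm_comp = expr_comp$tpm[match(tx$transcript_id,
                                     expr_comp$transcript_id)])
    list(ref = ref, up = up, gene_share = sum(gene_w[up]) / sum(gene_w),
         records = recs, run_t = run_t, run_c = run_c)
  })
}

# three replicate runs over one reference, merged into a comparison matrix
replicate_matrix <- function() {
  cached("replicate_matrix", {
    ref <- make_reference(sirv = TRUE, long = FALSE,
                          background_genes = 15, seed = 81)
    runs <- lapply(1:3, function(r) run_pipeline(
      flic_config(seed = 81 + r, total_molecules = 5000,
                  min_ccs = 1),
      ref = ref))
    samples <- lapply(runs, function(run)
      classified_with_chains(run$clusters_pass, run$classified))
    names(samples) <- paste0("rep", 1:3)
    list(ref = ref, runs = runs, mat = merge_samples(samples))
  })
}
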