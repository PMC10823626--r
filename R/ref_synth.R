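# Synthetic reference generator.
#
# Emulates a SIRV-Set-4-like spike-in panel: a multi-isoform module (seven
# genes, 69 isoforms, 160-2,940 bp spliced lengths, mixing mono- and
# multi-exonic forms, alternative start/stop sites and antisense
# transcripts), a long mono-exonic module (roughly 4/6/8/10/12 kb, three
# transcripts each) and an optional multi-gene background standing in for a
# complex total-RNA sample.  Actual commercial sequences are never
# reproduced; only the structural properties matter downstream.

# One gene locus: a master exon skeleton shared by all isoforms of the gene,
# so isoforms re-use splice sites (alternative starts/ends, skipped exons).
make_gene_locus <- function(length_max) {
  n_exon <- sample(5:9, 1L)
  exon_len <- c(sample(80:120, 1L),
                sample(100:400, n_exon - 1L, replace = TRUE))
  # master spliced length must exceed length_max so any target is reachable
  while (sum(exon_len) < length_max + 80)
    exon_len <- exon_len + ceiling((length_max + 80 - sum(exon_len)) / n_exon)
  intron_len <- sample(60:300, n_exon - 1L, replace = TRUE)
  starts <- cumsum(c(0L, head(exon_len, -1L) + intron_len))
  list(exon_starts = as.integer(starts),
       exon_ends = as.integer(starts + exon_len),
       span = sum(exon_len) + sum(intron_len))
}

# Draw one isoform over a locus: either a mono-exon of exact length L placed
# inside the locus span, or a consecutive run of master exons (optionally
# skipping one internal exon) with terminal exons trimmed to hit L exactly.
draw_isoform <- function(locus, L, force = c("any", "mono", "multi")) {
  force <- match.arg(force)
  n <- length(locus$exon_starts)
  lens <- locus$exon_ends - locus$exon_starts
  mono <- switch(force, mono = TRUE, multi = FALSE,
                 any = runif(1) < 0.25)
  if (mono || n == 1L) {
    off <- locus$exon_starts[1L] + sample.int(locus$span - L + 1L, 1L) - 1L
    return(list(starts = off, ends = off + L))
  }
  # pick a start exon small enough that at least two exons are needed
  cand <- which(lens < L)
  cand <- cand[cand < n]
  if (length(cand) == 0L) return(NULL)
  s <- cand[sample.int(length(cand), 1L)]
  idx <- s
  skip_done <- FALSE
  while (sum(lens[idx]) < L && max(idx) < n) {
    nxt <- max(idx) + 1L
    if (!skip_done && runif(1) < 0.25 && nxt < n) {   # skip one internal exon
      nxt <- nxt + 1L
      skip_done <- TRUE
    }
    idx <- c(idx, nxt)
  }
  if (sum(lens[idx]) < L || length(idx) < 2L) return(NULL)   # retry
  starts <- locus$exon_starts[idx]
  ends <- locus$exon_ends[idx]
  excess <- sum(ends - starts) - L
  k <- length(idx)
  trim_last <- min(excess, (ends[k] - starts[k]) - 20L)
  trim_first <- excess - trim_last
  if (trim_first > (ends[1L] - starts[1L]) - 20L) return(NULL)
  ends[k] <- ends[k] - trim_last
  starts[1L] <- starts[1L] + trim_first
  list(starts = starts, ends = ends)
}

# Write canonical splice dinucleotides (GT..AG on the transcript strand) at
# every master intron of a locus, in place on the contig sequence.
write_splice_sites <- function(seq, locus, strand) {
  n <- length(locus$exon_starts)
  if (n < 2L) return(seq)
  donors <- locus$exon_ends[-n]        # intron starts (0-based)
  acceptors <- locus$exon_starts[-1L]  # intron ends (0-based, half-open)
  for (i in seq_len(n - 1L)) {
    if (strand == "+") {
      substr(seq, donors[i] + 1L, donors[i] + 2L) <- "GT"
      substr(seq, acceptors[i] - 1L, acceptors[i]) <- "AG"
    } else {
      substr(seq, donors[i] + 1L, donors[i] + 2L) <- "CT"
      substr(seq, acceptors[i] - 1L, acceptors[i]) <- "AC"
    }
  }
  seq
}

make_module <- function(n_genes, n_isoforms, length_min, length_max, seed,
                        class, prefix, flank = 200L, antisense = TRUE) {
  if (n_isoforms < n_genes) stop("n_isoforms must be >= n_genes")
  if (length_min < 50) stop("length_min below 50 bp cannot host exons")
  if (length_min > length_max) stop("length_min must not exceed length_max")
  with_seed(seed, {
    per_gene <- rep(n_isoforms %/% n_genes, n_genes)
    extra <- n_isoforms %% n_genes
    if (extra > 0) per_gene[seq_len(extra)] <- per_gene[seq_len(extra)] + 1L
    genome <- character(0)
    tx_rows <- list()
    ex_rows <- list()
    for (g in seq_len(n_genes)) {
      locus <- make_gene_locus(length_max)
      contig <- paste0(prefix, g)
      gene_id <- paste0(prefix, "G", g)
      strand <- sample(c("+", "-"), 1L)
      seq <- random_dna(locus$span + 2L * flank)
      # shift locus coordinates by the upstream flank, then stamp GT..AG
      locus$exon_starts <- locus$exon_starts + flank
      locus$exon_ends <- locus$exon_ends + flank
      seq <- write_splice_sites(seq, locus, strand)
      genome[contig] <- seq
      seen <- list()
      n_iso <- per_gene[g]
      for (i in seq_len(n_iso)) {
        force <- "any"
        if (g == 1L && i == 1L) force <- "mono"
        if (g == 1L && i == 2L && n_iso >= 2L) force <- "multi"
        anti <- antisense && g == 2L && i == n_iso
        if (anti) force <- "mono"
        iso_strand <- if (anti) { if (strand == "+") "-" else "+" } else strand
        iso <- NULL
        for (try in seq_len(200L)) {
          L <- length_min + sample.int(length_max - length_min + 1L, 1L) - 1L
          cand <- if (anti) {
            # anchored on a sense exon so opposite-strand exon overlap is
            # guaranteed (keeps the Antisense category testable)
            s2 <- locus$exon_starts[min(2L, length(locus$exon_starts))]
            list(starts = s2, ends = s2 + L)
          } else draw_isoform(locus, L, force = force)
          if (is.null(cand)) next
          # isoforms of a panel must be separable under the default
          # collapse rule, or downstream recall is ill-defined
          cand_chain <- new_chain(contig, iso_strand, cand$starts, cand$ends)
          if (!any(vapply(seen, function(prev)
            mergeable(cand_chain, prev), logical(1)))) {
            iso <- cand
            seen <- c(seen, list(cand_chain))
            break
          }
        }
        if (is.null(iso)) stop("could not draw isoform for gene ", gene_id)
        tid <- paste0(gene_id, "_I", i)
        tx_rows[[tid]] <- data.frame(transcript_id = tid, gene_id = gene_id,
                                     contig_id = contig, strand = iso_strand,
                                     class = class)
        ex_rows[[tid]] <- data.frame(transcript_id = tid,
                                     start = iso$starts, end = iso$ends)
      }
    }
    ann <- flic_annotation(do.call(rbind, tx_rows), do.call(rbind, ex_rows))
    list(genome = genome, annotation = ann)
  })
}

#' Generate a SIRV-like multi-isoform spike-in module
#'
#' Builds `n_genes` synthetic loci carrying `n_isoforms` transcripts in
#' total, with spliced lengths uniform in `[length_min, length_max]`.
#' Isoforms of a gene share a master exon skeleton (so splice sites recur
#' across isoforms, with alternative starts/ends and occasional exon
#' skipping), at least one transcript is mono-exonic and one multi-exonic
#' (when `n_isoforms >= 2`), and when `n_genes >= 2` one transcript is
#' antisense within an existing gene span.  Splice sites are written as
#' GT..AG on the transcript strand.  Defaults mirror a 7-gene / 69-isoform
#' / 160-2,940 bp spike-in panel.
#'
#' @param n_genes number of gene loci (each on its own contig).
#' @param n_isoforms total transcripts across loci (`>= n_genes`).
#' @param length_min,length_max spliced-length bounds in bp
#'   (`length_min >= 50`).
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param prefix contig / gene id prefix.
#' @return list with `genome` (named character vector of contig sequences)
#'   and `annotation` (a [flic_annotation()]).
#' @export
make_sirv_like_module <- function(n_genes = 7, n_isoforms = 69,
                                  length_min = 160, length_max = 2940,
                                  seed = 1, prefix = "SIM") {
  make_module(n_genes, n_isoforms, length_min, length_max, seed,
              class = "sirv_isoform", prefix = prefix)
}

#' Generate a long mono-exonic spike-in module
#'
#' One mono-exonic transcript per copy per nominal size, each on its own
#' contig, flagged `long_sirv`.  Emitted lengths are drawn within 1% of the
#' nominal size (the panel sizes are nominal, not exact).
#'
#' @param sizes nominal transcript sizes in bp (each `>= 1000`).
#' @param copies_per_size transcripts per size.
#' @param seed integer seed.
#' @param prefix contig / gene id prefix.
#' @return list(genome, annotation) as in [make_sirv_like_module()].
#' @export
make_long_module <- function(sizes = c(4000, 6000, 8000, 10000, 12000),
                             copies_per_size = 3, seed = 1,
                             prefix = "LONG") {
  if (length(sizes) == 0L) stop("sizes must be non-empty")
  if (any(sizes < 1000)) stop("long-module sizes must be >= 1000 bp")
  with_seed(seed, {
    genome <- character(0)
    tx <- list(); ex <- list()
    k <- 0L
    for (s in sizes) {
      for (cp in seq_len(copies_per_size)) {
        k <- k + 1L
        L <- as.integer(round(s * runif(1, 0.99, 1.01)))
        contig <- paste0(prefix, k)
        gene_id <- paste0(prefix, "G", k)
        tid <- paste0(gene_id, "_I1")
        genome[contig] <- random_dna(L + 400L)
        tx[[tid]] <- data.frame(transcript_id = tid, gene_id = gene_id,
                                contig_id = contig, strand = "+",
                                class = "long_sirv")
        ex[[tid]] <- data.frame(transcript_id = tid, start = 200L,
                                end = 200L + L)
      }
    }
    list(genome = genome,
         annotation = flic_annotation(do.call(rbind, tx), do.call(rbind, ex)))
  })
}

#' Generate a background gene module
#'
#' Same generator as the spike-in module but flagged `background`; stands in
#' for the complexity of a total-RNA sample.  The default length range
#' (400-4,000 bp) populates both the short and the long size-selection
#' fraction.
#'
#' @inheritParams make_sirv_like_module
#' @export
make_background_module <- function(n_genes = 50, n_isoforms = 150,
                                   length_min = 400, length_max = 4000,
                                   seed = 1, prefix = "BG") {
  make_module(n_genes, n_isoforms, length_min, length_max, seed,
              class = "background", prefix = prefix)
}

#' Assemble a full synthetic reference
#'
#' @param sirv,long include the isoform / long spike-in modules.
#' @param background_genes number of background genes (0 disables; isoform
#'   count is three per gene).
#' @param seed integer seed (modules draw named substreams from it).
#' @param ... passed to [make_sirv_like_module()].
#' @return list(genome, annotation).
#' @export
make_reference <- function(sirv = TRUE, long = TRUE, background_genes = 0,
                           seed = 1, ...) {
  parts <- list()
  if (sirv)
    parts$sirv <- make_sirv_like_module(seed = substream_seed(seed, "sirv"), ...)
  if (long)
    parts$long <- make_long_module(seed = substream_seed(seed, "long"))
  if (background_genes > 0)
    parts$bg <- make_background_module(
      n_genes = background_genes, n_isoforms = 3 * background_genes,
      seed = substream_seed(seed, "background"))
  if (length(parts) == 0L) stop("no modules requested")
  genome <- do.call(c, lapply(parts, function(p) p$genome))
  names(genome) <- sub("^[a-z]+\\.", "", names(genome))
  ann <- do.call(combine_annotations, lapply(parts, function(p) p$annotation))
  list(genome = genome, annotation = ann)
}

#' Spliced (RNA-sense) sequence of transcripts
#'
#' Concatenates exon substrings in genomic order and reverse-complements the
#' result for minus-strand transcripts.
#'
#' @param ann `flic_annotation`.
#' @param genome named character vector of contig sequences.
#' @param transcript_ids transcripts to materialise (default: all).
#' @return named character vector of spliced sequences.
#' @export
transcript_sequences <- function(ann, genome, transcript_ids = NULL) {
  ids <- transcript_ids %||% ann$transcripts$transcript_id
  out <- vapply(ids, function(tid) {
    ch <- transcript_chain(ann, tid)
    ctg <- genome[[ch$contig]]
    if (is.null(ctg) || any(ch$ends > nchar(ctg)) || any(ch$starts < 0))
      stop("exon out of contig bounds for ", tid)
    s <- paste(substring(ctg, ch$starts + 1L, ch$ends), collapse = "")
    if (ch$strand == "-") revcomp(s) else s
  }, character(1))
  names(out) <- ids
  out
}

#' @rdname transcript_sequences
#' @param transcript_id single transcript id.
#' @export
transcript_sequence <- function(ann, transcript_id, genome) {
  transcript_sequences(ann, genome, transcript_id)[[1L]]
}
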