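# Independent oracles: deliberately naive re-implementations (plain loops,
# no shared index code) used to verify the package's optimised paths.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# spliced length by summing the exon table directly
oracle_spliced_length <- function(ann, transcript_id) {
  e <- ann$exons[ann$exons$transcript_id == transcript_id, ]
  sum(e$end - e$start)
}

# per-exon slice-and-join transcript sequence
oracle_transcript_seq <- function(ann, transcript_id, genome) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  e <- ann$exons[ann$exons$transcript_id == transcript_id, ]
  e <- e[order(e$start), ]
  s <- ""
  for (i in seq_len(nrow(e)))
    s <- paste0(s, substr(genome[[tx$contig_id]], e$start[i] + 1, e$end[i]))
  if (tx$strand == "-") oracle_revcomp(s) else s
}

oracle_size_partition <- function(lengths) {
  list(long = which(lengths > 2000),
       short = which(lengths >= 500 & lengths <= 2000),
       discarded = which(lengths < 500))
}

# genes overlapping an interval, by linear scan
oracle_genes_overlapping <- function(ann, contig, start, end,
                                     strand = NULL) {
  g <- ann$genes
  hit <- g$contig_id == contig & g$start < end & g$end > start
  if (!is.null(strand)) hit <- hit & g$strand == strand
  g$gene_id[hit]
}

# independent transcription of the merge rule
oracle_mergeable <- function(a, b, d5 = 100, d3 = 30, gap = 10) {
  if (a$contig != b$contig || a$strand != b$strand) return(FALSE)
  ends5 <- function(c) if (c$strand == "+") min(c$starts) else max(c$ends)
  ends3 <- function(c) if (c$strand == "+") max(c$ends) else min(c$starts)
  if (abs(ends5(a) - ends5(b)) >= d5) return(FALSE)
  if (abs(ends3(a) - ends3(b)) >= d3) return(FALSE)
  na <- length(a$starts); nb <- length(b$starts)
  if (na != nb) return(FALSE)
  if (na == 1) return(TRUE)
  for (i in seq_len(na - 1)) {
    if (abs(a$ends[i] - b$ends[i]) > gap) return(FALSE)
    if (abs(a$starts[i + 1] - b$starts[i + 1]) > gap) return(FALSE)
  }
  TRUE
}

# all-pairs single-linkage partition; returns member-id sets
oracle_collapse_partition <- function(ids, chains, d5 = 100, d3 = 30,
                                      gap = 10) {
  n <- length(ids)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (comp[i] != comp[j] &&
          oracle_mergeable(chains[[i]], chains[[j]], d5, d3, gap)) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(ids, comp), function(x) sort(x)))
}

# rule-by-rule reference classifier, all linear scans
oracle_classify <- function(chain, ann, end_tolerance = 50) {
  tx <- ann$transcripts
  exons_of <- function(id) {
    e <- ann$exons[ann$exons$transcript_id == id, ]
    e[order(e$start), ]
  }
  introns_of <- function(id) {
    e <- exons_of(id)
    if (nrow(e) < 2) return(NULL)
    cbind(e$end[-nrow(e)], e$start[-1])
  }
  span_s <- min(chain$starts); span_e <- max(chain$ends)
  qi <- if (length(chain$starts) > 1)
    cbind(chain$ends[-length(chain$ends)], chain$starts[-1]) else NULL
  same <- which(tx$contig_id == chain$contig & tx$strand == chain$strand)
  anti_strand <- if (chain$strand == "+") "-" else "+"
  gs <- oracle_genes_overlapping(ann, chain$contig, span_s, span_e,
                                 chain$strand)
  go <- oracle_genes_overlapping(ann, chain$contig, span_s, span_e,
                                 anti_strand)
  anti_exon_olap <- {
    hit <- FALSE
    for (id in tx$transcript_id[tx$contig_id == chain$contig &
                                tx$strand == anti_strand]) {
      e <- exons_of(id)
      for (k in seq_along(chain$starts))
        if (any(e$start < chain$ends[k] & e$end > chain$starts[k]))
          hit <- TRUE
    }
    hit
  }
  in_intron <- {
    hit <- FALSE
    for (id in tx$transcript_id[tx$contig_id == chain$contig]) {
      im <- introns_of(id)
      if (!is.null(im) && any(im[, 1] <= span_s & span_e <= im[, 2]))
        hit <- TRUE
    }
    hit
  }

  if (!is.null(qi)) {
    for (id in tx$transcript_id[same]) {       # FSM: identical intron chain
      im <- introns_of(id)
      if (!is.null(im) && nrow(im) == nrow(qi) && all(im == qi))
        return("FSM")
    }
    retained <- FALSE                           # query exon spans an intron
    for (id in tx$transcript_id[same]) {
      im <- introns_of(id)
      if (is.null(im)) next
      for (k in seq_along(chain$starts))
        if (any(chain$starts[k] < im[, 1] & im[, 2] < chain$ends[k]))
          retained <- TRUE
    }
    if (!retained) {                            # ISM: contiguous sub-chain
      for (id in tx$transcript_id[same]) {
        im <- introns_of(id)
        if (is.null(im) || nrow(im) < nrow(qi)) next
        for (off in 0:(nrow(im) - nrow(qi))) {
          if (all(im[off + seq_len(nrow(qi)), , drop = FALSE] == qi))
            return("ISM")
        }
      }
    }
    if (length(gs) == 0) {
      if (length(go) > 0) return("antisense")
      return("intergenic")
    }
    if (length(gs) >= 2) return("fusion")
    donors <- c(); acceptors <- c()
    for (id in tx$transcript_id[same]) {
      im <- introns_of(id)
      if (is.null(im)) next
      if (chain$strand == "+") {
        donors <- c(donors, im[, 1]); acceptors <- c(acceptors, im[, 2])
      } else {
        donors <- c(donors, im[, 2]); acceptors <- c(acceptors, im[, 1])
      }
    }
    qd <- if (chain$strand == "+") qi[, 1] else qi[, 2]
    qa <- if (chain$strand == "+") qi[, 2] else qi[, 1]
    if (all(qd %in% donors) && all(qa %in% acceptors)) return("NIC")
    return("NNC")
  }

  # mono-exon query
  for (id in tx$transcript_id[same]) {         # FSM: mono containment
    e <- exons_of(id)
    if (nrow(e) == 1 && span_s >= e$start - end_tolerance &&
        span_e <= e$end + end_tolerance)
      return("FSM")
  }
  for (id in tx$transcript_id[same]) {         # ISM: inside one exon
    e <- exons_of(id)
    if (nrow(e) > 1 && any(e$start <= span_s & span_e <= e$end))
      return("ISM")
  }
  if (length(gs) == 0) {
    if (length(go) > 0) {
      if (anti_exon_olap) return("antisense")
      if (in_intron) return("genic_intronic")
      return("antisense")
    }
    return("intergenic")
  }
  if (in_intron) return("genic_intronic")
  "genic_genomic"
}

oracle_length_bins <- function(lens, support, width = 1000) {
  out <- list()
  for (i in seq_along(lens)) {
    b <- floor(lens[i] / width)
    key <- as.character(b)
    out[[key]] <- (out[[key]] %||% 0) + support[i]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
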