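# Transcript annotation container.
#
# Internal coordinates are 0-based half-open throughout; GTF I/O converts to
# 1-based inclusive on disk.  A transcript is a strand-aware chain of
# non-overlapping exons in increasing genomic order.

#' Build a transcript annotation
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `contig_id`, `strand` ("+"/"-") and `class` (one of `"sirv_isoform"`,
#'   `"long_sirv"`, `"background"`).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open genomic intervals).
#' @return object of class `flic_annotation`: the two tables (exons sorted,
#'   transcripts gaining a `spliced_len` column), a derived `genes` table
#'   (span covering all its transcripts, dominant strand) and an interval
#'   index used by overlap queries.
#' @export
flic_annotation <- function(transcripts, exons) {
  stopifnot(all(c("transcript_id", "gene_id", "contig_id", "strand", "class")
                %in% names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  if (anyDuplicated(transcripts$transcript_id))
    stop("transcript_ids must be unique")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start))
    stop("exon end must exceed exon start (0-based half-open)")
  # successive exons of one transcript must be separated by >= 1 bp intron
  by_tx <- split(exons, exons$transcript_id)
  for (tx in by_tx) {
    if (nrow(tx) > 1L && any(tx$start[-1L] <= tx$end[-nrow(tx)]))
      stop("overlapping or abutting exons in transcript ", tx$transcript_id[1L])
  }
  len <- vapply(by_tx, function(tx) sum(tx$end - tx$start), numeric(1))
  transcripts$spliced_len <- as.integer(len[transcripts$transcript_id])
  if (any(is.na(transcripts$spliced_len)))
    stop("every transcript needs at least one exon")

  span <- do.call(rbind, lapply(by_tx, function(tx) {
    data.frame(transcript_id = tx$transcript_id[1L],
               start = min(tx$start), end = max(tx$end))
  }))
  tx_span <- merge(transcripts, span, by = "transcript_id")
  genes <- do.call(rbind, lapply(split(tx_span, tx_span$gene_id), function(g) {
    if (length(unique(g$contig_id)) != 1L)
      stop("gene ", g$gene_id[1L], " spans multiple contigs")
    data.frame(gene_id = g$gene_id[1L], contig_id = g$contig_id[1L],
               strand = names(sort(table(g$strand), decreasing = TRUE))[1L],
               start = min(g$start), end = max(g$end))
  }))
  rownames(genes) <- NULL
  ann <- structure(list(transcripts = transcripts, exons = exons,
                        genes = genes),
                   class = "flic_annotation")
  ann$index <- build_index(ann)
  ann
}

# IRanges-backed gene/exon interval index, one per contig.
build_index <- function(ann) {
  tx <- ann$transcripts
  ex <- merge(ann$exons, tx[, c("transcript_id", "contig_id", "strand",
                                "gene_id")], by = "transcript_id")
  list(
    genes = split(ann$genes, ann$genes$contig_id),
    exons = split(ex, ex$contig_id)
  )
}

#' Genes overlapping a genomic interval
#'
#' @param ann `flic_annotation`.
#' @param contig_id contig name.
#' @param start,end 0-based half-open query interval.
#' @param strand optional strand filter.
#' @return character vector of gene ids (gene span overlap).
#' @export
genes_overlapping <- function(ann, contig_id, start, end, strand = NULL) {
  g <- ann$index$genes[[contig_id]]
  if (is.null(g)) return(character(0))
  if (!is.null(strand)) g <- g[g$strand == strand, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start + 1L, end),
    IRanges::IRanges(g$start + 1L, g$end))
  g$gene_id[unique(S4Vectors::subjectHits(hits))]
}

#' Exon rows of the annotation overlapping an interval
#'
#' @inheritParams genes_overlapping
#' @return data.frame of exon rows (transcript_id, start, end, contig_id,
#'   strand, gene_id).
#' @export
exons_overlapping <- function(ann, contig_id, start, end, strand = NULL) {
  e <- ann$index$exons[[contig_id]]
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), contig_id = character(0),
                      strand = character(0), gene_id = character(0))
  if (is.null(e)) return(empty)
  if (!is.null(strand)) e <- e[e$strand == strand, , drop = FALSE]
  if (nrow(e) == 0L) return(empty)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start + 1L, end),
    IRanges::IRanges(e$start + 1L, e$end))
  e[unique(S4Vectors::subjectHits(hits)), , drop = FALSE]
}

#' Combine annotations
#'
#' @param ... `flic_annotation` objects over disjoint transcript_id sets.
#' @return combined `flic_annotation`.
#' @export
combine_annotations <- function(...) {
  anns <- list(...)
  flic_annotation(do.call(rbind, lapply(anns, function(a) a$transcripts)),
                  do.call(rbind, lapply(anns, function(a) a$exons)))
}

#' @export
print.flic_annotation <- function(x, ...) {
  cat("flic_annotation:", nrow(x$transcripts), "transcripts,",
      nrow(x$genes), "genes,",
      length(unique(x$transcripts$contig_id)), "contigs\n")
  cat("  classes:", paste(names(table(x$transcripts$class)),
                          table(x$transcripts$class),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Exon chain of one transcript
#'
#' @param ann `flic_annotation`.
#' @param transcript_id transcript id.
#' @return `flic_chain`: list(contig, strand, starts, ends), 0-based
#'   half-open, increasing genomic order.
#' @export
transcript_chain <- function(ann, transcript_id) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  if (nrow(tx) != 1L) stop("unknown transcript ", transcript_id)
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  new_chain(tx$contig_id, tx$strand, ex$start, ex$end)
}

new_chain <- function(contig, strand, starts, ends) {
  o <- order(starts)
  structure(list(contig = contig, strand = strand,
                 starts = as.integer(starts[o]), ends = as.integer(ends[o])),
            class = "flic_chain")
}

chain_len <- function(chain) sum(chain$ends - chain$starts)

# Internal splice junctions as intron (start, end) pairs, 0-based half-open.
chain_introns <- function(chain) {
  n <- length(chain$starts)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  cbind(chain$ends[-n], chain$starts[-1L])
}

chain_key <- function(chain) {
  paste(chain$contig, chain$strand,
        paste(chain$starts, collapse = ","),
        paste(chain$ends, collapse = ","), sep = "|")
}
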