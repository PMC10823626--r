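# Format readers/writers.  Standard formats go through Biostrings and
# rtracklayer; the only package-specific conversion is between internal
# 0-based half-open exon coordinates and the 1-based inclusive convention of
# GTF/GFF on disk.

#' Read / write FASTA
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Reads are written with uniform Q30 qualities (the package's HiFi proxy).
#'
#' @param path file path.
#' @return `read_fastq`: named character vector of sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fastq
#' @param seqs named character vector of sequences.
#' @export
write_fastq <- function(seqs, path) {
  qual <- vapply(nchar(seqs), function(n)
    paste(rep("?", n), collapse = ""), character(1))   # '?' = Q30, Phred+33
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

# annotation -> GRanges of gene/transcript/exon features (1-based inclusive)
annotation_to_granges <- function(ann) {
  span <- do.call(rbind, lapply(split(ann$exons, ann$exons$transcript_id),
                                function(e) data.frame(
                                  transcript_id = e$transcript_id[1L],
                                  start = min(e$start), end = max(e$end))))
  tx <- merge(ann$transcripts, span, by = "transcript_id")
  g <- ann$genes
  ex <- merge(ann$exons, ann$transcripts, by = "transcript_id")
  feat <- rbind(
    data.frame(contig = g$contig_id, start = g$start, end = g$end,
               strand = g$strand, type = "gene", gene_id = g$gene_id,
               transcript_id = NA_character_,
               transcript_class = NA_character_),
    data.frame(contig = tx$contig_id, start = tx$start, end = tx$end,
               strand = tx$strand, type = "transcript", gene_id = tx$gene_id,
               transcript_id = tx$transcript_id, transcript_class = tx$class),
    data.frame(contig = ex$contig_id, start = ex$start, end = ex$end,
               strand = ex$strand, type = "exon", gene_id = ex$gene_id,
               transcript_id = ex$transcript_id, transcript_class = ex$class))
  gr <- GenomicRanges::GRanges(feat$contig,
                               IRanges::IRanges(feat$start + 1L, feat$end),
                               strand = feat$strand)
  S4Vectors::mcols(gr) <- feat[, c("type", "gene_id", "transcript_id",
                                   "transcript_class")]
  gr
}

#' Write an annotation as GTF
#'
#' Emits gene, transcript and exon features with `gene_id`,
#' `transcript_id` and `transcript_class` attributes; coordinates become
#' 1-based inclusive on disk.
#'
#' @param ann `flic_annotation`.
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  rtracklayer::export(annotation_to_granges(ann), path, format = "gtf")
  invisible(path)
}

#' Read a GTF into an annotation
#'
#' Exon features are grouped by `transcript_id`; `transcript_class`
#' defaults to `"background"` when absent.  Malformed lines are reported
#' with their line number before parsing.
#'
#' @param path GTF path.
#' @return `flic_annotation`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF record at line ", i, ": expected 9 fields")
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))) ||
        as.integer(f[4]) > as.integer(f[5]))
      stop("bad coordinates in GTF at line ", i)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features")
  md <- S4Vectors::mcols(ex)
  cls <- if ("transcript_class" %in% names(md)) md$transcript_class
         else rep(NA_character_, length(ex))
  df <- data.frame(
    transcript_id = md$transcript_id,
    gene_id = md$gene_id,
    contig_id = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    class = ifelse(is.na(cls), "background", cls),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex))
  first <- !duplicated(df$transcript_id)
  flic_annotation(df[first, c("transcript_id", "gene_id", "contig_id",
                              "strand", "class")],
                  df[, c("transcript_id", "start", "end")])
}

#' Read / write exon chains as BED12
#'
#' Blocks carry the exon structure; the thick range equals the chain span.
#'
#' @param path file path.
#' @return `read_bed12`: data.frame with `name`, `contig`, `strand` and a
#'   `chain` list-column of `flic_chain` objects.
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  contigs <- as.character(GenomicRanges::seqnames(gr))
  chains <- lapply(seq_along(gr), function(i) {
    span_start <- GenomicRanges::start(gr)[i] - 1L     # back to 0-based
    b <- md$blocks[[i]]
    bs <- span_start + IRanges::start(b) - 1L
    new_chain(contigs[i], strands[i], bs, bs + IRanges::width(b))
  })
  data.frame(name = md$name, contig = contigs, strand = strands,
             chain = I(chains))
}

#' @rdname read_bed12
#' @param chains data.frame as returned by `read_bed12` (columns `name`,
#'   `chain`).
#' @export
write_bed12 <- function(chains, path) {
  lines <- vapply(seq_len(nrow(chains)), function(i) {
    ch <- chains$chain[[i]]
    span <- c(min(ch$starts), max(ch$ends))
    paste(ch$contig, span[1], span[2], chains$name[i], 0, ch$strand,
          span[1], span[2], "0,0,0", length(ch$starts),
          paste0(paste(ch$ends - ch$starts, collapse = ","), ","),
          paste0(paste(ch$starts - span[1], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' @param path file path.
#' @return `read_tsv`: data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname read_tsv
#' @param df data.frame.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
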