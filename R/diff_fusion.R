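# Tumor-vs-comparator differential isoform filters and fusion-candidate
# calling.  These are deterministic threshold filters (no statistical
# model): read-count and TPM thresholds, inclusive five-fold enrichment
# with a pseudocount of one for zero support, and the fusion rules
# (>= 2 loci, >= 5% of the read per locus, >= 99% combined coverage,
# >= 5 supporting FLNC reads), with spike-in partners flagged as
# concatenation-artifact sentinels.

#' Differential isoform expression filter
#'
#' Keeps full-splice-match isoforms with at least `min_reads` long reads
#' and `min_tpm` short-read TPM in the tumor, whose long-read counts and
#' TPM values are both at least `min_fold`-fold higher than the comparator
#' (zero comparator values are assumed `pseudocount`).  Fold thresholds
#' are applied to the unrounded ratios; the returned audit columns carry
#' the one-decimal reported folds.
#'
#' @param records data.frame with columns `category`, `reads_tumor`,
#'   `reads_comp`, `tpm_tumor`, `tpm_comp` (plus ids carried through).
#' @param min_reads minimum tumor long-read support.
#' @param min_tpm minimum tumor TPM.
#' @param min_fold minimum enrichment (inclusive).
#' @param pseudocount zero replacement for fold computation.
#' @return passing records with `read_fold` and `tpm_fold` columns.
#' @export
de_filter <- function(records, min_reads = 10, min_tpm = 10, min_fold = 5,
                      pseudocount = 1) {
  stopifnot(min_reads > 0, min_tpm > 0, min_fold > 0)
  raw_fold <- function(a, b) {
    ifelse(a == 0, pseudocount, a) / ifelse(b == 0, pseudocount, b)
  }
  rf <- raw_fold(records$reads_tumor, records$reads_comp)
  tf <- raw_fold(records$tpm_tumor, records$tpm_comp)
  keep <- records$category == "FSM" &
    records$reads_tumor >= min_reads &
    records$tpm_tumor >= min_tpm &
    rf >= min_fold & tf >= min_fold
  out <- records[keep, , drop = FALSE]
  out$read_fold <- mapply(fold_change, records$reads_tumor[keep],
                          records$reads_comp[keep],
                          MoreArgs = list(pseudocount = pseudocount))
  out$tpm_fold <- mapply(fold_change, records$tpm_tumor[keep],
                         records$tpm_comp[keep],
                         MoreArgs = list(pseudocount = pseudocount))
  out
}

#' Unique genes represented by passing isoforms
#'
#' @param records data.frame with a `gene_id` column.
#' @return sorted character vector of distinct gene ids.
#' @export
unique_gene_rollup <- function(records) {
  sort(unique(records$gene_id[!is.na(records$gene_id)]))
}

#' Tumor-unique novel isoform filter
#'
#' Novel isoforms (NIC or NNC) with at least `min_reads` tumor long reads
#' and zero comparator reads; TPM plays no role here.
#'
#' @param records as for [de_filter()].
#' @param min_reads minimum tumor long-read support.
#' @return passing records.
#' @export
novel_filter <- function(records, min_reads = 10) {
  keep <- records$category %in% c("NIC", "NNC") &
    records$reads_tumor >= min_reads &
    records$reads_comp == 0
  records[keep, , drop = FALSE]
}

#' Fusion candidate filter
#'
#' @param candidates data.frame with a `loci` list-column (each element a
#'   data.frame with `gene_id`, `fraction`, `is_spikein`), plus
#'   `combined_coverage` and `flnc_support`.
#' @param min_frac minimum aligned fraction of the read per locus.
#' @param min_cov minimum combined alignment coverage.
#' @param min_flnc minimum supporting FLNC reads.
#' @return passing candidates with a `spikein_partner` flag column (TRUE
#'   marks a likely concatenation artifact).
#' @export
fusion_filter <- function(candidates, min_frac = 0.05, min_cov = 0.99,
                          min_flnc = 5) {
  stopifnot(min_frac > 0, min_frac <= 1, min_cov > 0, min_cov <= 1,
            min_flnc >= 1)
  if (nrow(candidates) == 0L) {
    candidates$spikein_partner <- logical(0)
    return(candidates)
  }
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    lo <- candidates$loci[[i]]
    nrow(lo) >= 2L && all(lo$fraction >= min_frac) &&
      candidates$combined_coverage[i] >= min_cov &&
      candidates$flnc_support[i] >= min_flnc
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  out$spikein_partner <- vapply(out$loci, function(lo) any(lo$is_spikein),
                                logical(1))
  out
}

#' Derive fusion candidates from simulation truth
#'
#' A refined read that still spans two or more truth segments from
#' distinct transcripts (a junction the splitter missed and the residual
#' screen did not catch) is a fusion candidate.  Candidates are grouped by
#' their partner set; per-locus aligned fractions come from the truth
#' overlap lengths.
#'
#' @param flnc output of [refine_reads()].
#' @param matched output of [match_sreads_to_truth()] -- only used for the
#'   sread coordinate join.
#' @param truth truth table from the simulation.
#' @param ann `flic_annotation` (spike-in flags).
#' @return candidate data.frame for [fusion_filter()].
#' @export
fusion_candidates_from_truth <- function(flnc, matched, truth, ann) {
  spike_of <- setNames(ann$transcripts$class %in%
                         c("sirv_isoform", "long_sirv"),
                       ann$transcripts$transcript_id)
  gene_of <- setNames(ann$transcripts$gene_id,
                      ann$transcripts$transcript_id)
  tr_by_read <- split(truth, truth$read_id)
  keys <- character(0)
  events <- list()
  live <- which(flnc$status == "flnc")
  midx <- match(flnc$sread_id, matched$sread_id)
  for (i in live) {
    if (is.na(midx[i])) next
    m <- matched[midx[i], , drop = FALSE]
    tr <- tr_by_read[[m$parent_read_id]]
    if (is.null(tr)) next
    ov <- pmin(m$end, tr$end) - pmax(m$start, tr$start) + 1L
    hit <- which(ov > 25L & tr$artifact == "none")
    txs <- unique(tr$transcript_id[hit])
    if (length(txs) < 2L) next
    key <- paste(sort(txs), collapse = "+")
    frac <- vapply(txs, function(t)
      sum(ov[hit][tr$transcript_id[hit] == t]), numeric(1)) /
      (m$end - m$start + 1L)
    if (!key %in% keys) {
      keys <- c(keys, key)
      events[[key]] <- list(
        loci = data.frame(gene_id = unname(gene_of[txs]),
                          fraction = unname(frac),
                          is_spikein = unname(spike_of[txs])),
        coverage = sum(frac), n = 1L)
    } else {
      events[[key]]$n <- events[[key]]$n + 1L
    }
  }
  if (length(events) == 0L)
    return(data.frame(candidate_id = character(0), loci = I(list()),
                      combined_coverage = numeric(0),
                      flnc_support = integer(0)))
  data.frame(candidate_id = names(events),
             loci = I(lapply(events, `[[`, "loci")),
             combined_coverage = pmin(1, vapply(events, `[[`, numeric(1),
                                                "coverage")),
             flnc_support = vapply(events, `[[`, integer(1), "n"))
}
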