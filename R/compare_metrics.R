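# Cross-sample comparison: GFFCompare-style non-redundant merging of
# classified isoforms, replicate concordance at read-support thresholds,
# and the ratio/percentage arithmetic used throughout the analysis.  All
# printed percentages and folds are half-up to one decimal.

#' Join cluster chains onto their classification
#'
#' @param clusters output of [collapse_flnc()].
#' @param classified output of [classify_isoforms()] for those clusters.
#' @return data.frame(cluster_id, chain, support, category,
#'   matched_transcript, gene_ids) ready for [merge_samples()].
#' @export
classified_with_chains <- function(clusters, classified) {
  m <- match(clusters$cluster_id, classified$cluster_id)
  data.frame(cluster_id = clusters$cluster_id, chain = I(clusters$chain),
             support = clusters$support,
             category = classified$category[m],
             matched_transcript = classified$matched_transcript[m],
             gene_ids = classified$gene_ids[m])
}

#' Merge classified isoforms across samples
#'
#' Builds the non-redundant isoform x sample support matrix: isoforms are
#' merged across samples with the same end/junction rules as read
#' collapsing ([mergeable()]), per-sample support is summed over merged
#' members, and rows classified as intergenic (the "unknown" class analog)
#' are dropped when `drop_unknown`.
#'
#' @param samples named list; each element a data.frame from
#'   [classified_with_chains()].
#' @param drop_unknown drop intergenic rows (default TRUE).
#' @inheritParams mergeable
#' @return object of class `flic_comparison`: `rows` (row_id, category,
#'   matched_transcript, chain), `support` (matrix rows x samples) and
#'   `provenance` (member cluster ids per row).
#' @export
merge_samples <- function(samples, drop_unknown = TRUE, d5 = 100, d3 = 30,
                          gap = 10) {
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  pooled <- do.call(rbind, lapply(names(samples), function(s) {
    x <- samples[[s]]
    if (nrow(x) == 0L) return(NULL)
    data.frame(id = paste0(s, ":", x$cluster_id), sample = s,
               chain = I(x$chain), support = x$support,
               category = x$category,
               matched_transcript = x$matched_transcript)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L)
    stop("no isoforms to merge")
  cl <- collapse_flnc(pooled[, c("id", "chain")], d5, d3, gap)
  n <- nrow(cl)
  sup <- matrix(0, nrow = n, ncol = length(samples),
                dimnames = list(cl$cluster_id, names(samples)))
  category <- character(n)
  matched <- character(n)
  prov <- vector("list", n)
  for (i in seq_len(n)) {
    mem <- match(cl$members[[i]], pooled$id)
    for (j in mem)
      sup[i, pooled$sample[j]] <- sup[i, pooled$sample[j]] + pooled$support[j]
    # row annotation from the highest-supported member (deterministic ties)
    lead <- mem[order(-pooled$support[mem], pooled$id[mem])][1L]
    category[i] <- pooled$category[lead]
    matched[i] <- pooled$matched_transcript[lead]
    prov[[i]] <- pooled$id[mem]
  }
  keep <- if (drop_unknown) category != "intergenic" else rep(TRUE, n)
  structure(list(
    rows = data.frame(row_id = cl$cluster_id[keep],
                      category = category[keep],
                      matched_transcript = matched[keep],
                      chain = I(cl$chain[keep])),
    support = sup[keep, , drop = FALSE],
    provenance = prov[keep]),
    class = "flic_comparison")
}

#' @export
print.flic_comparison <- function(x, ...) {
  cat("flic_comparison:", nrow(x$rows), "non-redundant isoforms x",
      ncol(x$support), "samples\n")
  invisible(x)
}

#' Replicate concordance at a support threshold
#'
#' A row "passes" in a sample when its support there is at least
#' `min_support`; counts and one-decimal percentages are relative to rows
#' passing in at least one sample.
#'
#' @param mat `flic_comparison`.
#' @param min_support support threshold (2, 4 and 10 in the workflow).
#' @return list(n_unique, n_in_all, n_in_at_least_2, pct_in_all,
#'   pct_in_at_least_2).
#' @export
overlap_stats <- function(mat, min_support) {
  stopifnot(min_support >= 1)
  pass <- mat$support >= min_support
  n_samp <- rowSums(pass)
  n_unique <- sum(n_samp >= 1L)
  n_all <- sum(n_samp == ncol(pass))
  n_two <- sum(n_samp >= 2L)
  list(n_unique = n_unique, n_in_all = n_all, n_in_at_least_2 = n_two,
       pct_in_all = if (n_unique) percent_of(n_all, n_unique) else NA_real_,
       pct_in_at_least_2 = if (n_unique) percent_of(n_two, n_unique)
                           else NA_real_)
}

#' Fold change with zero handling
#'
#' Any zero operand is replaced by `pseudocount` before division (an
#' isoform with zero supporting reads is assumed one read).  Results are
#' half-up to `decimals`; folds of 1,000 or more report as whole numbers.
#'
#' @param numerator,denominator non-negative counts or expression values.
#' @param pseudocount replacement for zero operands.
#' @param decimals decimal places for folds under 1,000.
#' @return fold ratio.
#' @export
fold_change <- function(numerator, denominator, pseudocount = 1,
                        decimals = 1) {
  stopifnot(numerator >= 0, denominator >= 0)
  num <- ifelse(numerator == 0, pseudocount, numerator)
  den <- ifelse(denominator == 0, pseudocount, denominator)
  r <- num / den
  ifelse(r >= 1000, round_half_up(r, 0), round_half_up(r, decimals))
}

#' Mean spike-in recall over replicates
#'
#' @param detected_counts detected isoform counts per replicate.
#' @param total truth panel size.
#' @return mean recall in percent, one decimal.
#' @export
mean_recall <- function(detected_counts, total) {
  if (length(detected_counts) == 0L) stop("no replicate counts supplied")
  stopifnot(total >= 1, all(detected_counts <= total))
  round_half_up(mean(detected_counts) / total * 100, 1)
}

#' Low-expression transcript panel
#'
#' Transcripts whose short-read TPM equals `tpm_equal` (within `tol`) in
#' every replicate table.
#'
#' @param tpm_tables list of data.frames with `transcript_id` and `tpm`.
#' @param tpm_equal the defining TPM value (0.5 by convention).
#' @param tol numeric equality tolerance.
#' @return character vector of transcript ids.
#' @export
low_expression_panel <- function(tpm_tables, tpm_equal = 0.5, tol = 1e-9) {
  stopifnot(length(tpm_tables) >= 1)
  sets <- lapply(tpm_tables, function(tab)
    tab$transcript_id[abs(tab$tpm - tpm_equal) <= tol])
  Reduce(intersect, sets)
}

#' Panel detection across replicates
#'
#' A panel transcript is detected in a sample when an FSM row matched to it
#' has support of at least `min_support` there.
#'
#' @param panel transcript ids from [low_expression_panel()].
#' @param mat `flic_comparison`.
#' @param min_support per-sample support needed to call detection.
#' @return list(n_in_all, n_in_at_least_one, pct_in_all,
#'   pct_in_at_least_one), percentages over the panel size.
#' @export
panel_detection <- function(panel, mat, min_support = 1) {
  stopifnot(length(panel) > 0)
  fsm <- mat$rows$category == "FSM" &
    mat$rows$matched_transcript %in% panel
  det <- matrix(FALSE, nrow = length(panel), ncol = ncol(mat$support),
                dimnames = list(panel, colnames(mat$support)))
  if (any(fsm)) {
    sub <- mat$support[fsm, , drop = FALSE] >= min_support
    for (k in which(fsm)) {
      t <- mat$rows$matched_transcript[k]
      det[t, ] <- det[t, ] | (mat$support[k, ] >= min_support)
    }
  }
  n_all <- sum(rowSums(det) == ncol(det))
  n_any <- sum(rowSums(det) >= 1L)
  list(n_in_all = n_all, n_in_at_least_one = n_any,
       pct_in_all = percent_of(n_all, length(panel)),
       pct_in_at_least_one = percent_of(n_any, length(panel)))
}
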