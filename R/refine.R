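# FLNC refinement: primer detection/trimming with orientation, poly(A)
# trimming, and a residual-concatemer screen.  Statuses mirror the
# full-length non-concatemer definition: a read must show both primers, a
# qualifying poly(A) run, and no internal primer/barcode remnant.

# best terminal primer match: try window lengths m-max_edit..m+max_edit at
# the given end of every sequence; vectorised over sequences via adist.
terminal_match <- function(seqs, primer, max_edit, end = c("head", "tail")) {
  end <- match.arg(end)
  m <- nchar(primer)
  L <- nchar(seqs)
  best_d <- rep(Inf, length(seqs))
  best_w <- rep(NA_integer_, length(seqs))
  for (w in seq.int(max(1L, m - max_edit), m + max_edit)) {
    frag <- if (end == "head") substr(seqs, 1L, pmin(w, L))
            else substr(seqs, pmax(1L, L - w + 1L), L)
    d <- as.integer(adist(frag, primer)) + (w > L) * 1000L
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_w[upd] <- w
  }
  list(dist = best_d, width = best_w)
}

#' Detect and trim cDNA primers from an s-read
#'
#' Tests every primer pair in both orientations (bounded edit distance at
#' each end), trims the winning pair and returns the insert in sense
#' orientation.
#'
#' @param sread s-read sequence (single string).
#' @param primer_pairs list of primer pairs (each `list(pair_id, p5, p3)`).
#' @param max_edit maximum edit distance per primer.
#' @return list(insert, pair_id, orientation, dist) or `NULL` when neither
#'   orientation shows both primers (status `no_primer`).
#' @export
detect_and_trim_primers <- function(sread, primer_pairs = list(default_primer_pair()),
                                    max_edit = 3) {
  r <- refine_primer_pass(sread, primer_pairs, max_edit)
  if (is.na(r$pair_id)) return(NULL)
  list(insert = r$insert, pair_id = r$pair_id, orientation = r$orientation,
       dist = r$dist)
}

# batch primer pass; returns data.frame(insert, pair_id, orientation, dist)
refine_primer_pass <- function(seqs, primer_pairs, max_edit) {
  n <- length(seqs)
  out <- data.frame(insert = seqs, pair_id = NA_character_,
                    orientation = NA_character_, dist = rep(Inf, n))
  rc <- revcomp(seqs)
  for (pp in primer_pairs) {
    for (orient in c("forward", "reverse")) {
      ws <- if (orient == "forward") seqs else rc
      h5 <- terminal_match(ws, pp$p5, max_edit, "head")
      h3 <- terminal_match(ws, pp$p3, max_edit, "tail")
      ok <- h5$dist <= max_edit & h3$dist <= max_edit
      d <- h5$dist + h3$dist
      upd <- ok & d < out$dist
      if (any(upd)) {
        L <- nchar(ws[upd])
        out$insert[upd] <- substr(ws[upd], h5$width[upd] + 1L,
                                  L - h3$width[upd])
        out$pair_id[upd] <- pp$pair_id
        out$orientation[upd] <- orient
        out$dist[upd] <- d[upd]
      }
    }
  }
  out
}

#' Trim a trailing poly(A) run
#'
#' Finds the longest suffix containing at most `max_mismatch` non-A bases
#' and starting with an A; qualifies when it holds at least `min_a_run`
#' A's.
#'
#' @param insert insert sequence (after primer trimming).
#' @param min_a_run minimum number of A's in the tail.
#' @param max_mismatch non-A bases tolerated inside the run.
#' @return list(insert, polya_len), or `NULL` when no qualifying run
#'   (status `no_polya`).
#' @export
trim_polya <- function(insert, min_a_run = 20, max_mismatch = 1) {
  stopifnot(min_a_run >= 1)
  L <- nchar(insert)
  scan <- min(L, 400L)
  tail_chars <- strsplit(substr(insert, L - scan + 1L, L), "", fixed = TRUE)[[1]]
  is_a <- rev(tail_chars) == "A"          # index 1 = last base
  mism <- cumsum(!is_a)
  valid <- which(mism <= max_mismatch & is_a)  # suffix must start with A
  if (length(valid) == 0L) return(NULL)
  k <- max(valid)
  if (sum(is_a[seq_len(k)]) < min_a_run) return(NULL)
  list(insert = substr(insert, 1L, L - k), polya_len = k)
}

#' Residual-concatemer screen
#'
#' Fails when an internal (non-terminal) mismatch-tolerant occurrence of
#' any primer or junction barcode is found — the signature of a missed
#' junction.  The per-pattern mismatch budget scales with pattern length
#' (one mismatch per 12 bp, capped at `max_edit`), which keeps the scan
#' sensitive for the 24-bp primers that flank every junction while
#' avoiding chance hits of short barcodes in genuine transcript sequence.
#'
#' @param insert insert sequence.
#' @param primers character vector of primer sequences.
#' @param barcodes character vector of junction barcodes.
#' @param max_edit cap on the per-pattern mismatch budget.
#' @param margin bases at each end ignored as trimming slop.
#' @return TRUE (pass) or FALSE (residual concatemer).
#' @export
drop_residual_concatemers <- function(insert, primers, barcodes = character(0),
                                      max_edit = 3, margin = 5) {
  pats <- unique(c(primers, revcomp(primers), barcodes,
                   if (length(barcodes)) revcomp(barcodes)))
  L <- nchar(insert)
  subj <- Biostrings::DNAString(insert)
  for (p in pats) {
    m <- Biostrings::matchPattern(p, subj,
                                  max.mismatch = residual_budget(p, max_edit))
    if (any(Biostrings::start(m) > margin &
            Biostrings::end(m) <= L - margin))
      return(FALSE)
  }
  TRUE
}

residual_budget <- function(pattern, max_edit) {
  min(max_edit, nchar(pattern) %/% 12L)
}

# batch Hamming residual scan; returns logical (TRUE = residual found)
batch_residual <- function(seqs, primers, barcodes, max_edit, margin = 5) {
  pats <- unique(c(primers, revcomp(primers), barcodes,
                   if (length(barcodes)) revcomp(barcodes)))
  flag <- logical(length(seqs))
  subj <- Biostrings::DNAStringSet(seqs)
  L <- nchar(seqs)
  for (p in pats) {
    h <- batch_hits(p, subj, residual_budget(p, max_edit))
    if (nrow(h) == 0L) next
    internal <- h$start > margin & h$end <= L[h$read] - margin
    flag[unique(h$read[internal])] <- TRUE
  }
  flag
}

#' Refine s-reads into FLNC reads
#'
#' Runs primer detection, the residual-concatemer screen and poly(A)
#' trimming over a batch of s-reads.  Status values: `flnc`, `no_primer`,
#' `residual_concatemer`, `no_polya`, `short`.
#'
#' @param sreads s-read table from [split_reads()] (or a data.frame with
#'   `sread_id` and `sequence`).
#' @param primer_pairs list of primer pairs.
#' @param barcodes junction barcodes for the residual screen.
#' @param max_edit primer / internal-scan edit budget.
#' @param min_a_run,max_mismatch poly(A) rule, see [trim_polya()].
#' @param min_len inserts shorter than this after trimming are statused
#'   `short` and excluded from clustering.
#' @param require_polya set `FALSE` to accept reads without a poly(A) run
#'   (tail trimming still applies when a run is present).
#' @return data.frame(flnc_id, sread_id, status, sequence, polya_len,
#'   pair_id, orientation); `sequence` is the sense-oriented insert.
#' @export
refine_reads <- function(sreads, primer_pairs = list(default_primer_pair()),
                         barcodes = character(0), max_edit = 3,
                         min_a_run = 20, max_mismatch = 1, min_len = 80,
                         require_polya = TRUE) {
  if (is.character(sreads))
    sreads <- data.frame(sread_id = names(sreads) %||%
                           sprintf("sread%06d", seq_along(sreads)),
                         sequence = unname(sreads))
  n <- nrow(sreads)
  out <- data.frame(flnc_id = paste0("flnc_", sreads$sread_id),
                    sread_id = sreads$sread_id,
                    status = rep("flnc", n),
                    sequence = rep(NA_character_, n),
                    polya_len = rep(0L, n),
                    pair_id = NA_character_, orientation = NA_character_)
  if (n == 0L) return(out)
  pp <- refine_primer_pass(sreads$sequence, primer_pairs, max_edit)
  out$pair_id <- pp$pair_id
  out$orientation <- pp$orientation
  out$sequence <- pp$insert
  no_primer <- is.na(pp$pair_id)
  out$status[no_primer] <- "no_primer"

  live <- which(!no_primer)
  if (length(live)) {
    prims <- unlist(lapply(primer_pairs, function(p) c(p$p5, p$p3)))
    res <- batch_residual(out$sequence[live], prims, barcodes, max_edit)
    out$status[live[res]] <- "residual_concatemer"
    live <- live[!res]
  }
  for (i in live) {
    pa <- trim_polya(out$sequence[i], min_a_run, max_mismatch)
    if (is.null(pa)) {
      if (require_polya) out$status[i] <- "no_polya"
    } else {
      out$sequence[i] <- pa$insert
      out$polya_len[i] <- pa$polya_len
    }
  }
  ok <- out$status == "flnc"
  out$status[ok & nchar(out$sequence) < min_len] <- "short"
  out
}
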