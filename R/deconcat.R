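# Concatemer read splitting ("SKERA-style"): locate approximate junction
# barcodes, validate their order against the best-matching array design, and
# emit the inter-barcode intervals as segmented reads (s-reads).
#
# Matching strategy: a batch Hamming pass (vmatchPattern) over the whole
# read set for every barcode in both orientations, then a per-read
# edit-distance fallback (matchPattern with indels) for expected barcodes
# the Hamming pass did not find.  Hits are accepted in order of (edit
# distance, position) subject to non-overlap and design barcode order, which
# makes tie-breaking deterministic.

# all Hamming hits of `pattern` across `subjects` (DNAStringSet)
batch_hits <- function(pattern, subjects, max_edit) {
  m <- Biostrings::vmatchPattern(pattern, subjects, max.mismatch = max_edit)
  st <- Biostrings::startIndex(m)
  n_hit <- lengths(st)
  idx <- rep(seq_along(st), n_hit)
  if (length(idx) == 0L)
    return(data.frame(read = integer(0), start = integer(0),
                      end = integer(0)))
  data.frame(read = idx, start = unlist(st),
             end = unlist(st) + nchar(pattern) - 1L)
}

# per-read fallback allowing indels; hits whose width differs from the
# barcode by more than one base are discarded (at HiFi error rates a
# barcode with two or more indels is vanishingly rare, while permissive
# multi-indel windows are the main source of spurious matches)
indel_hits <- function(pattern, subject_chr, max_edit) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject_chr),
                                max.mismatch = max_edit, with.indels = TRUE)
  if (length(m) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  w <- Biostrings::width(m)
  keep <- abs(w - nchar(pattern)) <= 1L
  data.frame(start = Biostrings::start(m)[keep],
             end = Biostrings::end(m)[keep])
}

edit_dist <- function(a, b) as.integer(adist(a, b))

# Accept hits greedily by (distance, position) with non-overlap and
# strictly increasing barcode order between positional neighbours.
accept_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$dist, hits$start, hits$bc_idx), , drop = FALSE]
  acc <- hits[0, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (nrow(acc)) {
      if (any(h$start <= acc$end & h$end >= acc$start)) next
      if (h$bc_idx %in% acc$bc_idx) next
      before <- acc$bc_idx[acc$start < h$start]
      after <- acc$bc_idx[acc$start > h$start]
      if (length(before) && max(before) >= h$bc_idx) next
      if (length(after) && min(after) <= h$bc_idx) next
    }
    acc <- rbind(acc, h)
  }
  acc[order(acc$start), , drop = FALSE]
}

#' Split concatemer reads at junction barcodes
#'
#' Emits the maximal intervals not covered by accepted barcode hits as
#' s-reads, with barcodes trimmed.  Whole-read orientation (forward or
#' reverse complement) is decided once per read by total barcode hit count.
#' A read with no barcode match yields a single s-read.  Segments shorter
#' than 50 bp are emitted but flagged `short`.
#'
#' @param reads data.frame with `read_id` and `sequence` columns (or a
#'   named character vector).
#' @param designs list of [make_array_design()] objects.
#' @param max_edit maximum barcode edit distance (default 3).
#' @return list with `sreads` (sread_id, parent_read_id, ordinal, sequence,
#'   left_bc, right_bc, start, end, short) and `reads` (read_id, design_id,
#'   orientation, n_segments, full_array).
#' @export
split_reads <- function(reads, designs, max_edit = 3) {
  stopifnot(max_edit >= 0, length(designs) >= 1)
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads) %||%
                          sprintf("read%06d", seq_along(reads)),
                        sequence = unname(reads))
  if (!length(unlist(lapply(designs, `[[`, "barcodes")))) {
    # barcode-less (monomer) designs: identity split
    sreads <- data.frame(
      sread_id = paste0(reads$read_id, "/1"),
      parent_read_id = reads$read_id, ordinal = 1L,
      sequence = reads$sequence, left_bc = NA_character_,
      right_bc = NA_character_, start = 1L, end = nchar(reads$sequence),
      short = nchar(reads$sequence) < 50L, row.names = NULL)
    meta <- data.frame(read_id = reads$read_id,
                       design_id = designs[[1]]$design_id,
                       orientation = "forward", n_segments = 1L,
                       full_array = designs[[1]]$arity == 1L,
                       row.names = NULL)
    return(list(sreads = sreads, reads = meta))
  }

  # barcode table across designs
  bc_tab <- do.call(rbind, lapply(designs, function(d) {
    if (!length(d$barcodes)) return(NULL)
    data.frame(design_id = d$design_id, bc_idx = seq_along(d$barcodes),
               bc = unname(d$barcodes), row.names = NULL)
  }))
  subjects <- Biostrings::DNAStringSet(reads$sequence)
  Lens <- nchar(reads$sequence)

  hit_list <- list()
  for (r in seq_len(nrow(bc_tab))) {
    for (orient in c("forward", "reverse")) {
      pat <- if (orient == "forward") bc_tab$bc[r] else revcomp(bc_tab$bc[r])
      h <- batch_hits(pat, subjects, max_edit)
      if (nrow(h) == 0L) next
      if (orient == "reverse") {   # map to reverse-complement coordinates
        L <- Lens[h$read]
        ns <- L - h$end + 1L
        h$end <- L - h$start + 1L
        h$start <- ns
      }
      h$design_id <- bc_tab$design_id[r]
      h$bc_idx <- bc_tab$bc_idx[r]
      h$bc <- bc_tab$bc[r]
      h$orient <- orient
      hit_list[[length(hit_list) + 1L]] <- h
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list)
          else data.frame(read = integer(0), start = integer(0),
                          end = integer(0), design_id = character(0),
                          bc_idx = integer(0), bc = character(0),
                          orient = character(0))

  hits_by_read <- split(hits, factor(hits$read, levels = seq_len(nrow(reads))))
  nr <- nrow(reads)
  # whole-read orientation decided once per read; batch the revcomps
  n_fwd <- vapply(hits_by_read, function(h) sum(h$orient == "forward"),
                  integer(1))
  n_rev <- vapply(hits_by_read, function(h) sum(h$orient == "reverse"),
                  integer(1))
  orient_vec <- ifelse(n_rev > n_fwd, "reverse", "forward")
  ws_vec <- reads$sequence
  rev_idx <- which(orient_vec == "reverse")
  if (length(rev_idx)) ws_vec[rev_idx] <- revcomp(ws_vec[rev_idx])
  m_design <- character(nr); m_orient <- character(nr)
  m_nseg <- integer(nr); m_full <- logical(nr)
  s_seq <- vector("list", nr); s_start <- vector("list", nr)
  s_end <- vector("list", nr); s_left <- vector("list", nr)
  s_right <- vector("list", nr)
  arity_of <- setNames(vapply(designs, `[[`, integer(1), "arity"),
                       vapply(designs, `[[`, character(1), "design_id"))
  bc_of <- setNames(lapply(designs, `[[`, "barcodes"),
                    vapply(designs, `[[`, character(1), "design_id"))

  for (i in seq_len(nrow(reads))) {
    h <- hits_by_read[[i]]
    orientation <- orient_vec[i]
    h <- h[h$orient == orientation, , drop = FALSE]
    ws <- ws_vec[i]
    L <- Lens[i]

    # best design: most hits, then design order
    if (nrow(h)) {
      tab <- table(factor(h$design_id, levels = names(arity_of)))
      best <- names(tab)[which.max(tab)]
    } else best <- names(arity_of)[1L]
    h <- h[h$design_id == best, , drop = FALSE]
    exp_bc <- bc_of[[best]]

    # edit distances for Hamming hits
    if (nrow(h))
      h$dist <- mapply(function(s, e, b) edit_dist(substr(ws, s, e), b),
                       h$start, h$end, h$bc)

    # fallback with indels for expected barcodes the Hamming pass missed
    missing <- setdiff(seq_along(exp_bc), unique(h$bc_idx))
    for (mi in missing) {
      f <- indel_hits(exp_bc[mi], ws, max_edit)
      if (nrow(f) == 0L) next
      f$design_id <- best
      f$bc_idx <- mi
      f$bc <- exp_bc[mi]
      f$orient <- orientation
      f$read <- i
      f$dist <- mapply(function(s, e) edit_dist(substr(ws, s, e), exp_bc[mi]),
                       f$start, f$end)
      h <- rbind(h, f[, names(h)])
    }

    acc <- if (nrow(h)) accept_hits(h) else h
    # s-reads = intervals between accepted barcode hits
    bounds_s <- c(1L, acc$end + 1L)
    bounds_e <- c(acc$start - 1L, L)
    left <- c(NA_character_, acc$bc)
    right <- c(acc$bc, NA_character_)
    keep <- bounds_e >= bounds_s
    bounds_s <- bounds_s[keep]; bounds_e <- bounds_e[keep]
    left <- left[keep]; right <- right[keep]
    n_seg <- length(bounds_s)
    if (n_seg == 0L) {      # read is nothing but barcodes
      n_seg <- 1L; bounds_s <- 1L; bounds_e <- L
      left <- NA_character_; right <- NA_character_
    }
    segs <- substring(ws, bounds_s, bounds_e)
    # report coordinates in the input read; sequences stay in the working
    # (array-sense) orientation
    if (orientation == "reverse") {
      in_start <- L - bounds_e + 1L
      in_end <- L - bounds_s + 1L
    } else {
      in_start <- bounds_s
      in_end <- bounds_e
    }
    s_seq[[i]] <- segs; s_start[[i]] <- in_start; s_end[[i]] <- in_end
    s_left[[i]] <- left; s_right[[i]] <- right
    m_design[i] <- best
    m_orient[i] <- orientation
    m_nseg[i] <- n_seg
    m_full[i] <- n_seg == arity_of[[best]] &&
      length(setdiff(seq_along(exp_bc), acc$bc_idx)) == 0L
  }
  parent <- rep(reads$read_id, m_nseg)
  ordinal <- sequence(m_nseg)
  seqs <- unlist(s_seq)
  sreads <- data.frame(
    sread_id = paste0(parent, "/", ordinal),
    parent_read_id = parent, ordinal = ordinal, sequence = seqs,
    left_bc = unlist(s_left), right_bc = unlist(s_right),
    start = unlist(s_start), end = unlist(s_end),
    short = nchar(seqs) < 50L)
  meta <- data.frame(read_id = reads$read_id, design_id = m_design,
                     orientation = m_orient, n_segments = m_nseg,
                     full_array = m_full)
  list(sreads = sreads, reads = meta)
}

#' @rdname split_reads
#' @param sequence a single read sequence.
#' @export
split_read <- function(sequence, designs, max_edit = 3) {
  split_reads(setNames(sequence, "read"), designs, max_edit)$sreads
}

#' Match s-reads to simulation truth segments
#'
#' Joins each s-read to the truth segment of its parent read with the
#' largest coordinate overlap (both are in input-read coordinates).
#'
#' @param split output of [split_reads()].
#' @param truth truth data.frame from [concatenate()] (possibly updated by
#'   [apply_hifi_errors()]).
#' @return the `sreads` table with `transcript_id`, `molecule_id`,
#'   `artifact` and `truth_overlap` columns (`NA` when no overlap).
#' @export
match_sreads_to_truth <- function(split, truth) {
  sr <- split$sreads
  sr$transcript_id <- NA_character_
  sr$molecule_id <- NA_character_
  sr$artifact <- NA_character_
  sr$truth_overlap <- 0L
  tr_by_read <- split(truth, truth$read_id)
  for (i in seq_len(nrow(sr))) {
    tr <- tr_by_read[[sr$parent_read_id[i]]]
    if (is.null(tr)) next
    ov <- pmin(sr$end[i], tr$end) - pmax(sr$start[i], tr$start) + 1L
    j <- which.max(ov)
    if (length(j) && ov[j] > 0L) {
      sr$transcript_id[i] <- tr$transcript_id[j]
      sr$molecule_id[i] <- tr$molecule_id[j]
      sr$artifact[i] <- tr$artifact[j]
      sr$truth_overlap[i] <- ov[j]
    }
  }
  sr
}

#' Array-completeness statistics
#'
#' A read is a full array when its observed segment count equals the
#' assigned design's arity and every expected junction barcode was found in
#' order.
#'
#' @param split output of [split_reads()].
#' @param designs the design list used for splitting.
#' @return list of class `flic_array_stats`: n_reads, n_sreads,
#'   n_full_arrays, full_array_fraction, and a `per_design` data.frame.
#' @export
array_efficiency <- function(split, designs) {
  meta <- split$reads
  per <- do.call(rbind, lapply(designs, function(d) {
    m <- meta[meta$design_id == d$design_id, , drop = FALSE]
    data.frame(design_id = d$design_id, arity = d$arity,
               n_reads = nrow(m),
               n_sreads = sum(m$n_segments),
               n_full = sum(m$full_array),
               full_array_fraction =
                 if (nrow(m)) sum(m$full_array) / nrow(m) else NA_real_)
  }))
  structure(list(n_reads = nrow(meta),
                 n_sreads = sum(meta$n_segments),
                 n_full_arrays = sum(meta$full_array),
                 full_array_fraction =
                   if (nrow(meta)) sum(meta$full_array) / nrow(meta)
                   else NA_real_,
                 per_design = per),
            class = "flic_array_stats")
}

#' @export
print.flic_array_stats <- function(x, ...) {
  cat("flic_array_stats:", x$n_reads, "reads ->", x$n_sreads, "s-reads;",
      sprintf("full-array fraction %.3f", x$full_array_fraction), "\n")
  print(x$per_design, row.names = FALSE)
  invisible(x)
}

#' Fold gain in segmented reads over a monomer run
#'
#' @param stats `flic_array_stats` (or an s-read count).
#' @param monomer_read_count reads of the non-concatemer comparator.
#' @return fold ratio, one decimal (half-up).
#' @export
sread_gain <- function(stats, monomer_read_count) {
  if (monomer_read_count <= 0) stop("monomer read count must be positive")
  n <- if (inherits(stats, "flic_array_stats")) stats$n_sreads else stats
  round_half_up(n / monomer_read_count, 1)
}
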