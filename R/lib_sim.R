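# Wet-lab simulator: expression sampling, cDNA synthesis with
# template-switching (TSO) artifacts, bead-capture length bias, two-fraction
# size selection, barcode-directed concatenation into dimer/tetramer arrays,
# and a HiFi error model.  Every read carries hidden truth segments so
# downstream stages can be tested against an oracle.

# Fixed synthetic 5'/3' cDNA primers (any pair of distinguishable,
# non-A-rich sequences works; only their detectability matters).
FLIC_PRIMER5 <- "GCAATGAAGTCGCAGGGTTGACTC"
FLIC_PRIMER3 <- "GTACTCTGCGTTGATACCACTGCT"

#' Default cDNA primer pair
#'
#' @return list with `pair_id`, `p5`, `p3` (sense-orientation sequences; a
#'   sense molecule reads `p5 + insert + polyA + p3`).
#' @export
default_primer_pair <- function() {
  list(pair_id = "iso1", p5 = FLIC_PRIMER5, p3 = FLIC_PRIMER3)
}

#' Sample an expression profile and molecule counts
#'
#' Spike-in transcripts (classes `sirv_isoform`, `long_sirv`) are equimolar
#' among themselves and receive `spikein_fraction` of the total abundance
#' (2% is the library design point); background transcripts receive the
#' remainder under a log-normal abundance profile.  TPM values are the
#' design abundances (they sum to exactly 1e6); molecule counts are one
#' multinomial draw.
#'
#' @param ann `flic_annotation`.
#' @param total_molecules molecules to draw.
#' @param spikein_fraction proportion of molecules from spike-ins.
#' @param background_profile `"lognormal"` or `"uniform"`.
#' @param sdlog log-normal sd for the background profile.
#' @param gene_fold optional named vector of per-gene abundance multipliers
#'   (used to spike differential expression into one condition).
#' @param seed integer seed.
#' @return data.frame(transcript_id, tpm, copies).
#' @export
sample_expression <- function(ann, total_molecules,
                              spikein_fraction = 0.02,
                              background_profile = c("lognormal", "uniform"),
                              sdlog = 1.5, gene_fold = NULL, seed = 1) {
  background_profile <- match.arg(background_profile)
  stopifnot(total_molecules >= 0, spikein_fraction >= 0,
            spikein_fraction <= 1)
  tx <- ann$transcripts
  if (nrow(tx) == 0L) stop("empty annotation")
  spike <- tx$class %in% c("sirv_isoform", "long_sirv")
  with_seed(seed, {
    w <- numeric(nrow(tx))
    if (any(spike)) w[spike] <- 1 / sum(spike)
    if (any(!spike)) {
      wb <- if (background_profile == "lognormal")
        rlnorm(sum(!spike), meanlog = 0, sdlog = sdlog)
      else rep(1, sum(!spike))
      if (!is.null(gene_fold)) {
        f <- gene_fold[tx$gene_id[!spike]]
        wb <- wb * ifelse(is.na(f), 1, f)
      }
      w[!spike] <- wb / sum(wb)
    }
    # weight the two blocks; degrade gracefully when one block is absent
    fr_spike <- if (!any(!spike)) 1 else if (!any(spike)) 0 else spikein_fraction
    w[spike] <- w[spike] * fr_spike
    w[!spike] <- w[!spike] * (1 - fr_spike)
    w <- w / sum(w)
    copies <- if (total_molecules == 0) integer(nrow(tx))
              else as.integer(rmultinom(1, total_molecules, w))
    data.frame(transcript_id = tx$transcript_id,
               tpm = w * 1e6, copies = copies)
  })
}

#' Synthesize cDNA molecules
#'
#' One molecule per sampled copy: `p5 + insert + polyA + p3`, error-free at
#' this stage.  TSO artifact molecules are added at `tso_artifact_rate`
#' (binomial in the copy total): an internal transcript fragment flanked by
#' primers but with no oligo(dT)-derived poly(A) structure.
#'
#' @param records output of [sample_expression()].
#' @param ann,genome the reference.
#' @param tso_artifact_rate artifact molecules per genuine copy.
#' @param polya_len poly(A) tail length in bp.
#' @param primer_pair list(pair_id, p5, p3).
#' @param seed integer seed.
#' @return data.frame(molecule_id, transcript_id, artifact, sequence,
#'   length); `artifact` is `"none"` or `"tso_artifact"`.
#' @export
synthesize_cdna <- function(records, ann, genome, tso_artifact_rate = 0.02,
                            polya_len = 30, primer_pair = default_primer_pair(),
                            seed = 1) {
  stopifnot(tso_artifact_rate >= 0, tso_artifact_rate < 1)
  expressed <- records[records$copies > 0, , drop = FALSE]
  tail_a <- paste(rep("A", polya_len), collapse = "")
  with_seed(seed, {
    seqs <- if (nrow(expressed)) {
      transcript_sequences(ann, genome, expressed$transcript_id)
    } else character(0)
    src <- rep(expressed$transcript_id, expressed$copies)
    insert <- rep(unname(seqs), expressed$copies)
    mol_seq <- paste0(primer_pair$p5, insert, tail_a, primer_pair$p3)
    n <- length(src)
    n_art <- if (n > 0) rbinom(1, n, tso_artifact_rate) else 0L
    art_seq <- character(0); art_src <- character(0)
    if (n_art > 0) {
      pick <- sample.int(n, n_art, replace = TRUE)
      art_src <- src[pick]
      art_seq <- vapply(pick, function(i) {
        ins <- insert[i]
        L <- nchar(ins)
        fs <- sample.int(max(L - 100L, 1L), 1L)
        fl <- min(L - fs + 1L, sample(100:1000, 1L))
        paste0(primer_pair$p5, substr(ins, fs, fs + fl - 1L), primer_pair$p3)
      }, character(1))
    }
    out <- data.frame(
      molecule_id = sprintf("mol%07d", seq_len(n + n_art)),
      transcript_id = c(src, art_src),
      artifact = rep(c("none", "tso_artifact"), c(n, n_art)),
      sequence = c(mol_seq, art_seq))
    out$length <- nchar(out$sequence)
    out
  })
}

#' Length-dependent capture retention probability
#'
#' 1 up to `knee_bp`, then a logistic decline in log-length towards
#' `floor_retention`.  Defaults are calibrated so that capture of ~12 kb
#' molecules is effectively zero while ~10 kb molecules retain at a low but
#' nonzero rate, reproducing the loss of the longest spike-ins.
#'
#' @param length_bp molecule lengths.
#' @param knee_bp length up to which retention is 1.
#' @param floor_retention lower bound of the retention curve.
#' @param steepness logistic steepness in log-length.
#' @param midpoint_bp logistic midpoint.
#' @return retention probabilities in `[0, 1]`.
#' @export
capture_retention <- function(length_bp, knee_bp = 2000, floor_retention = 0,
                              steepness = 35, midpoint_bp = 8000) {
  stopifnot(knee_bp > 0, floor_retention >= 0, floor_retention <= 1)
  norm <- plogis(steepness * (log(midpoint_bp) - log(knee_bp)))
  r <- plogis(steepness * (log(midpoint_bp) - log(length_bp))) / norm
  r[length_bp <= knee_bp] <- 1
  pmax(pmin(r, 1), floor_retention)
}

#' Bead-capture filter
#'
#' Removes every TSO-artifact molecule (the purpose of the capture step)
#' and thins the remainder by the length-dependent retention probability of
#' [capture_retention()].
#'
#' @param molecules data.frame from [synthesize_cdna()].
#' @inheritParams capture_retention
#' @param seed integer seed.
#' @return retained molecules (same columns).
#' @export
capture_filter <- function(molecules, knee_bp = 2000, floor_retention = 0,
                           steepness = 35, midpoint_bp = 8000, seed = 1) {
  keep_type <- molecules$artifact == "none"
  r <- capture_retention(molecules$length, knee_bp, floor_retention,
                         steepness, midpoint_bp)
  with_seed(seed, {
    kept <- keep_type & (runif(nrow(molecules)) < r)
    molecules[kept, , drop = FALSE]
  })
}

#' Two-fraction size selection
#'
#' Partition on total molecule length: the long fraction (> 2,000 bp) feeds
#' dimer arrays, the short fraction (500-2,000 bp, bounds inclusive) feeds
#' tetramer arrays, and molecules under 500 bp are discarded.
#'
#' @param molecules data.frame of molecules.
#' @param long_min exclusive lower bound of the long fraction.
#' @param short_min inclusive lower bound of the short fraction.
#' @return list(long, short, discarded) of molecule data.frames.
#' @export
size_select <- function(molecules, long_min = 2000, short_min = 500) {
  len <- molecules$length
  list(long = molecules[len > long_min, , drop = FALSE],
       short = molecules[len >= short_min & len <= long_min, , drop = FALSE],
       discarded = molecules[len < short_min, , drop = FALSE])
}

#' Create a concatemer array design
#'
#' `arity + 1` junction barcodes (none for the monomer design) with a
#' minimum pairwise edit distance, generated by rejection sampling.
#'
#' @param arity segments per full array: 1 (monomer), 2 (dimer) or
#'   4 (tetramer).
#' @param barcode_len barcode length in bp.
#' @param min_dist minimum pairwise edit distance between barcodes.
#' @param seed integer seed.
#' @param design_id label (defaults to monomer/dimer/tetramer).
#' @return object of class `flic_array_design`.
#' @export
make_array_design <- function(arity, barcode_len = 16, min_dist = 5,
                              seed = 1, design_id = NULL) {
  stopifnot(arity %in% c(1, 2, 4))
  design_id <- design_id %||%
    c("1" = "monomer", "2" = "dimer", "4" = "tetramer")[as.character(arity)]
  n_bc <- if (arity == 1) 0L else arity + 1L
  barcodes <- character(0)
  with_seed(seed, {
    while (length(barcodes) < n_bc) {
      cand <- random_dna(barcode_len)
      if (length(barcodes) == 0L || min(adist(cand, barcodes)) >= min_dist)
        barcodes <- c(barcodes, cand)
    }
  })
  structure(list(design_id = design_id, arity = as.integer(arity),
                 barcodes = barcodes),
            class = "flic_array_design")
}

#' @export
print.flic_array_design <- function(x, ...) {
  cat("flic_array_design", x$design_id, "- arity", x$arity, "with",
      length(x$barcodes), "junction barcodes\n")
  invisible(x)
}

#' Concatenate molecules into arrays
#'
#' Molecules are drawn without replacement into arrays of `design$arity`
#' segments, each flanked by the ordered junction barcodes
#' (`B1 m1 B2 m2 ... B(k+1)`).  With probability `1 - full_array_rate` an
#' array is truncated uniformly to 1..arity-1 segments (incomplete
#' ligation); leftover molecules form a final partial array.  Each emitted
#' read is reverse-complemented with probability `flip_prob` (sequencing
#' strand is arbitrary); truth coordinates follow the emitted sequence.
#'
#' @param molecules molecule data.frame (a size fraction).
#' @param design `flic_array_design`.
#' @param full_array_rate probability an array carries all `arity` segments.
#' @param seed integer seed.
#' @param n_arrays build exactly this many arrays (error if molecules run
#'   short); default: consume all molecules.
#' @param flip_prob probability a read is emitted reverse-complemented.
#' @param read_prefix read id prefix.
#' @return list with `reads` (read_id, design_id, sequence,
#'   n_segments_true, flipped), `truth` (read_id, segment_index,
#'   molecule_id, transcript_id, artifact, start, end, rc; 1-based
#'   inclusive read coordinates) and `lost` (molecule ids dropped by
#'   truncation).
#' @export
concatenate <- function(molecules, design, full_array_rate = 1, seed = 1,
                        n_arrays = NULL, flip_prob = 0.5,
                        read_prefix = NULL) {
  stopifnot(inherits(design, "flic_array_design"),
            full_array_rate > 0, full_array_rate <= 1)
  if (nrow(molecules) == 0L)
    return(list(reads = data.frame(read_id = character(0),
                                   design_id = character(0),
                                   sequence = character(0),
                                   n_segments_true = integer(0),
                                   flipped = logical(0)),
                truth = data.frame(), lost = character(0)))
  arity <- design$arity
  read_prefix <- read_prefix %||% paste0(design$design_id, "_read")
  with_seed(seed, {
    idx <- sample.int(nrow(molecules))
    if (!is.null(n_arrays)) {
      need <- n_arrays * arity
      if (length(idx) < need)
        stop("need ", need, " molecules for ", n_arrays, " arrays, have ",
             length(idx))
      idx <- idx[seq_len(need)]
    }
    groups <- split(idx, ceiling(seq_along(idx) / arity))
    ng <- length(groups)
    r_seq <- character(ng); r_k <- integer(ng); r_flip <- logical(ng)
    t_read <- vector("list", ng); t_g <- vector("list", ng)
    t_start <- vector("list", ng); t_end <- vector("list", ng)
    lost_list <- vector("list", ng)
    rid <- sprintf("%s%06d", read_prefix, seq_len(ng))
    for (gi in seq_len(ng)) {
      g <- groups[[gi]]
      k <- length(g)
      if (k == arity && arity > 1L && runif(1) > full_array_rate) {
        k_new <- sample.int(arity - 1L, 1L)
        lost_list[[gi]] <- molecules$molecule_id[g[(k_new + 1L):k]]
        g <- g[seq_len(k_new)]
        k <- k_new
      }
      segs <- molecules$sequence[g]
      if (length(design$barcodes)) {
        bcs <- design$barcodes[seq_len(k + 1L)]
        pieces <- character(2L * k + 1L)
        pieces[seq(1L, 2L * k + 1L, by = 2L)] <- bcs
        pieces[seq(2L, 2L * k, by = 2L)] <- segs
      } else pieces <- segs
      seq <- paste(pieces, collapse = "")
      piece_len <- nchar(pieces)
      piece_end <- cumsum(piece_len)
      seg_slots <- if (length(design$barcodes)) seq(2L, 2L * k, by = 2L)
                   else seq_len(k)
      starts <- piece_end[seg_slots] - piece_len[seg_slots] + 1L
      ends <- piece_end[seg_slots]
      flip <- runif(1) < flip_prob
      if (flip) {
        L <- nchar(seq)
        new_starts <- L - ends + 1L
        new_ends <- L - starts + 1L
        # segment order reverses in the emitted read
        starts <- rev(new_starts); ends <- rev(new_ends)
        g <- rev(g)
      }
      r_seq[gi] <- seq; r_k[gi] <- k; r_flip[gi] <- flip
      t_read[[gi]] <- rep(rid[gi], k); t_g[[gi]] <- g
      t_start[[gi]] <- starts; t_end[[gi]] <- ends
    }
    flip_idx <- which(r_flip)
    if (length(flip_idx)) r_seq[flip_idx] <- revcomp(r_seq[flip_idx])
    gall <- unlist(t_g)
    reads <- data.frame(read_id = rid, design_id = design$design_id,
                        sequence = unname(r_seq), n_segments_true = r_k,
                        flipped = r_flip, row.names = NULL)
    truth <- data.frame(
      read_id = unlist(t_read),
      segment_index = sequence(r_k),
      molecule_id = unname(molecules$molecule_id[gall]),
      transcript_id = unname(molecules$transcript_id[gall]),
      artifact = unname(molecules$artifact[gall]),
      start = unname(unlist(t_start)), end = unname(unlist(t_end)),
      rc = rep(r_flip, r_k), row.names = NULL)
    list(reads = reads, truth = truth, lost = unlist(lost_list) %||%
           character(0))
  })
}

#' Inject HiFi-style sequencing errors
#'
#' Substitutions, insertions and deletions at `per_base_error` total rate
#' (default 0.001, the ~Q30 accuracy of circular consensus reads) in a
#' configurable 2:1:1 ratio.  Truth segment offsets are shifted through the
#' injected indels.
#'
#' @param sim list(reads, truth) from [concatenate()].
#' @param per_base_error total error rate per base (`< 0.1`).
#' @param sub_frac,ins_frac,del_frac error-type proportions (must sum to 1).
#' @param seed integer seed.
#' @return `sim` with mutated sequences, updated truth offsets and an
#'   `n_edits` column on `reads`.
#' @export
apply_hifi_errors <- function(sim, per_base_error = 0.001, sub_frac = 0.5,
                              ins_frac = 0.25, del_frac = 0.25, seed = 1) {
  stopifnot(per_base_error >= 0, per_base_error < 0.1,
            abs(sub_frac + ins_frac + del_frac - 1) < 1e-9)
  reads <- sim$reads
  truth <- sim$truth
  reads$n_edits <- 0L
  if (per_base_error == 0 || nrow(reads) == 0L)
    return(list(reads = reads, truth = truth, lost = sim$lost))
  truth_by_read <- split(seq_len(nrow(truth)), truth$read_id)
  with_seed(seed, {
    for (i in seq_len(nrow(reads))) {
      s <- reads$sequence[i]
      L <- nchar(s)
      k <- rbinom(1, L, per_base_error)
      if (k == 0L) next
      pos <- sort(sample.int(L, min(k, L)))
      type <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE,
                     prob = c(sub_frac, ins_frac, del_frac))
      for (j in rev(seq_along(pos))) {       # right to left: stable positions
        p <- pos[j]
        if (type[j] == "sub") {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
        } else if (type[j] == "ins") {
          s <- paste0(substr(s, 1L, p - 1L), sample(DNA_BASES, 1L),
                      substr(s, p, nchar(s)))
        } else {
          s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
        }
      }
      reads$sequence[i] <- s
      reads$n_edits[i] <- length(pos)
      tr <- truth_by_read[[reads$read_id[i]]]
      if (length(tr)) {
        ins_pos <- pos[type == "ins"]; del_pos <- pos[type == "del"]
        shift <- function(b) {
          b + vapply(b, function(x) sum(ins_pos <= x), numeric(1)) -
            vapply(b, function(x) sum(del_pos <= x), numeric(1))
        }
        newL <- nchar(s)
        truth$start[tr] <- pmax(1L, pmin(newL, shift(truth$start[tr])))
        truth$end[tr] <- pmax(truth$start[tr], pmin(newL, shift(truth$end[tr])))
      }
    }
    list(reads = reads, truth = truth, lost = sim$lost)
  })
}
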