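# Clustering of FLNC reads into high-quality (HQ) isoforms.  Two aligned
# reads merge when their strand-aware 5'/3' ends differ by less than 100/30
# bp and their internal splice junctions agree within a 10-bp wobble;
# clusters are the connected components of that relation (single linkage),
# computed in a deterministic order.

chain_end5 <- function(chain) {
  if (chain$strand == "+") chain$starts[1L] else chain$ends[length(chain$ends)]
}
chain_end3 <- function(chain) {
  if (chain$strand == "+") chain$ends[length(chain$ends)] else chain$starts[1L]
}

#' Are two aligned exon chains mergeable?
#'
#' @param a,b `flic_chain` objects.
#' @param d5 maximum 5' end difference in bp (exclusive bound).
#' @param d3 maximum 3' end difference in bp (exclusive bound).
#' @param gap splice-junction wobble tolerance in bp (inclusive: a 10-bp
#'   shift passes at the default, 11 fails).
#' @return TRUE/FALSE; chains on different contigs or strands are FALSE.
#' @export
mergeable <- function(a, b, d5 = 100, d3 = 30, gap = 10) {
  if (a$contig != b$contig || a$strand != b$strand) return(FALSE)
  if (abs(chain_end5(a) - chain_end5(b)) >= d5) return(FALSE)
  if (abs(chain_end3(a) - chain_end3(b)) >= d3) return(FALSE)
  ja <- chain_introns(a); jb <- chain_introns(b)
  if (nrow(ja) != nrow(jb)) return(FALSE)
  if (nrow(ja) == 0L) return(TRUE)
  all(abs(ja - jb) <= gap)
}

# union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) {
  while (p[i] != i) i <- p[i]
  i
}
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[max(ri, rj)] <- min(ri, rj)
  p
}

#' Collapse aligned FLNC reads into HQ isoform clusters
#'
#' Reads are processed in a deterministic order (contig, strand, 5'
#' genomic position, id); identical chains are pooled first, then unique
#' chains within a sliding genomic window are tested pairwise with
#' [mergeable()] and joined by union-find.  Single-linkage semantics:
#' reads whose ends differ by more than the window can still end up in one
#' cluster through intermediates.
#'
#' @param reads data.frame with columns `id` and `chain` (list of
#'   `flic_chain`).
#' @inheritParams mergeable
#' @return data.frame(cluster_id, chain, support, representative,
#'   members); `chain` holds the representative chain (longest genomic
#'   span, ties to the lexicographically smallest id), `members` the read
#'   ids.  `sum(support)` equals `nrow(reads)`.
#' @export
collapse_flnc <- function(reads, d5 = 100, d3 = 30, gap = 10) {
  empty <- data.frame(cluster_id = character(0), chain = I(list()),
                      support = integer(0), representative = character(0),
                      members = I(list()))
  if (nrow(reads) == 0L) return(empty)
  key <- vapply(reads$chain, chain_key, character(1))
  ord <- order(vapply(reads$chain, function(c) c$contig, character(1)),
               vapply(reads$chain, function(c) c$strand, character(1)),
               vapply(reads$chain, function(c) min(c$starts), numeric(1)),
               reads$id)
  reads <- reads[ord, , drop = FALSE]
  key <- key[ord]

  uniq <- !duplicated(key)
  ukey <- key[uniq]
  uchain <- reads$chain[uniq]
  uidx <- match(key, ukey)              # read -> unique chain
  nu <- length(ukey)
  p <- uf_new(nu)

  ucontig <- vapply(uchain, function(c) c$contig, character(1))
  ustrand <- vapply(uchain, function(c) c$strand, character(1))
  ustart <- vapply(uchain, function(c) min(c$starts), numeric(1))
  win <- max(d5, d3)
  for (grp in split(seq_len(nu), paste(ucontig, ustrand))) {
    grp <- grp[order(ustart[grp])]
    for (ii in seq_along(grp)) {
      i <- grp[ii]
      jj <- ii + 1L
      while (jj <= length(grp) && ustart[grp[jj]] - ustart[i] < win) {
        j <- grp[jj]
        if (mergeable(uchain[[i]], uchain[[j]], d5, d3, gap))
          p <- uf_union(p, i, j)
        jj <- jj + 1L
      }
    }
  }
  root <- vapply(seq_len(nu), function(i) uf_find(p, i), integer(1))
  comp <- split(seq_len(nu), root)

  rows <- lapply(comp, function(us) {
    ridx <- which(uidx %in% us)
    ids <- reads$id[ridx]
    chains <- uchain[us]
    span <- vapply(chains, function(c) max(c$ends) - min(c$starts), numeric(1))
    # representative: longest span, tie to smallest member id of that chain
    first_id <- vapply(us, function(u) min(reads$id[uidx == u]), character(1))
    best <- order(-span, first_id)[1L]
    list(chain = chains[[best]], support = length(ids),
         representative = min(ids), members = ids)
  })
  ord2 <- order(vapply(rows, function(r) r$chain$contig, character(1)),
                vapply(rows, function(r) r$chain$strand, character(1)),
                vapply(rows, function(r) min(r$chain$starts), numeric(1)),
                vapply(rows, function(r) r$representative, character(1)))
  rows <- rows[ord2]
  data.frame(cluster_id = sprintf("cl%06d", seq_along(rows)),
             chain = I(lapply(rows, `[[`, "chain")),
             support = vapply(rows, `[[`, integer(1), "support"),
             representative = vapply(rows, `[[`, character(1), "representative"),
             members = I(lapply(rows, `[[`, "members")))
}

#' Filter clusters by CCS read support
#'
#' @param clusters output of [collapse_flnc()].
#' @param min_ccs minimum supporting read count (2 is the default isoform
#'   calling rule; 4 and 10 are the raised thresholds).
#' @return clusters with `support >= min_ccs`, order preserved.
#' @export
filter_by_support <- function(clusters, min_ccs) {
  stopifnot(min_ccs >= 1)
  clusters[clusters$support >= min_ccs, , drop = FALSE]
}

#' Attach truth exon chains to FLNC reads
#'
#' Simulation-mode stand-in for spliced alignment: each FLNC read inherits
#' the exon chain of its source transcript, optionally with strand-aware
#' random end jitter emulating mapper end variability (drawn once per
#' read; terminal exons never shrink below 1 bp).
#'
#' @param flnc output of [refine_reads()] (status `flnc` rows are used).
#' @param matched s-read/truth join from [match_sreads_to_truth()].
#' @param ann `flic_annotation`.
#' @param jitter_sd5,jitter_sd3 normal sd of the 5'/3' end jitter in bp
#'   (0 = exact truth chains).
#' @param seed integer seed.
#' @return data.frame(id, transcript_id, chain) for clustering.
#' @export
align_truth <- function(flnc, matched, ann, jitter_sd5 = 0, jitter_sd3 = 0,
                        seed = 1) {
  keep <- flnc$status == "flnc"
  src <- matched$transcript_id[match(flnc$sread_id[keep], matched$sread_id)]
  ok <- !is.na(src) & src %in% ann$transcripts$transcript_id
  ids <- flnc$flnc_id[keep][ok]
  src <- src[ok]
  chains0 <- lapply(unique(src), function(t) transcript_chain(ann, t))
  names(chains0) <- unique(src)
  with_seed(seed, {
    chains <- lapply(seq_along(ids), function(i) {
      ch <- chains0[[src[i]]]
      if (jitter_sd5 > 0 || jitter_sd3 > 0) {
        j5 <- as.integer(round(rnorm(1, 0, jitter_sd5)))
        j3 <- as.integer(round(rnorm(1, 0, jitter_sd3)))
        n <- length(ch$starts)
        if (ch$strand == "+") {
          ch$starts[1L] <- min(ch$starts[1L] + j5, ch$ends[1L] - 1L)
          ch$ends[n] <- max(ch$ends[n] + j3, ch$starts[n] + 1L)
        } else {
          ch$ends[n] <- max(ch$ends[n] - j5, ch$starts[n] + 1L)
          ch$starts[1L] <- min(ch$starts[1L] - j3, ch$ends[1L] - 1L)
        }
        ch$starts <- pmax(ch$starts, 0L)
      }
      ch
    })
    data.frame(id = ids, transcript_id = src, chain = I(chains))
  })
}
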