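# Structural classification of HQ isoforms against a reference annotation,
# following the nine SQANTI3-style categories.  Decision order (documented,
# since the underlying tools do not print theirs): splice-match classes
# first (FSM, ISM), then fusion, then splice-site novelty (NIC, NNC);
# chains without same-strand gene overlap fall through to antisense /
# genic_intronic / genic_genomic / intergenic.

FLIC_CATEGORIES <- c("FSM", "ISM", "NIC", "NNC", "genic_genomic",
                     "antisense", "fusion", "intergenic", "genic_intronic")

intron_key <- function(introns) {
  if (nrow(introns) == 0L) return("")
  paste(introns[, 1L], introns[, 2L], sep = "-", collapse = "|")
}

# reference feature tables reused across queries
build_classify_index <- function(ann) {
  tx <- ann$transcripts
  chains <- lapply(tx$transcript_id, function(t) transcript_chain(ann, t))
  names(chains) <- tx$transcript_id
  introns <- lapply(chains, chain_introns)
  multi <- vapply(introns, nrow, integer(1)) > 0L
  keystr <- vapply(introns, intron_key, character(1))
  cs <- paste(tx$contig_id, tx$strand)

  donors <- list(); acceptors <- list(); intron_tab <- list()
  for (grp in unique(cs)) {
    sel <- which(cs == grp & multi)
    dd <- integer(0); aa <- integer(0); it <- matrix(integer(0), ncol = 2)
    for (i in sel) {
      im <- introns[[i]]
      if (tx$strand[i] == "+") {
        dd <- c(dd, im[, 1L]); aa <- c(aa, im[, 2L])
      } else {
        dd <- c(dd, im[, 2L]); aa <- c(aa, im[, 1L])
      }
      it <- rbind(it, im)
    }
    donors[[grp]] <- unique(dd)
    acceptors[[grp]] <- unique(aa)
    intron_tab[[grp]] <- unique(it)
  }
  list(tx = tx, chains = chains, introns = introns, multi = multi,
       keystr = keystr, cs = cs, donors = donors, acceptors = acceptors,
       intron_tab = intron_tab)
}

# best FSM/ISM match among candidate transcript ids: closest total end
# distance, ties to lexicographically smallest id
best_match <- function(cands, chain, idx) {
  if (length(cands) == 1L) return(cands)
  dist <- vapply(cands, function(t) {
    r <- idx$chains[[t]]
    abs(chain_end5(r) - chain_end5(chain)) +
      abs(chain_end3(r) - chain_end3(chain))
  }, numeric(1))
  cands[order(dist, cands)][1L]
}

classify_chain <- function(chain, ann, idx, end_tolerance = 50) {
  grp <- paste(chain$contig, chain$strand)
  span_s <- min(chain$starts); span_e <- max(chain$ends)
  gs <- genes_overlapping(ann, chain$contig, span_s, span_e,
                          strand = chain$strand)
  anti_strand <- if (chain$strand == "+") "-" else "+"
  go <- genes_overlapping(ann, chain$contig, span_s, span_e,
                          strand = anti_strand)
  qi <- chain_introns(chain)
  multi <- nrow(qi) > 0L

  res <- function(category, matched = NA_character_, genes = gs) {
    list(category = category, matched = matched,
         genes = paste(sort(unique(genes)), collapse = ","))
  }

  # exon-level overlap helpers
  exon_olap <- function(strand) {
    any(vapply(seq_along(chain$starts), function(i) {
      nrow(exons_overlapping(ann, chain$contig, chain$starts[i],
                             chain$ends[i], strand = strand)) > 0L
    }, logical(1)))
  }
  within_intron <- function() {
    for (g2 in c(grp, paste(chain$contig, anti_strand))) {
      it <- idx$intron_tab[[g2]]
      if (!is.null(it) && nrow(it) &&
          any(it[, 1L] <= span_s & span_e <= it[, 2L]))
        return(TRUE)
    }
    FALSE
  }

  same_grp_tx <- which(idx$cs == grp)
  # splice-match classes first, against same contig/strand transcripts
  # (covers annotated antisense transcripts whose host gene is sense)
  if (multi) {
    qkey <- intron_key(qi)
    hit <- idx$tx$transcript_id[same_grp_tx][
      idx$keystr[same_grp_tx] == qkey & idx$multi[same_grp_tx]]
    if (length(hit))
      return(res("FSM", matched = best_match(hit, chain, idx),
                 genes = idx$tx$gene_id[match(best_match(hit, chain, idx),
                                              idx$tx$transcript_id)]))
    # intron retention: a query exon spans a whole annotated intron; such
    # chains are novel-in-catalog, never truncated matches
    it <- idx$intron_tab[[grp]] %||% matrix(integer(0), ncol = 2)
    retained <- nrow(it) > 0L &&
      any(vapply(seq_along(chain$starts), function(k) {
        any(chain$starts[k] < it[, 1L] & it[, 2L] < chain$ends[k])
      }, logical(1)))
    # ISM: contiguous intron sub-chain of a reference
    needle <- paste0("|", qkey, "|")
    ism <- idx$tx$transcript_id[same_grp_tx][vapply(same_grp_tx, function(i) {
      idx$multi[i] && grepl(needle, paste0("|", idx$keystr[i], "|"),
                            fixed = TRUE)
    }, logical(1))]
    if (length(ism) && !retained) {
      m <- best_match(ism, chain, idx)
      return(res("ISM", matched = m,
                 genes = idx$tx$gene_id[match(m, idx$tx$transcript_id)]))
    }
    if (length(gs) == 0L) {
      if (length(go) > 0L && exon_olap(anti_strand))
        return(res("antisense", genes = go))
      if (length(go) > 0L) return(res("antisense", genes = go))
      return(res("intergenic", genes = character(0)))
    }
    if (length(gs) >= 2L) return(res("fusion"))
    dset <- idx$donors[[grp]] %||% integer(0)
    aset <- idx$acceptors[[grp]] %||% integer(0)
    if (chain$strand == "+") {
      qd <- qi[, 1L]; qa <- qi[, 2L]
    } else {
      qd <- qi[, 2L]; qa <- qi[, 1L]
    }
    if (all(qd %in% dset) && all(qa %in% aset)) return(res("NIC"))
    return(res("NNC"))
  }

  # mono-exon query: splice-match classes first
  mono_ref <- idx$tx$transcript_id[same_grp_tx][!idx$multi[same_grp_tx]]
  cont <- mono_ref[vapply(mono_ref, function(t) {
    r <- idx$chains[[t]]
    span_s >= r$starts[1L] - end_tolerance &&
      span_e <= r$ends[1L] + end_tolerance
  }, logical(1))]
  if (length(cont)) {
    m <- best_match(cont, chain, idx)
    return(res("FSM", matched = m,
               genes = idx$tx$gene_id[match(m, idx$tx$transcript_id)]))
  }
  # inside one exon of a same-strand multi-exon reference -> ISM
  multi_ref <- idx$tx$transcript_id[same_grp_tx][idx$multi[same_grp_tx]]
  ism <- multi_ref[vapply(multi_ref, function(t) {
    r <- idx$chains[[t]]
    any(r$starts <= span_s & span_e <= r$ends)
  }, logical(1))]
  if (length(ism)) {
    m <- best_match(ism, chain, idx)
    return(res("ISM", matched = m,
               genes = idx$tx$gene_id[match(m, idx$tx$transcript_id)]))
  }
  if (length(gs) == 0L) {
    if (length(go) > 0L) {
      if (exon_olap(anti_strand)) return(res("antisense", genes = go))
      if (within_intron()) return(res("genic_intronic", genes = go))
      return(res("antisense", genes = go))
    }
    return(res("intergenic", genes = character(0)))
  }
  if (within_intron()) return(res("genic_intronic"))
  res("genic_genomic")
}

#' Classify one exon chain
#'
#' @param chain `flic_chain` to classify.
#' @param ann reference `flic_annotation`.
#' @param end_tolerance bp window for mono-exon FSM containment.
#' @return list(category, matched, genes).
#' @export
classify_isoform <- function(chain, ann, end_tolerance = 50) {
  classify_chain(chain, ann, build_classify_index(ann), end_tolerance)
}

#' Classify a set of HQ isoform clusters
#'
#' Applies the structural rules to every cluster and assigns novel gene
#' ids to intergenic isoforms (one id per overlapping intergenic group on
#' a contig/strand), so unique-gene counting includes novel loci.
#'
#' @param clusters output of [collapse_flnc()] (columns `cluster_id`,
#'   `chain`, `support`).
#' @param ann reference `flic_annotation`.
#' @param end_tolerance bp window for mono-exon FSM containment.
#' @return data.frame(cluster_id, category, matched_transcript, gene_ids,
#'   spliced_len, support).
#' @export
classify_isoforms <- function(clusters, ann, end_tolerance = 50) {
  idx <- build_classify_index(ann)
  n <- nrow(clusters)
  out <- data.frame(cluster_id = clusters$cluster_id,
                    category = character(n),
                    matched_transcript = NA_character_,
                    gene_ids = NA_character_,
                    spliced_len = vapply(clusters$chain, chain_len, numeric(1)),
                    support = clusters$support)
  for (i in seq_len(n)) {
    r <- classify_chain(clusters$chain[[i]], ann, idx, end_tolerance)
    out$category[i] <- r$category
    out$matched_transcript[i] <- r$matched
    out$gene_ids[i] <- r$genes
  }
  # novel gene ids for intergenic isoforms: overlap clusters per contig/strand
  ig <- which(out$category == "intergenic")
  if (length(ig)) {
    contig <- vapply(clusters$chain[ig], function(c) c$contig, character(1))
    strand <- vapply(clusters$chain[ig], function(c) c$strand, character(1))
    s <- vapply(clusters$chain[ig], function(c) min(c$starts), numeric(1))
    e <- vapply(clusters$chain[ig], function(c) max(c$ends), numeric(1))
    gid <- integer(length(ig))
    counter <- 0L
    for (grp in split(seq_along(ig), paste(contig, strand))) {
      grp <- grp[order(s[grp])]
      cur_end <- -Inf
      for (k in grp) {
        if (s[k] > cur_end) counter <- counter + 1L
        gid[k] <- counter
        cur_end <- max(cur_end, e[k])
      }
    }
    out$gene_ids[ig] <- sprintf("novelGene_%03d", gid)
  }
  out
}

#' Spike-in isoform recall
#'
#' A truth transcript is detected when some FSM isoform matches it with at
#' least `min_support` reads (one CCS read by default).
#'
#' @param classified output of [classify_isoforms()].
#' @param truth_ids spike-in transcript ids.
#' @param min_support minimum cluster support.
#' @return list(n_detected, recall) with recall in percent, one decimal.
#' @export
sirv_recall <- function(classified, truth_ids, min_support = 1) {
  stopifnot(length(truth_ids) > 0)
  hit <- classified$category == "FSM" &
    classified$support >= min_support &
    classified$matched_transcript %in% truth_ids
  det <- unique(classified$matched_transcript[hit])
  list(n_detected = length(det),
       recall = percent_of(length(det), length(truth_ids)))
}

#' Read support per transcript-length bin
#'
#' @param classified output of [classify_isoforms()].
#' @param bin_width bin width in bp (1,000 bp bins by default).
#' @return data.frame(bin_start, bin_end, n_isoforms, support); bin b is
#'   `[b*width, (b+1)*width)`.  `sum(support)` is conserved.
#' @export
length_bins <- function(classified, bin_width = 1000) {
  stopifnot(bin_width > 0)
  if (nrow(classified) == 0L)
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      n_isoforms = integer(0), support = numeric(0)))
  b <- floor(classified$spliced_len / bin_width)
  agg <- aggregate(cbind(n_isoforms = 1, support = classified$support),
                   by = list(bin = b), FUN = sum)
  data.frame(bin_start = agg$bin * bin_width,
             bin_end = (agg$bin + 1) * bin_width,
             n_isoforms = agg$n_isoforms, support = agg$support)
}

#' Mean length of intergenic isoforms
#'
#' @param classified output of [classify_isoforms()].
#' @return mean spliced length of intergenic isoforms, or `NA` when none.
#' @export
intergenic_length_summary <- function(classified) {
  len <- classified$spliced_len[classified$category == "intergenic"]
  if (length(len) == 0L) return(NA_real_)
  mean(len)
}
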