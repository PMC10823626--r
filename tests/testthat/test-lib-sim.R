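test_that("equimolar spike-in sampling distributes copies evenly", {
  ref <- make_sirv_like_module(7, 69, 160, 2940, seed = 1)
  expr <- sample_expression(ref$annotation, 69000, spikein_fraction = 1,
                            seed = 1)
  expect_equal(sum(expr$copies), 69000)
  expect_equal(sum(expr$tpm), 1e6, tolerance = 1e-9)
  # each isoform ~1000 copies; 5 sigma of the multinomial marginal
  sd1 <- sqrt(69000 * (1 / 69) * (68 / 69))
  expect_true(all(abs(expr$copies - 1000) < 5 * sd1))
})

test_that("2% spike-in fraction lands within binomial error", {
  ref <- make_reference(sirv = TRUE, long = FALSE, background_genes = 20,
                        seed = 2)
  expr <- sample_expression(ref$annotation, 100000, spikein_fraction = 0.02,
                            seed = 3)
  spike <- ref$annotation$transcripts$class == "sirv_isoform"
  n_spike <- sum(expr$copies[spike])
  expect_lt(abs(n_spike - 2000), 3 * sqrt(100000 * 0.02 * 0.98))
  expect_equal(sum(expr$tpm), 1e6, tolerance = 1e-9)
})

test_that("zero molecules yields zero copies; empty annotation errors", {
  ref <- make_sirv_like_module(2, 4, 200, 600, seed = 4)
  expr <- sample_expression(ref$annotation, 0, seed = 1)
  expect_true(all(expr$copies == 0))
  empty <- structure(list(transcripts = data.frame()), class = "flic_annotation")
  expect_error(sample_expression(empty, 10, seed = 1), "empty annotation")
})

test_that("cDNA synthesis emits one molecule per copy plus artifacts", {
  ref <- make_sirv_like_module(3, 6, 300, 900, seed = 5)
  expr <- sample_expression(ref$annotation, 1000, spikein_fraction = 1,
                            seed = 2)
  m0 <- synthesize_cdna(expr, ref$annotation, ref$genome,
                        tso_artifact_rate = 0, seed = 1)
  expect_equal(nrow(m0), 1000)
  expect_true(all(m0$artifact == "none"))
  m1 <- synthesize_cdna(expr, ref$annotation, ref$genome,
                        tso_artifact_rate = 0.1, seed = 4)
  n_art <- sum(m1$artifact == "tso_artifact")
  expect_lt(abs(n_art - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  # inserts are exact transcript sequences flanked by adapters (pre-error)
  seqs <- transcript_sequences(ref$annotation, ref$genome)
  pp <- default_primer_pair()
  genuine <- m1[m1$artifact == "none", ][1:10, ]
  expect_identical(
    genuine$sequence,
    unname(paste0(pp$p5, seqs[genuine$transcript_id], strrep("A", 30),
                  pp$p3)))
  # artifacts carry no oligo(dT) tail
  art <- m1[m1$artifact == "tso_artifact", ]
  expect_false(any(grepl(paste0(strrep("A", 30), pp$p3), art$sequence,
                         fixed = TRUE)))
})

test_that("capture retention is 1 below the knee and vanishing at 12 kb", {
  expect_true(all(capture_retention(c(100, 500, 2000)) == 1))
  r <- capture_retention(c(2500, 4000, 6000, 8000, 10000, 12000))
  expect_true(all(diff(r) < 0))               # monotone decline
  expect_gt(r[5], 0)                           # 10 kb low but nonzero
  expect_lt(r[6], 1e-5)                        # 12 kb effectively zero
  mols <- data.frame(molecule_id = sprintf("m%05d", 1:10000),
                     transcript_id = "t", artifact = "none",
                     sequence = "A", length = 12000)
  kept <- capture_filter(mols, seed = 7)
  expect_equal(nrow(kept), 0)
})

test_that("capture thins by length binomially and removes artifacts", {
  mols <- data.frame(molecule_id = sprintf("m%05d", 1:10000),
                     transcript_id = "t",
                     artifact = rep(c("none", "tso_artifact"), c(9000, 1000)),
                     sequence = "A", length = 8000)
  kept <- capture_filter(mols, seed = 3)
  expect_true(all(kept$artifact == "none"))
  p <- capture_retention(8000)
  expect_lt(abs(nrow(kept) - 9000 * p), 3 * sqrt(9000 * p * (1 - p)))
  # everything under the knee is retained
  short <- data.frame(molecule_id = "m1", transcript_id = "t",
                      artifact = "none", sequence = "A", length = 1500)
  expect_equal(nrow(capture_filter(short, seed = 1)), 1)
})

test_that("size selection partitions exactly at the documented bounds", {
  mols <- data.frame(molecule_id = paste0("m", 1:4), transcript_id = "t",
                     artifact = "none", sequence = "A",
                     length = c(400, 500, 2000, 2001))
  fr <- size_select(mols)
  expect_equal(fr$discarded$length, 400)
  expect_equal(sort(fr$short$length), c(500, 2000))
  expect_equal(fr$long$length, 2001)
  empty <- size_select(mols[0, ])
  expect_equal(vapply(empty, nrow, integer(1)),
               c(long = 0L, short = 0L, discarded = 0L))
  withr::with_seed(8, {
    lens <- sample(100:5000, 1000, replace = TRUE)
    m <- data.frame(molecule_id = paste0("m", seq_along(lens)),
                    transcript_id = "t", artifact = "none", sequence = "A",
                    length = lens)
    fr2 <- size_select(m)
    o <- oracle_size_partition(lens)
    expect_identical(fr2$long$molecule_id, m$molecule_id[o$long])
    expect_identical(fr2$short$molecule_id, m$molecule_id[o$short])
    expect_identical(fr2$discarded$molecule_id, m$molecule_id[o$discarded])
  })
})

test_that("array designs have distinct, well-separated barcodes", {
  for (arity in c(2, 4)) {
    d <- make_array_design(arity, seed = 6)
    expect_length(d$barcodes, arity + 1)
    expect_true(all(nchar(d$barcodes) == 16))
    dm <- adist(d$barcodes)
    expect_true(all(dm[upper.tri(dm)] >= 5))
  }
  expect_length(make_array_design(1, seed = 1)$barcodes, 0)
})

test_that("full arrays pack exactly and reconstruct byte-for-byte", {
  mols <- random_molecules(8, seed = 10)
  des <- make_array_design(4, seed = 2)
  sim <- concatenate(mols, des, full_array_rate = 1, seed = 1,
                     flip_prob = 0)
  expect_equal(nrow(sim$reads), 2)
  expect_true(all(sim$reads$n_segments_true == 4))
  # reconstruction oracle: barcodes + truth-extracted segments = read
  for (i in 1:2) {
    tr <- sim$truth[sim$truth$read_id == sim$reads$read_id[i], ]
    segs <- substring(sim$reads$sequence[i], tr$start, tr$end)
    expect_identical(segs, mols$sequence[match(tr$molecule_id,
                                               mols$molecule_id)])
    rebuilt <- paste0(paste0(des$barcodes[1:4], segs, collapse = ""),
                      des$barcodes[5])
    expect_identical(rebuilt, sim$reads$sequence[i])
  }
  # flipped reads reconstruct through reverse complement
  simf <- concatenate(mols, des, full_array_rate = 1, seed = 3,
                      flip_prob = 1)
  tr <- simf$truth[simf$truth$read_id == simf$reads$read_id[1], ]
  segs <- substring(simf$reads$sequence[1], tr$start, tr$end)
  expect_identical(revcomp(segs),
                   mols$sequence[match(tr$molecule_id, mols$molecule_id)])
})

test_that("dimer full-array rate is recovered within 3 sigma", {
  mols <- random_molecules(20000, len_min = 100, len_max = 150, seed = 11)
  des <- make_array_design(2, seed = 4)
  sim <- concatenate(mols, des, full_array_rate = 0.777, seed = 9)
  n <- nrow(sim$reads)
  frac <- mean(sim$reads$n_segments_true == 2)
  expect_lt(abs(frac - 0.777), 3 * sqrt(0.777 * 0.223 / n))
  # conservation: every molecule packed or lost at ligation
  expect_equal(sum(sim$reads$n_segments_true) + length(sim$lost), 20000)
  expect_identical(concatenate(mols[0, ], des, seed = 1)$reads$read_id,
                   character(0))
})

test_that("error-free reads pass through the error model unchanged", {
  mols <- random_molecules(16, seed = 12)
  des <- make_array_design(4, seed = 5)
  sim <- concatenate(mols, des, full_array_rate = 1, seed = 2)
  out <- apply_hifi_errors(sim, per_base_error = 0, seed = 1)
  expect_identical(out$reads$sequence, sim$reads$sequence)
  expect_identical(out$truth, sim$truth)
  expect_true(all(out$reads$n_edits == 0))
})

test_that("injected edit totals follow the configured rate", {
  withr::with_seed(13, {
    n <- 500
    mols <- data.frame(
      molecule_id = sprintf("m%04d", 1:n), transcript_id = "t",
      artifact = "none",
      sequence = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""),
        character(1)),
      length = 2000)
  })
  des <- make_array_design(1, seed = 1)
  sim <- concatenate(mols, des, full_array_rate = 1, seed = 3,
                     flip_prob = 0)
  total_bases <- sum(nchar(sim$reads$sequence))
  expect_gte(total_bases, 1e6)
  out <- apply_hifi_errors(sim, per_base_error = 0.001, seed = 5)
  expected <- total_bases * 0.001
  expect_lt(abs(sum(out$reads$n_edits) - expected),
            3 * sqrt(total_bases * 0.001 * 0.999))
  # edit-count oracle on a sample of reads: Levenshtein distance between
  # original and mutated read never exceeds, and usually equals, the
  # injected edit count
  idx <- which(out$reads$n_edits > 0)[1:50]
  d <- mapply(function(a, b) adist(a, b),
              sim$reads$sequence[idx], out$reads$sequence[idx])
  expect_true(all(d <= out$reads$n_edits[idx]))
  expect_gt(mean(d == out$reads$n_edits[idx]), 0.9)
})

test_that("truth offsets track indels within alignment slack", {
  mols <- random_molecules(40, len_min = 400, len_max = 800, seed = 14)
  des <- make_array_design(4, seed = 6)
  sim <- concatenate(mols, des, full_array_rate = 1, seed = 4)
  out <- apply_hifi_errors(sim, per_base_error = 0.01, seed = 7)
  for (i in seq_len(nrow(out$truth))) {
    tr <- out$truth[i, ]
    seg <- substr(out$reads$sequence[out$reads$read_id == tr$read_id],
                  tr$start, tr$end)
    orig <- mols$sequence[mols$molecule_id == tr$molecule_id]
    if (tr$rc) orig <- revcomp(orig)
    # extraction at updated offsets stays within the injected edit budget
    n_ed <- out$reads$n_edits[out$reads$read_id == tr$read_id]
    expect_lte(adist(seg, orig), n_ed + 2)
  }
})

test_that("molecule conservation holds across the simulation", {
  run <- small_run()
  cnt <- run$report$counts
  expect_true(run$report$conserved)
  expect_equal(cnt$molecules,
               cnt$tso_artifacts + cnt$capture_dropped +
                 cnt$size_discarded + cnt$packed + cnt$ligation_lost +
                 cnt$unligated)
  # s-read arithmetic: truth segments count exactly
  expect_equal(sum(run$sim$reads$n_segments_true), nrow(run$sim$truth))
})
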