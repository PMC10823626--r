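test_that("structural categories follow the documented rules", {
  ann <- tiny_annotation()
  ch <- function(s, e, strand = "+") new_chain("c1", strand, s, e)
  cls <- function(x) classify_isoform(x, ann)$category
  expect_equal(cls(ch(c(100, 300, 600), c(200, 400, 700))), "FSM")
  expect_equal(cls(ch(c(120, 300, 600), c(200, 400, 680))), "FSM")
  expect_equal(cls(ch(c(310, 600), c(400, 700))), "ISM")
  expect_equal(cls(ch(c(100, 600), c(200, 700))), "FSM")       # tA2
  expect_equal(cls(ch(c(100, 300, 625), c(200, 400, 700))), "NNC")
  expect_equal(cls(ch(c(100, 600), c(450, 700))), "NNC")       # novel donor
  expect_equal(cls(ch(5100, 5500)), "FSM")                     # mono ref
  expect_equal(cls(ch(110, 190)), "ISM")                       # inside exon
  expect_equal(cls(ch(210, 290)), "genic_intronic")
  expect_equal(cls(ch(150, 250)), "genic_genomic")
  expect_equal(cls(ch(120, 390, "-")), "antisense")
  expect_equal(cls(ch(8050, 8150, "+")), "antisense")
  expect_equal(cls(ch(20000, 20500)), "intergenic")
  expect_equal(cls(ch(c(100, 5000), c(700, 5600))), "fusion")
  # annotated minus-strand transcript matches itself
  expect_equal(cls(ch(c(8000, 8500), c(8200, 8800), "-")), "FSM")
})

test_that("exon skipping with annotated sites is novel-in-catalog", {
  # mirrors a skipped-internal-exons isoform of an annotated 4-exon gene
  tx <- data.frame(transcript_id = "t4", gene_id = "g4", contig_id = "c2",
                   strand = "+", class = "background")
  ex <- data.frame(transcript_id = "t4",
                   start = c(100, 300, 600, 900),
                   end = c(200, 400, 700, 1000))
  ann <- flic_annotation(tx, ex)
  skipped <- new_chain("c2", "+", c(100, 300, 900), c(200, 400, 1000))
  r <- classify_isoform(skipped, ann)
  expect_equal(r$category, "NIC")
})

test_that("retained introns with annotated junctions are novel-in-catalog", {
  # mirrors a two-intron retention in an annotated transcript
  tx <- data.frame(transcript_id = "t5", gene_id = "g5", contig_id = "c3",
                   strand = "+", class = "background")
  ex <- data.frame(transcript_id = "t5",
                   start = c(100, 300, 600, 900),
                   end = c(200, 400, 700, 1000))
  ann <- flic_annotation(tx, ex)
  retained <- new_chain("c3", "+", c(100, 900), c(700, 1000))
  expect_equal(classify_isoform(retained, ann)$category, "NIC")
})

test_that("classifier agrees with the rule-by-rule oracle", {
  ref <- make_reference(sirv = FALSE, long = FALSE, background_genes = 10,
                        seed = 51)
  ann <- ref$annotation
  idx <- flicsim:::build_classify_index(ann)
  withr::with_seed(52, {
    mism <- 0L
    for (k in seq_len(500)) {
      tid <- sample(ann$transcripts$transcript_id, 1)
      ch <- transcript_chain(ann, tid)
      op <- sample(c("keep", "shift_ends", "shift_junction", "drop_exon",
                     "retain", "flip", "move_far", "mono"), 1)
      n <- length(ch$starts)
      if (op == "shift_ends") {
        ch$starts[1] <- max(0, ch$starts[1] + sample(-200:200, 1))
        if (ch$starts[1] >= ch$ends[1]) ch$starts[1] <- ch$ends[1] - 10
        ch$ends[n] <- ch$ends[n] + sample(-50:200, 1)
        if (ch$ends[n] <= ch$starts[n]) ch$ends[n] <- ch$starts[n] + 10
      } else if (op == "shift_junction" && n > 1) {
        j <- sample(n - 1, 1)
        d <- sample(c(-30:-1, 1:30), 1)
        new_end <- ch$ends[j] + d
        if (new_end > ch$starts[j] && new_end < ch$starts[j + 1])
          ch$ends[j] <- new_end
      } else if (op == "drop_exon" && n > 2) {
        j <- sample(2:(n - 1), 1)
        ch$starts <- ch$starts[-j]; ch$ends <- ch$ends[-j]
      } else if (op == "retain" && n > 1) {
        j <- sample(n - 1, 1)
        ch$starts <- ch$starts[-(j + 1)]; ch$ends <- ch$ends[-j]
      } else if (op == "flip") {
        ch$strand <- if (ch$strand == "+") "-" else "+"
      } else if (op == "move_far") {
        off <- 50000L
        ch$starts <- ch$starts + off; ch$ends <- ch$ends + off
      } else if (op == "mono") {
        s <- sample(ch$starts, 1)
        ch <- new_chain(ch$contig, ch$strand, s, s + sample(80:400, 1))
      }
      got <- flicsim:::classify_chain(ch, ann, idx)$category
      want <- oracle_classify(ch, ann)
      if (got != want) mism <- mism + 1L
    }
    expect_equal(mism, 0L)
  })
})

test_that("every isoform receives exactly one category", {
  run <- small_run()
  expect_true(all(run$classified$category %in%
                    flicsim:::FLIC_CATEGORIES))
  expect_equal(nrow(run$classified), nrow(run$clusters_pass))
  expect_equal(sum(table(run$classified$category)), nrow(run$classified))
})

test_that("error-free end-to-end run recalls every spike-in as FSM", {
  run <- clean_spike_run()
  spike <- run$reference$annotation$transcripts$transcript_id
  r <- sirv_recall(run$classified, spike, min_support = 1)
  expect_equal(r$n_detected, 69)
  expect_equal(r$recall, 100.0)
  expect_true(all(run$classified$category == "FSM"))
  # with the standard two-read support rule the result is unchanged here
  r2 <- sirv_recall(run$classified, spike, min_support = 2)
  expect_equal(r2$recall, 100.0)
})

test_that("recall arithmetic reports one-decimal percentages", {
  cl <- data.frame(cluster_id = paste0("c", 1:69),
                   category = "FSM",
                   matched_transcript = paste0("t", 1:69),
                   gene_ids = "g", spliced_len = 500,
                   support = rep(c(5, 0), c(64, 5)))
  r <- sirv_recall(cl, paste0("t", 1:69), min_support = 1)
  expect_equal(r$n_detected, 64)
  expect_equal(r$recall, 92.8)                  # 64/69
  full <- sirv_recall(cl[1:69, ], paste0("t", 1:69), min_support = 0)
  expect_equal(full$recall, 100.0)
})

test_that("length bins conserve support and match the binning oracle", {
  one <- data.frame(cluster_id = "c1", category = "FSM",
                    matched_transcript = "t", gene_ids = "g",
                    spliced_len = 1500, support = 7)
  b <- length_bins(one)
  expect_equal(b$bin_start, 1000)
  expect_equal(b$bin_end, 2000)
  expect_equal(b$support, 7)
  expect_equal(nrow(length_bins(one[0, ])), 0)
  withr::with_seed(6, {
    df <- data.frame(cluster_id = paste0("c", 1:300), category = "FSM",
                     matched_transcript = "t", gene_ids = "g",
                     spliced_len = sample(100:12000, 300, TRUE),
                     support = sample(1:40, 300, TRUE))
    b2 <- length_bins(df)
    expect_equal(sum(b2$support), sum(df$support))   # conservation
    o <- oracle_length_bins(df$spliced_len, df$support)
    for (i in seq_len(nrow(b2)))
      expect_equal(b2$support[i],
                   o[[as.character(b2$bin_start[i] / 1000)]])
  })
})

test_that("intergenic length summary is a plain mean or absent", {
  df <- data.frame(cluster_id = c("a", "b", "c"),
                   category = c("intergenic", "intergenic", "FSM"),
                   matched_transcript = NA, gene_ids = "x",
                   spliced_len = c(1000, 2000, 700), support = 1)
  expect_equal(intergenic_length_summary(df), 1500)
  expect_true(is.na(intergenic_length_summary(df[df$category == "FSM", ])))
  withr::with_seed(8, {
    lens <- sample(200:4000, 50)
    df2 <- data.frame(cluster_id = paste0("i", 1:50),
                      category = "intergenic", matched_transcript = NA,
                      gene_ids = "x", spliced_len = lens, support = 1)
    expect_equal(intergenic_length_summary(df2), sum(lens) / 50)
  })
})

test_that("intergenic isoforms receive clustered novel gene ids", {
  ann <- tiny_annotation()
  chains <- list(new_chain("c1", "+", 30000, 30500),
                 new_chain("c1", "+", 30200, 30900),
                 new_chain("c1", "+", 40000, 40400))
  cl <- data.frame(cluster_id = c("x1", "x2", "x3"), chain = I(chains),
                   support = c(1, 2, 3))
  out <- classify_isoforms(cl, ann)
  expect_true(all(out$category == "intergenic"))
  expect_equal(out$gene_ids[1], out$gene_ids[2])    # overlapping pair
  expect_false(out$gene_ids[3] == out$gene_ids[1])  # distant isoform
})
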