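fake_sample <- function(chains, supports, categories = "FSM",
                        matched = NA_character_) {
  n <- length(chains)
  data.frame(cluster_id = sprintf("c%03d", seq_len(n)),
             chain = I(chains),
             support = supports,
             category = rep_len(categories, n),
             matched_transcript = rep_len(matched, n),
             gene_ids = "g")
}

iso_chain <- function(off = 0, contig = "c1") {
  new_chain(contig, "+", c(1000, 1600) + off, c(1400, 2000) + off)
}

# same isoform with end variability only (junctions untouched)
iso_variant <- function(d5 = 0, d3 = 0) {
  new_chain("c1", "+", c(1000 + d5, 1600), c(1400, 2000 + d3))
}

test_that("the same isoform across samples becomes one row", {
  s1 <- fake_sample(list(iso_variant()), 5, matched = "tX")
  s2 <- fake_sample(list(iso_chain(3000)), 4)   # unrelated isoform
  s3 <- fake_sample(list(iso_variant(d5 = 20, d3 = -8)), 7, matched = "tX")
  m <- merge_samples(list(a = s1, b = s2, c = s3))
  expect_equal(nrow(m$rows), 2)
  shared <- which(m$rows$matched_transcript == "tX")
  expect_equal(unname(m$support[shared, ]), c(5, 0, 7))
})

test_that("disjoint samples union with zero off-diagonal support", {
  s1 <- fake_sample(list(iso_chain(), iso_chain(5000)), c(3, 6))
  s2 <- fake_sample(list(iso_chain(10000)), 2)
  m <- merge_samples(list(x = s1, y = s2))
  expect_equal(nrow(m$rows), 3)
  expect_equal(sum(m$support > 0), 3)
  expect_equal(sum(m$support), 11)
})

test_that("intergenic rows are dropped as the unknown-class analog", {
  s1 <- fake_sample(list(iso_chain(), iso_chain(5000)), c(3, 6),
                    categories = c("FSM", "intergenic"))
  m <- merge_samples(list(a = s1))
  expect_equal(nrow(m$rows), 1)
  m2 <- merge_samples(list(a = s1), drop_unknown = FALSE)
  expect_equal(nrow(m2$rows), 2)
})

test_that("merged replicate rows match a brute-force pairwise merge", {
  withr::with_seed(61, {
    reps <- lapply(1:3, function(r) {
      offs <- sample(seq(0, 40000, by = 4000), 6)
      jitter <- sample(-40:40, 6, replace = TRUE)
      fake_sample(lapply(offs + jitter, iso_chain),
                  sample(1:20, 6, replace = TRUE))
    })
    m <- merge_samples(setNames(reps, c("r1", "r2", "r3")))
    # oracle: all-pairs single linkage over the pooled chains
    pooled_chains <- do.call(c, lapply(reps, function(s) s$chain))
    ids <- sprintf("p%02d", seq_along(pooled_chains))
    want <- oracle_collapse_partition(ids, pooled_chains)
    expect_equal(nrow(m$rows), length(want))
    expect_equal(sum(m$support), sum(vapply(reps, function(s)
      sum(s$support), numeric(1))))
  })
})

test_that("merging a matrix with itself is idempotent", {
  s1 <- fake_sample(list(iso_chain(), iso_chain(5000), iso_chain(9000)),
                    c(3, 6, 2))
  m1 <- merge_samples(list(a = s1))
  back <- data.frame(cluster_id = m1$rows$row_id, chain = I(m1$rows$chain),
                     support = as.vector(m1$support),
                     category = m1$rows$category,
                     matched_transcript = m1$rows$matched_transcript,
                     gene_ids = "g")
  m2 <- merge_samples(list(a = back))
  expect_equal(nrow(m2$rows), nrow(m1$rows))
})

test_that("overlap statistics count passing rows and percentages", {
  sup <- rbind(c(5, 4, 12), c(2, 0, 3), c(11, 10, 10), c(0, 0, 4))
  mat <- structure(list(
    rows = data.frame(row_id = paste0("r", 1:4), category = "FSM",
                      matched_transcript = NA,
                      chain = I(replicate(4, iso_chain(),
                                          simplify = FALSE))),
    support = sup, provenance = list()), class = "flic_comparison")
  o2 <- overlap_stats(mat, 2)
  expect_equal(o2$n_unique, 4)
  expect_equal(o2$n_in_all, 2)
  expect_equal(o2$n_in_at_least_2, 3)
  o10 <- overlap_stats(mat, 10)
  expect_equal(o10$n_unique, 2)
  expect_equal(o10$n_in_all, 1)
  expect_equal(o10$pct_in_all, 50.0)
  # single row present everywhere
  one <- structure(list(rows = mat$rows[1, ],
                        support = sup[1, , drop = FALSE],
                        provenance = list()), class = "flic_comparison")
  expect_equal(overlap_stats(one, 2)$pct_in_all, 100.0)
  # monotone in the threshold, and in-all never exceeds in-at-least-2
  for (t in c(2, 4, 10)) {
    o <- overlap_stats(mat, t)
    expect_lte(o$n_in_all, o$n_in_at_least_2)
    expect_lte(o$pct_in_all, o$pct_in_at_least_2)
  }
  n_uni <- vapply(c(2, 4, 10), function(t)
    overlap_stats(mat, t)$n_unique, numeric(1))
  expect_true(all(diff(n_uni) <= 0))
})

test_that("fold change handles zeros, rounding and large folds", {
  expect_equal(fold_change(8432861, 2501016), 3.4)
  expect_equal(fold_change(11676, 0), 11676)
  expect_equal(fold_change(5, 5), 1.0)
  expect_equal(fold_change(0, 0), 1.0)
  expect_equal(fold_change(192220, 103591), 1.9)
  expect_equal(fold_change(42195, 19598), 2.2)
  expect_equal(fold_change(34020, 15362), 2.2)
  expect_equal(fold_change(20, 2), 10.0)
  expect_equal(fold_change(15, 2), 7.5)
})

test_that("mean recall reproduces the one-decimal averages", {
  expect_equal(mean_recall(c(64, 61, 61), 69), 89.9)
  expect_equal(mean_recall(c(62, 54, 50), 69), 80.2)
  expect_equal(mean_recall(c(69, 69, 69), 69), 100.0)
  expect_error(mean_recall(integer(0), 69), "no replicate")
})

test_that("the low-expression panel is an exact intersection", {
  t1 <- data.frame(transcript_id = c("a", "b", "c"), tpm = c(0.5, 0.5, 2))
  t2 <- data.frame(transcript_id = c("a", "b", "c"), tpm = c(0.5, 0.6, 0.5))
  t3 <- data.frame(transcript_id = c("a", "b", "c"), tpm = c(0.5, 0.5, 0.5))
  expect_equal(low_expression_panel(list(t1, t2, t3)), "a")
  # b excluded: 0.6 in one replicate
  expect_false("b" %in% low_expression_panel(list(t1, t2, t3)))
  withr::with_seed(62, {
    tabs <- lapply(1:3, function(r)
      data.frame(transcript_id = paste0("t", 1:50),
                 tpm = sample(c(0.5, 1, 2), 50, replace = TRUE)))
    got <- low_expression_panel(tabs)
    want <- Reduce(intersect, lapply(tabs, function(tb)
      tb$transcript_id[tb$tpm == 0.5]))
    expect_setequal(got, want)
  })
})

test_that("panel detection counts FSM rows per replicate", {
  chains <- replicate(3, iso_chain(), simplify = FALSE)
  chains <- list(iso_chain(), iso_chain(5000), iso_chain(9000))
  mat <- structure(list(
    rows = data.frame(row_id = paste0("r", 1:3),
                      category = c("FSM", "FSM", "NIC"),
                      matched_transcript = c("p1", "p2", NA),
                      chain = I(chains)),
    support = rbind(c(2, 1, 3), c(4, 0, 0), c(9, 9, 9)),
    provenance = list()), class = "flic_comparison")
  pd <- panel_detection(c("p1", "p2", "p3"), mat)
  expect_equal(pd$n_in_all, 1)               # p1 everywhere
  expect_equal(pd$n_in_at_least_one, 2)      # p2 in one sample
  expect_equal(pd$pct_in_all, 33.3)
  expect_equal(pd$pct_in_at_least_one, 66.7)
  none <- panel_detection(c("q1", "q2"), mat)
  expect_equal(none$pct_in_all, 0.0)
})
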