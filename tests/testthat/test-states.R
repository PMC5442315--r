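# State classification cascade, transition matrices and set overlap.

# Build a consensus-list for one gene from explicit intervals.
cons_for <- function(k4 = NULL, k27 = NULL, chrom = "chr1") {
  mk <- function(m) if (is.null(m)) NULL else
    data.frame(chrom = chrom, start = m[, 1], end = m[, 2],
               signal = seq_len(nrow(m)), stringsAsFactors = FALSE)
  list(H3K4me3 = mk(k4), H3K27me3 = mk(k27))
}

test_that("definition-forced H, E and partial cases classify correctly", {
  g <- one_gene(2000, 5000, "+")    # TSS 2000
  # broad K27 containing a narrow K4 whose midpoint (2050) is in the window
  call <- classify_states(g, cons_for(k4 = rbind(c(1700, 2400)),
                                      k27 = rbind(c(1000, 3000))))
  expect_equal(call$label, "H")
  expect_true(call$inner_at_tss)
  # mirrored: narrow K27 inside a broad K4 domain
  call2 <- classify_states(g, cons_for(k4 = rbind(c(500, 4000)),
                                       k27 = rbind(c(1800, 2300))))
  expect_equal(call2$label, "E")
  # partial overlap, K27 spanning more
  call3 <- classify_states(g, cons_for(k4 = rbind(c(2500, 3500)),
                                       k27 = rbind(c(1000, 3000))))
  expect_equal(call3$label, "K27_gt_K4")
  expect_false(call3$inner_at_tss)
})

test_that("containment with an off-window inner peak falls to partial", {
  g <- one_gene(2000, 9000, "+")
  # K4 contained in K27 but midpoint at 4000, outside TSS +-500
  call <- classify_states(g, cons_for(k4 = rbind(c(3800, 4200)),
                                      k27 = rbind(c(2400, 8000))))
  expect_equal(call$label, "K27_gt_K4")
  expect_false(call$inner_at_tss)
})

test_that("single-mark, unmarked and disjoint configurations label correctly", {
  g <- one_gene(2000, 5000, "+")
  expect_equal(classify_states(g, cons_for(k4 = rbind(c(1800, 2400))))$label,
               "K4_only")
  expect_equal(classify_states(g, cons_for(k27 = rbind(c(1800, 4000))))$label,
               "K27_only")
  expect_equal(classify_states(g, cons_for())$label, "Unmarked")
  expect_equal(classify_states(g, cons_for(k4 = rbind(c(1800, 2400)),
                                           k27 = rbind(c(3500, 4500))))$label,
               "Non")
})

test_that("equal spans break ties to K27_gt_K4 and rule order favours H", {
  g <- one_gene(2000, 5000, "+")
  # identical intervals: mutual containment, both midpoints on TSS -> H
  call <- classify_states(g, cons_for(k4 = rbind(c(1800, 2200)),
                                      k27 = rbind(c(1800, 2200))))
  expect_equal(call$label, "H")
  # equal spans, partial overlap -> K27_gt_K4
  call2 <- classify_states(g, cons_for(k4 = rbind(c(1500, 2500)),
                                       k27 = rbind(c(2000, 3000))))
  expect_equal(call2$label, "K27_gt_K4")
})

test_that("cascade output matches the truth-table oracle on random pairs", {
  set.seed(19)
  params <- state_params()
  for (k in 1:400) {
    pts4 <- sort(sample(seq(0, 4000, by = 50), 2))
    pts27 <- sort(sample(seq(0, 4000, by = 50), 2))
    if (pts4[1] == pts4[2] || pts27[1] == pts27[2]) next
    tss <- sample(c(500, 2000, 3500), 1)
    got <- samstates:::.classify_pair(pts4[1], pts4[2], pts27[1], pts27[2],
                                      tss, params)
    want <- oracle_state(pts4[1], pts4[2], pts27[1], pts27[2], tss)
    expect_identical(got$label, want)
  }
})

test_that("swapping the marks maps H<->E and the partial labels", {
  set.seed(23)
  swap_map <- c(H = "E", E = "H", K27_gt_K4 = "K4_gt_K27",
                K4_gt_K27 = "K27_gt_K4", Non = "Non", Unmarked = "Unmarked",
                K4_only = "K27_only", K27_only = "K4_only")
  g <- one_gene(2000, 6000, "+")
  for (k in 1:100) {
    k4 <- sort(sample(seq(0, 7000, 100), 2)); k27 <- sort(sample(seq(0, 7000, 100), 2))
    if (k4[1] == k4[2] || k27[1] == k27[2]) next
    a <- classify_states(g, cons_for(k4 = rbind(k4), k27 = rbind(k27)))$label
    b <- classify_states(g, cons_for(k4 = rbind(k27), k27 = rbind(k4)))$label
    if (identical(k4, k27)) {
      expect_equal(b, a)             # identical intervals: symmetric by rule order
    } else if (a == "K27_gt_K4" && (k27[2] - k27[1]) == (k4[2] - k4[1])) {
      expect_equal(b, "K27_gt_K4")   # documented tie-break is asymmetric
    } else {
      expect_equal(b, unname(swap_map[a]))
    }
  }
})

test_that("the cascade is total over random multi-region sets", {
  set.seed(31)
  g <- one_gene(3000, 8000, "+")
  for (k in 1:60) {
    n4 <- sample(0:3, 1); n27 <- sample(0:3, 1)
    mk <- function(n) if (n == 0) NULL else {
      s <- sort(sample(seq(0, 10000, 100), n))
      m <- cbind(s, s + sample(seq(200, 2000, 100), n, replace = TRUE))
      m[!duplicated(m[, 1]), , drop = FALSE]
    }
    cons <- cons_for(k4 = mk(n4), k27 = mk(n27))
    cons <- lapply(cons, function(d) if (is.null(d)) NULL else merge_regions(d))
    call <- classify_states(g, cons)
    expect_equal(nrow(call), 1L)
    expect_true(call$label %in% state_labels())
  }
})

test_that("transition matrices count moves and keep exact row sums", {
  calls0 <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                       label = c("H", "H", "E", "Non"))
  tm_same <- transition_matrix(calls0, calls0)
  expect_true(all(tm_same$counts[upper.tri(tm_same$counts)] == 0))
  expect_true(all(tm_same$counts[lower.tri(tm_same$counts)] == 0))
  expect_equal(sum(diag(tm_same$counts)), 4)

  calls1 <- calls0
  calls1$label[1] <- "Non"
  tm <- transition_matrix(calls0, calls1)
  expect_equal(tm$counts["H", "Non"], 1)
  expect_equal(tm$counts["H", "H"], 1)
  expect_equal(unname(rowSums(tm$counts)), unname(tm$n_per_row))
  expect_equal(tm$row_fractions["H", "Non"], 0.5)
  expect_error(transition_matrix(calls0,
                                 data.frame(gene_id = "x", label = "H")),
               "disjoint")
})

test_that("state set overlap is exact set arithmetic", {
  ov <- state_set_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_equal(ov, list(n_common = 2L, frac_a = 2 / 3, frac_b = 2 / 3))
  expect_equal(state_set_overlap(c("a"), c("b"))$n_common, 0L)
  expect_equal(state_set_overlap(c("a", "b"), c("a", "b", "c"))$frac_a, 1)
})

test_that("pipeline state calls recover the planted labels per state", {
  sim <- simulate_dataset(sim_config(seed = 77, n_genes = 1500))
  res <- run_chromatin_pipeline(sim)
  m <- merge(res$calls, sim$truth$states, by = c("gene_id", "timepoint"),
             suffixes = c("_called", "_true"))
  for (lab in state_labels()) {
    tp_true <- m$label_true == lab
    tp_called <- m$label_called == lab
    recall <- sum(tp_true & tp_called) / sum(tp_true)
    precision <- sum(tp_true & tp_called) / sum(tp_called)
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  }
})
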