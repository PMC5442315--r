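# Gene-mark profiling and mark--expression association statistics.

test_that("profile_genes applies the TSS +-500 bp window, strand-aware", {
  g <- one_gene(1000, 3000, "+")
  cons <- list(H3K4me3 = data.frame(chrom = "chr1", start = 600, end = 1200,
                                    signal = 2))
  p <- profile_genes(g, cons)
  expect_true(p$tss_marked)          # window [500, 1501) overlaps [600, 1200)
  expect_equal(p$tss_signal, 2)

  cons2 <- list(H3K4me3 = data.frame(chrom = "chr1", start = 1600, end = 2200,
                                     signal = 3))
  p2 <- profile_genes(g, cons2)
  expect_false(p2$tss_marked)
  expect_equal(p2$body_signal, 3)    # fully inside the body
  expect_true(p2$body_signal > 0)

  gm <- one_gene(1000, 3000, "-")    # window anchored at 2999: [2499, 3500)
  p3 <- profile_genes(gm, cons2)
  expect_false(p3$tss_marked)        # [1600, 2200) misses the minus window
  expect_equal(p3$body_signal, 3)
})

test_that("minus-strand TSS window anchors at end - 1", {
  gm <- one_gene(1000, 3000, "-")
  cons <- list(H3K4me3 = data.frame(chrom = "chr1", start = 2600, end = 2700,
                                    signal = 5))
  p <- profile_genes(gm, cons)
  expect_true(p$tss_marked)          # window [2499, 3500)
  cons_far <- list(H3K4me3 = data.frame(chrom = "chr1", start = 1000,
                                        end = 2400, signal = 5))
  expect_false(profile_genes(gm, cons_far)$tss_marked)
})

test_that("body_signal is the overlap-length-weighted mean", {
  g <- one_gene(0, 1000, "+")
  cons <- list(H3K4me3 = data.frame(chrom = "chr1",
                                    start = c(0, 800), end = c(200, 1200),
                                    signal = c(2, 7)))
  p <- profile_genes(g, cons)
  expect_equal(p$body_signal, (2 * 200 + 7 * 200) / 400)
  expect_equal(p$n_regions, 2L)
})

test_that("genes on chromosomes absent from the consensus get empty profiles", {
  g <- gene_table("gX", "chr9", 100, 2000, "+")
  p <- profile_genes(g, list(H3K4me3 = data.frame(chrom = "chr1", start = 0,
                                                  end = 10, signal = 1)))
  expect_false(p$tss_marked)
  expect_true(is.na(p$tss_signal))
  expect_equal(p$n_regions, 0L)
})

test_that("marked_fraction computes per-timepoint proportions and s.e.", {
  fpkm <- matrix(c(5, 5, 0.2, 0.2, 5, 5, 0.2, 0.2), 4, 2,
                 dimnames = list(paste0("g", 1:4), c("0LD", "1LD")))
  ex <- expr_from_matrix(fpkm)
  prof_tp <- function(marked) data.frame(
    gene_id = paste0("g", 1:4), mark = "H3K4me3", n_regions = 1L,
    tss_marked = marked, tss_signal = 1, body_signal = 1,
    stringsAsFactors = FALSE)
  profiles <- list(`0LD` = prof_tp(c(TRUE, FALSE, TRUE, FALSE)),
                   `1LD` = prof_tp(c(TRUE, FALSE, TRUE, FALSE)))
  mf <- marked_fraction(profiles, ex, "H3K4me3", "expressed")
  expect_equal(mf$per_timepoint$proportion, c(0.5, 0.5))
  expect_equal(mf$mean, 0.5)
  expect_equal(mf$se, 0)             # zero dispersion across time points
  mfn <- marked_fraction(profiles, ex, "H3K4me3", "non_expressed")
  expect_equal(mfn$mean, 0.5)
  # empty stratum flagged
  ex_all <- expr_from_matrix(matrix(5, 4, 2, dimnames = dimnames(fpkm)))
  w <- capture_warnings(mfe <- marked_fraction(profiles, ex_all, "H3K4me3",
                                               "non_expressed"))
  expect_true(length(w) > 0 && all(grepl("empty stratum", w)))
  expect_true(all(is.na(mfe$per_timepoint$proportion)))
})

test_that("spearman_with_t matches its closed form and reference on ranks", {
  expect_equal(spearman_with_t(1:3, 1:3), list(rho = 1, p = 0, n = 3L))
  expect_equal(spearman_with_t(1:3, 3:1)$rho, -1)
  # ties: rho must equal the Pearson correlation of mid-ranks
  x <- c(1, 2, 2, 4); y <- c(2, 1, 3, 4)
  st <- spearman_with_t(x, y)
  oracle_rho <- unname(cor.test(rank(x), rank(y), method = "pearson")$estimate)
  expect_equal(st$rho, oracle_rho, tolerance = 1e-12)
  t_or <- oracle_rho * sqrt((4 - 2) / (1 - oracle_rho^2))
  expect_equal(st$p, 2 * pt(-abs(t_or), 2), tolerance = 1e-12)
  # tie-free data: agreement with the standard Spearman estimate
  set.seed(5)
  a <- rnorm(50); b <- a + rnorm(50)
  st2 <- spearman_with_t(a, b)
  expect_equal(st2$rho, cor(a, b, method = "spearman"), tolerance = 1e-12)
  expect_warning(stc <- spearman_with_t(rep(1, 5), 1:5), "constant")
  expect_true(is.na(stc$rho))
  expect_error(spearman_with_t(1:2, 1:2), ">= 3")
})

test_that("pipeline recovers planted marked fractions and Spearman rho", {
  sim <- simulate_dataset(sim_config(seed = 44, n_genes = 2000))
  res <- run_chromatin_pipeline(sim)
  # planted: 66% of expressed genes carry K4 at the TSS at baseline
  p0 <- res$marked$expressed$per_timepoint$proportion[1L]
  marked_states <- c("Non", "H", "E", "K27_gt_K4", "K4_gt_K27", "K4_only")
  plant <- sum(sim$config$state_fractions[marked_states])
  n0 <- res$marked$expressed$per_timepoint$n[1L]
  # allow binomial spread plus the ~2% discordance-removal deficit
  expect_lt(abs(p0 - plant), 2.576 * sqrt(plant * (1 - plant) / n0) + 0.03)
  # silent stratum: ~5% at baseline
  p0n <- res$marked$non_expressed$per_timepoint$proportion[1L]
  expect_lt(abs(p0n - 0.05), 0.03)
  # recovered correlation close to the planted 0.31
  expect_true(all(abs(res$correlation$rho - 0.31) < 0.06))
  expect_true(all(res$correlation$p < 0.001))
})
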