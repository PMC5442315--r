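# Expressed-gene flags, DE direction classification, slope test and ddCt.

test_that("expressed-gene flags use strict FPKM > 1 on replicate means", {
  fpkm <- matrix(c(0.2, 0.8, 1.5, 0.9,   # g1: expressed at 2LD only
                   0, 0, 0, 0,           # g2: silent
                   1, 1, 1, 1),          # g3: exactly 1 everywhere -> silent
                 3, 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:3),
                                 c("0LD", "1LD", "2LD", "3LD")))
  fl <- expressed_genes(expr_from_matrix(fpkm))
  expect_identical(unname(fl$global), c(TRUE, FALSE, FALSE))
  expect_identical(unname(fl$local["g1", ]), c(FALSE, FALSE, TRUE, FALSE))
  # replicate averaging happens before thresholding
  ex2 <- rbind(
    data.frame(gene_id = "g", timepoint = "0LD", replicate = 1, fpkm = 0.4, count = 4),
    data.frame(gene_id = "g", timepoint = "0LD", replicate = 2, fpkm = 2.0, count = 20))
  fl2 <- expressed_genes(ex2)
  expect_true(fl2$global[["g"]])         # mean 1.2 > 1
})

test_that("DE direction classification follows consistency rules", {
  sig <- rbind(
    data.frame(gene_id = "gU", contrast = c("0->1", "0->3"),
               direction = "up", significant = 1),
    data.frame(gene_id = "gC", contrast = c("0->1", "2->3"),
               direction = c("up", "down"), significant = 1),
    data.frame(gene_id = "gN", contrast = "0->1", direction = "up",
               significant = 0))
  cls <- classify_de_direction(sig, gene_universe = c("gU", "gC", "gN", "gX"))
  got <- setNames(cls$de_class, cls$gene_id)
  expect_equal(got[["gU"]], "up")
  expect_equal(got[["gC"]], "complex")
  expect_equal(got[["gN"]], "ns")
  expect_equal(got[["gX"]], "ns")
  bad <- data.frame(gene_id = "g", contrast = "c", direction = "sideways",
                    significant = 1)
  expect_error(classify_de_direction(bad), "unknown direction")
})

test_that("generator significance calls reproduce the planted DE classes", {
  cfg <- sim_config(seed = 61, n_genes = 3000,
                    de_spec = c(up = 0.02, down = 0.02, complex = 0.005))
  sim <- simulate_dataset(cfg)
  cls <- classify_de_direction(sim$signif, gene_universe = sim$genes$gene_id)
  m <- merge(cls, sim$truth$de, by = "gene_id")
  expect_identical(m$de_class.x, m$de_class.y)
  expect_equal(sum(m$de_class.x == "up"), round(0.02 * 3000))
  expect_equal(sum(m$de_class.x == "complex"), round(0.005 * 3000))
})

test_that("slope test matches a closed-form OLS oracle", {
  y <- c(1.0, 2.1, 2.9, 4.2); t <- 0:3
  st <- slope_test(y, t)
  # independent closed-form arithmetic
  beta <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  alpha <- mean(y) - beta * mean(t)
  rss <- sum((y - alpha - beta * t)^2)
  se <- sqrt(rss / (4 - 2) / sum((t - mean(t))^2))
  p <- 2 * pt(-abs(beta / se), df = 2)
  expect_equal(st$slope, beta, tolerance = 1e-12)
  expect_equal(st$p, p, tolerance = 1e-12)
  # perfect fit and constant series conventions
  expect_equal(slope_test(c(1, 2, 3, 4), 0:3)[c("slope", "p")],
               list(slope = 1, p = 0))
  expect_equal(slope_test(rep(2, 4), 0:3)[c("slope", "p")],
               list(slope = 0, p = 1))
  expect_error(slope_test(c(1, 2), 0:1), ">= 3")
})

test_that("slope test p-value is invariant to affine time rescaling", {
  set.seed(3)
  y <- rnorm(6)
  p1 <- slope_test(y, 0:5)$p
  p2 <- slope_test(y, 10 + 3 * (0:5))$p
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("ddCt relative expression follows the capped formula", {
  rec <- rbind(
    data.frame(sample = "cal", gene = "T", ct = 29),
    data.frame(sample = "cal", gene = "R", ct = 25),
    data.frame(sample = "s1", gene = "T", ct = 30),
    data.frame(sample = "s1", gene = "R", ct = 25))
  out <- ddct_relative_expression(rec, "T", "R", "cal")
  expect_equal(out$rel_expr[out$sample == "s1"], 2^-(5 - 4))  # = 0.5
  expect_equal(out$rel_expr[out$sample == "cal"], 1)          # own calibrator
  # undetected calibrator target capped at 40 cycles
  rec2 <- rbind(
    data.frame(sample = "cal", gene = "T", ct = NA),
    data.frame(sample = "cal", gene = "R", ct = 25),
    data.frame(sample = "s1", gene = "T", ct = 35),
    data.frame(sample = "s1", gene = "R", ct = 25))
  out2 <- ddct_relative_expression(rec2, "T", "R", "cal")
  expect_equal(out2$rel_expr[out2$sample == "s1"], 2^-(10 - 15),
               tolerance = 1e-12)                             # = 32
  # missing reference errors
  rec3 <- rec[rec$gene == "T" | rec$sample == "cal", ]
  expect_error(ddct_relative_expression(rec3, "T", "R", "cal"), "missing")
})

test_that("ddCt output is invariant to a constant Ct shift", {
  rec <- rbind(
    data.frame(sample = rep(c("cal", "s1", "s2"), each = 2),
               gene = rep(c("T", "R"), 3),
               ct = c(28, 24, 31, 25, 26, 23)))
  out1 <- ddct_relative_expression(rec, "T", "R", "cal")
  rec2 <- rec; rec2$ct <- rec2$ct + 3
  out2 <- ddct_relative_expression(rec2, "T", "R", "cal")
  expect_equal(out1$rel_expr, out2$rel_expr, tolerance = 1e-12)
})
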