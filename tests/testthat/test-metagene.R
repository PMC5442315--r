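# Metagene matrices: bin layout, strand handling, fractional weighting,
# mass conservation and row ordering.

test_that("TSS-anchored matrix has (up+down)/binwidth columns", {
  g <- one_gene(20000, 23000, "+")
  trk <- signal_track(data.frame(chrom = "chr1", start = 0, end = 50000,
                                 value = 2))
  m <- tss_anchored_matrix(g, trk)
  expect_equal(ncol(m), 120L)
  expect_equal(ncol(tss_anchored_matrix(g, trk, upstream = 1000,
                                        downstream = 2000, binwidth = 50)), 60L)
})

test_that("constant signal fills every cell on both strands", {
  gp <- one_gene(20000, 23000, "+")
  gm <- one_gene(20000, 23000, "-")
  trk <- signal_track(data.frame(chrom = "chr1", start = 0, end = 60000,
                                 value = 2))
  for (g in list(gp, gm)) {
    expect_true(all(tss_anchored_matrix(g, trk) == 2))
    expect_true(all(body_normalized_matrix(g, trk) == 2))
  }
})

test_that("a downstream block lands in downstream bins after strand flip", {
  # minus-strand gene: TSS at 29999; transcript-downstream means lower coords
  g <- one_gene(20000, 30000, "-")
  trk <- signal_track(data.frame(chrom = "chr1", start = 28000, end = 29000,
                                 value = 6))   # offsets +1000..+1999 downstream
  m <- tss_anchored_matrix(g, trk)
  # per-base oracle: transcript offset o maps to base 29999 - o
  oracle <- vapply(seq_len(120), function(b) {
    offs <- (-4000 + (b - 1) * 100):(-4000 + b * 100 - 1)
    bases <- 29999 - offs
    mean(ifelse(bases >= 28000 & bases < 29000, 6, 0))
  }, numeric(1))
  expect_equal(unname(m[1, ]), oracle)
  expect_true(all(m[1, 51:60] == 6))     # +1000..+1999 downstream bins
  expect_true(all(m[1, 1:50] == 0))
})

test_that("bins beyond the chromosome are zeroed and masked", {
  g <- one_gene(1000, 4000, "+")         # window starts at -3000
  trk <- signal_track(data.frame(chrom = "chr1", start = 0, end = 10000,
                                 value = 1))
  m <- tss_anchored_matrix(g, trk, chrom_sizes = c(chr1 = 8000))
  mask <- attr(m, "mask")
  expect_true(all(mask[1, 1:30]))        # -4000..-1001 out of range
  expect_true(all(m[1, 1:30] == 0))
  expect_true(all(m[1, 41:90] == 1))
  expect_true(all(mask[1, 111:120]))     # beyond the 8 kb chromosome
  expect_true(all(m[1, 111:120] == 0))
})

test_that("body matrix has 2*flank_bins + body_bins columns and short genes use
           fractional weighting", {
  trk <- signal_track(data.frame(chrom = "chr1",
                                 start = c(5000, 5020, 5040),
                                 end = c(5020, 5040, 5100),
                                 value = c(3, 9, 1)))
  g <- one_gene(5000, 5055, "+")         # length 55: bins of 1.1 bases
  m <- body_normalized_matrix(g, trk)
  expect_equal(ncol(m), 70L)
  expect_true("g1" %in% attr(m, "short_genes") == FALSE)
  body <- m[1, 11:60]
  # per-base oracle with fractional boundary weighting
  val_at <- function(x) ifelse(x < 5020, 3, ifelse(x < 5040, 9, 1))
  oracle <- vapply(0:49, function(b) {
    lo <- 5000 + b * 1.1; hi <- lo + 1.1
    xs <- seq(floor(lo), ceiling(hi) - 1)
    w <- pmin(hi, xs + 1) - pmax(lo, xs)
    w <- pmax(w, 0)
    sum(val_at(xs) * w) / 1.1
  }, numeric(1))
  expect_equal(unname(body), oracle, tolerance = 1e-12)
  # gene of length 500: body bins of 10 bp
  g2 <- one_gene(5000, 5500, "+")
  m2 <- body_normalized_matrix(g2, trk)
  expect_equal(unname(m2[1, 11]), 3)     # first 10 bp all value 3
})

test_that("body bins conserve total signal mass exactly", {
  set.seed(9)
  sim <- simulate_dataset(sim_config(seed = 9, n_genes = 200))
  trk <- sim$tracks$H3K4me3$`0LD`
  mb <- body_normalized_matrix(sim$genes, trk, chrom_sizes = sim$chrom_sizes)
  for (i in sample(nrow(sim$genes), 50)) {
    g <- sim$genes[i, ]
    L <- g$end - g$start
    mass <- sum(mb[g$gene_id, 11:60]) * (L / 50)
    cd <- trk$chroms[[g$chrom]]
    oracle <- sum(cd$value * pmax(pmin(cd$end, g$end) - pmax(cd$start, g$start), 0))
    expect_equal(mass, oracle, tolerance = 1e-9)
  }
})

test_that("mirroring the genome and flipping strands leaves matrices unchanged", {
  sim <- simulate_dataset(sim_config(seed = 15, n_genes = 150))
  trk <- sim$tracks$H3K27me3$`1LD`
  cs <- sim$chrom_sizes
  genes <- sim$genes
  Lc <- cs[[1]]
  fg <- genes
  fg$start <- Lc - genes$end
  fg$end <- Lc - genes$start
  fg$strand <- ifelse(genes$strand == "+", "-", "+")
  tdf <- do.call(rbind, lapply(names(trk$chroms), function(cc)
    cbind(chrom = cc, trk$chroms[[cc]])))
  ftrk <- signal_track(data.frame(chrom = tdf$chrom, start = Lc - tdf$end,
                                  end = Lc - tdf$start, value = tdf$value))
  for (fn in list(function(g, t) tss_anchored_matrix(g, t, chrom_sizes = cs),
                  function(g, t) body_normalized_matrix(g, t, chrom_sizes = cs))) {
    a <- fn(genes, trk); b <- fn(fg, ftrk)
    expect_identical(unname(a[, ]), unname(b[, ]))
    expect_identical(unname(attr(a, "mask")), unname(attr(b, "mask")))
  }
})

test_that("order_rows puts expressed genes first, with documented tie-breaks", {
  mat <- matrix(1:10, 5, 2, dimnames = list(paste0("g", 1:5), c("b1", "b2")))
  fpkm <- c(g1 = 10, g2 = 0.5, g3 = 3, g4 = 0.2, g5 = 3)
  k27 <- c(g1 = 0, g2 = 5, g3 = 0, g4 = 9, g5 = 0)
  out <- order_rows(mat, fpkm, silent_signal = k27)
  # expressed desc by fpkm, ties (g3, g5) lexicographic; silent desc by K27
  expect_equal(rownames(out), c("g1", "g3", "g5", "g4", "g2"))
  out2 <- order_rows(mat, fpkm)          # silent sorted by own row means
  expect_equal(rownames(out2)[1:3], c("g1", "g3", "g5"))
})

test_that("rows ordered by expression track the planted signal coupling", {
  sim <- simulate_dataset(sim_config(seed = 25, n_genes = 600))
  trk <- sim$tracks$H3K4me3$`0LD`
  mt <- tss_anchored_matrix(sim$genes, trk, chrom_sizes = sim$chrom_sizes)
  fl <- expressed_genes(sim$expression)
  fp <- fl$mean_fpkm[, "0LD"]
  k27 <- body_normalized_matrix(sim$genes, sim$tracks$H3K27me3$`0LD`,
                                chrom_sizes = sim$chrom_sizes)
  out <- order_rows(mt, fp, silent_signal = rowMeans(k27))
  n_expr <- sum(fp[rownames(mt)] > 1)
  top <- rowMeans(out[seq_len(floor(n_expr / 3)), , drop = FALSE])
  bottom <- rowMeans(out[(n_expr - floor(n_expr / 3)):n_expr, , drop = FALSE])
  # planted positive signal-expression coupling: top rows carry more K4
  expect_gt(mean(top), mean(bottom))
})
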