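# Seeded synthetic-data generator.  Emits a gene annotation, per-mark
# per-replicate enrichment regions with ChIP/H3-style signal levels, per-mark
# base-resolution signal tracks, a replicated expression table and external
# significance calls, together with the full ground truth (state labels,
# expression tiers, DE classes, per-region discordance flags) so that every
# pipeline step can be recovery-tested.

#' Chromatin state labels
#'
#' The eight joint H3K4me3/H3K27me3 configurations: `H` (harbouring: broad
#' H3K27me3 containing a narrow H3K4me3 peak at the TSS), `E` (embedded:
#' narrow H3K27me3 inside a broad H3K4me3 domain), partial overlaps
#' (`K27_gt_K4`, `K4_gt_K27`), `Non` (both marks present, disjoint),
#' single-mark (`K4_only`, `K27_only`) and `Unmarked`.
#'
#' @return character vector of the eight labels, in display order.
#' @export
state_labels <- function() {
  c("Non", "H", "E", "K27_gt_K4", "K4_gt_K27", "K4_only", "K27_only", "Unmarked")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.complete_fractions <- function(x, what) {
  full <- stats::setNames(rep(0, length(state_labels())), state_labels())
  bad <- setdiff(names(x), state_labels())
  if (length(bad)) stop(what, ": unknown state label ", bad[1L])
  full[names(x)] <- x
  if (abs(sum(full) - 1) > 1e-9) stop(what, ": fractions must sum to 1")
  if (any(full < 0)) stop(what, ": negative fraction")
  full
}

.default_transition_spec <- function() {
  list(
    Non       = c(Non = 0.85, K4_only = 0.05, K27_only = 0.05, H = 0.05),
    # ~0.8 per-step H retention: about half of H-states resolve over 3 steps
    H         = c(H = 0.80, Non = 0.07, K27_gt_K4 = 0.07, E = 0.06),
    E         = c(E = 0.95, K4_gt_K27 = 0.03, K4_only = 0.02),
    K27_gt_K4 = c(K27_gt_K4 = 0.80, H = 0.10, Non = 0.10),
    K4_gt_K27 = c(K4_gt_K27 = 0.80, E = 0.10, Non = 0.10),
    K4_only   = c(K4_only = 0.92, Unmarked = 0.04, Non = 0.04),
    K27_only  = c(K27_only = 0.92, Unmarked = 0.04, Non = 0.04),
    Unmarked  = c(Unmarked = 0.92, K4_only = 0.04, K27_only = 0.04)
  )
}

# Silent genes move almost exclusively within the K27_only/Unmarked pool so
# that per-time-point marked proportions stay near-stationary in each stratum.
.default_silent_transition_spec <- function() {
  list(
    Non       = c(Non = 0.90, K27_only = 0.05, Unmarked = 0.05),
    H         = c(H = 0.90, K27_gt_K4 = 0.05, K27_only = 0.05),
    E         = c(E = 0.95, K27_only = 0.05),
    K27_gt_K4 = c(K27_gt_K4 = 0.90, K27_only = 0.10),
    K4_gt_K27 = c(K4_gt_K27 = 0.90, K27_only = 0.10),
    K4_only   = c(K4_only = 0.90, Unmarked = 0.10),
    K27_only  = c(K27_only = 0.95, Unmarked = 0.05),
    Unmarked  = c(Unmarked = 0.95, K27_only = 0.05)
  )
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: four daily
#' time points after a short-day to long-day shift, ~60% of genes expressed
#' (FPKM > 1), a planted Spearman correlation of 0.31 between TSS H3K4me3
#' signal and expression among expressed genes, ~66% of expressed and ~5% of
#' silent genes carrying H3K4me3 at the TSS, two ChIP replicates per mark with
#' 2% planted discordant regions, and DE-class fractions matching 148 up /
#' 146 down / 4 complex of ~19,940 expressed genes.
#'
#' @param seed integer seed fixing every draw.
#' @param n_genes number of genes.
#' @param n_chroms number of chromosomes (genes are laid out round-robin).
#' @param chrom_length chromosome length in bases; `NULL` auto-sizes to fit
#'   `n_genes` at `gene_pitch` spacing.
#' @param timepoints ordered time point labels.
#' @param frac_expressed fraction of genes expressed (FPKM > 1) at baseline.
#' @param expr_logmean,expr_logsd log-scale location/spread of expressed-gene
#'   FPKM.
#' @param target_rho_k4 planted Spearman correlation between TSS H3K4me3
#'   signal and FPKM among expressed genes (Gaussian copula on ranks).
#' @param state_fractions chromatin-state fractions for expressed genes
#'   (named over [state_labels()], sum 1).
#' @param silent_state_fractions state fractions for non-expressed genes.
#' @param replicate_noise_sd s.d. of the between-replicate signal difference.
#' @param frac_discordant fraction of regions planted with replicate
#'   disagreement far beyond the concordance filter threshold.
#' @param discordant_offset_mult planted discordant offset in units of
#'   `replicate_noise_sd` (see the methods vignette for the margin argument).
#' @param transition_spec named list of per-state transition probability
#'   vectors applied at each time step (expressed genes).
#' @param silent_transition_spec transition probabilities for non-expressed
#'   genes; the default keeps them almost entirely within the
#'   K27_only/Unmarked pool so per-time-point marked proportions stay
#'   near-stationary in each stratum.
#' @param de_spec fractions of genes consistently up / down / complex.
#' @param n_expr_reps expression replicates per time point.
#' @param gene_pitch TSS-to-TSS spacing in bases.
#' @param endpoint_jitter max per-replicate region endpoint jitter in bases.
#' @param k4_logmean,k4_logsd,k27_logmean,k27_logsd log-scale parameters of
#'   the mark signal (ChIP/H3 ratio) distributions.
#' @param count_depth expected read count per FPKM unit (Poisson).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 2000L, n_chroms = 5L,
                       chrom_length = NULL,
                       timepoints = c("0LD", "1LD", "2LD", "3LD"),
                       frac_expressed = 0.6,
                       expr_logmean = 1.5, expr_logsd = 1.2,
                       target_rho_k4 = 0.31,
                       state_fractions = c(Non = 0.06, H = 0.10, E = 0.12,
                                           K27_gt_K4 = 0.04, K4_gt_K27 = 0.04,
                                           K4_only = 0.30, K27_only = 0.08,
                                           Unmarked = 0.26),
                       silent_state_fractions = c(Non = 0.01, H = 0.01,
                                                  E = 0.005, K27_gt_K4 = 0.005,
                                                  K4_gt_K27 = 0.005,
                                                  K4_only = 0.015,
                                                  K27_only = 0.45,
                                                  Unmarked = 0.50),
                       replicate_noise_sd = 0.5, frac_discordant = 0.02,
                       discordant_offset_mult = 8,
                       transition_spec = .default_transition_spec(),
                       silent_transition_spec = .default_silent_transition_spec(),
                       de_spec = c(up = 148 / 19940, down = 146 / 19940,
                                   complex = 4 / 19940),
                       n_expr_reps = 4L, gene_pitch = 10000,
                       endpoint_jitter = 25,
                       k4_logmean = 0.8, k4_logsd = 0.9,
                       k27_logmean = 0.7, k27_logsd = 0.7,
                       count_depth = 20) {
  stopifnot(n_genes >= 1, n_chroms >= 1, length(timepoints) >= 1,
            frac_expressed >= 0, frac_expressed <= 1,
            abs(target_rho_k4) < 1,
            replicate_noise_sd > 0, frac_discordant >= 0, frac_discordant <= 1,
            discordant_offset_mult > 0, n_expr_reps >= 1)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
              timepoints = as.character(timepoints),
              frac_expressed = frac_expressed,
              expr_logmean = expr_logmean, expr_logsd = expr_logsd,
              target_rho_k4 = target_rho_k4,
              state_fractions = .complete_fractions(state_fractions,
                                                    "state_fractions"),
              silent_state_fractions = .complete_fractions(
                silent_state_fractions, "silent_state_fractions"),
              replicate_noise_sd = replicate_noise_sd,
              frac_discordant = frac_discordant,
              discordant_offset_mult = discordant_offset_mult,
              transition_spec = transition_spec,
              silent_transition_spec = silent_transition_spec,
              de_spec = de_spec,
              n_expr_reps = as.integer(n_expr_reps), gene_pitch = gene_pitch,
              endpoint_jitter = endpoint_jitter,
              k4_logmean = k4_logmean, k4_logsd = k4_logsd,
              k27_logmean = k27_logmean, k27_logsd = k27_logsd,
              count_depth = count_depth)
  for (spec in c("transition_spec", "silent_transition_spec")) {
    for (nm in names(cfg[[spec]])) {
      if (abs(sum(cfg[[spec]][[nm]]) - 1) > 1e-9)
        stop(spec, "[", nm, "] must sum to 1")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# Bounded replicate-difference noise: standard normal truncated at +-2,
# rescaled to unit variance (bound ~2.274 s.d.), then scaled by sd.
.rnoise_bounded <- function(n, sd) {
  p2 <- stats::pnorm(2)
  z <- stats::qnorm((1 - p2) + stats::runif(n) * (2 * p2 - 1))
  vtn <- 1 - 2 * 2 * stats::dnorm(2) / (2 * p2 - 1)
  sd * z / sqrt(vtn)
}

# State geometry in TSS-relative transcript coordinates (half-open offsets).
# Returns per-gene K4/K27 relative intervals (NA where the mark is absent).
# Margins are >= ~100 bp everywhere so that endpoint jitter and cross-replicate
# union cannot flip containment or overlap relations.
.state_geometry <- function(states) {
  n <- length(states)
  k4s <- k4e <- k27s <- k27e <- rep(NA_real_, n)
  rint <- function(m, lo, hi) round(stats::runif(m, lo, hi))
  inner_at_tss <- function(m, wlo = 150, whi = 600, mlo = -300, mhi = 300) {
    w <- rint(m, wlo, whi); mid <- rint(m, mlo, mhi)
    s <- mid - floor(w / 2)
    cbind(s, s + w)
  }
  outer_containing <- function(inner) {
    m <- nrow(inner)
    w_in <- inner[, 2] - inner[, 1]
    w_out <- rint(m, pmax(1500, w_in + 400), 4000)
    a <- rint(m, 150, w_out - w_in - 150)
    s <- inner[, 1] - a
    cbind(s, s + w_out)
  }
  idx <- which(states %in% c("H", "K4_only", "Non"))
  if (length(idx)) {
    inner <- inner_at_tss(length(idx))
    k4s[idx] <- inner[, 1]; k4e[idx] <- inner[, 2]
  }
  idx <- which(states == "H")
  if (length(idx)) {
    outer <- outer_containing(cbind(k4s[idx], k4e[idx]))
    k27s[idx] <- outer[, 1]; k27e[idx] <- outer[, 2]
  }
  idx <- which(states == "E")
  if (length(idx)) {
    inner <- inner_at_tss(length(idx))
    outer <- outer_containing(inner)
    k27s[idx] <- inner[, 1]; k27e[idx] <- inner[, 2]
    k4s[idx] <- outer[, 1]; k4e[idx] <- outer[, 2]
  }
  idx <- which(states == "K27_gt_K4")
  if (length(idx)) {
    m <- length(idx)
    inner <- inner_at_tss(m, wlo = 400, whi = 800, mlo = -150, mhi = 150)
    w4 <- inner[, 2] - inner[, 1]
    o <- rint(m, 100, w4 - 150)
    w27 <- rint(m, w4 + 500, 3500)
    side <- stats::runif(m) < 0.5
    s27 <- ifelse(side, inner[, 2] - o, inner[, 1] + o - w27)
    k4s[idx] <- inner[, 1]; k4e[idx] <- inner[, 2]
    k27s[idx] <- s27; k27e[idx] <- s27 + w27
  }
  idx <- which(states == "K4_gt_K27")
  if (length(idx)) {
    m <- length(idx)
    inner <- inner_at_tss(m, wlo = 400, whi = 800, mlo = -150, mhi = 150)
    w27 <- inner[, 2] - inner[, 1]
    o <- rint(m, 100, w27 - 150)
    w4 <- rint(m, w27 + 500, 3500)
    side <- stats::runif(m) < 0.5
    s4 <- ifelse(side, inner[, 2] - o, inner[, 1] + o - w4)
    k27s[idx] <- inner[, 1]; k27e[idx] <- inner[, 2]
    k4s[idx] <- s4; k4e[idx] <- s4 + w4
  }
  idx <- which(states == "Non")  # K4 already placed at TSS; distal K27
  if (length(idx)) {
    # downstream so the K27 region stays inside the gene body (length >= 2 kb)
    m <- length(idx)
    d <- rint(m, 1200, 1700); w27 <- rint(m, 800, 2000)
    k27s[idx] <- d; k27e[idx] <- d + w27
  }
  idx <- which(states == "K27_only")
  if (length(idx)) {
    m <- length(idx)
    w <- rint(m, 1500, 4000); mid <- rint(m, -500, 500)
    s <- mid - floor(w / 2)
    k27s[idx] <- s; k27e[idx] <- s + w
  }
  data.frame(k4s = k4s, k4e = k4e, k27s = k27s, k27e = k27e)
}

# Map a TSS-relative half-open offset interval to genome coordinates.
.rel_to_genome <- function(tss, strand, rs, re) {
  s <- ifelse(strand == "+", tss + rs, tss - re + 1)
  e <- ifelse(strand == "+", tss + re, tss - rs + 1)
  cbind(s, e)
}

#' Generate a synthetic chromatin/expression dataset
#'
#' Produces gene annotations, per-mark per-replicate enrichment regions with
#' planted chromatin-state geometry, per-mark signal tracks, a replicated
#' expression table whose ranks are coupled to the TSS H3K4me3 signal through
#' a Gaussian copula, external significance calls, and the full ground truth.
#' Identical configurations give byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all outputs are written as
#'   standard-format files (GFF3, narrowPeak, bedGraph, TSV).
#' @return a `sam_sim` list: `genes`, `peaks[[mark]][[tp]][[rep]]`,
#'   `tracks[[mark]][[tp]]`, `expression`, `signif`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- .with_seed(config$seed, .simulate_impl(config))
  if (!is.null(out_dir)) write_dataset(sim, out_dir)
  sim
}

.simulate_impl <- function(cfg) {
  n <- cfg$n_genes; tps <- cfg$timepoints; T <- length(tps)
  pitch <- cfg$gene_pitch
  slots_per_chrom <- ceiling(n / cfg$n_chroms)
  chrom_length <- cfg$chrom_length
  if (is.null(chrom_length)) {
    chrom_length <- slots_per_chrom * pitch + pitch
  } else {
    cap <- floor((chrom_length - pitch) / pitch)
    if (cap * cfg$n_chroms < n)
      stop("infeasible geometry: ", n, " genes do not fit on ", cfg$n_chroms,
           " chromosome(s) of length ", chrom_length, " at pitch ", pitch)
    slots_per_chrom <- cap
  }
  chroms <- paste0("chr", seq_len(cfg$n_chroms))

  ## --- genes -------------------------------------------------------------
  idx <- seq_len(n) - 1L
  chrom <- chroms[(idx %% cfg$n_chroms) + 1L]
  slot <- idx %/% cfg$n_chroms
  tss <- slot * pitch + pitch / 2
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  glen <- round(stats::runif(n, 2000, 3000))
  gstart <- ifelse(strand == "+", tss, tss - glen + 1)
  gend <- ifelse(strand == "+", tss + glen, tss + 1)
  genes <- gene_table(sprintf("GENE%05d", seq_len(n)), chrom, gstart, gend,
                      strand)

  ## --- expression tiers, copula coupling ---------------------------------
  expressed0 <- stats::runif(n) < cfg$frac_expressed
  r <- 2 * sin(pi * cfg$target_rho_k4 / 6)   # copula corr for target Spearman
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  z2[!expressed0] <- stats::rnorm(sum(!expressed0))  # silent: uncoupled
  fpkm_base <- ifelse(expressed0,
                      1.31 + exp(cfg$expr_logmean + cfg$expr_logsd * z1),
                      stats::runif(n, 0, 0.69))
  sig_floor <- max(0.8, 1.6 * cfg$replicate_noise_sd)
  k4_base <- sig_floor + exp(cfg$k4_logmean + cfg$k4_logsd * z2)
  k27_base <- sig_floor + stats::rlnorm(n, cfg$k27_logmean, cfg$k27_logsd)

  ## --- DE classes and per-timepoint expression ---------------------------
  de_class <- rep("ns", n)
  expr_idx <- which(expressed0)
  n_up <- round(cfg$de_spec[["up"]] * n)
  n_down <- round(cfg$de_spec[["down"]] * n)
  n_cx <- round(cfg$de_spec[["complex"]] * n)
  pick <- sample(expr_idx, min(length(expr_idx), n_up + n_down + n_cx))
  if (n_up > 0) de_class[pick[seq_len(min(n_up, length(pick)))]] <- "up"
  if (n_down > 0 && length(pick) > n_up)
    de_class[pick[(n_up + 1):min(n_up + n_down, length(pick))]] <- "down"
  if (n_cx > 0 && length(pick) > n_up + n_down)
    de_class[pick[(n_up + n_down + 1):min(n_up + n_down + n_cx, length(pick))]] <- "complex"

  step_up <- 1.6
  mult <- matrix(1, n, T)
  for (j in seq_len(T)) {
    k <- j - 1L
    mult[de_class == "up", j] <- step_up^k
    mult[de_class == "down", j] <- step_up^(-k)
    mult[de_class == "complex", j] <-
      if (j <= ceiling(T / 2)) step_up^k else step_up^(ceiling(T / 2) - 1) * step_up^(-(j - ceiling(T / 2)))
  }
  fpkm_tp <- fpkm_base * mult * matrix(exp(stats::rnorm(n * T, 0, 0.03)), n, T)
  # guard band: planted FPKM never falls in [0.69, 1.31) so replicate noise
  # cannot flip the expressed (FPKM > 1) status
  in_band <- fpkm_tp >= 0.69 & fpkm_tp < 1.31
  fpkm_tp[in_band] <- ifelse(fpkm_tp[in_band] >= 1, 1.31, 0.68)
  tier_tp <- fpkm_tp > 1

  ## --- expression replicates ---------------------------------------------
  R <- cfg$n_expr_reps
  expr_long <- data.frame(
    gene_id = rep(genes$gene_id, times = T * R),
    timepoint = rep(rep(tps, each = n), times = R),
    replicate = rep(seq_len(R), each = n * T),
    stringsAsFactors = FALSE)
  base_vals <- rep(as.vector(fpkm_tp), times = R)
  expr_long$fpkm <- base_vals * exp(stats::rnorm(n * T * R, 0, 0.05))
  expr_long$count <- stats::rpois(n * T * R, expr_long$fpkm * cfg$count_depth)
  expr_long <- expr_long[order(expr_long$gene_id, expr_long$timepoint,
                               expr_long$replicate), ]
  rownames(expr_long) <- NULL

  ## --- significance calls -------------------------------------------------
  contrasts <- if (T >= 2) paste0(tps[1L], "->", tps[-1L]) else character()
  sig_rows <- list()
  if (T >= 2) for (i in which(de_class %in% c("up", "down"))) {
    sig_rows[[length(sig_rows) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], contrast = contrasts,
      direction = de_class[i], significant = 1L, stringsAsFactors = FALSE)
  }
  if (T >= 2) for (i in which(de_class == "complex")) {
    sig_rows[[length(sig_rows) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i],
      contrast = c(paste0(tps[1L], "->", tps[2L]),
                   paste0(tps[T - 1L], "->", tps[T])),
      direction = c("up", "down"), significant = 1L, stringsAsFactors = FALSE)
  }
  signif <- if (length(sig_rows)) do.call(rbind, sig_rows)
            else data.frame(gene_id = character(), contrast = character(),
                            direction = character(), significant = integer(),
                            stringsAsFactors = FALSE)

  ## --- chromatin states over time -----------------------------------------
  labs <- state_labels()
  states <- matrix(NA_character_, n, T)
  draw_states <- function(m, fr) sample(labs, m, replace = TRUE, prob = fr)
  states[expressed0, 1L] <- draw_states(sum(expressed0), cfg$state_fractions)
  states[!expressed0, 1L] <- draw_states(sum(!expressed0),
                                         cfg$silent_state_fractions)
  if (T >= 2) for (j in 2:T) {
    states[, j] <- states[, j - 1L]
    for (stratum in c(TRUE, FALSE)) {
      spec <- if (stratum) cfg$transition_spec else cfg$silent_transition_spec
      for (from in labs) {
        ii <- which(states[, j - 1L] == from & expressed0 == stratum)
        if (!length(ii)) next
        p <- spec[[from]]
        if (is.null(p)) next
        states[ii, j] <- sample(names(p), length(ii), replace = TRUE, prob = p)
      }
    }
  }

  ## --- regions, replicates, tracks ----------------------------------------
  sdn <- cfg$replicate_noise_sd
  jit <- cfg$endpoint_jitter
  peaks <- list(H3K4me3 = list(), H3K27me3 = list())
  tracks <- list(H3K4me3 = list(), H3K27me3 = list())
  truth_regions <- list()
  for (j in seq_len(T)) {
    geo <- .state_geometry(states[, j])
    drift4 <- exp(stats::rnorm(n, 0, 0.05))
    drift27 <- exp(stats::rnorm(n, 0, 0.05))
    for (mark in c("H3K4me3", "H3K27me3")) {
      if (mark == "H3K4me3") {
        has <- !is.na(geo$k4s)
        gpos <- .rel_to_genome(tss[has], strand[has], geo$k4s[has], geo$k4e[has])
        sig <- (k4_base * drift4)[has]
      } else {
        has <- !is.na(geo$k27s)
        gpos <- .rel_to_genome(tss[has], strand[has], geo$k27s[has], geo$k27e[has])
        sig <- (k27_base * drift27)[has]
      }
      m <- sum(has)
      common <- exp(stats::rnorm(m, 0, 0.05))
      d <- .rnoise_bounded(m, sdn)
      disc <- stats::runif(m) < cfg$frac_discordant
      boost <- (cfg$discordant_offset_mult * sdn + stats::runif(m, 0, sdn)) * disc
      to_rep1 <- stats::runif(m) < 0.5
      s1 <- sig * common + d / 2 + boost * to_rep1
      s2 <- sig * common - d / 2 + boost * !to_rep1
      j1s <- gpos[, 1] + round(stats::runif(m, -jit, jit))
      j1e <- gpos[, 2] + round(stats::runif(m, -jit, jit))
      j2s <- gpos[, 1] + round(stats::runif(m, -jit, jit))
      j2e <- gpos[, 2] + round(stats::runif(m, -jit, jit))
      ord <- order(chrom[has], gpos[, 1])
      mk <- function(ss, ee, sg) data.frame(
        chrom = chrom[has], start = pmax(0, ss), end = ee,
        name = paste0(mark, "_", tps[j], "_", genes$gene_id[has]),
        score = pmin(1000, round(100 * sg)), strand = "*", signal = sg,
        stringsAsFactors = FALSE)[ord, ]
      rep1 <- mk(j1s, j1e, s1); rownames(rep1) <- NULL
      rep2 <- mk(j2s, j2e, s2); rownames(rep2) <- NULL
      peaks[[mark]][[tps[j]]] <- list(rep1 = rep1, rep2 = rep2)
      trk <- data.frame(chrom = chrom[has], start = gpos[, 1], end = gpos[, 2],
                        value = sig, stringsAsFactors = FALSE)[ord, ]
      tracks[[mark]][[tps[j]]] <- signal_track(trk)
      truth_regions[[length(truth_regions) + 1L]] <- data.frame(
        gene_id = genes$gene_id[has], timepoint = tps[j], mark = mark,
        chrom = chrom[has], start = gpos[, 1], end = gpos[, 2], signal = sig,
        rep1_signal = s1, rep2_signal = s2, discordant = disc,
        stringsAsFactors = FALSE)
    }
  }
  truth_regions <- do.call(rbind, truth_regions)
  rownames(truth_regions) <- NULL

  truth <- list(
    states = data.frame(gene_id = rep(genes$gene_id, times = T),
                        timepoint = rep(tps, each = n),
                        label = as.vector(states), stringsAsFactors = FALSE),
    expression = data.frame(gene_id = rep(genes$gene_id, times = T),
                            timepoint = rep(tps, each = n),
                            fpkm = as.vector(fpkm_tp),
                            expressed = as.vector(tier_tp),
                            stringsAsFactors = FALSE),
    de = data.frame(gene_id = genes$gene_id, de_class = de_class,
                    stringsAsFactors = FALSE),
    regions = truth_regions,
    k4_tss_signal = data.frame(gene_id = genes$gene_id, signal = k4_base,
                               expressed = expressed0, stringsAsFactors = FALSE))

  structure(list(genes = genes, peaks = peaks, tracks = tracks,
                 expression = expr_long, signif = signif, truth = truth,
                 config = cfg, chrom_sizes = stats::setNames(
                   rep(chrom_length, cfg$n_chroms), chroms)),
            class = "sam_sim")
}

#' Write a simulated dataset to standard-format files
#'
#' @param sim a `sam_sim` object from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sam_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genes_gff3(sim$genes, file.path(dir, "genes.gff3"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_signif_calls(sim$signif, file.path(dir, "significance.tsv"))
  for (mark in names(sim$peaks)) {
    for (tp in names(sim$peaks[[mark]])) {
      reps <- sim$peaks[[mark]][[tp]]
      for (r in seq_along(reps))
        write_narrowpeak(reps[[r]], file.path(dir, sprintf("%s_%s_rep%d.narrowPeak",
                                                           mark, tp, r)))
      write_bedgraph(sim$tracks[[mark]][[tp]],
                     file.path(dir, sprintf("%s_%s.bedGraph", mark, tp)))
    }
  }
  data.table::fwrite(data.table::as.data.table(sim$truth$states),
                     file.path(dir, "truth_states.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(sim$truth$expression),
                     file.path(dir, "truth_expression.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(sim$truth$regions),
                     file.path(dir, "truth_regions.tsv"), sep = "\t")
  writeLines(paste(names(sim$chrom_sizes), sim$chrom_sizes, sep = "\t"),
             file.path(dir, "chrom.sizes"))
  invisible(dir)
}

#' Simulate matched replicate signal pairs
#'
#' A minimal generator for exercising the replicate concordance filter in
#' isolation: `n` region pairs on one toy chromosome sharing coordinates, with
#' bounded concordant between-replicate signal noise and a planted fraction of
#' discordant pairs offset far beyond the 2-s.d. filter threshold.
#'
#' @param n number of region pairs.
#' @param frac_discordant fraction of planted discordant pairs.
#' @param noise_sd s.d. of the between-replicate signal difference.
#' @param seed integer seed.
#' @param offset_mult discordant offset in units of `noise_sd`.
#' @return list with `rep1`, `rep2` region data.frames and the logical
#'   `discordant` ground-truth flags (in `rep1` row order).
#' @export
simulate_signal_pairs <- function(n, frac_discordant = 0.02, noise_sd = 0.5,
                                  seed = 1L, offset_mult = 8) {
  .with_seed(seed, {
    start <- (seq_len(n) - 1) * 2000
    sig <- max(0.8, 1.6 * noise_sd) + stats::rlnorm(n, 0.8, 0.9)
    d <- .rnoise_bounded(n, noise_sd)
    disc <- stats::runif(n) < frac_discordant
    boost <- (offset_mult * noise_sd + stats::runif(n, 0, noise_sd)) * disc
    to1 <- stats::runif(n) < 0.5
    mk <- function(sg) data.frame(chrom = "chrT", start = start,
                                  end = start + 1000,
                                  name = sprintf("r%05d", seq_len(n)),
                                  score = 0, strand = "*", signal = sg,
                                  stringsAsFactors = FALSE)
    list(rep1 = mk(sig + d / 2 + boost * to1),
         rep2 = mk(sig - d / 2 + boost * !to1),
         discordant = disc)
  })
}
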