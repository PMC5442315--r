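# End-to-end driver: replicate peaks -> consensus -> per-gene profiles ->
# state calls -> transition matrices -> association statistics.

#' Run the full chromatin-state pipeline on a simulated experiment
#'
#' Convenience wrapper chaining [build_consensus()], [profile_genes()],
#' [classify_states_timecourse()], [transition_matrix()] (consecutive time
#' points plus first-to-last), [marked_fraction()] and
#' [tss_expression_correlation()].
#'
#' @param sim a `sam_sim` object ([simulate_dataset()]), or any list providing
#'   `genes`, `peaks`, `expression` and `config$timepoints`.
#' @param params [state_params()] for the classifier.
#' @param sd_mult concordance-filter threshold in standard deviations.
#' @param filter apply the concordance filter.
#' @return list with `consensus`, `profiles` (per time point), `calls`,
#'   `transitions` (named `from->to`), `marked`, `correlation`.
#' @export
run_chromatin_pipeline <- function(sim, params = state_params(), sd_mult = 2,
                                   filter = TRUE) {
  tps <- sim$config$timepoints
  cons <- build_consensus(sim$peaks, sd_mult = sd_mult, filter = filter)
  profiles <- lapply(tps, function(tp) profile_genes(sim$genes, list(
    H3K4me3 = cons$H3K4me3[[tp]], H3K27me3 = cons$H3K27me3[[tp]]),
    window_halfwidth = params$tss_halfwidth))
  names(profiles) <- tps
  calls <- classify_states_timecourse(sim$genes, cons, params)
  by_tp <- split(calls, calls$timepoint)
  transitions <- list()
  if (length(tps) >= 2) {
    for (j in seq_len(length(tps) - 1L)) {
      nm <- paste0(tps[j], "->", tps[j + 1L])
      transitions[[nm]] <- transition_matrix(by_tp[[tps[j]]], by_tp[[tps[j + 1L]]])
    }
    nm <- paste0(tps[1L], "->", tps[length(tps)])
    transitions[[nm]] <- transition_matrix(by_tp[[tps[1L]]],
                                           by_tp[[tps[length(tps)]]])
  }
  marked <- list(
    expressed = marked_fraction(profiles, sim$expression, "H3K4me3", "expressed"),
    non_expressed = marked_fraction(profiles, sim$expression, "H3K4me3",
                                    "non_expressed"))
  correlation <- tss_expression_correlation(profiles, sim$expression, "H3K4me3")
  list(consensus = cons, profiles = profiles, calls = calls,
       transitions = transitions, marked = marked, correlation = correlation)
}
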