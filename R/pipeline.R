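# End-to-end convenience wrapper: digest -> size-select -> simulate ->
# trim -> align -> call.

#' Run the full simulated RRBS pipeline
#'
#' Digests the genome with MspI, size-selects fragments, simulates
#' directional bisulfite read pairs from the truth methylome, trims (fill-in
#' and BWA-style quality trimming), aligns with the bisulfite-aware paired
#' aligner and extracts per-CpG calls plus conversion QC.
#'
#' @param genome An `rrbs_genome`.
#' @param truth A `methylome_truth`.
#' @param params A [library_params()].
#' @param quality_threshold Phred threshold for quality trimming (default 20).
#' @param seed_len Aligner seed length (default 50).
#' @param max_mismatch Aligner mismatch tolerance per mate (default 1).
#' @return List: `fragments` (all), `retained` (size-selected), `pairs`
#'   (simulated, untrimmed), `trimmed`, `alignments`, `calls` (a `cpg_calls`).
#' @export
run_rrbs_pipeline <- function(genome, truth, params,
                              quality_threshold = 20L, seed_len = 50L,
                              max_mismatch = 1L) {
  fragments <- digest_genome(genome)
  retained <- size_select(fragments, params$insert_min, params$insert_max)
  pairs <- simulate_read_pairs(genome, retained, truth, params)
  trimmed <- trim_pairs(pairs, threshold = quality_threshold)
  index <- build_index(genome, seed_len = seed_len)
  alignments <- align_pairs(trimmed, index, max_mismatch = max_mismatch,
                            insert_min = params$insert_min,
                            insert_max = params$insert_max)
  calls <- extract_calls(alignments, trimmed, genome)
  list(fragments = fragments, retained = retained, pairs = pairs,
       trimmed = trimmed, index = index, alignments = alignments,
       calls = calls)
}
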