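library(data.table)

# Hand-built truth object over explicit sites (used by simulator unit tests).
manual_truth <- function(contig, pos, m) {
  structure(list(sites = data.table(contig = contig, pos = as.integer(pos),
                                    m = m),
                 active_genes = character(0)),
            class = "methylome_truth")
}

# Constant-methylation truth over every CpG of a genome.
uniform_truth <- function(genome, m) {
  sites <- rbindlist(lapply(names(genome$contigs), function(cn) {
    p <- gregexpr("CG", genome$contigs[[cn]], fixed = TRUE)[[1]]
    p <- if (p[1] == -1L) integer(0) else as.integer(p) - 1L
    if (!length(p)) return(NULL)
    data.table(contig = cn, pos = p, m = m)
  }))
  structure(list(sites = sites, active_genes = character(0)),
            class = "methylome_truth")
}

# Wrap a plain genome (named character vector) as an rrbs_genome without genes.
as_genome <- function(contigs) {
  structure(list(contigs = contigs, genes = data.table(), spec = NULL),
            class = "rrbs_genome")
}

# Dense calls straight from a truth methylome: every CpG at fixed coverage.
dense_calls_from_truth <- function(truth, coverage = 100L) {
  s <- copy(truth$sites)
  s[, meth := as.integer(round(m * coverage))]
  s[, unmeth := coverage - meth]
  s[, m := NULL]
  s[]
}

# A small standard world shared by several test files.
small_world <- function(seed = 42L, n_genes = 35L, contig_length = 500000L,
                        n_contigs = 1L) {
  spec <- genome_spec(n_contigs = n_contigs, contig_length = contig_length,
                      n_genes = n_genes, seed = seed)
  g <- generate_genome(spec)
  truth <- generate_truth_methylome(g, seed = seed + 1L)
  list(genome = g, truth = truth)
}

# Memoised heavy fixtures for the acceptance suite.
.acc_cache <- new.env(parent = emptyenv())
acc_fixture <- function(name, builder) {
  if (!exists(name, envir = .acc_cache)) assign(name, builder(), envir = .acc_cache)
  get(name, envir = .acc_cache)
}
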