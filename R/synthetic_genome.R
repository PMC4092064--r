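# Synthetic genome, ground-truth methylome and expression counts.
#
# The generator emulates the statistical structure the downstream analyses
# assume: CpG-poor background (~1 CpG / 100 bp), CpG-dense islands centred on
# gene TSSs, a bimodal methylome (unmethylated active promoters, methylated
# background) and an expression table in which ~60% of genes are repressed.

#' Specification for a synthetic CpG-island genome
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp.
#' @param background_cpg_rate CpG starts per bp outside islands (default 0.01,
#'   i.e. roughly one CpG per 100 bp as in mammalian bulk sequence).
#' @param island_cpg_rate CpG starts per bp inside the island around each TSS
#'   (default 0.10).
#' @param island_half_width Island half-width in bp around the TSS.
#' @param n_genes Total number of genes placed on the genome.
#' @param gene_span Gene length in bp (fixed span; default 5000).
#' @param gene_spacing Minimum distance between consecutive TSSs (default
#'   13000 so that +/-6 kb TSS flanks never overlap a neighbour).
#' @param seed Integer seed; identical seeds reproduce output byte-identically.
#'
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_contigs = 1L, contig_length = 500000L,
                        background_cpg_rate = 0.01, island_cpg_rate = 0.10,
                        island_half_width = 500L, n_genes = 35L,
                        gene_span = 5000L, gene_spacing = 13000L, seed = 1L) {
  if (contig_length < 10L * island_half_width)
    stop("contig_length must be >= 10 * island_half_width", call. = FALSE)
  if (!(background_cpg_rate >= 0 && background_cpg_rate <= island_cpg_rate &&
        island_cpg_rate <= 0.5))
    stop("need 0 <= background_cpg_rate <= island_cpg_rate <= 0.5", call. = FALSE)
  margin <- max(6500L, gene_span + island_half_width)
  per_contig <- max(0L, (contig_length - 2L * margin) %/% gene_spacing + 1L)
  if (n_genes > per_contig * n_contigs)
    stop(sprintf(
      "genome too small: %d genes requested but only %d fit at %d bp spacing",
      n_genes, per_contig * n_contigs, gene_spacing), call. = FALSE)
  structure(list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    background_cpg_rate = background_cpg_rate,
    island_cpg_rate = island_cpg_rate,
    island_half_width = as.integer(island_half_width),
    n_genes = as.integer(n_genes),
    gene_span = as.integer(gene_span),
    gene_spacing = as.integer(gene_spacing),
    margin = margin,
    seed = as.integer(seed)), class = "genome_spec")
}

# Remove every native CG dinucleotide by rewriting its C to A or T.
# Replacing the C with A/T cannot create a new CG on either side.
.deplete_cg <- function(bases) {
  n <- length(bases)
  idx <- which(bases[-n] == "C" & bases[-1] == "G")
  if (length(idx)) bases[idx] <- sample(c("A", "T"), length(idx), replace = TRUE)
  bases
}

# Plant CpGs at per-position Bernoulli(rate), skipping collisions so planted
# sites never overlap (start positions at least 2 bp apart).
.plant_cpgs <- function(bases, rate_vec) {
  n <- length(bases)
  cand <- which(runif(n - 1L) < rate_vec[seq_len(n - 1L)])
  if (length(cand) > 1L) {
    keep <- logical(length(cand))
    keep[1L] <- TRUE
    last <- cand[1L]
    for (i in seq_along(cand)[-1L]) {
      if (cand[i] - last >= 2L) { keep[i] <- TRUE; last <- cand[i] }
    }
    cand <- cand[keep]
  }
  bases[cand] <- "C"
  bases[cand + 1L] <- "G"
  bases
}

#' Generate a synthetic genome with CpG islands at gene starts
#'
#' Background sequence is i.i.d. uniform over A/C/G/T with native CG
#' dinucleotides removed, after which CpGs are planted at the background rate
#' genome-wide and at the island rate within `island_half_width` of each TSS.
#' Genes have fixed span and are placed non-overlapping at regular spacing;
#' strands alternate deterministically under the seed.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `rrbs_genome`: a list with `contigs` (named
#'   character vector of sequences) and `genes` (data.table with columns
#'   `gene_id`, `contig`, `start`, `end`, `strand`, `tss`; all coordinates
#'   0-based, half-open; the TSS of a `-` strand gene is `end - 1`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    L <- spec$contig_length
    hw <- spec$island_half_width
    per_contig <- (L - 2L * spec$margin) %/% spec$gene_spacing + 1L
    contigs <- character(spec$n_contigs)
    names(contigs) <- sprintf("contig_%d", seq_len(spec$n_contigs))
    genes_list <- vector("list", spec$n_contigs)
    remaining <- spec$n_genes
    gid <- 0L
    for (ci in seq_len(spec$n_contigs)) {
      bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      bases <- .deplete_cg(bases)
      n_here <- min(per_contig, remaining)
      remaining <- remaining - n_here
      if (n_here > 0L) {
        tss <- spec$margin + (seq_len(n_here) - 1L) * spec$gene_spacing
        strand <- sample(c("+", "-"), n_here, replace = TRUE)
        start <- ifelse(strand == "+", tss, tss - spec$gene_span + 1L)
        end <- ifelse(strand == "+", tss + spec$gene_span, tss + 1L)
        genes_list[[ci]] <- data.table(
          gene_id = sprintf("gene_%04d", gid + seq_len(n_here)),
          contig = names(contigs)[ci],
          start = as.integer(start), end = as.integer(end),
          strand = strand, tss = as.integer(tss))
        gid <- gid + n_here
      } else {
        tss <- integer(0)
      }
      rate <- rep(spec$background_cpg_rate, L)
      for (t in tss) {
        lo <- max(1L, t - hw + 1L)
        hi <- min(L, t + hw)
        rate[lo:hi] <- spec$island_cpg_rate
      }
      bases <- .plant_cpgs(bases, rate)
      contigs[ci] <- paste(bases, collapse = "")
    }
    genes <- rbindlist(genes_list)
    structure(list(contigs = contigs, genes = genes, spec = spec),
              class = "rrbs_genome")
  })
}

#' @export
print.rrbs_genome <- function(x, ...) {
  cat(sprintf("rrbs_genome: %d contig(s), %s bp total, %d gene(s)\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

# All forward-strand CpG C positions (0-based) of one sequence.
cpg_positions <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Ground-truth methylome over every genomic CpG
#'
#' A fraction of genes is designated "active"; CpGs within
#' `promoter_half_width` of an active TSS receive the low methylation level,
#' all other CpGs the high level, each with truncated-normal jitter.
#' Methylation is keyed by the forward-strand position of the CpG's C and
#' applies to both strands (symmetric CpG methylation).
#'
#' @param genome An `rrbs_genome`.
#' @param m_low,m_high Low/high methylation probabilities (defaults 0.05, 0.85).
#' @param active_fraction Fraction of genes designated active (default 0.2).
#' @param jitter_sd Truncated-normal jitter sd on `m` (default 0.03; 0 gives
#'   exactly two truth values).
#' @param promoter_half_width Half-width of the unmethylated promoter window
#'   around active TSSs (default 1000 bp).
#' @param seed Integer seed.
#'
#' @return Object of class `methylome_truth`: list with `sites` (data.table
#'   `contig`, `pos` (0-based C position), `m`) and `active_genes` (character
#'   vector of gene ids).
#' @export
generate_truth_methylome <- function(genome, m_low = 0.05, m_high = 0.85,
                                     active_fraction = 0.2, jitter_sd = 0.03,
                                     promoter_half_width = 1000L, seed = 1L) {
  stopifnot(inherits(genome, "rrbs_genome"))
  if (!(m_low < m_high)) stop("m_low must be < m_high", call. = FALSE)
  stopifnot_scalar_prob(active_fraction, "active_fraction")
  with_seed(seed, {
    genes <- genome$genes
    n_active <- round(active_fraction * nrow(genes))
    active <- if (n_active > 0L) sort(sample(genes$gene_id, n_active)) else character(0)
    act <- genes[genes$gene_id %in% active]
    sites <- rbindlist(lapply(names(genome$contigs), function(cn) {
      pos <- cpg_positions(genome$contigs[[cn]])
      if (!length(pos)) return(NULL)
      data.table(contig = cn, pos = pos)
    }))
    sites[, m := m_high]
    if (nrow(act)) {
      for (i in seq_len(nrow(act))) {
        sites[contig == act$contig[i] &
                pos >= act$tss[i] - promoter_half_width &
                pos <= act$tss[i] + promoter_half_width, m := m_low]
      }
    }
    if (jitter_sd > 0) {
      sites[, m := pmin(1, pmax(0, m + rnorm(.N, 0, jitter_sd)))]
    }
    structure(list(sites = sites[], active_genes = active,
                   m_low = m_low, m_high = m_high,
                   promoter_half_width = as.integer(promoter_half_width)),
              class = "methylome_truth")
  })
}

#' Expression counts with the 60/20/20 repressed/low/high structure
#'
#' Exactly `round(repressed_fraction * n)` genes are repressed (counts drawn
#' from 0..9). Non-repressed genes get counts >= 10 spanning more than two
#' orders of magnitude (log-uniform). Active genes (from the truth methylome)
#' are kept out of the repressed set and, with probability `coupling`, receive
#' counts above the non-active range so they land in the "high" class.
#'
#' @param genes Gene table (from `generate_genome()`, or an `rrbs_genome`).
#' @param repressed_fraction Fraction of genes with count < 10 (default 0.6).
#' @param active_genes Character vector of active gene ids (optional).
#' @param coupling Probability an active gene is forced into the top count
#'   decade (default 1.0).
#' @param seed Integer seed.
#' @return data.table (`gene_id`, `count`, `class`); class assigned by
#'   [group_by_expression()] (repressed iff count < 10; low/high = median
#'   split of the rest).
#' @export
generate_expression <- function(genes, repressed_fraction = 0.6,
                                active_genes = character(0), coupling = 1.0,
                                seed = 1L) {
  if (inherits(genes, "rrbs_genome")) genes <- genes$genes
  if (!(repressed_fraction >= 0 && repressed_fraction < 1))
    stop("repressed_fraction must be in [0, 1)", call. = FALSE)
  stopifnot_scalar_prob(coupling, "coupling")
  with_seed(seed, {
    ids <- genes$gene_id
    n <- length(ids)
    n_rep <- round(repressed_fraction * n)
    pool <- setdiff(ids, active_genes)
    if (length(pool) < n_rep) {
      pool <- ids  # more repressed genes than non-active ones: coupling yields
    }
    repressed <- if (n_rep > 0L) sample(pool, n_rep) else character(0)
    counts <- integer(n)
    names(counts) <- ids
    counts[repressed] <- sample(0:9, length(repressed), replace = TRUE)
    rest <- setdiff(ids, repressed)
    # log-uniform over [10, ~5000); active genes pushed above 5000 so a full
    # coupling puts them all in the top (high) half
    counts[rest] <- pmin(4999L,
                         as.integer(round(10^runif(length(rest), 1, log10(5000)))))
    act_rest <- intersect(rest, active_genes)
    if (length(act_rest) && coupling > 0) {
      boost <- act_rest[runif(length(act_rest)) < coupling]
      counts[boost] <- as.integer(round(10^runif(length(boost), log10(5000), 6)))
    }
    expr <- data.table(gene_id = ids, count = unname(counts[ids]))
    grp <- group_by_expression(expr)
    expr[, class := grp$class[match(expr$gene_id, grp$gene_id)]]
    expr[]
  })
}
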