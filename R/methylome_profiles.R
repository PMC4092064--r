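# Genome-wide methylome analyses: region histograms, TSS meta-profiles,
# TSS CpG content classification, single-nucleotide histograms.

#' Mean methylation per region
#'
#' Unweighted mean of per-site methylation percentages over the sites inside
#' each region. Regions without any passing site are flagged `no_data`
#' (mean NA), not zero.
#'
#' @param calls Coverage-filtered call table (or `cpg_calls`).
#' @param regions data.table with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `region_id`.
#' @return data.table (`region_id`, `contig`, `start`, `end`, `mean_percent`,
#'   `n_sites`, `no_data`).
#' @export
region_mean_methylation <- function(calls, regions) {
  if (!all(c("contig", "start", "end") %in% names(regions)) ||
      any(regions$end < regions$start))
    stop("malformed regions", call. = FALSE)
  reg <- copy(as.data.table(regions))
  if (!"region_id" %in% names(reg))
    reg[, region_id := sprintf("region_%05d", .I)]
  pct <- methylation_percent(calls)
  reg[, `:=`(mean_percent = NA_real_, n_sites = 0L)]
  for (k in seq_len(nrow(reg))) {
    s <- pct[contig == reg$contig[k] & pos >= reg$start[k] & pos < reg$end[k]]
    if (nrow(s)) reg[k, `:=`(mean_percent = mean(s$percent), n_sites = nrow(s))]
  }
  reg[, no_data := n_sites == 0L]
  reg[]
}

#' Intergenic complement of the gene annotation
#'
#' Per-contig complement of the gene spans; pieces shorter than `min_width`
#' are dropped.
#'
#' @param genes Gene table (`contig`, `start`, `end`), non-overlapping.
#' @param genome `rrbs_genome` or named vector of contig lengths.
#' @param min_width Minimum retained piece width (default 1000 bp).
#' @return data.table (`contig`, `start`, `end`).
#' @export
intergenic_regions <- function(genes, genome, min_width = 1000L) {
  lens <- if (inherits(genome, "rrbs_genome")) nchar(genome$contigs) else genome
  out <- rbindlist(lapply(names(lens), function(cn) {
    g <- genes[genes$contig == cn]
    g <- g[order(g$start)]
    bounds_start <- c(0L, g$end)
    bounds_end <- c(g$start, as.integer(lens[[cn]]))
    data.table(contig = cn, start = bounds_start, end = bounds_end)
  }))
  out <- out[end - start >= min_width]
  out[]
}

#' TSS meta-profile with a sliding window
#'
#' Averages methylation in gene-oriented windows at fixed offsets from the
#' TSS: window `w` covers `[TSS + o_w, TSS + o_w + window)` with offsets
#' `o_w = -flank, -flank + step, ..., flank - window` (221 windows at the
#' defaults). Minus-strand genes are mirrored so that negative offsets are
#' biologically upstream. Each gene contributes the mean percentage of its
#' covered sites in the window; the profile value is the mean over
#' contributing genes (genes weighted equally). Genes whose TSS lies closer
#' than `flank` to a contig edge are skipped.
#'
#' @param calls Coverage-filtered call table (or `cpg_calls`).
#' @param genes Gene table with `contig`, `strand`, `tss`.
#' @param genome Optional `rrbs_genome`/named contig lengths for the edge
#'   check; if NULL, no genes are edge-skipped.
#' @param flank Flank size in bp (default 6000).
#' @param window Window size in bp (default 1000).
#' @param step Step size in bp (default 50).
#' @return data.table (`offset`, `mean_meth`, `n_genes`), one row per window.
#' @export
tss_meta_profile <- function(calls, genes, genome = NULL, flank = 6000L,
                             window = 1000L, step = 50L) {
  if (window > 2L * flank) stop("window must be <= 2 * flank", call. = FALSE)
  offsets <- seq(-flank, flank - window, by = step)
  g <- as.data.table(genes)
  if (!is.null(genome)) {
    lens <- if (inherits(genome, "rrbs_genome")) nchar(genome$contigs) else genome
    edge <- g$tss < flank | g$tss + flank > lens[g$contig]
    if (any(edge)) {
      message(sum(edge), " gene(s) skipped: TSS within ", flank,
              " bp of a contig edge")
      g <- g[!edge]
    }
  }
  empty <- data.table(offset = as.integer(offsets), mean_meth = NA_real_,
                      n_genes = 0L)
  if (nrow(g) == 0L) return(empty)
  pct <- methylation_percent(calls)
  # per gene, sites within the flank, in gene-oriented relative coordinates
  site_rel <- rbindlist(lapply(seq_len(nrow(g)), function(i) {
    s <- pct[contig == g$contig[i] & pos >= g$tss[i] - flank &
               pos < g$tss[i] + flank]
    if (!nrow(s)) return(NULL)
    r <- if (g$strand[i] == "-") g$tss[i] - s$pos else s$pos - g$tss[i]
    data.table(gene = i, r = r, percent = s$percent)
  }))
  if (is.null(site_rel) || nrow(site_rel) == 0L) return(empty)
  # expand each site into the windows containing it: o <= r <= o + window - 1
  o_min <- pmax(-flank, step * ceiling((site_rel$r - window + 1L) / step))
  o_max <- pmin(flank - window, step * floor(site_rel$r / step))
  n_win <- pmax(0L, (o_max - o_min) %/% step + 1L)
  keep <- n_win > 0L
  sr <- site_rel[keep]
  ex <- sr[rep(seq_len(nrow(sr)), n_win[keep])]
  ex[, offset := rep(o_min[keep], n_win[keep]) +
       (sequence(n_win[keep]) - 1L) * step]
  per_gene <- ex[, .(gmean = mean(percent)), by = .(gene, offset)]
  prof <- per_gene[, .(mean_meth = mean(gmean), n_genes = .N), by = offset]
  out <- merge(empty[, .(offset)], prof, by = "offset", all.x = TRUE)
  out[is.na(n_genes), n_genes := 0L]
  setorder(out, offset)
  out[]
}

#' CpG content around each TSS and high/low classification
#'
#' Counts CG-dinucleotide starts in `[TSS - half, TSS + half)` on forward
#' coordinates regardless of gene strand (a documented, deterministic
#' convention), expresses it as a percentage of the window length, and
#' classifies genes as high CpG content when the percentage exceeds
#' `threshold` (default 3.7).
#'
#' @param genome An `rrbs_genome`.
#' @param genes Gene table with `gene_id`, `contig`, `tss`.
#' @param half Window half-width in bp (default 500).
#' @param threshold Percent threshold for the high class (default 3.7).
#' @return data.table (`gene_id`, `cpg_count`, `cpg_percent`, `class`
#'   in "high"/"low"). Genes whose window leaves the contig are skipped.
#' @export
tss_cpg_content <- function(genome, genes, half = 500L, threshold = 3.7) {
  lens <- nchar(genome$contigs)
  g <- as.data.table(genes)
  oob <- g$tss - half < 0L | g$tss + half > lens[g$contig]
  if (any(oob)) {
    message(sum(oob), " gene(s) skipped: TSS window out of contig bounds")
    g <- g[!oob]
  }
  win <- substring(genome$contigs[g$contig], g$tss - half + 1L, g$tss + half)
  cnt <- vapply(win, function(s) {
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
  out <- data.table(gene_id = g$gene_id, cpg_count = cnt,
                    cpg_percent = 100 * cnt / (2 * half))
  out[, class := ifelse(cpg_percent > threshold, "high", "low")]
  out[]
}

#' Histogram of values in fixed-width percentage bins
#'
#' Bins of width `bin` over [0, 100]; the top bin is closed (`[90, 100]` at
#' the default width).
#'
#' @param values Numeric percentages in [0, 100]; NAs dropped.
#' @param bin Bin width (default 10).
#' @return data.table (`bin_low`, `bin_high`, `count`).
#' @export
methylation_histogram <- function(values, bin = 10) {
  values <- values[!is.na(values)]
  lows <- seq(0, 100 - bin, by = bin)
  idx <- pmin(floor(values / bin), length(lows) - 1)  # top bin closed
  counts <- tabulate(idx + 1L, nbins = length(lows))
  data.table(bin_low = lows, bin_high = lows + bin, count = counts)
}

#' Single-nucleotide methylation histogram
#'
#' Histogram of per-site methylation percentages over sites passing the
#' coverage threshold.
#'
#' @param calls Call table or `cpg_calls`.
#' @param min_cov Coverage threshold (default 10).
#' @param bin Bin width in percentage points (default 10).
#' @return data.table (`bin_low`, `bin_high`, `count`).
#' @export
single_site_histogram <- function(calls, min_cov = 10L, bin = 10) {
  pct <- methylation_percent(filter_by_coverage(calls, min_cov))
  methylation_histogram(pct$percent, bin)
}
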