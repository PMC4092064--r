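# Per-CpG methylation counts, bisulfite-conversion QC, replicate concordance.

# Cache of per-contig base classification used by extract_calls.
.genome_base_info <- function(genome) {
  lapply(genome$contigs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(b)
    nxt <- c(b[-1L], "")
    prv <- c("", b[-n])
    list(base = b,
         cpg_c = b == "C" & nxt == "G",
         cpg_g = b == "G" & prv == "C")
  })
}

#' Extract per-CpG methylation calls and conversion QC from alignments
#'
#' For every aligned base over a genomic CpG, top-strand evidence (read C =>
#' methylated, T => unmethylated, at the C position) and bottom-strand
#' evidence (G => methylated, A => unmethylated, at the G position) are pooled
#' into a single site keyed by the forward-strand C. Where mates overlap, the
#' overlapping positions are counted once (read 1 wins). Aligned bases over
#' non-CpG genomic cytosines feed the conversion QC by the same rule.
#'
#' @param alignments Output of [align_pairs()] (only `status == "accepted"`
#'   rows are used).
#' @param reads Trimmed pair table carrying `read_id`, `read1_seq`,
#'   `read2_seq` (e.g. the input to [align_pairs()]).
#' @param genome The `rrbs_genome` the reads were aligned to.
#' @return List of class `cpg_calls`: `calls` (data.table `contig`, `pos`
#'   (0-based forward C), `meth`, `unmeth`) and `qc` (list with
#'   `non_cpg_total`, `non_cpg_unconverted`, `non_cpg_methylation_percent`).
#' @export
extract_calls <- function(alignments, reads, genome) {
  acc <- alignments[alignments$status == "accepted"]
  aln <- merge(acc, reads[, .(read_id, read1_seq, read2_seq)], by = "read_id",
               sort = FALSE)
  lens <- nchar(genome$contigs)
  if (nrow(aln) && any(aln$start < 0L | aln$end > lens[aln$contig]))
    stop("alignment beyond contig bounds: corrupt input", call. = FALSE)
  info <- .genome_base_info(genome)
  if (nrow(aln) == 0L) {
    return(structure(list(
      calls = data.table(contig = character(0), pos = integer(0),
                         meth = integer(0), unmeth = integer(0)),
      qc = list(non_cpg_total = 0L, non_cpg_unconverted = 0L,
                non_cpg_methylation_percent = NA_real_)), class = "cpg_calls"))
  }
  top <- aln$strand == "top"
  l1 <- nchar(aln$read1_seq)
  l2 <- nchar(aln$read2_seq)
  # forward-oriented mate sequences and the forward interval each covers
  m1_fwd <- ifelse(top, aln$read1_seq, revcomp(aln$read1_seq))
  m2_fwd <- ifelse(top, revcomp(aln$read2_seq), aln$read2_seq)
  m1_start <- ifelse(top, aln$start, aln$end - l1)
  m2_start <- ifelse(top, aln$end - l2, aln$start)
  # mate-overlap deduplication: drop mate-2 bases inside mate 1's interval
  build <- function(seqs, starts, lens_r, mate) {
    chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    pair <- rep(seq_len(nrow(aln)), lens_r)
    offs <- rep(starts, lens_r)
    j <- sequence(lens_r) - 1L
    data.table(pair = pair, contig = aln$contig[pair],
               pos = offs + j, base = chars,
               top = top[pair], mate = mate)
  }
  ev <- rbind(build(m1_fwd, m1_start, l1, 1L),
              build(m2_fwd, m2_start, l2, 2L))
  ev <- ev[!(mate == 2L & pos >= m1_start[pair] & pos < m1_start[pair] + l1[pair])]
  # classify against the genome, per contig
  gbase <- character(nrow(ev)); cpgc <- logical(nrow(ev)); cpgg <- logical(nrow(ev))
  for (cn in unique(ev$contig)) {
    w <- which(ev$contig == cn)
    p1 <- ev$pos[w] + 1L
    gbase[w] <- info[[cn]]$base[p1]
    cpgc[w] <- info[[cn]]$cpg_c[p1]
    cpgg[w] <- info[[cn]]$cpg_g[p1]
  }
  ev[, `:=`(gbase = gbase, cpg_c = cpgc, cpg_g = cpgg)]
  # top-strand evidence lives at genomic C positions; bottom at G positions
  top_ev <- ev[top == TRUE & gbase == "C" & base %in% c("C", "T")]
  bot_ev <- ev[top == FALSE & gbase == "G" & base %in% c("G", "A")]
  cpg <- rbind(
    top_ev[cpg_c == TRUE, .(contig, site = pos, meth = base == "C")],
    bot_ev[cpg_g == TRUE, .(contig, site = pos - 1L, meth = base == "G")])
  calls <- cpg[, .(meth = sum(meth), unmeth = sum(!meth)),
               by = .(contig, pos = site)]
  setorder(calls, contig, pos)
  non_cpg <- rbind(
    top_ev[cpg_c == FALSE, .(unconv = base == "C")],
    bot_ev[cpg_g == FALSE, .(unconv = base == "G")])
  total <- nrow(non_cpg)
  unconv <- sum(non_cpg$unconv)
  structure(list(
    calls = calls,
    qc = list(non_cpg_total = total, non_cpg_unconverted = unconv,
              non_cpg_methylation_percent =
                if (total > 0L) 100 * unconv / total else NA_real_)),
    class = "cpg_calls")
}

#' @export
print.cpg_calls <- function(x, ...) {
  cat(sprintf("cpg_calls: %d site(s); non-CpG methylation %.3f%% (%d/%d)\n",
              nrow(x$calls),
              x$qc$non_cpg_methylation_percent,
              x$qc$non_cpg_unconverted, x$qc$non_cpg_total))
  invisible(x)
}

#' Per-site methylation percentages
#'
#' @param calls A call table (data.table with `meth`, `unmeth`) or a
#'   `cpg_calls` object.
#' @return data.table with an added `percent` column (100 * meth / coverage).
#' @export
methylation_percent <- function(calls) {
  dt <- if (inherits(calls, "cpg_calls")) copy(calls$calls) else copy(calls)
  dt[, percent := 100 * meth / (meth + unmeth)]
  dt[]
}

#' Coverage filter on a CpG call table
#'
#' Keeps sites with `meth + unmeth >= min_cov`. The default of 10 matches the
#' usual single-nucleotide threshold; 100 is used for high-stringency
#' replicate comparisons.
#'
#' @param calls Call table or `cpg_calls`.
#' @param min_cov Minimum coverage (default 10; must be >= 1).
#' @return Filtered call data.table.
#' @export
filter_by_coverage <- function(calls, min_cov = 10L) {
  if (min_cov < 1L) stop("min_cov must be >= 1", call. = FALSE)
  dt <- if (inherits(calls, "cpg_calls")) calls$calls else calls
  dt[dt$meth + dt$unmeth >= min_cov]
}

#' Pearson correlation of two replicates' methylation percentages
#'
#' Correlates per-site percentages over the sites passing `min_cov` in both
#' tables.
#'
#' @param table_a,table_b Call tables (or `cpg_calls`).
#' @param min_cov Coverage threshold applied to both tables.
#' @return List: `r` (Pearson correlation, NA when degenerate), `n_sites`,
#'   and `flag` (`"zero_variance"` when either percent vector is constant,
#'   otherwise NA).
#' @export
replicate_correlation <- function(table_a, table_b, min_cov = 10L) {
  a <- methylation_percent(filter_by_coverage(table_a, min_cov))
  b <- methylation_percent(filter_by_coverage(table_b, min_cov))
  shared <- merge(a[, .(contig, pos, pa = percent)],
                  b[, .(contig, pos, pb = percent)], by = c("contig", "pos"))
  if (nrow(shared) < 3L) stop("insufficient_sites", call. = FALSE)
  if (sd(shared$pa) == 0 || sd(shared$pb) == 0)
    return(list(r = NA_real_, n_sites = nrow(shared), flag = "zero_variance"))
  list(r = cor(shared$pa, shared$pb), n_sites = nrow(shared), flag = NA_character_)
}

#' Write a cytosine-report-style TSV
#'
#' Columns: contig, 1-based position of the forward-strand C, strand `+`,
#' methylated count, unmethylated count, context `CpG`. This is the only
#' 1-based file the package writes, matching the de-facto cytosine-report
#' dialect.
#'
#' @param calls Call table or `cpg_calls`.
#' @param path Output path.
#' @export
write_cytosine_report <- function(calls, path) {
  dt <- if (inherits(calls, "cpg_calls")) calls$calls else calls
  out <- data.table(contig = dt$contig, position = dt$pos + 1L, strand = "+",
                    meth = dt$meth, unmeth = dt$unmeth, context = "CpG")
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a cytosine-report-style TSV back into a call table
#'
#' @param path File written by [write_cytosine_report()].
#' @return data.table (`contig`, `pos` 0-based, `meth`, `unmeth`).
#' @export
read_cytosine_report <- function(path) {
  dt <- fread(path, sep = "\t",
              col.names = c("contig", "position", "strand", "meth", "unmeth",
                            "context"))
  data.table(contig = dt$contig, pos = dt$position - 1L,
             meth = dt$meth, unmeth = dt$unmeth)
}
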