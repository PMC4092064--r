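# In-silico MspI reduced representation and directional bisulfite read pairs.

#' Library simulation parameters
#'
#' @param insert_min,insert_max Size-selection bounds in bp (inclusive;
#'   defaults 150 and 250).
#' @param read_len Read length in bp (default 100).
#' @param conversion_efficiency Probability an unmethylated C is converted to
#'   T by bisulfite treatment (default 0.995).
#' @param meth_protection Probability a methylated C escapes conversion
#'   (default 1.0: no inappropriate conversion).
#' @param seq_error Per-base substitution error probability (default 0.001).
#' @param mean_depth Mean number of molecules (read pairs) sampled per
#'   retained fragment, Poisson distributed.
#' @param seed Integer seed.
#' @return Object of class `library_params`.
#' @export
library_params <- function(insert_min = 150L, insert_max = 250L,
                           read_len = 100L, conversion_efficiency = 0.995,
                           meth_protection = 1.0, seq_error = 0.001,
                           mean_depth = 30, seed = 1L) {
  stopifnot_scalar_prob(conversion_efficiency, "conversion_efficiency")
  stopifnot_scalar_prob(meth_protection, "meth_protection")
  stopifnot_scalar_prob(seq_error, "seq_error")
  if (insert_min > insert_max) stop("insert_min must be <= insert_max", call. = FALSE)
  if (read_len > insert_min) stop("read_len must be <= insert_min", call. = FALSE)
  structure(list(insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 read_len = as.integer(read_len),
                 conversion_efficiency = conversion_efficiency,
                 meth_protection = meth_protection,
                 seq_error = seq_error,
                 mean_depth = mean_depth,
                 seed = as.integer(seed)), class = "library_params")
}

#' MspI digestion of one sequence
#'
#' MspI cuts C^CGG: each CCGG occurrence at 0-based position `i` produces a
#' cut at offset `i + 1`. Fragments are the intervals between successive cuts
#' plus the two contig-end pieces; they tile the contig exactly.
#'
#' @param seq A single A/C/G/T string.
#' @param contig Optional contig name carried into the output.
#' @return data.table (`contig`, `start`, `end`, `length`), 0-based half-open.
#' @export
digest_mspi <- function(seq, contig = "contig_1") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGT]", seq)) stop("sequence must be over A/C/G/T", call. = FALSE)
  L <- nchar(seq)
  # CCGG cannot overlap itself, so fixed-string search finds every occurrence
  m <- gregexpr("CCGG", seq, fixed = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer(0) else as.integer(m)  # 1-based start == 0-based start+1
  bounds <- c(0L, cuts, L)
  dt <- data.table(contig = contig,
                   start = bounds[-length(bounds)],
                   end = bounds[-1])
  dt <- dt[end > start]
  dt[, length := end - start]
  dt[]
}

#' MspI digestion of a whole genome
#'
#' @param genome An `rrbs_genome` (or named character vector of sequences).
#' @return data.table of fragments over all contigs.
#' @export
digest_genome <- function(genome) {
  contigs <- if (inherits(genome, "rrbs_genome")) genome$contigs else genome
  rbindlist(lapply(names(contigs), function(cn) digest_mspi(contigs[[cn]], cn)))
}

#' Size selection of digestion fragments
#'
#' Keeps exactly the fragments whose length lies in
#' `[insert_min, insert_max]` (inclusive on both ends).
#'
#' @param fragments Fragment data.table from [digest_mspi()].
#' @param insert_min,insert_max Inclusive bounds in bp.
#' @return Filtered fragment data.table.
#' @export
size_select <- function(fragments, insert_min = 150L, insert_max = 250L) {
  stopifnot(all(c("start", "end") %in% names(fragments)))
  len <- fragments$end - fragments$start
  fragments[len >= insert_min & len <= insert_max]
}

# Dense per-genome methylation lookup: numeric vector over concatenated
# contigs, NA at non-CpG positions, indexed by global 0-based position + 1.
.truth_vector <- function(genome, truth) {
  lens <- nchar(genome$contigs)
  off <- contig_offsets(lens)
  v <- rep(NA_real_, sum(lens))
  s <- truth$sites
  v[off[s$contig] + s$pos + 1] <- s$m
  list(v = v, off = off)
}

#' Simulate directional bisulfite read pairs from retained fragments
#'
#' Per fragment, `Poisson(mean_depth)` molecules are drawn; each molecule
#' originates from the top or bottom original strand with probability 1/2.
#' MspI leaves 5'-CG overhangs, so the two strands of a fragment `[p, e)` are
#' staggered: the top-strand molecule covers `[p, e)` and the bottom-strand
#' molecule `[p + 2, e + 2)` (both begin 5'-CGG). Each molecule carries two
#' filled-in bases (an always-unmethylated C, then G) at its 3' end, which
#' appear as the two artifact bases at the start of read 2. Read 1 reads the
#' bisulfite-converted molecule 5'->3'; read 2 its complement from the other
#' end. Per-molecule CpG methylation states are drawn Bernoulli(m) from the
#' truth and shared between mates; every non-CpG C is treated as
#' unmethylated. Substitution errors are applied at `seq_error` per base.
#' Base qualities follow a two-level model (Q38 with an occasional low tail).
#'
#' @param genome An `rrbs_genome`.
#' @param fragments Retained fragments (after [size_select()]).
#' @param truth A `methylome_truth`.
#' @param params A [library_params()].
#' @return data.table with one row per pair: `read_id`, `read1_seq`,
#'   `read1_qual`, `read2_seq`, `read2_qual`, and the truth tag columns
#'   `contig`, `frag_start`, `frag_end` (the interval the molecule covers:
#'   the MspI fragment for top-strand molecules, offset +2 for bottom-strand
#'   ones), `origin_strand` ("top"/"bottom").
#' @export
simulate_read_pairs <- function(genome, fragments, truth, params) {
  stopifnot(inherits(genome, "rrbs_genome"), inherits(params, "library_params"))
  if (nrow(fragments) == 0L) {
    warning("empty fragment list: no reads simulated")
    return(data.table(read_id = character(0), read1_seq = character(0),
                      read1_qual = character(0), read2_seq = character(0),
                      read2_qual = character(0), contig = character(0),
                      frag_start = integer(0), frag_end = integer(0),
                      origin_strand = character(0)))
  }
  if (any(fragments$end - fragments$start < params$read_len))
    stop("all fragments must be at least read_len long (size-select first)",
         call. = FALSE)
  with_seed(params$seed, {
    tv <- .truth_vector(genome, truth)
    rl <- params$read_len
    n_mol <- rpois(nrow(fragments), params$mean_depth)
    mol <- fragments[rep(seq_len(nrow(fragments)), n_mol)]
    if (nrow(mol) == 0L) {
      warning("mean_depth drew zero molecules")
      return(simulate_read_pairs(genome, fragments[0], truth, params))
    }
    mol[, origin_strand := sample(c("top", "bottom"), .N, replace = TRUE)]
    # sticky-end stagger: bottom-strand molecules cover [start+2, end+2),
    # clamped back to the blunt interval at a contig's right edge
    clen <- nchar(genome$contigs)[mol$contig]
    shift <- ifelse(mol$origin_strand == "bottom" & mol$end + 2L <= clen, 2L, 0L)
    mol[, `:=`(start = start + shift, end = end + shift)]
    core_seq <- substring(genome$contigs[mol$contig], mol$start + 1L, mol$end)
    mol_seq <- ifelse(mol$origin_strand == "top", core_seq, revcomp(core_seq))
    lens <- mol$end - mol$start
    chars <- unlist(strsplit(mol_seq, "", fixed = TRUE), use.names = FALSE)
    N <- length(chars)
    mol_id <- rep(seq_len(nrow(mol)), lens)
    ends <- cumsum(lens)            # last index of each molecule
    offs <- ends - lens             # 0-based offset of each molecule's chars
    j0 <- seq_len(N) - 1L - offs[mol_id]  # 0-based within-molecule index
    # strand-local CpG context: C followed by G inside the same molecule
    nxt <- c(chars[-1L], "")
    nxt[ends] <- ""
    is_c <- chars == "C"
    is_cpg_c <- is_c & nxt == "G"
    # forward-strand genomic position of each base
    top_mol <- mol$origin_strand[mol_id] == "top"
    gpos <- mol$start[mol_id] + j0
    bot <- which(!top_mol)
    gpos[bot] <- mol$end[mol_id[bot]] - 1L - j0[bot]
    # CpG key: forward C position (bottom-strand C sits on the forward G)
    key <- gpos
    key[bot] <- key[bot] - 1L
    gidx <- tv$off[mol$contig[mol_id]] + key + 1
    m <- rep(NA_real_, N)
    m[is_cpg_c] <- tv$v[gidx[is_cpg_c]]
    m[is_cpg_c & is.na(m)] <- 0  # CpG without truth entry: treat unmethylated
    u <- runif(N)
    methylated <- is_cpg_c & u < m
    conv <- logical(N)
    # methylated C converts only on protection failure
    conv[methylated] <- runif(sum(methylated)) < (1 - params$meth_protection)
    unmeth_c <- is_c & !methylated
    conv[unmeth_c] <- runif(sum(unmeth_c)) < params$conversion_efficiency
    chars[conv] <- "T"
    # substitution sequencing errors
    if (params$seq_error > 0) {
      err <- which(runif(N) < params$seq_error)
      if (length(err)) {
        alpha <- c("A", "C", "G", "T")
        cur <- match(chars[err], alpha)
        chars[err] <- alpha[((cur - 1L + sample(1:3, length(err), replace = TRUE)) %% 4L) + 1L]
      }
    }
    # read 1: first rl bases of the converted molecule
    idx1 <- outer(offs, seq_len(rl), `+`)
    read1 <- collapse_rows(matrix(chars[idx1], ncol = rl))
    # read 2: fill-in "CA" + reverse complement of the molecule's last rl bases
    idx2 <- outer(ends, rev(seq_len(rl)) - rl, `+`)
    tailmat <- matrix(chars[idx2], ncol = rl)  # already reversed order
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    tailmat[] <- comp[tailmat]
    # artifact prefix: complement of the filled G (always C), then the
    # complement of the filled, unmethylated C (A when converted, G if not)
    fill <- cbind(rep("C", nrow(tailmat)),
                  ifelse(runif(nrow(tailmat)) < params$conversion_efficiency,
                         "A", "G"))
    if (params$seq_error > 0) {
      ferr <- which(runif(length(fill)) < params$seq_error)
      if (length(ferr)) {
        alpha <- c("A", "C", "G", "T")
        cur <- match(fill[ferr], alpha)
        fill[ferr] <- alpha[((cur - 1L + sample(1:3, length(ferr), replace = TRUE)) %% 4L) + 1L]
      }
    }
    read2 <- collapse_rows(cbind(fill, tailmat))
    # two-level quality model: Q38 with occasional low tail values
    qmat1 <- matrix(38L, nrow = nrow(mol), ncol = rl)
    qmat2 <- matrix(38L, nrow = nrow(mol), ncol = rl + 2L)
    low1 <- which(runif(length(qmat1)) < 0.03)
    low2 <- which(runif(length(qmat2)) < 0.03)
    qmat1[low1] <- sample(2:20, length(low1), replace = TRUE)
    qmat2[low2] <- sample(2:20, length(low2), replace = TRUE)
    chartab <- vapply(0:45, function(i) rawToChar(as.raw(i + 33L)), character(1))
    qual1 <- collapse_rows(matrix(chartab[qmat1 + 1L], nrow = nrow(qmat1)))
    qual2 <- collapse_rows(matrix(chartab[qmat2 + 1L], nrow = nrow(qmat2)))
    data.table(read_id = sprintf("pair%06d", seq_len(nrow(mol))),
               read1_seq = read1, read1_qual = qual1,
               read2_seq = read2, read2_qual = qual2,
               contig = mol$contig, frag_start = mol$start,
               frag_end = mol$end, origin_strand = mol$origin_strand)
  })
}

#' Write simulated pairs as a pair of FASTQ files plus a truth-tag TSV
#'
#' @param pairs Output of [simulate_read_pairs()].
#' @param prefix File prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`
#'   and `<prefix>_truth.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  ft <- paste0(prefix, "_truth.tsv")
  writeLines(as.vector(rbind(paste0("@", pairs$read_id, "/1"),
                             pairs$read1_seq, "+", pairs$read1_qual)), f1)
  writeLines(as.vector(rbind(paste0("@", pairs$read_id, "/2"),
                             pairs$read2_seq, "+", pairs$read2_qual)), f2)
  fwrite(pairs[, .(read_id, contig, frag_start, frag_end, origin_strand)],
         ft, sep = "\t")
  invisible(c(f1, f2, ft))
}

#' Read a FASTQ pair written by [write_fastq_pairs()]
#'
#' @param prefix File prefix used at write time.
#' @return data.table (`read_id`, `read1_seq`, `read1_qual`, `read2_seq`,
#'   `read2_qual`).
#' @export
read_fastq_pairs <- function(prefix) {
  rd <- function(f) {
    # conversion to character drops FASTQ metadata columns; that is fine here
    suppressWarnings({
      x <- Biostrings::readQualityScaledDNAStringSet(f)
      data.table(read_id = sub("/[12]$", "", names(x)),
                 seq = as.character(x),
                 qual = as.character(Biostrings::quality(x)))
    })
  }
  r1 <- rd(paste0(prefix, "_1.fastq"))
  r2 <- rd(paste0(prefix, "_2.fastq"))
  setnames(r1, c("seq", "qual"), c("read1_seq", "read1_qual"))
  setnames(r2, c("seq", "qual"), c("read2_seq", "read2_qual"))
  merge(r1, r2, by = "read_id", sort = FALSE)
}
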