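# Read trimming and a small three-letter bisulfite-aware paired-end aligner.
#
# The mapping contract: one exact 50 bp seed from the 5' end of each mate,
# full-read verification in fully converted space (read C->T vs text C->T for
# top-strand placements, G->A for bottom), uniqueness at the pair level, FR
# orientation, insert within [150, 250], at most one mismatch per mate.

#' BWA-style 3' quality trimming
#'
#' Chooses the cut point `x` (keeping bases `[0, x)`) that maximises
#' `S(x) = sum_{i=x..L-1} (threshold - q_i)`, with `S(L) = 0` and ties broken
#' toward keeping more bases. Reads whose tail is consistently below the
#' threshold are cut back to the last high-quality prefix.
#'
#' @param qual Quality: a Phred+33 string or an integer vector of scores.
#' @param threshold Minimum Phred score (default 20).
#' @param seq Optional read sequence, trimmed alongside.
#' @return List with `kept_length`, and `seq`/`qual` trimmed to that prefix
#'   (`qual` returned in the representation it came in).
#' @export
bwa_quality_trim <- function(qual, threshold = 20L, seq = NULL) {
  as_string <- is.character(qual)
  q <- if (as_string) as.integer(charToRaw(qual)) - 33L else as.integer(qual)
  if (length(q) == 0L) stop("qualities must be non-empty", call. = FALSE)
  k <- .bwa_cut(q, threshold)
  out <- list(kept_length = k)
  out$qual <- if (as_string) substr(qual, 1L, k) else q[seq_len(k)]
  if (!is.null(seq)) out$seq <- substr(seq, 1L, k)
  out
}

# cut index k (number of bases kept) for one integer quality vector
.bwa_cut <- function(q, threshold) {
  L <- length(q)
  # S(x) for x = 0..L; S(L) = 0
  s <- c(rev(cumsum(rev(threshold - q))), 0)
  ties <- which(s == max(s))
  max(ties) - 1L  # prefer the largest x (keep more)
}

# Batch quality trim over equal-or-varying-length Phred+33 strings.
.trim_batch <- function(seqs, quals, threshold = 20L) {
  n <- length(quals)
  keep <- integer(n)
  for (i in seq_len(n)) {
    keep[i] <- .bwa_cut(as.integer(charToRaw(quals[i])) - 33L, threshold)
  }
  list(seq = substr(seqs, 1L, keep), qual = substr(quals, 1L, keep),
       kept_length = keep)
}

#' Remove the two read-2 fill-in bases
#'
#' The MspI sticky-end fill-in contributes two uninformative bases at the
#' start of every read 2; they are removed before alignment and calling.
#'
#' @param seq Read-2 sequence(s).
#' @param qual Matching quality string(s).
#' @return List of `seq` and `qual` with the first two characters dropped;
#'   reads shorter than 2 become empty with a warning.
#' @export
trim_read2_fill_in <- function(seq, qual = NULL) {
  short <- nchar(seq) < 2L
  if (any(short)) warning(sum(short), " read(s) shorter than 2 bases discarded")
  out <- list(seq = substr(seq, 3L, nchar(seq)))
  if (!is.null(qual)) out$qual <- substr(qual, 3L, nchar(qual))
  out
}

#' Trim a table of read pairs
#'
#' Applies [trim_read2_fill_in()] to read 2, then [bwa_quality_trim()] to
#' both mates.
#'
#' @param pairs data.table with `read_id`, `read1_seq`, `read1_qual`,
#'   `read2_seq`, `read2_qual` (plus any extra columns, preserved).
#' @param threshold Phred threshold (default 20).
#' @return The table with trimmed sequences/qualities.
#' @export
trim_pairs <- function(pairs, threshold = 20L) {
  out <- copy(pairs)
  r2 <- trim_read2_fill_in(out$read2_seq, out$read2_qual)
  t2 <- .trim_batch(r2$seq, r2$qual, threshold)
  t1 <- .trim_batch(out$read1_seq, out$read1_qual, threshold)
  out[, `:=`(read1_seq = t1$seq, read1_qual = t1$qual,
             read2_seq = t2$seq, read2_qual = t2$qual)]
  out[]
}

#' Build a three-letter bisulfite index
#'
#' Stores the C->T and G->A converted forward text of every contig; seed
#' lookups are exact matches of `seed_len`-mers against these texts.
#'
#' @param genome An `rrbs_genome` (or named character vector of sequences).
#' @param seed_len Seed length in bp (default 50).
#' @return Object of class `bisulfite_index`.
#' @export
build_index <- function(genome, seed_len = 50L) {
  contigs <- if (inherits(genome, "rrbs_genome")) genome$contigs else genome
  short <- nchar(contigs) < seed_len
  if (any(short)) {
    warning("skipping ", sum(short), " contig(s) shorter than seed_len")
    contigs <- contigs[!short]
  }
  structure(list(
    ct = chartr("C", "T", contigs),
    ga = chartr("G", "A", contigs),
    contig_length = nchar(contigs),
    seed_len = as.integer(seed_len)), class = "bisulfite_index")
}

# Exact seed hits: match each unique seed k-mer against one converted text.
# Returns data.table(seed_idx, contig, pos) with pos 0-based.
.seed_hits <- function(seeds, texts) {
  uniq <- unique(seeds)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))
  hits <- rbindlist(lapply(names(texts), function(cn) {
    mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(texts[[cn]]))
    st <- Biostrings::startIndex(mi)
    n_per <- lengths(st)
    if (sum(n_per) == 0L) return(NULL)
    data.table(uniq_idx = rep(seq_along(st), n_per),
               contig = cn, pos = unlist(st) - 1L)
  }))
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.table(seed_idx = integer(0), contig = character(0), pos = integer(0)))
  map <- data.table(seed_idx = seq_along(seeds), uniq_idx = match(seeds, uniq))
  out <- merge(map, hits, by = "uniq_idx", allow.cartesian = TRUE)
  out[, uniq_idx := NULL]
  out[]
}

# count mismatches of converted reads against converted text windows
.window_mm <- function(texts, contig, start0, read_conv) {
  sub <- substring(texts[contig], start0 + 1L, start0 + nchar(read_conv))
  mismatch_count(read_conv, sub)
}

#' Align trimmed read pairs
#'
#' Directional three-letter search: read 1 is looked up in C->T space
#' (top-strand origin) and, reverse-complemented, in G->A space (bottom);
#' read 2 anchors the opposite fragment end in the same space. Candidate
#' fragment placements are scored by total mismatches in converted space over
#' the full reads; a pair is accepted iff exactly one placement attains the
#' minimal score, each mate has at most `max_mismatch` mismatches, the
#' orientation is FR, and the insert lies in `[insert_min, insert_max]`.
#'
#' @param pairs Trimmed pair table (see [trim_pairs()]).
#' @param index A [build_index()] result.
#' @param max_mismatch Maximum mismatches per mate (default 1).
#' @param insert_min,insert_max Accepted insert range in bp.
#' @param max_pairing_distance Maximum distance considered when pairing seed
#'   hits into candidate fragments (default 10000 bp).
#' @return data.table, one row per input pair: `read_id`, `status`
#'   ("accepted"/"rejected"), `reason` (NA or one of `unmapped`, `ambiguous`,
#'   `orientation`, `insert_size`, `too_many_mismatches`, `too_short`),
#'   `contig`, `start`, `end`, `strand` ("top"/"bottom"), `mm1`, `mm2`,
#'   `insert`.
#' @export
align_pairs <- function(pairs, index, max_mismatch = 1L,
                        insert_min = 150L, insert_max = 250L,
                        max_pairing_distance = 10000L) {
  stopifnot(inherits(index, "bisulfite_index"))
  k <- index$seed_len
  n <- nrow(pairs)
  res <- data.table(read_id = pairs$read_id, status = "rejected",
                    reason = NA_character_, contig = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = NA_character_, mm1 = NA_integer_,
                    mm2 = NA_integer_, insert = NA_integer_)
  len1 <- nchar(pairs$read1_seq)
  len2 <- nchar(pairs$read2_seq)
  ok <- len1 >= k & len2 >= k
  res[!ok, reason := "too_short"]
  if (!any(ok)) return(res[])
  idx_ok <- which(ok)
  r1 <- pairs$read1_seq[idx_ok]
  r2 <- pairs$read2_seq[idx_ok]
  l1 <- len1[idx_ok]
  l2 <- len2[idx_ok]
  r1rc <- revcomp(r1)
  r2rc <- revcomp(r2)
  # converted full reads for verification
  r1_ct <- chartr("C", "T", r1)
  r2rc_ct <- chartr("C", "T", r2rc)
  r1rc_ga <- chartr("G", "A", r1rc)
  r2_ga <- chartr("G", "A", r2)

  # --- seed hits --------------------------------------------------------
  # top route: read1 5' seed anchors the fragment start in CT space;
  #            revcomp(read2 5' seed) anchors the fragment end in CT space.
  h_p_top <- .seed_hits(substr(r1_ct, 1L, k), index$ct)
  h_e_top <- .seed_hits(substring(r2rc_ct, l2 - k + 1L, l2), index$ct)
  # bottom route: read2 5' seed anchors the start in GA space;
  #               revcomp(read1 5' seed) anchors the end in GA space.
  h_p_bot <- .seed_hits(substr(r2_ga, 1L, k), index$ga)
  h_e_bot <- .seed_hits(substring(r1rc_ga, l1 - k + 1L, l1), index$ga)

  h_e_top[, end := pos + k]
  h_e_bot[, end := pos + k]

  hit1 <- logical(length(idx_ok))  # read 1 seeded somewhere (either route)
  hit2 <- logical(length(idx_ok))
  hit1[unique(c(h_p_top$seed_idx, h_e_bot$seed_idx))] <- TRUE
  hit2[unique(c(h_e_top$seed_idx, h_p_bot$seed_idx))] <- TRUE
  any_hit <- hit1 & hit2

  # --- candidate placements --------------------------------------------
  cand_top <- merge(h_p_top[, .(seed_idx, contig, p = pos)],
                    h_e_top[, .(seed_idx, contig, e = end)],
                    by = c("seed_idx", "contig"), allow.cartesian = TRUE)
  cand_bot <- merge(h_p_bot[, .(seed_idx, contig, p = pos)],
                    h_e_bot[, .(seed_idx, contig, e = end)],
                    by = c("seed_idx", "contig"), allow.cartesian = TRUE)
  cand_top[, strand := "top"]
  cand_bot[, strand := "bottom"]
  cand <- rbind(cand_top, cand_bot)
  had_pairing <- logical(length(idx_ok))
  had_pairing[unique(cand$seed_idx)] <- TRUE
  # FR geometry: fragment long enough to contain both mates, bounded pairing
  cand <- cand[e - p >= pmax(l1[seed_idx], l2[seed_idx]) &
                 e - p <= max_pairing_distance]
  if (nrow(cand)) {
    # full-read verification in converted space
    top <- cand$strand == "top"
    mm1 <- integer(nrow(cand))
    mm2 <- integer(nrow(cand))
    si <- cand$seed_idx
    mm1[top] <- .window_mm(index$ct, cand$contig[top], cand$p[top],
                           r1_ct[si[top]])
    mm2[top] <- .window_mm(index$ct, cand$contig[top],
                           cand$e[top] - l2[si[top]], r2rc_ct[si[top]])
    mm2[!top] <- .window_mm(index$ga, cand$contig[!top], cand$p[!top],
                            r2_ga[si[!top]])
    mm1[!top] <- .window_mm(index$ga, cand$contig[!top],
                            cand$e[!top] - l1[si[!top]], r1rc_ga[si[!top]])
    cand[, `:=`(mm1 = mm1, mm2 = mm2, score = mm1 + mm2)]
    # keep per-read minimal-score placements, deduplicated
    cand <- unique(cand, by = c("seed_idx", "contig", "p", "e", "strand"))
    best <- cand[, .SD[score == min(score)], by = seed_idx]
    nbest <- best[, .N, by = seed_idx]
    amb <- idx_ok[nbest[N > 1L, seed_idx]]
    if (length(amb)) res[amb, reason := "ambiguous"]
    uniq <- best[best$seed_idx %in% nbest[N == 1L, seed_idx]]
    if (nrow(uniq)) {
      i <- idx_ok[uniq$seed_idx]
      ins <- uniq$e - uniq$p
      rsn <- rep(NA_character_, nrow(uniq))
      rsn[uniq$mm1 > max_mismatch | uniq$mm2 > max_mismatch] <- "too_many_mismatches"
      rsn[is.na(rsn) & (ins < insert_min | ins > insert_max)] <- "insert_size"
      res[i, `:=`(reason = rsn, contig = uniq$contig,
                  start = uniq$p, end = uniq$e, strand = uniq$strand,
                  mm1 = uniq$mm1, mm2 = uniq$mm2, insert = ins)]
      acc <- i[is.na(rsn)]
      if (length(acc)) res[acc, status := "accepted"]
    }
  }
  # both mates seeded but no admissible pairing -> orientation;
  # either mate without any seed hit -> unmapped
  res[idx_ok[!had_pairing & any_hit], reason := "orientation"]
  res[idx_ok[!any_hit], reason := "unmapped"]
  # had pairing but all candidates failed geometry filter
  still <- which(res$status == "rejected" & is.na(res$reason))
  res[still, reason := "orientation"]
  res[]
}

#' Align a single read pair
#'
#' Convenience wrapper around [align_pairs()] for one trimmed pair.
#'
#' @param read1_seq,read2_seq Trimmed mate sequences.
#' @param index A [build_index()] result.
#' @param ... Passed to [align_pairs()].
#' @return One-row alignment data.table.
#' @export
align_pair <- function(read1_seq, read2_seq, index, ...) {
  align_pairs(data.table(read_id = "pair", read1_seq = read1_seq,
                         read2_seq = read2_seq), index, ...)
}
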