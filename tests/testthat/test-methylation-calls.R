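# Hand-built alignment scenarios: a 20 bp contig with one CpG at pos 4.
#          0123456789
hand_world <- function() {
  contig <- "AATTCGATTACCATTAGGAT"   # CpG: C at 4, G at 5; non-CpG Cs at 10,11
  as_genome(c(chr = contig))
}

hand_tables <- function(n_top_meth, n_top_unmeth, read1_len = 10, insert = 20) {
  n <- n_top_meth + n_top_unmeth
  base_at_cpg <- c(rep("C", n_top_meth), rep("T", n_top_unmeth))
  # top-strand read 1 covering [0, 10): genomic AATTCGATTA with C4 as C or T
  r1 <- vapply(base_at_cpg, function(b)
    paste0("AATT", b, "GATTA"), character(1))
  # read 2 (already trimmed) covers [10, 20): revcomp of converted CCATTAGGAT
  r2 <- rep("ATCCTAATAA", n)
  reads <- data.table(read_id = sprintf("r%02d", seq_len(n)),
                      read1_seq = r1, read2_seq = r2)
  aln <- data.table(read_id = reads$read_id, status = "accepted",
                    reason = NA_character_, contig = "chr", start = 0L,
                    end = 20L, strand = "top", mm1 = 0L, mm2 = 0L,
                    insert = 20L)
  list(reads = reads, aln = aln)
}

test_that("per-site counts and percentages follow the evidence rule", {
  w <- hand_world()
  h <- hand_tables(10, 0)
  calls <- extract_calls(h$aln, h$reads, w)
  expect_identical(calls$calls[, .(contig, pos, meth, unmeth)],
                   data.table(contig = "chr", pos = 4L, meth = 10L, unmeth = 0L))
  expect_identical(methylation_percent(calls)$percent, 100)
  h2 <- hand_tables(7, 3)
  calls2 <- extract_calls(h2$aln, h2$reads, w)
  expect_identical(methylation_percent(calls2)$percent, 70)
})

test_that("bottom-strand evidence pools into the forward-strand site", {
  w <- hand_world()
  # bottom molecule covering [0,20): at the CpG's G (pos 5) the
  # forward-oriented base is G (methylated) or A (unmethylated).
  # bottom read 1 covers the 3' end [10,20) in forward space; its raw
  # sequence is the revcomp of the forward image
  raw_r1 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTATTAGGAT")))
  # bottom read2 (trimmed) covers [0,10) forward-oriented; CpG G at 5 as G
  r2_meth <- "AATTCGATTA"
  r2_unmeth <- "AATTCAATTA"
  reads <- data.table(read_id = c("b1", "b2"),
                      read1_seq = c(raw_r1, raw_r1),
                      read2_seq = c(r2_meth, r2_unmeth))
  aln <- data.table(read_id = c("b1", "b2"), status = "accepted",
                    reason = NA_character_, contig = "chr", start = 0L,
                    end = 20L, strand = "bottom", mm1 = 0L, mm2 = 0L,
                    insert = 20L)
  calls <- extract_calls(aln, reads, w)
  row <- calls$calls[pos == 4L]
  expect_identical(row$meth, 1L)
  expect_identical(row$unmeth, 1L)
})

test_that("overlapping mates are counted once with read 1 winning", {
  w <- hand_world()
  # mates overlap across [5, 15): read1 covers [0,15), read2 covers [5,20)
  r1 <- "AATTCGATTATTAT"              # 14 bp, covers [0,14)
  r1 <- paste0(r1, "T")               # 15 bp
  r2_fwd <- "GATTATTATTAGGAT"         # forward image of [5,20), converted
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2_fwd)))
  reads <- data.table(read_id = "o1", read1_seq = r1, read2_seq = r2)
  aln <- data.table(read_id = "o1", status = "accepted", reason = NA_character_,
                    contig = "chr", start = 0L, end = 20L, strand = "top",
                    mm1 = 0L, mm2 = 0L, insert = 20L)
  calls <- extract_calls(aln, reads, w)
  # the CpG at 4 is covered by both mates; counted once (read 1: C => meth)
  expect_identical(calls$calls[pos == 4L, meth + unmeth], 1L)
  # non-CpG Cs at 10,11 are inside read 1's span: counted once each
  expect_identical(calls$qc$non_cpg_total, 2L)
})

test_that("conversion QC sees unconverted non-CpG cytosines", {
  w <- hand_world()
  # read1 over [0,10) with the non-CpG C at... none in [0,10) except CpG C.
  # use read2 span [10,20): forward CCATTAGGAT; leave one C unconverted
  r2_fwd_conv <- "TTATTAGGAT"    # both Cs converted
  r2_fwd_unconv <- "CTATTAGGAT"  # C at 10 unconverted
  mk <- function(fwd, id) {
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    list(reads = data.table(read_id = id, read1_seq = "AATTTGATTA",
                            read2_seq = r2),
         aln = data.table(read_id = id, status = "accepted",
                          reason = NA_character_, contig = "chr", start = 0L,
                          end = 20L, strand = "top", mm1 = 0L, mm2 = 0L,
                          insert = 20L))
  }
  a <- mk(r2_fwd_conv, "x1"); b <- mk(r2_fwd_unconv, "x2")
  calls <- extract_calls(rbind(a$aln, b$aln), rbind(a$reads, b$reads), w)
  expect_identical(calls$qc$non_cpg_total, 4L)
  expect_identical(calls$qc$non_cpg_unconverted, 1L)
  expect_equal(calls$qc$non_cpg_methylation_percent, 25)
})

test_that("simulated conversion QC sits near 1 - efficiency and below 1%", {
  w <- small_world(seed = 127, n_genes = 5, contig_length = 120000)
  truth0 <- uniform_truth(w$genome, 0)
  params <- library_params(conversion_efficiency = 0.995, seq_error = 0,
                           mean_depth = 60, seed = 19)
  pr <- run_rrbs_pipeline(w$genome, truth0, params)
  qc <- pr$calls$qc
  expect_gt(qc$non_cpg_total, 10000)
  p_hat <- qc$non_cpg_methylation_percent / 100
  expect_lt(abs(p_hat - 0.005), 3 * sqrt(0.005 * 0.995 / qc$non_cpg_total))
  expect_lt(qc$non_cpg_methylation_percent, 1)
})

test_that("coverage filtering is an inclusive, monotone brute-force filter", {
  t1 <- data.table(contig = "c", pos = 1:2 * 10L, meth = c(5L, 5L),
                   unmeth = c(4L, 5L))
  expect_identical(filter_by_coverage(t1, 10)$pos, 20L)
  expect_error(filter_by_coverage(t1, 0), "min_cov")
  set.seed(131)
  tbl <- data.table(contig = "c", pos = seq_len(500),
                    meth = rpois(500, 8L), unmeth = rpois(500, 8L))
  for (mc in c(1, 10, 25)) {
    expect_identical(filter_by_coverage(tbl, mc),
                     tbl[tbl$meth + tbl$unmeth >= mc])
  }
  n_rows <- vapply(c(1, 5, 10, 20, 50),
                   function(mc) nrow(filter_by_coverage(tbl, mc)), numeric(1))
  expect_true(all(diff(n_rows) <= 0))
})

test_that("counts conservation: evidence equals deduplicated CpG base coverage", {
  w <- small_world(seed = 137, n_genes = 3, contig_length = 80000)
  params <- library_params(seq_error = 0, mean_depth = 10, seed = 23)
  pr <- run_rrbs_pipeline(w$genome, w$truth, params)
  total_evidence <- pr$calls$calls[, sum(meth + unmeth)]
  # independent audit: per accepted pair, count genomic CpG positions covered
  # (C positions for top molecules, G positions for bottom), mate overlap
  # counted once
  acc <- merge(pr$alignments[status == "accepted"],
               pr$trimmed[, .(read_id, read1_seq, read2_seq)], by = "read_id")
  contig_chars <- strsplit(w$genome$contigs[[1]], "")[[1]]
  audit <- 0L
  for (i in seq_len(nrow(acc))) {
    l1 <- nchar(acc$read1_seq[i]); l2 <- nchar(acc$read2_seq[i])
    if (acc$strand[i] == "top") {
      cov1 <- acc$start[i]:(acc$start[i] + l1 - 1L)
      cov2 <- (acc$end[i] - l2):(acc$end[i] - 1L)
    } else {
      cov1 <- (acc$end[i] - l1):(acc$end[i] - 1L)
      cov2 <- acc$start[i]:(acc$start[i] + l2 - 1L)
    }
    cov <- union(cov1, cov2)
    if (acc$strand[i] == "top") {
      hits <- cov[contig_chars[cov + 1L] == "C" &
                    contig_chars[cov + 2L] == "G"]
    } else {
      hits <- cov[contig_chars[cov + 1L] == "G" &
                    c("", contig_chars)[cov + 1L] == "C"]
    }
    audit <- audit + length(hits)
  }
  expect_identical(total_evidence, audit)
})

test_that("replicate correlation handles identity, anti-correlation and degeneracy", {
  mk <- function(pcts, cov = 20L) data.table(contig = "c",
                                             pos = seq_along(pcts) * 10L,
                                             meth = as.integer(round(cov * pcts / 100)),
                                             unmeth = cov - as.integer(round(cov * pcts / 100)))
  a <- mk(c(0, 50, 100))
  expect_equal(replicate_correlation(a, a, 10)$r, 1.0)
  b <- mk(c(100, 50, 0))
  expect_equal(replicate_correlation(a, b, 10)$r, -1.0)
  expect_error(replicate_correlation(mk(c(0, 100)), mk(c(0, 100)), 10),
               "insufficient_sites")
  const <- mk(c(50, 50, 50))
  expect_identical(replicate_correlation(const, const, 10)$flag, "zero_variance")
})

test_that("cytosine report round-trips through its 1-based dialect", {
  tbl <- data.table(contig = c("c1", "c2"), pos = c(0L, 99L),
                    meth = c(3L, 7L), unmeth = c(7L, 3L))
  f <- tempfile(fileext = ".tsv")
  write_cytosine_report(tbl, f)
  raw <- fread(f, header = FALSE)
  expect_identical(raw$V2, c(1L, 100L))   # 1-based in the file only
  expect_identical(raw$V3, c("+", "+"))
  expect_identical(raw$V6, c("CpG", "CpG"))
  back <- read_cytosine_report(f)
  expect_identical(back, tbl)
})
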