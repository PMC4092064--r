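# Independent linear-scan digestion oracle: walk the sequence, cut after the
# C of every CCGG.
digest_oracle <- function(seq) {
  n <- nchar(seq)
  cuts <- integer(0)
  for (i in seq_len(max(0, n - 3))) {
    if (substr(seq, i, i + 3) == "CCGG") cuts <- c(cuts, i)  # 0-based cut == i
  }
  bounds <- unique(c(0L, cuts, n))
  data.table(start = bounds[-length(bounds)], end = bounds[-1])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

test_that("digest_mspi matches its worked examples", {
  expect_identical(digest_mspi("ATATATAT")[, .(start, end)],
                   data.table(start = 0L, end = 8L))
  f <- digest_mspi("ACCGGTTCCGGA")
  expect_identical(f$start, c(0L, 2L, 8L))
  expect_identical(f$end, c(2L, 8L, 12L))
  expect_identical(f$length, c(2L, 6L, 4L))
  f2 <- digest_mspi("CCGGCCGG")
  expect_identical(f2$start, c(0L, 1L, 5L))
  expect_identical(f2$end, c(1L, 5L, 8L))
  expect_error(digest_mspi("ACGN"), "A/C/G/T")
})

test_that("digestion equals the linear-scan oracle and conserves the contig", {
  set.seed(71)
  for (i in 1:50) {
    s <- random_seq(sample(500:2000, 1))
    f <- digest_mspi(s)
    o <- digest_oracle(s)
    expect_identical(f[, .(start, end)], o)
    # conservation: concatenating fragment sequences reproduces the contig
    expect_identical(paste(substring(s, f$start + 1, f$end), collapse = ""), s)
  }
})

test_that("internal fragments start with the MspI stub CGG", {
  set.seed(73)
  s <- random_seq(20000)
  f <- digest_mspi(s)
  internal <- f[start != 0L]
  expect_true(all(substring(s, internal$start + 1, internal$start + 3) == "CGG"))
})

test_that("size selection keeps exactly the inclusive 150-250 range", {
  mk <- function(lens) data.table(contig = "c", start = 0L,
                                  end = as.integer(lens), length = as.integer(lens))
  expect_identical(nrow(size_select(mk(c(149, 150, 250, 251)))), 2L)
  expect_identical(size_select(mk(c(149, 150, 250, 251)))$end, c(150L, 250L))
  set.seed(79)
  lens <- sample(50:400, 1000, TRUE)
  expect_identical(nrow(size_select(mk(lens))),
                   sum(lens >= 150 & lens <= 250))
})

# A tiny single-fragment world where every read is predictable.
tiny_library <- function(m, conversion_efficiency = 1, seq_error = 0,
                         mean_depth = 30, seed = 3) {
  set.seed(101)
  core <- gsub("CCGG", "ACGG", random_seq(196), fixed = TRUE)
  contig <- paste0(random_seq(40), "CCGG", core, "CCGG", random_seq(40))
  g <- as_genome(c(chrA = contig))
  frags <- size_select(digest_mspi(contig, "chrA"))
  truth <- uniform_truth(g, m)
  params <- library_params(conversion_efficiency = conversion_efficiency,
                           seq_error = seq_error, mean_depth = mean_depth,
                           seed = seed)
  pairs <- simulate_read_pairs(g, frags, truth, params)
  list(genome = g, frags = frags, truth = truth, pairs = pairs)
}

test_that("fully methylated molecules keep every CpG cytosine in read 1", {
  tl <- tiny_library(m = 1)
  expect_gt(nrow(tl$pairs), 0)
  for (i in seq_len(nrow(tl$pairs))) {
    p <- tl$pairs[i]
    mol <- substring(tl$genome$contigs[["chrA"]], p$frag_start + 1, p$frag_end)
    if (p$origin_strand == "bottom")
      mol <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mol)))
    ml <- strsplit(mol, "")[[1]]
    r1 <- strsplit(p$read1_seq, "")[[1]]
    is_cpg_c <- ml == "C" & c(ml[-1], "") == "G"
    idx <- which(is_cpg_c[seq_along(r1)])
    expect_true(all(r1[idx] == "C"))
    # non-CpG Cs are all converted
    non_cpg <- which(ml == "C" & !is_cpg_c)[which(ml == "C" & !is_cpg_c) <= length(r1)]
    expect_true(all(r1[non_cpg] == "T"))
  }
})

test_that("fully unmethylated molecules leave no C in read 1", {
  tl <- tiny_library(m = 0)
  expect_false(any(grepl("C", tl$pairs$read1_seq, fixed = TRUE)))
})

test_that("conversion failures appear at the expected binomial rate", {
  # count retained Cs at non-CpG C positions over many molecules
  tl <- tiny_library(m = 0, conversion_efficiency = 0.995, mean_depth = 3000,
                     seed = 7)
  n_c <- sum(vapply(tl$pairs$read1_seq,
                    function(s) sum(charToRaw(s) == charToRaw("C")),
                    numeric(1)))
  total_c <- 0
  for (strand in c("top", "bottom")) {
    off <- if (strand == "bottom") 2L else 0L  # sticky-end stagger
    mol <- substring(tl$genome$contigs[["chrA"]], tl$frags$start + 1 + off,
                     tl$frags$end + off)
    if (strand == "bottom")
      mol <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mol)))
    ml <- strsplit(mol, "")[[1]][1:100]
    total_c <- total_c + sum(ml == "C") * sum(tl$pairs$origin_strand == strand)
  }
  # all m=0: every genomic C (CpG or not) converts at 0.995
  phat <- n_c / total_c
  expect_lt(abs(phat - 0.005), 3 * sqrt(0.005 * 0.995 / total_c))
})

test_that("bottom-strand molecules are staggered by the sticky-end fill-in", {
  tl <- tiny_library(m = 1)
  bot <- tl$pairs[origin_strand == "bottom"]
  top <- tl$pairs[origin_strand == "top"]
  expect_true(all(bot$frag_start == tl$frags$start + 2L))
  expect_true(all(top$frag_start == tl$frags$start))
  # both strands read CGG (methylated here) at the 5' end of read 1
  expect_true(all(substr(tl$pairs$read1_seq, 1, 3) == "CGG"))
  # read 2 starts with the fill-in image C + A at full conversion
  expect_true(all(substr(tl$pairs$read2_seq, 1, 2) == "CA"))
})

test_that("error-free read_1 stubs are >=99% CGG/TGG on internal fragments", {
  w <- small_world(seed = 83, n_genes = 10, contig_length = 200000)
  frags <- size_select(digest_genome(w$genome))
  clen <- nchar(w$genome$contigs)[frags$contig]
  internal <- frags[start > 0 & end < clen]
  params <- library_params(seq_error = 0, mean_depth = 50, seed = 89)
  pairs <- simulate_read_pairs(w$genome, internal, w$truth, params)
  frac <- mean(substr(pairs$read1_seq, 1, 3) %in% c("CGG", "TGG"))
  expect_gte(frac, 0.99)
})

test_that("identical seed gives byte-identical FASTQ output", {
  tl1 <- tiny_library(m = 0.5, seq_error = 0.001, seed = 13)
  tl2 <- tiny_library(m = 0.5, seq_error = 0.001, seed = 13)
  d <- tempfile(); dir.create(d)
  write_fastq_pairs(tl1$pairs, file.path(d, "a"))
  write_fastq_pairs(tl2$pairs, file.path(d, "b"))
  for (suf in c("_1.fastq", "_2.fastq")) {
    fa <- file.path(d, paste0("a", suf)); fb <- file.path(d, paste0("b", suf))
    expect_identical(readBin(fa, "raw", file.size(fa)),
                     readBin(fb, "raw", file.size(fb)))
  }
  # round trip through the FASTQ reader preserves sequences and qualities
  back <- read_fastq_pairs(file.path(d, "a"))
  expect_identical(back$read1_seq, tl1$pairs$read1_seq)
  expect_identical(back$read2_qual, tl1$pairs$read2_qual)
})

test_that("an empty fragment list yields an empty stream with a warning", {
  tl <- tiny_library(m = 1)
  expect_warning(
    out <- simulate_read_pairs(tl$genome, tl$frags[0], tl$truth,
                               library_params(seed = 1)),
    "empty fragment")
  expect_identical(nrow(out), 0L)
})
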