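test_that("FASTA round trip preserves sequences and order", {
  seqs <- c(one = "ACGTACGTAC", two = strrep("GATTACA", 3))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(length(back), 2L)
  expect_equal(names(back), c("one", "two"))
  expect_equal(as.character(back), c(one = seqs[["one"]],
                                     two = paste0(seqs[["two"]])))
  expect_equal(sum(Biostrings::width(back)), 10L + 21L)

  # writing what was read reproduces the sequences byte-identically
  f2 <- tempfile(fileext = ".fa")
  write_fasta(back, f2)
  expect_identical(as.character(read_fasta(f2)), as.character(back))
})

test_that("read_fasta rejects empty and malformed input", {
  f <- tempfile(fileext = ".fa")
  file.create(f)
  expect_error(read_fasta(f), "no records")
  writeLines(c(">empty_record", "", ">ok", "ACGT"), f)
  expect_error(read_fasta(f), "empty record")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("read_fasta upcases lower-case bases", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">x", "acgtn"), f)
  expect_equal(as.character(read_fasta(f)), c(x = "ACGTN"))
})

test_that("gc_percent excludes ambiguity codes from both terms", {
  expect_equal(gc_percent("GGCCNNAA"), 100 * 4 / 6)
  expect_equal(gc_percent("NNNN"), NA_real_)
  expect_equal(gc_percent(c("GGGG", "ATAT")), c(100, 0))
  # agreement with the character-counting oracle on random sequences
  set.seed(41)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE),
               collapse = "")
    expect_equal(gc_percent(s), oracle_gc(s))
  }
})

test_that("scaffold_stats partitions megabases around an inclusive cutoff", {
  asm <- Biostrings::DNAStringSet(c(
    small1 = make_seq_gc(60000, 40),
    small2 = make_seq_gc(39999, 40),
    exact = make_seq_gc(100000, 50),
    large = make_seq_gc(300000, 50)))
  st <- scaffold_stats(asm, cutoff = 100000L)
  expect_equal(st$n_records, 4L)
  # the record of exactly 100,000 bases counts as at-or-above
  expect_equal(st$mb_at_or_above_cutoff, 0.4)
  expect_equal(st$mb_below_cutoff, 0.099999)
  expect_equal(st$mb_below_cutoff + st$mb_at_or_above_cutoff, st$total_mb)
  expect_equal(st$pct_below + st$pct_at_or_above, 100)

  # invariant under record reordering
  st2 <- scaffold_stats(rev(asm), cutoff = 100000L)
  expect_equal(st2$pct_at_or_above, st$pct_at_or_above)
  expect_equal(st2$gc_percent, st$gc_percent)

  expect_error(scaffold_stats(Biostrings::DNAStringSet()), "empty")
})

test_that("clean_cds applies keyword, structural and redundancy rules", {
  cds <- c(
    "g1 hypothetical protein X" = "ATGAAATAA",
    "g2 kinase" = "ATGAAATAA",
    "g3 kinase-like" = "ATGAAATAA",          # duplicate of g2
    "g4 real gene" = "ATGCCCTAA",
    "g5 no start" = "CCCAAATAA",
    "g6 no stop" = "ATGAAACCC",
    "g7 internal stop" = "ATGTAACCCTAA",
    "g8 frameshifted" = "ATGAAATAAT",
    "g9 Mitochondrial NADH" = "ATGGGGTAA")
  res <- clean_cds(cds)
  expect_equal(nrow(res$accepted) + nrow(res$rejected), length(cds))
  expect_setequal(res$accepted$id, c("g2", "g4"))
  reasons <- setNames(res$rejected$rejection_reason, res$rejected$id)
  expect_equal(reasons[["g1"]], "keyword-excluded")
  expect_equal(reasons[["g3"]], "redundant")
  expect_equal(reasons[["g5"]], "no-start")
  expect_equal(reasons[["g6"]], "no-stop")
  expect_equal(reasons[["g7"]], "internal-stop")
  expect_equal(reasons[["g8"]], "length-not-multiple-of-3")
  # keyword matching is case-insensitive substring on the description
  expect_equal(reasons[["g9"]], "keyword-excluded")
})

test_that("clean_cds honours alternative genetic codes", {
  # ciliate-style: TAA/TAG reassigned, TGA the only stop
  cds <- c("g1 x" = "ATGTAACCCTGA")
  std <- clean_cds(cds)
  expect_equal(std$rejected$rejection_reason, "internal-stop")
  cil <- clean_cds(cds, stop_codons = "TGA")
  expect_equal(nrow(cil$accepted), 1L)
})

test_that("segment tables round-trip through TSV", {
  segs <- data.frame(chrom = "chr2", start = 0L, end = 50000L,
                     n_windows = 2L, size = 50000,
                     gc_percent = 40, name = "2Ts1",
                     stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_segment_table(segs, f)
  tab <- read.delim(f)
  expect_equal(tab$start, 1)         # 1-based inclusive in the file
  expect_equal(tab$end, 50000)
  expect_equal(tab$size_kb, 50)
  expect_equal(tab$gc_percent, 40)
  back <- read_segment_table(f)
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)
  expect_equal(back$gc_percent, segs$gc_percent)
  expect_equal(back$name, segs$name)

  # empty segment list gives a header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_segment_table(segs[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
})
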