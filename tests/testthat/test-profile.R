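test_that("empty alignment stream yields an all-zero, fully flagged profile", {
  refs <- c(r1 = "ACGTACGT")
  prof <- build_profile(refs, data.frame(qname = character(),
                                         flag = integer(),
                                         ref_id = character(),
                                         pos = integer(), cigar = character(),
                                         seq = character()))
  expect_equal(nrow(prof), 8L)
  expect_true(all(prof$coverage == 0L))
  expect_true(all(prof$start_count == 0L))
  expect_true(all(prof$arrest_rate == 0))
  expect_true(all(prof$mismatch_rate == 0))
  expect_true(all(grepl("arrest_undefined", prof$flags)))
  expect_true(all(grepl("mismatch_undefined", prof$flags)))
})

test_that("a single matching read is counted at each covered position", {
  refs <- c(r = "ACGTACGTAA")
  aln <- data.frame(qname = "x", flag = 0L, ref_id = "r", pos = 3L,
                    cigar = "5M", seq = "GTACG")
  prof <- build_profile(refs, aln)
  expect_equal(prof$coverage, c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(prof$start_count[3L], 1L)
  expect_true(all(prof$mismatch_rate == 0))
})

test_that("arrest rate is the defining ratio e(p+1) / c(p+1)", {
  # 10 reads cover p+1 = 7; 4 of them have leftmost position 7
  refs <- c(r = "ACGTACGTACGT")
  long <- data.frame(qname = paste0("l", 1:6), flag = 0L, ref_id = "r",
                     pos = 4L, cigar = "6M", seq = "TACGTA")
  stop7 <- data.frame(qname = paste0("s", 1:4), flag = 0L, ref_id = "r",
                      pos = 7L, cigar = "3M", seq = "GTA")
  prof <- build_profile(refs, rbind(long, stop7))
  ar <- arrest_rate(prof, "r", 6L)
  expect_true(ar$defined)
  expect_equal(ar$value, 0.4)
  expect_equal(prof$arrest_rate[6L], 0.4)
})

test_that("complete arrest gives a = 1 and zero coverage at p", {
  refs <- c(r = "ACGTACGTACGT")
  aln <- data.frame(qname = paste0("s", 1:5), flag = 0L, ref_id = "r",
                    pos = 7L, cigar = "3M", seq = "GTA")
  prof <- build_profile(refs, aln)
  expect_equal(arrest_rate(prof, "r", 6L)$value, 1)
  expect_equal(prof$coverage[6L], 0L)
  # and with no read starting at p+1 the arrest rate is 0
  aln2 <- data.frame(qname = "x", flag = 0L, ref_id = "r", pos = 5L,
                     cigar = "5M", seq = "ACGTA")
  prof2 <- build_profile(refs, aln2)
  expect_equal(arrest_rate(prof2, "r", 6L)$value, 0)
  # undefined when nothing covers p+1
  expect_false(arrest_rate(prof2, "r", 11L)$defined)
})

test_that("mismatch rate and composition follow the stated arithmetic", {
  # ref-A position with calls A:2 C:1 G:1 T:6 -> m = 0.8, (G,T,C) shares
  refs <- c(r = "CCACC")
  bases <- c("A", "A", "C", "G", rep("T", 6))
  aln <- data.frame(qname = paste0("b", seq_along(bases)), flag = 0L,
                    ref_id = "r", pos = 3L, cigar = "1M", seq = bases)
  ms <- mismatch_stats(build_profile(refs, aln), "r", 3L)
  expect_equal(ms$m, 0.8)
  expect_equal(ms$composition, c(G = 0.125, T = 0.75, C = 0.125))

  # perfect match
  aln2 <- data.frame(qname = "p", flag = 0L, ref_id = "r", pos = 1L,
                     cigar = "5M", seq = "CCACC")
  ms2 <- mismatch_stats(build_profile(refs, aln2), "r", 3L)
  expect_equal(ms2$m, 0)
  expect_equal(unname(ms2$composition), c(0, 0, 0))

  # single mismatch type saturates its share
  aln3 <- data.frame(qname = paste0("t", 1:10), flag = 0L, ref_id = "r",
                     pos = 3L, cigar = "1M", seq = rep("T", 10))
  ms3 <- mismatch_stats(build_profile(refs, aln3), "r", 3L)
  expect_equal(ms3$m, 1)
  expect_equal(ms3$composition, c(G = 0, T = 1, C = 0))

  # zero calls -> undefined flag, m = 0
  ms4 <- mismatch_stats(build_profile(refs, aln3), "r", 5L)
  expect_false(ms4$defined)
  expect_equal(ms4$m, 0)
})

test_that("N calls and deletions are excluded from mismatch statistics", {
  refs <- c(r = "AAAAA")
  aln <- data.frame(qname = c("a", "n", "d"), flag = 0L, ref_id = "r",
                    pos = c(2L, 2L, 1L),
                    cigar = c("3M", "3M", "2M1D2M"),
                    seq = c("ATA", "NNN", "AAAA"))
  prof <- build_profile(refs, aln)
  expect_equal(prof$DEL[3L], 1L)
  expect_equal(prof$N[3L], 1L)
  expect_equal(prof$coverage[3L], 3L)  # A + N + DEL
  ms <- mismatch_stats(prof, "r", 3L)
  expect_equal(ms$m, 1)  # the single T is the only A/C/G/T call at p
})

test_that("profile equals the brute-force per-read oracle on random instances", {
  set.seed(42)
  for (i in 1:40) {
    inst <- random_alignment_instance()
    prof <- build_profile(inst$refs, inst$aln)
    orc <- oracle_profile(inst$refs, inst$aln)
    expect_equal(prof$coverage, orc$coverage)
    expect_equal(prof$start_count, orc$start_count)
    for (b in c("A", "C", "G", "T", "N", "DEL")) {
      expect_equal(prof[[b]], orc[[b]])
    }
    # invariant: base counts sum to coverage
    expect_true(all(rowSums(prof[, c("A", "C", "G", "T", "N", "DEL")]) ==
                      prof$coverage))
  }
})

test_that("profiles are invariant under read-order permutation", {
  set.seed(7)
  inst <- random_alignment_instance()
  p1 <- build_profile(inst$refs, inst$aln)
  p2 <- build_profile(inst$refs,
                      inst$aln[sample(nrow(inst$aln)), , drop = FALSE])
  attr(p1, "skipped") <- attr(p2, "skipped") <- NULL
  expect_equal(p1, p2)
})

test_that("reads not covering p+1 never influence a(p)", {
  refs <- c(r = "ACGTACGTACGTACGT")
  base <- data.frame(qname = c("c1", "c2", "s1"), flag = 0L, ref_id = "r",
                     pos = c(5L, 5L, 8L), cigar = c("6M", "6M", "4M"),
                     seq = c("ACGTAC", "ACGTAC", "TACG"))
  far <- data.frame(qname = c("f1", "f2"), flag = 0L, ref_id = "r",
                    pos = c(1L, 12L), cigar = c("4M", "5M"),
                    seq = c("ACGT", "GTACG"))
  a1 <- arrest_rate(build_profile(refs, base), "r", 7L)$value
  a2 <- arrest_rate(build_profile(refs, rbind(base, far)), "r", 7L)$value
  expect_equal(a1, a2)
})

test_that("unknown references error, reverse-strand reads are skipped with a count", {
  refs <- c(r = "ACGTACGT")
  bad <- data.frame(qname = "x", flag = 0L, ref_id = "nope", pos = 1L,
                    cigar = "4M", seq = "ACGT")
  expect_error(build_profile(refs, bad), "nope")

  mixed <- data.frame(qname = c("f", "r"), flag = c(0L, 16L), ref_id = "r",
                      pos = 1L, cigar = "4M", seq = "ACGT")
  expect_warning(prof <- build_profile(refs, mixed), "reverse-strand")
  expect_equal(prof$coverage[1L], 1L)
  expect_equal(attr(prof, "skipped")[["reverse_strand"]], 1L)
})

test_that("soft-clipped alignments are rejected", {
  refs <- c(r = "ACGTACGT")
  clip <- data.frame(qname = "x", flag = 0L, ref_id = "r", pos = 1L,
                     cigar = "2S4M", seq = "GGACGT")
  expect_error(build_profile(refs, clip), "end-to-end")
})

test_that("profile TSV round trip is lossless and re-serialization byte-identical", {
  set.seed(11)
  inst <- random_alignment_instance(max_reads = 50L, max_len = 100L)
  prof <- build_profile(inst$refs, inst$aln)
  attr(prof, "skipped") <- NULL
  f1 <- tempfile()
  f2 <- tempfile()
  write_profile(prof, f1)
  back <- read_profile(f1)
  expect_equal(back, prof)
  write_profile(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed profile rows are rejected with a line number", {
  refs <- c(r = "ACGT")
  prof <- build_profile(refs, data.frame(
    qname = "x", flag = 0L, ref_id = "r", pos = 1L, cigar = "4M",
    seq = "ACGT"))
  f <- tempfile()
  write_profile(prof, f)
  lines <- readLines(f)
  lines[3] <- sub("\t1\t", "\t-1\t", lines[3])  # negative coverage on line 3
  writeLines(lines, f)
  expect_error(read_profile(f), "line 3")
})

test_that("SAM write/read round trip preserves the alignment fields", {
  set.seed(5)
  inst <- random_alignment_instance(max_reads = 20L)
  sam <- tempfile(fileext = ".sam")
  write_sam(inst$aln, inst$refs, sam)
  back <- read_sam(sam)
  ord <- order(back$qname)
  orig <- inst$aln[order(inst$aln$qname), ]
  rownames(orig) <- NULL
  expect_equal(back[ord, c("qname", "ref_id", "pos", "cigar", "seq")],
               orig[, c("qname", "ref_id", "pos", "cigar", "seq")],
               ignore_attr = TRUE)
  prof_direct <- build_profile(inst$refs, inst$aln)
  prof_sam <- build_profile(inst$refs, sam)
  attr(prof_direct, "skipped") <- attr(prof_sam, "skipped") <- NULL
  expect_equal(prof_sam, prof_direct)
})
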