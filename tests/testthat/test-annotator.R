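test_that("ORF finding recovers minimal and planted ORFs with exact coordinates", {
  tiny <- find_orfs(list(id = "t", seq = "ATGAAATAA"), min_len_aa = 2)
  expect_equal(nrow(tiny$orfs), 1L)
  expect_equal(c(tiny$orfs$start, tiny$orfs$end), c(0, 9))
  expect_equal(tiny$orfs$len_aa, 2L)
  expect_equal(tiny$orfs$aa, "MK")

  tv <- make_totivirus_contig(gag_len_aa = 650, pol_len_aa = 1350,
                              total_nt = 7247, seed = 7)
  ann <- find_orfs(tv$contig, min_len_aa = 200)
  gag <- ann$orfs[ann$orfs$label == "GAG", ]
  pol <- ann$orfs[ann$orfs$label == "POL", ]
  expect_equal(nrow(gag), 1L)
  expect_equal(nrow(pol), 1L)
  want <- tv$truth
  expect_equal(c(gag$start, gag$end),
               c(want$start[want$label == "GAG"],
                 want$end[want$label == "GAG"]))
  expect_equal(c(pol$start, pol$end),
               c(want$start[want$label == "POL"],
                 want$end[want$label == "POL"]))
  expect_equal(ann$orientation, "+")
})

test_that("ORF coordinates mirror under reverse complement", {
  tv <- make_totivirus_contig(gag_len_aa = 300, pol_len_aa = 600,
                              total_nt = 3500, seed = 9)
  fwd <- find_orfs(tv$contig, min_len_aa = 150)
  L <- fwd$genome_len_nt
  rc <- data.frame(id = "rc", seq = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tv$contig$seq))),
    stringsAsFactors = FALSE)
  rev <- find_orfs(rc, min_len_aa = 150)
  expect_equal(nrow(fwd$orfs), nrow(rev$orfs))
  f <- fwd$orfs[order(fwd$orfs$start), ]
  r <- rev$orfs[order(-rev$orfs$end), ]
  expect_equal(f$start, L - r$end)
  expect_equal(f$end, L - r$start)
  expect_true(all(f$strand != r$strand))
  # on the flipped contig POL lies 5' of GAG, so orientation flips
  expect_equal(rev$orientation, "-")
})

test_that("random sequence rarely contains long ORFs", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed + 300)
    contig <- list(id = "r", seq = .rand_dna_chr(1000))
    ann <- find_orfs(contig, min_len_aa = 300)
    hits <- hits + nrow(ann$orfs)
  }
  expect_equal(hits, 0L)
})

test_that("triage requires both length and a GAG+POL layout", {
  tv <- make_totivirus_contig(gag_len_aa = 650, pol_len_aa = 1350,
                              total_nt = 7247, seed = 11,
                              id = "near_complete_1")
  short <- make_totivirus_contig(gag_len_aa = 400, pol_len_aa = 550,
                                 total_nt = 3100, seed = 12,
                                 id = "short_two_orf")
  set.seed(13)
  frag <- data.frame(id = "fragment", desc = "",
                     seq = paste0("TAGATAGATAGA",
                                  substr(tv$contig$seq, 1000, 2999)),
                     stringsAsFactors = FALSE)
  contigs <- rbind(tv$contig, short$contig, frag)
  tri <- triage_viral_contigs(contigs, near_complete_min_nt = 5000,
                              min_len_aa = 200)
  expect_equal(tri$report$class,
               c("near_complete", "partial", "partial"))
  expect_equal(tri$near_complete$id, "near_complete_1")

  # a long contig without both ORFs stays partial
  set.seed(14)
  long_random <- data.frame(id = "lr", desc = "",
                            seq = .rand_dna_chr(6000),
                            stringsAsFactors = FALSE)
  expect_equal(triage_viral_contigs(long_random)$report$class, "partial")
})

test_that("triage partitions a 5 + 48 contig set stably under permutation", {
  set.seed(15)
  longs <- lapply(1:5, function(i) {
    make_totivirus_contig(gag_len_aa = 600, pol_len_aa = 1300,
                          total_nt = 7000 + 100 * i, seed = 20 + i,
                          id = sprintf("long%d", i))$contig
  })
  shorts <- lapply(1:48, function(i) {
    data.frame(id = sprintf("short%d", i), desc = "",
               seq = .rand_dna_chr(sample(600:3000, 1)),
               stringsAsFactors = FALSE)
  })
  contigs <- do.call(rbind, c(longs, shorts))
  tri <- triage_viral_contigs(contigs)
  expect_equal(nrow(tri$near_complete), 5L)
  expect_equal(nrow(tri$partial), 48L)
  perm <- contigs[sample(nrow(contigs)), ]
  tri2 <- triage_viral_contigs(perm)
  expect_setequal(tri2$near_complete$id, tri$near_complete$id)
})

test_that("occupancy trimming keeps the boundary column and matches the recount oracle", {
  # 10 rows; column 2 has exactly one residue (occupancy 0.10): kept;
  # column 3 is all-gap: removed; solid columns bound the ends
  aln <- as_alignment(stats::setNames(
    c("AC-A", rep("A--A", 9)), sprintf("t%d", 1:10)))
  tr <- trim_alignment(aln, min_occupancy = 0.10)
  expect_equal(nchar(tr[[1]]), 3L)          # all-gap column dropped
  expect_equal(attr(tr, "kept_cols"), c(1L, 2L, 4L))

  set.seed(16)
  for (rep in 1:40) {
    a <- random_gappy_alignment(sample(3:12, 1), sample(10:60, 1))
    got <- trim_alignment(a, min_occupancy = 0.25)
    m <- do.call(rbind, strsplit(unclass(a), ""))
    occ <- colMeans(m != "-")
    solid <- which(occ >= 0.5)
    want_cols <- if (!length(solid)) integer(0) else {
      rng <- solid[1]:solid[length(solid)]
      rng[occ[rng] >= 0.25]
    }
    expect_equal(attr(got, "kept_cols"), want_cols)
    # idempotence
    expect_equal(unclass(trim_alignment(got, min_occupancy = 0.25)),
                 unclass(got), ignore_attr = TRUE)
    # lowering the occupancy bar never removes more columns
    loose <- trim_alignment(a, min_occupancy = 0.05)
    expect_true(all(attr(got, "kept_cols") %in%
                      attr(loose, "kept_cols")))
  }
})

test_that("concatenation is keyed by taxon and records partitions", {
  p1 <- as_alignment(c(x = "AB"))
  p2 <- as_alignment(c(x = "CD"))
  expect_equal(unclass(concat_alignments(list(p1, p2)))[["x"]], "ABCD")

  set.seed(17)
  a1 <- random_gappy_alignment(4, 100)
  a2 <- random_gappy_alignment(4, 250)
  cc <- concat_alignments(list(gag = a1, pol = a2))
  expect_equal(nchar(cc[[1]]), 350L)
  expect_equal(attr(cc, "partitions")$end, c(100, 350))
  # shuffling row order of part 2 leaves the result unchanged
  a2_shuf <- as_alignment(unclass(a2)[sample(length(a2))])
  cc2 <- concat_alignments(list(gag = a1, pol = a2_shuf))
  expect_identical(c(unclass(cc)), c(unclass(cc2))[names(cc)])

  bad <- as_alignment(stats::setNames(unclass(a2), paste0("z", 1:4)))
  expect_error(concat_alignments(list(a1, bad)), "taxon mismatch")
})

test_that("pairwise identity counts matches over co-occupied columns", {
  expect_equal(pairwise_identity(as_alignment(
    c(a = "MKVW", b = "MKVW")))["a", "b"], 100)
  expect_equal(pairwise_identity(as_alignment(
    c(a = "AAAA", b = "AAAT")))["a", "b"], 75)
  # gap columns are excluded from the denominator
  expect_equal(pairwise_identity(as_alignment(
    c(a = "AA--AA", b = "AAG-AT")))["a", "b"], 100 * 3 / 4)
  # no co-occupied columns: undefined
  expect_true(is.na(pairwise_identity(as_alignment(
    c(a = "AA--", b = "--AA")))["a", "b"]))

  set.seed(18)
  for (rep in 1:20) {
    a <- random_gappy_alignment(2, 40, gap_prob = 0.3)
    m <- do.call(rbind, strsplit(unclass(a), ""))
    co <- m[1, ] != "-" & m[2, ] != "-"
    want <- if (!any(co)) NA_real_ else
      100 * sum(m[1, co] == m[2, co]) / sum(co)
    expect_equal(pairwise_identity(a)[1, 2], want)
  }
})

test_that("alignments survive FASTA and PHYLIP round trips", {
  aln <- as_alignment(c(tx_one = "MKV-W", tx_two = "MQVEW",
                        tx_three = "---EW"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, fa, "fasta")
  expect_equal(unclass(read_alignment(fa)), unclass(aln))
  ph <- withr::local_tempfile(fileext = ".phy")
  write_alignment(aln, ph, "phylip")
  lines <- readLines(ph)
  expect_equal(lines[1], "3 5")
  expect_equal(length(lines), 4L)
})
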