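test_that("six-frame translation follows the standard code and strand symmetry", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr[["+1"]], "MK")
  expect_equal(six_frame_translate("TTTCAT")[["-1"]], "MK")
  # trailing partial codons dropped; stops rendered *
  expect_equal(six_frame_translate("ATGTAAAC")[["+1"]], "M*")
  # ambiguity codes translate to X
  expect_equal(six_frame_translate("ATGNNN")[["+1"]], "MX")
  # shorter than a codon: six empty frames, no error
  expect_equal(unname(six_frame_translate("AT")), rep("", 6))

  set.seed(11)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    expect_equal(six_frame_translate(s)[["+1"]],
                 six_frame_translate(rc)[["-1"]])
  }
})

test_that("planted protein fragments are found at 100 percent identity", {
  set.seed(21)
  pro <- generate_viral_proteome(2, "Totiviridae", mean_len_aa = 300,
                                 seed = 21)
  frag <- substr(pro$proteins$seq[1], 41, 140)  # 100 aa
  insert <- reverse_translate(frag)
  genome <- data.frame(
    id = "g1",
    seq = paste0(paste(sample(c("A", "C", "G", "T"), 4000,
                              replace = TRUE), collapse = ""),
                 insert,
                 paste(sample(c("A", "C", "G", "T"), 4000,
                              replace = TRUE), collapse = "")),
    stringsAsFactors = FALSE)
  hits <- translated_search(genome, pro)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$subject_id, "VP_Totiviridae_1")
  expect_gte(top$aln_len_aa, 60)
  # hit coordinates cover the planted window
  expect_lte(top$start, 4000 + 10)
  expect_gte(top$end, 4000 + nchar(insert) - 10)
  expect_equal(top$subject_family, "Totiviridae")
  # the planted region itself is matched perfectly: every mismatch of the
  # maximal-scoring segment lies in its overhang beyond the plant
  overhang_aa <- (max(0, 4000 - top$start) +
                    max(0, top$end - 4000 - nchar(insert))) / 3
  mismatches <- top$aln_len_aa * (1 - top$pct_identity / 100)
  expect_lte(round(mismatches), ceiling(overhang_aa))
  expect_gte(top$pct_identity, 95)
})

test_that("degraded fragments are recovered near the local-alignment optimum", {
  set.seed(31)
  pro <- generate_viral_proteome(1, "Parvoviridae", mean_len_aa = 400,
                                 seed = 31)
  frag <- substr(pro$proteins$seq[1], 1, 200)
  clean <- reverse_translate(frag)
  chars <- strsplit(clean, "")[[1]]
  pos <- sample(length(chars), round(0.5 * length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                            chars[p]), 1)
  degraded <- paste(chars, collapse = "")
  genome <- data.frame(
    id = "g1",
    seq = paste0(strrep("AC", 1000), degraded, strrep("GT", 1000)),
    stringsAsFactors = FALSE)
  # twilight-zone homology: shorter seeds and a lower score floor, as a
  # sensitive search mode would use
  hits <- translated_search(genome, pro, kmer_k = 2, min_score = 35)
  expect_gt(nrow(hits), 0)
  top <- hits[which.max(hits$score), ]
  # amino-acid identity of the reported hit is within 10 points of the
  # brute-force local alignment optimum over the planted window
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  frames <- six_frame_translate(degraded)
  best_pid <- 0
  best_score <- -Inf
  for (fa in frames) {
    if (nchar(fa) < 10) next
    a <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(fa), Biostrings::AAString(frag),
      type = "local", substitutionMatrix = B, gapOpening = 11,
      gapExtension = 1)
    if (Biostrings::score(a) > best_score) {
      best_score <- Biostrings::score(a)
      best_pid <- 100 * Biostrings::nmatch(a) /
        nchar(as.character(Biostrings::alignedPattern(a)))
    }
  }
  expect_lte(abs(top$pct_identity - best_pid), 10)
})

test_that("reported scores never exceed the Smith-Waterman optimum", {
  set.seed(41)
  pro <- generate_viral_proteome(2, "Totiviridae", mean_len_aa = 150,
                                 seed = 41)
  frag <- substr(pro$proteins$seq[1], 1, 120)
  window <- paste0(.rand_dna_chr(300), reverse_translate(frag),
                   .rand_dna_chr(300))
  genome <- data.frame(id = "w1", seq = window, stringsAsFactors = FALSE)
  hits <- translated_search(genome, pro, min_score = 40)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    prot <- pro$proteins$seq[pro$proteins$id == hits$subject_id[i]]
    expect_lte(hits$score[i], sw_best_frame_score(window, prot))
  }
})

test_that("strand handling is consistent under reverse complement", {
  set.seed(51)
  pro <- generate_viral_proteome(1, "Totiviridae", mean_len_aa = 200,
                                 seed = 51)
  frag <- substr(pro$proteins$seq[1], 1, 80)
  seqchr <- paste0(.rand_dna_chr(500), reverse_translate(frag),
                   .rand_dna_chr(500))
  L <- nchar(seqchr)
  fwd <- translated_search(data.frame(id = "g", seq = seqchr), pro)
  rev <- translated_search(
    data.frame(id = "g", seq = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqchr)))), pro)
  expect_equal(nrow(fwd), nrow(rev))
  fwd <- fwd[order(fwd$start), ]
  rev <- rev[order(-rev$end), ]
  expect_equal(fwd$start, L - rev$end)
  expect_equal(fwd$end, L - rev$start)
  expect_true(all(fwd$strand != rev$strand))
  expect_equal(fwd$score, rev$score)
})

test_that("raising min_score only removes hits", {
  set.seed(61)
  pro <- generate_viral_proteome(2, "Parvoviridae", mean_len_aa = 200,
                                 seed = 61)
  genome <- data.frame(
    id = "g",
    seq = paste0(.rand_dna_chr(1000),
                 reverse_translate(substr(pro$proteins$seq[1], 1, 100)),
                 .rand_dna_chr(1000)),
    stringsAsFactors = FALSE)
  lo <- translated_search(genome, pro, min_score = 40)
  hi <- translated_search(genome, pro, min_score = 120)
  expect_lte(nrow(hi), nrow(lo))
  key <- function(h) paste(h$seq_id, h$start, h$end, h$subject_id)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("random genomes yield no hits at default thresholds", {
  n_hit <- 0L
  for (seed in 1:20) {
    set.seed(seed + 700)
    genome <- data.frame(id = "g", seq = .rand_dna_chr(20000),
                         stringsAsFactors = FALSE)
    pro <- generate_viral_proteome(5, c("FamA", "FamB"),
                                   mean_len_aa = 150, seed = seed + 900)
    n_hit <- n_hit + (nrow(translated_search(genome, pro)) > 0L)
  }
  expect_lte(n_hit / 20, 0.05)
})

test_that("the host-proteome screen discards exactly the decoy-matching candidates", {
  set.seed(71)
  pro <- generate_viral_proteome(5, "Totiviridae", mean_len_aa = 150,
                                 seed = 71)
  cands <- data.frame(
    id = sprintf("cand%d", 1:5),
    seq = vapply(1:5, function(i) {
      reverse_translate(substr(pro$proteins$seq[i], 1, 80))
    }, ""), stringsAsFactors = FALSE)
  # empty host proteome: everything retained
  none <- host_protein_screen(cands, data.frame(id = character(0),
                                                seq = character(0)))
  expect_equal(none$retained$id, cands$id)
  # host proteome holding a copy of protein 3: only cand3 discarded
  host <- data.frame(id = "decoy_P3", seq = pro$proteins$seq[3],
                     stringsAsFactors = FALSE)
  scr <- host_protein_screen(cands, host)
  expect_equal(scr$discarded$id, "cand3")
  expect_equal(scr$retained$id, cands$id[-3])
  expect_match(scr$discarded$reason, "decoy_P3")
})
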