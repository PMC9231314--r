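# Shared helpers and independent oracles used across the suite.

.rand_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force transitive interval clustering: hits (data frame with
# seq_id, subject_family, start, end) are connected when on the same
# contig, of the same family, and separated by a gap strictly less than
# max_gap_nt (overlap counts as connected). Components are found by
# label propagation, independently of the IRanges-based implementation.
brute_force_merge <- function(hits, max_gap_nt = 50) {
  n <- nrow(hits)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        same <- hits$seq_id[i] == hits$seq_id[j] &&
          hits$subject_family[i] == hits$subject_family[j]
        if (!same) next
        gap <- max(hits$start[i], hits$start[j]) -
          min(hits$end[i], hits$end[j])
        if (gap < max_gap_nt && comp[j] != comp[i]) {
          old <- max(comp[i], comp[j])
          new <- min(comp[i], comp[j])
          comp[comp == old] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    data.frame(seq_id = hits$seq_id[idx[1]],
               family = hits$subject_family[idx[1]],
               start = min(hits$start[idx]), end = max(hits$end[idx]),
               n_hits = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$seq_id, out$family, out$start), , drop = FALSE]
}

random_hit_set <- function(n, n_contigs = 2, n_families = 2,
                           region = 2000) {
  data.frame(
    seq_id = sample(sprintf("ctg%d", seq_len(n_contigs)), n,
                    replace = TRUE),
    subject_family = sample(sprintf("Fam%d", seq_len(n_families)), n,
                            replace = TRUE),
    start = s <- sample.int(region, n, replace = TRUE),
    end = s + sample.int(150, n, replace = TRUE),
    strand = "+", frame = 1L,
    subject_id = sprintf("P%d", seq_len(n)),
    subject_protein_class = "Capsid",
    pct_identity = runif(n, 20, 100),
    score = runif(n, 50, 500),
    aln_len_aa = 30L, stringsAsFactors = FALSE)
}

# Optimal gapped Smith-Waterman score of a nucleotide window against a
# protein, maximised over the six frame translations (BLOSUM62, gap
# open 11 / extend 1). Any ungapped alignment score is a lower bound.
sw_best_frame_score <- function(window_nt, protein_aa) {
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  frames <- six_frame_translate(window_nt)
  best <- -Inf
  for (fa in frames) {
    if (nchar(fa) < 2) next
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(fa), Biostrings::AAString(protein_aa),
      type = "local", substitutionMatrix = B, gapOpening = 11,
      gapExtension = 1, scoreOnly = TRUE)
    best <- max(best, s)
  }
  best
}

random_gappy_alignment <- function(n_rows, n_cols, gap_prob = 0.5) {
  rows <- vapply(seq_len(n_rows), function(i) {
    ch <- sample(c("A", "C", "D", "E", "F", "-"), n_cols, replace = TRUE,
                 prob = c(rep((1 - gap_prob) / 5, 5), gap_prob))
    paste(ch, collapse = "")
  }, "")
  as_alignment(stats::setNames(rows, sprintf("tx%d", seq_len(n_rows))))
}
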