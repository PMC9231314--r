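# standard genetic code as a codon -> amino-acid lookup; non-ACGT codons
# (ambiguity codes) translate to X
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Trailing partial codons are dropped, stop codons
#' are rendered `*`, ambiguous codons (e.g. containing `N`) translate to
#' `X`, and frames `-1..-3` read the reverse complement.
#'
#' @param seq Nucleotide string.
#' @return Named character vector with elements `+1`, `+2`, `+3`, `-1`,
#'   `-2`, `-3`. Sequences shorter than 3 nt yield six empty strings.
#' @export
six_frame_translate <- function(seq) {
  frames <- stats::setNames(rep("", 6L),
                            c("+1", "+2", "+3", "-1", "-2", "-3"))
  if (nchar(seq) < 3L) return(frames)
  fwd <- toupper(seq)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  tab <- .codon_table()
  tr1 <- function(x, off) {
    len <- ((nchar(x) - off + 1L) %/% 3L) * 3L
    if (len < 3L) return("")
    starts <- seq.int(off, off + len - 3L, by = 3L)
    aa <- tab[substring(x, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  for (f in 1:3) {
    frames[[paste0("+", f)]] <- tr1(fwd, f)
    frames[[paste0("-", f)]] <- tr1(rev, f)
  }
  frames
}

.blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Translated homology search (seed and extend)
#'
#' Searches genome nucleotide sequences against a protein database by
#' six-frame translation, exact amino-acid k-mer seeding and ungapped
#' X-drop extension under BLOSUM62 — the same class of algorithm as a
#' BLASTx-style search, scaled for assembly screening with a labeled viral
#' protein set. Per (genome region, subject) only the best-scoring hit is
#' kept (ties broken by percent identity, then subject id).
#'
#' @param genome Sequence data frame (`id`, `seq`) of genome contigs, as
#'   from [read_sequences()].
#' @param proteins Protein data frame (`id`, `seq`), or the list returned
#'   by [generate_viral_proteome()] (its taxonomy is then used).
#' @param taxonomy Optional data frame `protein_id`, `family`,
#'   `protein_class` labeling the subjects.
#' @param kmer_k Seed length in amino acids.
#' @param min_score Minimum ungapped BLOSUM62 score to report a hit.
#' @param min_aln_len_aa Minimum alignment length in residues.
#' @param x_drop X-drop termination threshold for extension.
#'
#' @return Data frame with one row per hit: `seq_id`, `start`, `end`
#'   (0-based half-open nucleotide coordinates on the forward strand),
#'   `strand`, `frame` (+1..+3 / -1..-3), `subject_id`, `subject_family`,
#'   `subject_protein_class`, `pct_identity` (amino-acid level), `score`,
#'   `aln_len_aa`, `s_start_aa`, `s_end_aa`.
#' @export
translated_search <- function(genome, proteins, taxonomy = NULL,
                              kmer_k = 3L, min_score = 70,
                              min_aln_len_aa = 15L, x_drop = 20) {
  if (is.list(proteins) && !is.data.frame(proteins) &&
      !is.null(proteins$proteins)) {
    if (is.null(taxonomy)) taxonomy <- proteins$taxonomy
    proteins <- proteins$proteins
  }
  empty <- data.frame(seq_id = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      frame = integer(0), subject_id = character(0),
                      subject_family = character(0),
                      subject_protein_class = character(0),
                      pct_identity = numeric(0), score = numeric(0),
                      aln_len_aa = integer(0), s_start_aa = integer(0),
                      s_end_aa = integer(0), stringsAsFactors = FALSE)
  if (nrow(proteins) == 0L || nrow(genome) == 0L) return(empty)
  B <- .blosum62()
  letters <- paste(rownames(B), collapse = "")
  out <- list()
  for (g in seq_len(nrow(genome))) {
    L <- nchar(genome$seq[g])
    frames <- six_frame_translate(genome$seq[g])
    for (fn in names(frames)) {
      fa <- frames[[fn]]
      if (nchar(fa) < kmer_k) next
      raw <- cpp_seed_extend(fa, proteins$seq, B, letters,
                             as.integer(kmer_k), x_drop, min_score,
                             as.integer(min_aln_len_aa))
      if (nrow(raw) == 0L) next
      f <- abs(as.integer(fn))
      if (startsWith(fn, "+")) {
        start <- (f - 1L) + 3 * raw$q_start_aa
        end <- (f - 1L) + 3 * raw$q_end_aa
        strand <- "+"
      } else {
        start <- L - ((f - 1L) + 3 * raw$q_end_aa)
        end <- L - ((f - 1L) + 3 * raw$q_start_aa)
        strand <- "-"
      }
      out[[length(out) + 1L]] <- data.frame(
        seq_id = genome$id[g], start = start, end = end, strand = strand,
        frame = as.integer(fn), subject_id = proteins$id[raw$subject],
        subject_family = NA_character_,
        subject_protein_class = NA_character_,
        pct_identity = 100 * raw$n_match / raw$aln_len_aa,
        score = raw$score, aln_len_aa = raw$aln_len_aa,
        s_start_aa = raw$s_start_aa, s_end_aa = raw$s_end_aa,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  if (!is.null(taxonomy)) {
    i <- match(hits$subject_id, taxonomy$protein_id)
    hits$subject_family <- taxonomy$family[i]
    hits$subject_protein_class <- taxonomy$protein_class[i]
  }
  .dedupe_hits(hits)
}

# Keep only the best-scoring hit per (contig, subject, overlapping region).
# Tie-break: higher score, then higher pct_identity, then subject_id.
.dedupe_hits <- function(hits) {
  ord <- order(hits$seq_id, hits$subject_id, -hits$score,
               -hits$pct_identity)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  grp <- paste(hits$seq_id, hits$subject_id)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    kept_s <- numeric(0)
    kept_e <- numeric(0)
    for (i in idx) {
      if (any(pmax(kept_s, hits$start[i]) < pmin(kept_e, hits$end[i]))) {
        keep[i] <- FALSE
      } else {
        kept_s <- c(kept_s, hits$start[i])
        kept_e <- c(kept_e, hits$end[i])
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$seq_id, hits$start, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Host-proteome false-positive screen
#'
#' Discards candidate EVE sequences that receive any translated-search hit
#' against the host proteome at the same thresholds as the viral search —
#' the analogue of rejecting candidates that match a host (e.g.
#' \emph{D. melanogaster}-like) protein.
#'
#' @param candidates Data frame with at least `id` and `seq` (candidate
#'   nucleotide sequences); other columns are carried through.
#' @param host_proteome Protein data frame (`id`, `seq`); may be empty.
#' @param kmer_k,min_score,min_aln_len_aa,x_drop Search thresholds, as in
#'   [translated_search()].
#'
#' @return List with `retained` and `discarded` data frames (input order
#'   preserved); `discarded` gains a `reason` column naming the matched
#'   host protein.
#' @export
host_protein_screen <- function(candidates, host_proteome,
                                kmer_k = 3L, min_score = 70,
                                min_aln_len_aa = 15L, x_drop = 20) {
  if (is.null(host_proteome) || nrow(host_proteome) == 0L ||
      nrow(candidates) == 0L) {
    return(list(retained = candidates,
                discarded = candidates[0, , drop = FALSE]))
  }
  hits <- translated_search(
    data.frame(id = candidates$id, seq = candidates$seq,
               stringsAsFactors = FALSE),
    host_proteome, kmer_k = kmer_k, min_score = min_score,
    min_aln_len_aa = min_aln_len_aa, x_drop = x_drop)
  bad <- candidates$id %in% hits$seq_id
  discarded <- candidates[bad, , drop = FALSE]
  if (nrow(discarded)) {
    discarded$reason <- vapply(discarded$id, function(id) {
      h <- hits[hits$seq_id == id, ]
      paste0("host protein hit: ", h$subject_id[which.max(h$score)])
    }, "")
  }
  list(retained = candidates[!bad, , drop = FALSE], discarded = discarded)
}
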