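.DEFAULT_FAMILY_CODES <- c(Partitiviridae = "Partiti", Parvoviridae = "Parvo",
                           Rhabdoviridae = "Rhabdo", Totiviridae = "Toti",
                           Xinmoviridae = "Xinmo")

.family_code <- function(family, codes = .DEFAULT_FAMILY_CODES) {
  ifelse(family %in% names(codes), codes[family],
         sub("viridae$", "", family))
}

#' Merge nearby same-family hits into EVE candidates
#'
#' Within each (contig, family) group, hits whose interval gap is strictly
#' less than `max_gap_nt` are unioned transitively into a single candidate
#' spanning from the minimum start to the maximum end. Hits from different
#' families never merge; overlapping hits always do. Merging is
#' strand-agnostic because decayed EVEs scramble reading frames.
#'
#' @param hits Translated-hit data frame (from [translated_search()] or
#'   [tabular_to_hits()]) with non-missing `subject_family`.
#' @param max_gap_nt Strict gap threshold in nucleotides (default 50: hits
#'   closer than 50 bp merge).
#'
#' @return Data frame of candidates: `candidate_id`, `seq_id`, `start`,
#'   `end` (0-based half-open union), `family`, `n_hits`, best-hit fields
#'   (`best_subject_id`, `best_pct_identity`, `best_score`,
#'   `best_protein_class`; best = highest score, then highest percent
#'   identity, then lexicographic subject id) and a list column `hits`
#'   holding the constituent hit rows.
#' @export
merge_hits <- function(hits, max_gap_nt = 50L) {
  if (nrow(hits) == 0L) {
    return(data.frame(candidate_id = character(0), seq_id = character(0),
                      start = numeric(0), end = numeric(0),
                      family = character(0), n_hits = integer(0),
                      best_subject_id = character(0),
                      best_pct_identity = numeric(0),
                      best_score = numeric(0),
                      best_protein_class = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(is.na(hits$subject_family))) {
    stop("merge_hits requires family labels on all hits")
  }
  grp <- paste(hits$seq_id, hits$subject_family, sep = "\r")
  out <- list()
  for (g in unique(grp)) {
    sub <- hits[grp == g, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    red <- IRanges::reduce(ir, min.gapwidth = max_gap_nt,
                           with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (i in seq_along(red)) {
      members <- sub[revmap[[i]], , drop = FALSE]
      best <- members[order(-members$score, -members$pct_identity,
                            members$subject_id)[1], ]
      cand <- data.frame(
        candidate_id = NA_character_,
        seq_id = sub$seq_id[1],
        start = as.numeric(IRanges::start(red)[i] - 1L),
        end = as.numeric(IRanges::end(red)[i]),
        family = sub$subject_family[1],
        n_hits = length(revmap[[i]]),
        best_subject_id = best$subject_id,
        best_pct_identity = best$pct_identity,
        best_score = best$score,
        best_protein_class = best$subject_protein_class,
        stringsAsFactors = FALSE)
      cand$hits <- I(list(members))
      out[[length(out) + 1L]] <- cand
    }
  }
  cands <- do.call(rbind, out)
  cands <- cands[order(cands$seq_id, cands$start, cands$family), ,
                 drop = FALSE]
  cands$candidate_id <- sprintf("%s:%s:%d", cands$seq_id,
                                .family_code(cands$family),
                                seq_len(nrow(cands)))
  rownames(cands) <- NULL
  cands
}

#' Contamination filter: require host flanking sequence
#'
#' A candidate is discarded if and only if it has less than `min_flank_nt`
#' of contig sequence on \emph{both} sides, i.e. the viral region occupies
#' essentially the whole contig — the signature of co-sequenced viral
#' contamination rather than a genuine integration.
#'
#' @param candidates Candidate data frame from [merge_hits()] (needs
#'   `seq_id`, `start`, `end`).
#' @param contigs Sequence data frame (`id`, `seq`) containing every
#'   candidate contig.
#' @param min_flank_nt Minimum host flank per side (default 50 nt).
#'
#' @return List with `retained` and `discarded`; discarded rows carry
#'   `reason = "no host flank"`.
#' @export
contamination_filter <- function(candidates, contigs, min_flank_nt = 50L) {
  if (nrow(candidates) == 0L) {
    return(list(retained = candidates,
                discarded = candidates[0, , drop = FALSE]))
  }
  idx <- match(candidates$seq_id, contigs$id)
  if (anyNA(idx)) {
    stop("unknown contig: ", candidates$seq_id[which(is.na(idx))[1]])
  }
  clen <- nchar(contigs$seq)[idx]
  left <- candidates$start
  right <- clen - candidates$end
  drop <- left < min_flank_nt & right < min_flank_nt
  discarded <- candidates[drop, , drop = FALSE]
  if (nrow(discarded)) discarded$reason <- "no host flank"
  list(retained = candidates[!drop, , drop = FALSE], discarded = discarded)
}

#' Call EVEs in genome assemblies
#'
#' Full screening pipeline per assembly: translated homology search against
#' the labeled viral proteome, transitive merging of nearby same-family
#' hits, host-proteome false-positive screen, and the host-flank
#' contamination filter. Locus labels are left as `"np"` (not placed);
#' [assign_loci()] fills them in across assemblies.
#'
#' @param assemblies Named list of sequence data frames (`id`, `seq`).
#' @param viral_proteome List with `proteins` and `taxonomy`, as from
#'   [generate_viral_proteome()], or a protein data frame plus `taxonomy`.
#' @param host_proteome Optional host protein data frame (`id`, `seq`);
#'   `NULL` disables the false-positive screen.
#' @param taxonomy Taxonomy data frame if `viral_proteome` is a plain
#'   protein data frame.
#' @param params Named list overriding defaults: `kmer_k`, `min_score`,
#'   `min_aln_len_aa`, `x_drop`, `max_gap_nt`, `min_flank_nt`,
#'   `family_codes`.
#' @param hits Optional externally produced translated-hit data frame per
#'   assembly (named list), e.g. ingested DIAMOND/BLASTx tabular output via
#'   [tabular_to_hits()]; when supplied the built-in search is skipped.
#'
#' @return Data frame of EVE records: `name`, `assembly`, `seq_id`,
#'   `start`, `end`, `span`, `family`, `best_hit_subject`,
#'   `best_hit_pct_identity`, `protein_class`, `locus_label` (all `"np"`),
#'   `seq`. Discarded candidates (with reasons) are attached as attribute
#'   `"discarded"`.
#' @export
call_eves <- function(assemblies, viral_proteome, host_proteome = NULL,
                      taxonomy = NULL, params = list(), hits = NULL) {
  p <- utils::modifyList(list(kmer_k = 3L, min_score = 70,
                              min_aln_len_aa = 15L, x_drop = 20,
                              max_gap_nt = 50L, min_flank_nt = 50L,
                              family_codes = .DEFAULT_FAMILY_CODES),
                         params)
  recs <- list()
  disc <- list()
  for (asm in names(assemblies)) {
    contigs <- assemblies[[asm]]
    h <- if (!is.null(hits)) hits[[asm]] else translated_search(
      contigs, viral_proteome, taxonomy = taxonomy, kmer_k = p$kmer_k,
      min_score = p$min_score, min_aln_len_aa = p$min_aln_len_aa,
      x_drop = p$x_drop)
    cands <- merge_hits(h, max_gap_nt = p$max_gap_nt)
    if (nrow(cands)) {
      cidx <- match(cands$seq_id, contigs$id)
      cands$seq <- substring(contigs$seq[cidx], cands$start + 1L,
                             cands$end)
      cands$id <- cands$candidate_id
    }
    scr <- host_protein_screen(cands, host_proteome, kmer_k = p$kmer_k,
                               min_score = p$min_score,
                               min_aln_len_aa = p$min_aln_len_aa,
                               x_drop = p$x_drop)
    flt <- contamination_filter(scr$retained, contigs,
                                min_flank_nt = p$min_flank_nt)
    kept <- flt$retained
    if (nrow(kept)) {
      recs[[asm]] <- data.frame(
        name = paste0(.family_code(kept$family, p$family_codes), "EVE"),
        assembly = asm, seq_id = kept$seq_id, start = kept$start,
        end = kept$end, span = kept$end - kept$start,
        family = kept$family, best_hit_subject = kept$best_subject_id,
        best_hit_pct_identity = kept$best_pct_identity,
        protein_class = kept$best_protein_class, locus_label = "np",
        seq = kept$seq, stringsAsFactors = FALSE)
    }
    dd <- rbind(
      if (nrow(scr$discarded)) cbind(scr$discarded[
        setdiff(names(scr$discarded), "hits")], assembly = asm),
      if (nrow(flt$discarded)) cbind(flt$discarded[
        setdiff(names(flt$discarded), "hits")], assembly = asm))
    if (!is.null(dd) && nrow(dd)) disc[[asm]] <- dd
  }
  out <- if (length(recs)) do.call(rbind, recs) else data.frame(
    name = character(0), assembly = character(0), seq_id = character(0),
    start = numeric(0), end = numeric(0), span = numeric(0),
    family = character(0), best_hit_subject = character(0),
    best_hit_pct_identity = numeric(0), protein_class = character(0),
    locus_label = character(0), seq = character(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "discarded") <- if (length(disc)) do.call(rbind, disc) else NULL
  out
}

#' Summarize EVE records
#'
#' Table-style summary of an EVE call set: total count, per-family counts,
#' span range, distinct placed loci and the number of distinct
#' contigs/chromosomes bearing at least one EVE in a named assembly.
#'
#' @param records EVE record data frame (needs `family`, `span` or
#'   `start`/`end`, `locus_label`, `assembly`, `seq_id`).
#' @param assembly_of_interest Assembly whose distinct EVE-bearing contigs
#'   are counted (e.g. the chromosome-level assembly); default: all.
#'
#' @return List with `total`, `family_counts` (named integer vector),
#'   `span_min`, `span_max`, `n_loci` (distinct non-`np` locus labels) and
#'   `n_chromosomes`.
#' @export
summarize_eves <- function(records, assembly_of_interest = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(total = 0L, family_counts = integer(0), span_min = 0,
                span_max = 0, n_loci = 0L, n_chromosomes = 0L))
  }
  span <- if ("span" %in% names(records)) records$span else
    records$end - records$start
  sub <- if (is.null(assembly_of_interest)) records else
    records[records$assembly == assembly_of_interest, , drop = FALSE]
  list(total = nrow(records),
       family_counts = c(table(records$family)),
       span_min = min(span), span_max = max(span),
       n_loci = length(setdiff(unique(records$locus_label), "np")),
       n_chromosomes = length(unique(sub$seq_id)))
}

#' Write EVE records as TSV
#'
#' @param records EVE record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eve_tsv <- function(records, path) {
  cols <- setdiff(names(records), c("seq", "hits"))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write EVE records as BED
#'
#' Emits 0-based half-open BED6 intervals (score column = rounded percent
#' identity of the best viral hit) for genome-browser use.
#'
#' @param records EVE record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eve_bed <- function(records, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = records$seq_id,
    ranges = IRanges::IRanges(start = records$start + 1L,
                              end = records$end),
    strand = "*",
    name = paste0(records$name, ifelse(records$locus_label == "np", "",
                                       paste0("_", records$locus_label))),
    score = round(records$best_hit_pct_identity))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
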