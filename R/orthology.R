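.DEFAULT_LOCUS_CODES <- c(Totiviridae = "T", Parvoviridae = "PR",
                          Partitiviridae = "PT", Rhabdoviridae = "Rh",
                          Xinmoviridae = "Xi")

.locus_code <- function(family, codes = .DEFAULT_LOCUS_CODES) {
  ifelse(family %in% names(codes), codes[family],
         toupper(substr(family, 1L, 2L)))
}

#' Extract the genomic window around an EVE
#'
#' Returns the window of `window_nt` nucleotides centered on the EVE,
#' clipped at contig edges (clipped windows are shorter, they are not
#' re-extended on the other side).
#'
#' @param contigs Sequence data frame (`id`, `seq`) of the assembly.
#' @param eve One EVE record (one-row data frame or list with `seq_id`,
#'   `start`, `end`; optional `assembly` used in the output id).
#' @param window_nt Window width (default 20 kb).
#'
#' @return One-row sequence data frame whose `id` encodes assembly, contig
#'   and 0-based half-open window coordinates.
#' @export
extract_flank_region <- function(contigs, eve, window_nt = 20000L) {
  i <- match(eve$seq_id, contigs$id)
  if (is.na(i)) stop("unknown contig: ", eve$seq_id)
  clen <- nchar(contigs$seq[i])
  center <- floor((eve$start + eve$end) / 2)
  half <- floor(window_nt / 2)
  ws <- max(0, center - half)
  we <- min(clen, center + (window_nt - half))
  asm <- if (!is.null(eve$assembly)) eve$assembly else "assembly"
  data.frame(
    id = sprintf("%s|%s:%d-%d", asm, eve$seq_id, ws, we),
    desc = "EVE flank window",
    seq = substring(contigs$seq[i], ws + 1L, we),
    stringsAsFactors = FALSE)
}

# Global nucleotide identity of two sequences: match +1, mismatch -1,
# gap -2 per gapped position; identity = matches / alignment columns.
.global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 2)
  100 * Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

# Matched nucleotides of the best local alignment of a flank against a
# reference window (match +1 / mismatch -1 scoring).
.flank_match_nt <- function(flank, window) {
  if (!nzchar(flank) || !nzchar(window)) return(0L)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(flank), Biostrings::DNAString(window),
    type = "local", substitutionMatrix = sm, gapOpening = 5,
    gapExtension = 2)
  Biostrings::nmatch(aln)
}

.eve_flanks <- function(contigs, eve, flank_nt) {
  i <- match(eve$seq_id, contigs$id)
  clen <- nchar(contigs$seq[i])
  left <- substring(contigs$seq[i], max(0, eve$start - flank_nt) + 1L,
                    eve$start)
  right <- substring(contigs$seq[i], eve$end + 1L,
                     min(clen, eve$end + flank_nt))
  list(left = left, right = right)
}

#' Assign orthologous locus labels to EVEs across assemblies
#'
#' Two EVEs of the same family in different assemblies are placed at one
#' locus iff (a) their EVE sequences align globally at
#' `>= min_identity_pct` nucleotide identity and (b) both of the
#' non-reference EVE's flanks align to the reference EVE's window with at
#' least `min_flank_match_nt` matched nucleotides. Loci are anchored on
#' the reference assembly (typically the chromosome-level one) and
#' labeled per family in reference-coordinate order (`T1`, `T2`, ... for
#' Totiviridae, `PR1`, ... for Parvoviridae, and so on). EVEs that fail
#' placement keep the label `"np"`.
#'
#' @param eves EVE record data frame from [call_eves()] covering all
#'   assemblies; must carry EVE sequences in `seq` (extracted from
#'   `assemblies` when absent).
#' @param assemblies Named list of sequence data frames, one per assembly.
#' @param reference Name of the reference assembly (default: first).
#' @param min_identity_pct EVE-to-EVE nucleotide identity bar (default 98).
#' @param min_flank_match_nt Minimum matched flank nucleotides per side
#'   (default 50).
#' @param window_nt Reference window width (default 20 kb).
#' @param flank_nt How much flank to take from the query EVE for placement
#'   (default 500 nt per side; clipped windows may give less, down to
#'   `min_flank_match_nt`).
#' @param locus_codes Named map family -> locus label prefix.
#'
#' @return An object of class `locus_set`: list with `records` (input
#'   records with `locus_label` filled in), `loci` (per-locus lists:
#'   `locus_label`, `family`, `reference_assembly`, `members` data frame,
#'   `identity_matrix` with 100 on the diagonal) and `reference`.
#' @export
assign_loci <- function(eves, assemblies, reference = NULL,
                        min_identity_pct = 98, min_flank_match_nt = 50L,
                        window_nt = 20000L, flank_nt = 500L,
                        locus_codes = .DEFAULT_LOCUS_CODES) {
  if (is.null(reference)) reference <- names(assemblies)[1]
  if (!reference %in% names(assemblies)) {
    stop("unknown reference assembly: ", reference)
  }
  eves <- as.data.frame(eves)
  if (nrow(eves) == 0L) {
    return(structure(list(records = eves, loci = list(),
                          reference = reference), class = "locus_set"))
  }
  if (is.null(eves[["seq"]])) {
    eves$seq <- vapply(seq_len(nrow(eves)), function(i) {
      ctg <- assemblies[[eves$assembly[i]]]
      substring(ctg$seq[match(eves$seq_id[i], ctg$id)],
                eves$start[i] + 1L, eves$end[i])
    }, "")
  }
  eves$locus_label <- "np"
  is_ref <- eves$assembly == reference
  ref <- eves[is_ref, , drop = FALSE]
  ref <- ref[order(ref$family, ref$seq_id, ref$start), , drop = FALSE]
  # label reference anchors per family in coordinate order
  if (nrow(ref)) {
    for (fam in unique(ref$family)) {
      idx <- which(ref$family == fam)
      ref$locus_label[idx] <- paste0(.locus_code(fam, locus_codes),
                                     seq_along(idx))
    }
  }
  # reference windows, computed once
  ref_windows <- lapply(seq_len(nrow(ref)), function(i) {
    extract_flank_region(assemblies[[reference]], ref[i, ],
                         window_nt = window_nt)$seq
  })
  # place non-reference EVEs on the best passing anchor
  members <- stats::setNames(
    lapply(seq_len(nrow(ref)), function(i) {
      m <- ref[i, , drop = FALSE]
      m
    }), ref$locus_label)
  other <- which(!is_ref)
  for (i in other) {
    cand <- which(ref$family == eves$family[i])
    best_lab <- NA_character_
    best_id <- -Inf
    for (j in cand) {
      ident <- .global_identity(eves$seq[i], ref$seq[j])
      if (ident < min_identity_pct || ident <= best_id) next
      fl <- .eve_flanks(assemblies[[eves$assembly[i]]], eves[i, ],
                        flank_nt)
      okL <- .flank_match_nt(fl$left, ref_windows[[j]]) >=
        min_flank_match_nt
      okR <- okL && .flank_match_nt(fl$right, ref_windows[[j]]) >=
        min_flank_match_nt
      if (okR) {
        best_lab <- ref$locus_label[j]
        best_id <- ident
      }
    }
    if (!is.na(best_lab)) {
      eves$locus_label[i] <- best_lab
      row <- eves[i, , drop = FALSE]
      members[[best_lab]] <- rbind(members[[best_lab]], row)
    }
  }
  # write anchor labels back onto the reference rows of `eves`
  for (j in seq_len(nrow(ref))) {
    sel <- eves$assembly == reference & eves$seq_id == ref$seq_id[j] &
      eves$start == ref$start[j] & eves$end == ref$end[j]
    eves$locus_label[sel] <- ref$locus_label[j]
  }
  loci <- lapply(names(members), function(lab) {
    mem <- members[[lab]]
    n <- nrow(mem)
    im <- matrix(100, n, n,
                 dimnames = list(mem$assembly, mem$assembly))
    if (n > 1L) {
      for (a in seq_len(n - 1L)) {
        for (b in seq((a + 1L), n)) {
          im[a, b] <- im[b, a] <- .global_identity(mem$seq[a], mem$seq[b])
        }
      }
    }
    list(locus_label = lab, family = mem$family[1],
         reference_assembly = reference, members = mem,
         identity_matrix = im)
  })
  names(loci) <- names(members)
  structure(list(records = eves, loci = loci, reference = reference),
            class = "locus_set")
}

#' Summarize a locus assignment
#'
#' @param loci A `locus_set` from [assign_loci()].
#'
#' @return List with `presence` (logical locus x assembly matrix),
#'   `member_counts` (named integer vector) and `n_chromosomes` (distinct
#'   reference contigs/chromosomes bearing a locus).
#' @export
orthology_summary <- function(loci) {
  stopifnot(inherits(loci, "locus_set"))
  if (!length(loci$loci)) {
    return(list(presence = matrix(logical(0), 0, 0),
                member_counts = integer(0), n_chromosomes = 0L))
  }
  assemblies <- sort(unique(unlist(
    lapply(loci$loci, function(l) l$members$assembly))))
  presence <- t(vapply(loci$loci, function(l) {
    assemblies %in% l$members$assembly
  }, logical(length(assemblies))))
  colnames(presence) <- assemblies
  rownames(presence) <- names(loci$loci)
  ref_chroms <- vapply(loci$loci, function(l) {
    m <- l$members[l$members$assembly == loci$reference, , drop = FALSE]
    if (nrow(m)) m$seq_id[1] else NA_character_
  }, "")
  list(presence = presence,
       member_counts = vapply(loci$loci, function(l) nrow(l$members), 0L),
       n_chromosomes = length(unique(stats::na.omit(ref_chroms))))
}

#' Locus presence matrix from labeled EVE records
#'
#' Builds the locus-by-assembly presence matrix directly from the
#' `locus_label` column of an EVE record table (e.g. a packaged report
#' fixture), without recomputing orthology from sequence.
#'
#' @param records EVE record data frame with `locus_label` and `assembly`.
#' @return Logical matrix, one row per non-`np` locus label.
#' @export
locus_presence <- function(records) {
  placed <- records[records$locus_label != "np", , drop = FALSE]
  labs <- sort(unique(placed$locus_label))
  asms <- sort(unique(records$assembly))
  m <- matrix(FALSE, length(labs), length(asms),
              dimnames = list(labs, asms))
  for (i in seq_len(nrow(placed))) {
    m[placed$locus_label[i], placed$assembly[i]] <- TRUE
  }
  m
}
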