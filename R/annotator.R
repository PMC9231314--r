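#' Find open reading frames in a contig
#'
#' Enumerates all ATG-to-stop ORFs of at least `min_len_aa` codons
#' (excluding the stop) on all six reading frames. The two longest
#' mutually non-overlapping ORFs are labeled `GAG` and `POL` following the
#' canonical totivirus layout: the longer of the two (the RdRP-bearing
#' ORF) is `POL` and is expected 3' of `GAG`; the contig's implied
#' orientation is reported rather than the sequence being rewritten. Equal
#' lengths fall back to labeling by coordinate (5'-most = `GAG`) with a
#' warning.
#'
#' @param contig One-row sequence data frame or list with `id` and `seq`.
#' @param min_len_aa Minimum ORF length in amino acids (stop excluded).
#'
#' @return List with `contig_id`, `genome_len_nt`, `orientation` (`"+"` if
#'   the labeled ORFs lie on the forward strand, `"-"` if on the reverse,
#'   `NA` if unlabeled) and `orfs`, a data frame with `start`, `end`
#'   (0-based half-open nucleotide coordinates on the input contig,
#'   including the stop codon), `strand`, `frame`, `len_aa`, `aa` and
#'   `label` (`GAG`, `POL` or `other`).
#' @export
find_orfs <- function(contig, min_len_aa = 100L) {
  id <- contig$id[1]
  seq <- contig$seq[1]
  L <- nchar(seq)
  if (L < 3L * min_len_aa) {
    stop("contig shorter than 3 * min_len_aa")
  }
  frames <- six_frame_translate(seq)
  rows <- list()
  for (fn in names(frames)) {
    aa <- strsplit(frames[[fn]], "")[[1]]
    if (!length(aa)) next
    m_pos <- which(aa == "M")
    s_pos <- which(aa == "*")
    if (!length(m_pos) || !length(s_pos)) next
    nxt <- findInterval(m_pos, s_pos) + 1L
    ok <- nxt <= length(s_pos)
    m_pos <- m_pos[ok]
    stops <- s_pos[nxt[ok]]
    len_aa <- stops - m_pos
    keep <- len_aa >= min_len_aa
    if (!any(keep)) next
    m_pos <- m_pos[keep]; stops <- stops[keep]; len_aa <- len_aa[keep]
    f <- abs(as.integer(fn))
    i0 <- m_pos - 1L            # 0-based aa index of ATG
    j1 <- stops                  # 0-based aa index one past the stop
    if (startsWith(fn, "+")) {
      start <- (f - 1L) + 3L * i0
      end <- (f - 1L) + 3L * j1
      strand <- "+"
    } else {
      start <- L - ((f - 1L) + 3L * j1)
      end <- L - ((f - 1L) + 3L * i0)
      strand <- "-"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = start, end = end, strand = strand, frame = as.integer(fn),
      len_aa = len_aa,
      aa = substring(frames[[fn]], m_pos, stops - 1L),
      label = "other", stringsAsFactors = FALSE)
  }
  orfs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    start = numeric(0), end = numeric(0), strand = character(0),
    frame = integer(0), len_aa = integer(0), aa = character(0),
    label = character(0), stringsAsFactors = FALSE)
  orientation <- NA_character_
  if (nrow(orfs) >= 1L) {
    ord <- order(-orfs$len_aa, orfs$start)
    top1 <- ord[1]
    top2 <- NA_integer_
    for (i in ord[-1]) {
      disjoint <- orfs$end[i] <= orfs$start[top1] ||
        orfs$start[i] >= orfs$end[top1]
      if (disjoint && orfs$aa[i] != orfs$aa[top1]) { top2 <- i; break }
    }
    if (!is.na(top2)) {
      if (orfs$len_aa[top1] == orfs$len_aa[top2]) {
        warning("equal-length top ORFs; labeling GAG/POL by coordinate")
        five <- if (orfs$start[top1] < orfs$start[top2]) top1 else top2
        three <- if (five == top1) top2 else top1
        orfs$label[five] <- "GAG"; orfs$label[three] <- "POL"
        orientation <- orfs$strand[three]
      } else {
        pol <- top1; gag <- top2   # POL is the longer ORF
        orfs$label[pol] <- "POL"; orfs$label[gag] <- "GAG"
        # orientation such that POL is 3'-most of the pair
        orientation <- if (orfs$start[pol] > orfs$start[gag]) "+" else "-"
      }
    }
  }
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  rownames(orfs) <- NULL
  list(contig_id = id, genome_len_nt = L, orientation = orientation,
       orfs = orfs)
}

#' Triage viral contigs into near-complete and partial
#'
#' A contig is classed `near_complete` iff it is longer than
#' `near_complete_min_nt` \emph{and} its ORF annotation labels both a GAG
#' and a POL ORF; everything else is `partial`.
#'
#' @param contigs Sequence data frame (`id`, `seq`).
#' @param near_complete_min_nt Length threshold, strict (default 5000 nt:
#'   "longer than 5 kb").
#' @param min_len_aa Minimum ORF length used for annotation.
#'
#' @return List with `near_complete` and `partial` (sequence data frames)
#'   and `report` (data frame: `contig_id`, `length_nt`, `n_orfs`,
#'   `has_gag`, `has_pol`, `class`).
#' @export
triage_viral_contigs <- function(contigs, near_complete_min_nt = 5000L,
                                 min_len_aa = 200L) {
  rep_rows <- lapply(seq_len(nrow(contigs)), function(i) {
    len <- nchar(contigs$seq[i])
    if (len >= 3L * min_len_aa) {
      ann <- find_orfs(contigs[i, ], min_len_aa = min_len_aa)
      has_gag <- "GAG" %in% ann$orfs$label
      has_pol <- "POL" %in% ann$orfs$label
      n_orfs <- nrow(ann$orfs)
    } else {
      has_gag <- has_pol <- FALSE
      n_orfs <- 0L
    }
    data.frame(contig_id = contigs$id[i], length_nt = len,
               n_orfs = n_orfs, has_gag = has_gag, has_pol = has_pol,
               class = if (len > near_complete_min_nt && has_gag &&
                           has_pol) "near_complete" else "partial",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  list(near_complete = contigs[report$class == "near_complete", ,
                               drop = FALSE],
       partial = contigs[report$class == "partial", , drop = FALSE],
       report = report)
}

#' Validate and construct an alignment
#'
#' An alignment is a named character vector of equal-length gapped
#' amino-acid (or nucleotide) strings; names are taxon ids.
#'
#' @param x Named character vector, or a sequence data frame (`id`,
#'   `seq`) as from [read_sequences()].
#' @return Named character vector of class `alignment`.
#' @export
as_alignment <- function(x) {
  if (is.data.frame(x)) x <- stats::setNames(x$seq, x$id)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("alignment rows must be named by taxon id")
  }
  if (anyDuplicated(names(x))) stop("duplicated taxon ids in alignment")
  if (length(unique(nchar(x))) > 1L) {
    stop("alignment rows have unequal lengths")
  }
  structure(toupper(x), class = "alignment")
}

.aln_matrix <- function(aln) {
  if (!length(aln) || nchar(aln[1]) == 0L) {
    return(matrix(character(0), nrow = length(aln), ncol = 0,
                  dimnames = list(names(aln), NULL)))
  }
  do.call(rbind, strsplit(unclass(aln), ""))
}

#' Trim an alignment by end occupancy and column occupancy
#'
#' Two-stage trimming used to prepare alignments for tree inference:
#' first, leading and trailing columns are removed until a column with at
#' least `end_occupancy` non-gap characters is met (both ends); then,
#' within the remaining block, a column is retained iff its non-gap
#' fraction is at least `min_occupancy`. A column occupied in exactly
#' `min_occupancy` of the rows is therefore kept.
#'
#' @param aln An [as_alignment()] object.
#' @param min_occupancy Column occupancy threshold (default 0.10).
#' @param end_occupancy Occupancy defining the trusted ends (default 0.5).
#'
#' @return Trimmed `alignment`; attribute `kept_cols` holds the original
#'   1-based column indices retained. May be zero-width.
#' @export
trim_alignment <- function(aln, min_occupancy = 0.10,
                           end_occupancy = 0.5) {
  aln <- as_alignment(aln)
  m <- .aln_matrix(aln)
  if (ncol(m) == 0L) return(aln)
  occ <- colMeans(m != "-")
  solid <- which(occ >= end_occupancy)
  if (!length(solid)) {
    out <- as_alignment(stats::setNames(rep("", length(aln)), names(aln)))
    attr(out, "kept_cols") <- integer(0)
    return(out)
  }
  range_cols <- solid[1]:solid[length(solid)]
  kept <- range_cols[occ[range_cols] >= min_occupancy]
  out <- as_alignment(stats::setNames(
    apply(m[, kept, drop = FALSE], 1L, paste, collapse = ""),
    names(aln)))
  attr(out, "kept_cols") <- kept
  out
}

#' Concatenate alignments over a shared taxon set
#'
#' Row-wise concatenation keyed by taxon id (row order of later parts is
#' irrelevant). All parts must contain exactly the same taxa.
#'
#' @param parts List of [as_alignment()] objects.
#' @return Concatenated `alignment` in the taxon order of the first part;
#'   attribute `partitions` is a data frame (`part`, `start`, `end`) of
#'   1-based column ranges for partition files.
#' @export
concat_alignments <- function(parts) {
  stopifnot(length(parts) >= 1L)
  parts <- lapply(parts, as_alignment)
  taxa <- names(parts[[1]])
  for (i in seq_along(parts)[-1]) {
    extra <- setdiff(names(parts[[i]]), taxa)
    missing <- setdiff(taxa, names(parts[[i]]))
    if (length(extra) || length(missing)) {
      stop("taxon mismatch in part ", i, ": ",
           if (length(missing)) paste("missing", paste(missing,
                                                       collapse = ", ")),
           if (length(extra)) paste(" extra", paste(extra,
                                                    collapse = ", ")))
    }
  }
  widths <- vapply(parts, function(p) nchar(p[[1]]), 0)
  joined <- vapply(taxa, function(tx) {
    paste(vapply(parts, function(p) unclass(p)[[tx]], ""), collapse = "")
  }, "")
  out <- as_alignment(stats::setNames(joined, taxa))
  ends <- cumsum(widths)
  part_names <- names(parts)
  if (is.null(part_names)) part_names <- paste0("part", seq_along(parts))
  attr(out, "partitions") <- data.frame(
    part = part_names, start = c(1, utils::head(ends, -1) + 1),
    end = ends, stringsAsFactors = FALSE)
  out
}

#' Pairwise percent identity over an alignment
#'
#' Identity between two rows is the number of identical characters divided
#' by the number of columns where both rows have a non-gap character.
#' Pairs with no co-occupied columns are reported as `NA`.
#'
#' @param aln An [as_alignment()] object with at least two rows.
#' @return Symmetric numeric matrix (percent, diagonal 100).
#' @export
pairwise_identity <- function(aln) {
  aln <- as_alignment(aln)
  if (length(aln) < 2L) stop("need at least two alignment rows")
  m <- .aln_matrix(aln)
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(names(aln), names(aln)))
  gap <- m == "-"
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      co <- !gap[a, ] & !gap[b, ]
      out[a, b] <- out[b, a] <- if (!any(co)) NA_real_ else
        100 * sum(m[a, co] == m[b, co]) / sum(co)
    }
  }
  out
}

#' Write an alignment to aligned FASTA or relaxed PHYLIP
#'
#' @param aln An [as_alignment()] object.
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"` (relaxed: name, space, row).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  aln <- as_alignment(aln)
  if (format == "fasta") {
    return(write_sequences(
      data.frame(id = names(aln), seq = unclass(aln),
                 stringsAsFactors = FALSE), path, format = "fasta"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln), nchar(aln[[1]])), con)
  writeLines(paste(names(aln), unclass(aln)), con)
  invisible(path)
}

#' Read an alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file.
#' @return An [as_alignment()] object.
#' @export
read_alignment <- function(path) {
  as_alignment(read_sequences(path, format = "fasta"))
}

#' Write a NEXUS-style partition (sets) block
#'
#' @param aln A concatenated alignment from [concat_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(aln, path) {
  parts <- attr(aln, "partitions")
  if (is.null(parts)) stop("alignment carries no partition attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#nexus", con)
  writeLines("begin sets;", con)
  writeLines(sprintf("  charset %s = %d-%d;", parts$part, parts$start,
                     parts$end), con)
  writeLines("end;", con)
  invisible(path)
}

#' Export ORF annotations as GFF3
#'
#' @param annotation Result of [find_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
orfs_to_gff <- function(annotation, path) {
  orfs <- annotation$orfs
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "evescreen"
  S4Vectors::mcols(gr)$ID <- sprintf("%s_orf%d", annotation$contig_id,
                                     seq_len(nrow(orfs)))
  S4Vectors::mcols(gr)$Name <- orfs$label
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
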