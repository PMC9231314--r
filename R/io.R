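#' Read sequences from FASTA or FASTQ
#'
#' Reads a sequence file into a plain data frame with one row per record.
#' Parsing is delegated to \pkg{Biostrings}; this wrapper normalises case,
#' keeps records in file order and enforces the FASTQ contract that the
#' quality string has the same length as the sequence.
#'
#' @param path Path to an uncompressed FASTA or FASTQ file.
#' @param format Either `"fasta"` or `"fastq"`.
#'
#' @return A data frame with columns `id` (first whitespace-delimited token
#'   of the header), `desc` (remainder of the header, possibly empty) and
#'   `seq` (upper-case sequence). FASTQ input adds a `qual` column
#'   (Sanger/Phred+33 quality string). An empty file yields a zero-row
#'   data frame.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    recs <- .headers_to_records(names(set), toupper(as.character(set)))
    if (any(!nzchar(recs$id))) {
      stop("FASTA parse error: empty record id in ", path)
    }
    return(recs)
  }
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    list(quals = as.character(S4Vectors::mcols(set)$qualities),
         seqs = toupper(as.character(set)), names = names(set))
  }, error = function(e) {
    stop("FASTQ parse error in ", path,
         " (malformed record or quality length mismatch): ",
         conditionMessage(e))
  })
  quals <- parsed$quals
  seqs <- parsed$seqs
  # byte-wise lengths: malformed records can yield non-UTF8 quality bytes
  bad <- which(nchar(quals, type = "bytes") !=
                 nchar(seqs, type = "bytes"))
  if (length(bad)) {
    # 4-line FASTQ records: quality line of record i is line 4 * i
    stop("FASTQ parse error near line ", 4L * bad[1],
         ": quality length != sequence length")
  }
  recs <- .headers_to_records(parsed$names, seqs)
  recs$qual <- unname(quals)
  recs
}

.headers_to_records <- function(headers, seqs) {
  headers <- if (is.null(headers)) character(length(seqs)) else headers
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  data.frame(id = id, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records Data frame with columns `id`, `seq` and optionally `desc`
#'   (FASTA header remainder) and `qual` (required for FASTQ).
#' @param path Output file path.
#' @param format `"fasta"` (wrapped at `wrap` columns) or `"fastq"`.
#' @param wrap FASTA line width; fixed default 80 for reproducible output.
#'
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq"),
                            wrap = 80L) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  header <- records$id
  if (!is.null(records$desc)) {
    header <- ifelse(nzchar(records$desc),
                     paste(records$id, records$desc), records$id)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_len(nrow(records))) {
      writeLines(paste0(">", header[i]), con)
      s <- records$seq[i]
      starts <- seq(1L, max(nchar(s), 1L), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
    }
  } else {
    if (is.null(records$qual)) {
      stop("FASTQ output requires a 'qual' column")
    }
    if (any(nchar(records$qual) != nchar(records$seq))) {
      stop("quality length != sequence length")
    }
    writeLines(paste0("@", header, "\n", records$seq, "\n+\n", records$qual),
               con)
  }
  invisible(path)
}

#' Parse a printed coordinate string
#'
#' Parses the `"SEQID:START-END"` dialect used in EVE report tables into a
#' genomic interval. The printed pair is interpreted so that the interval
#' span equals `END - START`; internally coordinates are 0-based,
#' half-open (`start = START`, `end = END`).
#'
#' @param text Character vector of coordinate strings.
#'
#' @return A data frame with columns `seq_id`, `start`, `end`, `strand`
#'   (always `"."`) and `span`.
#' @export
parse_coordinate_string <- function(text) {
  m <- regmatches(text, regexec("^(.+):([0-9]+)-([0-9]+)$", text))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("coordinate parse error: '", text[bad][1],
         "' does not match SEQID:START-END")
  }
  seq_id <- vapply(m, `[`, "", 2L)
  start <- as.numeric(vapply(m, `[`, "", 3L))
  end <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(end <= start)) {
    i <- which(end <= start)[1]
    stop("coordinate dialect error: END <= START in '", text[i], "'")
  }
  data.frame(seq_id = seq_id, start = start, end = end, strand = ".",
             span = end - start, stringsAsFactors = FALSE)
}

.OUTFMT6_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                   "mismatches", "gap_opens", "q_start", "q_end",
                   "s_start", "s_end", "evalue", "bitscore")

#' Read a 12-column tabular homology hit file
#'
#' Reads hits in the standard 12-column tab-separated dialect
#' (BLAST/DIAMOND `outfmt 6` column order), as produced by external
#' translated-search runs, so they can be plugged into the EVE caller in
#' place of the built-in search.
#'
#' @param path Path to a tab-separated file, 12 columns, no header.
#'
#' @return Data frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`. Query/subject
#'   coordinates are 1-based inclusive as in the dialect.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (is.null(nf) || length(nf) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12), .OUTFMT6_COLS))
    return(.type_tabular(out))
  }
  if (any(nf != 12L)) {
    stop("tabular parse error at row ", which(nf != 12L)[1],
         ": expected 12 columns, found ", nf[nf != 12L][1])
  }
  out <- utils::read.table(path, sep = "\t", quote = "",
                           col.names = .OUTFMT6_COLS,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  .type_tabular(out)
}

.type_tabular <- function(x) {
  num <- c("pct_identity", "evalue", "bitscore")
  int <- c("aln_length", "mismatches", "gap_opens",
           "q_start", "q_end", "s_start", "s_end")
  for (cc in num) x[[cc]] <- as.numeric(x[[cc]])
  for (cc in int) x[[cc]] <- as.integer(x[[cc]])
  if (any(is.na(x$pct_identity)) ||
      any(x$pct_identity < 0 | x$pct_identity > 100)) {
    stop("tabular parse error: pct_identity outside [0, 100]")
  }
  if (any(is.na(x$aln_length)) || any(x$aln_length < 1L)) {
    stop("tabular parse error: aln_length < 1")
  }
  x
}

#' Write hits in the 12-column tabular dialect
#'
#' @param hits Data frame as returned by [read_tabular_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  stopifnot(all(.OUTFMT6_COLS %in% names(hits)))
  utils::write.table(hits[, .OUTFMT6_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert external tabular hits to internal translated-hit records
#'
#' Maps the 1-based inclusive nucleotide query coordinates of the tabular
#' dialect onto the internal 0-based half-open convention, inferring strand
#' and frame from the orientation of `q_start`/`q_end`.
#'
#' @param rows Data frame from [read_tabular_hits()] where the query is a
#'   genome contig (nucleotide coordinates) and the subject a protein.
#' @param taxonomy Optional data frame with columns `protein_id`, `family`,
#'   `protein_class` used to label subjects.
#'
#' @return A translated-hit data frame as produced by [translated_search()].
#' @export
tabular_to_hits <- function(rows, taxonomy = NULL) {
  fwd <- rows$q_start <= rows$q_end
  start <- ifelse(fwd, rows$q_start - 1L, rows$q_end - 1L)
  end <- ifelse(fwd, rows$q_end, rows$q_start)
  frame_off <- (start %% 3L) + 1L
  hits <- data.frame(
    seq_id = rows$query_id,
    start = as.numeric(start),
    end = as.numeric(end),
    strand = ifelse(fwd, "+", "-"),
    frame = as.integer(ifelse(fwd, frame_off, -frame_off)),
    subject_id = rows$subject_id,
    subject_family = NA_character_,
    subject_protein_class = NA_character_,
    pct_identity = rows$pct_identity,
    score = rows$bitscore,
    aln_len_aa = rows$aln_length,
    stringsAsFactors = FALSE
  )
  if (!is.null(taxonomy)) {
    i <- match(hits$subject_id, taxonomy$protein_id)
    hits$subject_family <- taxonomy$family[i]
    hits$subject_protein_class <- taxonomy$protein_class[i]
  }
  hits
}
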