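#' Count read placements per feature
#'
#' Collapses read placements to one count per feature. A read placed on
#' several features is counted once, toward its best placement (highest
#' `score`); reads whose best placement is tied between features are
#' dropped entirely. Without a `score` column every multi-placed read is a
#' tie and is dropped.
#'
#' @param placements Data frame with columns `read_id`, `feature_id` and
#'   optionally `score`.
#' @param features Data frame with `feature_id` (and typically
#'   `length_nt`); placements on unknown features are an error.
#'
#' @return `features` with a `count` column appended (zero for features
#'   without placements).
#' @export
count_reads <- function(placements, features) {
  stopifnot(all(c("feature_id") %in% names(features)))
  counts <- stats::setNames(rep(0, nrow(features)), features$feature_id)
  if (nrow(placements)) {
    unknown <- setdiff(placements$feature_id, features$feature_id)
    if (length(unknown)) {
      stop("placement on unknown feature: ", unknown[1])
    }
    score <- if (!is.null(placements$score)) placements$score else
      rep(0, nrow(placements))
    keep <- vapply(split(seq_len(nrow(placements)), placements$read_id),
                   function(idx) {
                     if (length(idx) == 1L) return(idx)
                     s <- score[idx]
                     best <- idx[s == max(s)]
                     feats <- unique(placements$feature_id[best])
                     if (length(feats) > 1L) NA_integer_ else best[1]
                   }, 0L)
    keep <- keep[!is.na(keep)]
    if (length(keep)) {
      tab <- table(placements$feature_id[keep])
      counts[names(tab)] <- as.numeric(tab)
    }
  }
  features$count <- unname(counts[features$feature_id])
  features
}

#' Read placements from minimal SAM text
#'
#' Parses uncompressed SAM text just deeply enough to recover (read,
#' reference, mapping quality) triples: header lines are skipped, unmapped
#' records (`RNAME == "*"` or flag bit 0x4) are dropped, and `MAPQ` is
#' exposed as the placement score.
#'
#' @param path Path to a SAM text file.
#' @return Data frame `read_id`, `feature_id`, `score` suitable for
#'   [count_reads()].
#' @export
read_sam_placements <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(read_id = character(0), feature_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 11L
  if (any(short)) {
    stop("SAM parse error at record ", which(short)[1],
         ": fewer than 11 fields")
  }
  out <- data.frame(
    read_id = vapply(fields, `[`, "", 1L),
    flag = as.integer(vapply(fields, `[`, "", 2L)),
    feature_id = vapply(fields, `[`, "", 3L),
    score = as.numeric(vapply(fields, `[`, "", 5L)),
    stringsAsFactors = FALSE)
  out <- out[out$feature_id != "*" & bitwAnd(out$flag, 4L) == 0L, ,
             drop = FALSE]
  out$flag <- NULL
  rownames(out) <- NULL
  out
}

#' Transcripts per million over CDS features
#'
#' `TPM_i = 1e6 * (count_i / length_i) / sum_j (count_j / length_j)`.
#' The denominator uses only the supplied feature set, so TPM values sum
#' to one million per sample by construction.
#'
#' @param counts Numeric vector of read counts (named by feature), or a
#'   features-by-samples matrix of counts.
#' @param length_nt Feature lengths in nucleotides, aligned with the rows
#'   of `counts`.
#'
#' @return Numeric vector (or matrix) of TPM values, same shape and names
#'   as `counts`.
#' @export
tpm <- function(counts, length_nt) {
  if (any(length_nt < 1)) stop("feature lengths must be >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.matrix(counts)) {
    return(apply(counts, 2L, tpm, length_nt = length_nt))
  }
  if (sum(counts) == 0) stop("no expressed features")
  rate <- counts / length_nt
  1e6 * rate / sum(rate)
}

#' Expression ratios against a housekeeping gene
#'
#' `ratio = TPM_target / TPM_housekeeping`, rounded half-even to
#' `round_dp` decimals (the rounding used for printed report tables).
#'
#' @param tpm_values Named TPM vector or features-by-samples TPM matrix.
#' @param targets Feature ids to report ratios for.
#' @param housekeeping Housekeeping feature id (TPM must be positive).
#' @param round_dp Decimal places (default 3); `NULL` disables rounding.
#'
#' @return Named numeric vector (or targets-by-samples matrix) of ratios.
#' @export
expression_ratio <- function(tpm_values, targets, housekeeping,
                             round_dp = 3L) {
  if (is.matrix(tpm_values)) {
    out <- vapply(colnames(tpm_values), function(s) {
      expression_ratio(tpm_values[, s], targets, housekeeping, round_dp)
    }, numeric(length(targets)))
    if (length(targets) == 1L) {
      out <- matrix(out, nrow = 1L,
                    dimnames = list(targets, colnames(tpm_values)))
    }
    return(out)
  }
  hk <- tpm_values[[housekeeping]]
  if (is.null(hk) || is.na(hk) || hk <= 0) {
    stop("housekeeping TPM must be positive")
  }
  r <- tpm_values[targets] / hk
  if (!is.null(round_dp)) r <- round(r, round_dp)
  stats::setNames(as.numeric(r), targets)
}

#' Build a TPM table with housekeeping ratios
#'
#' Convenience wrapper producing a report in the layout of a printed
#' abundance table: TPM per feature and sample, plus the ratio of each
#' target to the housekeeping gene.
#'
#' @param counts Features-by-samples count matrix (rownames = feature
#'   ids).
#' @param length_nt Feature lengths aligned with rows.
#' @param housekeeping Housekeeping feature id.
#' @param round_dp Decimals for ratios.
#'
#' @return List with `tpm` (matrix), `ratios` (targets-by-samples matrix
#'   over all non-housekeeping features) and `housekeeping`.
#' @export
tpm_table <- function(counts, length_nt, housekeeping, round_dp = 3L) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (!housekeeping %in% rownames(counts)) {
    stop("unknown housekeeping feature: ", housekeeping)
  }
  tt <- tpm(counts, length_nt)
  targets <- setdiff(rownames(counts), housekeeping)
  list(tpm = tt,
       ratios = expression_ratio(tt, targets, housekeeping, round_dp),
       housekeeping = housekeeping)
}
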