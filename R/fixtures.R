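#' Load a packaged report-table fixture
#'
#' The package ships the curated report tables of the black soldier fly
#' virome study as plain TSV fixtures (with JSON schema sidecars under
#' `extdata/`): `"table1"` — 27 EVE records with coordinate strings;
#' `"table2"` — the 5 RNA-seq datasets carrying near-complete virus
#' contigs; `"table3"` — TPM values for the viral \emph{pol}/\emph{gag}
#' CDS features and \emph{Actin-5C}. Fixtures are validated against their
#' invariants at load time and treated as canonical: any violation is a
#' hard error.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#'
#' @return For `"table1"`, an EVE record data frame (columns `name`,
#'   `assembly`, `seq_id`, `start`, `end`, `span`, `family`,
#'   `best_hit_subject`, `best_hit_pct_identity`, `protein_class`,
#'   `locus_label`) compatible with [summarize_eves()] and
#'   [locus_presence()]. For `"table2"`, the records data frame. For
#'   `"table3"`, a features-by-samples TPM matrix.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", switch(name,
                                        table1 = "table1_eves.tsv",
                                        table2 = "table2_contigs.tsv",
                                        table3 = "table3_tpm.tsv"),
                      package = "evescreen", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  switch(name,
         table1 = .load_table1(raw),
         table2 = .load_table2(raw),
         table3 = .load_table3(raw))
}

.load_table1 <- function(raw) {
  if (nrow(raw) != 27L) {
    stop("fixture invariant violated: table1 must have 27 records, found ",
         nrow(raw))
  }
  allowed <- c("PT", "PR1", "PR2", "PR3", "Rh", "T1", "T2", "T3", "Xi",
               "np")
  bad <- setdiff(unique(raw$locus_label), allowed)
  if (length(bad)) {
    stop("fixture invariant violated: unknown locus label ", bad[1])
  }
  coords <- parse_coordinate_string(raw$coordinates)
  out <- data.frame(
    name = raw$eve_name, assembly = paste0("BGA", raw$bga),
    seq_id = coords$seq_id, start = coords$start, end = coords$end,
    span = coords$span, family = raw$family,
    best_hit_subject = raw$best_hit,
    best_hit_pct_identity = raw$aa_pct,
    protein_class = raw$protein_class, locus_label = raw$locus_label,
    stringsAsFactors = FALSE)
  out
}

.load_table2 <- function(raw) {
  if (nrow(raw) != 5L) {
    stop("fixture invariant violated: table2 must have 5 records, found ",
         nrow(raw))
  }
  raw
}

.load_table3 <- function(raw) {
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw$feature
  storage.mode(m) <- "numeric"
  if (length(m) != 15L || anyNA(m)) {
    stop("fixture invariant violated: table3 must have 15 numeric cells")
  }
  sums <- colSums(m)
  if (any(abs(sums - 1e6) > 1e-6 * 1e6)) {
    stop("fixture invariant violated: TPM columns must sum to 1,000,000")
  }
  m
}
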