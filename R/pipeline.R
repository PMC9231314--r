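#' Default pipeline configuration
#'
#' Central defaults for every stage. Interval, flank and occupancy
#' thresholds carry the values the screening protocol fixes (merge gap
#' < 50 bp, >= 50 bp host flank, 20 kb orthology windows, 98 percent
#' orthology identity, 10 percent alignment column occupancy, 5 kb
#' near-complete contig bar, 3-decimal ratios); search sensitivity
#' parameters (`kmer_k`, `min_score`, `min_aln_len_aa`, `x_drop`) are
#' this implementation's own calibration of its seed-and-extend engine.
#'
#' @param ... Named overrides.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(kmer_k = 3L, min_score = 80, min_aln_len_aa = 15L,
              x_drop = 20, max_gap_nt = 50L, min_flank_nt = 50L,
              window_nt = 20000L, min_identity_pct = 98,
              min_flank_match_nt = 50L, flank_nt = 500L,
              min_occupancy = 0.10, end_occupancy = 0.5,
              near_complete_min_nt = 5000L, orf_min_len_aa = 200L,
              round_dp = 3L, read_len = 100L, seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Generate the reference synthetic EVE screening dataset
#'
#' Builds the full study-condition scenario with known ground truth:
#' three host assemblies (the third, `BGA3`, acts as the chromosome-level
#' reference) carrying nine EVE loci from five viral families. Five loci
#' (three Totiviridae, one Partitiviridae, one Rhabdoviridae) are
#' orthologous across all three assemblies with conserved flanks; two
#' Parvoviridae loci are shared by two assemblies, and one Parvoviridae
#' and the Xinmoviridae locus are private to the reference. Planted
#' nucleotide identities span 0.60-1.00, with older (lower-identity)
#' insertions given longer fragments, mirroring decayed but sizeable
#' genomic fossils. Optionally adds a flankless all-viral contig
#' (sequencing-contamination mimic, expected to be removed by the
#' contamination filter) and a host-proteome "decoy" insert (expected to
#' be removed by the false-positive screen).
#'
#' @param seed Integer master seed.
#' @param contig_len Host contig length (default 24 kb; conserved flank
#'   windows clip to the contig).
#' @param with_contamination Add the flankless viral contig to `BGA2`.
#' @param with_decoy Add the decoy insert and its host-proteome copy.
#' @param n_host_proteins Size of the host proteome.
#'
#' @return List with `assemblies`, `proteome`, `host_proteome`, `truth`
#'   (planted EVE data frame with `expect_call` and `expect_discard`
#'   columns) and `seed`.
#' @export
simulate_eve_dataset <- function(seed = 1L, contig_len = 24000L,
                                 with_contamination = TRUE,
                                 with_decoy = TRUE,
                                 n_host_proteins = 10L) {
  families <- c("Partitiviridae", "Parvoviridae", "Rhabdoviridae",
                "Totiviridae", "Xinmoviridae")
  proteome <- generate_viral_proteome(2L, families, mean_len_aa = 450L,
                                      seed = seed)
  all3 <- c("BGA1", "BGA2", "BGA3")
  # nine loci: family, source protein, fragment length (aa), identity,
  # carrying assemblies; lower identity <-> longer fragment
  loci <- list(
    list("Totiviridae",    "VP_Totiviridae_1",    100L, 1.00, all3),
    list("Totiviridae",    "VP_Totiviridae_2",    150L, 0.90, all3),
    list("Totiviridae",    "VP_Totiviridae_1",    220L, 0.80, all3),
    list("Partitiviridae", "VP_Partitiviridae_1", 180L, 0.85, all3),
    list("Rhabdoviridae",  "VP_Rhabdoviridae_1",  260L, 0.75, all3),
    list("Parvoviridae",   "VP_Parvoviridae_1",   120L, 0.95,
         c("BGA2", "BGA3")),
    list("Parvoviridae",   "VP_Parvoviridae_2",   300L, 0.70,
         c("BGA1", "BGA3")),
    list("Parvoviridae",   "VP_Parvoviridae_1",   380L, 0.60, "BGA3"),
    list("Xinmoviridae",   "VP_Xinmoviridae_1",   340L, 0.65, "BGA3"))
  pos <- as.integer(floor(contig_len * 11 / 24))
  specs <- lapply(seq_along(loci), function(i) {
    l <- loci[[i]]
    eve_plant_spec(family = l[[1]], source_protein_id = l[[2]],
                   fragment_aa_range = c(1L, l[[3]]),
                   target_nt_identity = l[[4]],
                   insert_contig = sprintf("contig%d", i),
                   insert_pos = pos,
                   present_in_assemblies = l[[5]],
                   flank_conserved = TRUE)
  })
  n_core <- 9L
  lens <- list(BGA1 = rep(contig_len, n_core),
               BGA2 = rep(contig_len, n_core),
               BGA3 = rep(contig_len, n_core))
  if (with_contamination) {
    # all-viral contig: a 150 aa fragment with < 50 nt flank on each side
    lens$BGA2 <- c(lens$BGA2, 150L * 3L + 60L)
    specs[[length(specs) + 1L]] <- eve_plant_spec(
      family = "Totiviridae", source_protein_id = "VP_Totiviridae_2",
      fragment_aa_range = c(1L, 150L), target_nt_identity = 1.0,
      insert_contig = sprintf("contig%d", n_core + 1L), insert_pos = 30L,
      present_in_assemblies = "BGA2", flank_conserved = FALSE)
  }
  decoy_protein <- "VP_Xinmoviridae_2"  # not a source of any real locus
  if (with_decoy) {
    k <- length(lens$BGA1) + 1L
    lens$BGA1 <- c(lens$BGA1, contig_len)
    specs[[length(specs) + 1L]] <- eve_plant_spec(
      family = "Xinmoviridae", source_protein_id = decoy_protein,
      fragment_aa_range = c(1L, 200L), target_nt_identity = 1.0,
      insert_contig = sprintf("contig%d", k), insert_pos = pos,
      present_in_assemblies = "BGA1", flank_conserved = FALSE)
  }
  asm_specs <- lapply(lens, function(l) list(n_contigs = length(l),
                                             contig_len = l))
  ds <- plant_eves(asm_specs, specs, proteome, seed = seed + 1L)
  decoys <- if (with_decoy) {
    proteome$proteins[proteome$proteins$id == decoy_protein, ,
                      drop = FALSE]
  } else NULL
  host <- generate_host_proteome(n_host_proteins, seed = seed + 2L,
                                 decoys = decoys)
  truth <- ds$truth$planted_eves
  truth$expect_discard <- ""
  if (with_contamination) {
    contam <- truth$assembly == "BGA2" &
      truth$seq_id == sprintf("contig%d", n_core + 1L)
    truth$expect_discard[contam] <- "no host flank"
  }
  if (with_decoy) {
    dec <- truth$assembly == "BGA1" & truth$locus_id == length(specs)
    truth$expect_discard[dec] <- "host screen"
  }
  truth$expect_call <- truth$expect_discard == "" & truth$detectable
  list(assemblies = ds$assemblies, proteome = proteome,
       host_proteome = host, truth = truth, seed = seed)
}

#' Compare EVE calls against planted ground truth
#'
#' A truth insertion counts as recovered when at least one call of the
#' same family overlaps its interval on the right assembly and contig; a
#' call is a false positive when it overlaps no truth insertion at all
#' (of any family). Fragmented calls over one insertion are not penalized.
#'
#' @param records EVE record data frame from [call_eves()].
#' @param truth Planted-EVE truth data frame (needs `assembly`, `seq_id`,
#'   `start`, `end`, `family`, `expect_call`).
#'
#' @return List with `recall` (fraction of `expect_call` insertions
#'   recovered), `n_expected`, `n_recovered`, `false_positives` (count)
#'   and per-row logical vectors `recovered` / `is_fp`.
#' @export
evaluate_calls <- function(records, truth) {
  exp_rows <- which(truth$expect_call)
  recovered <- vapply(exp_rows, function(i) {
    any(records$assembly == truth$assembly[i] &
          records$seq_id == truth$seq_id[i] &
          records$family == truth$family[i] &
          pmax(records$start, truth$start[i]) <
          pmin(records$end, truth$end[i]))
  }, logical(1))
  is_fp <- vapply(seq_len(nrow(records)), function(j) {
    !any(truth$assembly == records$assembly[j] &
           truth$seq_id == records$seq_id[j] &
           pmax(truth$start, records$start[j]) <
           pmin(truth$end, records$end[j]))
  }, logical(1))
  list(recall = if (length(exp_rows)) mean(recovered) else NA_real_,
       n_expected = length(exp_rows), n_recovered = sum(recovered),
       false_positives = sum(is_fp), recovered = recovered,
       is_fp = is_fp)
}

#' Build a synthetic totivirus-like contig
#'
#' Constructs a double-ORF contig with the canonical totivirus layout: a
#' 5'-proximal GAG (capsid) ORF and a longer 3' POL (RdRP) ORF, separated
#' and flanked by stop-codon-rich spacers so no spurious ORF spans the
#' planted ones. Coordinates of both ORFs are returned as ground truth.
#'
#' @param gag_len_aa GAG length in amino acids (including the initial M,
#'   excluding the stop).
#' @param pol_len_aa POL length in amino acids.
#' @param total_nt Total contig length; remaining space becomes UTRs.
#' @param seed Integer seed.
#' @param id Contig id.
#'
#' @return List with `contig` (one-row sequence data frame) and `truth`
#'   (data frame of planted ORF coordinates, 0-based half-open, stop
#'   included).
#' @export
make_totivirus_contig <- function(gag_len_aa = 600L, pol_len_aa = 1300L,
                                  total_nt = 7247L, seed = 1L,
                                  id = "toti_contig") {
  .with_seed(seed, {
    stopblock <- "TAGATAGATAGA"  # stops in all three forward frames
    orf_nt <- function(len_aa) {
      aa <- paste0("M", paste(sample(setdiff(.AA20, "M"), len_aa - 1L,
                                     replace = TRUE), collapse = ""))
      paste0(reverse_translate(aa), "TAA")
    }
    gag <- orf_nt(gag_len_aa)
    pol <- orf_nt(pol_len_aa)
    core <- sum(nchar(gag), nchar(pol), 3L * nchar(stopblock))
    pad <- total_nt - core
    if (pad < 0L) stop("total_nt too small for the requested ORFs")
    utr5 <- floor(pad / 2)
    utr3 <- pad - utr5
    seq <- paste0(.random_dna(utr5), stopblock, gag, stopblock, pol,
                  stopblock, .random_dna(utr3))
    gag_start <- utr5 + nchar(stopblock)
    pol_start <- gag_start + nchar(gag) + nchar(stopblock)
    truth <- data.frame(
      label = c("GAG", "POL"),
      start = c(gag_start, pol_start),
      end = c(gag_start + nchar(gag), pol_start + nchar(pol)),
      len_aa = c(gag_len_aa, pol_len_aa), stringsAsFactors = FALSE)
    list(contig = data.frame(id = id, desc = "synthetic totivirus-like",
                             seq = seq, stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Map error-free reads to features by exact substring search
#'
#' A deliberately simple internal mapper for synthetic, error-free reads:
#' a read is placed on every feature whose sequence contains it as an
#' exact forward-strand substring. Placement scores are constant, so
#' reads matching several features are ties and are dropped by
#' [count_reads()].
#'
#' @param reads Read data frame (`id`, `seq`), e.g. from
#'   [simulate_reads()].
#' @param features Feature data frame (`feature_id`, `seq`).
#' @return Placement data frame `read_id`, `feature_id`, `score`.
#' @export
map_reads <- function(reads, features) {
  out <- list()
  for (j in seq_len(nrow(features))) {
    hit <- which(vapply(reads$seq, function(r) {
      grepl(r, features$seq[j], fixed = TRUE)
    }, logical(1)))
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = reads$id[hit], feature_id = features$feature_id[j],
        score = 1, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(0), feature_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read a pipeline configuration from YAML
#'
#' Values found in the file override the defaults of [default_config()];
#' unknown keys are kept (stages ignore what they do not use).
#'
#' @param path Path to a YAML file of configuration keys.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Run a pipeline stage
#'
#' Thin orchestration over the package functions with file-based inputs
#' and outputs, deterministic under `config$seed`. A run manifest
#' (configuration, package version, input checksums) is written next to
#' the results.
#'
#' @param command One of `"simulate"`, `"find-eves"`, `"assign-loci"`,
#'   `"annotate-virus"`, `"quantify"`, `"report"`.
#' @param config Configuration list from [default_config()], plus paths:
#'   `out_dir` always; `assembly_paths` (named FASTA vector) and
#'   `viral_proteome_path`/`taxonomy_path`/`host_proteome_path` for
#'   `find-eves`; `eve_tsv` for `assign-loci`; `contigs_path` for
#'   `annotate-virus`; `counts_path` (TSV: feature, length_nt, then one
#'   column per sample) and `housekeeping` for `quantify`.
#'
#' @return Invisible list of the stage's main results; files are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(command = c("simulate", "find-eves",
                                     "assign-loci", "annotate-virus",
                                     "quantify", "report"),
                         config = default_config()) {
  command <- match.arg(command)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(
    command,
    "simulate" = .stage_simulate(config),
    "find-eves" = .stage_find_eves(config),
    "assign-loci" = .stage_assign_loci(config),
    "annotate-virus" = .stage_annotate(config),
    "quantify" = .stage_quantify(config),
    "report" = .stage_report(config))
  .write_manifest(command, config)
  invisible(res)
}

.write_manifest <- function(command, config) {
  paths <- unlist(config[grepl("_path|_paths|_tsv", names(config))])
  sums <- if (length(paths)) {
    existing <- paths[file.exists(paths)]
    as.list(tools::md5sum(existing))
  } else list()
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("evescreen")),
    config = config[!vapply(config, is.function, logical(1))],
    input_md5 = sums)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.stage_simulate <- function(config) {
  ds <- simulate_eve_dataset(seed = config$seed)
  for (asm in names(ds$assemblies)) {
    write_sequences(ds$assemblies[[asm]],
                    file.path(config$out_dir, paste0(asm, ".fasta")))
  }
  write_sequences(ds$proteome$proteins,
                  file.path(config$out_dir, "viral_proteins.fasta"))
  utils::write.table(ds$proteome$taxonomy,
                     file.path(config$out_dir, "viral_taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sequences(ds$host_proteome,
                  file.path(config$out_dir, "host_proteins.fasta"))
  utils::write.table(ds$truth,
                     file.path(config$out_dir, "truth_planted_eves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ds
}

.read_assemblies <- function(config) {
  stats::setNames(lapply(config$assembly_paths, read_sequences),
                  names(config$assembly_paths))
}

.stage_find_eves <- function(config) {
  assemblies <- .read_assemblies(config)
  proteins <- read_sequences(config$viral_proteome_path)
  taxonomy <- utils::read.delim(config$taxonomy_path,
                                stringsAsFactors = FALSE)
  host <- if (!is.null(config$host_proteome_path)) {
    read_sequences(config$host_proteome_path)
  } else NULL
  recs <- call_eves(assemblies, proteins, host_proteome = host,
                    taxonomy = taxonomy,
                    params = config[c("kmer_k", "min_score",
                                      "min_aln_len_aa", "x_drop",
                                      "max_gap_nt", "min_flank_nt")])
  write_eve_tsv(cbind(recs[setdiff(names(recs), "seq")]),
                file.path(config$out_dir, "eve_calls.tsv"))
  if (nrow(recs)) {
    write_eve_bed(recs, file.path(config$out_dir, "eve_calls.bed"))
  }
  disc <- attr(recs, "discarded")
  if (!is.null(disc)) {
    utils::write.table(disc[setdiff(names(disc), c("seq", "hits"))],
                       file.path(config$out_dir, "eve_discarded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  recs
}

.stage_assign_loci <- function(config) {
  assemblies <- .read_assemblies(config)
  eves <- utils::read.delim(config$eve_tsv, stringsAsFactors = FALSE)
  ls <- assign_loci(eves, assemblies,
                    reference = config$reference,
                    min_identity_pct = config$min_identity_pct,
                    min_flank_match_nt = config$min_flank_match_nt,
                    window_nt = config$window_nt,
                    flank_nt = config$flank_nt)
  write_eve_tsv(ls$records,
                file.path(config$out_dir, "eve_calls_with_loci.tsv"))
  summ <- orthology_summary(ls)
  utils::write.table(
    data.frame(locus = rownames(summ$presence), summ$presence,
               members = summ$member_counts, check.names = FALSE),
    file.path(config$out_dir, "locus_presence.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  ls
}

.stage_annotate <- function(config) {
  contigs <- read_sequences(config$contigs_path)
  tri <- triage_viral_contigs(
    contigs, near_complete_min_nt = config$near_complete_min_nt,
    min_len_aa = config$orf_min_len_aa)
  utils::write.table(tri$report,
                     file.path(config$out_dir, "contig_triage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(tri$near_complete))) {
    ann <- find_orfs(tri$near_complete[i, ],
                     min_len_aa = config$orf_min_len_aa)
    orfs_to_gff(ann, file.path(config$out_dir,
                               paste0(ann$contig_id, "_orfs.gff3")))
  }
  tri
}

.stage_quantify <- function(config) {
  tab <- utils::read.delim(config$counts_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(counts) <- tab$feature
  tt <- tpm_table(counts, tab$length_nt, config$housekeeping,
                  round_dp = config$round_dp)
  utils::write.table(
    data.frame(feature = rownames(tt$tpm), round(tt$tpm, 3),
               check.names = FALSE),
    file.path(config$out_dir, "tpm.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(feature = rownames(tt$ratios), tt$ratios,
               check.names = FALSE),
    file.path(config$out_dir, "ratios.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tt
}

.stage_report <- function(config) {
  t1 <- load_fixture("table1")
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  s <- summarize_eves(t1, assembly_of_interest = "BGA3")
  summary_df <- data.frame(
    metric = c("total_eves", "span_min_nt", "span_max_nt",
               "distinct_loci", "bga3_chromosomes",
               "distinct_bioprojects"),
    value = c(s$total, s$span_min, s$span_max, s$n_loci,
              s$n_chromosomes, length(unique(t2$bioproject))))
  utils::write.table(summary_df,
                     file.path(config$out_dir, "report_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ratios <- expression_ratio(t3, c("pol", "gag"), "Actin-5C",
                             round_dp = config$round_dp)
  utils::write.table(
    data.frame(feature = rownames(ratios), ratios, check.names = FALSE),
    file.path(config$out_dir, "report_ratios.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  list(summary = summary_df, ratios = ratios)
}
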