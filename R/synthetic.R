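#' @useDynLib evescreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Run expr with a fixed seed without clobbering the caller's RNG stream.
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

.random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.random_aa <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

# codon table keyed by amino acid, stop codons excluded
.codons_by_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
      tab[["*"]] <<- NULL
    }
    tab
  }
})

#' Reverse-translate a protein with uniform codon choice
#'
#' Each residue is back-translated to one of its synonymous codons chosen
#' uniformly at random (standard genetic code, stops excluded). Uses the
#' current RNG stream; seed externally for reproducibility.
#'
#' @param aa Amino-acid string (20 standard letters).
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa) {
  tab <- .codons_by_aa()
  res <- strsplit(aa, "")[[1]]
  bad <- setdiff(unique(res), names(tab))
  if (length(bad)) stop("cannot reverse-translate residue(s): ",
                        paste(bad, collapse = ", "))
  paste(vapply(res, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
}

# Point-mutate nt string to an exact target identity (substitutions only).
.degrade_to_identity <- function(nt, target_identity) {
  n <- nchar(nt)
  n_mut <- round((1 - target_identity) * n)
  if (n_mut == 0L) {
    return(list(seq = nt, realized = 1))
  }
  chars <- strsplit(nt, "")[[1]]
  pos <- sample.int(n, n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), realized = 1 - n_mut / n)
}

#' Generate a labeled viral protein reference set
#'
#' Random i.i.d. amino-acid sequences labeled with a viral family and a
#' protein class (`Capsid`, `RdRP` or `ORF1`), emulating a family-annotated
#' viral protein database for translated homology search.
#'
#' @param n_per_family Number of proteins per family (>= 1).
#' @param families Character vector of family names, e.g. `"Totiviridae"`.
#' @param mean_len_aa Mean protein length in residues; individual lengths
#'   vary uniformly within +/- 20 percent.
#' @param seed Integer seed.
#'
#' @return A list with `proteins` (data frame `id`, `desc`, `seq`) and
#'   `taxonomy` (data frame `protein_id`, `family`, `protein_class`).
#' @export
generate_viral_proteome <- function(n_per_family, families,
                                    mean_len_aa = 300L, seed = 1L) {
  stopifnot(n_per_family >= 1L, length(families) >= 1L)
  .with_seed(seed, {
    classes <- c("Capsid", "RdRP", "ORF1")
    rows <- list()
    for (fam in families) {
      for (i in seq_len(n_per_family)) {
        len <- max(50L, round(stats::runif(1, 0.8, 1.2) * mean_len_aa))
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("VP_%s_%d", fam, i),
          family = fam,
          protein_class = classes[(i - 1L) %% 3L + 1L],
          seq = .random_aa(len),
          stringsAsFactors = FALSE
        )
      }
    }
    tab <- do.call(rbind, rows)
    list(
      proteins = data.frame(id = tab$id,
                            desc = paste(tab$family, tab$protein_class),
                            seq = tab$seq, stringsAsFactors = FALSE),
      taxonomy = data.frame(protein_id = tab$id, family = tab$family,
                            protein_class = tab$protein_class,
                            stringsAsFactors = FALSE)
    )
  })
}

#' Specify one EVE to plant in synthetic assemblies
#'
#' @param family Viral family of the source protein.
#' @param source_protein_id Id of a protein in the generated viral proteome.
#' @param fragment_aa_range Integer pair: 1-based inclusive residue range of
#'   the protein fragment to endogenize (length >= 30 aa).
#' @param target_nt_identity Nucleotide identity of the planted copy to its
#'   clean reverse-translation, in (0, 1]. Values below 0.3 are allowed but
#'   the ground truth marks them as not expected to be detectable.
#' @param insert_contig Contig name (e.g. `"contig1"`) to plant into.
#' @param insert_pos 0-based position at which the planted fragment starts
#'   (the host sequence there is replaced, keeping contig length fixed).
#' @param present_in_assemblies Character vector of assembly names carrying
#'   this insertion.
#' @param flank_conserved If `TRUE` and the EVE is present in more than one
#'   assembly, the insertion site and up to +/- 20 kb of flanking host
#'   sequence are made identical across those assemblies (orthologous
#'   insertion); the planted EVE sequence itself is shared too.
#'
#' @return A list of class `eve_plant_spec`.
#' @export
eve_plant_spec <- function(family, source_protein_id, fragment_aa_range,
                           target_nt_identity, insert_contig, insert_pos,
                           present_in_assemblies, flank_conserved = TRUE) {
  stopifnot(length(fragment_aa_range) == 2L,
            fragment_aa_range[2] >= fragment_aa_range[1])
  if (diff(fragment_aa_range) + 1L < 30L) {
    stop("EVE fragment must be at least 30 aa")
  }
  if (target_nt_identity <= 0 || target_nt_identity > 1) {
    stop("target_nt_identity must be in (0, 1]")
  }
  structure(list(family = family,
                 source_protein_id = source_protein_id,
                 fragment_aa_range = as.integer(fragment_aa_range),
                 target_nt_identity = target_nt_identity,
                 insert_contig = insert_contig,
                 insert_pos = as.integer(insert_pos),
                 present_in_assemblies = present_in_assemblies,
                 flank_conserved = isTRUE(flank_conserved)),
            class = "eve_plant_spec")
}

#' Plant degraded viral fragments into synthetic host assemblies
#'
#' Builds random host assemblies and overwrites specified regions with
#' reverse-translated, point-mutated fragments of viral proteins, recording
#' exact ground truth. Orthologous insertions (`flank_conserved`) share
#' both the realized EVE sequence and up to +/- `flank_window_nt` of host
#' flank across the carrying assemblies.
#'
#' @param assembly_specs Named list: assembly name -> list with `n_contigs`
#'   and `contig_len` (scalar or vector of per-contig lengths).
#' @param eve_specs List of [eve_plant_spec()] objects.
#' @param proteome Result of [generate_viral_proteome()] (or a compatible
#'   list with `proteins` and `taxonomy`).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of (specs, seed).
#' @param gc Host background GC content.
#' @param flank_window_nt Width of the conserved flank on each side for
#'   orthologous insertions (clipped at contig edges).
#'
#' @return List with `assemblies` (named list of sequence data frames as in
#'   [read_sequences()]) and `truth`, a list holding `planted_eves` (data
#'   frame: `assembly`, `seq_id`, `start`, `end`, `family`,
#'   `source_protein_id`, `protein_class`, `realized_identity`, `locus_id`,
#'   `flank_conserved`, `detectable`) and `seed`.
#' @export
plant_eves <- function(assembly_specs, eve_specs, proteome, seed = 1L,
                       gc = 0.5, flank_window_nt = 20000L) {
  .with_seed(seed, {
    assemblies <- lapply(assembly_specs, function(sp) {
      lens <- rep_len(sp$contig_len, sp$n_contigs)
      data.frame(id = sprintf("contig%d", seq_len(sp$n_contigs)),
                 desc = "",
                 seq = vapply(lens, .random_dna, "", gc = gc),
                 stringsAsFactors = FALSE)
    })
    truth <- list()
    placed <- list()  # per (assembly, contig): planted intervals
    for (k in seq_along(eve_specs)) {
      sp <- eve_specs[[k]]
      prot <- proteome$proteins[proteome$proteins$id == sp$source_protein_id, ]
      if (nrow(prot) != 1L) {
        stop("unknown source protein: ", sp$source_protein_id)
      }
      frag_aa <- substr(prot$seq, sp$fragment_aa_range[1],
                        sp$fragment_aa_range[2])
      clean_nt <- reverse_translate(frag_aa)
      deg <- .degrade_to_identity(clean_nt, sp$target_nt_identity)
      len <- nchar(deg$seq)
      conserved <- sp$flank_conserved && length(sp$present_in_assemblies) > 1L
      shared_left <- if (conserved) .random_dna(flank_window_nt, gc) else NULL
      shared_right <- if (conserved) .random_dna(flank_window_nt, gc) else NULL
      for (asm in sp$present_in_assemblies) {
        if (is.null(assemblies[[asm]])) stop("unknown assembly: ", asm)
        ctg <- match(sp$insert_contig, assemblies[[asm]]$id)
        if (is.na(ctg)) {
          stop("unknown contig '", sp$insert_contig, "' in assembly ", asm)
        }
        clen <- nchar(assemblies[[asm]]$seq[ctg])
        s <- sp$insert_pos
        e <- s + len
        if (s < 0L || e > clen) {
          stop("insert does not fit contig '", sp$insert_contig,
               "' of assembly ", asm)
        }
        key <- paste(asm, sp$insert_contig)
        prev <- placed[[key]]
        if (!is.null(prev) && any(pmax(prev$start, s) < pmin(prev$end, e))) {
          stop("insert overlaps a previous insert on ", key)
        }
        placed[[key]] <- rbind(prev, data.frame(start = s, end = e))
        seqchr <- assemblies[[asm]]$seq[ctg]
        if (conserved) {
          lw <- min(flank_window_nt, s)
          rw <- min(flank_window_nt, clen - e)
          substr(seqchr, s - lw + 1L, s) <-
            substr(shared_left, flank_window_nt - lw + 1L, flank_window_nt)
          if (rw > 0L) {
            substr(seqchr, e + 1L, e + rw) <- substr(shared_right, 1L, rw)
          }
        }
        # per-assembly private realization unless the locus is conserved
        ins <- if (conserved) deg else .degrade_to_identity(
          clean_nt, sp$target_nt_identity)
        substr(seqchr, s + 1L, e) <- ins$seq
        assemblies[[asm]]$seq[ctg] <- seqchr
        pc <- proteome$taxonomy$protein_class[
          match(sp$source_protein_id, proteome$taxonomy$protein_id)]
        truth[[length(truth) + 1L]] <- data.frame(
          assembly = asm, seq_id = sp$insert_contig,
          start = s, end = e, family = sp$family,
          source_protein_id = sp$source_protein_id,
          protein_class = if (is.na(pc)) NA_character_ else pc,
          realized_identity = ins$realized,
          locus_id = k, flank_conserved = conserved,
          detectable = ins$realized >= 0.3,
          stringsAsFactors = FALSE
        )
      }
    }
    planted <- if (length(truth)) do.call(rbind, truth) else data.frame()
    list(assemblies = assemblies,
         truth = list(planted_eves = planted, seed = seed))
  })
}

#' Generate a synthetic host proteome
#'
#' Host proteins are produced as translations of random stop-free host
#' ORFs. Optionally a "decoy" copy of a viral protein is appended to
#' exercise the discard path of the host-protein false-positive screen.
#'
#' @param n_proteins Number of host proteins.
#' @param mean_len_aa Mean length in residues.
#' @param seed Integer seed.
#' @param decoys Optional data frame (`id`, `seq`) of proteins to copy in
#'   verbatim; ids are prefixed `"decoy_"`.
#'
#' @return Data frame `id`, `desc`, `seq`.
#' @export
generate_host_proteome <- function(n_proteins, mean_len_aa = 350L,
                                   seed = 1L, decoys = NULL) {
  .with_seed(seed, {
    seqs <- vapply(seq_len(n_proteins), function(i) {
      len <- max(50L, round(stats::runif(1, 0.8, 1.2) * mean_len_aa))
      orf <- reverse_translate(.random_aa(len))
      as.character(Biostrings::translate(Biostrings::DNAString(orf)))
    }, "")
    out <- data.frame(id = sprintf("HOST_%04d", seq_len(n_proteins)),
                      desc = "host protein", seq = seqs,
                      stringsAsFactors = FALSE)
    if (!is.null(decoys) && nrow(decoys)) {
      out <- rbind(out, data.frame(id = paste0("decoy_", decoys$id),
                                   desc = "decoy viral protein copy",
                                   seq = decoys$seq,
                                   stringsAsFactors = FALSE))
    }
    out
  })
}

#' Simulate error-free RNA-seq reads with known abundances
#'
#' Draws exactly `true_count` error-free single-end reads per feature with
#' uniform start positions, for validating counting and TPM arithmetic.
#'
#' @param features Data frame with columns `feature_id`, `seq`,
#'   `true_count`.
#' @param read_len Read length; must not exceed the shortest feature.
#' @param seed Integer seed.
#'
#' @return List with `reads` (data frame `id`, `desc`, `seq`, `qual`;
#'   `desc` records the source feature) and `truth` (list with `counts`
#'   and normalized `proportions`, both named by feature).
#' @export
simulate_reads <- function(features, read_len = 100L, seed = 1L) {
  stopifnot(all(c("feature_id", "seq", "true_count") %in% names(features)))
  if (read_len > min(nchar(features$seq))) {
    stop("read_len exceeds the shortest feature sequence")
  }
  .with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(features))) {
      n <- features$true_count[i]
      if (n == 0L) next
      L <- nchar(features$seq[i])
      starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
      out[[i]] <- data.frame(
        id = sprintf("%s_read%d", features$feature_id[i], seq_len(n)),
        desc = features$feature_id[i],
        seq = substring(features$seq[i], starts, starts + read_len - 1L),
        qual = strrep("I", read_len),
        stringsAsFactors = FALSE
      )
    }
    reads <- do.call(rbind, out)
    counts <- stats::setNames(as.numeric(features$true_count),
                              features$feature_id)
    list(reads = reads,
         truth = list(counts = counts,
                      proportions = counts / sum(counts),
                      seed = seed))
  })
}
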