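test_that("flank windows are centered, clipped and truth-conserved", {
  contigs <- data.frame(id = "c1", seq = strrep("ACGTT", 20000),
                        stringsAsFactors = FALSE)  # 100 kb
  eve <- list(seq_id = "c1", start = 50000, end = 50400,
              assembly = "X")
  win <- extract_flank_region(contigs, eve)
  expect_equal(nchar(win$seq), 20000L)
  expect_match(win$id, "X\\|c1:40200-60200")

  near <- list(seq_id = "c1", start = 3000, end = 3400)
  clipped <- extract_flank_region(contigs, near)
  expect_lt(nchar(clipped$seq), 20000L)
  expect_match(clipped$id, ":0-13200$")

  expect_error(extract_flank_region(contigs, list(seq_id = "zz",
                                                  start = 1, end = 2)),
               "unknown contig")

  # planted orthologous EVEs: windows identical outside the EVE span
  pro <- generate_viral_proteome(1, "Totiviridae", mean_len_aa = 200,
                                 seed = 3)
  spec <- eve_plant_spec("Totiviridae", "VP_Totiviridae_1", c(1, 40),
                         0.9, "contig1", 4000, c("A", "B"))
  ds <- plant_eves(list(A = list(n_contigs = 1, contig_len = 9000),
                        B = list(n_contigs = 1, contig_len = 9000)),
                   list(spec), pro, seed = 5)
  tr <- ds$truth$planted_eves
  wa <- extract_flank_region(ds$assemblies$A, as.list(tr[1, ]),
                             window_nt = 4000)
  wb <- extract_flank_region(ds$assemblies$B, as.list(tr[2, ]),
                             window_nt = 4000)
  expect_identical(wa$seq, wb$seq)
})

test_that("a single EVE in a single assembly founds locus 1 of its family", {
  pro <- generate_viral_proteome(1, "Totiviridae", mean_len_aa = 200,
                                 seed = 31)
  spec <- eve_plant_spec("Totiviridae", "VP_Totiviridae_1", c(1, 50),
                         1.0, "contig1", 3000, "A",
                         flank_conserved = FALSE)
  ds <- plant_eves(list(A = list(n_contigs = 1, contig_len = 8000)),
                   list(spec), pro, seed = 32)
  tr <- ds$truth$planted_eves
  recs <- data.frame(name = "TotiEVE", assembly = "A",
                     seq_id = tr$seq_id, start = tr$start, end = tr$end,
                     family = tr$family, locus_label = "np",
                     stringsAsFactors = FALSE)
  ls <- assign_loci(recs, ds$assemblies, reference = "A")
  expect_equal(ls$records$locus_label, "T1")
  expect_equal(names(ls$loci), "T1")
  expect_equal(unname(orthology_summary(ls)$member_counts), 1L)
})

test_that("conserved loci join across assemblies and private loci stay separate", {
  pro <- generate_viral_proteome(2, "Totiviridae", mean_len_aa = 300,
                                 seed = 41)
  shared <- eve_plant_spec("Totiviridae", "VP_Totiviridae_1", c(1, 60),
                           0.9, "contig1", 3000, c("A", "B", "C"))
  private <- eve_plant_spec("Totiviridae", "VP_Totiviridae_2", c(1, 60),
                            0.9, "contig2", 4000, "C",
                            flank_conserved = FALSE)
  ds <- plant_eves(list(A = list(n_contigs = 2, contig_len = 9000),
                        B = list(n_contigs = 2, contig_len = 9000),
                        C = list(n_contigs = 2, contig_len = 9000)),
                   list(shared, private), pro, seed = 42)
  tr <- ds$truth$planted_eves
  recs <- data.frame(name = "TotiEVE", assembly = tr$assembly,
                     seq_id = tr$seq_id, start = tr$start, end = tr$end,
                     family = tr$family, locus_label = "np",
                     stringsAsFactors = FALSE)
  ls <- assign_loci(recs, ds$assemblies, reference = "C")
  s <- orthology_summary(ls)
  expect_equal(unname(s$member_counts[c("T1", "T2")]), c(3L, 1L))
  expect_equal(unname(s$presence["T1", c("A", "B", "C")]),
               c(TRUE, TRUE, TRUE))
  expect_equal(unname(s$presence["T2", c("A", "B", "C")]),
               c(FALSE, FALSE, TRUE))
})

test_that("same-family EVEs below the identity bar with alien flanks stay apart", {
  pro <- generate_viral_proteome(1, "Totiviridae", mean_len_aa = 300,
                                 seed = 51)
  # two insertions of the same fragment, private flanks, degraded copies:
  # mutual identity far below 98 percent
  s1 <- eve_plant_spec("Totiviridae", "VP_Totiviridae_1", c(1, 80),
                       0.75, "contig1", 3000, "A",
                       flank_conserved = FALSE)
  s2 <- eve_plant_spec("Totiviridae", "VP_Totiviridae_1", c(1, 80),
                       0.75, "contig1", 3000, "B",
                       flank_conserved = FALSE)
  ds <- plant_eves(list(A = list(n_contigs = 1, contig_len = 9000),
                        B = list(n_contigs = 1, contig_len = 9000)),
                   list(s1, s2), pro, seed = 52)
  tr <- ds$truth$planted_eves
  recs <- data.frame(name = "TotiEVE", assembly = tr$assembly,
                     seq_id = tr$seq_id, start = tr$start, end = tr$end,
                     family = tr$family, locus_label = "np",
                     stringsAsFactors = FALSE)
  ls <- assign_loci(recs, ds$assemblies, reference = "A")
  # the B copy fails placement and remains np
  labs <- ls$records$locus_label[ls$records$assembly == "B"]
  expect_equal(labs, "np")
})

test_that("locus assignment is a partition, symmetric in assembly order, and monotone in the identity bar", {
  ds <- simulate_eve_dataset(seed = 61, contig_len = 8000,
                             with_contamination = FALSE,
                             with_decoy = FALSE)
  tr <- ds$truth
  recs <- data.frame(name = "EVE", assembly = tr$assembly,
                     seq_id = tr$seq_id, start = tr$start, end = tr$end,
                     family = tr$family, locus_label = "np",
                     stringsAsFactors = FALSE)
  ls <- assign_loci(recs, ds$assemblies, reference = "BGA3")
  # partition: each EVE appears in at most one locus member list
  all_members <- do.call(rbind, lapply(ls$loci, `[[`, "members"))
  key <- paste(all_members$assembly, all_members$seq_id,
               all_members$start)
  expect_false(anyDuplicated(key) > 0)
  # every placed record is in exactly one locus
  placed <- ls$records[ls$records$locus_label != "np", ]
  expect_equal(nrow(placed), nrow(all_members))
  # symmetry: reordering the non-reference assemblies changes nothing
  ls2 <- assign_loci(recs[rev(seq_len(nrow(recs))), ],
                     ds$assemblies[c("BGA2", "BGA1", "BGA3")],
                     reference = "BGA3")
  m1 <- ls$records[order(ls$records$assembly, ls$records$seq_id,
                         ls$records$start), ]
  m2 <- ls2$records[order(ls2$records$assembly, ls2$records$seq_id,
                          ls2$records$start), ]
  expect_equal(m1$locus_label, m2$locus_label)
  # a stricter identity bar never merges previously distinct loci
  strict <- assign_loci(recs, ds$assemblies, reference = "BGA3",
                        min_identity_pct = 99.5)
  for (lab in names(strict$loci)) {
    km <- strict$loci[[lab]]$members
    kl <- paste(km$assembly, km$seq_id, km$start)
    orig <- ls$loci[[lab]]$members
    ol <- paste(orig$assembly, orig$seq_id, orig$start)
    expect_true(all(kl %in% ol))
  }
  # identity matrices are symmetric with a 100 diagonal
  for (l in ls$loci) {
    expect_equal(l$identity_matrix, t(l$identity_matrix))
    expect_true(all(diag(l$identity_matrix) == 100))
  }
})
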