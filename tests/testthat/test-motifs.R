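test_that("protein motif scans match the pattern definitions", {
  hits <- scan_protein_motifs("DSDYAGEIQ", type = "aa")
  expect_equal(hits$motif_name, "dutpase")
  expect_equal(hits$start, 1L)
  zf <- scan_protein_motifs("CAACAAAAHAAAAC", type = "aa")
  expect_equal(zf$motif_name, "gag_zinc_finger")
  gp <- scan_protein_motifs("GYAAGAGLGAAAAGAAAG", type = "aa")
  expect_true("g_patch" %in% gp$motif_name)
  expect_equal(nrow(scan_protein_motifs("AAAA", type = "aa")), 0L)
})

test_that("motif scanning agrees exactly with a brute-force oracle", {
  set.seed(55)
  alphabet <- c("C", "H", "G", "Y", "L", "D", "S", "E", "I", "Q", "A", "X")
  for (i in 1:60) {
    aa <- paste(sample(alphabet, 400, replace = TRUE,
                       prob = c(3, 2, 4, 2, 2, 1, 1, 1, 1, 1, 2, 1)),
                collapse = "")
    got <- scan_protein_motifs(aa, type = "aa")
    for (mn in c("dutpase", "gag_zinc_finger", "g_patch")) {
      expect_identical(sort(got$start[got$motif_name == mn]),
                       sort(oracle_motif_starts(aa, mn)))
    }
  }
})

test_that("nucleotide input is translated in the three forward frames", {
  # plant the dUTPase nt encoding in frame 1 (offset 1)
  aa <- "DSDYAGEIQ"
  codons <- c(D = "GAT", S = "TCT", Y = "TAT", A = "GCT", G = "GGT",
              E = "GAA", I = "ATT", Q = "CAA")
  nt <- paste(codons[strsplit(aa, "")[[1]]], collapse = "")
  seq <- paste0("A", nt, "GG")
  hits <- scan_protein_motifs(seq, type = "nt")
  expect_equal(hits$frame, 1L)
  expect_equal(hits$motif_name, "dutpase")
})

test_that("A/T-rich stretch detection recovers planted windows", {
  set.seed(66)
  bg <- function(n) random_dna(n, c(A = .25, C = .25, G = .25, T = .25))
  at <- random_dna(830, c(A = .38, C = .15, G = .15, T = .32))  # ~70% AT
  seqv <- paste0(bg(2000), at, bg(2000))
  hits <- find_at_rich_stretches(seqv, min_len = 800, min_at = 0.67)
  expect_equal(nrow(hits), 1L)
  # slack = window granularity (qualifying windows reach ~140 nt into the
  # 50%-AT background); the merged run's own fraction can dip slightly
  # slack scales with realised window composition; overlap is what matters
  expect_lt(abs(hits$start - 2001), 260)
  expect_lt(abs(hits$end - 2830), 260)
  expect_gt(min(hits$end, 2830) - max(hits$start, 2001), 700)
  expect_gte(hits$at_fraction, 0.65)

  expect_equal(nrow(find_at_rich_stretches(strrep("GC", 600))), 0L)
  all_at <- find_at_rich_stretches(strrep("AT", 500))
  expect_equal(all_at$start, 1L)
  expect_equal(all_at$end, 1000L)
  expect_equal(all_at$at_fraction, 1.0)
})

test_that("base composition summaries exclude N and gaps", {
  one <- nucleotide_frequencies("AAAA")
  expect_equal(one$summary$mean[one$summary$base == "A"], 100)
  two <- nucleotide_frequencies(c("AATT", "GGCC"))
  expect_equal(two$summary$mean, rep(25, 4))
  withN <- nucleotide_frequencies("AAN-")
  expect_equal(unname(withN$per_sequence[1, "A"]), 1)
  expect_warning(nucleotide_frequencies(c("ACGT", "NNN")), "skipping")
})

test_that("PBS detection assigns the right tRNA, with and without indel", {
  lib <- pbs_library()
  tp <- provirus_template()
  rec <- find_pbs(tp$sequence, 548L)
  expect_true(rec$applicable)
  expect_equal(rec$assigned_trna, "K")
  expect_equal(rec$identity_percent, 100)
  expect_equal(rec$length, 18L)
  expect_false(rec$indel)

  # single-nucleotide insertion between PBS residues 10 and 11
  pbs <- lib$sequence[1]
  mut <- paste0(substr(pbs, 1, 10), "A", substr(pbs, 11, 18))
  seqv <- paste0(substr(tp$sequence, 1, 551), mut,
                 substr(tp$sequence, 570, 6358))
  rec2 <- find_pbs(seqv, 548L)
  expect_equal(rec2$length, 19L)
  expect_true(rec2$indel)
  expect_equal(rec2$assigned_trna, "K")
  expect_equal(rec2$identity_percent, 100)

  # missing 5'LTR -> not-applicable, not an error
  rec3 <- find_pbs(tp$sequence, NA)
  expect_false(rec3$applicable)

  # assignment invariant to flanking sequence outside the scanned window
  seq_flank <- paste0(strrep("T", 548), substr(tp$sequence, 549, 600))
  expect_equal(find_pbs(seq_flank, 548L)$assigned_trna, rec$assigned_trna)
})

test_that("PBS profiles count symbols per column", {
  p1 <- pbs_alignment_profile("ACGT")
  expect_equal(unname(p1["A", 1]), 1L)
  expect_equal(colSums(p1), rep(1L, 4), ignore_attr = TRUE)
  p2 <- pbs_alignment_profile(c("ACGT", "ACGT"))
  expect_equal(unname(p2["C", 2]), 2L)
  # modal symbol recovers the master at most columns
  master <- pbs_library()$sequence[1]
  msa <- simulate_msa_from_consensus(master, rep(0.05, 8), seed = 77)
  prof <- pbs_alignment_profile(unclass(msa))
  modal <- rownames(prof)[apply(prof, 2, which.max)]
  expect_gte(mean(modal == strsplit(master, "")[[1]]), 0.85)
})

test_that("ORF integrity reports stops, frameshifts and intact structures", {
  codons <- c("ATG", "GCT", "GGT", "TCA" , "TAA", "GCT", "GGT", "GCT", "TGA")
  # codon 5 is TAA -> internal stop at residue 5 (terminal TGA is not internal)
  region <- paste(codons, collapse = "")
  ref <- paste(rep("ATG", 9), collapse = "")
  rep1 <- assess_orf_integrity(region, ref)
  expect_equal(rep1$internal_stops, 5L)
  expect_false(rep1$intact)

  rep2 <- assess_orf_integrity(ref, ref)
  expect_true(rep2$intact)
  expect_equal(rep2$putein_length_aa, 9L)

  # 1-nt deletion at the codon 17/18 boundary
  ref_cds <- strrep("GCT", 30)
  reg <- paste0(substr(ref_cds, 1, 51), "-", substr(ref_cds, 53, 90))
  rep3 <- assess_orf_integrity(reg, ref_cds)
  expect_equal(rep3$frameshifts$codon, 18)
  expect_true(rep3$frameshifts$at_boundary)
  expect_false(rep3$intact)
  expect_error(assess_orf_integrity("AC", "AC"), "input error")
})

test_that("subtype classification keys on the pol-3'/env-5' window", {
  tI <- provirus_template(subtype = "I")
  tII <- provirus_template(subtype = "II")
  ref <- tII$sequence
  expect_equal(classify_subtype(tI$sequence, ref), "I")
  expect_equal(classify_subtype(tII$sequence, ref), "II")
  # window deleted -> unassigned
  v <- strsplit(tI$sequence, "")[[1]]
  v[3159:4130] <- "-"
  expect_equal(classify_subtype(paste(v, collapse = ""), ref), "unassigned")
})

test_that("LTR regulatory motif conservation is scored at reference coordinates", {
  tp <- provirus_template()
  cons <- ltr_motif_conservation(tp$sequence, tp$sequence)
  expect_true(all(cons$conserved))
  v <- strsplit(tp$sequence, "")[[1]]
  v[30] <- "G"   # break the 5'LTR TATA box
  cons2 <- ltr_motif_conservation(paste(v, collapse = ""), tp$sequence)
  expect_equal(cons2$mismatches[cons2$motif == "tata" & cons2$ltr == "5'LTR"], 1L)
  expect_true(all(cons2$conserved[cons2$ltr == "3'LTR"]))
})
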