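test_that("template carries the reference feature frame", {
  tp <- provirus_template()
  expect_equal(nchar(tp$sequence), 6358)
  f <- function(x) tp$features[tp$features$feature == x, c("start", "end")]
  expect_equal(unlist(f("ltr5"), use.names = FALSE), c(1, 548))
  expect_equal(unlist(f("ltr3"), use.names = FALSE), c(5811, 6358))
  expect_equal(unlist(f("gag"), use.names = FALSE), c(698, 1314))
  expect_equal(unlist(f("pol"), use.names = FALSE), c(1316, 3786))
  expect_equal(unlist(f("env"), use.names = FALSE), c(3801, 5780))
  # the two LTR copies are identical at integration
  expect_identical(substr(tp$sequence, 1, 548), substr(tp$sequence, 5811, 6358))
  # regulatory motifs sit at their LTR-unit offsets in both copies
  expect_equal(substr(tp$sequence, 30, 35), "TATAAA")
  expect_equal(substr(tp$sequence, 5840, 5845), "TATAAA")
  expect_equal(substr(tp$sequence, 65, 72), "GTGGAAAG")
  expect_equal(substr(tp$sequence, 384, 389), "AATAAA")
  expect_equal(substr(tp$sequence, 6194, 6199), "AATAAA")
  # deterministic default
  expect_identical(tp$sequence, provirus_template()$sequence)
})

test_that("zero-age simulation is the identity with all-zero truth", {
  tp <- provirus_template()
  sim <- simulate_provirus(tp, 0, seed = 1)
  expect_identical(sim$sequence, tp$sequence)
  expect_equal(sim$truth$n_substitutions, 0)
  expect_true(all(sim$truth$region_substitutions == 0))
  expect_error(simulate_provirus(tp, -1), "config error")
})

test_that("inter-LTR divergence converges on the clock expectation", {
  tp <- provirus_template()
  ltr <- substr(tp$sequence, 1, 548)
  set.seed(101)
  d <- replicate(400, {
    pr <- simulate_ltr_pair(ltr, 20)
    p_distance(pr$ltr5, pr$ltr3)$d_percent
  })
  # exact expectation: both copies hit with p = 1 - exp(-0.002*20), a
  # coincident identical hit matches with probability 1/3
  p <- 1 - exp(-0.002 * 20)
  expected <- 100 * (2 * p - 4 * p^2 / 3)
  mc_se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / 548 / 400)
  expect_lt(abs(mean(d) - expected), 4 * mc_se)
  # and the naive 2(1-exp(-rt)) bound from above
  expect_lt(mean(d), 100 * 2 * p)
})

test_that("CpG hypermutation increases transition counts at CpG sites", {
  ltr <- strrep("ACGT", 137)   # CpG-dense
  count_ct_ga <- function(mult) {
    set.seed(7)
    sum(replicate(60, {
      pr <- simulate_ltr_pair(ltr, 20, cpg_multiplier = mult)
      a <- strsplit(ltr, "")[[1]]
      b <- strsplit(pr$ltr5, "")[[1]]
      sum((a == "C" & b == "T") | (a == "G" & b == "A"))
    }))
  }
  expect_gt(count_ct_ga(5), count_ct_ga(1))
})

test_that("solo-LTR records are single LTR-length relics", {
  tp <- provirus_template()
  sim <- simulate_provirus(tp, 15, seed = 3)
  solo <- make_solo_ltr(sim)
  expect_equal(nchar(solo), 548)
  out <- simulate_locus_set(2, 3, c(chr1 = 1e6, chr2 = 1e6), seed = 4)
  expect_equal(sum(out$loci$kind == "solo_ltr"), 3)
  expect_true(all(nchar(out$sequences[out$loci$kind == "solo_ltr"]) == 548))
  out0 <- simulate_locus_set(2, 0, c(chr1 = 1e6), seed = 4)
  expect_false(any(out0$loci$kind == "solo_ltr"))
  expect_error(simulate_locus_set(1, 0, numeric(0)), "config error")
})

test_that("insertion chromosomes follow length-proportional sampling", {
  lens <- c(a = 3e6, b = 1e6)
  out <- simulate_locus_set(0, 400, lens, emit_sequences = FALSE, seed = 11)
  obs <- table(factor(out$loci$chrom, names(lens)))
  chi <- overall_chi_square(as.numeric(obs), expected_counts(lens, 400))
  expect_gt(chi$p_value, 0.01)
  # a 9-fold enrichment multiplier on a small chromosome shows up as a
  # ~9-fold observed/expected ratio (exactly 9 only in the small-share limit)
  lens9 <- c(a = 1e7, b = 1e7, c = 1e7, d = 1e5)
  out9 <- simulate_locus_set(0, 2000, lens9, enrichment = c(d = 9),
                             emit_sequences = FALSE, seed = 12)
  fold <- sum(out9$loci$chrom == "d") / expected_counts(lens9, 2000)[["d"]]
  expect_gt(fold, 7)
  expect_lt(fold, 11)
})

test_that("msa-from-consensus realises requested divergences", {
  cons <- random_dna(800)
  expect_error(simulate_msa_from_consensus(cons, c(0.1, 0.8)), "config error")
  msa0 <- simulate_msa_from_consensus(cons, c(0, 0), seed = 5)
  expect_true(all(unclass(msa0) == cons))

  msa <- simulate_msa_from_consensus(cons, c(0.02, 0.04), seed = 6)
  truth <- attr(msa, "truth")
  for (i in 1:2) {
    sd_i <- sqrt(truth$divergences[i] * (1 - truth$divergences[i]) / 800)
    expect_lt(abs(truth$realized[i] - truth$divergences[i]), 3 * sd_i + 1e-9)
    expect_equal(p_distance(msa[[i]], cons)$d_percent / 100,
                 unname(truth$realized[i]))
  }

  # rebuilt majority consensus recovers the generator
  msa10 <- simulate_msa_from_consensus(cons, rep(0.05, 10), seed = 7)
  rebuilt <- majority_consensus(msa10)
  agree <- mean(strsplit(rebuilt, "")[[1]] == strsplit(cons, "")[[1]])
  expect_gte(agree, 0.99)
})

test_that("truth alignment maps indels consistently", {
  tp <- provirus_template()
  sim <- simulate_provirus(tp, 5, indel_rate = 0.002, seed = 9)
  aln <- sim$truth$alignment
  expect_equal(nchar(aln$template), nchar(aln$mutant))
  expect_identical(gsub("-", "", aln$template, fixed = TRUE), tp$sequence)
  expect_identical(gsub("-", "", aln$mutant, fixed = TRUE), sim$sequence)
  # targeted lesions: planted stop codon lands in the right codon
  sim2 <- simulate_provirus(tp, 0, stops = data.frame(region = "gag", codon = 5),
                            seed = 10)
  gag <- sim_region(sim2, "gag")
  expect_equal(substr(gag, 13, 15), "TAA")
})
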