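# End-to-end orchestration: simulate a locus set with ground truth, date
# every provirus, test the chromosomal distribution, build a bootstrap NJ
# tree and scan sequence features; write all stage outputs (TSV / FASTA /
# Newick / JSON) under one output directory with deterministic per-stage
# seeds derived from the run seed.

#' GRCh37/hg19 chromosome lengths
#'
#' Standard assembly lengths (bp) for chromosomes 1-22, X and Y; the default
#' genome background for the locus simulator and distribution statistics.
#'
#' @return Named numeric vector.
#' @export
hg19_chrom_lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566)
}

#' Run the full simulate -> date -> distribute -> phylo -> motifs pipeline
#'
#' Every stochastic stage receives a seed derived deterministically from the
#' run seed, so a rerun with the same configuration reproduces every output.
#' No stage mutates its inputs; all files are written under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Run seed (integer).
#' @param n_proviruses,n_solo_ltrs Locus set composition.
#' @param chrom_lengths Chromosome background (default [hg19_chrom_lengths()]).
#' @param enrichment Optional per-chromosome enrichment multipliers.
#' @param age_range True ages, My.
#' @param rate Substitution rate, % per nt per My.
#' @param cv_threshold Dating component exclusion threshold.
#' @param n_boot Bootstrap replicates for dating dispersion and tree
#'   support.
#' @param halve_ltr,mask_cpg Dating mode flags.
#' @param template Optional [provirus_template()].
#' @return Invisibly, the run summary (also written to `summary.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_proviruses = 8,
                         n_solo_ltrs = 20,
                         chrom_lengths = hg19_chrom_lengths(),
                         enrichment = NULL, age_range = c(20, 40),
                         rate = 0.2, cv_threshold = 0.20, n_boot = 200,
                         halve_ltr = TRUE, mask_cpg = TRUE, template = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(template)) template <- provirus_template()
  seeds <- list(simulate = seed + 101L, dating = seed + 202L,
                phylo = seed + 303L)
  warnings_log <- character(0)

  # --- simulate -------------------------------------------------------------
  sim <- simulate_locus_set(n_proviruses, n_solo_ltrs, chrom_lengths,
                            enrichment = enrichment, age_range = age_range,
                            rate = rate, template = template,
                            seed = seeds$simulate)
  write_locus_table(sim$loci, file.path(out_dir, "loci.tsv"))
  write_fasta(sim$sequences, file.path(out_dir, "sequences.fasta"))

  # --- dating ---------------------------------------------------------------
  prov <- sim$loci$name[sim$loci$kind == "provirus"]
  ltr5 <- vapply(prov, function(nm) {
    substr(sim$sequences[[nm]], 1, 548)
  }, character(1))
  ltr3 <- vapply(prov, function(nm) {
    s <- sim$sequences[[nm]]
    substr(s, nchar(s) - 547, nchar(s))
  }, character(1))
  estimates <- list()
  if (length(prov) >= 2L) {
    cons <- majority_consensus(as_msa(ltr5))
    estimates <- lapply(seq_along(prov), function(i) {
      comp <- rbind(
        divergence_estimate(ltr5[i], ltr3[i], method = "ltr_vs_ltr",
                            region_label = "ltr_vs_ltr", rate = rate,
                            halve_ltr = halve_ltr, mask_cpg = mask_cpg,
                            n_boot = n_boot, seed = seeds$dating + i),
        divergence_estimate(ltr5[i], cons, method = "ltr_vs_consensus",
                            region_label = "ltr_vs_consensus", rate = rate,
                            mask_cpg = mask_cpg, n_boot = n_boot,
                            seed = seeds$dating + 1000L + i))
      comp$region <- comp$region_label
      aggregate_locus_age(comp, cv_threshold = cv_threshold, locus = prov[i])
    })
    ages <- summarize_age_table(estimates, rate = rate)
    write.table(ages$table, file.path(out_dir, "age_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    excl <- sum(vapply(estimates, function(e) sum(e$excluded), integer(1)))
    if (excl > 0L)
      warnings_log <- c(warnings_log,
                        sprintf("%d dating component(s) excluded by CV rule", excl))
  } else {
    ages <- NULL
  }

  # --- distribution ---------------------------------------------------------
  dist <- chrom_distribution(sim$loci, chrom_lengths)
  write.table(dist$table, file.path(out_dir, "distribution.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- phylogeny ------------------------------------------------------------
  tree <- NULL
  if (length(prov) >= 4L) {
    tree <- withCallingHandlers(
      bootstrap_support(as_msa(ltr5), model = "k2p", n = n_boot,
                        seed = seeds$phylo),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    write_newick(tree, file.path(out_dir, "tree.nwk"))
  }

  # --- motifs ---------------------------------------------------------------
  pbs <- lapply(prov, function(nm) find_pbs(sim$sequences[[nm]], 548L))
  pbs_tab <- data.frame(
    locus = prov,
    trna = vapply(pbs, function(r) if (r$applicable) r$assigned_trna else NA_character_,
                  character(1)),
    identity = vapply(pbs, function(r) if (r$applicable) r$identity_percent else NA_real_,
                      numeric(1)),
    length = vapply(pbs, function(r) if (r$applicable) r$length else NA_integer_,
                    integer(1)), stringsAsFactors = FALSE)
  write.table(pbs_tab, file.path(out_dir, "pbs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  freqs <- nucleotide_frequencies(sim$sequences)

  summary <- list(
    config = list(seed = seed, n_proviruses = n_proviruses,
                  n_solo_ltrs = n_solo_ltrs, age_range = age_range,
                  rate = rate, cv_threshold = cv_threshold, n_boot = n_boot,
                  halve_ltr = halve_ltr, mask_cpg = mask_cpg,
                  enrichment = enrichment, out_dir = out_dir),
    stage_seeds = seeds,
    n_loci = nrow(sim$loci),
    overall_distribution = dist$overall,
    mean_per_chromosome_p = dist$mean_p,
    column_means = if (!is.null(ages)) as.list(ages$column_means) else NULL,
    base_composition = as.list(setNames(freqs$report$mean, freqs$report$base)),
    warnings = warnings_log)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(summary)
}
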