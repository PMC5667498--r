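# Provirus simulator with known ground truth. The generator emulates a
# Betaretrovirus-like provirus (5'LTR-gag-pol-env-3'LTR) inserted in a host
# background and evolving neutrally under a Poisson substitution clock, with
# the two LTR copies identical at integration and diverging independently
# afterwards. Optional processes: CpG hypermutation, indels, targeted lesions
# (premature stops, frameshifts, secondary insertions) and solo-LTR
# recombination products.

# reference feature frame of the simulated provirus (1-based inclusive)
.TEMPLATE_FEATURES <- data.frame(
  feature = c("ltr5", "pbs", "gag", "pol", "env", "ppt", "ltr3",
              "tata5", "sv40_5", "polya5", "tata3", "sv40_3", "polya3"),
  start   = c(1, 552, 698, 1316, 3801, 5786, 5811,
              30, 65, 384, 5840, 5875, 6194),
  end     = c(548, 569, 1314, 3786, 5780, 5798, 6358,
              35, 72, 389, 5845, 5882, 6199),
  stringsAsFactors = FALSE
)

# run expr with a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.sample_bases <- function(n, freqs = c(A = 0.33, C = 0.21, G = 0.18, T = 0.28)) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Build a reference provirus template
#'
#' Generates a 6358-nt provirus with the canonical feature frame: 5'LTR
#' 1-548 and 3'LTR 5811-6358 (identical copies) flanking gag (698-1314),
#' pol (1316-3786) and env (3801-5780); PBS at 552-569 (3 nt downstream of
#' the 5'LTR), PPT at 5786-5798; each LTR carries a TATA box (TATAAA),
#' an SV40 enhancer (GTGGAAAG) and a PolyA signal (AATAAA) at positions
#' 30-35, 65-72 and 384-389 of the LTR unit. Background composition defaults
#' to the A-biased profile typical of the group (A 33%, T 28%, C 21%, G 18%).
#'
#' @param subtype `"I"` plants a ~70% A/T-rich stretch across the reference
#'   window 3159-4130 (pol 3'/env 5'); `"II"` fills that window at ~50% A/T
#'   (a coding-like segment).
#' @param seed Integer seed for the template's private RNG stream; the
#'   default yields one fixed reference template.
#' @param base_freqs Named background base frequencies (A, C, G, T).
#' @param pbs PBS sequence planted at 552-569 (default: the packaged Lys
#'   exemplar).
#' @return Object of class `provirus_template`: list with `sequence`
#'   (character string), `features` (data.frame feature/start/end) and
#'   `subtype`.
#' @export
provirus_template <- function(subtype = c("II", "I"), seed = 6358L,
                              base_freqs = c(A = 0.33, C = 0.21, G = 0.18, T = 0.28),
                              pbs = NULL) {
  subtype <- match.arg(subtype)
  if (is.null(pbs)) pbs <- pbs_library()$sequence[1]
  .with_seed(seed, {
    ltr <- .sample_bases(548, base_freqs)
    ltr[30:35] <- strsplit("TATAAA", "")[[1]]
    ltr[65:72] <- strsplit("GTGGAAAG", "")[[1]]
    ltr[384:389] <- strsplit("AATAAA", "")[[1]]
    body <- .sample_bases(6358 - 2 * 548, base_freqs)  # positions 549..5810
    seqv <- c(ltr, body, ltr)
    seqv[552:569] <- strsplit(pbs, "")[[1]]
    seqv[5786:5798] <- strsplit("AGGAAGGGAGGGA", "")[[1]]  # polypurine tract
    win <- 3159:4130
    at_frac <- if (subtype == "I") 0.70 else 0.50
    seqv[win] <- .sample_bases(length(win), c(
      A = at_frac * 0.55, T = at_frac * 0.45,
      C = (1 - at_frac) * 0.55, G = (1 - at_frac) * 0.45))
    structure(list(sequence = paste(seqv, collapse = ""),
                   features = .TEMPLATE_FEATURES, subtype = subtype),
              class = "provirus_template")
  })
}

#' @export
print.provirus_template <- function(x, ...) {
  cat(sprintf("Provirus template: %d nt, subtype %s, %d features\n",
              nchar(x$sequence), x$subtype, nrow(x$features)))
  invisible(x)
}

# One Poisson-clock draw over a character vector of bases.
# p = per-site substitution probability; at CpG sites the transition
# alternative (C->T on the plus strand C, G->A on the G) is weighted by
# cpg_multiplier. Context is evaluated on the current sequence scanning
# 5'->3' when cpg_multiplier > 1.
.mutate_bases <- function(bases, p, cpg_multiplier = 1) {
  n <- length(bases)
  if (p <= 0 || n == 0L) return(bases)
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  if (cpg_multiplier == 1) {
    hit <- runif(n) < p
    if (any(hit)) {
      idx <- which(hit & bases %in% c("A", "C", "G", "T"))
      bases[idx] <- vapply(bases[idx], function(b) sample(alts[[b]], 1L),
                           character(1))
    }
    return(bases)
  }
  u <- runif(n)
  for (i in seq_len(n)) {
    b <- bases[i]
    if (!(b %in% c("A", "C", "G", "T"))) next
    is_cpg_c <- b == "C" && i < n && bases[i + 1L] == "G"
    is_cpg_g <- b == "G" && i > 1L && bases[i - 1L] == "C"
    w <- c(1, 1, 1)                       # weights over alts[[b]]
    if (is_cpg_c) w[alts[["C"]] == "T"] <- cpg_multiplier
    if (is_cpg_g) w[alts[["G"]] == "A"] <- cpg_multiplier
    p_tot <- (p / 3) * sum(w)
    if (u[i] < p_tot) {
      bases[i] <- sample(alts[[b]], 1L, prob = w)
    }
  }
  bases
}

#' Simulate neutral evolution of a provirus
#'
#' Applies one substitution draw to every site with probability
#' `1 - exp(-(rate/100) * age_my)` (Poisson clock, at most one realised
#' substitution per site), uniform among the three alternative bases except
#' at CpG sites, where the C->T / G->A transition is weighted by
#' `cpg_multiplier`. The two LTR copies start identical (they are copies in
#' the template) and receive independent draws. Optional indels, targeted
#' lesions and a complete ground-truth record are returned.
#'
#' @param template A [provirus_template()].
#' @param age_my True age in million years (>= 0).
#' @param rate Substitution rate in % per nt per My (default 0.2).
#' @param cpg_multiplier CpG transition weight (>= 1).
#' @param indel_rate Per-site indel event probability (geometric lengths,
#'   mean 3); default 0 so dating analyses are substitution-only.
#' @param stops Optional data.frame `region`, `codon`: plant TAA at that
#'   codon of the region's reading frame.
#' @param frameshifts Optional data.frame `region`, `codon`: delete 1 nt at
#'   that codon boundary (a codon-disrupting lesion).
#' @param secondary_insertion Optional `c(pos, len)`: insert `len` random nt
#'   after template position `pos` (emulates a nested mobile-element
#'   integration).
#' @param seed Optional integer seed (private stream).
#' @return List of class `sim_provirus` with `sequence` (mutant, ungapped),
#'   `features` (template frame), and `truth`: `age_my`, `rate`,
#'   `n_substitutions`, `region_substitutions` (named counts),
#'   `alignment` (template/mutant gapped pair), `lesions`.
#' @export
simulate_provirus <- function(template, age_my, rate = 0.2, cpg_multiplier = 1,
                              indel_rate = 0, stops = NULL, frameshifts = NULL,
                              secondary_insertion = NULL, seed = NULL) {
  if (age_my < 0 || rate < 0) stop("config error: negative age or rate", call. = FALSE)
  if (cpg_multiplier < 1) stop("config error: cpg_multiplier must be >= 1", call. = FALSE)
  .with_seed(seed, {
    tmpl <- strsplit(template$sequence, "")[[1]]
    p <- 1 - exp(-(rate / 100) * age_my)
    mut <- .mutate_bases(tmpl, p, cpg_multiplier)

    # targeted lesions in the reference frame (before indel realisation)
    lesions <- list(stops = stops, frameshifts = frameshifts,
                    secondary_insertion = secondary_insertion)
    feat <- template$features
    if (!is.null(stops)) {
      for (k in seq_len(nrow(stops))) {
        r <- feat[feat$feature == stops$region[k], ]
        pos <- r$start + 3L * (stops$codon[k] - 1L)
        mut[pos:(pos + 2L)] <- c("T", "A", "A")
      }
    }

    # indel operations: data.frame(pos, type, len). pos = template position
    # (deletion starts at pos; insertion goes after pos)
    ops <- data.frame(pos = integer(), type = character(), len = integer(),
                      stringsAsFactors = FALSE)
    if (!is.null(frameshifts)) {
      for (k in seq_len(nrow(frameshifts))) {
        r <- feat[feat$feature == frameshifts$region[k], ]
        pos <- r$start + 3L * frameshifts$codon[k]  # boundary after codon k
        ops <- rbind(ops, data.frame(pos = pos, type = "del", len = 1L))
      }
    }
    if (!is.null(secondary_insertion)) {
      ops <- rbind(ops, data.frame(pos = as.integer(secondary_insertion[1]),
                                   type = "ins",
                                   len = as.integer(secondary_insertion[2])))
    }
    if (indel_rate > 0) {
      ev <- which(runif(length(tmpl)) < indel_rate)
      if (length(ev)) {
        ops <- rbind(ops, data.frame(
          pos = ev,
          type = sample(c("ins", "del"), length(ev), replace = TRUE),
          len = rgeom(length(ev), 1 / 3) + 1L))
      }
    }

    aln <- .realize_indels(tmpl, mut, ops)
    n_sub <- sum(tmpl != mut)
    regions <- c("ltr5", "gag", "pol", "env", "ltr3")
    reg_counts <- vapply(regions, function(f) {
      r <- feat[feat$feature == f, ]
      sum(tmpl[r$start:r$end] != mut[r$start:r$end])
    }, integer(1))

    structure(list(
      sequence = gsub("-", "", aln$mutant, fixed = TRUE),
      features = feat,
      truth = list(age_my = age_my, rate = rate,
                   cpg_multiplier = cpg_multiplier,
                   n_substitutions = n_sub,
                   region_substitutions = reg_counts,
                   alignment = aln, lesions = lesions)),
      class = "sim_provirus")
  })
}

# Realize indel ops into a gapped template/mutant alignment pair.
# Deletions remove mutant residues; insertions add random residues to the
# mutant with gaps in the template row.
.realize_indels <- function(tmpl, mut, ops) {
  n <- length(tmpl)
  if (nrow(ops) == 0L) {
    return(list(template = paste(tmpl, collapse = ""),
                mutant = paste(mut, collapse = "")))
  }
  del <- rep(FALSE, n)
  ins_after <- vector("list", n + 1L)  # index i+1 = insertions after pos i
  for (k in seq_len(nrow(ops))) {
    if (ops$type[k] == "del") {
      to <- min(n, ops$pos[k] + ops$len[k] - 1L)
      del[ops$pos[k]:to] <- TRUE
    } else {
      i <- ops$pos[k] + 1L
      ins_after[[i]] <- c(ins_after[[i]], paste(.sample_bases(ops$len[k]),
                                                collapse = ""))
    }
  }
  t_out <- character(0); m_out <- character(0)
  if (!is.null(ins_after[[1]])) {
    ins <- paste(unlist(ins_after[[1]]), collapse = "")
    t_out <- strrep("-", nchar(ins)); m_out <- ins
  }
  for (i in seq_len(n)) {
    t_out <- c(t_out, tmpl[i])
    m_out <- c(m_out, if (del[i]) "-" else mut[i])
    if (!is.null(ins_after[[i + 1L]])) {
      ins <- paste(unlist(ins_after[[i + 1L]]), collapse = "")
      t_out <- c(t_out, strrep("-", nchar(ins)))
      m_out <- c(m_out, ins)
    }
  }
  list(template = paste(t_out, collapse = ""),
       mutant = paste(m_out, collapse = ""))
}

#' Simulate one inter-LTR divergence experiment
#'
#' Evolves two initially identical copies of an LTR independently under the
#' Poisson clock (see [simulate_provirus()]) for `age_my` million years.
#'
#' @param ltr Ancestral LTR sequence (ungapped).
#' @param age_my True age in My.
#' @param rate Substitution rate, % per nt per My.
#' @param cpg_multiplier CpG transition weight (>= 1).
#' @param seed Optional integer seed (private stream).
#' @return List with `ltr5` and `ltr3`, the two evolved copies.
#' @export
simulate_ltr_pair <- function(ltr, age_my, rate = 0.2, cpg_multiplier = 1,
                              seed = NULL) {
  if (age_my < 0 || rate < 0) stop("config error: negative age or rate", call. = FALSE)
  .with_seed(seed, {
    v <- strsplit(normalize_residues(ltr), "")[[1]]
    p <- 1 - exp(-(rate / 100) * age_my)
    list(ltr5 = paste(.mutate_bases(v, p, cpg_multiplier), collapse = ""),
         ltr3 = paste(.mutate_bases(v, p, cpg_multiplier), collapse = ""))
  })
}

#' Extract a feature region from a simulated provirus
#'
#' Uses the truth alignment to map the template feature interval onto the
#' (possibly indel-bearing) mutant sequence.
#'
#' @param sim A [simulate_provirus()] result.
#' @param feature Feature name from the template frame.
#' @return Ungapped mutant substring for the feature (may be empty if fully
#'   deleted).
#' @export
sim_region <- function(sim, feature) {
  r <- sim$features[sim$features$feature == feature, ]
  if (nrow(r) != 1L) stop("unknown feature: ", feature, call. = FALSE)
  t_aln <- strsplit(sim$truth$alignment$template, "")[[1]]
  m_aln <- strsplit(sim$truth$alignment$mutant, "")[[1]]
  tpos <- cumsum(t_aln != "-")
  cols <- which(tpos >= r$start & tpos <= r$end & t_aln != "-")
  paste(m_aln[cols][m_aln[cols] != "-"], collapse = "")
}

#' Produce a solo-LTR recombination product
#'
#' LTR-LTR homologous recombination deletes the internal region between the
#' two LTR copies, leaving a single LTR-length relic. Modelled as a chimera:
#' the 5' half of the 5'LTR joined to the 3' half of the 3'LTR.
#'
#' @param sim A [simulate_provirus()] result.
#' @return Single LTR-length character string.
#' @export
make_solo_ltr <- function(sim) {
  l5 <- sim_region(sim, "ltr5")
  l3 <- sim_region(sim, "ltr3")
  half <- nchar(l5) %/% 2L
  paste0(substr(l5, 1L, half), substr(l3, half + 1L, nchar(l3)))
}

#' Simulate a set of integrated loci across chromosomes
#'
#' Insertion chromosomes are drawn proportionally to chromosome length,
#' optionally weighted by per-chromosome enrichment multipliers (e.g. a
#' 9-fold excess on one chromosome). Solo-LTR relics are emitted as
#' single-LTR records derived from simulated proviruses by internal
#' deletion.
#'
#' @param n_proviruses,n_solo_ltrs Numbers of full proviruses and solo LTRs.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param enrichment Optional named multipliers (default 1 for all).
#' @param age_range True ages drawn uniformly from this range (My).
#' @param rate Substitution rate, % per nt per My.
#' @param template Template passed to [simulate_provirus()].
#' @param emit_sequences Evolve and return sequences (default). With
#'   `FALSE` only the locus table is generated (nominal lengths), which is
#'   what distribution-calibration studies need.
#' @param seed Optional integer seed.
#' @return List with `loci` (data.frame name/chrom/start/end/strand/context/
#'   kind), `sequences` (named character vector), `truth` (list of truth
#'   records; solo entries carry the parent provirus truth).
#' @export
simulate_locus_set <- function(n_proviruses, n_solo_ltrs, chrom_lengths,
                               enrichment = NULL, age_range = c(20, 40),
                               rate = 0.2, template = NULL,
                               emit_sequences = TRUE, seed = NULL) {
  if (length(chrom_lengths) < 1L || is.null(names(chrom_lengths)))
    stop("config error: chromosome length table required", call. = FALSE)
  .with_seed(seed, {
    if (is.null(template) && emit_sequences) template <- provirus_template()
    mult <- setNames(rep(1, length(chrom_lengths)), names(chrom_lengths))
    if (!is.null(enrichment)) mult[names(enrichment)] <- enrichment
    w <- chrom_lengths * mult
    n_total <- n_proviruses + n_solo_ltrs
    loci <- NULL; seqs <- character(0); truths <- list()
    if (n_total > 0L) {
      chroms <- sample(names(chrom_lengths), n_total, replace = TRUE,
                       prob = w / sum(w))
      ages <- runif(n_total, age_range[1], age_range[2])
      kind <- c(rep("provirus", n_proviruses), rep("solo_ltr", n_solo_ltrs))
      nms <- sprintf("%s_%s_%03d", kind, chroms, seq_len(n_total))
      if (emit_sequences) {
        lens <- integer(n_total)
        for (i in seq_len(n_total)) {
          sim <- simulate_provirus(template, ages[i], rate = rate)
          s <- if (kind[i] == "provirus") sim$sequence else make_solo_ltr(sim)
          lens[i] <- nchar(s)
          seqs[nms[i]] <- s
          truths[[nms[i]]] <- sim$truth
        }
      } else {
        lens <- ifelse(kind == "provirus", 6358L, 548L)
      }
      starts <- floor(runif(n_total, 1, chrom_lengths[chroms] - lens))
      loci <- data.frame(name = nms, chrom = chroms, start = starts,
                         end = starts + lens - 1,
                         strand = sample(c("+", "-"), n_total, replace = TRUE),
                         context = "intergenic", kind = kind,
                         stringsAsFactors = FALSE)
    }
    list(loci = loci, sequences = seqs, truth = truths)
  })
}

#' Simulate an alignment of diverged copies of a consensus
#'
#' Each member is the consensus with every site substituted independently
#' with probability equal to the requested expected p-distance (uniform
#' choice among the three alternatives), so realised p-distances are
#' binomial around their targets.
#'
#' @param consensus Ungapped nucleotide string.
#' @param divergences Numeric vector in `[0, 0.75)`, one per member.
#' @param seed Optional integer seed.
#' @return An `erv_msa` (no gaps); attribute `truth` holds the realised
#'   per-member p-distances.
#' @export
simulate_msa_from_consensus <- function(consensus, divergences, seed = NULL) {
  if (any(divergences < 0 | divergences >= 0.75))
    stop("config error: divergence must be in [0, 0.75)", call. = FALSE)
  .with_seed(seed, {
    cons <- strsplit(normalize_residues(consensus), "")[[1]]
    members <- vapply(seq_along(divergences), function(i) {
      paste(.mutate_direct(cons, divergences[i]), collapse = "")
    }, character(1))
    names(members) <- sprintf("member_%02d", seq_along(divergences))
    msa <- as_msa(members)
    realized <- vapply(members, function(m) {
      mean(strsplit(m, "")[[1]] != cons)
    }, numeric(1))
    attr(msa, "truth") <- list(divergences = divergences, realized = realized)
    msa
  })
}

# substitute each site with exactly probability p (uniform alternatives)
.mutate_direct <- function(bases, p) {
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  hit <- which(runif(length(bases)) < p & bases %in% names(alts))
  bases[hit] <- vapply(bases[hit], function(b) sample(alts[[b]], 1L),
                       character(1))
  bases
}
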