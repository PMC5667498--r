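# Integration dating from LTR divergence. A provirus' two LTRs are identical
# at integration; their post-insertion divergence D (% divergent sites,
# p-distance with pairwise deletion, CpG dinucleotides removed) gives the
# age as T = D% / rate, halved for the LTR-vs-LTR comparison because both
# copies accumulate substitutions independently. Component estimates
# (LTR vs LTR, LTR vs consensus, gene vs consensus) are averaged per locus
# after excluding high-dispersion components.

#' Round half away from zero
#'
#' Table-style rounding (22.375 -> 22.4 at 1 decimal), as opposed to the
#' IEEE half-to-even rule of [round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column the most frequent symbol among `{A,C,G,T,-}` wins; `N` never
#' wins (it is ignored in the tally). Columns where the gap wins are omitted,
#' so the consensus is ungapped. Ties between bases are broken
#' alphabetically (A < C < G < T); a base beats the gap on a tie.
#'
#' @param msa An [as_msa()] alignment (>= 2 members).
#' @return Ungapped consensus string.
#' @export
majority_consensus <- function(msa) {
  if (length(msa) < 2L) stop("input error: need >= 2 aligned members", call. = FALSE)
  m <- .msa_matrix(msa)
  symbols <- c("A", "C", "G", "T", "-")   # tie order: bases first, gap last
  cons <- apply(m, 2, function(col) {
    counts <- vapply(symbols, function(s) sum(col == s), integer(1))
    if (all(counts == 0L)) return("-")    # all-N column: drop
    symbols[which.max(counts)]            # first max = alphabetical tie-break
  })
  paste(cons[cons != "-"], collapse = "")
}

#' Mask CpG dinucleotide sites in an aligned pair
#'
#' Any adjacent pair of non-gap residues reading C then G in either sequence
#' (adjacency located ignoring gaps) has both alignment columns replaced by
#' `N` in both sequences, so the sites are excluded downstream by pairwise
#' deletion. This removes the hypermutating CpG signal before dating.
#'
#' @param a,b Equal-length gapped sequences.
#' @return List with `a` and `b` masked.
#' @export
mask_cpg_sites <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("input error: unequal lengths", call. = FALSE)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  mask <- rep(FALSE, length(av))
  for (v in list(av, bv)) {
    res <- which(v != "-")
    if (length(res) >= 2L) {
      first <- res[-length(res)]; second <- res[-1]
      cg <- v[first] == "C" & v[second] == "G"
      mask[first[cg]] <- TRUE
      mask[second[cg]] <- TRUE
    }
  }
  av[mask & av != "-"] <- "N"
  bv[mask & bv != "-"] <- "N"
  list(a = paste(av, collapse = ""), b = paste(bv, collapse = ""))
}

#' p-distance with pairwise deletion
#'
#' Sites where either sequence has `-` or `N` are excluded; the distance is
#' the percentage of mismatching retained sites.
#'
#' @param a,b Equal-length gapped sequences.
#' @return List with `d_percent` and `sites_used`.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("input error: unequal lengths", call. = FALSE)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  use <- !(av %in% c("-", "N")) & !(bv %in% c("-", "N"))
  n <- sum(use)
  if (n == 0L) stop("undefined distance: no usable sites after pairwise deletion",
                    call. = FALSE)
  list(d_percent = 100 * sum(av[use] != bv[use]) / n, sites_used = n)
}

#' Age from inter-LTR divergence
#'
#' `T = D% / rate / 2`: the divergence between the two LTR copies of one
#' provirus accumulates on both copies independently, hence the halving.
#'
#' @param d_percent Percent divergent sites.
#' @param rate Substitution rate, % per nt per My.
#' @return Age in My.
#' @export
age_from_ltr_pair <- function(d_percent, rate = 0.2) {
  if (rate <= 0) stop("config error: rate must be positive", call. = FALSE)
  d_percent / rate / 2
}

#' Age from divergence to a consensus
#'
#' `T = D% / rate` (no halving: the consensus approximates the ancestral
#' state, so the divergence is one lineage's worth).
#'
#' @inheritParams age_from_ltr_pair
#' @return Age in My.
#' @export
age_from_consensus <- function(d_percent, rate = 0.2) {
  if (rate <= 0) stop("config error: rate must be positive", call. = FALSE)
  d_percent / rate
}

#' Bootstrap dispersion of a pairwise divergence
#'
#' Alignment columns are resampled with replacement `n` times; the SD of the
#' replicate D% values is returned. Deterministic under a fixed seed.
#'
#' @param a,b Equal-length gapped sequences.
#' @param n Number of replicates (>= 2).
#' @param seed Optional integer seed (private stream).
#' @return List with `bootstrap_sd`, `n_boot` and the replicate values.
#' @export
bootstrap_divergence <- function(a, b, n = 1000, seed = NULL) {
  if (n < 2) stop("config error: need n >= 2 replicates", call. = FALSE)
  p_distance(a, b)   # validates and errors on degenerate pairs
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  L <- length(av)
  .with_seed(seed, {
    reps <- vapply(seq_len(n), function(i) {
      idx <- sample.int(L, L, replace = TRUE)
      use <- !(av[idx] %in% c("-", "N")) & !(bv[idx] %in% c("-", "N"))
      if (!any(use)) return(NA_real_)
      100 * sum(av[idx][use] != bv[idx][use]) / sum(use)
    }, numeric(1))
    list(bootstrap_sd = sd(reps, na.rm = TRUE), n_boot = n, replicates = reps)
  })
}

#' One divergence/age component estimate
#'
#' Measures D% between an aligned pair (optionally CpG-masked), its bootstrap
#' dispersion, and the implied age.
#'
#' @param a,b Equal-length gapped sequences.
#' @param method `"ltr_vs_ltr"`, `"ltr_vs_consensus"` or
#'   `"gene_vs_consensus"`.
#' @param region_label Region name for reporting (e.g. `"5'LTR"`, `"pol"`).
#' @param rate Substitution rate, % per nt per My.
#' @param halve_ltr Halve the LTR-vs-LTR age (see [age_from_ltr_pair()]).
#' @param mask_cpg Remove CpG dinucleotide sites before measuring.
#' @param n_boot Bootstrap replicates (0 disables).
#' @param seed Optional integer seed for the bootstrap.
#' @return One-row data.frame: method, region_label, d_percent, sites_used,
#'   bootstrap_sd, n_boot, t_my.
#' @export
divergence_estimate <- function(a, b, method = "ltr_vs_ltr",
                                region_label = method, rate = 0.2,
                                halve_ltr = TRUE, mask_cpg = TRUE,
                                n_boot = 0, seed = NULL) {
  if (mask_cpg) {
    m <- mask_cpg_sites(a, b); a <- m$a; b <- m$b
  }
  pd <- p_distance(a, b)
  bsd <- NA_real_
  if (n_boot >= 2) bsd <- bootstrap_divergence(a, b, n_boot, seed)$bootstrap_sd
  t_my <- if (method == "ltr_vs_ltr" && halve_ltr) {
    age_from_ltr_pair(pd$d_percent, rate)
  } else {
    age_from_consensus(pd$d_percent, rate)
  }
  data.frame(method = method, region_label = region_label,
             d_percent = pd$d_percent, sites_used = pd$sites_used,
             bootstrap_sd = bsd, n_boot = n_boot, t_my = t_my,
             stringsAsFactors = FALSE)
}

#' Aggregate component ages into a per-locus age estimate
#'
#' A component is excluded when its bootstrap coefficient of variation
#' (`bootstrap_sd / d_percent`) exceeds `cv_threshold`, or when flagged as
#' excluded in the input. The final T is the arithmetic mean of retained
#' component ages. If every component is excluded the locus is flagged
#' undatable (final T is `NA`), not an error.
#'
#' @param components data.frame with columns `region` (or `region_label`) and
#'   `t_my`; optional `d_percent`, `bootstrap_sd`, `excluded` (logical),
#'   `note`.
#' @param cv_threshold Relative-dispersion exclusion threshold (default 0.20).
#' @param locus Locus name for reporting.
#' @return Object of class `age_estimate`.
#' @export
aggregate_locus_age <- function(components, cv_threshold = 0.20, locus = NA_character_) {
  stopifnot(nrow(components) >= 1L)
  if (is.null(components$region) && !is.null(components$region_label))
    components$region <- components$region_label
  excl <- if (!is.null(components$excluded)) isTRUE_v(components$excluded)
          else rep(FALSE, nrow(components))
  reason <- ifelse(excl, "flagged", NA_character_)
  if (!is.null(components$bootstrap_sd) && !is.null(components$d_percent)) {
    cv <- components$bootstrap_sd / components$d_percent
    high <- !is.na(cv) & cv > cv_threshold
    reason[high & !excl] <- sprintf("bootstrap CV %.2f > %.2f", cv[high & !excl],
                                    cv_threshold)
    excl <- excl | high
  }
  retained <- components$t_my[!excl]
  final <- if (length(retained)) mean(retained) else NA_real_
  structure(list(locus = locus, components = components, excluded = excl,
                 exclusion_reason = reason,
                 final_t_my = final, undatable = !length(retained),
                 cv_threshold = cv_threshold),
            class = "age_estimate")
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("Age estimate for locus %s\n", x$locus))
  df <- x$components
  df$excluded <- x$excluded
  print(df, row.names = FALSE)
  if (x$undatable) cat("Final T: undatable (all components excluded)\n")
  else cat(sprintf("Final T: %.1f My (mean of %d retained components)\n",
                   round_half_up(x$final_t_my, 1), sum(!x$excluded)))
  invisible(x)
}

#' Summarise per-locus age estimates into an age table
#'
#' Builds the canonical dating table: one row per locus, one column per
#' method/region component, an `average` column (per-locus mean of retained
#' components), plus per-method column means over the loci possessing that
#' component and the implied mean divergence per method
#' (`rate * mean(T)`, with the LTR-vs-LTR back-conversion left unhalved so
#' that it matches the T = D/rate reading of the printed column mean).
#'
#' @param estimates List of [aggregate_locus_age()] objects.
#' @param rate Substitution rate used for the implied divergences.
#' @param digits Decimals for the rounded table (values are also kept at
#'   full precision).
#' @return Object of class `age_table`: list with `table` (rounded
#'   data.frame), `column_means`, `implied_divergence`, `full` (unrounded).
#' @export
summarize_age_table <- function(estimates, rate = 0.2, digits = 1) {
  stopifnot(length(estimates) >= 1L)
  canonical <- c("ltr_vs_ltr", "ltr_vs_consensus", "gag", "pol", "env")
  regions <- unique(unlist(lapply(estimates, function(e) e$components$region)))
  regions <- c(intersect(canonical, regions), setdiff(regions, canonical))
  rows <- lapply(estimates, function(e) {
    v <- setNames(rep(NA_real_, length(regions)), regions)
    keep <- !e$excluded
    v[e$components$region[keep]] <- e$components$t_my[keep]
    c(v, average = e$final_t_my)
  })
  full <- as.data.frame(do.call(rbind, rows))
  full <- cbind(locus = vapply(estimates, function(e) e$locus, character(1)),
                full, stringsAsFactors = FALSE)
  col_means <- vapply(regions, function(r) mean(full[[r]], na.rm = TRUE),
                      numeric(1))
  implied <- rate * col_means
  tab <- full
  for (r in c(regions, "average")) tab[[r]] <- round_half_up(tab[[r]], digits)
  structure(list(table = tab,
                 column_means = round_half_up(col_means, digits),
                 implied_divergence = round_half_up(implied, digits),
                 full = full, rate = rate),
            class = "age_table")
}

#' @export
print.age_table <- function(x, ...) {
  cat("Estimated times of integration (My)\n")
  print(x$table, row.names = FALSE)
  cat("Column means:", paste(sprintf("%s=%.1f", names(x$column_means),
                                     x$column_means), collapse = "  "), "\n")
  cat("Implied mean divergence (%):",
      paste(sprintf("%s=%.1f", names(x$implied_divergence),
                    x$implied_divergence), collapse = "  "), "\n")
  invisible(x)
}

#' Read a component-age fixture table
#'
#' TSV with columns `locus`, `region`, `t_my`, optional `excluded`, `note`;
#' one row per dating component.
#'
#' @param path Path to the TSV (default: the packaged reference table).
#' @param cv_threshold Passed to [aggregate_locus_age()].
#' @return List of `age_estimate` objects, one per locus (input order).
#' @export
read_age_components <- function(path = system.file("extdata",
                                                   "reference_age_components.tsv",
                                                   package = "ervclock"),
                                cv_threshold = 0.20) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "region", "t_my") %in% names(df)))
  loci <- unique(df$locus)
  lapply(loci, function(l) {
    aggregate_locus_age(df[df$locus == l, , drop = FALSE],
                        cv_threshold = cv_threshold, locus = l)
  })
}

#' Date one simulated or real provirus from its two LTRs
#'
#' Convenience wrapper: CpG-mask the aligned LTR pair, measure D% with
#' pairwise deletion, convert to age.
#'
#' @param ltr5,ltr3 Equal-length (aligned) LTR sequences.
#' @param rate Substitution rate, % per nt per My.
#' @param halve_ltr Halve (default TRUE, the independent-accumulation
#'   argument).
#' @param mask_cpg Remove CpG sites first.
#' @return Age in My.
#' @export
date_ltr_pair <- function(ltr5, ltr3, rate = 0.2, halve_ltr = TRUE,
                          mask_cpg = TRUE) {
  if (mask_cpg) {
    m <- mask_cpg_sites(ltr5, ltr3); ltr5 <- m$a; ltr3 <- m$b
  }
  d <- p_distance(ltr5, ltr3)$d_percent
  if (halve_ltr) age_from_ltr_pair(d, rate) else age_from_consensus(d, rate)
}
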