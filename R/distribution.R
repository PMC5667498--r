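# Chromosomal distribution of integration events versus a length-
# proportional random model: expected counts E_c = L_c * N / sum(L), an
# overall goodness-of-fit chi-square across chromosomes, and per-chromosome
# 1-df tests on the {this chromosome, all others} partition.

#' Expected integration counts under length-proportional randomness
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param total_insertions Total number of integration events N.
#' @return Named numeric vector `E_c = L_c * N / sum(L)` (sums to N exactly).
#' @export
expected_counts <- function(chrom_lengths, total_insertions) {
  if (length(chrom_lengths) < 1L)
    stop("input error: empty chromosome table", call. = FALSE)
  if (any(chrom_lengths <= 0))
    stop("input error: chromosome lengths must be positive", call. = FALSE)
  chrom_lengths * total_insertions / sum(chrom_lengths)
}

#' Overall chi-square test of the integration distribution
#'
#' `X^2 = sum (O - E)^2 / E` with `df = k - 1`; the p-value is the upper
#' chi-square tail. Chromosomes with zero expectation are excluded with a
#' warning (df adjusted).
#'
#' @param observed,expected Aligned named vectors of observed and expected
#'   counts.
#' @return List: statistic, df, p_value, n_excluded.
#' @export
overall_chi_square <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  drop <- expected == 0
  if (any(drop)) {
    warning(sum(drop), " chromosome(s) with zero expectation excluded")
    observed <- observed[!drop]; expected <- expected[!drop]
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       n_excluded = sum(drop))
}

#' Per-chromosome enrichment/depletion tests
#'
#' For each chromosome c, a 1-df chi-square on the two-cell partition
#' `{c, all others}`: observed `(O_c, N - O_c)` against expected
#' `(E_c, N - E_c)`.
#'
#' @inheritParams overall_chi_square
#' @return List: `p_values` (named), `statistics` (named), `mean_p`.
#' @export
per_chromosome_tests <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  N <- sum(observed)
  stats <- vapply(seq_along(observed), function(i) {
    e1 <- expected[i]; e2 <- N - expected[i]
    if (e1 <= 0 || e2 <= 0) return(NA_real_)
    (observed[i] - e1)^2 / e1 + ((N - observed[i]) - e2)^2 / e2
  }, numeric(1))
  names(stats) <- names(observed)
  p <- pchisq(stats, 1L, lower.tail = FALSE)
  list(p_values = p, statistics = stats, mean_p = mean(p, na.rm = TRUE))
}

#' Full chromosomal-distribution analysis of a locus table
#'
#' Counts integration events per chromosome (optionally collapsing
#' duplicated loci that share one integration), builds length-proportional
#' expectations, and runs the overall and per-chromosome chi-square tests.
#'
#' @param loci Locus data.frame with a `chrom` column; an optional
#'   `duplicate_of` column collapses rows onto their parent locus.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param collapse_duplicates Honour `duplicate_of` (default TRUE).
#' @return Object of class `chrom_dist`: per-chromosome table (observed,
#'   expected, fold, p), overall test, mean per-chromosome p.
#' @export
chrom_distribution <- function(loci, chrom_lengths, collapse_duplicates = TRUE) {
  if (collapse_duplicates && !is.null(loci$duplicate_of)) {
    loci <- loci[is.na(loci$duplicate_of) | loci$duplicate_of == "", ,
                 drop = FALSE]
  }
  obs <- vapply(names(chrom_lengths), function(ch) sum(loci$chrom == ch),
                numeric(1))
  exp_c <- expected_counts(chrom_lengths, sum(obs))
  overall <- overall_chi_square(obs, exp_c)
  per <- per_chromosome_tests(obs, exp_c)
  tab <- data.frame(chrom = names(chrom_lengths),
                    length_bp = as.numeric(chrom_lengths),
                    observed = obs, expected = exp_c,
                    fold = ifelse(exp_c > 0, obs / exp_c, NA_real_),
                    p_value = per$p_values, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, overall = overall, mean_p = per$mean_p),
            class = "chrom_dist")
}

#' @export
print.chrom_dist <- function(x, ...) {
  cat("Chromosomal distribution vs length-proportional expectation\n")
  tab <- x$table
  tab$expected <- round(tab$expected, 2)
  tab$fold <- round(tab$fold, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall: X2 = %.3f, df = %d, p = %.3g;  mean per-chromosome p = %.2f\n",
              x$overall$statistic, x$overall$df, x$overall$p_value, x$mean_p))
  invisible(x)
}
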