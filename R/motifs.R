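# Sequence-feature detection: PBS extraction and tRNA assignment, protein
# motif patterns characteristic of Betaretroviruses (Pro G-patch, Pro
# dUTPase, Gag NC zinc fingers), A/T-rich stretch detection, nucleotide
# composition bias, ORF integrity (premature stops / frameshifts) and the
# type I/II subtype call.

#' Load a PBS library
#'
#' A primer-binding-site library is a TSV with columns `trna` (one-letter
#' amino-acid code of the priming tRNA), `sequence` (18 nt) and `name`. The
#' packaged default is a small synthetic library (a lysine exemplar plus
#' decoys); real libraries plug in via `path`.
#'
#' @param path Path to the library TSV.
#' @return data.frame with `trna`, `sequence`, `name`.
#' @export
pbs_library <- function(path = system.file("extdata", "pbs_library_synthetic.tsv",
                                           package = "ervclock")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trna", "sequence") %in% names(df)))
  df$sequence <- normalize_residues(df$sequence)
  df
}

# identity (matches / 18 * 100) of an 18-char candidate vs an 18-char
# library entry, both as character vectors; "-" never matches
.pbs_identity <- function(cand, lib) {
  100 * sum(cand == lib & cand != "-") / length(lib)
}

#' Locate and type the primer binding site
#'
#' The PBS sits 3 nt downstream of the 5'LTR and is canonically 18 nt long;
#' windows of length 17-19 are scanned (single-indel alignment against each
#' library entry tolerated, with an indel flag). The tRNA of the
#' maximal-identity library entry is assigned; ties go to the first entry.
#'
#' @param sequence Ungapped provirus sequence.
#' @param ltr5_end 1-based position of the last 5'LTR nucleotide, or `NA`
#'   when the provirus lacks its 5'LTR (yields a not-applicable record).
#' @param library A [pbs_library()] data.frame.
#' @return List of class `pbs_record`: `applicable`, `sequence`, `aligned`
#'   (18-char, gaps for a 17-nt PBS), `offset_from_ltr_end` (3), `length`,
#'   `indel`, `assigned_trna`, `identity_percent`, `library_name`.
#' @export
find_pbs <- function(sequence, ltr5_end, library = pbs_library()) {
  if (is.null(ltr5_end) || is.na(ltr5_end)) {
    return(structure(list(applicable = FALSE), class = "pbs_record"))
  }
  start <- ltr5_end + 4L   # 3 spacer residues after the LTR
  if (start + 16L > nchar(sequence)) {
    return(structure(list(applicable = FALSE), class = "pbs_record"))
  }
  libv <- lapply(library$sequence, function(s) strsplit(s, "")[[1]])
  best <- list(identity = -1)
  for (len in 17:19) {
    if (start + len - 1L > nchar(sequence)) next
    cand <- strsplit(substr(sequence, start, start + len - 1L), "")[[1]]
    # candidate alignments onto the 18-column library frame
    alns <- if (len == 18L) {
      list(list(a = cand, indel = FALSE))
    } else if (len == 19L) {
      lapply(seq_len(19L), function(j) list(a = cand[-j], indel = TRUE))
    } else {
      lapply(seq_len(18L), function(j) {
        list(a = append(cand, "-", after = j - 1L), indel = TRUE)
      })
    }
    for (al in alns) {
      for (e in seq_along(libv)) {
        id <- .pbs_identity(al$a, libv[[e]])
        if (id > best$identity) {
          best <- list(identity = id, entry = e, len = len,
                       aligned = paste(al$a, collapse = ""),
                       seq = paste(cand, collapse = ""), indel = al$indel)
        }
      }
    }
  }
  structure(list(applicable = TRUE, sequence = best$seq,
                 aligned = best$aligned, offset_from_ltr_end = 3L,
                 length = best$len, indel = best$indel,
                 assigned_trna = library$trna[best$entry],
                 identity_percent = best$identity,
                 library_name = library$name[best$entry]),
            class = "pbs_record")
}

#' @export
print.pbs_record <- function(x, ...) {
  if (!x$applicable) {
    cat("PBS: not applicable (no 5'LTR)\n")
  } else {
    cat(sprintf("PBS %s (%d nt%s), tRNA %s, identity %.1f%%\n", x$sequence,
                x$length, if (x$indel) ", indel" else "", x$assigned_trna,
                x$identity_percent))
  }
  invisible(x)
}

#' Logo-ready per-position profile of PBS records
#'
#' @param records List of applicable [find_pbs()] records (their `aligned`
#'   18-column forms), or a character vector of equal-length sequences.
#' @return Integer matrix, rows `A,C,G,T,-`, one column per position; column
#'   sums equal the number of records contributing a residue at the column.
#' @export
pbs_alignment_profile <- function(records) {
  seqs <- if (is.character(records)) records
          else vapply(Filter(function(r) r$applicable, records),
                      function(r) r$aligned, character(1))
  if (length(seqs) < 1L) stop("input error: no PBS records", call. = FALSE)
  stopifnot(length(unique(nchar(seqs))) == 1L)
  m <- do.call(rbind, strsplit(seqs, ""))
  symbols <- c("A", "C", "G", "T", "-")
  prof <- vapply(seq_len(ncol(m)), function(j) {
    vapply(symbols, function(s) sum(m[, j] == s), integer(1))
  }, integer(length(symbols)))
  rownames(prof) <- symbols
  prof
}

# Betaretroviral protein motif patterns; x = any residue, the G-patch
# spacer run is bounded (1-15) because an unbounded run is degenerate
.PROTEIN_MOTIFS <- list(
  g_patch = list(pattern = "GYx2GxGLGx4GxnG", regex = "GY..G.GLG....G.{1,15}G"),
  dutpase = list(pattern = "DSDYxGEIQ", regex = "DSDY.GEIQ"),
  gag_zinc_finger = list(pattern = "CX2CX4HX4C", regex = "C..C....H....C")
)

# all (overlapping) matches of a regex via lookahead capture
.overlapping_matches <- function(seq, regex) {
  m <- gregexpr(paste0("(?=(", regex, "))"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer(),
                                     text = character()))
  st <- as.integer(attr(m, "capture.start")[, 1])
  ln <- as.integer(attr(m, "capture.length")[, 1])
  data.frame(start = st, end = st + ln - 1L,
             text = substring(seq, st, st + ln - 1L), stringsAsFactors = FALSE)
}

#' Scan for Betaretroviral protein motifs
#'
#' Searches the Pro C-terminal G-patch (GYx2GxGLGx4GxnG, spacer run bounded
#' 1-15), Pro N-terminal dUTPase (DSDYxGEIQ) and Gag NC zinc finger
#' (CX2CX4HX4C) patterns. Nucleotide input is translated in all three
#' forward reading frames (optionally both strands); overlapping hits are
#' all reported.
#'
#' @param x Amino-acid or nucleotide string.
#' @param type `"auto"` guesses from the alphabet; `"aa"` or `"nt"` force.
#' @param both_strands Also scan the reverse-complement frames of nucleotide
#'   input.
#' @param motifs Subset of motif names to scan.
#' @return data.frame: motif_name, pattern, frame (0/1/2, `NA` for aa
#'   input), strand, start, end (aa coordinates in the translated frame),
#'   matched_text. Empty data.frame when no hits.
#' @export
scan_protein_motifs <- function(x, type = c("auto", "aa", "nt"),
                                both_strands = FALSE,
                                motifs = names(.PROTEIN_MOTIFS)) {
  type <- match.arg(type)
  x <- toupper(x)
  if (type == "auto") {
    type <- if (grepl("^[ACGTNU-]*$", x)) "nt" else "aa"
  }
  frames <- if (type == "aa") {
    data.frame(frame = NA_integer_, strand = "+", aa = x,
               stringsAsFactors = FALSE)
  } else {
    strands <- if (both_strands) c("+", "-") else "+"
    do.call(rbind, lapply(strands, function(s) {
      nt <- if (s == "+") x else reverse_complement(x)
      do.call(rbind, lapply(0:2, function(f) {
        sub <- substr(nt, f + 1L, nchar(nt))
        sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
        aa <- if (nchar(sub) >= 3L) {
          as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                             if.fuzzy.codon = "X"))
        } else ""
        data.frame(frame = f, strand = s, aa = aa, stringsAsFactors = FALSE)
      }))
    }))
  }
  hits <- lapply(seq_len(nrow(frames)), function(i) {
    do.call(rbind, lapply(motifs, function(mn) {
      mm <- .overlapping_matches(frames$aa[i], .PROTEIN_MOTIFS[[mn]]$regex)
      if (nrow(mm) == 0L) return(NULL)
      data.frame(motif_name = mn, pattern = .PROTEIN_MOTIFS[[mn]]$pattern,
                 frame = frames$frame[i], strand = frames$strand[i],
                 start = mm$start, end = mm$end, matched_text = mm$text,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(motif_name = character(), pattern = character(),
                      frame = integer(), strand = character(),
                      start = integer(), end = integer(),
                      matched_text = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Find A/T-rich stretches
#'
#' Reports maximal runs formed by merging every window of length `min_len`
#' whose A+T fraction is at least `min_at`.
#'
#' @param sequence Ungapped nucleotide string.
#' @param min_len Minimum qualifying window length (default 800 nt).
#' @param min_at Minimum A+T fraction in a qualifying window (default 0.67).
#' @return data.frame: start, end, length, at_fraction (fraction over the
#'   merged interval). Zero rows when nothing qualifies.
#' @export
find_at_rich_stretches <- function(sequence, min_len = 800, min_at = 0.67) {
  stopifnot(min_len >= 1, min_at > 0, min_at <= 1)
  v <- strsplit(toupper(sequence), "")[[1]]
  L <- length(v)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      at_fraction = numeric())
  if (L < min_len) return(empty)
  cs <- cumsum(v %in% c("A", "T"))
  starts <- seq_len(L - min_len + 1L)
  frac <- (cs[starts + min_len - 1L] - c(0, cs)[starts]) / min_len
  ok <- which(frac >= min_at)
  if (!length(ok)) return(empty)
  # merge overlapping qualifying windows into maximal runs
  runs <- split(ok, cumsum(c(1L, diff(ok) > min_len)))
  out <- do.call(rbind, lapply(runs, function(r) {
    s <- min(r); e <- max(r) + min_len - 1L
    data.frame(start = s, end = e, length = e - s + 1L,
               at_fraction = (cs[e] - c(0, cs)[s]) / (e - s + 1L))
  }))
  rownames(out) <- NULL
  out
}

#' Per-base composition summary across sequences
#'
#' Frequencies are computed per sequence over `{A,C,G,T}` (N and gaps are
#' excluded from the denominator), then summarised across sequences.
#'
#' @param sequences Character vector of sequences.
#' @return List: `per_sequence` (matrix of fractions, one row per sequence),
#'   `summary` (data.frame base/mean/min/max/sd, in percent, full
#'   precision), `report` (the summary with integer-rounded percentages).
#' @export
nucleotide_frequencies <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(sequences, function(s) {
    v <- strsplit(toupper(s), "")[[1]]
    v <- v[v %in% bases]
    if (!length(v)) {
      warning("skipping sequence with no unambiguous bases")
      return(NULL)
    }
    vapply(bases, function(b) mean(v == b), numeric(1))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("input error: no usable sequences", call. = FALSE)
  per <- do.call(rbind, rows)
  colnames(per) <- bases
  summ <- data.frame(base = bases,
                     mean = 100 * colMeans(per),
                     min = 100 * apply(per, 2, min),
                     max = 100 * apply(per, 2, max),
                     sd = 100 * apply(per, 2, sd),
                     stringsAsFactors = FALSE)
  report <- summ
  for (cl in c("mean", "min", "max", "sd")) {
    report[[cl]] <- as.integer(round_half_up(report[[cl]], 0))
  }
  list(per_sequence = per, summary = summ, report = report)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Assess ORF integrity against a reference coding sequence
#'
#' Input is a codon-aware pairwise alignment of the region against the
#' reference CDS (equal-length gapped strings; the reference reading frame
#' starts at its first non-gap base). Internal stop codons are reported by
#' reference residue index; any gap run (in either row) whose length is not
#' a multiple of 3 is a frameshift at its codon position.
#'
#' @param region_aln Gapped region sequence.
#' @param reference_aln Gapped reference CDS (ungapped length a multiple
#'   of 3).
#' @return List of class `orf_report`: `putein_length_aa`, `internal_stops`
#'   (reference residue indices), `frameshifts` (data.frame codon /
#'   at_boundary), `intact`.
#' @export
assess_orf_integrity <- function(region_aln, reference_aln) {
  if (nchar(region_aln) != nchar(reference_aln))
    stop("input error: alignment rows differ in length", call. = FALSE)
  rv <- strsplit(toupper(region_aln), "")[[1]]
  fv <- strsplit(toupper(reference_aln), "")[[1]]
  ref_len <- sum(fv != "-")
  if (ref_len < 3L || sum(rv != "-") < 3L)
    stop("input error: need at least one codon", call. = FALSE)
  ref_pos <- cumsum(fv != "-")          # reference coordinate per column
  n_codons <- ref_len %/% 3L

  # frameshifts: gap runs of non-codon length in either row
  fs <- list()
  for (row in list(rv, fv)) {
    r <- rle(row == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths %% 3L != 0L)) {
      p <- max(1L, ref_pos[starts[k]])
      codon <- ceiling(p / 3)
      fs[[length(fs) + 1L]] <- data.frame(codon = codon,
                                          at_boundary = p %% 3L == 1L)
    }
  }
  frameshifts <- if (length(fs)) unique(do.call(rbind, fs))
                 else data.frame(codon = integer(), at_boundary = logical())

  # stops: translate region codons in the reference frame
  stops <- integer(0)
  aa_count <- 0L
  for (k in seq_len(n_codons)) {
    cols <- which(ref_pos %in% ((3L * (k - 1L) + 1L):(3L * k)) & fv != "-")
    codon <- paste(rv[cols], collapse = "")
    if (grepl("-", codon, fixed = TRUE) || nchar(codon) != 3L) next
    if (codon %in% .STOP_CODONS) {
      if (k < n_codons) stops <- c(stops, k)
    } else if (!grepl("N", codon, fixed = TRUE)) {
      aa_count <- aa_count + 1L
    }
  }
  structure(list(putein_length_aa = aa_count, internal_stops = stops,
                 frameshifts = frameshifts,
                 intact = length(stops) == 0L && nrow(frameshifts) == 0L),
            class = "orf_report")
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf("ORF integrity: %s; %d aa; stops at [%s]; %d frameshift(s)\n",
              if (x$intact) "intact" else "defective", x$putein_length_aa,
              paste(x$internal_stops, collapse = ","), nrow(x$frameshifts)))
  invisible(x)
}

# columns of an alignment covered by a reference-coordinate window
.map_ref_window <- function(ref_aln, start, end) {
  fv <- strsplit(ref_aln, "")[[1]]
  pos <- cumsum(fv != "-")
  which(pos >= start & pos <= end & fv != "-")
}

#' Classify a provirus as type I or II
#'
#' Types differ in the pol-3'/env-5' reference window (3159-4130): type I
#' proviruses carry an A/T-rich stretch there, type II a coding-like
#' (Rec-bearing) segment of ordinary composition. The call is `"I"` when
#' the query's window contains a qualifying A/T-rich run (>= `min_at` over
#' >= `min_len` nt), `"II"` when the window is present but not A/T-rich,
#' and `"unassigned"` when the window is (almost entirely) deleted.
#'
#' @param query_aln,ref_aln Equal-length gapped strings: the provirus
#'   aligned to the group reference.
#' @param window Reference window, 1-based inclusive.
#' @param min_at,min_len A/T-richness thresholds.
#' @return `"I"`, `"II"` or `"unassigned"`.
#' @export
classify_subtype <- function(query_aln, ref_aln, window = c(3159, 4130),
                             min_at = 0.67, min_len = 600) {
  cols <- .map_ref_window(ref_aln, window[1], window[2])
  if (!length(cols)) return("unassigned")
  qv <- strsplit(query_aln, "")[[1]][cols]
  region <- paste(qv[qv != "-"], collapse = "")
  if (nchar(region) < min_len) return("unassigned")
  hits <- find_at_rich_stretches(region, min_len = min_len, min_at = min_at)
  if (nrow(hits) > 0L) "I" else "II"
}

#' Conservation of LTR regulatory motifs
#'
#' Scores the TATA box (TATAAA), SV40 enhancer (GTGGAAAG) and PolyA signal
#' (AATAAA) at their mapped reference coordinates in both LTRs as
#' exact-match / mismatch counts.
#'
#' @param query_aln,ref_aln Equal-length gapped strings: provirus aligned to
#'   the group reference.
#' @param features Feature frame with the motif coordinates (default: the
#'   template frame).
#' @return data.frame: motif, ltr, expected, observed, mismatches,
#'   conserved.
#' @export
ltr_motif_conservation <- function(query_aln, ref_aln,
                                   features = .TEMPLATE_FEATURES) {
  motifs <- data.frame(
    feature = c("tata5", "sv40_5", "polya5", "tata3", "sv40_3", "polya3"),
    motif = rep(c("tata", "sv40", "polya"), 2),
    ltr = rep(c("5'LTR", "3'LTR"), each = 3),
    expected = rep(c("TATAAA", "GTGGAAAG", "AATAAA"), 2),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(motifs)), function(i) {
    f <- features[features$feature == motifs$feature[i], ]
    cols <- .map_ref_window(ref_aln, f$start, f$end)
    obs <- paste(strsplit(query_aln, "")[[1]][cols], collapse = "")
    exp_v <- strsplit(motifs$expected[i], "")[[1]]
    obs_v <- strsplit(obs, "")[[1]]
    mm <- if (length(obs_v) == length(exp_v)) sum(obs_v != exp_v)
          else length(exp_v)
    data.frame(motif = motifs$motif[i], ltr = motifs$ltr[i],
               expected = motifs$expected[i], observed = obs,
               mismatches = mm, conserved = mm == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
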