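#' @importFrom stats sd rbinom runif rgeom setNames pchisq
#' @importFrom utils read.delim write.table head tail
NULL

# Canonical nucleotide alphabets. N is treated as missing data downstream
# (excluded by pairwise deletion); "-" only ever appears inside alignments.
.NUC_ALPHABET <- c("A", "C", "G", "T", "N")
.GAP_ALPHABET <- c(.NUC_ALPHABET, "-")

#' Normalise a nucleotide string
#'
#' Uppercases, maps U to T, and validates against the `{A,C,G,T,N}` alphabet
#' (plus `-` when `gapped = TRUE`).
#'
#' @param x Character vector of sequences.
#' @param gapped Allow the alignment gap character `-`.
#' @param what Label used in error messages.
#' @return Normalised character vector.
#' @export
normalize_residues <- function(x, gapped = FALSE, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  allowed <- if (gapped) .GAP_ALPHABET else .NUC_ALPHABET
  bad <- !grepl(paste0("^[", paste(allowed, collapse = ""), "]*$"), x)
  if (any(bad)) {
    ch <- setdiff(unique(strsplit(paste(x[bad], collapse = ""), "")[[1]]), allowed)
    stop(sprintf("illegal character(s) in %s: %s", what,
                 paste(ch, collapse = " ")), call. = FALSE)
  }
  x
}

#' Read a FASTA file into named nucleotide strings
#'
#' Sequences are returned as a named character vector in canonical uppercase
#' form (U mapped to T). Records with characters outside `{A,C,G,T,N,-}`
#' raise a format error naming the offending record.
#'
#' @param path Path to a FASTA or aligned-FASTA file.
#' @param gapped Allow `-` (aligned FASTA).
#' @return Named character vector of sequences; names carry the full header
#'   line (id plus description).
#' @export
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop("FASTA format error at line 1: empty file", call. = FALSE)
  if (!startsWith(first, ">"))
    stop("FASTA format error at line 1: expected '>' header", call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("FASTA format error: no records in ", path, call. = FALSE)
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("FASTA format error: empty sequence for record ",
         names(seqs)[!nzchar(seqs)][1L], call. = FALSE)
  }
  out <- vapply(seq_along(seqs), function(i) {
    normalize_residues(seqs[[i]], gapped = gapped,
                       what = paste0("record '", names(seqs)[i], "'"))
  }, character(1))
  names(out) <- names(seqs)
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param wrap Line width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}

#' Interval length on 1-based inclusive coordinates
#'
#' @param start,end 1-based inclusive positions.
#' @return `end - start + 1`.
#' @export
locus_length <- function(start, end) {
  if (any(end < start)) stop("coordinate error: end < start", call. = FALSE)
  as.integer(end - start + 1)
}

#' Parse one locus row in `name | chrom:start-end (strand)` convention
#'
#' Accepts thousands separators, ASCII hyphen or en-dash between start and
#' end, and an optional trailing `(+)`/`(-)` (Unicode minus tolerated).
#' Strand defaults to `+` when absent.
#'
#' @param text_row A single row, fields separated by `|`.
#' @return One-row data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand`, `length`, `context`.
#' @export
parse_locus_row <- function(text_row) {
  stopifnot(length(text_row) == 1L)
  parts <- trimws(strsplit(text_row, "|", fixed = TRUE)[[1]])
  if (length(parts) < 2L)
    stop("format error: expected 'name | chrom:start-end (strand)'", call. = FALSE)
  name <- parts[1]
  coord <- parts[2]
  context <- if (length(parts) >= 3L) parts[3] else "intergenic"
  strand <- "+"
  strand_m <- regmatches(coord, regexpr("\\(([+−–-])\\)", coord))
  if (length(strand_m) == 1L && nzchar(strand_m)) {
    s <- substr(strand_m, 2, 2)
    strand <- if (s == "+") "+" else "-"
    coord <- trimws(sub("\\(([+−–-])\\)", "", coord))
  }
  coord <- gsub(",", "", coord)
  # en-dash / em-dash / minus all accepted as the range separator
  coord <- gsub("[‒–—−]", "-", coord)
  m <- regmatches(coord, regexec("^([^:]+):([0-9]+)-([0-9]+)$", coord))[[1]]
  if (length(m) != 4L)
    stop("format error: cannot parse coordinates '", coord, "'", call. = FALSE)
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (is.na(start) || is.na(end))
    stop("format error: non-numeric positions in '", coord, "'", call. = FALSE)
  if (end < start) stop("coordinate error: start > end", call. = FALSE)
  data.frame(name = name, chrom = m[2], start = start, end = end,
             strand = strand, length = locus_length(start, end),
             context = context, stringsAsFactors = FALSE)
}

#' Read a locus table (TSV with header name chrom start end strand context)
#'
#' @param path Path to the TSV.
#' @return data.frame with a derived `length` column.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("locus table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$context)) df$context <- "intergenic"
  df$length <- locus_length(df$start, df$end)
  df
}

#' Write a locus table as TSV
#' @param loci data.frame of loci.
#' @param path Output path.
#' @export
write_locus_table <- function(loci, path) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Strand is metadata only throughout the package; complementing is always
#' explicit via this utility.
#'
#' @param x Character vector of (possibly gapped) sequences.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN-", "TGCAN-", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# --- alignment helpers ------------------------------------------------------

#' Construct a multiple alignment from equal-length gapped strings
#'
#' @param seqs Named character vector over `{A,C,G,T,N,-}`.
#' @return An object of class `erv_msa`: a named character vector with an
#'   `alignment_length` attribute.
#' @export
as_msa <- function(seqs) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  seqs <- vapply(seqs, normalize_residues, character(1), gapped = TRUE)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("alignment members must have identical length", call. = FALSE)
  structure(seqs, alignment_length = len, class = "erv_msa")
}

#' @export
print.erv_msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x), attr(x, "alignment_length")))
  invisible(x)
}

# character matrix view of an alignment (rows = members)
.msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unclass(msa), ""))
}
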