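# shared fixture builders: everything is generated in code under fixed seeds

random_dna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# additive distance matrix (path lengths) from a rooted ape tree
tree_distances <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[order(rownames(D)), order(colnames(D))]
}

# unrooted topology equality
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

ref_extdata <- function(file) system.file("extdata", file, package = "ervclock")

# character-by-character motif matcher, independent of the regex engine
oracle_motif_starts <- function(aa, motif) {
  v <- strsplit(aa, "")[[1]]
  n <- length(v)
  fixed <- list(
    dutpase = strsplit("DSDY.GEIQ", "")[[1]],
    gag_zinc_finger = strsplit("C..C....H....C", "")[[1]]
  )
  match_at <- function(pat, i) {
    if (i + length(pat) - 1L > n) return(FALSE)
    all(pat == "." | pat == v[i:(i + length(pat) - 1L)])
  }
  if (motif %in% names(fixed)) {
    return(which(vapply(seq_len(n), function(i) match_at(fixed[[motif]], i),
                        logical(1))))
  }
  # g_patch: GYxxGxGLGxxxxG x{1..15} G
  head_pat <- strsplit("GY..G.GLG....G", "")[[1]]
  starts <- integer(0)
  for (i in seq_len(n)) {
    if (!match_at(head_pat, i)) next
    tail_start <- i + 14L
    hit <- FALSE
    for (k in 1:15) {
      j <- tail_start + k
      if (j > n) break
      if (v[j] == "G") hit <- TRUE
    }
    if (hit) starts <- c(starts, i)
  }
  starts
}

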