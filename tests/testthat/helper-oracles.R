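# Independent oracles and shared fixtures for the test suite.

# Naive O(n*L) site scanner: tests every window against the motif and its
# reverse complement by direct string comparison. Only supports unambiguous
# motifs (all three assay enzymes are), which keeps it entirely independent
# of the package's Biostrings-based scanning path.
naive_find_sites <- function(template, enzyme) {
  L <- nchar(template)
  w <- nchar(enzyme$recognition)
  empty <- data.frame(enzyme = character(0L), strand = character(0L),
                      start = integer(0L), end = integer(0L),
                      stringsAsFactors = FALSE)
  if (L < w) return(empty)
  wins <- substring(template, 1:(L - w + 1L), w:L)
  motifs <- list(top = enzyme$recognition,
                 bottom = rflpkit::reverse_complement(enzyme$recognition))
  if (enzyme$palindromic) motifs <- motifs["top"]
  rows <- list()
  for (strand in names(motifs)) {
    hit <- which(wins == motifs[[strand]])
    if (length(hit) > 0L)
      rows[[strand]] <- data.frame(enzyme = enzyme$name, strand = strand,
                                   start = hit, end = hit + w - 1L,
                                   stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_template <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_iupac <- function(n) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  paste(sample(codes, n, replace = TRUE), collapse = "")
}

# Memoized default fixtures (deterministic, so safe to share across tests).
.fixture_env <- new.env(parent = emptyenv())

fixture_seqs <- function() {
  if (is.null(.fixture_env$seqs))
    .fixture_env$seqs <- default_amplicon_seqs()
  .fixture_env$seqs
}

fixture_enzymes <- function() {
  if (is.null(.fixture_env$enz))
    .fixture_env$enz <- default_enzymes()
  .fixture_env$enz
}
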