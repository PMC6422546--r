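# File formats: plain FASTA (60-column), tab-separated band/fragment/call
# tables, and the fixture-FASTA header convention.

#' Read / write plain FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as plain character
#' vectors. Written FASTA is wrapped at 60 columns; headers are free text
#' (the fixture convention is `<snp> key=value ...`).
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA: ", path)
  stats::setNames(as.character(set), names(set))
}

parse_fasta_metadata <- function(headers) {
  out <- lapply(headers, function(h) {
    toks <- strsplit(trimws(h), "[[:space:]]+")[[1L]]
    kv <- grep("=", toks, fixed = TRUE, value = TRUE)
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    c(id = toks[1L], vals)
  })
  out
}

#' Read fixture amplicons into the nested snp/allele structure
#'
#' Expects the header convention written by [make_fixtures()]:
#' `<snp> allele=<wild|variant> ...`. Accepts a single multi-record FASTA or
#' a directory containing `amplicon_*.fa` files.
#'
#' @param path FASTA file or fixture directory.
#' @return Nested list `seqs[[snp]][[allele]]`, as consumed by
#'   [predict_patterns()], [call_genotype()] and [validate_multiplex()].
#' @export
read_amplicon_fasta <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "^amplicon_.*\\.fa$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no amplicon_*.fa files in ", path)
    seqs <- unlist(lapply(files, read_fasta))
  } else {
    seqs <- read_fasta(path)
  }
  meta <- parse_fasta_metadata(names(seqs))
  out <- list()
  for (i in seq_along(seqs)) {
    m <- meta[[i]]
    if (!"allele" %in% names(m))
      stop("amplicon header lacks allele=... metadata: ", names(seqs)[i])
    out[[m[["id"]]]][[m[["allele"]]]] <- unname(seqs[i])
  }
  out
}

#' Read / write observed band tables
#'
#' The band table is TSV with header `sample`, `tube`, `band_bp`, one row per
#' observed band.
#'
#' @param path TSV file path.
#' @return `read_bands_tsv` returns a named list (by sample) of named lists
#'   (by tube) of numeric band-size vectors.
#' @export
read_bands_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "tube", "band_bp")
  if (!all(need %in% names(tab)))
    stop("band table needs columns ", paste(need, collapse = ", "),
         ": ", path)
  tab$band_bp <- as.numeric(tab$band_bp)
  if (anyNA(tab$band_bp)) stop("non-numeric band_bp in ", path)
  out <- list()
  for (s in unique(tab$sample)) {
    sub <- tab[tab$sample == s, ]
    out[[as.character(s)]] <-
      lapply(split(sub$band_bp, sub$tube), as.numeric)
  }
  out
}

#' Write a per-template fragment report as TSV
#'
#' @param report data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
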