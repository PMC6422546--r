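# Nucleotide-sequence primitives: validation, reverse complement, IUPAC
# matching, GC%, Wallace-rule Tm, and primer quality control.

# Degeneracy sets of the IUPAC nucleotide codes (DNA only; U is rejected).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Validate a DNA sequence string
#'
#' Upper-cases the input and checks every character against the DNA alphabet.
#' Templates must be unambiguous A/C/G/T; motifs (e.g. enzyme recognition
#' sites) may use the full IUPAC code. `U` is always rejected: this package
#' models DNA only.
#'
#' @param x single character string.
#' @param iupac if `TRUE`, allow ambiguity codes (R, Y, S, W, K, M, B, D, H,
#'   V, N) in addition to A/C/G/T.
#' @return The validated, upper-cased sequence string.
#' @export
as_dna <- function(x, iupac = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string")
  s <- toupper(gsub("[[:space:]]", "", x))
  if (nchar(s) == 0L) stop("sequence is empty")
  alphabet <- if (iupac) names(IUPAC_SETS) else c("A", "C", "G", "T")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0L)
    stop(sprintf("invalid %s base '%s' at position %d",
                 if (iupac) "IUPAC" else "DNA", chars[bad[1L]], bad[1L]))
  s
}

#' Reverse complement of a DNA sequence
#'
#' IUPAC-aware: R pairs with Y, S with S, W with W, K with M, N with N, and
#' so on. An involution: `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param s DNA sequence string (IUPAC codes allowed).
#' @return The reverse-complemented sequence string.
#' @export
reverse_complement <- function(s) {
  s <- as_dna(s, iupac = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

base_counts <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  c(A = sum(chars == "A"), C = sum(chars == "C"),
    G = sum(chars == "G"), T = sum(chars == "T"))
}

#' GC content of an unambiguous DNA sequence
#'
#' @param s DNA sequence string (A/C/G/T only; GC content is undefined for
#'   ambiguity codes and they raise an error).
#' @return Percentage of G+C bases, rounded half-up to one decimal.
#' @export
gc_percent <- function(s) {
  s <- as_dna(s)
  n <- base_counts(s)
  round_half_up(100 * (n[["G"]] + n[["C"]]) / nchar(s), 1L)
}

#' Wallace-rule melting temperature
#'
#' The rule of thumb for short oligonucleotides: Tm = 2(A+T) + 4(G+C) degrees
#' Celsius.
#'
#' @param s DNA sequence string (A/C/G/T only).
#' @return Integer Tm in degrees Celsius.
#' @export
wallace_tm <- function(s) {
  s <- as_dna(s)
  n <- base_counts(s)
  as.integer(2L * (n[["A"]] + n[["T"]]) + 4L * (n[["G"]] + n[["C"]]))
}

#' Match a window of template against an IUPAC motif
#'
#' @param motif motif string, IUPAC codes allowed.
#' @param window template window of the same length.
#' @return `TRUE` iff every window base lies in the degeneracy set of the
#'   corresponding motif base.
#' @export
iupac_match <- function(motif, window) {
  motif <- as_dna(motif, iupac = TRUE)
  window <- as_dna(window, iupac = TRUE)
  if (nchar(motif) != nchar(window))
    stop(sprintf("length mismatch: motif %d nt, window %d nt",
                 nchar(motif), nchar(window)))
  m <- strsplit(motif, "", fixed = TRUE)[[1L]]
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  all(mapply(function(mb, wb) all(IUPAC_SETS[[wb]] %in% IUPAC_SETS[[mb]]),
             m, w))
}

#' Construct a primer record
#'
#' Length, GC% and Wallace Tm are always recomputed from the sequence; values
#' printed in a primer table (datasheet, publication) can be supplied
#' alongside for consistency checking by [primer_qc()].
#'
#' @param name primer identifier, e.g. `"*4_F"`.
#' @param sequence primer sequence 5'->3' (unambiguous A/C/G/T).
#' @param printed_length,printed_tm,printed_gc optional values as printed in
#'   the source table.
#' @return An object of class `primer_record`.
#' @export
primer_record <- function(name, sequence, printed_length = NA_integer_,
                          printed_tm = NA_integer_, printed_gc = NA_real_) {
  sequence <- as_dna(sequence)
  structure(list(
    name = name,
    sequence = sequence,
    length_nt = nchar(sequence),
    tm_c = wallace_tm(sequence),
    gc_pct = gc_percent(sequence),
    printed_length = as.integer(printed_length),
    printed_tm = as.integer(printed_tm),
    printed_gc = as.numeric(printed_gc)
  ), class = "primer_record")
}

#' @export
print.primer_record <- function(x, ...) {
  cat(sprintf("primer %s: %s (%d nt, Tm %d C, GC %.1f%%)\n",
              x$name, x$sequence, x$length_nt, x$tm_c, x$gc_pct))
  invisible(x)
}

#' Primer quality-control report
#'
#' Applies standard multiplex-PCR primer design rules: length 18-30 nt and GC
#' content 40-60%. When the record carries printed (datasheet) values, these
#' are additionally checked for consistency with the sequence: a printed Tm
#' deviating by more than 2 degrees from the Wallace value, a printed GC%
#' differing from the recomputed one, or a printed length differing from the
#' sequence length each raise a warning flag.
#'
#' @param p a [primer_record()].
#' @return A data.frame with columns `rule`, `status` (`"pass"`/`"warn"`) and
#'   `detail`; never errors.
#' @export
primer_qc <- function(p) {
  stopifnot(inherits(p, "primer_record"))
  rules <- list()
  add <- function(rule, ok, detail)
    rules[[length(rules) + 1L]] <<- data.frame(
      rule = rule, status = if (ok) "pass" else "warn", detail = detail,
      stringsAsFactors = FALSE)

  add("length_18_30", p$length_nt >= 18L && p$length_nt <= 30L,
      sprintf("%d nt", p$length_nt))
  add("gc_40_60", p$gc_pct >= 40 && p$gc_pct <= 60,
      sprintf("%.1f%%", p$gc_pct))
  if (!is.na(p$printed_length))
    add("printed_length_consistent", p$printed_length == p$length_nt,
        sprintf("printed %d vs sequence %d", p$printed_length, p$length_nt))
  if (!is.na(p$printed_tm))
    add("printed_tm_within_2C", abs(p$printed_tm - p$tm_c) <= 2L,
        sprintf("printed %d vs Wallace %d", p$printed_tm, p$tm_c))
  if (!is.na(p$printed_gc))
    add("printed_gc_consistent", abs(p$printed_gc - p$gc_pct) < 0.05,
        sprintf("printed %.1f vs computed %.1f", p$printed_gc, p$gc_pct))
  out <- do.call(rbind, rules)
  out$primer <- p$name
  out[, c("primer", "rule", "status", "detail")]
}

#' The six CYP3A4 genotyping primers
#'
#' The published primer set for the CYP3A4*4 (rs55951658 A>G), CYP3A4*18B
#' (rs2242480 G>A) and CYP3A4*22 (rs35599367 C>T) multiplex assay, with the
#' lengths, melting temperatures and GC percentages as printed in the source
#' table. Note the *22_F row is internally inconsistent (its printed GC/Tm do
#' not match its printed sequence); [primer_qc()] flags this.
#'
#' @return A named list of [primer_record()] objects
#'   (`*4_F`, `*4_R`, `*18B_F`, `*18B_R`, `*22_F`, `*22_R`).
#' @export
cyp3a4_primers <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "primers.tsv", package = "rflpkit"),
    stringsAsFactors = FALSE, check.names = FALSE)
  recs <- lapply(seq_len(nrow(tab)), function(i)
    primer_record(tab$name[i], tab$sequence[i],
                  printed_length = tab$printed_length[i],
                  printed_tm = tab$printed_tm[i],
                  printed_gc = tab$printed_gc[i]))
  names(recs) <- tab$name
  recs
}

#' Read a primer table from TSV
#'
#' Expects at least columns `name` and `sequence`; optional columns
#' `printed_length`, `printed_tm`, `printed_gc` are carried into the records.
#'
#' @param path TSV file path.
#' @return Named list of [primer_record()] objects.
#' @export
read_primer_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("name", "sequence") %in% names(tab)))
    stop("primer table needs columns 'name' and 'sequence': ", path)
  grab <- function(col, i) if (col %in% names(tab)) tab[[col]][i] else NA
  recs <- lapply(seq_len(nrow(tab)), function(i)
    primer_record(tab$name[i], tab$sequence[i],
                  printed_length = grab("printed_length", i),
                  printed_tm = grab("printed_tm", i),
                  printed_gc = grab("printed_gc", i)))
  names(recs) <- tab$name
  recs
}
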