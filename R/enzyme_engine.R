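# Restriction-enzyme model: recognition-site scanning on both strands,
# cut-coordinate arithmetic (including type IIS offset cutters), and complete
# digestion of linear templates.
#
# Coordinate convention: 1-based, inclusive; "cut after x" means cleavage of
# the phosphodiester bond between positions x and x+1 of the top strand.
# For a top-strand recognition match starting at s, the top-strand cut falls
# after s + cut_top - 1 and the bottom-strand cut after s + cut_bottom - 1.
# Fragment sizes are counted from TOP-strand cut positions only: the 4-nt
# staggered overhangs of BsmAI/BseYI do not resolve on an agarose gel.

#' Construct a restriction enzyme
#'
#' @param name enzyme identifier, e.g. `"BsmAI"`.
#' @param recognition top-strand recognition motif (IUPAC codes allowed,
#'   length >= 4).
#' @param cut_top,cut_bottom positive integer offsets: for a top-strand match
#'   starting at 1-based position s, the top strand is cleaved after
#'   coordinate `s + cut_top - 1` and the bottom strand after
#'   `s + cut_bottom - 1`. BsmAI GTCTC(1/5) is `cut_top = 6, cut_bottom = 10`;
#'   blunt RsaI GT^AC is `cut_top = 2, cut_bottom = 2`.
#' @return An object of class `restriction_enzyme` with a derived
#'   `palindromic` flag.
#' @export
restriction_enzyme <- function(name, recognition, cut_top, cut_bottom) {
  recognition <- as_dna(recognition, iupac = TRUE)
  if (nchar(recognition) < 4L)
    stop("recognition motif must be at least 4 nt: ", name)
  cut_top <- as.integer(cut_top); cut_bottom <- as.integer(cut_bottom)
  if (is.na(cut_top) || cut_top < 1L || is.na(cut_bottom) || cut_bottom < 1L)
    stop("cut offsets must be positive integers: ", name)
  structure(list(
    name = name,
    recognition = recognition,
    cut_top = cut_top,
    cut_bottom = cut_bottom,
    palindromic = identical(recognition, reverse_complement(recognition))
  ), class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("%s: %s (top cut after base %d, bottom after %d%s)\n",
              x$name, x$recognition, x$cut_top, x$cut_bottom,
              if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Load restriction-enzyme definitions from a JSON config
#'
#' The config is a JSON array of objects with fields `name`, `recognition`,
#' `cut_top`, `cut_bottom`. With no argument, the shipped config defining the
#' three assay enzymes (BsmAI, RsaI, BseYI) is loaded.
#'
#' @param path JSON file; defaults to the packaged `enzymes.json`.
#' @return Named list of [restriction_enzyme()] objects.
#' @export
load_enzymes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.json", package = "rflpkit")
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  enz <- lapply(cfg, function(e)
    restriction_enzyme(e$name, e$recognition, e$cut_top, e$cut_bottom))
  names(enz) <- vapply(enz, `[[`, character(1L), "name")
  enz
}

#' @rdname load_enzymes
#' @export
default_enzymes <- function() load_enzymes()

empty_sites <- function() {
  data.frame(enzyme = character(0L), strand = character(0L),
             start = integer(0L), end = integer(0L),
             stringsAsFactors = FALSE)
}

#' Find recognition sites of an enzyme on a template
#'
#' Scans the top strand for the recognition motif and for its reverse
#' complement (a bottom-strand site). Overlapping matches are all reported.
#' For palindromic enzymes the two scans would report every physical site
#' twice, so only the top-strand scan is kept.
#'
#' @param template unambiguous A/C/G/T sequence string.
#' @param enzyme a [restriction_enzyme()].
#' @return data.frame with columns `enzyme`, `strand` (`"top"`/`"bottom"`),
#'   `start`, `end` (1-based inclusive top-strand coordinates of the matched
#'   window), sorted by `start`. A template shorter than the motif yields
#'   zero rows.
#' @export
find_sites <- function(template, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  template <- as_dna(template)
  L <- nchar(template)
  w <- nchar(enzyme$recognition)
  if (L < w) return(empty_sites())
  subject <- Biostrings::DNAString(template)
  scan1 <- function(motif, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                  fixed = "subject")
    if (length(m) == 0L) return(empty_sites())
    data.frame(enzyme = enzyme$name, strand = strand,
               start = IRanges::start(m), end = IRanges::end(m),
               stringsAsFactors = FALSE)
  }
  out <- scan1(enzyme$recognition, "top")
  if (!enzyme$palindromic)
    out <- rbind(out, scan1(reverse_complement(enzyme$recognition), "bottom"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute cut coordinates for every site of an enzyme
#'
#' A bottom-strand site has the cut geometry of a top-strand site on the
#' reverse-complemented template, reflected back into top-strand coordinates:
#' for a bottom-strand match ending at e, the top strand is cleaved after
#' `e - cut_bottom` and the bottom strand after `e - cut_top`. Events whose
#' top-strand cut falls at or beyond either molecule end (<= 0 or >= length)
#' are dropped with a warning.
#'
#' @inheritParams find_sites
#' @return data.frame with the [find_sites()] columns plus `top_cut_after`
#'   and `bottom_cut_after` (top-strand coordinates; cleavage is between x
#'   and x+1).
#' @export
cut_positions <- function(template, enzyme) {
  template <- as_dna(template)
  sites <- find_sites(template, enzyme)
  L <- nchar(template)
  if (nrow(sites) == 0L) {
    sites$top_cut_after <- integer(0L)
    sites$bottom_cut_after <- integer(0L)
    return(sites)
  }
  top <- sites$strand == "top"
  sites$top_cut_after <- ifelse(top,
                                sites$start + enzyme$cut_top - 1L,
                                sites$end - enzyme$cut_bottom)
  sites$bottom_cut_after <- ifelse(top,
                                   sites$start + enzyme$cut_bottom - 1L,
                                   sites$end - enzyme$cut_top)
  off <- sites$top_cut_after <= 0L | sites$top_cut_after >= L
  if (any(off)) {
    warning(sprintf(
      "%s: dropping %d cut event(s) falling outside the molecule",
      enzyme$name, sum(off)))
    sites <- sites[!off, , drop = FALSE]
  }
  rownames(sites) <- NULL
  sites
}

#' Digest a linear template to completion
#'
#' Collects the top-strand cut coordinates of all enzymes (duplicates
#' collapse to a single cut) and returns the fragment lengths between
#' consecutive cuts and the molecule ends, in 5'->3' order along the top
#' strand. Fragment lengths always sum to the template length.
#'
#' @param template unambiguous A/C/G/T sequence string.
#' @param enzymes a single [restriction_enzyme()] or a list of them; an empty
#'   list returns the intact molecule.
#' @return Integer vector of fragment lengths, ordered 5'->3'.
#' @export
digest_linear <- function(template, enzymes) {
  template <- as_dna(template)
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  L <- nchar(template)
  cuts <- integer(0L)
  for (e in enzymes)
    cuts <- c(cuts, cut_positions(template, e)$top_cut_after)
  cuts <- sort(unique(cuts))
  diff(c(0L, cuts, L))
}

#' Number of recognition sites of an enzyme in a template
#'
#' Counts physical sites on both strands (palindromic sites once each).
#'
#' @inheritParams find_sites
#' @return Integer site count.
#' @export
site_count <- function(template, enzyme) {
  nrow(find_sites(template, enzyme))
}
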