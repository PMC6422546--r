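# In-silico PCR: primer binding-site location, single-pair amplification and
# multiplex amplification with cross-pair chimera screening.
#
# Binding model: exact full-length primer matches only. The assay's primers
# were designed and specificity-checked against the genome, so mismatch
# tolerance would add parameters with no data behind them; `max_mismatch`
# exists as a forward-compatible hook and currently only 0 is supported.

#' Construct a primer pair
#'
#' @param name target identifier, e.g. `"CYP3A4*22"`.
#' @param forward,reverse [primer_record()] objects.
#' @param expected_size expected product size in bp (optional, used in
#'   reports); must be at least the summed primer lengths when given.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, expected_size = NA_integer_) {
  stopifnot(inherits(forward, "primer_record"),
            inherits(reverse, "primer_record"))
  expected_size <- as.integer(expected_size)
  if (!is.na(expected_size) &&
      expected_size < forward$length_nt + reverse$length_nt)
    stop("expected_size smaller than the two primers combined: ", name)
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_size = expected_size), class = "primer_pair")
}

#' The three published CYP3A4 primer pairs
#'
#' @return Named list of [primer_pair()] objects for CYP3A4*4 (244 bp),
#'   CYP3A4*18B (331 bp) and CYP3A4*22 (793 bp).
#' @export
cyp3a4_pairs <- function() {
  p <- cyp3a4_primers()
  list(
    "CYP3A4*4"   = primer_pair("CYP3A4*4",   p[["*4_F"]],   p[["*4_R"]],   244L),
    "CYP3A4*18B" = primer_pair("CYP3A4*18B", p[["*18B_F"]], p[["*18B_R"]], 331L),
    "CYP3A4*22"  = primer_pair("CYP3A4*22",  p[["*22_F"]],  p[["*22_R"]],  793L)
  )
}

#' Locate exact primer binding sites on a template
#'
#' Reports full-length exact matches of the primer on the top strand and of
#' its reverse complement on the top strand (i.e. the primer annealing to the
#' bottom strand).
#'
#' @param template unambiguous A/C/G/T sequence string.
#' @param primer a [primer_record()].
#' @return data.frame with columns `primer`, `strand` (`"top"`/`"bottom"`),
#'   `start`, `end` (top-strand window coordinates), sorted by `start`.
#' @export
find_binding_sites <- function(template, primer) {
  stopifnot(inherits(primer, "primer_record"))
  template <- as_dna(template)
  subject <- Biostrings::DNAString(template)
  scan1 <- function(seq, strand) {
    if (nchar(template) < nchar(seq))
      return(data.frame(primer = character(0L), strand = character(0L),
                        start = integer(0L), end = integer(0L),
                        stringsAsFactors = FALSE))
    m <- Biostrings::matchPattern(Biostrings::DNAString(seq), subject)
    data.frame(primer = rep(primer$name, length(m)),
               strand = rep(strand, length(m)),
               start = IRanges::start(m), end = IRanges::end(m),
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan1(primer$sequence, "top"),
               scan1(reverse_complement(primer$sequence), "bottom"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

amplify_one_strand <- function(template, pair, max_size, strand_label) {
  f <- find_binding_sites(template, pair$forward)
  f <- f[f$strand == "top", , drop = FALSE]
  r <- find_binding_sites(template, pair$reverse)
  r <- r[r$strand == "bottom", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    span <- r$end[j] - f$start[i] + 1L
    if (span < pair$forward$length_nt + pair$reverse$length_nt) next
    if (span > max_size) next
    out[[length(out) + 1L]] <- data.frame(
      pair = pair$name, strand = strand_label,
      start = f$start[i], end = r$end[j], length = span,
      sequence = substr(template, f$start[i], r$end[j]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    data.frame(pair = character(0L), strand = character(0L),
               start = integer(0L), end = integer(0L), length = integer(0L),
               sequence = character(0L), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Amplify a template with one primer pair
#'
#' Products are all (forward top-strand hit, reverse bottom-strand hit)
#' combinations with the forward 5' end upstream of the reverse 5' end and a
#' span of at most `max_size`. The product is the inclusive span between the
#' two primer 5' ends. Both template orientations are searched; product
#' sequences are strand-canonical (they always begin with the forward
#' primer). Minus-strand products report `start`/`end` on the given
#' template's top strand.
#'
#' @param template unambiguous A/C/G/T sequence string.
#' @param pair a [primer_pair()].
#' @param max_size maximum product size in bp (default 5000, a generous bound
#'   over the largest expected product of this assay, 793 bp).
#' @return data.frame with columns `pair`, `strand` (`"+"`/`"-"`), `start`,
#'   `end`, `length`, `sequence`. Zero products is an empty frame, not an
#'   error; more than one product per pair is a non-specificity signal that
#'   [multiplex_amplify()] reports.
#' @export
amplify <- function(template, pair, max_size = 5000L) {
  stopifnot(inherits(pair, "primer_pair"))
  if (max_size <= 0L) stop("max_size must be positive")
  template <- as_dna(template)
  L <- nchar(template)
  plus <- amplify_one_strand(template, pair, max_size, "+")
  minus <- amplify_one_strand(reverse_complement(template), pair, max_size, "-")
  if (nrow(minus) > 0L) {
    # map revcomp coordinates back onto the top strand of the input
    s <- L - minus$end + 1L
    e <- L - minus$start + 1L
    minus$start <- s
    minus$end <- e
  }
  out <- rbind(plus, minus)
  out <- unique(out)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multiplex in-silico PCR
#'
#' Runs [amplify()] for every template x pair combination and screens every
#' ordered cross-pair combination (forward of one pair with reverse of
#' another) for chimeric products, a multiplex design hazard.
#'
#' @param templates named list (or character vector) of template sequences.
#' @param pairs list of [primer_pair()] objects.
#' @param max_size passed to [amplify()].
#' @return List with `products` (data.frame: `template` plus the [amplify()]
#'   columns, and `specific` = FALSE where one pair yielded several products
#'   on one template) and `chimeras` (same shape, one row per cross-pair
#'   product; zero rows for a clean design).
#' @export
multiplex_amplify <- function(templates, pairs, max_size = 5000L) {
  if (length(templates) == 0L) stop("no templates supplied")
  if (length(pairs) == 0L) stop("no primer pairs supplied")
  templates <- as.list(templates)
  if (is.null(names(templates)) || any(names(templates) == ""))
    names(templates) <- paste0("template", seq_along(templates))
  run <- function(pair_list, tag) {
    rows <- list()
    for (tn in names(templates)) for (p in pair_list) {
      hit <- amplify(templates[[tn]], p, max_size)
      if (nrow(hit) > 0L) {
        hit$template <- tn
        rows[[length(rows) + 1L]] <- hit
      }
    }
    if (length(rows) == 0L)
      data.frame(template = character(0L), pair = character(0L),
                 strand = character(0L), start = integer(0L),
                 end = integer(0L), length = integer(0L),
                 sequence = character(0L), stringsAsFactors = FALSE)
    else {
      out <- do.call(rbind, rows)
      out[, c("template", "pair", "strand", "start", "end", "length",
              "sequence")]
    }
  }
  products <- run(pairs, "product")
  if (nrow(products) > 0L) {
    key <- paste(products$template, products$pair)
    products$specific <- !(key %in% key[duplicated(key)])
  } else products$specific <- logical(0L)

  chim_pairs <- list()
  for (i in seq_along(pairs)) for (j in seq_along(pairs)) {
    if (i == j) next
    pi <- pairs[[i]]; pj <- pairs[[j]]
    chim_pairs[[length(chim_pairs) + 1L]] <- primer_pair(
      paste0(pi$name, "_F+", pj$name, "_R"), pi$forward, pj$reverse)
  }
  chimeras <- run(chim_pairs, "chimera")
  list(products = products, chimeras = chimeras)
}
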