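# Seeded generator of synthetic amplicon and locus sequences standing in for
# patient CYP3A4 DNA. A TemplateLayout pins down everything the assay's
# published fragment tables constrain -- primers at the ends, recognition
# sites at positions chosen so the digests reproduce the published fragment
# sizes, and the SNP base that creates or destroys a site -- and the
# remaining positions are filled from a seeded uniform ACGT stream with
# rejection of any spurious recognition site or off-target primer match.
#
# The true genomic context of rs55951658 / rs2242480 / rs35599367 is NOT
# reproduced: these sequences encode only the published constraints.

DEFAULT_FIXTURE_SEED <- 20180830L

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Declare a synthetic template layout
#'
#' @param name layout identifier, conventionally the SNP name.
#' @param length amplicon length in bp.
#' @param primer_f,primer_r forward and reverse [primer_record()]s; the
#'   forward primer is stamped at position 1 and the reverse complement of
#'   the reverse primer at the 3' end.
#' @param placements data.frame with columns `motif` (stamped on the top
#'   strand) and `start` (1-based); placements must not overlap each other or
#'   the primer regions.
#' @param snp list with `position`, `wild_base`, `variant_base`; the SNP base
#'   is applied after placements, so a placement may spell the site-creating
#'   allele and the wild allele overwrites it (how CYP3A4*4 A>G gains its
#'   extra BsmAI site).
#' @param seed default RNG seed for [build_amplicon()].
#' @return Object of class `template_layout`.
#' @export
template_layout <- function(name, length, primer_f, primer_r, placements,
                            snp, seed = DEFAULT_FIXTURE_SEED) {
  stopifnot(inherits(primer_f, "primer_record"),
            inherits(primer_r, "primer_record"),
            is.data.frame(placements),
            all(c("motif", "start") %in% names(placements)))
  length <- as.integer(length)
  lf <- primer_f$length_nt
  lr <- primer_r$length_nt
  if (length < lf + lr) stop("layout shorter than its two primers: ", name)
  occupied <- rep(FALSE, length)
  occupied[seq_len(lf)] <- TRUE
  occupied[(length - lr + 1L):length] <- TRUE
  for (i in seq_len(nrow(placements))) {
    s <- placements$start[i]
    e <- s + nchar(placements$motif[i]) - 1L
    if (s < 1L || e > length) stop("placement outside template: ", name)
    if (any(occupied[s:e]))
      stop("overlapping placements or primer collision in layout: ", name)
    occupied[s:e] <- TRUE
  }
  if (snp$position < 1L || snp$position > length)
    stop("SNP position outside template: ", name)
  for (b in c(snp$wild_base, snp$variant_base)) as_dna(b)
  structure(list(name = name, length = length,
                 primer_f = primer_f, primer_r = primer_r,
                 placements = placements, snp = snp,
                 seed = as.integer(seed)),
            class = "template_layout")
}

#' @export
print.template_layout <- function(x, ...) {
  cat(sprintf("layout %s: %d bp, %d placement(s), SNP %s>%s at %d, seed %d\n",
              x$name, x$length, nrow(x$placements),
              x$snp$wild_base, x$snp$variant_base, x$snp$position, x$seed))
  invisible(x)
}

# Stamp the deterministic part of a layout. Returns list(chars, fixed):
# character vector of the template (NA where free) and the fixed-position
# mask.
stamp_layout <- function(layout, allele) {
  allele <- match.arg(allele, c("wild", "variant"))
  L <- layout$length
  chars <- rep(NA_character_, L)
  fixed <- rep(FALSE, L)
  put <- function(seq, at) {
    v <- strsplit(seq, "", fixed = TRUE)[[1L]]
    idx <- at:(at + length(v) - 1L)
    chars[idx] <<- v
    fixed[idx] <<- TRUE
  }
  put(layout$primer_f$sequence, 1L)
  put(reverse_complement(layout$primer_r$sequence),
      L - layout$primer_r$length_nt + 1L)
  for (i in seq_len(nrow(layout$placements)))
    put(layout$placements$motif[i], layout$placements$start[i])
  snp_base <- if (allele == "wild") layout$snp$wild_base else
    layout$snp$variant_base
  chars[layout$snp$position] <- snp_base
  fixed[layout$snp$position] <- TRUE
  list(chars = chars, fixed = fixed)
}

# Fill free positions randomly, then repeatedly re-randomize the free part of
# any window that carries an unintended enzyme site or primer match. Windows
# consisting entirely of fixed bases are design-inherent (the stamped
# placements, or a site the primer sequence itself carries, like the
# bottom-strand BsmAI site inside the *4 forward primer) and are accepted.
fill_and_repair <- function(chars, fixed, enzymes, primers,
                            designed_span = NULL, max_rounds = 1000L,
                            context = "template") {
  free <- which(!fixed)
  chars[free] <- sample(c("A", "C", "G", "T"), length(free), replace = TRUE)
  inherent <- function(s, e) {
    if (all(fixed[s:e])) return(TRUE)
    if (!is.null(designed_span) &&
        s >= designed_span[1L] && e <= designed_span[2L]) return(TRUE)
    FALSE
  }
  for (round in seq_len(max_rounds)) {
    seqstr <- paste(chars, collapse = "")
    offend <- integer(0L)
    windows <- list()
    for (e in enzymes) {
      hits <- find_sites(seqstr, e)
      if (nrow(hits) > 0L)
        windows <- c(windows, lapply(seq_len(nrow(hits)), function(i)
          c(hits$start[i], hits$end[i])))
    }
    for (p in primers) {
      hits <- find_binding_sites(seqstr, p)
      if (nrow(hits) > 0L)
        windows <- c(windows, lapply(seq_len(nrow(hits)), function(i)
          c(hits$start[i], hits$end[i])))
    }
    for (w in windows) {
      if (inherent(w[1L], w[2L])) next
      idx <- w[1L]:w[2L]
      offend <- c(offend, idx[!fixed[idx]])
    }
    offend <- unique(offend)
    if (length(offend) == 0L) return(chars)
    chars[offend] <- sample(c("A", "C", "G", "T"), length(offend),
                            replace = TRUE)
  }
  stop(sprintf("layout infeasible: could not purge spurious sites from %s after %d repair rounds",
               context, max_rounds))
}

#' Build a synthetic amplicon from a layout
#'
#' Produces a sequence of exactly `layout$length` bp: forward primer at
#' position 1, reverse-complemented reverse primer at the 3' end, placements
#' and the allele's SNP base stamped, all remaining positions drawn from a
#' seeded uniform ACGT stream. The result is then scanned with every enzyme
#' (both strands) and every primer; any spurious match touching a random
#' position is re-randomized until clean (at most 1000 rounds, after which
#' the layout is declared infeasible). Generation is deterministic given
#' (layout, allele, seed).
#'
#' @param layout a [template_layout()].
#' @param allele `"wild"` or `"variant"`.
#' @param enzymes enzymes to screen against (default: the three assay
#'   enzymes).
#' @param primers primers to screen against (default: all six assay primers,
#'   so fixtures are multiplex-clean).
#' @param seed RNG seed; defaults to the layout's.
#' @return The amplicon sequence string.
#' @export
build_amplicon <- function(layout, allele = c("wild", "variant"),
                           enzymes = default_enzymes(),
                           primers = cyp3a4_primers(),
                           seed = layout$seed) {
  stopifnot(inherits(layout, "template_layout"))
  allele <- match.arg(allele)
  st <- stamp_layout(layout, allele)
  chars <- with_seed(seed,
    fill_and_repair(st$chars, st$fixed, enzymes, primers,
                    context = paste(layout$name, allele)))
  paste(chars, collapse = "")
}

#' Embed a synthetic amplicon in random flanking sequence
#'
#' Builds the amplicon, then adds `flank_bp` of seeded random sequence on
#' each side. Flanks are re-randomized until they harbour no primer match and
#' no recognition site touching any flank position, so in-silico PCR on the
#' locus recovers exactly the designed amplicon.
#'
#' @inheritParams build_amplicon
#' @param flank_bp flank length in bp (>= 0) on each side.
#' @return List with `sequence` (the locus string), `amplicon_start`,
#'   `amplicon_end` (1-based coordinates of the embedded amplicon).
#' @export
build_locus <- function(layout, allele = c("wild", "variant"), flank_bp = 200L,
                        enzymes = default_enzymes(),
                        primers = cyp3a4_primers(),
                        seed = layout$seed) {
  stopifnot(inherits(layout, "template_layout"))
  allele <- match.arg(allele)
  flank_bp <- as.integer(flank_bp)
  if (flank_bp < 0L) stop("flank_bp must be >= 0")
  st <- stamp_layout(layout, allele)
  with_seed(seed, {
    amp_chars <- fill_and_repair(st$chars, st$fixed, enzymes, primers,
                                 context = paste(layout$name, allele))
    if (flank_bp == 0L)
      return(list(sequence = paste(amp_chars, collapse = ""),
                  amplicon_start = 1L, amplicon_end = layout$length))
    L <- layout$length + 2L * flank_bp
    chars <- rep(NA_character_, L)
    fixed <- rep(FALSE, L)
    span <- c(flank_bp + 1L, flank_bp + layout$length)
    chars[span[1L]:span[2L]] <- amp_chars
    fixed[span[1L]:span[2L]] <- TRUE
    chars <- fill_and_repair(chars, fixed, enzymes, primers,
                             designed_span = span,
                             context = paste(layout$name, allele, "locus"))
    list(sequence = paste(chars, collapse = ""),
         amplicon_start = span[1L], amplicon_end = span[2L])
  })
}

#' The canonical CYP3A4 template layouts
#'
#' Three allele-parametric layouts (one per SNP; [build_amplicon()] selects
#' the allele) encoding the published fragment constraints:
#'
#' * `CYP3A4*4` (244 bp): a BsmAI GTCTC at 98-102 (top cut after 103) plus
#'   the bottom-strand site the forward primer itself carries (cut after 14)
#'   give the wild digest; the SNP A>G at 145 completes a second stamped
#'   GTCTC at 145-149 (cut after 150), splitting the 141-bp fragment into
#'   47 + 94 in the variant.
#' * `CYP3A4*18B` (331 bp): an RsaI GTAC at 114-117 (cut after 115) gives
#'   115 + 216; the SNP G>A at 114 destroys the site (undigested 331).
#' * `CYP3A4*22` (793 bp): BseYI CCCAGC at 219-224 (cut after 219; destroyed
#'   by the C>T SNP at 219), RsaI GTAC at 111-114 (cut after 112) and three
#'   top-strand BsmAI GTCTC at 148/204/263 (cuts after 153/209/268, i.e.
#'   fragments 153, 56, 59, 525). Fragment order along an amplicon is not
#'   observable on a gel; these positions fix one consistent order.
#'
#' @return Named list of [template_layout()] objects.
#' @export
default_layouts <- function() {
  p <- cyp3a4_primers()
  list(
    "CYP3A4*4" = template_layout(
      name = "CYP3A4*4", length = 244L,
      primer_f = p[["*4_F"]], primer_r = p[["*4_R"]],
      placements = data.frame(
        motif = c("GTCTC", "GTCTC"),
        start = c(98L, 145L),
        stringsAsFactors = FALSE),
      snp = list(position = 145L, wild_base = "A", variant_base = "G")),
    "CYP3A4*18B" = template_layout(
      name = "CYP3A4*18B", length = 331L,
      primer_f = p[["*18B_F"]], primer_r = p[["*18B_R"]],
      placements = data.frame(
        motif = "GTAC", start = 114L, stringsAsFactors = FALSE),
      snp = list(position = 114L, wild_base = "G", variant_base = "A")),
    "CYP3A4*22" = template_layout(
      name = "CYP3A4*22", length = 793L,
      primer_f = p[["*22_F"]], primer_r = p[["*22_R"]],
      placements = data.frame(
        motif = c("GTAC", "GTCTC", "GTCTC", "CCCAGC", "GTCTC"),
        start = c(111L, 148L, 204L, 219L, 263L),
        stringsAsFactors = FALSE),
      snp = list(position = 219L, wild_base = "C", variant_base = "T"))
  )
}

#' Build all six default amplicons
#'
#' @param seed RNG seed shared by all layouts.
#' @return Nested list: `seqs[[snp]][[allele]]` with alleles `"wild"` and
#'   `"variant"`.
#' @export
default_amplicon_seqs <- function(seed = DEFAULT_FIXTURE_SEED) {
  layouts <- default_layouts()
  enzymes <- default_enzymes()
  primers <- cyp3a4_primers()
  lapply(layouts, function(ly) list(
    wild = build_amplicon(ly, "wild", enzymes, primers, seed = seed),
    variant = build_amplicon(ly, "variant", enzymes, primers, seed = seed)))
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Write the complete fixture set to a directory
#'
#' Writes, per SNP and allele, an amplicon FASTA and a locus FASTA (amplicon
#' embedded in clean random flanks), plus the default assay definition
#' (`assay.json`) and a manifest TSV of expected fragment sizes per enzyme
#' (computed by digesting the built sequences, not hard-coded).
#'
#' @param out_dir output directory (created if missing).
#' @param seed RNG seed recorded in every FASTA header.
#' @param flank_bp locus flank length.
#' @return Invisibly, the manifest data.frame.
#' @export
make_fixtures <- function(out_dir, seed = DEFAULT_FIXTURE_SEED,
                          flank_bp = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layouts <- default_layouts()
  enzymes <- default_enzymes()
  primers <- cyp3a4_primers()
  manifest <- list()
  amp_all <- character(0L)
  for (snp in names(layouts)) {
    ly <- layouts[[snp]]
    for (allele in c("wild", "variant")) {
      amp <- build_amplicon(ly, allele, enzymes, primers, seed = seed)
      loc <- build_locus(ly, allele, flank_bp, enzymes, primers, seed = seed)
      hdr <- sprintf("%s allele=%s seed=%d length=%d", snp, allele, seed,
                     nchar(amp))
      write_fasta(stats::setNames(amp, hdr),
                  file.path(out_dir, sprintf("amplicon_%s_%s.fa",
                                             sanitize_name(snp), allele)))
      lhdr <- sprintf("%s allele=%s seed=%d length=%d amplicon=%d-%d",
                      snp, allele, seed, nchar(loc$sequence),
                      loc$amplicon_start, loc$amplicon_end)
      write_fasta(stats::setNames(loc$sequence, lhdr),
                  file.path(out_dir, sprintf("locus_%s_%s.fa",
                                             sanitize_name(snp), allele)))
      amp_all[hdr] <- amp
      for (en in names(enzymes)) {
        fr <- digest_linear(amp, enzymes[[en]])
        manifest[[length(manifest) + 1L]] <- data.frame(
          snp = snp, allele = allele, enzyme = en,
          n_sites = site_count(amp, enzymes[[en]]),
          fragments = paste(fr, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  write_fasta(amp_all, file.path(out_dir, "amplicons.fa"))
  write_assay_json(default_assay(), file.path(out_dir, "assay.json"))
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
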