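# The assay decision layer: per-genotype band-pattern prediction per
# digestion tube (with cross-digestion background), an agarose-gel
# visibility/co-migration model, genotype calling from observed band sizes,
# and multiplex distinguishability validation.

#' Agarose gel model
#'
#' Three parameters describe what a stained high-percentage agarose gel can
#' actually resolve: bands below `min_visible_bp` run off or stain too weakly
#' to score (in the published gels the 15/56/59-bp fragments are never seen
#' while 88 and 112 bp are, so the default threshold sits between); bands
#' closer in size than `comigration_rel` merge into one; and an observed band
#' matches an expected one within `sizing_tolerance_rel` (a 4% high
#' resolution gel sizes small fragments to within a few percent).
#'
#' @param min_visible_bp smallest scoreable band, bp (default 75).
#' @param comigration_rel relative size difference below which two bands
#'   co-migrate (default 0.05).
#' @param sizing_tolerance_rel relative error allowed when matching observed
#'   to expected bands (default 0.05).
#' @return Object of class `gel_model`.
#' @export
gel_model <- function(min_visible_bp = 75, comigration_rel = 0.05,
                      sizing_tolerance_rel = 0.05) {
  if (min_visible_bp <= 0 || comigration_rel <= 0 ||
      sizing_tolerance_rel <= 0)
    stop("all gel-model parameters must be positive")
  structure(list(min_visible_bp = min_visible_bp,
                 comigration_rel = comigration_rel,
                 sizing_tolerance_rel = sizing_tolerance_rel),
            class = "gel_model")
}

#' Default multiplex assay definition
#'
#' The published three-tube design: one multiplex PCR, then the product
#' split into a BsmAI tube diagnostic for CYP3A4*4 (rs55951658 A>G), an RsaI
#' tube for CYP3A4*18B (rs2242480 G>A) and a BseYI tube for CYP3A4*22
#' (rs35599367 C>T). Tubes are named after their enzyme.
#'
#' @return Object of class `assay_definition` with elements `snps`
#'   (data.frame: name, rs, wild_base, variant_base), `tubes` (data.frame:
#'   tube, enzyme, diagnostic_snp) and `amplicon_sizes` (named bp vector).
#' @export
default_assay <- function() {
  assay_definition(
    snps = data.frame(
      name = c("CYP3A4*4", "CYP3A4*18B", "CYP3A4*22"),
      rs = c("rs55951658", "rs2242480", "rs35599367"),
      wild_base = c("A", "G", "C"),
      variant_base = c("G", "A", "T"),
      stringsAsFactors = FALSE),
    tubes = data.frame(
      tube = c("BsmAI", "RsaI", "BseYI"),
      enzyme = c("BsmAI", "RsaI", "BseYI"),
      diagnostic_snp = c("CYP3A4*4", "CYP3A4*18B", "CYP3A4*22"),
      stringsAsFactors = FALSE),
    amplicon_sizes = c("CYP3A4*4" = 244L, "CYP3A4*18B" = 331L,
                       "CYP3A4*22" = 793L))
}

#' Construct an assay definition
#'
#' @param snps data.frame with at least `name`; optional `rs`, `wild_base`,
#'   `variant_base`.
#' @param tubes data.frame with `tube`, `enzyme`, `diagnostic_snp`; every SNP
#'   must be diagnostic in exactly one tube.
#' @param amplicon_sizes named integer vector of expected product sizes.
#' @return Object of class `assay_definition`.
#' @export
assay_definition <- function(snps, tubes, amplicon_sizes) {
  stopifnot(is.data.frame(snps), "name" %in% names(snps),
            is.data.frame(tubes),
            all(c("tube", "enzyme", "diagnostic_snp") %in% names(tubes)))
  tally <- table(factor(tubes$diagnostic_snp, levels = snps$name))
  if (any(tally != 1L))
    stop("each SNP must be assigned exactly one diagnostic tube; got: ",
         paste(sprintf("%s=%d", names(tally), tally), collapse = ", "))
  structure(list(snps = snps, tubes = tubes,
                 amplicon_sizes = amplicon_sizes),
            class = "assay_definition")
}

#' Write / read an assay definition as JSON
#'
#' @param assay an [assay_definition()].
#' @param path JSON file path.
#' @return `read_assay_json` returns an [assay_definition()];
#'   `write_assay_json` returns `path` invisibly.
#' @export
write_assay_json <- function(assay, path) {
  stopifnot(inherits(assay, "assay_definition"))
  jsonlite::write_json(
    list(snps = assay$snps, tubes = assay$tubes,
         amplicon_sizes = as.list(assay$amplicon_sizes)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_assay_json
#' @export
read_assay_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  assay_definition(snps = x$snps, tubes = x$tubes,
                   amplicon_sizes = unlist(x$amplicon_sizes))
}

norm_genotype <- function(g) {
  g <- tolower(g)
  out <- c(wild = "wild", wt = "wild",
           het = "het", heterozygous = "het",
           hom = "hom", homozygous = "hom", homozygous_variant = "hom")[g]
  if (any(is.na(out)))
    stop("unknown genotype code: ", paste(g[is.na(out)], collapse = ", "))
  unname(out)
}

alleles_present <- function(genotype) {
  switch(genotype, wild = "wild", hom = "variant",
         het = c("wild", "variant"))
}

genotype_label <- function(g)
  c(wild = "wild", het = "heterozygous", hom = "homozygous_variant")[[g]]

# Fragment set for one SNP under one genotype in one tube: the union of both
# present alleles' digests (a heterozygote shows both alleles' bands; band
# intensity/dosage is not modelled).
snp_tube_bands <- function(snp, genotype, enzyme, amplicon_seqs) {
  if (is.null(amplicon_seqs[[snp]]))
    stop("no amplicon sequences supplied for SNP ", snp)
  bands <- integer(0L)
  for (allele in alleles_present(genotype)) {
    seq <- amplicon_seqs[[snp]][[allele]]
    if (is.null(seq))
      stop(sprintf("missing %s-allele sequence for SNP %s", allele, snp))
    bands <- c(bands, digest_linear(seq, enzyme))
  }
  sort(unique(bands))
}

#' Predict the band pattern of every tube for a full genotype
#'
#' Each tube shows the diagnostic SNP's digest plus the cross-digestion
#' background of every other amplicon in the multiplex (e.g. the BsmAI tube
#' carries the undigested 331-bp CYP3A4*18B product and the 153/525-bp
#' CYP3A4*22 cross-digest). A heterozygous SNP contributes the union of both
#' alleles' fragments.
#'
#' @param assay an [assay_definition()].
#' @param genotypes named character vector, one of
#'   `"wild"`/`"het"`/`"hom"` (synonyms `heterozygous`,
#'   `homozygous_variant` accepted) per SNP.
#' @param amplicon_seqs nested list `amplicon_seqs[[snp]][[allele]]` of
#'   amplicon sequences with alleles `"wild"` and `"variant"`, e.g. from
#'   [default_amplicon_seqs()] or [read_amplicon_fasta()].
#' @param enzymes named list of [restriction_enzyme()]s covering every tube.
#' @return Named list (by tube) of `band_pattern` objects: `tube`, `enzyme`,
#'   `bands` (sorted unique bp), `by_snp` (each SNP's own fragment set).
#' @export
predict_patterns <- function(assay, genotypes, amplicon_seqs,
                             enzymes = default_enzymes()) {
  stopifnot(inherits(assay, "assay_definition"))
  gt <- stats::setNames(norm_genotype(genotypes), names(genotypes))
  missing_snp <- setdiff(assay$snps$name, names(gt))
  if (length(missing_snp) > 0L)
    stop("no genotype supplied for: ", paste(missing_snp, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(assay$tubes))) {
    tube <- assay$tubes$tube[i]
    enzyme <- enzymes[[assay$tubes$enzyme[i]]]
    if (is.null(enzyme))
      stop("enzyme not in config: ", assay$tubes$enzyme[i])
    by_snp <- lapply(stats::setNames(assay$snps$name, assay$snps$name),
                     function(s)
                       snp_tube_bands(s, gt[[s]], enzyme, amplicon_seqs))
    out[[tube]] <- structure(
      list(tube = tube, enzyme = enzyme$name,
           bands = sort(unique(unlist(by_snp))),
           by_snp = by_snp, visible_bands = NULL),
      class = "band_pattern")
  }
  out
}

#' @export
print.band_pattern <- function(x, ...) {
  cat(sprintf("tube %s (%s): bands %s", x$tube, x$enzyme,
              paste(x$bands, collapse = ", ")))
  if (!is.null(x$visible_bands))
    cat(sprintf(" | visible %s", paste(round(x$visible_bands, 1),
                                       collapse = ", ")))
  cat("\n")
  invisible(x)
}

# Visibility + co-migration on a plain size vector: drop sub-threshold bands,
# then chain-merge neighbours closer than comigration_rel (merged band at the
# cluster mean).
visible_band_sizes <- function(bands, gel) {
  b <- sort(bands[bands >= gel$min_visible_bp])
  if (length(b) == 0L) return(numeric(0L))
  cluster <- cumsum(c(1L, diff(b) / b[-length(b)] >= gel$comigration_rel))
  as.numeric(tapply(b, cluster, mean))
}

#' Apply the gel model to a band pattern
#'
#' Drops bands below the visibility threshold and merges co-migrating bands
#' into a single band at their mean size.
#'
#' @param pattern a `band_pattern` (from [predict_patterns()]) or a plain
#'   numeric vector of band sizes.
#' @param gel a [gel_model()].
#' @return Same type as the input: a pattern with `visible_bands` filled in,
#'   or the filtered numeric vector.
#' @export
apply_gel_model <- function(pattern, gel = gel_model()) {
  stopifnot(inherits(gel, "gel_model"))
  if (is.numeric(pattern)) return(visible_band_sizes(pattern, gel))
  stopifnot(inherits(pattern, "band_pattern"))
  pattern$visible_bands <- visible_band_sizes(pattern$bands, gel)
  pattern
}

all_genotype_combos <- function(snps) {
  combos <- expand.grid(rep(list(c("wild", "het", "hom")), length(snps)),
                        stringsAsFactors = FALSE)
  names(combos) <- snps
  combos
}

# TRUE iff every band of a matches some band of b within rel. tolerance.
bands_subset <- function(a, b, tol) {
  if (length(a) == 0L) return(TRUE)
  if (length(b) == 0L) return(FALSE)
  all(vapply(a, function(x) any(abs(x - b) / b <= tol), logical(1L)))
}

bands_equivalent <- function(a, b, tol)
  bands_subset(a, b, tol) && bands_subset(b, a, tol)

#' Call genotypes from observed band sizes
#'
#' For each SNP, every full genotype combination of the assay is scored
#' against the observed bands of the SNP's diagnostic tube. A combination
#' explains a tube when (a) every observed band (at or above the visibility
#' threshold; smaller bands are uninformative under the gel model and are
#' dropped) matches a predicted visible band within the sizing tolerance, and
#' (b) every visible band of the diagnostic SNP's own digest is present among
#' the observed bands. Cross-digestion background bands from the other
#' amplicons may be absent without penalty -- on the published gels the
#' 112-bp CYP3A4*22 background band is not always seen, and its absence must
#' not degrade a CYP3A4*18B call. The SNP's call is the unique genotype among
#' explaining combinations; several distinct candidates give `ambiguous`
#' (never tie-broken), none gives `fail`.
#'
#' @param observed named list: tube name -> numeric vector of observed band
#'   sizes (bp) for one sample.
#' @param assay an [assay_definition()].
#' @param amplicon_seqs as in [predict_patterns()].
#' @param gel a [gel_model()].
#' @param enzymes named enzyme list.
#' @return data.frame with columns `snp`, `tube`, `call` (`wild`,
#'   `heterozygous`, `homozygous_variant`, `ambiguous`, `fail`) and
#'   `evidence`.
#' @export
call_genotype <- function(observed, assay, amplicon_seqs, gel = gel_model(),
                          enzymes = default_enzymes()) {
  stopifnot(inherits(assay, "assay_definition"), inherits(gel, "gel_model"))
  snps <- assay$snps$name
  combos <- all_genotype_combos(snps)
  tol <- gel$sizing_tolerance_rel

  # cache: tube -> snp -> genotype -> raw fragment set
  frag <- list()
  for (i in seq_len(nrow(assay$tubes))) {
    tube <- assay$tubes$tube[i]
    enzyme <- enzymes[[assay$tubes$enzyme[i]]]
    if (is.null(enzyme))
      stop("enzyme not in config: ", assay$tubes$enzyme[i])
    frag[[tube]] <- lapply(stats::setNames(snps, snps), function(s)
      lapply(stats::setNames(c("wild", "het", "hom"),
                             c("wild", "het", "hom")),
             function(g) snp_tube_bands(s, g, enzyme, amplicon_seqs)))
  }

  rows <- list()
  for (i in seq_len(nrow(assay$tubes))) {
    tube <- assay$tubes$tube[i]
    snp <- assay$tubes$diagnostic_snp[i]
    obs <- observed[[tube]]
    if (is.null(obs) || length(obs) == 0L) {
      rows[[snp]] <- data.frame(snp = snp, tube = tube, call = "fail",
                                evidence = "no bands",
                                stringsAsFactors = FALSE)
      next
    }
    obs_vis <- sort(obs[obs >= gel$min_visible_bp])
    if (length(obs_vis) == 0L) {
      rows[[snp]] <- data.frame(
        snp = snp, tube = tube, call = "fail",
        evidence = "no bands at or above the visibility threshold",
        stringsAsFactors = FALSE)
      next
    }
    matching <- character(0L)
    for (k in seq_len(nrow(combos))) {
      combo <- as.character(combos[k, ])
      names(combo) <- snps
      pred <- sort(unique(unlist(lapply(snps, function(s)
        frag[[tube]][[s]][[combo[[s]]]]))))
      pred_vis <- visible_band_sizes(pred, gel)
      diag_vis <- visible_band_sizes(frag[[tube]][[snp]][[combo[[snp]]]],
                                     gel)
      if (bands_subset(obs_vis, pred_vis, tol) &&
          bands_subset(diag_vis, obs_vis, tol))
        matching <- c(matching, combo[[snp]])
    }
    cand <- unique(matching)
    if (length(cand) == 0L) {
      rows[[snp]] <- data.frame(
        snp = snp, tube = tube, call = "fail",
        evidence = sprintf("no genotype explains observed bands {%s}",
                           paste(obs_vis, collapse = ", ")),
        stringsAsFactors = FALSE)
    } else if (length(cand) > 1L) {
      rows[[snp]] <- data.frame(
        snp = snp, tube = tube, call = "ambiguous",
        evidence = sprintf("candidates: %s",
                           paste(vapply(cand, genotype_label, character(1L)),
                                 collapse = ", ")),
        stringsAsFactors = FALSE)
    } else {
      diag_vis <- visible_band_sizes(frag[[tube]][[snp]][[cand]], gel)
      matched <- vapply(diag_vis, function(d)
        any(abs(obs_vis - d) / d <= tol), logical(1L))
      rows[[snp]] <- data.frame(
        snp = snp, tube = tube, call = genotype_label(cand),
        evidence = sprintf("diagnostic bands matched: %s",
                           paste(round(diag_vis[matched], 1),
                                 collapse = ", ")),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[assay$snps$name])
  rownames(out) <- NULL
  out
}

#' Validate a multiplex PCR-RFLP design
#'
#' Three checks: (a) the cross-digestion matrix -- which enzyme cuts which
#' amplicon/allele, the in-silico analogue of the published
#' digestion-frequency table; (b) per-tube distinguishability of the three
#' genotype patterns of the diagnostic SNP after the gel model (patterns that
#' mutually match within the sizing tolerance are collisions: the assay
#' cannot resolve those genotypes); (c) a primer QC summary.
#'
#' @param assay an [assay_definition()].
#' @param amplicon_seqs as in [predict_patterns()].
#' @param gel a [gel_model()].
#' @param enzymes named enzyme list.
#' @param primers named list of [primer_record()]s for the QC summary.
#' @return List of class `multiplex_validation`: `cross_digestion`
#'   (data.frame: enzyme, snp, allele, n_sites, n_fragments, cut,
#'   fragments), `collisions` (data.frame: tube, snp, genotype_a,
#'   genotype_b), `primer_qc` (data.frame) and `ok` (no collisions).
#' @export
validate_multiplex <- function(assay, amplicon_seqs, gel = gel_model(),
                               enzymes = default_enzymes(),
                               primers = cyp3a4_primers()) {
  stopifnot(inherits(assay, "assay_definition"))
  cross <- list()
  for (en in names(enzymes)) for (snp in assay$snps$name)
    for (allele in c("wild", "variant")) {
      seq <- amplicon_seqs[[snp]][[allele]]
      if (is.null(seq))
        stop(sprintf("missing %s-allele sequence for SNP %s", allele, snp))
      fr <- digest_linear(seq, enzymes[[en]])
      cross[[length(cross) + 1L]] <- data.frame(
        enzyme = en, snp = snp, allele = allele,
        n_sites = site_count(seq, enzymes[[en]]),
        n_fragments = length(fr), cut = length(fr) > 1L,
        fragments = paste(fr, collapse = ","), stringsAsFactors = FALSE)
    }
  cross <- do.call(rbind, cross)

  collisions <- list()
  genos <- c("wild", "het", "hom")
  for (i in seq_len(nrow(assay$tubes))) {
    tube <- assay$tubes$tube[i]
    enzyme <- enzymes[[assay$tubes$enzyme[i]]]
    snp <- assay$tubes$diagnostic_snp[i]
    pats <- lapply(stats::setNames(genos, genos), function(g)
      visible_band_sizes(snp_tube_bands(snp, g, enzyme, amplicon_seqs), gel))
    for (a in 1:2) for (b in (a + 1L):3L)
      if (bands_equivalent(pats[[genos[a]]], pats[[genos[b]]],
                           gel$sizing_tolerance_rel))
        collisions[[length(collisions) + 1L]] <- data.frame(
          tube = tube, snp = snp,
          genotype_a = genotype_label(genos[a]),
          genotype_b = genotype_label(genos[b]), stringsAsFactors = FALSE)
  }
  collisions <- if (length(collisions) > 0L) do.call(rbind, collisions)
    else data.frame(tube = character(0L), snp = character(0L),
                    genotype_a = character(0L), genotype_b = character(0L),
                    stringsAsFactors = FALSE)

  qc <- do.call(rbind, lapply(primers, primer_qc))
  rownames(qc) <- NULL
  structure(list(cross_digestion = cross, collisions = collisions,
                 primer_qc = qc, ok = nrow(collisions) == 0L),
            class = "multiplex_validation")
}

#' @export
print.multiplex_validation <- function(x, ...) {
  cat(sprintf("multiplex validation: %s\n",
              if (x$ok) "OK (all genotype patterns distinguishable)"
              else sprintf("%d collision(s)", nrow(x$collisions))))
  cut_tab <- x$cross_digestion[x$cross_digestion$allele == "wild", ]
  for (en in unique(cut_tab$enzyme)) {
    sub <- cut_tab[cut_tab$enzyme == en, ]
    cat(sprintf("  %s cuts (wild alleles): %s\n", en,
                paste(sprintf("%s=%s", sub$snp,
                              ifelse(sub$cut, "cut", "ND")),
                      collapse = ", ")))
  }
  warns <- sum(x$primer_qc$status == "warn")
  cat(sprintf("  primer QC: %d rule(s) checked, %d warning(s)\n",
              nrow(x$primer_qc), warns))
  invisible(x)
}
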