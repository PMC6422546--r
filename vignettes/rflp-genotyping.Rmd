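---
title: "In-silico multiplex PCR-RFLP genotyping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico multiplex PCR-RFLP genotyping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpkit)
```

## The assay being modelled

PCR-RFLP genotypes a SNP by exploiting a restriction site that the variant
base creates or destroys: amplify the region, digest the product, and read
the genotype from fragment sizes on a gel. A heterozygote carries both
alleles, so its lane shows the union of both alleles' bands. The assay
modelled here genotypes three CYP3A4 star alleles in one multiplex PCR
(products of 244, 331 and 793 bp) whose pooled product is then split into
three digestion tubes:

| tube | enzyme | diagnostic SNP | informative contrast |
|---|---|---|---|
| 1 | *Bsm*AI | CYP3A4\*4 (A>G) | variant **creates** a third GTCTC site: 141 → 47 + 94 |
| 2 | *Rsa*I | CYP3A4\*18B (G>A) | variant **destroys** the GTAC site: 115 + 216 → 331 |
| 3 | *Bse*YI | CYP3A4\*22 (C>T) | variant **destroys** the CCCAGC site: 219 + 574 → 793 |

Because all three amplicons sit in every tube, each lane also carries
cross-digestion background: *Bsm*AI and *Rsa*I both cut the long \*22
product (into 56/59/153/525 and 112/681 bp respectively) while leaving the
other non-target amplicon intact. Separate tubes exist precisely so that
this background is constant and interpretable.

## Cut-site geometry

Coordinates are 1-based and inclusive; "cut after x" means cleavage between
positions x and x+1 of the top strand. An enzyme is `(recognition, t, b)`:
for a top-strand match starting at s, the top strand is cut after s + t − 1
and the bottom strand after s + b − 1. This one parameterisation covers the
three mechanistic classes in the assay:

* *Rsa*I, GT^AC: `(GTAC, 2, 2)` — palindromic, blunt.
* *Bse*YI, C^CCAGC: `(CCCAGC, 1, 5)` — non-palindromic, staggered, cutting
  inside the site.
* *Bsm*AI, GTCTC(1/5): `(GTCTC, 6, 10)` — type IIS, cutting downstream of
  the site.

A bottom-strand site (the template window matches the reverse-complemented
motif) has the geometry of a top-strand site on the flipped molecule; the
reflection works out to a top-strand cut after `end − b` and a bottom-strand
cut after `end − t`. Fragment sizes are computed from **top-strand cut
positions only**: the 4-nt 5' overhangs left by *Bsm*AI and *Bse*YI are real
but invisible on an agarose gel, and the published fragment tables print one
length per fragment accordingly. Digestion is always complete (partial
digests are out of scope); cuts that would fall outside the molecule are
dropped with a warning rather than an error, since a site hanging over an
amplicon end is a physically possible but unproductive binding event.

Scanning is overlap-complete on both strands, with IUPAC degeneracy allowed
in motifs, and palindromic sites reported once. The implementation rides on
`Biostrings::matchPattern`; the test suite checks it against an independent
naive window-by-window scanner on a thousand random templates, and checks
the conservation invariant (fragments sum to template length) throughout.

## In-silico PCR

Primer binding is exact full-length matching on either strand. The assay's
primers were BLAST-checked for specificity by design, so a mismatch-tolerant
annealing model would add parameters the assay provides no data to fit; the
`primer_pair` surface keeps a hook for bounded-mismatch matching should a
future design need it. A product is any forward-hit/reverse-hit combination
with the forward 5' end upstream and a span of at most `max_size` (default
5000 bp, a generous bound over the largest expected product of 793 bp).
Multiple products for one pair are reported and flagged, never suppressed:
non-specificity is a design signal. `multiplex_amplify` additionally screens
every cross-pair primer combination for chimeric products. Product sequences
are strand-canonical (they begin with the forward primer), so amplifying the
reverse-complemented template returns identical sequences.

## The gel model

Three positive parameters, all CLI-overridable:

* `min_visible_bp = 75` — on the published 4% high-resolution gels the 15,
  56 and 59 bp fragments are never visible while 88 and 112 bp are; 75
  separates the two groups with margin on both sides.
* `comigration_rel = 0.05` — bands closer than 5% in size merge into one
  (e.g. the 112 and 115 bp bands in the *Rsa*I tube appear as a single
  band); the merged band is placed at the cluster mean.
* `sizing_tolerance_rel = 0.05` — an observed band matches an expected one
  within 5% relative error, reflecting realistic sizing against a 50-bp
  ladder on high-percentage agarose.

## Genotype calling

For the diagnostic tube of each SNP, the caller enumerates every full
genotype combination of the assay (3 SNPs × wild/het/hom = 27), predicts the
tube's visible pattern, and accepts a combination when (a) every observed
band at or above the visibility threshold matches a predicted band within
the sizing tolerance, and (b) every visible band of the diagnostic SNP's own
digest is present among the observed bands. Three deliberate asymmetries:

* Observed bands *below* the visibility threshold are dropped before
  matching — under the gel model such a band could not have been scored
  reliably, so it must not veto a call.
* Predicted **background** bands (from the other amplicons' cross-digests)
  may be absent without penalty. This generalises a concrete behaviour of
  the published gels, where the 112-bp \*22 background band is visible in
  some lanes and not others; its absence must not degrade an \*18B call.
* Diagnostic bands are mandatory in both directions: a missing diagnostic
  band rejects the genotype, and an observed band no genotype explains
  fails the call outright.

The SNP's call is the unique genotype among accepted combinations. Several
distinct candidates yield `ambiguous` with all candidates listed — a
genotyping tool must fail loudly, so ambiguity is never tie-broken — and
zero candidates yield `fail` with the unexplained bands named.
`validate_multiplex` runs the complementary design-time check: pairwise
distinguishability of the three genotype patterns per tube after the gel
model, plus the cross-digestion matrix and a primer QC summary.

## Synthetic templates

No patient DNA is available to a simulation, so the package generates its
own: a `template_layout` fixes everything the published assay constrains —
the two primers stamped at the ends, recognition sites at positions chosen
so the digests reproduce the published fragment sizes, and the SNP base
whose substitution creates or destroys a site — and every remaining position
is drawn from a seeded uniform ACGT stream. The filled sequence is then
scanned with all three enzymes (both strands) and all six primers, and any
spurious site or off-target primer match that touches a random position is
re-randomized, up to 1000 repair rounds before the layout is declared
infeasible. Matches lying entirely inside fixed positions are part of the
design and stay.

Two layout decisions were genuinely open:

* **Fragment order.** A gel reveals fragment sizes, not their order along
  the amplicon, so the layouts fix one consistent order: \*4 = 15|88|141
  (variant splits the terminal 141 into 47|94), \*18B = 115|216, \*22
  *Bsm*AI order 153|56|59|525 — chosen so the three \*22 *Bsm*AI sites clear
  the *Rsa*I site at 111–114 and the *Bse*YI site at 219–224.
* **SNP–site coupling.** \*4 A>G completes a GTCTC at the SNP's own
  position; \*18B G>A turns GTAC into ATAC; \*22 C>T turns CCCAGC into
  TCCAGC. Each matches the published direction of the effect (site gained
  for \*4, lost for \*18B/\*22).

One consequence is documented rather than patched: the \*4 forward primer
sequence contains GAGAC — a bottom-strand *Bsm*AI site — at primer positions
20–24, which under GTCTC(1/5) forces a cut after amplicon coordinate 14.
The published table prints the two 5'-proximal wild \*4 fragments as 15 and
88 bp; the synthetic build necessarily yields 14 and 89. Whether the
published 15 reflects a different offset convention or a genomic site one
base away cannot be decided from the assay description alone, so the
package keeps the standard GTCTC(1/5) convention, and every diagnostic
quantity (the 141-bp wild fragment, the 47/94-bp variant fragments, the
site counts 2 and 3) is unaffected. The published primer table also has one
internally inconsistent row — the \*22 forward primer's printed GC% and Tm
do not match its printed 24-mer sequence — which `primer_qc()` surfaces as
a consistency warning instead of trusting either number.

Defaults: the generator seed is 20180830 and is recorded in FASTA headers;
loci embed the amplicon in 200-bp flanks kept free of primer matches and
recognition sites, so in-silico PCR recovers exactly the designed amplicon.
Flanks are uniform ACGT; GC-matched composition is deliberately not
emulated.

## What the synthetic data does and does not show

The generator emulates the *combinatorial* content of the assay — site
placement, SNP coupling, fragment arithmetic, multiplex interactions — so
passing tests demonstrate that the method logic (scanning, cutting, pattern
prediction, calling) is correct on sequences that satisfy the assay's
constraints. It does not emulate the true CYP3A4 genomic context, real
annealing thermodynamics, partial digestion, band intensity or gel
artefacts; agreement here therefore says nothing new about wet-lab
performance on patient DNA, only about the internal consistency of the
published design and the correctness of this implementation.

## Problem sizes and numerics

All quantities are exact integer arithmetic on sequences of a few hundred
bp; nothing is iterative except the generator's rejection loop. The
property-style tests run the scanner-oracle comparison and conservation
check on 1000 random 500-bp templates and the genotype round trip over all
27 genotype combinations, which together complete in well under a minute.
Ties in cut coordinates (two sites cutting at the same position, or two
enzymes agreeing) collapse to a single cut by construction. GC percentages
round half-up to one decimal, matching how primer tables print them.
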