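layouts <- default_layouts()
enz <- fixture_enzymes()
seqs <- fixture_seqs()

# expected fragment multisets per SNP x allele x enzyme; the wild *4 BsmAI
# set is {14, 89, 141} rather than the published {15, 88, 141} because the
# forward primer itself carries a bottom-strand BsmAI site whose cut falls
# after coordinate 14 under the GTCTC(1/5) convention (the 141-bp and
# mutant 47/94-bp diagnostic fragments are convention-independent)
expected_fragments <- list(
  "CYP3A4*4" = list(
    wild = list(BsmAI = c(14, 89, 141), RsaI = 244, BseYI = 244),
    variant = list(BsmAI = c(14, 47, 89, 94), RsaI = 244, BseYI = 244)),
  "CYP3A4*18B" = list(
    wild = list(BsmAI = 331, RsaI = c(115, 216), BseYI = 331),
    variant = list(BsmAI = 331, RsaI = 331, BseYI = 331)),
  "CYP3A4*22" = list(
    wild = list(BsmAI = c(56, 59, 153, 525), RsaI = c(112, 681),
                BseYI = c(219, 574)),
    variant = list(BsmAI = c(56, 59, 153, 525), RsaI = c(112, 681),
                   BseYI = 793)))

test_that("every default amplicon digests to the published fragment multiset", {
  for (snp in names(expected_fragments))
    for (allele in c("wild", "variant"))
      for (en in names(enz)) {
        got <- digest_linear(seqs[[snp]][[allele]], enz[[en]])
        expect_equal(sort(got),
                     sort(expected_fragments[[snp]][[allele]][[en]]),
                     info = paste(snp, allele, en))
      }
})

test_that("site counts match the published digestion frequencies", {
  expect_equal(site_count(seqs[["CYP3A4*4"]]$wild, enz$BsmAI), 2L)
  expect_equal(site_count(seqs[["CYP3A4*4"]]$variant, enz$BsmAI), 3L)
  expect_equal(site_count(seqs[["CYP3A4*18B"]]$wild, enz$RsaI), 1L)
  expect_equal(site_count(seqs[["CYP3A4*18B"]]$variant, enz$RsaI), 0L)
  expect_equal(site_count(seqs[["CYP3A4*18B"]]$wild, enz$BseYI), 0L)
  expect_equal(site_count(seqs[["CYP3A4*22"]]$wild, enz$BsmAI), 3L)
  expect_equal(site_count(seqs[["CYP3A4*22"]]$wild, enz$BseYI), 1L)
  expect_equal(site_count(seqs[["CYP3A4*22"]]$variant, enz$BseYI), 0L)
})

test_that("amplicons have the published lengths and primer-stamped ends", {
  pairs <- cyp3a4_pairs()
  sizes <- c("CYP3A4*4" = 244L, "CYP3A4*18B" = 331L, "CYP3A4*22" = 793L)
  for (snp in names(layouts)) for (allele in c("wild", "variant")) {
    s <- seqs[[snp]][[allele]]
    expect_equal(nchar(s), unname(sizes[snp]))
    f <- pairs[[snp]]$forward$sequence
    r <- reverse_complement(pairs[[snp]]$reverse$sequence)
    expect_equal(substr(s, 1, nchar(f)), f)
    expect_equal(substr(s, nchar(s) - nchar(r) + 1, nchar(s)), r)
  }
})

test_that("generation is deterministic given layout and seed", {
  a1 <- build_amplicon(layouts[["CYP3A4*22"]], "wild", seed = 123)
  a2 <- build_amplicon(layouts[["CYP3A4*22"]], "wild", seed = 123)
  a3 <- build_amplicon(layouts[["CYP3A4*22"]], "wild", seed = 124)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  l1 <- build_locus(layouts[["CYP3A4*4"]], "wild", 100, seed = 55)
  l2 <- build_locus(layouts[["CYP3A4*4"]], "wild", 100, seed = 55)
  expect_identical(l1$sequence, l2$sequence)
})

test_that("fragment tables hold across seeds (constraints, not accidents)", {
  for (seed in c(1L, 77L)) {
    amp <- build_amplicon(layouts[["CYP3A4*18B"]], "wild", seed = seed)
    expect_equal(digest_linear(amp, enz$RsaI), c(115L, 216L))
    amp22 <- build_amplicon(layouts[["CYP3A4*22"]], "wild", seed = seed)
    expect_equal(sort(digest_linear(amp22, enz$BsmAI)),
                 c(56L, 59L, 153L, 525L))
  }
})

test_that("alleles differ only at the SNP position", {
  for (snp in names(layouts)) {
    w <- strsplit(seqs[[snp]]$wild, "")[[1]]
    v <- strsplit(seqs[[snp]]$variant, "")[[1]]
    diffs <- which(w != v)
    expect_equal(diffs, layouts[[snp]]$snp$position)
    expect_equal(w[diffs], layouts[[snp]]$snp$wild_base)
    expect_equal(v[diffs], layouts[[snp]]$snp$variant_base)
  }
})

test_that("built amplicons carry no recognition sites beyond the design", {
  # total site tally per amplicon over all three enzymes equals the designed
  # tally exactly (already asserted per enzyme above); additionally no
  # amplicon contains an off-target primer match
  primers <- cyp3a4_primers()
  pairs <- cyp3a4_pairs()
  for (snp in names(seqs)) for (allele in c("wild", "variant")) {
    s <- seqs[[snp]][[allele]]
    own <- c(pairs[[snp]]$forward$name, pairs[[snp]]$reverse$name)
    for (pn in names(primers)) {
      hits <- find_binding_sites(s, primers[[pn]])
      if (pn %in% own) expect_equal(nrow(hits), 1L)
      else expect_equal(nrow(hits), 0L)
    }
  }
})

test_that("loci embed the amplicon in primer-free, site-free flanks", {
  locus <- build_locus(layouts[["CYP3A4*18B"]], "wild", flank_bp = 150)
  s <- locus$sequence
  expect_equal(nchar(s), 331L + 300L)
  expect_equal(substr(s, locus$amplicon_start, locus$amplicon_end),
               seqs[["CYP3A4*18B"]]$wild)
  # no enzyme site touches a flank position
  for (e in enz) {
    hits <- find_sites(s, e)
    if (nrow(hits) > 0L) {
      expect_true(all(hits$start >= locus$amplicon_start &
                      hits$end <= locus$amplicon_end))
    }
  }
  # other pairs' primers find nothing on this locus
  prod <- amplify(s, cyp3a4_pairs()[["CYP3A4*4"]])
  expect_equal(nrow(prod), 0L)
})

test_that("layout validation catches inconsistent declarations", {
  p <- cyp3a4_primers()
  expect_error(template_layout(
    "bad", 100L, p[["*4_F"]], p[["*4_R"]],
    placements = data.frame(motif = "GTAC", start = 80L),
    snp = list(position = 10L, wild_base = "A", variant_base = "G")),
    "collision|shorter")
  expect_error(template_layout(
    "bad", 300L, p[["*4_F"]], p[["*4_R"]],
    placements = data.frame(motif = c("GTAC", "GTCTC"),
                            start = c(100L, 102L)),
    snp = list(position = 10L, wild_base = "A", variant_base = "G")),
    "overlap")
})

test_that("make_fixtures writes a complete, reproducible fixture set", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  m1 <- make_fixtures(d1, seed = 9L, flank_bp = 60L)
  make_fixtures(d2, seed = 9L, flank_bp = 60L)
  files <- list.files(d1)
  expect_true(all(c("amplicons.fa", "assay.json", "manifest.tsv")
                  %in% files))
  expect_equal(sum(grepl("^amplicon_.*\\.fa$", files)), 6L)
  expect_equal(sum(grepl("^locus_.*\\.fa$", files)), 6L)
  # same seed -> byte-identical outputs
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # manifest fragments agree with re-digestion of the written amplicons
  amp <- read_amplicon_fasta(file.path(d1, "amplicons.fa"))
  for (i in seq_len(nrow(m1))) {
    got <- digest_linear(amp[[m1$snp[i]]][[m1$allele[i]]],
                         enz[[m1$enzyme[i]]])
    expect_equal(paste(got, collapse = ","), m1$fragments[i])
  }
})
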