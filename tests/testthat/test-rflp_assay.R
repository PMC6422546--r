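seqs <- fixture_seqs()
assay <- default_assay()
gel <- gel_model()

test_that("assay definition enforces one diagnostic tube per SNP", {
  expect_error(assay_definition(
    snps = data.frame(name = c("a", "b")),
    tubes = data.frame(tube = "t1", enzyme = "RsaI", diagnostic_snp = "a"),
    amplicon_sizes = c(a = 100L, b = 200L)), "exactly one")
})

test_that("assay definitions round-trip through JSON", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_assay_json(assay, tmp)
  back <- read_assay_json(tmp)
  expect_equal(back$snps$name, assay$snps$name)
  expect_equal(back$tubes$diagnostic_snp, assay$tubes$diagnostic_snp)
  expect_equal(unname(back$amplicon_sizes[assay$snps$name]),
               unname(assay$amplicon_sizes))
})

test_that("all-wild tube predictions include diagnostic and cross-digestion bands", {
  gt <- c("CYP3A4*4" = "wild", "CYP3A4*18B" = "wild", "CYP3A4*22" = "wild")
  pats <- predict_patterns(assay, gt, seqs)
  # BsmAI tube: *4 digest (14/89/141 in the synthetic build), undigested
  # *18B 331, and the *22 cross-digest 56/59/153/525
  expect_setequal(pats$BsmAI$bands, c(14, 89, 141, 331, 56, 59, 153, 525))
  # RsaI tube: *18B 115/216, undigested *4 244, *22 cross-digest 112/681
  expect_setequal(pats$RsaI$bands, c(115, 216, 244, 112, 681))
  # BseYI tube: *22 219/574, undigested 244 and 331
  expect_setequal(pats$BseYI$bands, c(219, 574, 244, 331))
})

test_that("a homozygous-variant *18B shows the undigested product in the RsaI tube", {
  gt <- c("CYP3A4*4" = "wild", "CYP3A4*18B" = "hom", "CYP3A4*22" = "wild")
  pats <- predict_patterns(assay, gt, seqs)
  expect_setequal(pats$RsaI$bands, c(331, 244, 112, 681))
})

test_that("heterozygote band sets are the union of the homozygous sets", {
  for (snp in assay$snps$name) {
    gt_base <- c("CYP3A4*4" = "wild", "CYP3A4*18B" = "wild",
                 "CYP3A4*22" = "wild")
    for (tube in assay$tubes$tube) {
      g_wild <- gt_base
      g_hom <- gt_base;  g_hom[snp] <- "hom"
      g_het <- gt_base;  g_het[snp] <- "het"
      p <- lapply(list(wild = g_wild, hom = g_hom, het = g_het),
                  function(g) predict_patterns(assay, g, seqs)[[tube]])
      expect_setequal(p$het$by_snp[[snp]],
                      union(p$wild$by_snp[[snp]], p$hom$by_snp[[snp]]))
    }
  }
})

test_that("the gel model drops sub-threshold bands and merges co-migrating ones", {
  expect_equal(apply_gel_model(c(15, 88, 141), gel), c(88, 141))
  expect_equal(apply_gel_model(c(56, 59, 153, 525), gel), c(153, 525))
  expect_equal(apply_gel_model(numeric(0), gel), numeric(0))
  # 112 and 115 differ by ~2.6% -> merge at their mean
  expect_equal(apply_gel_model(c(112, 115, 216), gel), c(113.5, 216))
  # pattern objects gain visible_bands
  gt <- c("CYP3A4*4" = "wild", "CYP3A4*18B" = "wild", "CYP3A4*22" = "wild")
  pat <- predict_patterns(assay, gt, seqs)$BsmAI
  vis <- apply_gel_model(pat, gel)
  expect_setequal(vis$visible_bands, c(89, 141, 153, 331, 525))
})

test_that("genotypes are called from published-style observed band lists", {
  # heterozygous *18B: 115/216/331 plus background 244 and 112/681
  calls <- call_genotype(list(RsaI = c(115, 216, 331, 244, 112, 681)),
                         assay, seqs, gel)
  expect_equal(calls$call[calls$snp == "CYP3A4*18B"], "heterozygous")
  # wild *22: 219/574 plus undigested 244 and 331
  calls <- call_genotype(list(BseYI = c(219, 574, 244, 331)),
                         assay, seqs, gel)
  expect_equal(calls$call[calls$snp == "CYP3A4*22"], "wild")
  # *4 heterozygote: both allele patterns in the BsmAI tube
  calls <- call_genotype(list(BsmAI = c(88, 141, 47, 94, 331, 153, 525)),
                         assay, seqs, gel)
  expect_equal(calls$call[calls$snp == "CYP3A4*4"], "heterozygous")
  # missing background bands (the not-always-seen 112) do not degrade a call
  calls <- call_genotype(list(RsaI = c(331, 244, 681)), assay, seqs, gel)
  expect_equal(calls$call[calls$snp == "CYP3A4*18B"], "homozygous_variant")
})

test_that("empty or unexplained tubes fail loudly", {
  calls <- call_genotype(list(RsaI = numeric(0)), assay, seqs, gel)
  expect_equal(calls$call[calls$snp == "CYP3A4*18B"], "fail")
  expect_match(calls$evidence[calls$snp == "CYP3A4*18B"], "no bands")
  # a rogue band no genotype explains
  calls <- call_genotype(list(RsaI = c(115, 216, 500)), assay, seqs, gel)
  expect_equal(calls$call[calls$snp == "CYP3A4*18B"], "fail")
  # tube not supplied at all
  calls <- call_genotype(list(RsaI = c(115, 216)), assay, seqs, gel)
  expect_equal(calls$call[calls$snp == "CYP3A4*4"], "fail")
})

test_that("indistinguishable genotype patterns yield ambiguous, never a tie-break", {
  # degenerate assay: the variant amplicon equals the wild one, so all three
  # genotypes predict identical patterns
  degen <- seqs
  degen[["CYP3A4*18B"]]$variant <- degen[["CYP3A4*18B"]]$wild
  calls <- call_genotype(list(RsaI = c(115, 216, 244, 112, 681)),
                         assay, degen, gel)
  expect_equal(calls$call[calls$snp == "CYP3A4*18B"], "ambiguous")
  expect_match(calls$evidence[calls$snp == "CYP3A4*18B"], "candidates")
})

test_that("genotype round trip: predict -> gel -> call recovers all 27 combinations", {
  combos <- expand.grid(rep(list(c("wild", "het", "hom")), 3),
                        stringsAsFactors = FALSE)
  names(combos) <- assay$snps$name
  label <- c(wild = "wild", het = "heterozygous",
             hom = "homozygous_variant")
  for (k in seq_len(nrow(combos))) {
    gt <- unlist(combos[k, ])
    pats <- predict_patterns(assay, gt, seqs)
    obs <- lapply(pats, function(x) apply_gel_model(x, gel)$visible_bands)
    calls <- call_genotype(obs, assay, seqs, gel)
    expect_equal(calls$call,
                 unname(label[gt[calls$snp]]),
                 info = paste("combo", paste(gt, collapse = "/")))
    expect_false(any(calls$call == "ambiguous"))
  }
})

test_that("multiplex validation reproduces the cross-digestion matrix", {
  v <- validate_multiplex(assay, seqs, gel)
  expect_true(v$ok)
  cd <- v$cross_digestion
  getcut <- function(en, snp, allele)
    cd$cut[cd$enzyme == en & cd$snp == snp & cd$allele == allele]
  # BsmAI cuts *4 and *22 but never *18B
  expect_true(getcut("BsmAI", "CYP3A4*4", "wild"))
  expect_true(getcut("BsmAI", "CYP3A4*22", "wild"))
  expect_false(getcut("BsmAI", "CYP3A4*18B", "wild"))
  expect_false(getcut("BsmAI", "CYP3A4*18B", "variant"))
  # RsaI cuts wild *18B (site destroyed in the variant) and *22, never *4
  expect_true(getcut("RsaI", "CYP3A4*18B", "wild"))
  expect_false(getcut("RsaI", "CYP3A4*18B", "variant"))
  expect_true(getcut("RsaI", "CYP3A4*22", "wild"))
  expect_false(getcut("RsaI", "CYP3A4*4", "wild"))
  # BseYI cuts wild *22 only
  expect_true(getcut("BseYI", "CYP3A4*22", "wild"))
  expect_false(getcut("BseYI", "CYP3A4*22", "variant"))
  expect_false(getcut("BseYI", "CYP3A4*4", "wild"))
  expect_false(getcut("BseYI", "CYP3A4*18B", "wild"))
})

test_that("validation flags genotype-pattern collisions in degenerate designs", {
  degen <- seqs
  degen[["CYP3A4*18B"]]$variant <- degen[["CYP3A4*18B"]]$wild
  v <- validate_multiplex(assay, degen, gel)
  expect_false(v$ok)
  expect_true(all(v$collisions$snp == "CYP3A4*18B"))
  expect_equal(nrow(v$collisions), 3L)  # all three pairs collide
})
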