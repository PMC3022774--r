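make_edit_fixture <- function() {
  # 5 codons; edit site at column 5 (codon 2, position 2). References carry
  # CCA (Pro) edited to CTA (Leu); the target carries the same codon.
  refs <- c(r1 = "ATGCCAGGATTTAAA", r2 = "ATGCCAGGATTTAAA",
            r3 = "ATGCCAGGCTTTAAA")
  tgt <- c(target = "ATGCCAGGATTTAAA")
  aln <- gene_alignment(c(refs, tgt))
  cm <- tibble::tibble(codon = 1:5, col1 = seq(1, 15, 3), col2 = seq(2, 15, 3),
                       col3 = seq(3, 15, 3))
  ev <- edit_evidence(reference_id = rep(c("r1", "r2", "r3"), each = 1),
                      gene = "g", column = 5L, evidence = "experimental",
                      codon_position = 2L)
  list(aln = aln, cm = cm, ev = ev)
}

test_that("edit-site prediction requires C and scores reference consensus", {
  fx <- make_edit_fixture()
  pred <- predict_edit_sites(fx$aln, "target", fx$ev, fx$cm)
  expect_equal(nrow(pred), 1)
  expect_equal(pred$column, 5)
  expect_equal(pred$score, 1)        # unanimous evidence
  expect_equal(pred$codon_position, 2)
  # a target with T (already substituted) at the column is never predicted
  aln2 <- fx$aln
  aln2$seqs["target", 5] <- "T"
  pred2 <- predict_edit_sites(aln2, "target", fx$ev, fx$cm)
  expect_equal(nrow(pred2), 0)
  # property: no prediction without a target C, for random targets
  set.seed(3)
  for (i in 1:5) {
    aln3 <- fx$aln
    aln3$seqs["target", ] <- sample(c("A", "G", "T"), 15, TRUE)
    p <- predict_edit_sites(aln3, "target", fx$ev, fx$cm)
    expect_equal(nrow(p), 0)
  }
  # sub-cutoff consensus is not predicted
  aln4 <- fx$aln
  # make edited target codon encode a different aa than references' edited
  aln4$seqs["target", 4] <- "G"  # GCA -> edit GTA (Val) vs refs CTA (Leu)
  p4 <- predict_edit_sites(aln4, "target", fx$ev, fx$cm, cutoff = 0.2)
  expect_equal(nrow(p4), 0)
  expect_error(predict_edit_sites(fx$aln, "target", fx$ev, NULL), "frame")
})

test_that("edit evidence survives a TSV round trip", {
  fx <- make_edit_fixture()
  path <- tempfile(fileext = ".tsv")
  write_edit_evidence(fx$ev, path)
  back <- read_edit_evidence(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(fx$ev))
})

test_that("retention tallies are exhaustive and mutually exclusive", {
  aln <- aln_from(f = "CCTCA-NCG", d = "CCCCCCCCC")
  sites <- edit_evidence(reference_id = "d", gene = "g",
                         column = c(1L, 3L, 4L, 5L, 6L, 7L, 9L),
                         evidence = "experimental", codon_position = 2L)
  tly <- tally_retention(aln, "f", sites)
  expect_equal(tly$n_sites_assessed, tly$n_C + tly$n_T + tly$n_other)
  expect_equal(tly$n_sites_assessed, 5)   # gap and N excluded
  expect_equal(tly$n_outside_span, 2)
  expect_equal(tly$n_C, 2)
  expect_equal(tly$n_T, 1)
  expect_equal(tly$n_other, 2)
  allgap <- aln_from(f = "---", d = "CCC")
  s2 <- edit_evidence(reference_id = "d", gene = "g", column = 1:3,
                      evidence = "experimental", codon_position = 2L)
  expect_error(tally_retention(allgap, "f", s2), "untestable")
})

test_that("mechanism classification gives the expected binomial verdicts", {
  mk <- function(nC, nT) {
    out <- tibble::tibble(target_id = "x", n_sites_assessed = nC + nT,
                          n_C = nC, n_T = nT, n_other = 0L,
                          n_outside_span = 0L, verdict = NA_character_,
                          verdict_p = NA_real_)
    class(out) <- c("retention_tally", class(out))
    out
  }
  # full C retention at 22 sites: DNA-mediated
  v1 <- classify_mechanism(mk(22, 0), background_CtoT_rate = 0.02)
  expect_identical(v1$verdict, "DNA-mediated")
  # 20 C + 2 T: still DNA-mediated (2 T within background expectation)
  v2 <- classify_mechanism(mk(20, 2), background_CtoT_rate = 0.02)
  expect_identical(v2$verdict, "DNA-mediated")
  expect_gte(v2$p_DNA, 0.05)
  # all T: RNA-mediated
  v3 <- classify_mechanism(mk(0, 22), background_CtoT_rate = 0.02)
  expect_identical(v3$verdict, "RNA-mediated")
})
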