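test_that("Jukes-Cantor correction matches its closed form and bounds", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(jc_correct(0.1), 0.1073256, tolerance = 1e-6)
  expect_error(jc_correct(0.75), "undefined")
  expect_error(jc_correct(0.9), "undefined")
})

test_that("Nei-Gojobori counts match hand enumeration and the pathway oracle", {
  # identical sequences: no differences
  cnt0 <- count_ng_sites_and_diffs(rep("ATG", 5), rep("ATG", 5))
  expect_equal(cnt0$sd, 0); expect_equal(cnt0$nd, 0)
  # nine GGA/GGA plus one GGA/GGG: Gly fourfold third position
  cnt <- count_ng_sites_and_diffs(rep("GGA", 10), c(rep("GGA", 9), "GGG"))
  expect_equal(cnt$S, 10)
  expect_equal(cnt$N, 20)
  expect_equal(cnt$sd, 1)
  expect_equal(cnt$nd, 0)
  # two-difference codon TTT vs GTA equals the exhaustive two-pathway average
  orc <- oracle_ng_pair("TTT", "GTA")
  cnt2 <- count_ng_sites_and_diffs("TTT", "GTA")
  expect_equal(cnt2$sd, unname(orc$sd))
  expect_equal(cnt2$nd, unname(orc$nd))
  expect_equal(cnt2$S, unname(orc$S))
  expect_equal(cnt2$N, unname(orc$N))
  # codons with gaps/N/stops are dropped pairwise
  cnt3 <- count_ng_sites_and_diffs(c("ATG", "A-G", "TAA", "GGN"),
                                   c("ATG", "AAG", "ATG", "GGA"))
  expect_equal(cnt3$n_codons_used, 1)
  expect_equal(cnt3$n_dropped, 3)
})

test_that("pairwise dN/dS is symmetric, zero on identity, seed-reproducible", {
  pair <- simulate_divergent_pair(400, ds_true = 0.15, omega = 0.3, seed = 2)
  ab <- pairwise_dnds(pair, "anc", "des", n_bootstrap = 50, seed = 7)
  ba <- pairwise_dnds(pair, "des", "anc", n_bootstrap = 50, seed = 7)
  expect_equal(ab$dN, ba$dN)
  expect_equal(ab$dS, ba$dS)
  expect_equal(ab$se_dS, ba$se_dS)   # same seed, same codon resampling
  again <- pairwise_dnds(pair, "anc", "des", n_bootstrap = 50, seed = 7)
  expect_equal(ab$se_dN, again$se_dN)
  same <- gene_alignment(rbind(a = pair$seqs["anc", ], b = pair$seqs["anc", ]))
  z <- pairwise_dnds(same, "a", "b", n_bootstrap = 0)
  expect_equal(z$dN, 0); expect_equal(z$dS, 0)
})

test_that("edit-site recoding removes edit-driven differences", {
  # column 5 differs C vs T; recoding both to T removes that difference
  a <- "ATGCCAGGATTT"
  b <- "ATGCTAGGATTT"
  aln <- aln_from(x = a, y = b)
  d0 <- pairwise_dnds(aln, "x", "y", n_bootstrap = 0)
  d1 <- pairwise_dnds(aln, "x", "y", edit_sites = 5L, n_bootstrap = 0)
  expect_gt(d0$dN + d0$dS, 0)
  expect_equal(d1$dN + d1$dS, 0)
  expect_equal(d1$recoded_edit_sites, 1)
  # property: recoding never increases the NG difference counts (it can only
  # erase differences at the recoded columns, never create any elsewhere)
  set.seed(12)
  cm <- tibble::tibble(codon = 1:120, col1 = seq(1, 360, 3),
                       col2 = seq(2, 360, 3), col3 = seq(3, 360, 3))
  for (i in 1:5) {
    pr <- simulate_divergent_pair(120, 0.2, 0.5, seed = 40 + i)
    cols <- sort(sample(seq(2, 360, 3), 6))
    x0 <- aln_seq(pr, "anc"); y0 <- aln_seq(pr, "des")
    x1 <- x0; y1 <- y0
    x1[cols] <- "T"; y1[cols] <- "T"
    c0 <- count_ng_sites_and_diffs(codons_in_frame(x0, cm),
                                   codons_in_frame(y0, cm))
    c1 <- count_ng_sites_and_diffs(codons_in_frame(x1, cm),
                                   codons_in_frame(y1, cm))
    expect_lte(c1$sd + c1$nd, c0$sd + c0$nd + 1e-12)
  }
})

test_that("conversion-codon exclusion equals analysing the masked alignment", {
  pr <- simulate_divergent_pair(200, 0.2, 0.4, seed = 77)
  tract <- tibble::tibble(start = 91L, end = 150L)  # codons 31..50
  d_excl <- pairwise_dnds(pr, "anc", "des", exclude_tracts = tract,
                          n_bootstrap = 0)
  mk <- mask_tracts(pr, tract)
  d_mask <- pairwise_dnds(mk$alignment, "anc", "des", n_bootstrap = 0)
  expect_equal(d_excl$dN, d_mask$dN, tolerance = 1e-12)
  expect_equal(d_excl$dS, d_mask$dS, tolerance = 1e-12)
  expect_equal(d_excl$excluded_conversion_codons, 20)
})

test_that("divergence ratios reproduce the foreign/native contrast arithmetic", {
  mk <- function(dS) {
    out <- tibble::tibble(id_a = "a", id_b = "b", dN = dS / 2, dS = dS,
                          omega = 0.5, se_dN = 0, se_dS = 0, n_codons = 100L,
                          recoded_edit_sites = 0L,
                          excluded_conversion_codons = 0L, n_bootstrap = 0)
    class(out) <- c("divergence_estimate", class(out))
    out
  }
  expect_equal(divergence_ratio(mk(0.1), mk(0.1)), 1)
  expect_equal(divergence_ratio(mk(0.0058), mk(0.143)), 0.143 / 0.0058,
               tolerance = 1e-12)
  expect_equal(round(divergence_ratio(mk(0.0058), mk(0.143)), 1), 24.7)
  expect_equal(round(divergence_ratio(mk(0.0058), mk(0.092)), 1), 15.9)
  expect_warning(r <- divergence_ratio(mk(0), mk(0.1)), "infinite")
  expect_identical(r, Inf)
})

test_that("undefined estimates raise errors rather than silent values", {
  aln <- aln_from(x = "---", y = "ATG")
  expect_error(pairwise_dnds(aln, "x", "y", n_bootstrap = 0), "undefined")
  expect_error(pairwise_dnds(aln_from(x = "ACGT", y = "ACGT"), "x", "y"),
               "multiple of 3")
})
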