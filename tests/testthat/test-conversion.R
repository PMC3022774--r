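test_that("informative-site extraction encodes parent support correctly", {
  # query identical to parent A: all-0 string
  aln <- aln_from(pa = "ACGTACGTAC", pb = "TCGAACTTAG", q = "ACGTACGTAC")
  cfg <- extract_informative_sites(aln, "q", "pa", "pb")
  expect_true(all(cfg$sites$state == 0))
  # constructed half/half: 0^10 then 1^10
  set.seed(2)
  L <- 100
  pa <- sample(c("A", "C"), L, TRUE)
  pb <- pa
  iA <- seq(3, 48, 5); iB <- seq(53, 98, 5)
  pb[c(iA, iB)] <- ifelse(pa[c(iA, iB)] == "A", "G", "T")  # parents differ
  q <- pa; q[iB] <- pb[iB]                                 # query follows B late
  aln2 <- gene_alignment(rbind(pa = pa, pb = pb, q = q))
  cfg2 <- extract_informative_sites(aln2, "q", "pa", "pb")
  expect_identical(cfg2$sites$state, c(rep(0L, 10), rep(1L, 10)))
  # query-matches-neither columns are excluded (autapomorphies ignored)
  q3 <- q; q3[iB[3]] <- "N"; q3[iA[2]] <- setdiff(c("A","C","G","T"),
                                                  c(pa[iA[2]], pb[iA[2]]))[1]
  aln3 <- gene_alignment(rbind(pa = pa, pb = pb, q = q3))
  cfg3 <- extract_informative_sites(aln3, "q", "pa", "pb")
  expect_equal(nrow(cfg3$sites), 18)
  expect_equal(cfg3$n_excluded, 1)
})

test_that("tract detection is calibrated on interleaved sites and finds runs", {
  # perfectly interleaved 0/1: the max run of 1 is never significant
  pa <- rep(c("A", "C"), 30)
  pb <- rep(c("G", "T"), 30)
  q <- rep(c("A", "T"), 30)   # alternates support
  aln <- gene_alignment(rbind(pa = pa, pb = pb, q = q))
  cfg <- extract_informative_sites(aln, "q", "pa", "pb")
  tr <- detect_tracts(cfg, n_permutations = 2000, seed = 1)
  expect_equal(nrow(tr), 0)
  # 30 informative sites with a 12-run of 1s: p matches a direct
  # permutation oracle within Monte-Carlo error
  set.seed(4)
  states <- c(rep(0L, 8), rep(1L, 12), rep(c(0L, 0L, 1L, 0L, 0L), 2))
  pa2 <- rep("A", 30); pb2 <- rep("G", 30)   # every column informative
  q2 <- ifelse(states == 1L, "G", "A")
  aln2 <- gene_alignment(rbind(pa = pa2, pb = pb2, q = q2))
  cfg2 <- extract_informative_sites(aln2, "q", "pa", "pb")
  expect_equal(nrow(cfg2$sites), 30)
  expect_equal(sum(cfg2$sites$state), sum(states))
  tr2 <- detect_tracts(cfg2, n_permutations = 20000, alpha = 0.01, seed = 9)
  obs_run <- max(rle(cfg2$sites$state)$lengths[rle(cfg2$sites$state)$values == 1])
  # direct oracle: R-side permutation of the same labels
  set.seed(42)
  null_max <- replicate(20000, {
    perm <- sample(cfg2$sites$state)
    r <- rle(perm)
    m <- r$lengths[r$values == 1]
    if (length(m)) max(m) else 0
  })
  p_oracle <- (1 + sum(null_max >= obs_run)) / 20001
  cand <- attr(tr2, "candidates")
  p_pkg <- min(cand$perm_p)
  expect_lt(abs(p_pkg - p_oracle), 3 * sqrt(p_oracle * (1 - p_oracle) / 20000) + 2e-4)
  # detection is invariant to columns outside informative sites: interleave
  # constant (non-informative) columns and re-extract
  inter <- matrix("C", 3, 60, dimnames = list(c("pa", "pb", "q"), NULL))
  inter[, seq(1, 60, 2)] <- aln2$seqs[, 1:30]
  aln3 <- gene_alignment(inter)
  cfg3 <- extract_informative_sites(aln3, "q", "pa", "pb")
  expect_identical(cfg3$sites$state, cfg2$sites$state)
  # coarse-resolution warning
  expect_warning(detect_tracts(cfg2, n_permutations = 100, alpha = 0.001,
                               seed = 1), "resolution")
})

test_that("implanted tracts are detected with informative-span coordinates", {
  aln <- simulate_triplet(1200, parent_divergence = 0.12,
                          query_divergence = 0.02, tract = c(401, 650),
                          seed = 5)
  tru <- attr(aln, "truth")
  cfg <- extract_informative_sites(aln, "query", "parentA", "parentB")
  tr <- detect_tracts(cfg, n_permutations = 5000, seed = 2)
  expect_gte(nrow(tr), 1)
  expect_lt(tr$perm_p[1], 0.001)
  expect_lte(max(abs(tr$start[1] - tru$start), abs(tr$end[1] - tru$end)), 5)
})

test_that("alignment splitting at a tract is conservative and reversible", {
  aln <- rand_aln(4, 60, seed = 8)
  tract <- tibble::tibble(start = 21L, end = 40L)
  sp <- split_alignment_at_tract(aln, tract, "t2")
  expect_setequal(aln_ids(sp), c("t1", "t3", "t4", "t2__tract", "t2__rest"))
  tr_seq <- aln_seq(sp, "t2__tract"); rs_seq <- aln_seq(sp, "t2__rest")
  expect_true(all(tr_seq[1:20] == "-") && all(tr_seq[41:60] == "-"))
  expect_true(all(rs_seq[21:40] == "-"))
  merged <- ifelse(tr_seq == "-", rs_seq, tr_seq)
  expect_identical(merged, aln_seq(aln, "t2"))
  # whole-sequence tract flags an all-gap remainder
  expect_warning(split_alignment_at_tract(aln, tibble::tibble(start = 1L,
                                                              end = 60L), "t2"),
                 "all gaps")
})

test_that("tract masking unions overlaps and maps columns", {
  aln <- rand_aln(3, 50, seed = 2)
  none <- mask_tracts(aln, tibble::tibble(start = integer(), end = integer()))
  expect_identical(none$alignment$seqs, aln$seqs)
  tracts <- tibble::tibble(start = c(10L, 15L), end = c(20L, 30L))
  mk <- mask_tracts(aln, tracts)
  expect_equal(mk$column_map$original, c(1:9, 31:50))
  expect_equal(aln_length(mk$alignment), 29)
  masked <- mask_tracts(aln, tracts, action = "mask")
  expect_true(all(masked$alignment$seqs[, 10:30] == "N"))
  expect_equal(aln_length(masked$alignment), 50)
})

test_that("long tracts are confirmed phylogenetically via the AU test", {
  # an implanted 157-column tract from a distant lineage: the remainder
  # topology is rejected on the tract region
  tree <- ape::read.tree(text = paste0(
    "((a:0.02,b:0.02):0.4,(c:0.02,d:0.02):0.4,(e:0.02,q:0.02):0.4);"))
  mod <- gtr_model()
  aln <- sim_on_tree(tree, 600, mod, seed = 31)
  # overwrite q's central 157 columns with c's sequence (conversion from a
  # distant lineage)
  aln$seqs["q", 201:357] <- aln$seqs["c", 201:357]
  tract <- tibble::tibble(query_id = "q", converting_partner = "c",
                          start = 201L, end = 357L, length_nt = 157L,
                          n_supporting_sites = 30L, run_score = 30,
                          perm_p = 1e-4, au_p = NA_real_, needs_au = TRUE)
  out <- confirm_long_tract(aln, tract, n_restarts = 1, n_rell = 1000, seed = 5)
  expect_lt(out$au_p, 0.05)
  expect_true(out$confirmed)
  short <- tract; short$length_nt <- 80L
  expect_error(confirm_long_tract(aln, short), "longer than 100")
})
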