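test_that("FASTA round trip preserves sequences and metadata", {
  aln <- rand_aln(3, 12, seed = 1)
  aln$meta$taxon <- c("X", "Y", "Z")
  aln$meta$copy_class <- c("native", "foreign", "reference")
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_fasta_alignment(aln, fa, metadata_path = tsv)
  back <- read_fasta_alignment(fa, metadata = tsv)
  expect_equal(aln_length(back), 12)
  expect_equal(nrow(back$seqs), 3)
  expect_identical(back$seqs, aln$seqs)
  expect_identical(back$meta$copy_class, aln$meta$copy_class)
})

test_that("ragged alignments fail naming the offending record", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">ok1", "ACGTACGT", ">bad", "ACGTACG", ">ok2", "ACGTACGT"), fa)
  expect_error(read_fasta_alignment(fa), "bad")
  writeLines(character(0), fa)
  expect_error(suppressWarnings(read_fasta_alignment(fa)))
  expect_error(read_fasta_alignment(tempfile()), "not found")
})

test_that("header naming convention populates metadata; ambiguity maps to N", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1|Ptax|A|native", "ACGT", ">s2|Ctax||unknown", "ACRT"), fa)
  expect_warning(aln <- read_fasta_alignment(fa, gene = "atp1"), "N")
  expect_identical(aln$meta$taxon, c("Ptax", "Ctax"))
  expect_identical(aln$meta$copy_class, c("native", "unknown"))
  expect_identical(unname(aln$seqs["s2", 3]), "N")
  expect_identical(aln$meta$gene, c("atp1", "atp1"))
})

test_that("pairwise identity uses pairwise deletion and is symmetric", {
  aln <- aln_from(a = "ACGT", b = "ACGA")
  expect_equal(pairwise_identity(aln, "a", "b"), 0.75)
  aln2 <- aln_from(a = "ACGTAC", a2 = "ACGTAC")
  expect_equal(pairwise_identity(aln2, "a", "a2"), 1)
  # gaps and N excluded from the denominator
  aln3 <- aln_from(x = "AC-TNA", y = "ACGTCA")
  expect_equal(pairwise_identity(aln3, "x", "y"), 1)
  # symmetry over random alignments with gaps
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 2 * 60, TRUE,
                       prob = c(rep(0.22, 4), 0.06, 0.06)), 2, 60,
                dimnames = list(c("p", "q"), NULL))
    al <- gene_alignment(m)
    expect_equal(pairwise_identity(al, "p", "q"), pairwise_identity(al, "q", "p"))
  }
  alln <- aln_from(u = "---N", v = "ACGT")
  expect_error(pairwise_identity(alln, "u", "v"), "comparable")
})

test_that("block filtering matches a brute-force column classifier", {
  # fully conserved alignment: everything kept, identity map
  cons <- gene_alignment(matrix(rep(c("A", "C", "G", "T"), 3), 4, 12,
                                byrow = TRUE,
                                dimnames = list(paste0("s", 1:4), NULL)))
  fb <- filter_blocks(cons)
  expect_equal(fb$column_map$original, 1:12)
  # conserved island shorter than b4 is dropped
  set.seed(9)
  noise <- matrix(c("A", "C", "G", "T"), 4, 20)   # every column has 4 states
  island <- matrix("A", 4, 3)
  m <- cbind(noise[, 1:10], island, noise[, 11:20])
  rownames(m) <- paste0("s", 1:4)
  fb2 <- filter_blocks(gene_alignment(m), b4_min_block = 5)
  expect_equal(nrow(fb2$column_map), 0)
  # randomized alignment vs independent brute force
  set.seed(31)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 8 * 200, TRUE,
                     prob = c(0.4, 0.2, 0.15, 0.1, 0.15)), 8, 200,
              dimnames = list(paste0("s", 1:8), NULL))
  aln <- gene_alignment(m)
  b2 <- 0.5; b4 <- 5; b5 <- 0.5
  ok <- logical(200)
  for (j in 1:200) {
    col <- m[, j]
    gapfrac <- sum(col == "-") / 8
    bases <- col[col %in% c("A", "C", "G", "T")]
    cons_ok <- length(bases) > 0 &&
      max(tabulate(match(bases, c("A", "C", "G", "T")))) / length(bases) >= b2
    ok[j] <- gapfrac <= b5 && cons_ok
  }
  keep <- logical(200); j <- 1
  while (j <= 200) {
    if (ok[j]) {
      e <- j
      while (e < 200 && ok[e + 1]) e <- e + 1
      if (e - j + 1 >= b4) keep[j:e] <- TRUE
      j <- e + 1
    } else j <- j + 1
  }
  fb3 <- filter_blocks(aln, b2, b4, b5)
  expect_equal(fb3$column_map$original, which(keep))
  # invariant to sequence order
  perm <- sample(1:8)
  aln_p <- gene_alignment(m[perm, , drop = FALSE])
  fb4 <- filter_blocks(aln_p, b2, b4, b5)
  expect_equal(fb4$column_map, fb3$column_map)
  # kept-column map strictly increasing and in range
  expect_true(all(diff(fb3$column_map$original) > 0))
  expect_true(all(fb3$column_map$original >= 1 & fb3$column_map$original <= 200))
})

test_that("frame restoration logs indels and preserves the reference frame", {
  ref <- "ATGGCTGCTGCTGCTTAA"
  # identity: zero edits
  aln0 <- aln_from(ref = ref, ps = ref)
  fr0 <- restore_reading_frame(aln0, "ps", "ref")
  expect_equal(nrow(fr0$edits), 0)
  # single 1-bp deletion: one compensating gap edit, frameshifting
  ps1 <- "ATGGCTG-TGCTGCTTAA"
  fr1 <- restore_reading_frame(aln_from(ref = ref, ps = ps1), "ps", "ref")
  expect_equal(nrow(fr1$edits), 1)
  expect_identical(fr1$edits$kind, "inserted-gap")
  expect_true(fr1$edits$frameshifting)
  # frameshifting insertion is masked to N, not deleted
  refg <- "ATGGCT--GCTGCTTAA"
  psi <-  "ATGGCTAAGCTGCTTAA"
  fr2 <- restore_reading_frame(aln_from(ref = refg, ps = psi), "ps", "ref")
  expect_identical(fr2$restored[7:8], c("N", "N"))
  expect_identical(fr2$edits$kind, "deleted-base")
  # codons read in the restored frame carry no frameshift
  cods <- codons_in_frame(fr2$restored, fr2$codon_map)
  expect_equal(length(cods), 5)
  expect_false(anyNA(cods[c(1, 3, 4, 5)]))
  # a frame-broken reference is refused
  bad <- aln_from(ref = "ATGTAAGCTGCTGCTTAA", ps = ref)
  expect_error(restore_reading_frame(bad, "ps", "ref"), "frame")
})

test_that("pseudogene feature scan finds stops and frameshifts", {
  ref <- "ATGGCTGCTGCTGCTGGATAA"
  fr <- restore_reading_frame(aln_from(ref = ref, ps = ref), "ps", "ref")
  feats <- scan_pseudogene_features(fr)
  expect_equal(nrow(feats), 0)
  expect_true(attr(feats, "intact"))
  # in-frame TAA inserted mid-gene: premature stop at its codon index
  ps <- "ATGGCTTAAGCTGCTGGATAA"
  fr2 <- restore_reading_frame(aln_from(ref = ref, ps = ps), "ps", "ref")
  feats2 <- scan_pseudogene_features(fr2)
  expect_identical(feats2$feature, "premature-stop")
  expect_equal(feats2$codon, 3)
  # frameshifting deletion is reported as a feature
  ps3 <- "ATGG-TGCTGCTGCTGGATAA"
  fr3 <- restore_reading_frame(aln_from(ref = ref, ps = ps3), "ps", "ref")
  feats3 <- scan_pseudogene_features(fr3)
  expect_true("frameshift-indel" %in% feats3$feature)
})

test_that("simulated pseudogene frameshifts match the generator's ledger", {
  cfg <- sim_config(seed = 21)
  ds <- simulate_dataset(cfg)
  dels <- ds$truth$deletions
  expect_gt(nrow(dels), 0)    # pseudogene lineages do accumulate indels
  expect_true(any(dels$frameshifting))
  # every ledgered deletion appears as a gap run in the affected tip rows
  for (i in seq_len(nrow(dels))) {
    aln <- ds$alignments[[dels$gene[i]]]
    tips <- strsplit(dels$tip[i], "+", fixed = TRUE)[[1]]
    for (tp in tips) {
      row <- aln_seq(aln, paste0(tp, "_hgt"))
      span <- dels$start[i]:(dels$start[i] + dels$length[i] - 1)
      expect_true(all(row[span] == "-"))
    }
  }
})
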