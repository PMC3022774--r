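test_that("GTR+G+I likelihood matches closed forms and exhaustive summation", {
  # two taxa, one site, JC special case: P(same) = 1/4 + 3/4 exp(-4t/3)
  a2 <- aln_from(x = "A", y = "A")
  t2 <- ape::read.tree(text = "(x:0.05,y:0.05);")
  jc <- gtr_model()
  expect_equal(log_likelihood(a2, t2, jc)$total,
               log(0.25 * (0.25 + 0.75 * exp(-4 * 0.1 / 3))), tolerance = 1e-12)
  a2d <- aln_from(x = "A", y = "G")
  expect_equal(log_likelihood(a2d, t2, jc)$total,
               log(0.25 * (0.25 - 0.25 * exp(-4 * 0.1 / 3))), tolerance = 1e-12)
  # 4-taxon 10-site alignments vs exhaustive internal-state summation
  mod <- gtr_model(rates = c(1.3, 2.8, 0.7, 1.2, 3.5, 1),
                   base_freqs = c(0.31, 0.19, 0.23, 0.27),
                   shape = 0.6, k = 4, p_inv = 0.2)
  tree <- ape::read.tree(text = "((t1:0.12,t2:0.31):0.08,t3:0.22,t4:0.4);")
  for (s in 1:3) {
    aln <- rand_aln(4, 10, seed = 100 + s)
    aln$seqs[1, 2] <- "-"; aln$seqs[3, 5] <- "N"  # missing data handled
    mine <- log_likelihood(aln, tree, mod)
    # oracle tree: ((t1,t2),(t3,t4)) with internal branch 0.08 + 0 rooting:
    # the unrooted 4-taxon tree above has internal edge 0.08 between (t1,t2)
    # and (t3,t4)
    orc <- oracle_loglik_4tax(aln$seqs, c(0.12, 0.31, 0.22, 0.4, 0.08), mod)
    expect_equal(mine$per_site, orc, tolerance = 1e-8)
    expect_equal(mine$total, sum(orc), tolerance = 1e-8)
  }
})

test_that("mixture collapses to plain pruning and is rooting-invariant", {
  aln <- rand_aln(5, 40, seed = 7)
  tree <- ape::unroot(ape::rtree(5, tip.label = paste0("t", 1:5)))
  m1 <- gtr_model(rates = c(1, 2, 1, 1, 2, 1), base_freqs = rep(0.25, 4),
                  shape = Inf, k = 1, p_inv = 0)
  m4 <- gtr_model(rates = c(1, 2, 1, 1, 2, 1), base_freqs = rep(0.25, 4),
                  shape = 1e7, k = 4, p_inv = 0)
  expect_equal(log_likelihood(aln, tree, m1)$total,
               log_likelihood(aln, tree, m4)$total, tolerance = 1e-6)
  # invariance under re-rooting and leaf-order permutation
  mod <- gtr_model(rates = c(1, 3, 1, 1, 3, 1), base_freqs = c(.3, .2, .2, .3),
                   shape = 0.8, k = 4, p_inv = 0.1)
  base <- log_likelihood(aln, tree, mod)$total
  rr <- ape::root(tree, outgroup = "t3", resolve.root = TRUE)
  expect_equal(log_likelihood(aln, rr, mod)$total, base, tolerance = 1e-8)
  aln2 <- aln
  perm <- c(4, 1, 5, 3, 2)
  aln2$seqs <- aln$seqs[perm, ]
  aln2$meta <- aln$meta[perm, ]
  expect_equal(log_likelihood(aln2, tree, mod)$total, base, tolerance = 1e-10)
})

test_that("neighbor joining recovers additive distances exactly", {
  # four-point construction: ((a:2,b:3):1,(c:4,d:5)) gives additive matrix
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 5
  d["a", "c"] <- d["c", "a"] <- 7
  d["a", "d"] <- d["d", "a"] <- 8
  d["b", "c"] <- d["c", "b"] <- 8
  d["b", "d"] <- d["d", "b"] <- 9
  d["c", "d"] <- d["d", "c"] <- 9
  tr <- ape::nj(stats::as.dist(d))
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
  expect_equal(sort(tr$edge.length), c(1, 2, 3, 4, 5))
  # build_nj_tree on sequence data returns an unrooted tree over all records
  tr5 <- ape::unroot(ape::rtree(5, tip.label = paste0("t", 1:5)))
  tr5$edge.length <- tr5$edge.length * 0.1
  aln <- sim_on_tree(tr5, 300, gtr_model(), seed = 3)
  tr2 <- build_nj_tree(aln, distance = "JC")
  expect_setequal(tr2$tip.label, paste0("t", 1:5))
  expect_true(all(tr2$edge.length >= 0))
  expect_error(build_nj_tree(rand_aln(2, 50)), "at least 3")
})

test_that("ML search improves the likelihood and is seed-deterministic", {
  set.seed(5)
  tree <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.15,(c:0.05,d:0.05):0.15,(e:0.05,f:0.05):0.15);")
  mod <- gtr_model(rates = c(1, 2, 1, 1, 2, 1), base_freqs = rep(0.25, 4))
  aln <- sim_on_tree(tree, 400, mod, seed = 5)
  start <- build_nj_tree(aln)
  fit <- ml_search(aln, start = start, n_restarts = 2, seed = 1)
  expect_gte(fit$log_lik, log_likelihood(aln, start, fit$model)$total - 1e-6)
  # generating topology recovered (long internal branches)
  expect_equal(phangorn::RF.dist(ape::unroot(fit$tree), ape::unroot(tree)), 0)
  # determinism
  fit2 <- ml_search(aln, start = start, n_restarts = 2, seed = 1)
  expect_equal(fit$log_lik, fit2$log_lik)
  expect_equal(ape::write.tree(fit$tree), ape::write.tree(fit2$tree))
})

test_that("bootstrap support is high for a strongly supported clade", {
  tree <- ape::read.tree(
    text = "((a:0.02,b:0.02):0.3,(c:0.02,d:0.02):0.3,(e:0.02,f:0.02):0.3);")
  mod <- gtr_model()
  aln <- sim_on_tree(tree, 500, mod, seed = 11)
  fit <- ml_search(aln, n_restarts = 1, seed = 2)
  bt <- bootstrap_support(aln, fit, n_replicates = 20, seed = 3)
  expect_gte(clade_support(bt, c("a", "b")), 95)
  # single replicate gives support in {0, 100}
  bt1 <- bootstrap_support(aln, fit, n_replicates = 1, seed = 4)
  sup <- suppressWarnings(as.numeric(bt1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("SH and AU topology tests behave at the fixed points", {
  tree <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.2,(c:0.05,d:0.05):0.2,(e:0.05,f:0.05):0.2);")
  mod <- gtr_model()
  aln <- sim_on_tree(tree, 300, mod, seed = 13)
  fit <- ml_search(aln, n_restarts = 1, seed = 1)
  # identical candidates: deltas 0, p = 1 for both
  tt0 <- topology_test(aln, list(fit$tree, fit$tree), fit$model,
                       method = "SH", n_rell = 200, seed = 1)
  expect_equal(tt0$table$delta, c(0, 0))
  expect_equal(tt0$table$p_value, c(1, 1))
  # best tree keeps p = 1 by construction; contradicted tree is rejected
  wrong <- ape::read.tree(
    text = "((a:0.05,c:0.05):0.2,(b:0.05,d:0.05):0.2,(e:0.05,f:0.05):0.2);")
  tt <- topology_test(aln, list(fit$tree, wrong), fit$model, method = "SH",
                      n_rell = 500, seed = 2)
  expect_equal(tt$table$p_value[1], 1)
  expect_lt(tt$table$p_value[2], 0.05)
  au <- topology_test(aln, list(fit$tree, wrong), fit$model, method = "AU",
                      n_rell = 400, seed = 3)
  expect_gte(au$table$p_value[1], 0.5)
  expect_lt(au$table$p_value[2], 0.05)
  expect_error(topology_test(aln, list(fit$tree), fit$model), "at least 2")
  expect_named(glance(tt), c("method", "n_trees", "best_tree",
                             "n_rejected_05", "n_rell"))
})
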