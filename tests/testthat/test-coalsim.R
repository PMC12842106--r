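test_that("pairwise and n-sample coalescence times match Kingman closed forms", {
  # E[T2] = Ne for two haploid copies; E[TMRCA] = 2 Ne (1 - 1/n)
  ne <- 10000
  for (n in c(2, 5, 10)) {
    sizes <- c(ceiling(n / 2), floor(n / 2))
    set.seed(1000 + n)
    out <- morphdrift:::cpp_sim_batch(as.integer(sizes), ne, 0,
                                      list(0:1), 5000L, TRUE)
    expected <- 2 * ne * (1 - 1 / n)
    se <- sd(out$tmrca) / sqrt(length(out$tmrca))
    expect_lt(abs(mean(out$tmrca) - expected), 3 * se)
  }
})

test_that("single-sample and degenerate simulations behave", {
  mt <- star_morph_tree(c("X", "Y"), 100, 1000)
  gt <- simulate_gene_tree(mt, sample_config(c(X = 1, Y = 1)), seed = 1)
  expect_equal(length(gt$tree$tip.label), 2)
  expect_equal(s_statistic(gt), 1)
  # one lineage per morph: s always k - 1
  mt4 <- star_morph_tree(LETTERS[1:4], 0, 1000)
  sd4 <- s_distribution(mt4, sample_config(setNames(rep(1, 4),
                                                    LETTERS[1:4])),
                        reps = 200, seed = 2)
  expect_true(all(sd4$s == 3))
})

test_that("simulated gene trees are valid, labeled, and ultrametric", {
  mt <- star_morph_tree(names(study_fixture$config), 500, 2000)
  gt <- simulate_gene_tree(mt, study_fixture$config, seed = 9)
  tr <- gt$tree
  expect_equal(length(tr$tip.label), 41)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  expect_setequal(unique(unname(gt$demes)), names(study_fixture$config))
  expect_equal(unname(table(gt$demes)[names(study_fixture$config)]),
               as.integer(study_fixture$config), ignore_attr = TRUE)
})

test_that("deep divergence forces complete sorting, shallow none", {
  cfg <- sample_config(c(A = 4, B = 4, C = 4))
  deep <- s_distribution(star_morph_tree(LETTERS[1:3], 50 * 1000, 1000),
                         cfg, reps = 300, seed = 3)
  expect_true(mean(deep$s == 2) > 0.99)
  shallow <- s_distribution(star_morph_tree(LETTERS[1:3], 0, 1000),
                            cfg, reps = 300, seed = 4)
  expect_gt(mean(shallow$s > 2), 0.9)
})

test_that("at T = 0 the structured s matches permuted labels on panmictic trees", {
  cfg <- study_fixture$config
  mt0 <- star_morph_tree(names(cfg), 0, 10000)
  a <- s_distribution(mt0, cfg, reps = 3000, seed = 11)$s
  # independent route: single-population trees, morph labels assigned by
  # random permutation, transitions counted by a plain-R Fitch pass
  set.seed(12)
  b <- replicate(3000, {
    sim <- morphdrift:::cpp_sim_tree(41L, 10000, numeric(0), list())
    deme <- sample(rep(0:3, times = as.integer(cfg)))
    fitch_oracle(sim$parent, deme)
  })
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("the weak-sorting tail P(s >= s_obs) decreases with branch length", {
  cfg <- study_fixture$config
  grid <- c(0, 300, 700, 1100, 1600, 2500)
  tails <- vapply(seq_along(grid), function(i) {
    sd <- s_distribution(star_morph_tree(names(cfg), grid[i], 10000),
                         cfg, reps = 4000, seed = 20 + i)
    mean(sd$s >= 19)
  }, numeric(1))
  expect_true(all(diff(tails) < 0.02))  # non-increasing up to MC error
  # and the complete-sorting tail P(s <= s_obs) is non-decreasing
  tails_low <- vapply(seq_along(grid), function(i) {
    sd <- s_distribution(star_morph_tree(names(cfg), grid[i], 10000),
                         cfg, reps = 4000, seed = 40 + i)
    mean(sd$s <= 19)
  }, numeric(1))
  expect_true(all(diff(tails_low) > -0.02))
})

test_that("identical seeds reproduce stochastic stages bit for bit", {
  cfg <- study_fixture$config
  mt <- star_morph_tree(names(cfg), 800, 10000)
  expect_identical(s_distribution(mt, cfg, 500, seed = 5)$s,
                   s_distribution(mt, cfg, 500, seed = 5)$s)
  g1 <- simulate_gene_tree(mt, cfg, seed = 6)
  g2 <- simulate_gene_tree(mt, cfg, seed = 6)
  expect_identical(ape::write.tree(g1$tree), ape::write.tree(g2$tree))
  t1 <- tune_branch_length(19, mt, cfg, reps = 500, resolution = 50,
                           seed = 7)
  t2 <- tune_branch_length(19, mt, cfg, reps = 500, resolution = 50,
                           seed = 7)
  expect_identical(t1$tuned_length, t2$tuned_length)
  expect_identical(t1$trace, t2$trace)
})

test_that("tuning reports a search trace and respects its boundary invariant", {
  cfg <- study_fixture$config
  mt <- star_morph_tree(names(cfg), 0, 10000)
  tr <- tune_branch_length(19, mt, cfg, reps = 2000, resolution = 8,
                           seed = 8)
  expect_gte(tr$achieved_tail, tr$criterion_quantile)
  expect_true(all(c("length", "tail") %in% names(tr$trace)))
  expect_gt(nrow(tr$trace), 5)
  # a longer candidate than tuned fell below the criterion during search
  longer <- tr$trace[tr$trace$length > tr$tuned_length + 8, ]
  expect_true(any(longer$tail < tr$criterion_quantile))
})

test_that("tuning errors are informative at impossible configurations", {
  cfg <- study_fixture$config
  mt <- star_morph_tree(names(cfg), 0, 10000)
  expect_error(tune_branch_length(2, mt, cfg, reps = 200, seed = 1),
               "minimum possible")
  # s_obs at complete sorting: criterion met at any length -> upper bound
  expect_error(tune_branch_length(3, mt, cfg, reps = 200, seed = 1,
                                  upper = 500, resolution = 50),
               "upper")
})

test_that("bifurcating morph topologies run and behave like shallow stars at T ~ 0", {
  phy <- ape::read.tree(text = "((Red-Green,Green),(Red,Blue));")
  mt <- morph_tree(names(study_fixture$config), 0, 10000, topology = phy)
  sd0 <- s_distribution(mt, study_fixture$config, reps = 2000, seed = 31)
  star0 <- s_distribution(star_morph_tree(names(study_fixture$config),
                                          0, 10000),
                          study_fixture$config, reps = 2000, seed = 32)
  ks <- suppressWarnings(stats::ks.test(sd0$s, star0$s))
  expect_gt(ks$p.value, 0.01)
  # deeper bifurcating tree sorts more than its own zero-length version
  mt2 <- morph_tree(names(study_fixture$config), 2000, 10000,
                    topology = phy)
  sd2 <- s_distribution(mt2, study_fixture$config, reps = 2000, seed = 33)
  expect_lt(mean(sd2$s), mean(sd0$s))
})

test_that("selection test reports the resolution-limited p bound", {
  cfg <- study_fixture$config
  st <- selection_test(star_morph_tree(names(cfg), 0, 10000), cfg,
                       reps = 10, seed = 13)
  expect_equal(st$p_label, "< 0.1")
  expect_equal(st$p_value, 0.1)
  # deep divergence: complete sorting certain, drift not rejected
  deep <- selection_test(star_morph_tree(names(cfg), 50 * 10000, 10000),
                         cfg, reps = 200, seed = 14)
  expect_gt(deep$freq_complete_sorting, 0.99)
  expect_false(deep$reject_drift)
})

test_that("nuclear rescaling floors the quarter mitochondrial length", {
  expect_equal(nuclear_rescale(1105), 276)
  expect_equal(nuclear_rescale(0), 0)
  expect_equal(nuclear_rescale(4000), 1000)
})

test_that("drift test rejects sorted phenotypes and mostly accepts neutral truth", {
  # selection scenario: the phenotype is fully sorted (s_target = k - 1)
  # but the neutral mitochondrial genealogy is shallow and unsorted, so
  # no branch length compatible with the mtDNA can produce it by drift
  set.seed(61)
  cfg <- sample_config(setNames(rep(5, 4), LETTERS[1:4]))
  neut <- simulate_alignment(star_morph_tree(LETTERS[1:4], 100, 2000),
                             cfg, theta = 8)
  d <- morphdrift:::pairwise_diff_matrix(neut$alignment)
  tr <- neighbor_joining(d)
  gt <- gene_tree(tr, neut$alignment$labels[tr$tip.label])
  res <- run_drift_test(tree = gt, samples = cfg,
                        ne = 2000, reps = 1500, resolution = 16,
                        seed = 62)
  expect_true(res$test$reject_drift)

  # whereas a fully sorted mitochondrial tree is compatible with
  # arbitrarily deep divergence: the tuning bracket cannot close and
  # says so
  mono <- simulate_alignment(star_morph_tree(LETTERS[1:4], 0, 2000),
                             cfg, theta = 8, sorting = "monophyly")
  expect_equal(s_statistic(mono$tree), 3)
  expect_error(run_drift_test(s_obs = 3, samples = cfg, ne = 2000,
                              reps = 500, resolution = 32, seed = 63),
               "upper")

  # neutral truth: nuclear s drawn from its own null at the true length;
  # the adaptive procedure should reject at roughly the nominal 5%
  ne <- 2000; t_true <- 600
  cfg <- sample_config(setNames(rep(5, 4), LETTERS[1:4]))
  mt_true <- star_morph_tree(LETTERS[1:4], t_true, ne)
  mt_nuc <- star_morph_tree(LETTERS[1:4], t_true / 4, ne)
  rejections <- vapply(1:100, function(i) {
    s_mt <- s_distribution(mt_true, cfg, reps = 1, seed = 7000 + i)$s
    s_nuc <- s_distribution(mt_nuc, cfg, reps = 1, seed = 8000 + i)$s
    res <- tryCatch(
      run_drift_test(s_obs = s_mt, samples = cfg, ne = ne, reps = 1000,
                     resolution = 16, seed = 9000 + i, s_target = s_nuc),
      error = function(e) NULL)
    if (is.null(res)) return(NA)  # s_mt at a search boundary
    res$test$reject_drift
  }, logical(1))
  rate <- mean(rejections, na.rm = TRUE)
  expect_lte(rate, 0.15)
})
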