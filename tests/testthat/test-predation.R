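# the translocation experiment's printed design: 2 sites x 2 phenotypes
# x 50 containers, attacks 1/50, 12/50, 2/50, 8/50
study_counts <- data.frame(
  site = rep(c("CerroCordoba", "TermasMalleco"), each = 2),
  phenotype = c("Red-Green", "Blue", "Blue", "Red-Green"),
  attacks = c(1L, 12L, 2L, 8L),
  n = 50L)

test_that("count expansion and CSV reading reproduce the design", {
  tab <- predation_from_counts(study_counts)
  expect_equal(nrow(tab), 200)
  expect_equal(sum(tab$attacked), 23)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, csv, row.names = FALSE)
  back <- suppressMessages(read_predation_csv(csv))
  expect_equal(attack_summary(back)$cells$attacks[
    order(attack_summary(back)$cells$site,
          attack_summary(back)$cells$phenotype)],
    c(12, 1, 2, 8))
})

test_that("malformed predation input is rejected", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("site,phenotype,attacked", csv)
  expect_error(suppressMessages(read_predation_csv(csv)), "empty")
  writeLines(c("site,phenotype,attacked", "A,x,2"), csv)
  expect_error(suppressMessages(read_predation_csv(csv)), "0 or 1")
  # single site loads but flags the unavailable full model
  writeLines(c("site,phenotype,attacked", "A,x,1", "A,y,0"), csv)
  expect_message(read_predation_csv(csv), "unavailable")
})

test_that("saturated fit reproduces observed cell proportions exactly", {
  tab <- predation_from_counts(study_counts)
  fit <- fit_binomial_glm(tab)
  cells <- unique(data.frame(site = tab$site, phenotype = tab$phenotype))
  fitted_p <- predict(fit, cells, type = "response")
  obs <- mapply(function(s, p)
    mean(tab$attacked[tab$site == s & tab$phenotype == p]),
    cells$site, cells$phenotype)
  expect_equal(unname(fitted_p), unname(obs), tolerance = 1e-7)
  # intercept-only: the grand mean 23/200
  f0 <- fit_binomial_glm(tab, attacked ~ 1)
  expect_equal(unique(round(fitted(f0), 10)), 23 / 200)
})

test_that("degenerate all-zero outcomes are flagged as separation", {
  tab <- predation_table(rep(c("A", "B"), each = 4),
                         rep(c("x", "y"), 4), rep(0L, 8))
  fit <- fit_binomial_glm(tab, attacked ~ 1)
  expect_true(attr(fit, "separation"))
})

test_that("sequential deviances add up to null-minus-saturated", {
  tab <- predation_from_counts(study_counts)
  m0 <- fit_binomial_glm(tab, attacked ~ 1)
  m1 <- fit_binomial_glm(tab, attacked ~ site)
  m2 <- fit_binomial_glm(tab, attacked ~ site + phenotype)
  m3 <- fit_binomial_glm(tab, attacked ~ site * phenotype)
  seq_dev <- c(deviance(m0) - deviance(m1), deviance(m1) - deviance(m2),
               deviance(m2) - deviance(m3))
  expect_equal(sum(seq_dev), deviance(m0) - deviance(m3))
})

test_that("interaction LRT equals the additive model's cell-level residual deviance", {
  tab <- predation_from_counts(study_counts)
  dev <- deviance_tests(tab)
  chi_int <- dev$chisq[dev$term == "site:color"]
  agg <- aggregate(attacked ~ site + phenotype, tab,
                   function(x) c(a = sum(x), f = sum(1 - x)))
  m_add_cells <- glm(cbind(agg$attacked[, "a"], agg$attacked[, "f"]) ~
                       site + phenotype, binomial, data = agg)
  expect_equal(chi_int, deviance(m_add_cells))
  # Bernoulli and aggregated-binomial parameterizations give identical LRTs
  m_full_cells <- glm(cbind(agg$attacked[, "a"], agg$attacked[, "f"]) ~
                        site * phenotype, binomial, data = agg)
  expect_equal(deviance(m_add_cells) - deviance(m_full_cells), chi_int,
               tolerance = 1e-8)
})

test_that("IRLS coefficients match a direct likelihood maximization", {
  tab <- predation_from_counts(study_counts)
  fit <- fit_binomial_glm(tab)
  X <- model.matrix(attacked ~ site * phenotype, tab)
  y <- tab$attacked
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-6)
  expect_equal(-nll(coef(fit)), as.numeric(logLik(fit)), tolerance = 1e-9)
})

test_that("Type-II analysis of deviance matches the independent car route", {
  tab <- predation_from_counts(study_counts)
  dev <- deviance_tests(tab)
  ca <- car::Anova(fit_binomial_glm(tab), type = 2,
                   test.statistic = "LR")
  expect_equal(dev$chisq, unname(ca[["LR Chisq"]]), tolerance = 1e-10)
  expect_equal(dev$p, unname(ca[["Pr(>Chisq)"]]), tolerance = 1e-10)
  expect_equal(dev$df, c(1L, 1L, 1L))
})

test_that("a null design yields near-zero chi-squares", {
  flat <- predation_from_counts(within(study_counts, attacks <- 5L))
  dev <- deviance_tests(flat)
  expect_true(all(dev$chisq < 1e-8))
  expect_true(all(dev$p > 0.999))
})

test_that("attack summary reports cells, margins and grand mean", {
  tab <- predation_from_counts(study_counts)
  summ <- attack_summary(tab)
  expect_equal(summ$grand_mean, 0.115)
  expect_equal(sort(summ$cells$proportion),
               sort(c(1, 12, 2, 8) / 50))
  expect_equal(summ$site_margin$proportion, c(13 / 100, 10 / 100))
})

test_that("the Bernoulli generator respects its cell probabilities", {
  cells <- data.frame(site = rep(c("A", "B"), each = 2),
                      phenotype = rep(c("x", "y"), 2),
                      p = c(0.02, 0.24, 0.04, 0.16))
  tab <- simulate_predation(cells, n_per_cell = 50, seed = 3)
  expect_equal(nrow(tab), 200)
  summ <- attack_summary(tab)
  merged <- merge(summ$cells, cells)
  se <- sqrt(merged$p * (1 - merged$p) / 50)
  expect_true(all(abs(merged$proportion - merged$p) < 4 * se + 0.02))
  # boundary probabilities are deterministic
  zero <- simulate_predation(within(cells, p <- 0), 20, seed = 4)
  expect_true(all(zero$attacked == 0))
  one <- simulate_predation(within(cells, p <- 1), 20, seed = 5)
  expect_true(all(one$attacked == 1))
})
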