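test_that("split-chain Rhat matches its formula on hand-sized chains", {
  chains <- list(c(1, 2, 3, 4), c(2, 3, 4, 6))
  # manual split into four half-sequences of length 2
  seqs <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 6))
  mns <- sapply(seqs, mean)
  W <- mean(sapply(seqs, var))
  B <- 2 * var(mns)
  expected <- sqrt((1 / 2 * W + B / 2) / W)
  expect_equal(unname(gelman_rubin_rhat(chains)), expected)
  # unsplit variant, directly from the between/within decomposition
  mns2 <- sapply(chains, mean)
  W2 <- mean(sapply(chains, var))
  B2 <- 4 * var(mns2)
  expect_equal(unname(gelman_rubin_rhat(chains, split = FALSE)),
               sqrt((3 / 4 * W2 + B2 / 4) / W2))
  expect_error(gelman_rubin_rhat(list(1:10)), "insufficient-chains")
})

test_that("Rhat is near one for well-mixed chains and large for divergent ones", {
  set.seed(5)
  same <- replicate(4, rnorm(10000), simplify = FALSE)
  expect_lt(gelman_rubin_rhat(same), 1.02)
  expect_gte(gelman_rubin_rhat(same), 1 - 1e-8)
  far <- list(rnorm(500), rnorm(500, mean = 10))
  expect_gt(gelman_rubin_rhat(far), 1.5)
})

test_that("worked heritability and genetic-coefficient summaries are exact", {
  dP <- posterior_draws(va = 13.50, vpe = 8.22, vres = 3.89)
  expect_equal(summarize_heritability(dP)$mean, 13.50 / 25.61)
  dG <- posterior_draws(va = 20.60, vpe = 2.22, vres = 3.89)
  expect_equal(summarize_heritability(dG)$mean, 20.60 / 26.71)
  expect_equal(summarize_heritability(posterior_draws(0, 1, 1))$mean, 0)
  expect_equal(genetic_coefficient(dP, trait_mean = 174.8)$mean, 13.50 / 174.8)
  expect_equal(genetic_coefficient(posterior_draws(0, 1, 1), 174.8)$mean, 0)
  expect_error(genetic_coefficient(dP, trait_mean = -1), "invalid-argument")
  # year variance enters the heritability denominator when present
  dY <- posterior_draws(va = 10, vpe = 5, vres = 5, vyear = 5)
  expect_equal(summarize_heritability(dY)$mean, 10 / 25)
})

test_that("pure-noise data yield near-zero heritability and correct vres", {
  set.seed(61)
  n <- 150
  ids <- sprintf("i%03d", 1:n)
  dat <- data.frame(id = rep(ids, each = 2),
                    y = rnorm(2 * n, 100, sqrt(4)),
                    measurer = "M1")
  K <- diag(n); dimnames(K) <- list(ids, ids)
  fit <- fit_animal_model(y ~ 1, dat, K = K, n_iter = 2500, n_burnin = 500,
                          n_chains = 2, seed = 3)
  m <- do.call(rbind, fit$chains)
  expect_lt(mean(m[, "h2"]), 0.15)
  expect_lt(abs(mean(m[, "vres"]) - 4) / 4, 0.15)
  expect_true(all(m[, c("va", "vpe", "vres")] > 0))
  expect_true(all(m[, "h2"] > 0 & m[, "h2"] < 1))
})

test_that("single measurements identify only the sum of va and vpe", {
  set.seed(77)
  n <- 300
  ids <- sprintf("i%03d", 1:n)
  dat <- data.frame(id = ids, y = rnorm(n, 50, sqrt(10)), measurer = "M1")
  K <- diag(n); dimnames(K) <- list(ids, ids)
  expect_warning(
    fit <- fit_animal_model(y ~ 1, dat, K = K, n_iter = 2000, n_burnin = 500,
                            n_chains = 2, seed = 8),
    "identifiability")
  m <- do.call(rbind, fit$chains)
  # the total individual-plus-residual variance is recovered even though the
  # individual split is prior-dominated
  tot <- m[, "va"] + m[, "vpe"] + m[, "vres"]
  expect_lt(abs(mean(tot) - 10) / 10, 0.2)
})

test_that("posterior mass concentrates correctly on structured data", {
  sim <- small_sim(seed = 19)
  A <- build_a_matrix(as_pedigree(sim$dual, "genetic"))
  fit <- fit_animal_model(y ~ measurer, sim$pheno, K = A,
                          n_iter = 2500, n_burnin = 700, n_chains = 2,
                          seed = 4)
  m <- do.call(rbind, fit$chains)

  # sum conservation: total variance close to the phenotypic variance after
  # fixed effects
  vp <- var(lm(y ~ measurer, sim$pheno)$residuals)
  tot <- mean(m[, "va"] + m[, "vpe"] + m[, "vres"])
  expect_lt(abs(tot - vp) / vp, 0.15)

  # agreement with an independent REML fit of the individual-level model
  skip_if_not_installed("lme4")
  lmm <- lme4::lmer(y ~ measurer + (1 | id), data = sim$pheno)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  id_var <- vc$vcov[vc$grp == "id"]
  expect_lt(abs(mean(m[, "va"] + m[, "vpe"]) - id_var) / id_var, 0.2)
  expect_lt(abs(mean(m[, "vres"]) - vc$vcov[vc$grp == "Residual"]) /
              vc$vcov[vc$grp == "Residual"], 0.2)

  # convergence of the variance components across chains
  rhat <- gelman_rubin_rhat(fit$chains)
  expect_true(all(rhat[c("va", "vpe", "vres", "h2")] < 1.1))
})

test_that("posterior summaries are invariant to phenotype row order", {
  sim <- small_sim(seed = 23, n_founders = 20)
  A <- build_a_matrix(as_pedigree(sim$dual, "genetic"))
  fit1 <- fit_animal_model(y ~ measurer, sim$pheno, K = A,
                           n_iter = 600, n_burnin = 200, n_chains = 1,
                           seed = 5)
  shuffled <- sim$pheno[sample(nrow(sim$pheno)), ]
  fit2 <- fit_animal_model(y ~ measurer, shuffled, K = A,
                           n_iter = 600, n_burnin = 200, n_chains = 1,
                           seed = 5)
  expect_identical(fit1$chains, fit2$chains)
})

test_that("the sampler validates coverage and positive definiteness", {
  dat <- data.frame(id = c("a", "a", "b"), y = c(1, 2, 3), measurer = "M1")
  K <- diag(1); dimnames(K) <- list("a", "a")
  expect_error(fit_animal_model(y ~ 1, dat, K = K, n_iter = 10, n_burnin = 2,
                                n_chains = 1),
               "coverage error.*b")
  Kbad <- matrix(c(1, 1.5, 1.5, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(suppressWarnings(
    fit_animal_model(y ~ 1, dat, K = Kbad, n_iter = 10, n_burnin = 2,
                     n_chains = 1)),
    "decomposition error")
  expect_error(fit_animal_model(y ~ 1, dat, K = Kbad, n_iter = 10,
                                n_burnin = 20, n_chains = 1),
               "n_burnin")
})

test_that("model object methods expose coefficients, fit and residuals", {
  sim <- small_sim(seed = 29, n_founders = 20)
  A <- build_a_matrix(as_pedigree(sim$dual, "genetic"))
  fit <- fit_animal_model(y ~ measurer, sim$pheno, K = A,
                          n_iter = 800, n_burnin = 300, n_chains = 2, seed = 2)
  cf <- coef(fit)
  expect_true("(Intercept)" %in% names(cf))
  expect_lt(abs(cf["(Intercept)"] - 174.8), 3)
  expect_equal(length(fitted(fit)), nrow(sim$pheno))
  expect_equal(residuals(fit), fit$y - fitted(fit))
  # residual spread should be of the order of the residual sd, not the
  # phenotypic sd
  expect_lt(sd(residuals(fit)), sd(sim$pheno$y) * 0.8)
  s <- summary(fit)
  expect_true(all(c("va", "vpe", "vres", "h2") %in% s$table$quantity))
  expect_true(all(s$table$lower < s$table$upper))
})
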