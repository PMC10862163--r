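test_that("tabular A matrix reproduces textbook coefficients", {
  # founders only: identity
  f <- pedigree(c("a", "b", "c"), rep(NA, 3), rep(NA, 3))
  expect_equal(unclass(build_a_matrix(f)), diag(3), ignore_attr = TRUE)

  A <- unclass(build_a_matrix(ped_po_sibs()))
  expect_equal(A["s", "o1"], 0.5)   # parent-offspring
  expect_equal(A["o1", "o2"], 0.5)  # full sibs
  expect_equal(A["o1", "h1"], 0.25) # half sibs
  expect_equal(A["d", "h1"], 0)     # unrelated
  expect_equal(diag(A), rep(1, 6), ignore_attr = TRUE)

  # offspring of a full-sib mating: 1 + 0.5 * 0.5
  Ai <- unclass(build_a_matrix(ped_inbred()))
  expect_equal(Ai["x", "x"], 1.25)
})

test_that("tabular A matrix matches the gene-dropping Monte-Carlo oracle", {
  ped <- ped_inbred()
  A <- unclass(build_a_matrix(ped))
  A_mc <- genedrop_a_oracle(ped, n_rep = 20000, seed = 42)
  expect_lt(max(abs(A - A_mc[rownames(A), colnames(A)])), 0.02)

  # deeper 9-individual pedigree with half sibs and a grandparental loop
  ped2 <- pedigree(
    id   = c("f1", "f2", "f3", "f4", "a", "b", "c", "d", "e"),
    sire = c(NA, NA, NA, NA, "f1", "f1", "f3", "a", "c"),
    dam  = c(NA, NA, NA, NA, "f2", "f2", "f4", "b", "d"))
  A2 <- unclass(build_a_matrix(ped2))
  A2_mc <- genedrop_a_oracle(ped2, n_rep = 20000, seed = 7)
  expect_lt(max(abs(A2 - A2_mc[rownames(A2), colnames(A2)])), 0.02)
})

test_that("A matrix rejects broken pedigrees", {
  expect_error(pedigree(c("a", "a"), c(NA, NA), c(NA, NA)), "id-collision")
  expect_error(pedigree(c("a", "b"), c("b", "a"), c(NA, NA)),
               "cycle")
  expect_error(pedigree("a", "a", NA), "own parent")
})

test_that("dummy parents are shared within and distinct between broods", {
  ped <- pedigree(id = c("d1", "c1", "c2", "c3"),
                  sire = c(NA, NA, NA, NA),
                  dam = c(NA, "d1", "d1", "d1"))
  out <- insert_dummy_parents(ped)
  sires <- out$sire[out$id %in% c("c1", "c2", "c3")]
  expect_length(unique(sires), 1)
  expect_true(all(out$dummy[out$id %in% sires]))
  # full-sib covariance restored through the dummy sire
  A <- unclass(build_a_matrix(out))
  expect_equal(A["c1", "c2"], 0.5)

  # no missing parent: untouched
  full <- ped_po_sibs()
  expect_identical(as.data.frame(insert_dummy_parents(full))[, 1:4],
                   as.data.frame(full)[, 1:4])

  # two unrelated broods get distinct dummy sires
  two <- pedigree(id = c("d1", "d2", "x1", "x2", "y1", "y2"),
                  sire = rep(NA, 6),
                  dam = c(NA, NA, "d1", "d1", "d2", "d2"))
  out2 <- insert_dummy_parents(two)
  sx <- unique(out2$sire[out2$id %in% c("x1", "x2")])
  sy <- unique(out2$sire[out2$id %in% c("y1", "y2")])
  expect_length(sx, 1)
  expect_length(sy, 1)
  expect_false(sx == sy)
  # id collision with an existing individual is refused
  clash <- pedigree(id = c("d1", "Z_sire_1", "x1"),
                    sire = c(NA, NA, NA), dam = c(NA, NA, "d1"))
  expect_error(insert_dummy_parents(clash, prefix = "Z"), "id-collision")
})

test_that("IBS similarity follows the allele-sharing formula", {
  m0 <- rbind(i = c(0, 2, 1), j = c(0, 0, 1), k = c(2, 0, 1))
  colnames(m0) <- paste0("l", 1:3)
  G <- unclass(build_grm_ibs(genotype_matrix(m0, chrom = "1")))
  expect_equal(G["i", "j"], (1 + 0 + 1) / 3)  # hand enumeration
  expect_equal(diag(G), rep(1, 3), ignore_attr = TRUE)
  # opposite homozygotes at every locus share nothing
  h0 <- rbind(a = c(0, 0), b = c(2, 2))
  colnames(h0) <- c("l1", "l2")
  expect_equal(unclass(build_grm_ibs(genotype_matrix(h0)))["a", "b"], 0)
  # missing data: pairwise-complete loci only
  m <- rbind(a = c(0, NA, 1), b = c(0, 2, NA))
  colnames(m) <- paste0("l", 1:3)
  expect_equal(unclass(build_grm_ibs(genotype_matrix(m)))["a", "b"], 1)
  # all-missing individual is a coverage error naming it
  mm <- rbind(a = c(0, 1), z = c(NA, NA))
  colnames(mm) <- c("l1", "l2")
  expect_error(build_grm_ibs(genotype_matrix(mm)), "coverage error.*z")
})

test_that("marker similarity increases with pedigree kinship", {
  cfg <- sim_config(n_founders = 80, n_generations = 3, n_snps = 1200,
                    epp_rate = 0, seed = 17)
  dual <- simulate_pedigree(cfg)
  G <- unclass(build_grm_ibs(simulate_genotypes(dual, cfg)))
  A <- unclass(build_a_matrix(as_pedigree(dual, "genetic"),
                              ids = dual$id))
  lt <- lower.tri(A)
  po <- A == 0.5 & lt &
    (outer(dual$generation, dual$generation, "!="))  # parent-offspring
  hs <- A == 0.25 & lt
  un <- A == 0 & lt
  expect_gt(mean(G[po]), mean(G[hs]))
  expect_gt(mean(G[hs]), mean(G[un]))
})

test_that("trimming projects relationship coefficients through removed links", {
  # grandparent-grandchild with the intermediate generation excluded
  ped <- pedigree(id = c("g1", "g2", "m", "f", "x"),
                  sire = c(NA, NA, "g1", NA, "f"),
                  dam = c(NA, NA, "g2", NA, "m"))
  tr <- trim_to_common(ped, c("g1", "x"))
  A <- unclass(build_a_matrix(tr))
  expect_equal(dim(A), c(2L, 2L))
  expect_equal(A["g1", "x"], 0.25)  # oracle: full A subset
  full <- unclass(build_a_matrix(ped))
  expect_equal(A, full[c("g1", "x"), c("g1", "x")], ignore_attr = TRUE)

  # identity case and degenerate empty case
  m <- build_a_matrix(ped)
  expect_equal(unclass(trim_to_common(m, rownames(m))), unclass(m))
  expect_warning(trim_to_common(m, character()), "empty")
  expect_error(trim_to_common(m, "nope"), "lookup error")
  expect_error(trim_to_common(ped, "nope"), "lookup error")
})

test_that("pedigree summary counts parentages, sibs, depth and relatedness", {
  # two unrelated founders with two shared offspring
  ped <- pedigree(id = c("s", "d", "o1", "o2"),
                  sire = c(NA, NA, "s", "s"),
                  dam = c(NA, NA, "d", "d"))
  s <- pedigree_summary(ped)
  expect_equal(s$n_individuals, 4L)
  expect_equal(s$n_maternities, 2L)
  expect_equal(s$n_paternities, 2L)
  expect_equal(s$n_full_sib_pairs, 1L)
  expect_equal(s$max_depth, 2L)
  # off-diagonal A: four parent-offspring 0.5, one sib 0.5, one founder 0
  expect_equal(s$mean_pairwise_relatedness, 2.5 / 6)

  f <- pedigree(c("a", "b"), c(NA, NA), c(NA, NA))
  sf <- pedigree_summary(f)
  expect_equal(sf$max_depth, 1L)
  expect_equal(sf$n_full_sib_pairs, 0L)

  s0 <- pedigree_summary(pedigree(character(), character(), character()))
  expect_equal(s0$n_individuals, 0L)
  expect_equal(s0$mean_pairwise_relatedness, 0)

  # dummy parents are excluded from parentage counts
  withdum <- insert_dummy_parents(
    pedigree(id = c("d1", "c1", "c2"), sire = c(NA, NA, NA),
             dam = c(NA, "d1", "d1")))
  sd <- pedigree_summary(withdum)
  expect_equal(sd$n_paternities, 0L)
  expect_equal(sd$n_maternities, 2L)
  expect_equal(sd$n_individuals, 3L)
})

test_that("Mantel statistic matches direct enumeration and is label-invariant", {
  set.seed(1)
  n <- 12
  m1 <- matrix(rnorm(n * n), n); m1 <- m1 + t(m1); diag(m1) <- 1
  m2 <- matrix(rnorm(n * n), n); m2 <- m2 + t(m2); diag(m2) <- 1
  dimnames(m1) <- dimnames(m2) <- list(letters[1:n], letters[1:n])
  res <- mantel_correlation(m1, m2, n_perm = 199, n_boot = 100, seed = 3)
  # brute force over the 6 lower-triangle pairs
  v1 <- m1[lower.tri(m1)]
  v2 <- m2[lower.tri(m2)]
  expect_equal(res$r, cor(v1, v2))

  # self comparison: maximal statistic, minimal permutation p
  self <- mantel_correlation(m1, m1, n_perm = 99, n_boot = 50, seed = 3)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 100)

  # constant matrix: undefined correlation
  cm <- matrix(1, n, n, dimnames = dimnames(m1))
  expect_error(mantel_correlation(m1, cm, n_perm = 9, seed = 1),
               "undefined-correlation")

  # simultaneous relabeling leaves the result unchanged
  perm <- sample(letters[1:n])
  res2 <- mantel_correlation(m1[perm, perm], m2[perm, perm],
                             n_perm = 199, n_boot = 100, seed = 3)
  expect_equal(res2$r, res$r)

  # independent implementation agrees on the statistic
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(max(m1) - m1), as.dist(max(m2) - m2),
                      permutations = 19)
  expect_equal(unname(vg$statistic), cor(v1, v2))
})

test_that("paternity classification applies the similarity thresholds", {
  ids <- c("f1", "f2", "f3", "o1", "o2", "o3")
  S <- diag(1, 6); dimnames(S) <- list(ids, ids)
  S["f1", "o1"] <- S["o1", "f1"] <- 0.5    # clear within-pair
  S["f2", "o2"] <- S["o2", "f2"] <- 0.05   # clear EPP
  S["f3", "o3"] <- S["o3", "f3"] <- 0.2    # intermediate
  pairs <- data.frame(father = c("f1", "f2", "f3"),
                      offspring = c("o1", "o2", "o3"))
  res <- classify_paternity(relmatrix(pmin(S, 1), "genomic"), pairs)
  expect_equal(res$pairs$label, c("within_pair", "epp", "unresolved"))
  expect_equal(res$n_total, 3L)
  expect_equal(res$epp_rate_percent, 100 / 3)
  resd <- classify_paternity(relmatrix(pmin(S, 1), "genomic"), pairs,
                             drop_unresolved = TRUE)
  expect_equal(resd$epp_rate_percent, 50)
  expect_error(classify_paternity(relmatrix(pmin(S, 1), "genomic"),
                                  data.frame(father = "zz", offspring = "o1")),
               "lookup error")
})

test_that("genetic similarity recovers the true sires in a two-generation population", {
  # extra-pair sires are unrelated to the social males here, so the 0.3/0.1
  # thresholds split the two similarity distributions completely
  cfg <- sim_config(n_founders = 60, n_generations = 2, epp_rate = 0.3,
                    n_snps = 1200, seed = 23)
  dual <- simulate_pedigree(cfg)
  G <- build_grm_vanraden(simulate_genotypes(dual, cfg))
  off <- dual$generation == 2
  pairs <- data.frame(father = dual$social_sire[off],
                      offspring = dual$id[off])
  res <- classify_paternity(G, pairs)
  truth <- ifelse(dual$genetic_sire[off] == dual$social_sire[off],
                  "within_pair", "epp")
  expect_equal(res$pairs$label, truth)
  expect_equal(res$n_unresolved, 0L)
})
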