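#' Configuration for the synthetic population generator
#'
#' Defaults emulate a nest-box passerine study population: roughly 650
#' individuals over four discrete generations, about 20% extra-pair paternity
#' (EPP), a tarsus-length-like trait measured on a 0.1 mm scale
#' (mean 174.8 units = 17.48 mm, total variance about 25.6 units²) with
#' repeated measurements taken by a small pool of measurers.
#'
#' @param n_founders even number of generation-1 founders (half each sex).
#' @param n_generations total number of discrete generations including
#'   founders.
#' @param offspring_per_pair brood size per social pair.
#' @param epp_rate per-offspring probability that the genetic sire differs
#'   from the social sire.
#' @param n_snps number of simulated unlinked biallelic loci.
#' @param maf_low,maf_high founder minor-allele frequency bounds in (0, 0.5].
#' @param Va,Vpe,Vres additive genetic, permanent-environment and residual
#'   variances (trait-unit²).
#' @param trait_mean population trait mean (trait units).
#' @param n_measurers number of measurers.
#' @param measurer_effects trait-unit offset per measurer (length
#'   `n_measurers`; first is the reference).
#' @param repeats_low,repeats_high bounds of the per-individual number of
#'   repeated measurements (uniform integer).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 80, n_generations = 4,
                       offspring_per_pair = 3, epp_rate = 0.2,
                       n_snps = 1000, maf_low = 0.05, maf_high = 0.5,
                       Va = 13.5, Vpe = 8.2, Vres = 3.9,
                       trait_mean = 174.8, n_measurers = 5,
                       measurer_effects = c(0, 0.5, -0.3, 0.2, -0.4),
                       repeats_low = 1, repeats_high = 3, seed = 1) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_pair = as.integer(offspring_per_pair),
              epp_rate = epp_rate, n_snps = as.integer(n_snps),
              maf_low = maf_low, maf_high = maf_high,
              Va = Va, Vpe = Vpe, Vres = Vres, trait_mean = trait_mean,
              n_measurers = as.integer(n_measurers),
              measurer_effects = measurer_effects,
              repeats_low = as.integer(repeats_low),
              repeats_high = as.integer(repeats_high),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_founders < 2 || n_founders %% 2 != 0) {
      stop("invalid-config error: n_founders must be even and >= 2")
    }
    if (offspring_per_pair < 1) {
      stop("invalid-config error: offspring_per_pair must be >= 1")
    }
    if (epp_rate < 0 || epp_rate > 1) {
      stop("invalid-config error: epp_rate must lie in [0, 1]")
    }
    if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high) {
      stop("invalid-config error: need 0 < maf_low <= maf_high <= 0.5")
    }
    if (Va < 0 || Vpe < 0 || Vres < 0) {
      stop("invalid-config error: variances must be non-negative")
    }
    if (repeats_low < 1 || repeats_low > repeats_high) {
      stop("invalid-config error: repeats bounds must satisfy 1 <= low <= high")
    }
    if (length(measurer_effects) != n_measurers) {
      stop("invalid-config error: measurer_effects must have length n_measurers")
    }
  })
  invisible(cfg)
}

# independent deterministic seed streams for the three generator stages
sim_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) + offset * 1000003) %% 2147483647)
}

#' Simulate a dual (social/genetic) pedigree with extra-pair paternity
#'
#' Discrete non-overlapping generations; within each generation males and
#' females are randomly paired into monogamous social pairs, each producing
#' `offspring_per_pair` offspring of random balanced sex. Independently for
#' each offspring, with probability `epp_rate` the *genetic* sire is replaced
#' by a different male drawn uniformly from the parental generation; the
#' genetic dam always equals the social dam. Founders have missing parents.
#'
#' @param config a [sim_config()].
#' @return A data frame of class `"dual_pedigree"` with columns `id`,
#'   `social_sire`, `social_dam`, `genetic_sire`, `genetic_dam`,
#'   `generation`, `sex`.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, 0L))
  n0 <- config$n_founders
  sexes <- sample(rep(c("M", "F"), n0 / 2))
  rec <- data.frame(id = sprintf("I%05d", seq_len(n0)),
                    social_sire = NA_character_, social_dam = NA_character_,
                    genetic_sire = NA_character_, genetic_dam = NA_character_,
                    generation = 1L, sex = sexes, stringsAsFactors = FALSE)
  next_id <- n0 + 1L
  for (g in seq_len(config$n_generations - 1L)) {
    par <- rec[rec$generation == g, ]
    males <- sample(par$id[par$sex == "M"])
    females <- sample(par$id[par$sex == "F"])
    n_pairs <- min(length(males), length(females))
    if (n_pairs < 1) break
    sire <- rep(males[seq_len(n_pairs)], each = config$offspring_per_pair)
    dam <- rep(females[seq_len(n_pairs)], each = config$offspring_per_pair)
    n_off <- length(sire)
    ids <- sprintf("I%05d", seq(next_id, length.out = n_off))
    next_id <- next_id + n_off
    gsire <- sire
    all_males <- par$id[par$sex == "M"]
    if (length(all_males) >= 2 && config$epp_rate > 0) {
      epp <- stats::runif(n_off) < config$epp_rate
      for (k in which(epp)) {
        gsire[k] <- sample(setdiff(all_males, sire[k]), 1L)
      }
    }
    off_sex <- sample(rep_len(c("M", "F"), n_off))
    rec <- rbind(rec, data.frame(id = ids, social_sire = sire,
                                 social_dam = dam, genetic_sire = gsire,
                                 genetic_dam = dam, generation = g + 1L,
                                 sex = off_sex, stringsAsFactors = FALSE))
  }
  class(rec) <- c("dual_pedigree", "data.frame")
  attr(rec, "config") <- config
  rec
}

#' @export
print.dual_pedigree <- function(x, ...) {
  mism <- x$generation > 1 & x$genetic_sire != x$social_sire
  cat(sprintf(paste0("Dual pedigree: %d individuals, %d generations, ",
                     "%.1f%% extra-pair offspring\n"),
              nrow(x), max(x$generation), 100 * mean(mism[x$generation > 1])))
  invisible(x)
}

#' Convert a dual pedigree to a plain pedigree
#'
#' @param x a `"dual_pedigree"`.
#' @param links `"social"` (default) or `"genetic"` parent assignments.
#' @return A `"pedigree"`; the clutch key is the social pair, so broods are
#'   identifiable downstream.
#' @export
as_pedigree <- function(x, links = c("social", "genetic")) {
  links <- match.arg(links)
  stopifnot(inherits(x, "dual_pedigree"))
  if (links == "social") {
    pedigree(x$id, x$social_sire, x$social_dam,
             clutch = ifelse(is.na(x$social_sire), NA,
                             paste(x$social_sire, x$social_dam)))
  } else {
    pedigree(x$id, x$genetic_sire, x$genetic_dam)
  }
}

#' Gene-drop genotypes through the genetic pedigree links
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions at per-locus
#' minor-allele frequencies uniform in `[maf_low, maf_high]`; each offspring
#' receives, independently per locus (no linkage), one allele from each
#' *genetic* parent, a transmitted allele being the minor allele with
#' probability dosage/2. Marker similarity therefore reflects realized, not
#' social, relatedness.
#'
#' @param pedigree a `"dual_pedigree"` from [simulate_pedigree()].
#' @param config the same [sim_config()].
#' @return A `"genotype_matrix"` (all loci labelled chromosome `"1"`).
#' @export
simulate_genotypes <- function(pedigree, config) {
  validate_sim_config(config)
  stopifnot(inherits(pedigree, "dual_pedigree"))
  set.seed(sim_seed(config, 1L))
  n <- nrow(pedigree)
  L <- config$n_snps
  p <- stats::runif(L, config$maf_low, config$maf_high)
  G <- matrix(NA_real_, n, L, dimnames = list(pedigree$id,
                                              sprintf("snp%05d", seq_len(L))))
  ord <- order(pedigree$generation)
  si <- match(pedigree$genetic_sire, pedigree$id)
  di <- match(pedigree$genetic_dam, pedigree$id)
  for (i in ord) {
    if (is.na(si[i]) && is.na(di[i])) {
      G[i, ] <- stats::rbinom(L, 2L, p)
    } else if (is.na(si[i]) || is.na(di[i])) {
      stop("pedigree-integrity error: non-founder ", pedigree$id[i],
           " is missing a genetic parent")
    } else {
      G[i, ] <- stats::rbinom(L, 1L, G[si[i], ] / 2) +
                stats::rbinom(L, 1L, G[di[i], ] / 2)
    }
  }
  genotype_matrix(G, chrom = "1")
}

#' Simulate polygenic repeated-measure phenotypes
#'
#' Founder breeding values are Normal(0, Va); each non-founder's breeding
#' value is the mean of its *genetic* parents' values plus a Mendelian
#' sampling deviation Normal(0, Va/2) (non-inbred approximation). Each
#' individual gets a permanent-environment effect Normal(0, Vpe) and a
#' uniform number of repeat measurements in `[repeats_low, repeats_high]`;
#' each measurement is
#' `trait_mean + measurer_effect + breeding_value + permanent_env + Normal(0, Vres)`
#' with the measurer assigned uniformly per measurement.
#'
#' @param pedigree a `"dual_pedigree"`.
#' @param config the same [sim_config()].
#' @return A long-format data frame (`id`, `y`, `measurer`, `year`, `sex`,
#'   `age`) with attributes `breeding_values` and `permanent_env` (named
#'   numeric vectors of the true effects) for parameter-recovery tests.
#' @export
simulate_phenotypes <- function(pedigree, config) {
  validate_sim_config(config)
  stopifnot(inherits(pedigree, "dual_pedigree"))
  set.seed(sim_seed(config, 2L))
  n <- nrow(pedigree)
  ord <- order(pedigree$generation)
  si <- match(pedigree$genetic_sire, pedigree$id)
  di <- match(pedigree$genetic_dam, pedigree$id)
  bv <- numeric(n)
  for (i in ord) {
    bv[i] <- if (is.na(si[i])) {
      stats::rnorm(1, 0, sqrt(config$Va))
    } else {
      (bv[si[i]] + bv[di[i]]) / 2 + stats::rnorm(1, 0, sqrt(config$Va / 2))
    }
  }
  pe <- stats::rnorm(n, 0, sqrt(config$Vpe))
  names(bv) <- names(pe) <- pedigree$id
  reps <- config$repeats_low +
    sample.int(config$repeats_high - config$repeats_low + 1L, n,
               replace = TRUE) - 1L
  idx <- rep(seq_len(n), reps)
  within <- sequence(reps)
  measurer <- factor(paste0("M", sample.int(config$n_measurers,
                                            length(idx), replace = TRUE)),
                     levels = paste0("M", seq_len(config$n_measurers)))
  y <- config$trait_mean + config$measurer_effects[as.integer(measurer)] +
    bv[idx] + pe[idx] +
    stats::rnorm(length(idx), 0, sqrt(config$Vres))
  out <- data.frame(id = pedigree$id[idx], y = y, measurer = measurer,
                    year = 2000L + 2L * (pedigree$generation[idx] - 1L) +
                      within - 1L,
                    sex = pedigree$sex[idx], age = within,
                    stringsAsFactors = FALSE)
  attr(out, "breeding_values") <- bv
  attr(out, "permanent_env") <- pe
  attr(out, "config") <- config
  out
}
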