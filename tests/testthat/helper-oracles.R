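# Independent oracles used across tests.

# Monte-Carlo additive relationship matrix by gene dropping: founders carry
# unique allele labels, each offspring inherits one allele per parent chosen
# uniformly; A_ij is estimated as twice the probability that two alleles
# drawn one from each individual are identical by descent.
genedrop_a_oracle <- function(ped, n_rep = 10000, seed = 1) {
  set.seed(seed)
  ord <- order(ped$generation)
  id <- ped$id[ord]
  si <- match(ped$sire[ord], id)
  di <- match(ped$dam[ord], id)
  n <- length(id)
  AL1 <- AL2 <- matrix(NA_integer_, n, n_rep)
  founder_label <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      AL1[i, ] <- founder_label + 1L
      founder_label <- founder_label + 2L
      AL2[i, ] <- founder_label
    } else {
      pick1 <- sample.int(2, n_rep, replace = TRUE)
      pick2 <- sample.int(2, n_rep, replace = TRUE)
      AL1[i, ] <- ifelse(pick1 == 1L, AL1[si[i], ], AL2[si[i], ])
      AL2[i, ] <- ifelse(pick2 == 1L, AL1[di[i], ], AL2[di[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      kin <- mean((AL1[i, ] == AL1[j, ]) + (AL1[i, ] == AL2[j, ]) +
                    (AL2[i, ] == AL1[j, ]) + (AL2[i, ] == AL2[j, ])) / 4
      A[i, j] <- A[j, i] <- 2 * kin
    }
  }
  A
}

# Brute-force exact HWE p-value by direct factorial enumeration over all
# heterozygote counts compatible with the allele counts (totals <= 50).
hwe_bruteforce <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  stopifnot(n <= 50)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  w <- sapply(hs, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (max(nA, na) - h) / 2
    factorial(n) / (factorial(hom_r) * factorial(h) * factorial(hom_c)) * 2^h
  })
  p <- w / sum(w)
  sum(p[p <= p[match(n_Aa, hs)] * (1 + 1e-9)])
}

# small hand-made pedigrees
ped_po_sibs <- function() {
  # two founders, two shared offspring, one half-sib via another dam
  pedigree(id = c("s", "d", "d2", "o1", "o2", "h1"),
           sire = c(NA, NA, NA, "s", "s", "s"),
           dam = c(NA, NA, NA, "d", "d", "d2"))
}

ped_inbred <- function() {
  # full-sib mating: offspring of o1 x o2 has diagonal 1.25
  pedigree(id = c("s", "d", "o1", "o2", "x"),
           sire = c(NA, NA, "s", "s", "o1"),
           dam = c(NA, NA, "d", "d", "o2"))
}

# numeric content of a comparison report (for reproducibility checks)
report_values <- function(r) {
  list(h2_P = r$h2_P, h2_G = r$h2_G,
       summary_P = r$summary_P, summary_G = r$summary_G,
       mantel = r$mantel[c("r", "p", "ci")],
       epp = r$epp[c("n_epp", "n_total", "epp_rate_percent")],
       overlap = r$h2_cri_overlap, p_cmp = r$p_vaG_gt_vaP)
}

# deterministic small simulated bundle for model tests
small_sim <- function(seed = 1, n_founders = 40, epp = 0.2, n_snps = 400,
                      Va = 12.8, Vpe = 6.4, Vres = 6.4) {
  cfg <- sim_config(n_founders = n_founders, n_generations = 4,
                    epp_rate = epp, n_snps = n_snps,
                    Va = Va, Vpe = Vpe, Vres = Vres, seed = seed)
  dual <- simulate_pedigree(cfg)
  list(cfg = cfg, dual = dual,
       pheno = simulate_phenotypes(dual, cfg))
}
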