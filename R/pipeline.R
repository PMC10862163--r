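#' Configuration for an end-to-end pipeline run
#'
#' Either `mode = "synthetic"` with a [sim_config()], or `mode = "files"`
#' with paths to a pedigree CSV, a genotype file (0/1/2 CSV or PLINK text
#' prefix) and a phenotype CSV.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param sim a [sim_config()] (synthetic mode).
#' @param paths named list with `pedigree`, `genotypes` (CSV path or PLINK
#'   prefix), `phenotypes` (files mode).
#' @param qc named list of [apply_qc()] threshold overrides.
#' @param epp named list with `high` / `low` similarity thresholds.
#' @param mantel named list with `n_perm`, `n_boot`.
#' @param mcmc named list with `n_iter`, `n_burnin`, `n_chains`, `thin`.
#' @param out_dir output directory for stage artifacts (`NULL`: nothing is
#'   written).
#' @param grm_fit genomic matrix used for the G animal-model fit and the
#'   paternity classification: `"vanraden"` (allele-frequency-weighted,
#'   relatedness scale; default) or `"ibs"` (raw identity-by-state
#'   similarity). The Mantel comparison always uses the IBS matrix; its
#'   correlation is invariant to the affine difference between the two.
#' @param seed global seed; every stage seed is derived from it.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "files"), sim = sim_config(),
                       paths = NULL, qc = list(), epp = list(),
                       mantel = list(), mcmc = list(), out_dir = NULL,
                       grm_fit = c("vanraden", "ibs"), seed = 1) {
  mode <- match.arg(mode)
  grm_fit <- match.arg(grm_fit)
  if (mode == "files") {
    need <- c("pedigree", "genotypes", "phenotypes")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stop("files mode needs paths$pedigree, paths$genotypes, paths$phenotypes")
    }
  }
  mantel <- utils::modifyList(list(n_perm = 999, n_boot = 500), mantel)
  mcmc <- utils::modifyList(list(n_iter = 20000, n_burnin = 4000,
                                 n_chains = 4, thin = 1), mcmc)
  epp <- utils::modifyList(list(high = 0.3, low = 0.1), epp)
  structure(list(mode = mode, sim = sim, paths = paths, qc = qc, epp = epp,
                 mantel = mantel, mcmc = mcmc, out_dir = out_dir,
                 grm_fit = grm_fit, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` block is
#' passed to [sim_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$sim)) cfg$sim <- do.call(sim_config, cfg$sim)
  do.call(run_config, cfg)
}

stage_log <- function(enabled, stage, ..., files = character()) {
  if (!enabled) return(invisible())
  hashes <- if (length(files)) {
    paste(sprintf("%s=%s", basename(files),
                  substr(unname(tools::md5sum(files)), 1, 8)),
          collapse = " ")
  } else ""
  message(sprintf("[pipeline] %s %s %s", stage, paste0(..., collapse = " "),
                  hashes))
}

#' Run the full comparison pipeline
#'
#' Executes, in order: data generation (or ingestion), SNP quality control,
#' construction of the pedigree-based additive relationship matrix (social
#' links, dummy parents inserted, trimmed to the genotyped individuals) and
#' of the IBS genomic similarity matrix, Mantel comparison of the two,
#' genetic-similarity classification of extra-pair paternity, and two animal
#' model fits of the same phenotype data — one per relatedness matrix.
#' Reruns with the same configuration and seed are reproducible.
#'
#' @param config a [run_config()].
#' @param verbose log one line per stage (with output-file hashes when
#'   `out_dir` is set).
#' @return An object of class `"comparison_report"`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  wpath <- function(name) if (is.null(out)) NULL else file.path(out, name)
  save_csv <- function(obj, name, writer) {
    if (is.null(out)) return(character())
    p <- wpath(name); writer(obj, p); p
  }

  # stage: data -------------------------------------------------------------
  if (config$mode == "synthetic") {
    sim <- config$sim
    sim$seed <- as.integer((as.numeric(config$seed) +
                              as.numeric(sim$seed)) %% 2147483647)
    dual <- simulate_pedigree(sim)
    geno <- simulate_genotypes(dual, sim)
    pheno <- simulate_phenotypes(dual, sim)
    ped_social <- as_pedigree(dual, "social")
    f <- c(save_csv(dual, "pedigree_dual.csv",
                    function(o, p) utils::write.csv(o, p, row.names = FALSE)),
           save_csv(geno, "genotypes.csv", write_genotype_csv),
           save_csv(pheno, "phenotypes.csv", write_phenotypes_csv))
    stage_log(verbose, "simulate",
              sprintf("%d individuals, %d loci, %d measurements",
                      nrow(dual), ncol(geno), nrow(pheno)), files = f)
  } else {
    ped_social <- read_pedigree_csv(config$paths$pedigree)
    gp <- config$paths$genotypes
    geno <- if (file.exists(paste0(gp, ".ped"))) read_plink(gp)
            else read_genotype_csv(gp)
    pheno <- read_phenotypes_csv(config$paths$phenotypes)
    dual <- NULL
    stage_log(verbose, "ingest",
              sprintf("%d individuals, %d loci, %d measurements",
                      nrow(ped_social), ncol(geno), nrow(pheno)))
  }

  # stage: QC ---------------------------------------------------------------
  qc <- do.call(apply_qc, c(list(genotypes = geno), config$qc))
  f <- save_csv(qc$locus_report, "qc_locus_report.csv",
                function(o, p) utils::write.csv(o, p, row.names = FALSE))
  stage_log(verbose, "qc",
            sprintf("%d/%d loci, %d/%d individuals pass",
                    ncol(qc$genotypes), ncol(geno),
                    nrow(qc$genotypes), nrow(geno)), files = f)
  genotyped <- rownames(qc$genotypes)

  # stage: relatedness matrices ---------------------------------------------
  summary_full <- pedigree_summary(ped_social)
  ped_dummy <- insert_dummy_parents(ped_social)
  ped_trim <- trim_to_common(ped_dummy, genotyped)
  A <- build_a_matrix(ped_trim)
  summary_trimmed <- pedigree_summary(ped_trim)
  G <- build_grm_ibs(qc$genotypes)
  # relatedness-scale genomic matrix for variance estimation and paternity
  # (unrelated pairs near 0, parent-offspring near 0.5)
  G_fit <- if (config$grm_fit == "vanraden") {
    build_grm_vanraden(qc$genotypes)
  } else G
  f <- c(save_csv(A, "relmatrix_pedigree.csv", write_relmatrix_csv),
         save_csv(G, "relmatrix_genomic.csv", write_relmatrix_csv))
  stage_log(verbose, "relmat", sprintf("A %dx%d, G %dx%d",
                                       nrow(A), ncol(A), nrow(G), ncol(G)),
            files = f)

  # stage: matrix comparison + EPP -------------------------------------------
  mant <- mantel_correlation(A, G, n_perm = config$mantel$n_perm,
                             n_boot = config$mantel$n_boot,
                             seed = config$seed + 1L)
  ped_lookup <- ped_social
  pairs <- ped_lookup[!is.na(ped_lookup$sire) &
                        ped_lookup$sire %in% genotyped &
                        ped_lookup$id %in% genotyped &
                        !ped_lookup$dummy, c("sire", "id")]
  names(pairs) <- c("father", "offspring")
  epp <- classify_paternity(G_fit, pairs, high = config$epp$high,
                            low = config$epp$low)
  stage_log(verbose, "mantel+epp",
            sprintf("r = %.3f; EPP %d/%d", mant$r, epp$n_epp, epp$n_total))

  # stage: animal models ------------------------------------------------------
  pheno_fit <- pheno[pheno$id %in% genotyped, , drop = FALSE]
  mc <- config$mcmc
  fit_P <- fit_animal_model(y ~ measurer, pheno_fit, K = A,
                            n_iter = mc$n_iter, n_burnin = mc$n_burnin,
                            n_chains = mc$n_chains, thin = mc$thin,
                            seed = config$seed + 2L)
  fit_G <- fit_animal_model(y ~ measurer, pheno_fit, K = G_fit,
                            n_iter = mc$n_iter, n_burnin = mc$n_burnin,
                            n_chains = mc$n_chains, thin = mc$thin,
                            seed = config$seed + 3L)
  stage_log(verbose, "fit", sprintf("P h2 = %.2f, G h2 = %.2f",
                                    mean(draw_matrix(fit_P)[, "h2"]),
                                    mean(draw_matrix(fit_G)[, "h2"])))

  report <- build_report(fit_P, fit_G, mant, epp, qc,
                         summary_full, summary_trimmed, config)
  if (!is.null(out)) {
    jsonlite::write_json(report_as_list(report), wpath("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_table1(report), wpath("table1.txt"))
    stage_log(verbose, "report", "", files = c(wpath("report.json"),
                                               wpath("table1.txt")))
  }
  report
}

build_report <- function(fit_P, fit_G, mant, epp, qc,
                         summary_full, summary_trimmed, config) {
  sm_P <- summary(fit_P)$table
  sm_G <- summary(fit_G)$table
  h2_P <- summarize_heritability(fit_P)
  h2_G <- summarize_heritability(fit_G)
  gc_P <- genetic_coefficient(fit_P)
  gc_G <- genetic_coefficient(fit_G)
  overlap <- !(h2_P$lower > h2_G$upper || h2_G$lower > h2_P$upper)
  va_P <- draw_matrix(fit_P)[, "va"]
  va_G <- draw_matrix(fit_G)[, "va"]
  k <- min(length(va_P), length(va_G))
  p_G_gt_P <- mean(va_G[seq_len(k)] > va_P[seq_len(k)])
  structure(list(summary_P = sm_P, summary_G = sm_G,
                 h2_P = h2_P, h2_G = h2_G, gc_P = gc_P, gc_G = gc_G,
                 h2_cri_overlap = overlap, p_vaG_gt_vaP = p_G_gt_P,
                 mantel = mant, epp = epp, qc_attrition = qc$attrition,
                 pedigree_summary_full = summary_full,
                 pedigree_summary_trimmed = summary_trimmed,
                 trait_mean = fit_P$trait_mean, config = config),
            class = "comparison_report")
}

report_as_list <- function(r) {
  list(heritability = list(
         P = list(mean = r$h2_P$mean, lower = r$h2_P$lower, upper = r$h2_P$upper),
         G = list(mean = r$h2_G$mean, lower = r$h2_G$lower, upper = r$h2_G$upper),
         cri_overlap = r$h2_cri_overlap),
       genetic_coefficient = list(P = r$gc_P$mean, G = r$gc_G$mean),
       p_vaG_gt_vaP = r$p_vaG_gt_vaP,
       mantel = list(r = r$mantel$r, p = r$mantel$p, ci = r$mantel$ci),
       epp = list(n_epp = r$epp$n_epp, n_total = r$epp$n_total,
                  rate_percent = r$epp$epp_rate_percent),
       variance_components = list(P = r$summary_P, G = r$summary_G),
       qc_attrition = r$qc_attrition,
       seed = r$config$seed)
}

#' Two-column posterior summary table
#'
#' Formats the two model fits side by side — measurer contrasts, variance
#' components, heritability and genetic coefficient — as
#' `mean (lower, upper)` at 2 decimal places, pedigree-based (P) column
#' first, genomic (G) second. Either summary may be `NULL`, leaving a
#' placeholder column.
#'
#' @param x a `"comparison_report"`, or `NULL` if `P`/`G` are given.
#' @param P,G `summary(fit)$table` data frames (used when `x` is `NULL`).
#' @param gc_P,gc_G optional genetic-coefficient summaries.
#' @return Character vector of table lines.
#' @export
format_table1 <- function(x = NULL, P = NULL, G = NULL,
                          gc_P = NULL, gc_G = NULL) {
  if (inherits(x, "comparison_report")) {
    P <- x$summary_P; G <- x$summary_G; gc_P <- x$gc_P; gc_G <- x$gc_G
  }
  if (is.null(P) && is.null(G)) stop("formatting error: no summaries given")
  cell <- function(tab, q) {
    if (is.null(tab)) return("-")
    i <- match(q, tab$quantity)
    if (is.na(i)) stop("formatting error: missing component ", q)
    sprintf("%.2f (%.2f, %.2f)", tab$mean[i], tab$lower[i], tab$upper[i])
  }
  ref <- if (!is.null(P)) P else G
  fixed <- setdiff(ref$quantity, c("va", "vpe", "vyear", "vres", "h2"))
  rows <- c(stats::setNames(fixed, fixed),
            "Additive genetic" = "va", "Permanent environment" = "vpe",
            if ("vyear" %in% ref$quantity) c(Year = "vyear"),
            Residual = "vres", Heritability = "h2")
  lines <- sprintf("%-24s %-22s %-22s", "Component", "P", "G")
  for (nm in names(rows)) {
    lines <- c(lines, sprintf("%-24s %-22s %-22s", nm,
                              cell(P, rows[[nm]]), cell(G, rows[[nm]])))
  }
  gcell <- function(s) if (is.null(s)) "-" else
    sprintf("%.2f (%.2f, %.2f)", s$mean, s$lower, s$upper)
  lines <- c(lines, sprintf("%-24s %-22s %-22s", "Genetic coefficient",
                            gcell(gc_P), gcell(gc_G)))
  lines
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Pedigree (P) vs genomic (G) relatedness comparison\n\n")
  writeLines(format_table1(x))
  cat(sprintf("\nMantel r = %.3f (CI %.3f-%.3f), p = %.4g\n",
              x$mantel$r, x$mantel$ci[1], x$mantel$ci[2], x$mantel$p))
  cat(sprintf("EPP: %.2f%% (%d of %d classified father-offspring pairs)\n",
              x$epp$epp_rate_percent, x$epp$n_epp, x$epp$n_total))
  cat(sprintf("95%% CrIs for h2 %s; P(va_G > va_P) = %.3f\n",
              if (x$h2_cri_overlap) "overlap" else "do not overlap",
              x$p_vaG_gt_vaP))
  invisible(x)
}
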