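#' Mantel correlation between two relatedness matrices
#'
#' Pearson correlation over the strictly-lower-triangle pairs of two
#' symmetric matrices sharing a label set, with a one-sided permutation
#' p-value (simultaneous random row/column permutations of the second
#' matrix; `(1 + #[r_perm >= r]) / (n_perm + 1)`) and a bootstrap percentile
#' confidence interval obtained by resampling individuals with replacement,
#' excluding pairs formed by two copies of the same individual.
#'
#' @param m1,m2 `"relmatrix"` objects (or labelled symmetric matrices) with
#'   identical label sets; `m2` is reordered to `m1`'s labels internally.
#' @param n_perm number of permutations.
#' @param n_boot number of bootstrap resamples for the CI.
#' @param seed integer seed (mandatory for reproducibility).
#' @param conf confidence level of the bootstrap interval.
#' @return An object of class `"mantel_cor"`: list with `r`, `p`, `ci`,
#'   `n`, `n_perm`, `n_boot`.
#' @export
mantel_correlation <- function(m1, m2, n_perm = 9999, n_boot = 1000,
                               seed = 1, conf = 0.95) {
  m1 <- as.matrix(m1)
  m2 <- as.matrix(m2)
  labs <- rownames(m1)
  if (is.null(labs) || is.null(rownames(m2))) stop("matrices must be labelled")
  if (!setequal(labs, rownames(m2))) {
    stop("lookup error: label sets differ between the two matrices")
  }
  m2 <- m2[labs, labs, drop = FALSE]
  n <- nrow(m1)
  if (n < 3) stop("need at least 3 individuals")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  v2 <- m2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("undefined-correlation error: zero variance in off-diagonal entries")
  }
  r <- stats::cor(v1, v2)
  set.seed(as.integer(seed))
  rperm <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    stats::cor(v1, m2[idx, idx][lt])
  }, numeric(1))
  p <- (1 + sum(rperm >= r)) / (n_perm + 1)
  rboot <- vapply(seq_len(n_boot), function(k) {
    idx <- sample.int(n, replace = TRUE)
    keep <- lt & outer(idx, idx, "!=")  # drop duplicated-individual pairs
    b1 <- m1[idx, idx][keep]
    b2 <- m2[idx, idx][keep]
    if (length(b1) < 3 || stats::sd(b1) == 0 || stats::sd(b2) == 0) {
      return(NA_real_)
    }
    stats::cor(b1, b2)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(rboot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(r = r, p = p, ci = ci, n = n,
                 n_perm = n_perm, n_boot = n_boot, conf = conf),
            class = "mantel_cor")
}

#' @export
print.mantel_cor <- function(x, ...) {
  cat(sprintf("Mantel correlation: r = %.3f (%d%% CI %.3f-%.3f), p = %.4g (%d permutations, n = %d)\n",
              x$r, round(100 * x$conf), x$ci[1], x$ci[2], x$p, x$n_perm, x$n))
  invisible(x)
}

#' Classify social paternities from genetic similarity
#'
#' A social father-offspring pair is taken to be a true genetic
#' relationship if the pair's genetic similarity exceeds `high`, and an
#' extra-pair paternity (EPP) if it falls below `low`; values in between are
#' `unresolved`. By default unresolved pairs stay in the denominator of the
#' reported EPP rate (on well-separated data there are none).
#'
#' @param similarity a `"relmatrix"` (typically the IBS matrix).
#' @param pairs data frame with columns `father` and `offspring` (ids present
#'   in `similarity`).
#' @param high,low similarity thresholds.
#' @param drop_unresolved exclude unresolved pairs from the rate denominator.
#' @return An object of class `"paternity_classification"`: list with the
#'   per-pair table (`father`, `offspring`, `similarity`, `label`), counts
#'   `n_epp`, `n_within_pair`, `n_unresolved`, `n_total`, and
#'   `epp_rate_percent`.
#' @export
classify_paternity <- function(similarity, pairs, high = 0.3, low = 0.1,
                               drop_unresolved = FALSE) {
  stopifnot(is.data.frame(pairs), all(c("father", "offspring") %in% names(pairs)))
  labs <- rownames(similarity)
  miss <- setdiff(unique(c(pairs$father, pairs$offspring)), labs)
  if (length(miss)) {
    stop("lookup error: pair member(s) absent from similarity matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  sim <- as.matrix(similarity)[cbind(as.character(pairs$father),
                                     as.character(pairs$offspring))]
  label <- ifelse(sim > high, "within_pair",
                  ifelse(sim < low, "epp", "unresolved"))
  tab <- data.frame(father = pairs$father, offspring = pairs$offspring,
                    similarity = sim, label = label,
                    stringsAsFactors = FALSE)
  n_epp <- sum(label == "epp")
  n_unres <- sum(label == "unresolved")
  denom <- if (drop_unresolved) nrow(tab) - n_unres else nrow(tab)
  rate <- if (denom > 0) 100 * n_epp / denom else NA_real_
  structure(list(pairs = tab, n_epp = n_epp,
                 n_within_pair = sum(label == "within_pair"),
                 n_unresolved = n_unres, n_total = nrow(tab),
                 epp_rate_percent = rate),
            class = "paternity_classification")
}

#' @export
print.paternity_classification <- function(x, ...) {
  cat(sprintf("Paternity classification: %d pairs; %d EPP, %d within-pair, %d unresolved\n",
              x$n_total, x$n_epp, x$n_within_pair, x$n_unresolved))
  cat(sprintf("  EPP rate: %.2f%% (%d / %d)\n",
              x$epp_rate_percent, x$n_epp, x$n_total))
  invisible(x)
}
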