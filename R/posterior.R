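#' Construct posterior draws of variance components by hand
#'
#' Mainly for worked examples and tests: wraps vectors of variance-component
#' draws (recycled to a common length) in the same container the sampler
#' returns, so that [summarize_heritability()] and [genetic_coefficient()]
#' can be applied to published posterior means or externally produced chains.
#'
#' @param va,vpe,vres numeric vectors of draws.
#' @param vyear optional among-year variance draws.
#' @param chain optional chain index per draw (defaults to one chain).
#' @return An object of class `"posterior_draws"`.
#' @examples
#' summarize_heritability(posterior_draws(va = 13.50, vpe = 8.22, vres = 3.89))
#' @export
posterior_draws <- function(va, vpe, vres, vyear = NULL, chain = NULL) {
  n <- max(length(va), length(vpe), length(vres), length(vyear))
  m <- cbind(va = rep_len(va, n), vpe = rep_len(vpe, n),
             vres = rep_len(vres, n))
  if (!is.null(vyear)) m <- cbind(m, vyear = rep_len(vyear, n))
  if (any(m < 0)) stop("variance draws must be non-negative")
  if (is.null(chain)) chain <- rep(1L, n)
  chains <- lapply(split.data.frame(m, chain), as.matrix)
  structure(list(chains = unname(chains)), class = "posterior_draws")
}

# combined post-burn-in draw matrix across chains
draw_matrix <- function(x) {
  if (inherits(x, c("animal_model", "posterior_draws"))) {
    do.call(rbind, x$chains)
  } else if (is.matrix(x)) x
  else stop("cannot extract draws from object of class ", class(x)[1])
}

variance_cols <- function(m) {
  intersect(c("va", "vpe", "vyear", "vres"), colnames(m))
}

post_summary_row <- function(draws, quantity, conf = 0.95) {
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
  data.frame(quantity = quantity, mean = mean(draws),
             lower = qs[1], upper = qs[2])
}

#' Posterior summary of heritability
#'
#' Heritability is summarised as the posterior mean of the per-draw ratio of
#' the additive genetic variance to the sum of all fitted variance
#' components (mean-of-ratio, with equal-tailed credible interval); the
#' ratio of posterior means is also reported for transparency.
#'
#' @param x an `"animal_model"`, `"posterior_draws"`, or a draw matrix with
#'   columns `va`, `vpe`, `vres` (and optionally `vyear`).
#' @param conf credible level.
#' @return A `"posterior_summary"` data frame with columns `quantity`,
#'   `mean`, `lower`, `upper`, and attribute `ratio_of_means`.
#' @export
summarize_heritability <- function(x, conf = 0.95) {
  m <- draw_matrix(x)
  vc <- variance_cols(m)
  if (!all(c("va", "vres") %in% vc)) {
    stop("draws must include at least va and vres")
  }
  tot <- rowSums(m[, vc, drop = FALSE])
  h2 <- ifelse(tot > 0, m[, "va"] / tot, 0)
  out <- post_summary_row(h2, "h2", conf)
  attr(out, "ratio_of_means") <- mean(m[, "va"]) / mean(tot)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Posterior summary of the additive genetic coefficient
#'
#' The evolvability-style ratio of the additive genetic variance to the
#' population trait mean, summarised per draw. `trait_mean` must be on the
#' same measurement scale as the variance components.
#'
#' @inheritParams summarize_heritability
#' @param trait_mean positive trait mean; defaults to the mean of the
#'   fitted response for an `"animal_model"`.
#' @return A `"posterior_summary"` data frame.
#' @export
genetic_coefficient <- function(x, trait_mean = NULL, conf = 0.95) {
  if (is.null(trait_mean) && inherits(x, "animal_model")) {
    trait_mean <- x$trait_mean
  }
  if (is.null(trait_mean) || !is.finite(trait_mean) || trait_mean <= 0) {
    stop("invalid-argument error: trait_mean must be a positive number")
  }
  m <- draw_matrix(x)
  out <- post_summary_row(m[, "va"] / trait_mean, "genetic_coefficient", conf)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s: %.3f (95%% CrI %.3f, %.3f)\n",
              x$quantity, x$mean, x$lower, x$upper))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain Rhat: each chain is halved, and the diagnostic compares the
#' between-sequence and within-sequence variances,
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate that the
#' chains are mixing over the same distribution.
#'
#' @param chains a list of numeric vectors, or of matrices with one column
#'   per parameter (equal lengths, at least 2 chains after splitting is not
#'   required but at least 2 input chains are).
#' @param split halve each chain before computing the diagnostic.
#' @return Named numeric vector of Rhat values, one per parameter.
#' @export
gelman_rubin_rhat <- function(chains, split = TRUE) {
  if (!is.list(chains)) stop("chains must be a list")
  if (length(chains) < 2) {
    stop("insufficient-chains error: need at least 2 chains")
  }
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1, dimnames = list(NULL, "par"))
    else as.matrix(ch)
  })
  len <- unique(vapply(chains, nrow, integer(1)))
  if (length(len) != 1 || len < 2) stop("chains must share a length >= 2")
  if (split) {
    h <- floor(len / 2)
    chains <- c(lapply(chains, function(ch) ch[seq_len(h), , drop = FALSE]),
                lapply(chains, function(ch) ch[(len - h + 1):len, , drop = FALSE]))
  }
  n <- nrow(chains[[1]])
  vapply(colnames(chains[[1]]), function(p) {
    seqs <- vapply(chains, function(ch) ch[, p], numeric(n))
    mns <- colMeans(seqs)
    W <- mean(apply(seqs, 2, stats::var))
    B <- n * stats::var(mns)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' @export
print.animal_model <- function(x, ...) {
  m <- draw_matrix(x)
  cat("Bayesian animal model (conjugate Gibbs sampler)\n")
  cat(sprintf("  relatedness source: %s%s\n", x$K_source,
              if (x$jitter > 0) sprintf(" (diagonal jitter %.2g)", x$jitter) else ""))
  cat(sprintf("  %d measurements of %d individuals\n",
              length(x$y), length(x$ids)))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d draws\n",
              length(x$chains), x$n_iter, x$n_burnin, x$thin, nrow(m)))
  vc <- variance_cols(m)
  cat("  posterior means: ",
      paste(sprintf("%s = %.3g", vc, colMeans(m[, vc, drop = FALSE])),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  heritability (mean of ratio): %.3f\n", mean(m[, "h2"])))
  invisible(x)
}

#' @describeIn fit_animal_model posterior means, 95% credible intervals and
#'   split-chain Rhat for fixed effects, variance components and
#'   heritability.
#' @param object,x an `"animal_model"`.
#' @param conf credible level.
#' @param ... unused.
#' @export
summary.animal_model <- function(object, conf = 0.95, ...) {
  m <- draw_matrix(object)
  alpha <- (1 - conf) / 2
  rhat <- if (length(object$chains) >= 2) {
    gelman_rubin_rhat(object$chains)
  } else rep(NA_real_, ncol(m))
  tab <- data.frame(
    quantity = colnames(m),
    mean = colMeans(m),
    lower = apply(m, 2, stats::quantile, alpha, names = FALSE),
    upper = apply(m, 2, stats::quantile, 1 - alpha, names = FALSE),
    rhat = unname(rhat), row.names = NULL)
  structure(list(table = tab, conf = conf,
                 n_draws = nrow(m), n_chains = length(object$chains)),
            class = "summary.animal_model")
}

#' @export
print.summary.animal_model <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summaries (%d draws, %d chains, %d%% CrI)\n",
              x$n_draws, x$n_chains, round(100 * x$conf)))
  tab <- x$table
  tab$mean <- signif(tab$mean, digits)
  tab$lower <- signif(tab$lower, digits)
  tab$upper <- signif(tab$upper, digits)
  tab$rhat <- round(tab$rhat, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @describeIn fit_animal_model posterior means of the fixed effects.
#' @export
coef.animal_model <- function(object, ...) {
  m <- draw_matrix(object)
  fixed <- setdiff(colnames(m), c("va", "vpe", "vyear", "vres", "h2"))
  colMeans(m[, fixed, drop = FALSE])
}

#' @describeIn fit_animal_model posterior-mean fitted values (fixed effects
#'   plus individual genetic and permanent-environment effects), in the
#'   canonical row order of the fitted data.
#' @export
fitted.animal_model <- function(object, ...) object$fitted

#' @describeIn fit_animal_model response minus posterior-mean fitted values.
#' @export
residuals.animal_model <- function(object, ...) object$y - object$fitted

#' @describeIn fit_animal_model trace plots of the variance components and
#'   heritability.
#' @export
plot.animal_model <- function(x, ...) {
  vc <- c(variance_cols(draw_matrix(x)), "h2")
  op <- graphics::par(mfrow = c(length(vc), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in vc) {
    graphics::matplot(vapply(x$chains, function(ch) ch[, p],
                             numeric(nrow(x$chains[[1]]))),
                      type = "l", lty = 1, ylab = p, xlab = "")
  }
  invisible(x)
}
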