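#' Relatedness matrix container
#'
#' A labelled symmetric matrix of pairwise relatedness coefficients with a
#' provenance tag: `"pedigree"` for an additive (numerator) relationship
#' matrix A, `"genomic"` for a marker-based similarity matrix G.
#'
#' @param values square numeric matrix with identical row/column names.
#' @param source `"pedigree"` or `"genomic"`.
#' @return An object of class `"relmatrix"` (a numeric matrix with a
#'   `source` attribute).
#' @export
relmatrix <- function(values, source = c("pedigree", "genomic")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (!nrow(values) && !ncol(values)) {
    dimnames(values) <- list(character(), character())
    return(structure(values, source = source,
                     class = c("relmatrix", "matrix", "array")))
  }
  labs <- rownames(values)
  if (is.null(labs) || !identical(labs, colnames(values))) {
    stop("relmatrix needs identical row and column names")
  }
  if (anyDuplicated(labs)) stop("id-collision error: duplicated labels")
  if (nrow(values) && max(abs(values - t(values))) > 1e-12) {
    stop("relmatrix must be symmetric within 1e-12")
  }
  if (source == "genomic" && nrow(values) &&
      (min(values) < -1e-12 || max(values) > 1 + 1e-12)) {
    stop("genomic (IBS) relatedness entries must lie in [0, 1]")
  }
  structure(values, source = source, class = c("relmatrix", "matrix", "array"))
}

#' @export
print.relmatrix <- function(x, ...) {
  cat(sprintf("%s relatedness matrix: %d individuals\n",
              attr(x, "source"), nrow(x)))
  k <- min(6L, nrow(x))
  if (k) print(round(unclass(x)[1:k, 1:k, drop = FALSE], 4))
  if (nrow(x) > k) cat("... (", nrow(x), " x ", nrow(x), " total)\n", sep = "")
  invisible(x)
}

#' @export
trim_to_common.relmatrix <- function(x, ids) {
  ids <- as.character(ids)
  if (!length(ids)) {
    warning("empty id list: returning empty matrix")
    m <- matrix(numeric(), 0, 0, dimnames = list(character(), character()))
    return(relmatrix(m, attr(x, "source")))
  }
  unknown <- setdiff(ids, rownames(x))
  if (length(unknown)) {
    stop("lookup error: id(s) not in matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  relmatrix(unclass(x)[ids, ids, drop = FALSE], attr(x, "source"))
}

#' Additive relationship matrix by the tabular method
#'
#' Fills the numerator relationship matrix A in pedigree order:
#' `A[i,i] = 1 + 0.5 * A[sire_i, dam_i]` and, for previously placed `j`,
#' `A[j,i] = 0.5 * (A[j, sire_i] + A[j, dam_i])`, with unknown parents
#' contributing 0. Parent-offspring and full-sib pairs of unrelated,
#' non-inbred parents get 0.5, half-sibs 0.25; the diagonal is 1 plus the
#' inbreeding coefficient.
#'
#' If the pedigree was produced by [trim_to_common()] the matrix is computed
#' over all retained records (so links through excluded intermediates are
#' kept) and then projected onto the requested ids; `ids` gives the same
#' control directly.
#'
#' @param ped a `"pedigree"`.
#' @param ids optional ids to project the result onto.
#' @return A `"relmatrix"` with source `"pedigree"`.
#' @export
build_a_matrix <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(ids)) ids <- attr(ped, "target_ids")
  n <- nrow(ped)
  if (!n) {
    m <- matrix(numeric(), 0, 0, dimnames = list(character(), character()))
    return(relmatrix(m, "pedigree"))
  }
  ord <- ped_order(ped)
  id <- ped$id[ord]
  si <- match(ped$sire[ord], id)
  di <- match(ped$dam[ord], id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  col0 <- rep(0, n)  # virtual column for unknown parents
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    as_ <- if (is.na(s)) col0 else A[, s]
    ad_ <- if (is.na(d)) col0 else A[, d]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (as_[j] + ad_[j])
    }
    A[i, i] <- 1 + 0.5 * (if (is.na(s) || is.na(d)) 0 else A[s, d])
  }
  if (!is.null(ids)) A <- A[ids, ids, drop = FALSE]
  relmatrix(A, "pedigree")
}

#' Identity-by-state genomic similarity matrix
#'
#' PLINK-style IBS similarity from minor-allele dosages: for each pair the
#' mean over loci non-missing in both individuals of `(2 - |g_i - g_j|) / 2`,
#' i.e. the average proportion of alleles shared identical by state. The
#' diagonal is computed by the same formula (1 wherever the individual has
#' any non-missing call).
#'
#' @param genotypes a `"genotype_matrix"` (individuals x loci, dosages
#'   0/1/2 with `NA` for missing) or a plain matrix with row names.
#' @return A `"relmatrix"` with source `"genomic"`.
#' @export
build_grm_ibs <- function(genotypes) {
  G <- unclass(as.matrix(genotypes))
  if (is.null(rownames(G))) stop("genotype matrix needs individual row names")
  bad <- !is.na(G) & !(G %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  all_missing <- rownames(G)[rowSums(!is.na(G)) == 0]
  if (length(all_missing)) {
    stop("coverage error: individual(s) with all loci missing: ",
         paste(utils::head(all_missing, 5), collapse = ", "))
  }
  I0 <- (!is.na(G) & G == 0) + 0
  I1 <- (!is.na(G) & G == 1) + 0
  I2 <- (!is.na(G) & G == 2) + 0
  # sum over shared loci of |g_i - g_j|
  D <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
       tcrossprod(I1, I2) + tcrossprod(I2, I1) +
       2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  N <- tcrossprod(I0 + I1 + I2)  # shared non-missing locus counts
  if (any(N == 0)) {
    stop("coverage error: some pair(s) share no non-missing locus")
  }
  S <- (2 * N - D) / (2 * N)
  S <- (S + t(S)) / 2
  relmatrix(S, "genomic")
}

#' Allele-frequency-weighted genomic relationship matrix (VanRaden type)
#'
#' Sensitivity-analysis alternative to [build_grm_ibs()]:
#' `G = Z Z' / (2 * sum(p*(1-p)))` with `Z` the column-centred dosage matrix.
#' Missing dosages are imputed at the locus mean. Not used by the default
#' pipeline.
#'
#' @inheritParams build_grm_ibs
#' @return A labelled symmetric matrix (not a `"relmatrix"`: entries may be
#'   negative).
#' @export
build_grm_vanraden <- function(genotypes) {
  G <- unclass(as.matrix(genotypes))
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(G, 2, 2 * p)
  Z[is.na(Z)] <- 0
  M <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  (M + t(M)) / 2
}

#' Read / write relatedness matrices
#'
#' Square dialect: CSV with ids in the first column and as the header.
#' Long dialect: CSV `id1,id2,value` covering the lower triangle and diagonal.
#'
#' @param path file path.
#' @param source provenance tag for reading.
#' @export
read_relmatrix_csv <- function(path, source = c("pedigree", "genomic")) {
  d <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(d)
  rownames(m) <- rownames(d)
  relmatrix(m, match.arg(source))
}

#' @rdname read_relmatrix_csv
#' @param x a `"relmatrix"`.
#' @param long write the long (id1,id2,value) dialect instead of square.
#' @export
write_relmatrix_csv <- function(x, path, long = FALSE) {
  if (!long) {
    utils::write.csv(as.data.frame(unclass(x)), path, quote = FALSE)
  } else {
    idx <- which(lower.tri(x, diag = TRUE), arr.ind = TRUE)
    d <- data.frame(id1 = rownames(x)[idx[, 1]], id2 = colnames(x)[idx[, 2]],
                    value = unclass(x)[idx])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
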