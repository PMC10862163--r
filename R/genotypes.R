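#' Genotype matrix container
#'
#' Individuals x biallelic loci, coded as minor-allele dosages 0/1/2 with
#' `NA` for missing calls. Row names are individual ids; column names are
#' locus ids; the `chrom` attribute carries a chromosome label per locus.
#'
#' @param values numeric/integer matrix of dosages with dimnames.
#' @param chrom chromosome label per locus (recycled if length 1).
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(values, chrom = "1") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("genotype matrix needs individual row names and locus column names")
  }
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  chrom <- as.character(rep_len(chrom, ncol(values)))
  structure(values, chrom = chrom,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  chrom <- attr(x, "chrom")
  m <- unclass(x)[i, j, drop = FALSE]
  if (!missing(j)) {
    jj <- if (is.character(j)) match(j, colnames(x)) else j
    chrom <- chrom[jj]
  }
  genotype_matrix(m, chrom)
}

#' Read / write the 0/1/2 CSV genotype dialect
#'
#' CSV with individual ids in the first column, one column per locus, and an
#' optional first row named `chrom` giving per-locus chromosome labels.
#' Missing calls are empty cells or `NA`.
#'
#' @param path file path.
#' @export
read_genotype_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                       colClasses = "character")
  chrom <- "1"
  if (nrow(d) && rownames(d)[1] == "chrom") {
    chrom <- as.character(d[1, ])
    d <- d[-1, , drop = FALSE]
  }
  m0 <- as.matrix(d)
  m0[m0 == ""] <- NA
  m <- suppressWarnings(matrix(as.numeric(m0), nrow(m0), ncol(m0),
                               dimnames = dimnames(m0)))
  genotype_matrix(m, chrom)
}

#' @rdname read_genotype_csv
#' @param x a `"genotype_matrix"`.
#' @export
write_genotype_csv <- function(x, path) {
  out <- rbind(chrom = attr(x, "chrom"), unclass(x))
  utils::write.csv(out, path, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write PLINK text (.ped/.map) genotypes
#'
#' Tab-separated `.ped` with the six standard leading columns (family id,
#' individual id, father, mother, sex, phenotype) and two allele columns per
#' locus, alleles coded `A` (major) / `B` (minor), missing `0 0`; `.map`
#' with columns chromosome, locus id, genetic distance, position. Dosage is
#' the count of `B` alleles.
#'
#' @param prefix path without extension; `prefix.ped` and `prefix.map` are
#'   used.
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           colClasses = "character")
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "\t",
                           colClasses = "character")
  n_loci <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_loci) {
    stop(".ped has ", ncol(ped), " columns; expected ", 6 + 2 * n_loci)
  }
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, 2 * n_loci, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * n_loci, by = 2), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  dose <- (a1 == "B") + (a2 == "B")
  dose[miss] <- NA
  dimnames(dose) <- list(ped[, 2], map[, 2])
  genotype_matrix(dose, chrom = map[, 1])
}

#' @rdname read_plink
#' @param x a `"genotype_matrix"`.
#' @param ped optional `"pedigree"` supplying father/mother/sex columns.
#' @export
write_plink <- function(x, prefix, ped = NULL) {
  n_loci <- ncol(x)
  map <- data.frame(chrom = attr(x, "chrom"), id = colnames(x),
                    cm = 0, pos = seq_len(n_loci))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- rownames(x)
  sire <- dam <- rep("0", length(ids))
  sex <- rep("0", length(ids))
  if (!is.null(ped)) {
    i <- match(ids, ped$id)
    sire <- ifelse(is.na(ped$sire[i]), "0", ped$sire[i])
    dam <- ifelse(is.na(ped$dam[i]), "0", ped$dam[i])
    if ("sex" %in% names(ped)) {
      sex <- c(M = "1", F = "2")[as.character(ped$sex[i])]
      sex[is.na(sex)] <- "0"
    }
  }
  d <- unclass(x)
  a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, "B", "A"))
  a2 <- ifelse(is.na(d), "0", ifelse(d == 2, "B", "A"))
  allele <- matrix("", nrow(d), 2 * n_loci)
  allele[, seq(1, 2 * n_loci, by = 2)] <- a1
  allele[, seq(2, 2 * n_loci, by = 2)] <- a2
  out <- cbind("FAM1", ids, sire, dam, sex, "-9", allele)
  utils::write.table(out, paste0(prefix, ".ped"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read / write the long-format phenotype table
#'
#' CSV with columns `id`, `y`, `measurer`, `year`, `sex`, `age`; one row per
#' measurement, repeated rows per individual.
#'
#' @param path file path.
#' @export
read_phenotypes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "y", "measurer")
  if (!all(need %in% names(d))) {
    stop("phenotype CSV must have at least columns id, y, measurer")
  }
  d$id <- as.character(d$id)
  d$measurer <- factor(d$measurer)
  d
}

#' @rdname read_phenotypes_csv
#' @param x phenotype data frame.
#' @export
write_phenotypes_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
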