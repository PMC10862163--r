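#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `sire`, `dam` (character; `NA` for an unknown parent), an optional
#' `clutch` key identifying the nest/brood an individual hatched in, and a
#' logical `dummy` column marking placeholder parents inserted by
#' [insert_dummy_parents()]. Parents that are named but have no row of their
#' own are added automatically as founder records. The constructor validates
#' uniqueness of ids, absence of self-ancestry and acyclicity.
#'
#' @param id character vector of individual identifiers.
#' @param sire,dam character vectors of parental identifiers; `NA`, `""` or
#'   `"0"` denote an unknown parent.
#' @param clutch optional vector of clutch/nest keys (same length as `id`).
#' @param dummy optional logical vector flagging dummy individuals.
#' @return A data frame of class `"pedigree"`.
#' @examples
#' ped <- pedigree(c("a", "b", "x"), sire = c(NA, NA, "a"), dam = c(NA, NA, "b"))
#' @export
pedigree <- function(id, sire, dam, clutch = NULL, dummy = NULL) {
  id <- as.character(id)
  sire <- norm_parent(sire)
  dam <- norm_parent(dam)
  if (anyNA(id) || any(id == "")) stop("individual ids must be non-missing")
  if (anyDuplicated(id)) {
    stop("id-collision error: duplicated id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(sire == id, na.rm = TRUE) || any(dam == id, na.rm = TRUE)) {
    stop("pedigree-integrity error: individual listed as its own parent")
  }
  if (is.null(dummy)) dummy <- rep(FALSE, length(id))
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    dummy = as.logical(dummy), stringsAsFactors = FALSE)
  if (!is.null(clutch)) ped$clutch <- as.character(clutch)
  # add founder rows for named parents without a record
  extra <- setdiff(c(ped$sire, ped$dam), c(ped$id, NA))
  if (length(extra)) {
    add <- data.frame(id = extra, sire = NA_character_, dam = NA_character_,
                      dummy = FALSE, stringsAsFactors = FALSE)
    if (!is.null(ped$clutch)) add$clutch <- NA_character_
    ped <- rbind(ped, add)
  }
  ped$generation <- ped_generations(ped)  # errors on cycles
  class(ped) <- c("pedigree", "data.frame")
  ped
}

norm_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0" | x == "NA")] <- NA_character_
  x
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals (%d dummy), %d founders\n",
              nrow(x), sum(x$dummy),
              sum(is.na(x$sire) & is.na(x$dam))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

# generation index: founders 1, otherwise 1 + max(parent generations);
# fails on cyclic pedigrees
ped_generations <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  gen <- ifelse(is.na(si) & is.na(di), 1L, NA_integer_)
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      gs <- if (is.na(si[i])) 0L else gen[si[i]]
      gd <- if (is.na(di[i])) 0L else gen[di[i]]
      if (!is.na(gs) && !is.na(gd)) {
        gen[i] <- 1L + max(gs, gd)
        progressed <- TRUE
      }
    }
    if (!progressed) {
      stop("pedigree-integrity error: cycle detected involving id(s): ",
           paste(utils::head(ped$id[todo], 5), collapse = ", "))
    }
  }
  gen
}

# topological order: parents before offspring
ped_order <- function(ped) order(ped$generation, seq_len(nrow(ped)))

#' Read / write pedigree CSV
#'
#' The on-disk dialect is a CSV with header `id,sire,dam` and optional
#' `clutch` and `dummy` columns; unknown parents are blank or `"0"`.
#'
#' @param path file path.
#' @return [read_pedigree_csv()] returns a `"pedigree"`; `write_pedigree_csv()`
#'   returns `path` invisibly.
#' @export
read_pedigree_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(d))) {
    stop("pedigree CSV must have columns id, sire, dam")
  }
  pedigree(d$id, d$sire, d$dam,
           clutch = if ("clutch" %in% names(d)) d$clutch,
           dummy = if ("dummy" %in% names(d)) as.logical(d$dummy))
}

#' @rdname read_pedigree_csv
#' @param ped a `"pedigree"`.
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- as.data.frame(ped)[, intersect(c("id", "sire", "dam", "clutch", "dummy"),
                                        names(ped))]
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Insert shared dummy parents for sibling groups with unknown parents
#'
#' Field pedigrees of nest-box populations often know the brood an individual
#' hatched in even when a parent went unidentified. To retain the within-brood
#' covariance, every sibling group with a missing parental slot receives one
#' newly minted dummy founder per missing slot, shared by the whole group.
#' Sibling groups are identified by the `clutch` key when present, otherwise
#' by the known co-parent. Individuals missing both parents and lacking a
#' clutch key are left untouched (no sibling group is identifiable).
#'
#' Dummy individuals are flagged in the `dummy` column: they take part in
#' relationship-matrix recursion but are excluded from phenotype joins and
#' from [pedigree_summary()] parentage counts.
#'
#' @param ped a `"pedigree"`.
#' @param prefix prefix for generated dummy ids.
#' @return A `"pedigree"` with dummy parents inserted.
#' @export
insert_dummy_parents <- function(ped, prefix = "DUMMY") {
  stopifnot(inherits(ped, "pedigree"))
  ped <- as.data.frame(ped)
  has_clutch <- "clutch" %in% names(ped) && any(!is.na(ped$clutch))
  group_key <- function(rows, slot) {
    # slot is the missing one; group by clutch if available, else by co-parent
    other <- if (slot == "sire") ped$dam[rows] else ped$sire[rows]
    key <- if (has_clutch) ped$clutch[rows] else rep(NA_character_, length(rows))
    ifelse(!is.na(key), paste0("c:", key),
           ifelse(!is.na(other), paste0("p:", other), NA_character_))
  }
  counter <- 0L
  new_rows <- list()
  for (slot in c("sire", "dam")) {
    miss <- which(is.na(ped[[slot]]) & !(is.na(ped$sire) & is.na(ped$dam) & !has_clutch))
    miss <- miss[!is.na(group_key(miss, slot))]
    if (!length(miss)) next
    key <- group_key(miss, slot)
    for (k in unique(key)) {
      counter <- counter + 1L
      did <- paste0(prefix, "_", slot, "_", counter)
      if (did %in% ped$id) {
        stop("id-collision error: dummy id ", did, " already present")
      }
      ped[[slot]][miss[key == k]] <- did
      nr <- data.frame(id = did, sire = NA_character_, dam = NA_character_,
                       dummy = TRUE, stringsAsFactors = FALSE)
      if ("clutch" %in% names(ped)) nr$clutch <- NA_character_
      if ("generation" %in% names(ped)) nr$generation <- NA_integer_
      new_rows[[length(new_rows) + 1L]] <- nr
    }
  }
  if (length(new_rows)) {
    ped <- rbind(ped, do.call(rbind, new_rows)[, names(ped)])
  }
  pedigree(ped$id, ped$sire, ped$dam,
           clutch = if ("clutch" %in% names(ped)) ped$clutch,
           dummy = ped$dummy)
}

#' Summary statistics of a pedigree
#'
#' Counts maternities and paternities (offspring with a known, non-dummy dam
#' or sire), full-sibling pairs (unordered pairs sharing both known parents,
#' dummy parents counting as shared within their brood), the maximum pedigree
#' depth in generations (a founder generation counts as 1), and the mean
#' pairwise relatedness, i.e. the mean strictly-off-diagonal entry of the
#' additive relationship matrix over non-dummy individuals.
#'
#' @param ped a `"pedigree"`.
#' @return An object of class `"pedigree_summary"`: a list with elements
#'   `n_individuals`, `n_maternities`, `n_paternities`, `n_full_sib_pairs`,
#'   `mean_pairwise_relatedness`, `max_depth`.
#' @export
pedigree_summary <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  real <- !ped$dummy
  # a pedigree from trim_to_common() is summarised over its target ids only
  # (retained ancestors still contribute to relationship coefficients)
  target <- attr(ped, "target_ids")
  if (!is.null(target)) real <- real & ped$id %in% target
  if (!nrow(ped)) {
    out <- list(n_individuals = 0L, n_maternities = 0L, n_paternities = 0L,
                n_full_sib_pairs = 0L, mean_pairwise_relatedness = 0,
                max_depth = 0L)
    class(out) <- "pedigree_summary"
    return(out)
  }
  is_dummy <- stats::setNames(ped$dummy, ped$id)
  known_real <- function(p) !is.na(p) & !is_dummy[p]
  n_mat <- sum(known_real(ped$dam) & real)
  n_pat <- sum(known_real(ped$sire) & real)
  # full sibs: both parents known (dummy parents allowed: shared brood slot)
  both <- real & !is.na(ped$sire) & !is.na(ped$dam)
  fam <- table(paste(ped$sire[both], ped$dam[both]))
  n_fs <- sum(choose(fam, 2))
  A <- build_a_matrix(ped)
  keep <- ped$id[real]
  Ar <- unclass(A)[keep, keep, drop = FALSE]
  n <- length(keep)
  mpr <- if (n > 1) (sum(Ar) - sum(diag(Ar))) / (n * (n - 1)) else 0
  out <- list(n_individuals = sum(real),
              n_maternities = n_mat,
              n_paternities = n_pat,
              n_full_sib_pairs = as.integer(n_fs),
              mean_pairwise_relatedness = mpr,
              max_depth = max(ped$generation))
  class(out) <- "pedigree_summary"
  out
}

#' @export
print.pedigree_summary <- function(x, ...) {
  cat("Pedigree summary\n")
  cat(sprintf("  individuals:          %d\n", x$n_individuals))
  cat(sprintf("  maternities:          %d\n", x$n_maternities))
  cat(sprintf("  paternities:          %d\n", x$n_paternities))
  cat(sprintf("  full-sibling pairs:   %d\n", x$n_full_sib_pairs))
  cat(sprintf("  mean pairwise relatedness: %.4g\n", x$mean_pairwise_relatedness))
  cat(sprintf("  maximum depth (generations): %d\n", x$max_depth))
  invisible(x)
}

#' Restrict a pedigree or relatedness matrix to a set of individuals
#'
#' For a relatedness matrix the rows/columns are subset in the order of `ids`.
#' For a pedigree, records are trimmed to `ids` *plus* all their ancestors, so
#' that relationship coefficients passing through removed intermediates are
#' preserved; [build_a_matrix()] then projects the full matrix onto `ids`.
#'
#' @param x a `"pedigree"` or `"relmatrix"`.
#' @param ids character vector of individual ids to retain.
#' @return An object of the same class as `x`.
#' @export
trim_to_common <- function(x, ids) UseMethod("trim_to_common")

#' @export
trim_to_common.pedigree <- function(x, ids) {
  ids <- as.character(ids)
  if (!length(ids)) {
    warning("empty id list: returning empty pedigree")
    out <- pedigree(character(), character(), character())
    attr(out, "target_ids") <- character()
    return(out)
  }
  unknown <- setdiff(ids, x$id)
  if (length(unknown)) {
    stop("lookup error: id(s) not in pedigree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  # closure over ancestors
  keep <- ids
  repeat {
    rows <- x[x$id %in% keep, ]
    parents <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), keep)
    if (!length(parents)) break
    keep <- c(keep, parents)
  }
  out <- x[x$id %in% keep, , drop = FALSE]
  class(out) <- c("pedigree", "data.frame")
  attr(out, "target_ids") <- ids
  out
}
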