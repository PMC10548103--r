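#' Define a microsatellite locus panel
#'
#' A panel describes the loci a cohort was genotyped for, including loci that
#' are present in the raw data but excluded from analysis (e.g. because of a
#' non-negligible null-allele frequency).
#'
#' @param name character vector of unique locus names.
#' @param excluded logical vector (recycled); `TRUE` marks a locus that is
#'   serialized with the data but invisible to all downstream counting.
#' @param note free-text annotation per locus (e.g. the reason for exclusion).
#' @return A `locus_panel`: a data frame with columns `name`, `excluded`,
#'   `note`.
#' @examples
#' locus_panel(c("L01", "L02", "L03"), excluded = c(FALSE, FALSE, TRUE),
#'             note = c("", "", "suspected null alleles"))
#' @export
locus_panel <- function(name, excluded = FALSE, note = "") {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("locus names must be unique: ", paste(name[duplicated(name)], collapse = ", "))
  if (length(name) == 0L) stop("panel must contain at least one locus")
  p <- data.frame(name = name,
                  excluded = rep_len(as.logical(excluded), length(name)),
                  note = rep_len(as.character(note), length(name)),
                  stringsAsFactors = FALSE)
  class(p) <- c("locus_panel", "data.frame")
  p
}

#' Assemble a multilocus genotype table
#'
#' The central container: per-individual metadata plus two integer allele
#' matrices (individuals x loci). Allele pairs are unordered and stored
#' canonically with the smaller code first; a locus call is either complete
#' (two positive allele codes) or missing (both `NA`) -- half-calls are
#' rejected.
#'
#' @param individual_id character vector of unique ids.
#' @param generation one of `"P0"`, `"F1"`, `"F2"` per individual (or `NA`).
#' @param mother_id mother's id per individual, `NA` when unknown.
#' @param a1,a2 integer matrices of allele codes (> 0), one row per
#'   individual, one column per panel locus. `NA` in both marks a missing
#'   call. Pairs are sorted internally, so `(a, b)` and `(b, a)` yield
#'   identical tables.
#' @param panel a [locus_panel()]; column names of `a1`/`a2` must match
#'   `panel$name`.
#' @return A `genotype_table` object with elements `meta` (data frame:
#'   `individual_id`, `generation`, `mother_id`), `a1`, `a2`, `panel`.
#' @seealso [read_genotype_table()], [apply_locus_exclusions()]
#' @export
genotype_table <- function(individual_id, generation, mother_id, a1, a2, panel) {
  individual_id <- as.character(individual_id)
  n <- length(individual_id)
  if (anyDuplicated(individual_id))
    stop("duplicate individual id: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  generation <- rep_len(as.character(generation), n)
  bad_gen <- !is.na(generation) & !generation %in% c("P0", "F1", "F2")
  if (any(bad_gen))
    stop("generation must be P0, F1 or F2 (got: ",
         paste(unique(generation[bad_gen]), collapse = ", "), ")")
  mother_id <- rep_len(as.character(mother_id), n)
  if (!inherits(panel, "locus_panel")) panel <- locus_panel(panel)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  if (nrow(a1) != n) stop("allele matrices must have one row per individual")
  if (is.null(colnames(a1))) colnames(a1) <- panel$name
  if (is.null(colnames(a2))) colnames(a2) <- colnames(a1)
  unknown <- setdiff(colnames(a1), panel$name)
  if (length(unknown))
    stop("unknown locus column: ", paste(unknown, collapse = ", "))
  # align column order to the panel (loci absent from the matrices are errors)
  if (!all(panel$name %in% colnames(a1)))
    stop("allele matrices lack panel locus: ",
         paste(setdiff(panel$name, colnames(a1)), collapse = ", "))
  a1 <- a1[, panel$name, drop = FALSE]
  a2 <- a2[, panel$name, drop = FALSE]
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  half <- is.na(a1) != is.na(a2)
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1L, ]
    stop("half-called locus (one allele missing) for individual '",
         individual_id[w[1L]], "' at locus '", panel$name[w[2L]], "'")
  }
  # canonical unordered storage
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  rownames(a1) <- rownames(a2) <- individual_id
  structure(list(
    meta = data.frame(individual_id = individual_id, generation = generation,
                      mother_id = mother_id, stringsAsFactors = FALSE),
    a1 = a1, a2 = a2, panel = panel), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  n_excl <- sum(x$panel$excluded)
  cat("genotype_table:", nrow(x$meta), "individuals,",
      nrow(x$panel), "loci (", n_excl, "excluded )\n")
  gen <- table(x$meta$generation, useNA = "ifany")
  cat("  generations:", paste(names(gen), gen, sep = "=", collapse = ", "), "\n")
  cat("  missing calls:",
      sum(is.na(x$a1)), "/", length(x$a1), "\n")
  invisible(x)
}

#' Names of loci used in analysis
#'
#' @param table a [genotype_table()].
#' @return Character vector of non-excluded locus names.
#' @export
active_loci <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  table$panel$name[!table$panel$excluded]
}

#' Exclude loci from all downstream analysis
#'
#' Returns a copy of the table in which the named loci are flagged excluded.
#' The calls remain in the table (and are serialized), but every counting
#' operation -- maternal comparisons, candidate scoring, allele frequencies,
#' inbreeding coefficients -- ignores them. Idempotent and order-insensitive.
#'
#' @param table a [genotype_table()].
#' @param names character vector of locus names to exclude (may be empty).
#' @return The modified `genotype_table`. Excluding every locus is an error:
#'   at least one active locus is required downstream.
#' @export
apply_locus_exclusions <- function(table, names) {
  stopifnot(inherits(table, "genotype_table"))
  names <- as.character(names)
  unknown <- setdiff(names, table$panel$name)
  if (length(unknown))
    stop("unknown locus name: ", paste(unknown, collapse = ", "))
  table$panel$excluded <- table$panel$excluded | table$panel$name %in% names
  if (all(table$panel$excluded))
    stop("cannot exclude all loci: no active loci would remain")
  table
}

#' Subset a genotype table by individual
#'
#' @param table a [genotype_table()].
#' @param ids character vector of individual ids to keep, in the given order.
#' @return A `genotype_table` restricted to `ids`.
#' @export
subset_individuals <- function(table, ids) {
  stopifnot(inherits(table, "genotype_table"))
  ids <- as.character(ids)
  missing <- setdiff(ids, table$meta$individual_id)
  if (length(missing))
    stop("unknown individual id: ", paste(missing, collapse = ", "))
  idx <- match(ids, table$meta$individual_id)
  table$meta <- table$meta[idx, , drop = FALSE]
  rownames(table$meta) <- NULL
  table$a1 <- table$a1[idx, , drop = FALSE]
  table$a2 <- table$a2[idx, , drop = FALSE]
  table
}

# Internal: the unordered allele pair of one individual at active loci.
# Returns list(a1=named int, a2=named int) over `loci`.
.calls_of <- function(table, id, loci) {
  i <- match(id, table$meta$individual_id)
  if (is.na(i)) stop("unknown individual id: ", id)
  list(a1 = stats::setNames(table$a1[i, loci], loci),
       a2 = stats::setNames(table$a2[i, loci], loci))
}

#' Summarize missing-call rates
#'
#' @param table a [genotype_table()].
#' @return A list with `per_individual` (named rate vector), `per_locus`
#'   (named rate vector over all panel loci, excluded included) and `overall`
#'   (grand missing fraction). All rates are in `[0, 1]`.
#' @export
summarize_missingness <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  miss <- is.na(table$a1)
  list(per_individual = rowMeans(miss),
       per_locus = colMeans(miss),
       overall = mean(miss))
}
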