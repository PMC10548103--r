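#' Read a multilocus genotype table
#'
#' Two dialects are supported. `"tabular"` is the package's native flat file:
#' a comma-separated file with header
#' `id,generation,mother_id,<locus>_a,<locus>_b,...` where an empty field is
#' a missing allele (both alleles of a locus must be missing together).
#' `"genepop"` is the community-standard microsatellite exchange format:
#' a title line, one locus name per line, `Pop`, then
#' `id , 102104 000000` sample lines with 2- or 3-digit concatenated allele
#' codes and `00`/`000` (per allele) meaning missing.
#'
#' A YAML sidecar at `<path>.panel.yml`, written by [write_genotype_table()],
#' carries the locus-exclusion flags (and, for GenePop, the pedigree metadata
#' the format itself cannot hold). If absent, all loci are active and
#' metadata are `NA`.
#'
#' @param path file to read.
#' @param dialect `"tabular"` (default) or `"genepop"`.
#' @return A validated [genotype_table()] with canonically sorted allele
#'   pairs and uniform missing encoding.
#' @export
read_genotype_table <- function(path, dialect = c("tabular", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- .read_panel_sidecar(paste0(path, ".panel.yml"))
  switch(dialect,
         tabular = .read_tabular(path, sidecar),
         genepop = .read_genepop(path, sidecar))
}

#' Write a multilocus genotype table
#'
#' Serialization is lossless for both dialects:
#' `read_genotype_table(path, dialect)` after
#' `write_genotype_table(table, path, dialect)` reproduces the table exactly
#' (individual order, calls, missingness, panel flags). Excluded loci are
#' written with their calls; their flags live in the `<path>.panel.yml`
#' sidecar, which is always written. For GenePop, generation and mother ids
#' also go to the sidecar since the format has no field for them.
#'
#' @param table a [genotype_table()].
#' @param path output file.
#' @param dialect `"tabular"` or `"genepop"`. GenePop requires allele codes
#'   below 1000 (3-digit encoding).
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(table, path, dialect = c("tabular", "genepop")) {
  stopifnot(inherits(table, "genotype_table"))
  dialect <- match.arg(dialect)
  switch(dialect,
         tabular = .write_tabular(table, path),
         genepop = .write_genepop(table, path))
  .write_panel_sidecar(table, paste0(path, ".panel.yml"),
                       with_pedigree = dialect == "genepop")
  invisible(path)
}

.read_panel_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  yaml::read_yaml(path)
}

.write_panel_sidecar <- function(table, path, with_pedigree = FALSE) {
  out <- list(loci = lapply(seq_len(nrow(table$panel)), function(i) {
    list(name = table$panel$name[i],
         excluded = table$panel$excluded[i],
         note = table$panel$note[i])
  }))
  if (with_pedigree) {
    m <- table$meta
    out$individuals <- lapply(seq_len(nrow(m)), function(i) {
      list(id = m$individual_id[i],
           generation = if (is.na(m$generation[i])) NULL else m$generation[i],
           mother_id = if (is.na(m$mother_id[i])) NULL else m$mother_id[i])
    })
  }
  yaml::write_yaml(out, path)
}

.panel_from_sidecar <- function(sidecar, locus_names) {
  if (is.null(sidecar)) return(locus_panel(locus_names))
  sloci <- vapply(sidecar$loci, `[[`, "", "name")
  if (!setequal(sloci, locus_names))
    stop("panel sidecar loci do not match file loci")
  ord <- match(locus_names, sloci)
  locus_panel(locus_names,
              excluded = vapply(sidecar$loci, function(l) isTRUE(l$excluded), TRUE)[ord],
              note = vapply(sidecar$loci, function(l) {
                if (is.null(l$note)) "" else as.character(l$note)
              }, "")[ord])
}

.read_tabular <- function(path, sidecar) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  fixed <- c("id", "generation", "mother_id")
  if (length(header) < 3L || !identical(header[1:3], fixed))
    stop("tabular header must start with 'id,generation,mother_id' in ", path)
  locus_cols <- header[-(1:3)]
  if (length(locus_cols) %% 2L != 0L)
    stop("locus columns must come in <locus>_a,<locus>_b pairs in ", path)
  a_cols <- locus_cols[c(TRUE, FALSE)]
  b_cols <- locus_cols[c(FALSE, TRUE)]
  if (!all(grepl("_a$", a_cols)) || !all(grepl("_b$", b_cols)) ||
      !identical(sub("_a$", "", a_cols), sub("_b$", "", b_cols)))
    stop("unknown locus column layout in ", path,
         ": expected <locus>_a,<locus>_b pairs, got ",
         paste(locus_cols, collapse = ","))
  loci <- sub("_a$", "", a_cols)
  n <- length(lines) - 1L
  ids <- character(n); gen <- character(n); mom <- character(n)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
    length(f) <- length(header)           # pad trailing empties
    f[is.na(f)] <- ""
    if (f[1L] == "")
      stop("malformed row at line ", i + 1L, " of ", path, ": empty 'id' field")
    ids[i] <- f[1L]
    gen[i] <- if (f[2L] == "") NA_character_ else f[2L]
    mom[i] <- if (f[3L] == "") NA_character_ else f[3L]
    for (j in seq_along(loci)) {
      va <- f[3L + 2L * j - 1L]; vb <- f[3L + 2L * j]
      if (va == "" && vb == "") next
      ai <- suppressWarnings(as.integer(va)); bi <- suppressWarnings(as.integer(vb))
      if (is.na(ai) || is.na(bi))
        stop("malformed row at line ", i + 1L, " of ", path,
             ": field '", loci[j], "' has a half-call or non-integer allele ('",
             va, "','", vb, "')")
      a1[i, j] <- ai; a2[i, j] <- bi
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genotype_table(ids, gen, mom, a1, a2, .panel_from_sidecar(sidecar, loci))
}

.write_tabular <- function(table, path) {
  loci <- table$panel$name
  header <- c("id", "generation", "mother_id",
              as.vector(rbind(paste0(loci, "_a"), paste0(loci, "_b"))))
  m <- table$meta
  rows <- vapply(seq_len(nrow(m)), function(i) {
    calls <- as.vector(rbind(table$a1[i, ], table$a2[i, ]))
    calls <- ifelse(is.na(calls), "", as.character(calls))
    paste(c(m$individual_id[i],
            ifelse(is.na(m$generation[i]), "", m$generation[i]),
            ifelse(is.na(m$mother_id[i]), "", m$mother_id[i]),
            calls), collapse = ",")
  }, "")
  writeLines(c(paste(header, collapse = ","), rows), path)
}

.read_genepop <- function(path, sidecar) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GenePop file (too short): ", path)
  pop_at <- which(toupper(trimws(lines)) == "POP")[1L]
  if (is.na(pop_at) || pop_at < 3L)
    stop("malformed GenePop file (no Pop line after loci): ", path)
  # locus names: one per line, or a single comma-separated line
  locus_lines <- trimws(lines[2:(pop_at - 1L)])
  loci <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  sample_lines <- lines[-(1:pop_at)]
  sample_lines <- sample_lines[nzchar(trimws(sample_lines))]
  n <- length(sample_lines)
  ids <- character(n)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  for (i in seq_len(n)) {
    parts <- strsplit(sample_lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed GenePop sample line ", pop_at + i, " of ", path,
           ": missing comma separator")
    ids[i] <- trimws(parts[1L])
    toks <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "[ \t]+")[[1L]]
    if (length(toks) != length(loci))
      stop("malformed GenePop sample line ", pop_at + i, " of ", path,
           ": ", length(toks), " genotypes for ", length(loci), " loci")
    for (j in seq_along(toks)) {
      tok <- toks[j]
      w <- nchar(tok)
      if (!w %in% c(4L, 6L) || grepl("\\D", tok))
        stop("malformed GenePop genotype '", tok, "' at line ", pop_at + i,
             " of ", path, " (field '", loci[j], "')")
      half <- w / 2L
      ai <- as.integer(substr(tok, 1L, half))
      bi <- as.integer(substr(tok, half + 1L, w))
      if (ai == 0L && bi == 0L) next
      if (ai == 0L || bi == 0L)
        stop("half-called GenePop genotype '", tok, "' at line ", pop_at + i,
             " of ", path, " (field '", loci[j], "')")
      a1[i, j] <- ai; a2[i, j] <- bi
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gen <- rep(NA_character_, n); mom <- rep(NA_character_, n)
  if (!is.null(sidecar$individuals)) {
    sid <- vapply(sidecar$individuals, `[[`, "", "id")
    ord <- match(ids, sid)
    pull <- function(field) vapply(seq_len(n), function(i) {
      if (is.na(ord[i])) return(NA_character_)
      v <- sidecar$individuals[[ord[i]]][[field]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, "")
    gen <- pull("generation"); mom <- pull("mother_id")
  }
  genotype_table(ids, gen, mom, a1, a2, .panel_from_sidecar(sidecar, loci))
}

.write_genepop <- function(table, path) {
  if (any(table$a1 >= 1000L, na.rm = TRUE) || any(table$a2 >= 1000L, na.rm = TRUE))
    stop("GenePop dialect requires allele codes < 1000")
  loci <- table$panel$name
  rows <- vapply(seq_len(nrow(table$meta)), function(i) {
    g <- ifelse(is.na(table$a1[i, ]), "000000",
                sprintf("%03d%03d", table$a1[i, ], table$a2[i, ]))
    paste0(table$meta$individual_id[i], " ,  ", paste(g, collapse = " "))
  }, "")
  writeLines(c("selfarray genotype export", loci, "Pop", rows), path)
}

#' Read experiment metadata records
#'
#' Reads the per-individual mating-trial metadata that accompanies a genotype
#' table: pairing treatment, partner ids, copulation counts in each sexual
#' role, eggs and developed embryos laid in isolation and post-isolation,
#' juvenile counts and (optionally) body size.
#'
#' @param path a comma-separated file with header
#'   `individual_id,treatment,partner_ids,n_male_copulation_partners,n_female_copulation_partners,eggs_isolation,developed_embryos_isolation,eggs_post,developed_embryos_post,n_juveniles_reared,n_juveniles_dead,body_size`.
#'   `partner_ids` is a `;`-separated list; `body_size` may be empty.
#' @return A data frame of validated records (one row per individual;
#'   `partner_ids` is a list column).
#' @export
read_experiment_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(individual_id = "character",
                                       treatment = "character",
                                       partner_ids = "character"))
  validate_experiment_records(within(df, {
    partner_ids <- lapply(strsplit(partner_ids, ";", fixed = TRUE),
                          function(p) p[nzchar(p)])
  }))
}

#' Write experiment metadata records
#'
#' @param records a validated record data frame (see
#'   [read_experiment_records()] for the column contract).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_experiment_records <- function(records, path) {
  records <- validate_experiment_records(records)
  df <- records
  df$partner_ids <- vapply(records$partner_ids, paste, "", collapse = ";")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate experiment metadata records
#'
#' Enforces the record invariants: a known treatment level, exactly one
#' partner for once-paired individuals, non-negative counts, developed
#' embryos bounded by eggs within each phase, and dead juveniles bounded by
#' reared juveniles.
#'
#' @param records a data frame with the columns listed in
#'   [read_experiment_records()] (`partner_ids` as a list column).
#' @return The records, invisibly validated (returned unchanged).
#' @export
validate_experiment_records <- function(records) {
  need <- c("individual_id", "treatment", "partner_ids",
            "n_male_copulation_partners", "n_female_copulation_partners",
            "eggs_isolation", "developed_embryos_isolation",
            "eggs_post", "developed_embryos_post",
            "n_juveniles_reared", "n_juveniles_dead")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$individual_id))
    stop("duplicate individual_id in experiment records")
  bad <- !records$treatment %in% c("once_paired", "repeatedly_paired")
  if (any(bad))
    stop("unknown treatment for: ",
         paste(records$individual_id[bad], collapse = ", "))
  np <- lengths(records$partner_ids)
  bad <- records$treatment == "once_paired" & np != 1L
  if (any(bad))
    stop("once_paired individuals must have exactly one partner: ",
         paste(records$individual_id[bad], collapse = ", "))
  counts <- c("n_male_copulation_partners", "n_female_copulation_partners",
              "eggs_isolation", "developed_embryos_isolation",
              "eggs_post", "developed_embryos_post",
              "n_juveniles_reared", "n_juveniles_dead")
  for (cc in counts)
    if (any(records[[cc]] < 0, na.rm = TRUE))
      stop("negative count in column ", cc)
  if (any(records$developed_embryos_isolation > records$eggs_isolation))
    stop("developed embryos exceed eggs in isolation phase")
  if (any(records$developed_embryos_post > records$eggs_post))
    stop("developed embryos exceed eggs in post-isolation phase")
  if (any(records$n_juveniles_dead > records$n_juveniles_reared))
    stop("dead juveniles exceed reared juveniles")
  records
}
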