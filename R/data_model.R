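#' Construct a haploid multilocus genotype dataset
#'
#' The central container of the package: one row per haploid isolate, one
#' allele call per locus per isolate, for up to two marker systems (an STR
#' panel and an MLST panel whose "alleles" are whole-locus haplotypes).
#' Allele labels are opaque categorical integers; no size or stepwise
#' ordering is ever attached to them. Missing calls are `NA`.
#'
#' @param isolates Data frame with columns `id` (unique), `population`,
#'   and optionally `mating_type` (values `"mat1-1"`, `"mat1-2"`, or `NA`
#'   for unknown).
#' @param str Integer matrix of STR allele calls (isolates x loci), or
#'   `NULL` if the dataset carries no STR panel. Row order must follow
#'   `isolates`.
#' @param mlst Integer matrix of MLST haplotype-allele calls, or `NULL`.
#' @param populations Optional data frame of population metadata with
#'   columns `abbrev`, and optionally `name`, `region`, `lat`, `lon`.
#'   Populations absent from it are filled in with their own name as
#'   region.
#' @param loci Optional data frame with columns `id`, `system`
#'   (`"STR"`/`"MLST"`) and optionally `repeat_unit`. Derived from the
#'   matrices when omitted.
#' @return An object of class `mlg_dataset`.
#' @export
#' @examples
#' iso <- data.frame(id = c("a", "b", "c"), population = c("P1", "P1", "P2"))
#' m <- matrix(c(1L, 1L, 2L, 1L, 2L, 2L), ncol = 2,
#'             dimnames = list(iso$id, c("L1", "L2")))
#' d <- mlg_dataset(iso, str = m)
#' d
mlg_dataset <- function(isolates, str = NULL, mlst = NULL,
                        populations = NULL, loci = NULL) {
  isolates <- as.data.frame(isolates, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "population") %in% names(isolates)))
  isolates$id <- as.character(isolates$id)
  isolates$population <- as.character(isolates$population)
  if (is.null(isolates$mating_type)) isolates$mating_type <- NA_character_
  if (anyDuplicated(isolates$id)) {
    stop("duplicated isolate id(s): ",
         paste(unique(isolates$id[duplicated(isolates$id)]), collapse = ", "))
  }
  bad_mt <- !is.na(isolates$mating_type) &
    !isolates$mating_type %in% c("mat1-1", "mat1-2")
  if (any(bad_mt)) {
    warning("unknown mating-type token(s) parsed as unknown: ",
            paste(unique(isolates$mating_type[bad_mt]), collapse = ", "))
    isolates$mating_type[bad_mt] <- NA_character_
  }

  fix_mat <- function(m, sys) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (nrow(m) != nrow(isolates)) {
      stop(sys, " matrix has ", nrow(m), " rows but there are ",
           nrow(isolates), " isolates")
    }
    if (is.null(colnames(m))) {
      colnames(m) <- paste0(if (sys == "STR") "S" else "M", seq_len(ncol(m)))
    }
    rownames(m) <- isolates$id
    if (any(m < 0, na.rm = TRUE)) stop(sys, " allele labels must be >= 0")
    m
  }
  str <- fix_mat(str, "STR")
  mlst <- fix_mat(mlst, "MLST")
  if (is.null(str) && is.null(mlst)) stop("at least one marker system required")

  if (is.null(loci)) {
    loci <- rbind(
      if (!is.null(str))
        data.frame(id = colnames(str), system = "STR",
                   repeat_unit = NA_character_),
      if (!is.null(mlst))
        data.frame(id = colnames(mlst), system = "MLST",
                   repeat_unit = NA_character_)
    )
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(loci$repeat_unit)) loci$repeat_unit <- NA_character_
  if (anyDuplicated(loci$id)) stop("duplicated locus id(s)")

  pops_seen <- unique(isolates$population)
  if (is.null(populations)) {
    populations <- data.frame(abbrev = pops_seen)
  }
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  stopifnot("abbrev" %in% names(populations))
  for (col in c("name", "region")) {
    if (is.null(populations[[col]])) populations[[col]] <- populations$abbrev
  }
  for (col in c("lat", "lon")) {
    if (is.null(populations[[col]])) populations[[col]] <- NA_real_
  }
  missing_pop <- setdiff(pops_seen, populations$abbrev)
  if (length(missing_pop)) {
    populations <- rbind(
      populations[, c("abbrev", "name", "region", "lat", "lon")],
      data.frame(abbrev = missing_pop, name = missing_pop,
                 region = missing_pop, lat = NA_real_, lon = NA_real_))
  }
  ok_lat <- is.na(populations$lat) | abs(populations$lat) <= 90
  ok_lon <- is.na(populations$lon) | abs(populations$lon) <= 180
  if (!all(ok_lat & ok_lon)) stop("coordinates out of range")
  populations$n_isolates <-
    as.integer(table(factor(isolates$population,
                            levels = populations$abbrev)))

  structure(list(isolates = isolates, str = str, mlst = mlst,
                 loci = loci, populations = populations),
            class = "mlg_dataset")
}

#' @export
print.mlg_dataset <- function(x, ...) {
  cat("<mlg_dataset> ", nrow(x$isolates), " isolates, ",
      nrow(x$populations), " populations\n", sep = "")
  if (!is.null(x$str)) cat("  STR loci:  ", ncol(x$str), "\n", sep = "")
  if (!is.null(x$mlst)) cat("  MLST loci: ", ncol(x$mlst), "\n", sep = "")
  mt <- table(x$isolates$mating_type, useNA = "no")
  if (length(mt)) {
    cat("  mating types: ",
        paste(names(mt), mt, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of isolates in a dataset
#' @param dataset An `mlg_dataset`.
#' @return Integer count.
#' @export
n_isolates <- function(dataset) nrow(dataset$isolates)

## allele-call matrix for a marker system ("STR", "MLST", "COMBINED")
system_matrix <- function(dataset, system = c("STR", "MLST", "COMBINED")) {
  system <- match.arg(toupper(system), c("STR", "MLST", "COMBINED"))
  m <- switch(system,
    STR = dataset$str,
    MLST = dataset$mlst,
    COMBINED = {
      if (is.null(dataset$str) || is.null(dataset$mlst)) {
        cbind(dataset$str, dataset$mlst)
      } else {
        cbind(dataset$str, dataset$mlst)
      }
    })
  if (is.null(m) || ncol(m) == 0L) {
    stop("dataset has no loci for system ", system)
  }
  m
}

#' Subset a dataset by isolate ids
#'
#' @param dataset An `mlg_dataset`.
#' @param ids Character vector of isolate ids (order preserved), or a
#'   logical/integer index into the isolate rows.
#' @return An `mlg_dataset` with the selected isolates; population metadata
#'   is retained (with refreshed sizes) for populations still present.
#' @export
subset_isolates <- function(dataset, ids) {
  if (is.logical(ids) || is.numeric(ids)) {
    ids <- dataset$isolates$id[ids]
  }
  keep <- match(ids, dataset$isolates$id)
  if (anyNA(keep)) stop("unknown isolate id(s)")
  iso <- dataset$isolates[keep, , drop = FALSE]
  rownames(iso) <- NULL
  pops <- dataset$populations[
    dataset$populations$abbrev %in% unique(iso$population), , drop = FALSE]
  mlg_dataset(iso,
              str = if (!is.null(dataset$str))
                dataset$str[keep, , drop = FALSE],
              mlst = if (!is.null(dataset$mlst))
                dataset$mlst[keep, , drop = FALSE],
              populations = pops, loci = dataset$loci)
}

#' Read a delimited genotype table
#'
#' Expects a header line and one row per isolate. Mandatory columns `id`
#' and `population`; optional `mating_type`; every remaining column named
#' in `str_loci`/`mlst_loci` is an allele-call column. A malformed row
#' (wrong number of fields) is a hard error naming the offending isolate.
#'
#' @param path Path to a TSV/CSV file.
#' @param str_loci,mlst_loci Character vectors naming the allele columns of
#'   each marker system. By default every non-metadata column is treated as
#'   an STR locus.
#' @param sep Field separator (default tab).
#' @param missing_token Token(s) encoding a missing call (default `"NA"`).
#' @param zero_as_missing If `TRUE`, allele label 0 is also read as missing.
#' @param populations_file Optional TSV of population metadata
#'   (`abbrev`, `name`, `region`, `lat`, `lon`).
#' @return An `mlg_dataset`.
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, str_loci = NULL, mlst_loci = NULL,
                                sep = "\t", missing_token = "NA",
                                zero_as_missing = FALSE,
                                populations_file = NULL) {
  cf <- utils::count.fields(path, sep = sep, quote = "\"",
                            comment.char = "")
  if (length(unique(cf)) > 1L) {
    lines <- readLines(path)
    bad <- which(cf != cf[1])[1]
    first_field <- sub(paste0(sep, ".*$"), "", lines[bad])
    stop("row ", bad - 1L, " (isolate '", first_field, "') has ", cf[bad],
         " fields, expected ", cf[1])
  }
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), comment.char = "",
                           quote = "\"")
  stopifnot(all(c("id", "population") %in% names(tab)))
  meta_cols <- intersect(c("id", "population", "region", "mating_type"),
                         names(tab))
  allele_cols <- setdiff(names(tab), meta_cols)
  if (is.null(str_loci) && is.null(mlst_loci)) str_loci <- allele_cols
  str_loci <- str_loci %||% character(0)
  mlst_loci <- mlst_loci %||% character(0)
  missing_cols <- setdiff(c(str_loci, mlst_loci), names(tab))
  if (length(missing_cols)) {
    stop("locus column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  }

  parse_calls <- function(cols) {
    if (!length(cols)) return(NULL)
    m <- as.matrix(tab[, cols, drop = FALSE])
    m[m %in% missing_token] <- NA
    mm <- suppressWarnings(matrix(as.integer(m), nrow = nrow(m),
                                  dimnames = list(tab$id, cols)))
    if (any(is.na(mm) & !is.na(m))) {
      stop("non-integer allele label(s) in column(s): ",
           paste(cols[colSums(is.na(mm) & !is.na(m)) > 0], collapse = ", "))
    }
    if (zero_as_missing) mm[mm == 0L] <- NA_integer_
    mm
  }
  str <- parse_calls(str_loci)
  mlst <- parse_calls(mlst_loci)

  populations <- NULL
  if (!is.null(populations_file)) {
    populations <- utils::read.table(populations_file, sep = "\t",
                                     header = TRUE,
                                     stringsAsFactors = FALSE)
  } else if ("region" %in% names(tab)) {
    populations <- unique(data.frame(abbrev = tab$population,
                                     region = tab$region))
  }
  iso <- data.frame(id = tab$id, population = tab$population,
                    mating_type = if ("mating_type" %in% names(tab))
                      tab$mating_type else NA_character_)
  mlg_dataset(iso, str = str, mlst = mlst, populations = populations)
}

#' Write a dataset back to a delimited genotype table
#'
#' Inverse of [read_genotype_table()]: allele calls round-trip exactly.
#'
#' @param dataset An `mlg_dataset`.
#' @param path Output path.
#' @param sep Field separator.
#' @param missing_token Token used for missing calls.
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(dataset, path, sep = "\t",
                                 missing_token = "NA") {
  out <- data.frame(id = dataset$isolates$id,
                    population = dataset$isolates$population,
                    mating_type = dataset$isolates$mating_type,
                    stringsAsFactors = FALSE)
  for (m in list(dataset$str, dataset$mlst)) {
    if (!is.null(m)) for (cn in colnames(m)) out[[cn]] <- m[, cn]
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}

#' Assign multilocus genotype identifiers
#'
#' Two isolates share a genotype id iff their allele profiles over the
#' chosen marker system are identical at every locus. Ids are consecutive
#' integers in order of first appearance in isolate input order. Isolates
#' with a missing call at any locus of the system are, by default, excluded
#' from genotype-identity grouping (their assignment is `NA`); with
#' `missing_policy = "match_any"` a missing call matches anything and
#' isolates are greedily attached to the first compatible genotype.
#'
#' @param dataset An `mlg_dataset`.
#' @param system `"STR"`, `"MLST"`, or `"COMBINED"`.
#' @param missing_policy `"exclude"` (default) or `"match_any"`.
#' @return An object of class `genotype_table`: list with `system`,
#'   `assignments` (named integer vector, `NA` for excluded isolates),
#'   `members` (list of isolate-id vectors per genotype), `n_genotypes`,
#'   and `excluded` (ids of excluded isolates).
#' @export
#' @examples
#' d <- fixture_from_table3()
#' gt <- assign_genotypes(d, "MLST")
#' gt$n_genotypes
assign_genotypes <- function(dataset, system = c("STR", "MLST", "COMBINED"),
                             missing_policy = c("exclude", "match_any")) {
  system <- match.arg(toupper(system[1]), c("STR", "MLST", "COMBINED"))
  missing_policy <- match.arg(missing_policy)
  m <- system_matrix(dataset, system)
  ids <- dataset$isolates$id
  n <- nrow(m)
  assignments <- rep(NA_integer_, n)
  names(assignments) <- ids

  has_na <- rowSums(is.na(m)) > 0L
  if (missing_policy == "exclude") {
    keys <- rep(NA_character_, n)
    keys[!has_na] <- apply(m[!has_na, , drop = FALSE], 1L, paste,
                           collapse = "\r")
    first <- !duplicated(keys) & !is.na(keys)
    gid_of_key <- stats::setNames(seq_len(sum(first)), keys[first])
    assignments[!has_na] <- gid_of_key[keys[!has_na]]
  } else {
    reps <- list() # genotype id -> representative profile (may hold NAs)
    for (i in seq_len(n)) {
      found <- NA_integer_
      for (g in seq_along(reps)) {
        r <- reps[[g]]
        cmp <- r == m[i, ]
        if (all(cmp | is.na(r) | is.na(m[i, ]))) { found <- g; break }
      }
      if (is.na(found)) {
        reps[[length(reps) + 1L]] <- m[i, ]
        found <- length(reps)
      } else {
        # refine representative where it was missing
        fill <- is.na(reps[[found]]) & !is.na(m[i, ])
        reps[[found]][fill] <- m[i, fill]
      }
      assignments[i] <- found
    }
  }
  members <- split(ids[!is.na(assignments)],
                   assignments[!is.na(assignments)])
  members <- members[order(as.integer(names(members)))]
  structure(list(system = system,
                 assignments = assignments,
                 members = members,
                 n_genotypes = length(members),
                 excluded = ids[is.na(assignments)]),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> system=", x$system, ": ", x$n_genotypes,
      " genotypes over ", length(x$assignments), " isolates", sep = "")
  if (length(x$excluded)) cat(" (", length(x$excluded), " excluded)",
                              sep = "")
  cat("\n")
  invisible(x)
}

#' Clone-correct a dataset
#'
#' Collapses clonal copies of a multilocus genotype to a single retained
#' isolate. The default scope retains the first-encountered isolate of each
#' genotype within each population, so a genotype present in k populations
#' contributes k retained isolates; `"global"` keeps one isolate per
#' genotype overall. Selection is deterministic (input order). Isolates
#' without a genotype assignment (missing data excluded from grouping) are
#' retained unchanged, with a warning.
#'
#' @param dataset An `mlg_dataset`.
#' @param table A `genotype_table` built on `dataset`.
#' @param scope `"within_population"` (default) or `"global"`.
#' @return A clone-corrected `mlg_dataset`.
#' @export
#' @examples
#' d <- fixture_from_table3()
#' gt <- assign_genotypes(d, "MLST")
#' n_isolates(clonal_correct(d, gt)) # 100
clonal_correct <- function(dataset, table,
                           scope = c("within_population", "global")) {
  scope <- match.arg(scope)
  ids <- dataset$isolates$id
  if (!identical(names(table$assignments), ids)) {
    stop("genotype table was not built on this dataset")
  }
  g <- table$assignments
  if (anyNA(g)) {
    warning(sum(is.na(g)),
            " isolate(s) without genotype assignment retained as-is")
  }
  key <- if (scope == "within_population") {
    paste(dataset$isolates$population, g)
  } else {
    as.character(g)
  }
  keep <- is.na(g) | !duplicated(key)
  subset_isolates(dataset, ids[keep])
}

#' Summarise a dataset as JSON
#'
#' @param dataset An `mlg_dataset`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
dataset_summary_json <- function(dataset, path = NULL) {
  count_alleles <- function(m) {
    if (is.null(m)) return(NULL)
    vapply(seq_len(ncol(m)),
           function(j) length(unique(m[!is.na(m[, j]), j])), integer(1))
  }
  s <- list(
    n_isolates = nrow(dataset$isolates),
    n_populations = nrow(dataset$populations),
    populations = dataset$populations,
    str_loci = if (!is.null(dataset$str))
      data.frame(id = colnames(dataset$str),
                 n_alleles = count_alleles(dataset$str)),
    mlst_loci = if (!is.null(dataset$mlst))
      data.frame(id = colnames(dataset$mlst),
                 n_alleles = count_alleles(dataset$mlst)),
    mating_types = as.list(table(dataset$isolates$mating_type)))
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
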