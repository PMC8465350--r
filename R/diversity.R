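#' Allele frequency spectrum at one locus
#'
#' Frequencies are computed over non-missing calls only, either in the
#' whole sample (`scope = "TOTAL"`) or within one population.
#'
#' @param dataset An `mlg_dataset`.
#' @param locus Locus id (a column of one of the marker matrices).
#' @param scope `"TOTAL"` or a population abbreviation.
#' @return List of class `allele_spectrum`: `locus`, `scope`, `freqs`
#'   (named numeric summing to 1), `n_obs`.
#' @export
allele_frequencies <- function(dataset, locus, scope = "TOTAL") {
  m <- cbind(dataset$str, dataset$mlst)
  if (!locus %in% colnames(m)) stop("unknown locus: ", locus)
  calls <- m[, locus]
  if (scope != "TOTAL") {
    if (!scope %in% dataset$populations$abbrev) {
      stop("unknown population: ", scope)
    }
    calls <- calls[dataset$isolates$population == scope]
  }
  calls <- calls[!is.na(calls)]
  if (!length(calls)) {
    stop("no non-missing calls at locus ", locus, " in scope ", scope)
  }
  tab <- table(calls)
  freqs <- sort(stats::setNames(as.numeric(tab) / length(calls),
                                names(tab)),
                decreasing = TRUE)
  structure(list(locus = locus, scope = scope, freqs = freqs,
                 n_obs = length(calls)),
            class = "allele_spectrum")
}

## accept either an allele_spectrum or a bare frequency vector
as_freqs <- function(x) {
  if (inherits(x, "allele_spectrum")) x$freqs else as.numeric(x)
}

#' Nei's gene diversity
#'
#' `1 - sum(p^2)`: the probability that two allele copies drawn at random
#' differ. The unbiased small-sample variant multiplies by `n/(n-1)`
#' (requires an `allele_spectrum` carrying `n_obs`).
#'
#' @param freqs An `allele_spectrum` or numeric frequency vector.
#' @param unbiased Apply the `n/(n-1)` correction (default `FALSE`).
#' @return Numeric in `[0, 1)`.
#' @export
#' @examples
#' gene_diversity(c(0.5, 0.5)) # 0.5
gene_diversity <- function(freqs, unbiased = FALSE) {
  p <- as_freqs(freqs)
  h <- 1 - sum(p^2)
  if (unbiased) {
    if (!inherits(freqs, "allele_spectrum")) {
      stop("unbiased form needs an allele_spectrum (sample size)")
    }
    n <- freqs$n_obs
    h <- h * n / (n - 1)
  }
  h
}

#' Polymorphism information content (PIC)
#'
#' Botstein's marker-informativeness measure,
#' `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, with the conventional
#' low (< 0.25) / medium / high (> 0.5) classification.
#'
#' @param freqs An `allele_spectrum` or numeric frequency vector.
#' @return List with `pic` (numeric, always <= gene diversity) and `level`
#'   (`"low"`, `"medium"`, `"high"`).
#' @export
#' @examples
#' pic(c(0.5, 0.5)) # pic 0.375, level "medium"
pic <- function(freqs) {
  p <- as_freqs(freqs)
  sq <- p^2
  cross <- (sum(sq)^2 - sum(sq^2)) / 2 # sum over i<j of p_i^2 p_j^2
  value <- 1 - sum(sq) - 2 * cross
  level <- if (value < 0.25) "low" else if (value > 0.5) "high" else "medium"
  list(pic = value, level = level)
}

#' Call rate of a locus
#'
#' Fraction of isolates with a non-missing call.
#'
#' @param dataset An `mlg_dataset`.
#' @param locus Locus id.
#' @return Numeric in `[0, 1]` (0 with a warning when no isolate is called).
#' @export
availability <- function(dataset, locus) {
  m <- cbind(dataset$str, dataset$mlst)
  if (!locus %in% colnames(m)) stop("unknown locus: ", locus)
  a <- mean(!is.na(m[, locus]))
  if (a == 0) warning("locus ", locus, " has no non-missing calls")
  a
}

#' Per-locus diversity summary table
#'
#' One row per locus of the chosen system: observed allele count, PIC and
#' its class, gene diversity, major-allele frequency, and availability
#' (call rate). Frequencies are taken over the total sample.
#'
#' @param dataset An `mlg_dataset`.
#' @param system `"STR"` or `"MLST"`.
#' @return Data frame, one row per locus.
#' @export
locus_diversity_summary <- function(dataset, system = "STR") {
  m <- system_matrix(dataset, system)
  rows <- lapply(colnames(m), function(L) {
    sp <- allele_frequencies(dataset, L)
    pv <- pic(sp)
    data.frame(locus = L,
               n_alleles = length(sp$freqs),
               pic = pv$pic, pic_level = pv$level,
               major_allele_freq = max(sp$freqs),
               availability = availability(dataset, L),
               gene_diversity = gene_diversity(sp))
  })
  do.call(rbind, rows)
}

#' Per-population allele counts and private alleles
#'
#' An allele is private to a population iff it occurs there and in no
#' other population (presence/absence, no frequency threshold).
#'
#' @param dataset An `mlg_dataset`.
#' @param system `"STR"`, `"MLST"`, or `"COMBINED"`.
#' @return List of class `allele_summary`: `counts` and `private`
#'   (population x locus integer matrices), `pop_totals` (data frame with
#'   per-population totals), `total_alleles`, `total_private`,
#'   `shared_alleles`, `mean_alleles_per_locus`.
#' @export
#' @examples
#' d <- fixture_from_table1()
#' private_alleles(d)$total_private # 48
private_alleles <- function(dataset, system = "STR") {
  m <- system_matrix(dataset, system)
  pops <- dataset$populations$abbrev
  if (length(pops) < 2L) stop("private alleles need >= 2 populations")
  pop_of <- dataset$isolates$population
  counts <- matrix(0L, length(pops), ncol(m),
                   dimnames = list(pops, colnames(m)))
  priv <- counts
  for (L in seq_len(ncol(m))) {
    # populations in which each allele occurs
    occ <- table(pop_of[!is.na(m[, L])], m[!is.na(m[, L]), L])
    occ <- occ[, colSums(occ) > 0, drop = FALSE]
    present <- occ > 0
    n_pops_with <- colSums(present)
    counts[rownames(occ), L] <- as.integer(rowSums(present))
    priv[rownames(occ), L] <-
      as.integer(rowSums(present[, n_pops_with == 1L, drop = FALSE]))
  }
  per_locus_total <- vapply(seq_len(ncol(m)), function(L)
    length(unique(m[!is.na(m[, L]), L])), integer(1))
  pop_totals <- data.frame(population = pops,
                           n_alleles = as.integer(rowSums(counts)),
                           n_private = as.integer(rowSums(priv)))
  structure(list(counts = counts, private = priv, pop_totals = pop_totals,
                 per_locus_total = stats::setNames(per_locus_total,
                                                   colnames(m)),
                 total_alleles = sum(per_locus_total),
                 total_private = as.integer(sum(priv)),
                 shared_alleles = sum(per_locus_total) -
                   as.integer(sum(priv)),
                 mean_alleles_per_locus = mean(per_locus_total)),
            class = "allele_summary")
}

#' Nei's unbiased genotypic diversity
#'
#' `D = n/(n-1) * (1 - sum((n_i/n)^2))` over multilocus-genotype counts:
#' the probability that two isolates drawn without replacement carry
#' different genotypes. Depends on n, not only on genotype proportions
#' (e.g. counts `c(1, 1)` give 1, `c(2, 2)` give 2/3).
#'
#' @param genotype_counts Positive integer vector of genotype member
#'   counts; `sum(genotype_counts)` must be at least 2.
#' @return Numeric in `[0, 1]`.
#' @export
#' @examples
#' genotypic_diversity(c(3, 10)) # 0.385 at 3 d.p.
genotypic_diversity <- function(genotype_counts) {
  stopifnot(all(genotype_counts > 0))
  n <- sum(genotype_counts)
  if (n < 2) stop("genotypic diversity needs n >= 2")
  n / (n - 1) * (1 - sum((genotype_counts / n)^2))
}

#' Per-population genotype distribution and diversity
#'
#' One row per population: sample size, genotype counts, private genotypes
#' (all members in that population), and Nei's unbiased genotypic
#' diversity.
#'
#' @param dataset An `mlg_dataset`.
#' @param table A `genotype_table` built on `dataset`.
#' @return Data frame with columns `population`, `n`, `n_genotypes`,
#'   `genotypes` (label (count) string), `private_genotypes`, `diversity`.
#' @export
genotype_diversity_table <- function(dataset, table) {
  pop_of <- stats::setNames(dataset$isolates$population,
                            dataset$isolates$id)
  pops_per_g <- lapply(table$members, function(ids) unique(pop_of[ids]))
  private_of_g <- vapply(pops_per_g, function(p)
    if (length(p) == 1L) p else NA_character_, character(1))
  rows <- lapply(dataset$populations$abbrev, function(p) {
    ids <- dataset$isolates$id[pop_of == p]
    g <- table$assignments[ids]
    g <- g[!is.na(g)]
    cnt <- table(g)
    gl <- names(cnt)
    div <- if (length(g) >= 2) genotypic_diversity(as.integer(cnt)) else NA
    data.frame(population = p, n = length(ids),
               n_genotypes = length(cnt),
               genotypes = paste0(gl, " (", as.integer(cnt), ")",
                                  collapse = "; "),
               private_genotypes = paste(
                 gl[gl %in% names(private_of_g)[private_of_g == p]],
                 collapse = "; "),
               diversity = div)
  })
  do.call(rbind, rows)
}

#' Ranked genotype-frequency summary
#'
#' Genotypes ranked by member count (ties broken by genotype id), with the
#' share of the total sample, the number of populations of occurrence, and
#' whether the genotype is private to a single population.
#'
#' @param table A `genotype_table`.
#' @param dataset The `mlg_dataset` the table was built on.
#' @return Data frame with columns `rank`, `genotype`, `count`,
#'   `share_pct`, `n_populations`, `private_to` (`NA` when shared).
#' @export
#' @examples
#' d <- fixture_from_table3()
#' head(genotype_frequency_summary(assign_genotypes(d, "MLST"), d), 3)
genotype_frequency_summary <- function(table, dataset) {
  pop_of <- stats::setNames(dataset$isolates$population,
                            dataset$isolates$id)
  n_total <- sum(!is.na(table$assignments))
  gid <- as.integer(names(table$members))
  count <- vapply(table$members, length, integer(1))
  npop <- vapply(table$members,
                 function(ids) length(unique(pop_of[ids])), integer(1))
  priv <- vapply(table$members, function(ids) {
    p <- unique(pop_of[ids])
    if (length(p) == 1L) p else NA_character_
  }, character(1))
  o <- order(-count, gid)
  data.frame(rank = seq_along(o), genotype = gid[o], count = count[o],
             share_pct = 100 * count[o] / n_total,
             n_populations = npop[o], private_to = priv[o],
             row.names = NULL)
}
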