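extdata <- function(file) {
  p <- system.file("extdata", file, package = "mlgpop")
  if (p == "") stop("bundled data file not found: ", file)
  p
}

#' Load bundled population metadata
#'
#' The 19 sampling populations with region grouping, approximate
#' coordinates (synthetic, province-level approximations for
#' isolation-by-distance analyses), and sample sizes.
#'
#' @return Data frame: `abbrev`, `name`, `region`, `lat`, `lon`,
#'   `n_isolates`.
#' @export
population_metadata <- function() {
  utils::read.table(extdata("populations.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' MLST genotype-distribution fixture (239 isolates, 19 populations)
#'
#' Reconstructs, from the bundled genotype-distribution table, a dataset
#' of 239 isolates across 19 populations whose MLST genotype memberships
#' exactly encode the published per-population genotype counts (59
#' distinct genotypes). Per-locus allele labels are synthesized — each
#' genotype id is expanded to a 6-locus profile via its mixed-radix
#' digits — so genotype identities are preserved and distinct, but
#' individual allele calls are not the real sequence haplotypes.
#'
#' @return An `mlg_dataset` with a 6-locus MLST panel. The published
#'   genotype label of each isolate is kept in column `source_genotype`
#'   of `$isolates`.
#' @export
#' @examples
#' d <- fixture_from_table3()
#' n_isolates(d) # 239
fixture_from_table3 <- function() {
  tab <- utils::read.table(extdata("table3_mlst_genotypes.tsv"),
                           sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  pops <- population_metadata()
  n_loci <- 6L
  base <- 4L # 4^6 = 4096 label combinations >> 59 genotypes
  profile_of <- function(g) {
    x <- g - 1L
    d <- integer(n_loci)
    for (k in seq_len(n_loci)) {
      d[k] <- x %% base
      x <- x %/% base
    }
    d + 1L
  }
  rows <- tab[rep(seq_len(nrow(tab)), tab$count), ]
  ids <- sprintf("%s_%03d", rows$population,
                 stats::ave(seq_len(nrow(rows)), rows$population,
                            FUN = seq_along))
  mlst <- t(vapply(rows$genotype, profile_of, integer(n_loci)))
  colnames(mlst) <- c("its", "tub", "tef1", "rpb2", "mapk", "sp")
  iso <- data.frame(id = ids, population = rows$population,
                    mating_type = NA_character_,
                    source_genotype = rows$genotype)
  d <- mlg_dataset(iso[, c("id", "population", "mating_type")],
                   mlst = mlst, populations = pops)
  d$isolates$source_genotype <- iso$source_genotype
  d
}

## distribute S shared alleles so that each occurs in >= 2 populations and
## population p carries exactly cap[p] distinct shared alleles
design_shared <- function(cap, S) {
  P <- length(cap)
  stopifnot(max(cap) <= S, sum(cap) >= 2 * S)
  has <- matrix(FALSE, P, S)
  rem <- cap
  for (a in seq_len(S)) {
    o <- order(-rem)
    pick <- o[1:2]
    if (rem[pick[2]] <= 0) stop("infeasible shared-allele design")
    has[pick, a] <- TRUE
    rem[pick] <- rem[pick] - 1L
  }
  # distribute leftover capacity, balancing allele occupancy
  for (p in seq_len(P)) {
    while (rem[p] > 0L) {
      cand <- which(!has[p, ])
      a <- cand[order(colSums(has)[cand])][1]
      has[p, a] <- TRUE
      rem[p] <- rem[p] - 1L
    }
  }
  stopifnot(all(rowSums(has) == cap), all(colSums(has) >= 2))
  has
}

#' STR allele-count fixture (239 isolates, 20 loci)
#'
#' Builds a dataset realizing exactly the published per-population,
#' per-locus allele counts and private-allele counts for the 20-locus STR
#' panel (188 alleles in total, 48 of them private). Private alleles get
#' population-specific labels; shared alleles are placed by a
#' deterministic greedy design guaranteeing each occurs in at least two
#' populations. Individual isolate profiles are synthetic: calls cycle
#' through each population's designed allele set, so allele-level
#' statistics (counts, private alleles, frequencies up to within-population
#' multiplicity) are faithful but multilocus genotype structure is not.
#'
#' @return An `mlg_dataset` with a 20-locus STR panel.
#' @export
#' @examples
#' d <- fixture_from_table1()
#' private_alleles(d)$total_alleles # 188
fixture_from_table1 <- function() {
  tab <- utils::read.table(extdata("table1_population_allele_counts.tsv"),
                           sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tots <- utils::read.table(extdata("table1_locus_totals.tsv"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  pops <- population_metadata()
  loci <- tots$locus
  P <- nrow(pops)

  # designed allele set per (population, locus)
  sets <- vector("list", P)
  names(sets) <- pops$abbrev
  for (p in pops$abbrev) sets[[p]] <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    L <- loci[li]
    sub <- tab[tab$locus == L, ]
    sub <- sub[match(pops$abbrev, sub$population), ]
    total <- tots$n_alleles_total[li]
    n_priv <- sum(sub$n_private)
    S <- total - n_priv
    cap <- sub$n_alleles - sub$n_private
    has <- design_shared(cap, S)
    next_priv <- S
    for (pi in seq_len(P)) {
      shared_labels <- which(has[pi, ])
      priv_labels <- if (sub$n_private[pi] > 0) {
        lab <- next_priv + seq_len(sub$n_private[pi])
        lab
      } else integer(0)
      next_priv <- next_priv + sub$n_private[pi]
      sets[[pops$abbrev[pi]]][[li]] <- c(shared_labels, priv_labels)
    }
  }

  rows <- list()
  str <- matrix(NA_integer_, sum(pops$n_isolates), length(loci),
                dimnames = list(NULL, loci))
  r <- 0L
  for (pi in seq_len(P)) {
    p <- pops$abbrev[pi]
    np <- pops$n_isolates[pi]
    for (i in seq_len(np)) {
      r <- r + 1L
      for (li in seq_along(loci)) {
        s <- sets[[p]][[li]]
        stopifnot(length(s) <= np)
        str[r, li] <- s[(i - 1L) %% length(s) + 1L]
      }
    }
    rows[[p]] <- data.frame(id = sprintf("%s_%03d", p, seq_len(np)),
                            population = p)
  }
  iso <- do.call(rbind, rows)
  rownames(iso) <- NULL
  mlg_dataset(iso, str = str, populations = pops)
}
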