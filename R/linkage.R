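## resolve a dataset or bare allele matrix argument for the linkage tests
linkage_matrix <- function(x, system) {
  if (inherits(x, "mlg_dataset")) system_matrix(x, system) else as.matrix(x)
}

## per-locus pairwise mismatch indicator vectors over the i<j pairs;
## NA where either call is missing
pair_indicators <- function(m) {
  pr <- pair_index(nrow(m))
  lapply(seq_len(ncol(m)), function(L) {
    v <- m[, L]
    ind <- v[pr[, 1]] != v[pr[, 2]]
    ind # logical with NA where either side missing
  })
}

rbard_core <- function(ind_list) {
  vars <- vapply(ind_list, function(x) pop_var(x[!is.na(x)]), numeric(1))
  v_e <- sum(vars)
  d_tot <- Reduce(`+`, lapply(ind_list, function(x) {
    x[is.na(x)] <- 0
    as.numeric(x)
  }))
  v_o <- pop_var(d_tot)
  cross <- 0
  L <- length(vars)
  for (a in seq_len(L - 1L)) {
    cross <- cross + sum(sqrt(vars[a] * vars[(a + 1L):L]))
  }
  list(v_obs = v_o, v_exp = v_e,
       i_a = v_o / v_e - 1,
       r_bar_d = (v_o - v_e) / (2 * cross))
}

#' Index of association and rBarD
#'
#' Multilocus linkage-disequilibrium test for clonality. For every isolate
#' pair the mismatch distance is the number of loci with different allele
#' labels; `I_A = V_O / V_E - 1` compares the variance of these distances
#' (`V_O`) with its linkage-equilibrium expectation (`V_E`, the sum of
#' per-locus indicator variances), and rBarD standardizes by the number of
#' loci so that perfectly linked loci give exactly 1. Variances use the
#' population convention (divide by the number of pairs). The null
#' distribution independently shuffles each locus column across isolates;
#' `p = (1 + #(rBarD_perm >= rBarD_obs)) / (1 + n_perm)`. Missing calls
#' are handled pairwise-complete per locus pair.
#'
#' @param x An `mlg_dataset` or an allele matrix (isolates x loci).
#' @param system Marker system when `x` is a dataset.
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Optional integer seed.
#' @return Object of class `linkage_result`: `n_isolates`, `n_loci`,
#'   `v_obs`, `v_exp`, `i_a`, `r_bar_d`, `p_value`, `n_permutations`.
#' @export
#' @examples
#' m <- cbind(L1 = c(1, 1, 2, 2), L2 = c(1, 1, 2, 2))
#' index_of_association(m, n_perm = 0)$r_bar_d # 1
index_of_association <- function(x, system = "STR", n_perm = 999,
                                 seed = NULL) {
  m <- linkage_matrix(x, system)
  if (nrow(m) < 3L) stop("need >= 3 isolates")
  if (ncol(m) < 2L) stop("need >= 2 loci")
  ind <- pair_indicators(m)
  obs <- rbard_core(ind)
  if (obs$v_exp == 0) {
    stop("no variance: all loci monomorphic in this subset")
  }
  p_value <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      mp <- apply(m, 2L, sample)
      rbard_core(pair_indicators(mp))$r_bar_d
    }, numeric(1)))
    p_value <- (1 + sum(perm >= obs$r_bar_d)) / (1 + n_perm)
  }
  structure(list(n_isolates = nrow(m), n_loci = ncol(m),
                 v_obs = obs$v_obs, v_exp = obs$v_exp,
                 i_a = obs$i_a, r_bar_d = obs$r_bar_d,
                 p_value = p_value, n_permutations = as.integer(n_perm)),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("<linkage_result> I_A =", signif(x$i_a, 4),
      " rBarD =", signif(x$r_bar_d, 4))
  if (!is.na(x$p_value)) cat(", p =", signif(x$p_value, 3))
  cat("  (", x$n_isolates, " isolates, ", x$n_loci, " loci)\n", sep = "")
  invisible(x)
}

#' Phylogenetic compatibility of a locus pair
#'
#' Multi-allelic generalization of the four-gamete test: build a bipartite
#' graph with one node per observed allele of each locus and one edge per
#' observed allele combination; the pair is compatible iff the graph is
#' acyclic (a homoplasy-free phylogeny can explain both loci).
#' Missing entries are dropped pairwise.
#'
#' @param calls_a,calls_b Equal-length allele-call vectors.
#' @return `TRUE` if compatible.
#' @export
#' @examples
#' locus_pair_compatible(c(1, 1, 2, 2), c(1, 2, 1, 2)) # FALSE (4 gametes)
#' locus_pair_compatible(c(1, 1, 2), c(1, 2, 1))       # TRUE
locus_pair_compatible <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b))
  ok <- !is.na(calls_a) & !is.na(calls_b)
  a <- calls_a[ok]; b <- calls_b[ok]
  if (!length(a)) return(TRUE)
  combos <- unique(cbind(a, b))
  # nodes: alleles of locus A, then alleles of locus B
  ua <- unique(combos[, 1]); ub <- unique(combos[, 2])
  u <- match(combos[, 1], ua)
  v <- length(ua) + match(combos[, 2], ub)
  parent <- seq_len(length(ua) + length(ub))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(combos))) {
    ru <- find(u[e]); rv <- find(v[e])
    if (ru == rv) return(FALSE) # edge closes a cycle
    parent[ru] <- rv
  }
  TRUE
}

prc_core <- function(m) {
  L <- ncol(m)
  flags <- matrix(NA, L, L, dimnames = list(colnames(m), colnames(m)))
  for (a in seq_len(L - 1L)) {
    for (b in seq((a + 1L), L)) {
      flags[a, b] <- flags[b, a] <-
        locus_pair_compatible(m[, a], m[, b])
    }
  }
  list(prc = mean(flags[upper.tri(flags)]), flags = flags)
}

#' Proportion of phylogenetically compatible locus pairs (PrC)
#'
#' Applies [locus_pair_compatible()] to every locus pair. High
#' compatibility is the clonal expectation, so the permutation p-value
#' (per-locus column shuffles, as in [index_of_association()]) counts
#' permuted PrC values at least as large as observed: a small p means
#' compatibility exceeds the random-recombination expectation. An
#' observed PrC of 0 therefore forces p = 1.
#'
#' @inheritParams index_of_association
#' @return Object of class `compatibility_result`: `prc`,
#'   `pairwise_flags` (logical matrix over locus pairs), `p_value`,
#'   `n_permutations`.
#' @export
prc <- function(x, system = "STR", n_perm = 999, seed = NULL) {
  m <- linkage_matrix(x, system)
  poly <- vapply(seq_len(ncol(m)), function(L)
    length(unique(m[!is.na(m[, L]), L])) > 1L, logical(1))
  if (sum(poly) < 2L) stop("need >= 2 polymorphic loci")
  obs <- prc_core(m)
  p_value <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      prc_core(apply(m, 2L, sample))$prc
    }, numeric(1)))
    p_value <- (1 + sum(perm >= obs$prc)) / (1 + n_perm)
  }
  structure(list(prc = obs$prc, pairwise_flags = obs$flags,
                 p_value = p_value, n_permutations = as.integer(n_perm)),
            class = "compatibility_result")
}

#' @export
print.compatibility_result <- function(x, ...) {
  cat("<compatibility_result> PrC =", signif(x$prc, 4))
  if (!is.na(x$p_value)) cat(", p =", signif(x$p_value, 3))
  cat("\n")
  invisible(x)
}

#' Genotypes shared across mating types
#'
#' Multilocus genotypes whose members include both the `mat1-1` and
#' `mat1-2` idiomorphs — in a strictly clonal organism a genotype should
#' carry a single idiomorph, so such sharing is evidence of a recombinant
#' origin. Isolates of unknown mating type are ignored.
#'
#' @param table A `genotype_table`.
#' @param dataset The `mlg_dataset` the table was built on.
#' @return Integer vector of genotype ids (possibly empty).
#' @export
shared_genotype_mating_conflicts <- function(table, dataset) {
  mt <- stats::setNames(dataset$isolates$mating_type,
                        dataset$isolates$id)
  if (sum(!is.na(mt)) < 2L) stop("mating types known for < 2 isolates")
  hit <- vapply(table$members, function(ids) {
    types <- unique(stats::na.omit(mt[ids]))
    all(c("mat1-1", "mat1-2") %in% types)
  }, logical(1))
  as.integer(names(table$members)[hit])
}
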