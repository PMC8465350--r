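## symmetric/general Dirichlet draw via gamma variates
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulation parameters
#'
#' Defines the sampling design and evolutionary knobs of the synthetic
#' generator: subdivided populations drawn from diverging ancestral
#' clusters, clonal expansion with geometric clone sizes, a tunable
#' fraction of linkage-equilibrium (recombinant) offspring, per-locus
#' cluster mixing (hybrids), mating-type draws and missing data. The
#' defaults mirror the study design the package targets: 19 populations
#' of haploid fungal isolates (239 in total), a 20-locus STR panel with
#' 3 to 21 alleles per locus, a 6-locus sequence panel collapsed to
#' haplotype alleles, two ancestral clusters, and mating-type idiomorphs
#' near a 1:1.3 ratio.
#'
#' @param seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @param n_populations Number of populations (used when
#'   `isolates_per_population` is scalar or `NULL`).
#' @param isolates_per_population Integer vector of population sizes, a
#'   scalar recycled `n_populations` times, or `NULL` for the bundled
#'   19-population design.
#' @param n_str_loci,n_mlst_loci Panel sizes.
#' @param str_allele_range,mlst_allele_range Inclusive ranges for the
#'   number of possible alleles per locus.
#' @param n_clusters Number of ancestral clusters.
#' @param divergence Non-negative; inverse Dirichlet concentration tying
#'   cluster (and population) allele frequencies to the ancestral base.
#'   0 makes every population identical in expectation; larger values
#'   give more divergent clusters.
#' @param recombination_rate Fraction of isolates produced by per-locus
#'   independent resampling from their population's allele pool
#'   (linkage-equilibrium offspring) instead of clonal copying.
#' @param hybrid_fraction Fraction of founders drawing each locus's
#'   frequency source from a random cluster.
#' @param clone_p Geometric parameter of the clone-size distribution
#'   (expected clone size `1/clone_p`).
#' @param missing_rate Per-call missing probability.
#' @param mating_type_prob Probability an isolate carries `mat1-2`
#'   (default 0.565, i.e. idiomorph ratio 1:1.3).
#' @param mating_typed_rate Fraction of isolates with a known mating type.
#' @param coordinates Optional data frame (`abbrev`, `lat`, `lon`) of
#'   population coordinates.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed,
                       n_populations = 19,
                       isolates_per_population = NULL,
                       n_str_loci = 20, n_mlst_loci = 6,
                       str_allele_range = c(3, 21),
                       mlst_allele_range = c(2, 8),
                       n_clusters = 2,
                       divergence = 1,
                       recombination_rate = 0.1,
                       hybrid_fraction = 0.1,
                       clone_p = 0.5,
                       missing_rate = 0,
                       mating_type_prob = 0.565,
                       mating_typed_rate = 1,
                       coordinates = NULL) {
  if (is.null(isolates_per_population)) {
    md <- population_metadata()
    if (n_populations == nrow(md)) {
      isolates_per_population <- stats::setNames(md$n_isolates, md$abbrev)
      if (is.null(coordinates)) {
        coordinates <- md[, c("abbrev", "region", "lat", "lon")]
      }
    } else {
      isolates_per_population <- rep(12L, n_populations)
    }
  }
  if (length(isolates_per_population) == 1L) {
    isolates_per_population <- rep(isolates_per_population, n_populations)
  }
  n_populations <- length(isolates_per_population)
  stopifnot(all(isolates_per_population > 0),
            divergence >= 0,
            recombination_rate >= 0, recombination_rate <= 1,
            hybrid_fraction >= 0, hybrid_fraction <= 1,
            clone_p > 0, clone_p <= 1,
            missing_rate >= 0, missing_rate < 1,
            mating_type_prob >= 0, mating_type_prob <= 1,
            str_allele_range[1] >= 2 || n_str_loci == 0,
            mlst_allele_range[1] >= 2 || n_mlst_loci == 0)
  structure(list(seed = as.integer(seed),
                 n_populations = n_populations,
                 isolates_per_population = isolates_per_population,
                 n_str_loci = n_str_loci, n_mlst_loci = n_mlst_loci,
                 str_allele_range = str_allele_range,
                 mlst_allele_range = mlst_allele_range,
                 n_clusters = n_clusters, divergence = divergence,
                 recombination_rate = recombination_rate,
                 hybrid_fraction = hybrid_fraction,
                 clone_p = clone_p, missing_rate = missing_rate,
                 mating_type_prob = mating_type_prob,
                 mating_typed_rate = mating_typed_rate,
                 coordinates = coordinates),
            class = "sim_params")
}

#' Simulate a haploid multilocus dataset with known ground truth
#'
#' Generation proceeds per marker system: (1) ancestral base allele
#' frequencies per locus from a symmetric Dirichlet; (2) cluster
#' frequencies from a Dirichlet centred on the base with concentration
#' `conc / divergence` (equal to the base when `divergence = 0`);
#' (3) population frequencies likewise perturbed around their cluster's;
#' (4) founder genotypes by independent per-locus sampling (hybrid
#' founders pick a random cluster per locus); (5) clonal expansion with
#' geometric clone sizes; (6) a `recombination_rate` fraction of isolates
#' re-drawn per locus from their population's allele-frequency pool
#' (linkage-equilibrium offspring — exactly the null the permutation
#' tests construct); (7) mating types as independent draws; (8) missing
#' calls at `missing_rate`.
#'
#' @param params A [sim_params()] object.
#' @return List with `dataset` (an `mlg_dataset`) and `truth` (class
#'   `sim_truth`): the parameter echo, per-population cluster
#'   assignments, per-isolate founder/clone/recombinant/hybrid flags,
#'   per-isolate per-locus cluster of origin, and realized genotype
#'   counts.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_params(1, n_populations = 4,
#'                                    isolates_per_population = 10))
#' sim$dataset
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  P <- params$n_populations
  sizes <- params$isolates_per_population
  pop_names <- names(sizes) %||% sprintf("P%02d", seq_len(P))
  names(sizes) <- pop_names
  K <- params$n_clusters
  cluster_of_pop <- rep_len(seq_len(K), P) # interleaved assignment

  conc <- 10 # base concentration scaling the divergence knob
  make_system <- function(n_loci, allele_range, prefix) {
    if (n_loci == 0L) return(NULL)
    n_alleles <- sample(seq(allele_range[1], allele_range[2]), n_loci,
                        replace = TRUE)
    lapply(seq_len(n_loci), function(L) {
      k <- n_alleles[L]
      base <- rdirichlet1(rep(1, k))
      clus <- if (params$divergence <= 0) {
        matrix(rep(base, K), nrow = K, byrow = TRUE)
      } else {
        t(vapply(seq_len(K), function(c)
          rdirichlet1(base * conc / params$divergence + 1e-6),
          numeric(k)))
      }
      pops <- if (params$divergence <= 0) {
        matrix(rep(base, P), nrow = P, byrow = TRUE)
      } else {
        t(vapply(seq_len(P), function(p)
          rdirichlet1(clus[cluster_of_pop[p], ] * 5 * conc /
                        params$divergence + 1e-6),
          numeric(k)))
      }
      list(k = k, base = base, cluster_freq = clus, pop_freq = pops)
    })
  }
  sys_str <- make_system(params$n_str_loci, params$str_allele_range, "S")
  sys_mlst <- make_system(params$n_mlst_loci, params$mlst_allele_range, "M")

  n_total <- sum(sizes)
  n_loci_all <- params$n_str_loci + params$n_mlst_loci
  sys_all <- c(sys_str, sys_mlst)
  calls <- matrix(NA_integer_, n_total, n_loci_all)
  origin <- matrix(NA_integer_, n_total, n_loci_all)
  role <- character(n_total)
  pop_col <- character(n_total)
  is_hybrid <- logical(n_total)

  row0 <- 0L
  for (p in seq_len(P)) {
    np <- sizes[p]
    filled <- 0L
    while (filled < np) {
      hybrid <- stats::runif(1) < params$hybrid_fraction
      src_cluster <- if (hybrid) {
        sample(seq_len(K), n_loci_all, replace = TRUE)
      } else {
        rep(cluster_of_pop[p], n_loci_all)
      }
      founder <- vapply(seq_len(n_loci_all), function(L) {
        f <- if (hybrid) {
          sys_all[[L]]$cluster_freq[src_cluster[L], ]
        } else {
          sys_all[[L]]$pop_freq[p, ]
        }
        sample.int(sys_all[[L]]$k, 1L, prob = f)
      }, integer(1))
      clone_size <- min(1L + stats::rgeom(1, params$clone_p), np - filled)
      for (cc in seq_len(clone_size)) {
        r <- row0 + filled + cc
        calls[r, ] <- founder
        origin[r, ] <- src_cluster
        role[r] <- if (cc == 1L) "founder" else "clone"
        is_hybrid[r] <- hybrid
      }
      filled <- filled + clone_size
    }
    pop_col[(row0 + 1L):(row0 + np)] <- pop_names[p]

    # linkage-equilibrium offspring: each locus drawn independently from
    # the population's allele-frequency pool — the exact null that the
    # I_A/rBarD permutation test constructs
    idx <- (row0 + 1L):(row0 + np)
    recomb <- stats::runif(np) < params$recombination_rate
    for (r in idx[recomb]) {
      calls[r, ] <- vapply(seq_len(n_loci_all), function(L)
        sample.int(sys_all[[L]]$k, 1L,
                   prob = sys_all[[L]]$pop_freq[p, ]), integer(1))
      role[r] <- "recombinant"
    }
    row0 <- row0 + np
  }

  if (params$missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < params$missing_rate,
                   nrow(calls))
    calls[drop] <- NA_integer_
  }

  mt <- ifelse(stats::runif(n_total) < params$mating_type_prob,
               "mat1-2", "mat1-1")
  if (params$mating_typed_rate < 1) {
    mt[stats::runif(n_total) >= params$mating_typed_rate] <- NA_character_
  }

  str <- if (params$n_str_loci > 0)
    calls[, seq_len(params$n_str_loci), drop = FALSE]
  mlst <- if (params$n_mlst_loci > 0)
    calls[, params$n_str_loci + seq_len(params$n_mlst_loci),
          drop = FALSE]
  if (!is.null(str)) colnames(str) <- sprintf("S%02d",
                                              seq_len(ncol(str)))
  if (!is.null(mlst)) colnames(mlst) <- sprintf("M%02d",
                                                seq_len(ncol(mlst)))
  iso <- data.frame(id = sprintf("sim_%04d", seq_len(n_total)),
                    population = pop_col, mating_type = mt)
  populations <- data.frame(abbrev = pop_names)
  if (!is.null(params$coordinates)) {
    populations <- merge(populations, params$coordinates,
                         by = "abbrev", sort = FALSE)
  }
  dataset <- mlg_dataset(iso, str = str, mlst = mlst,
                         populations = populations)

  gt <- assign_genotypes(dataset,
                         if (!is.null(str)) "STR" else "MLST",
                         missing_policy = "exclude")
  truth <- structure(list(
    params = params,
    cluster_of_population = stats::setNames(cluster_of_pop, pop_names),
    role = stats::setNames(role, iso$id),
    is_hybrid = stats::setNames(is_hybrid, iso$id),
    locus_origin = origin,
    realized_genotype_counts =
      vapply(gt$members, length, integer(1))), class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Write a simulated dataset in the package's standard exchange formats
#'
#' Emits the genotype TSV and population-metadata TSV consumed by
#' [read_genotype_table()], plus the ground truth as JSON.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "genotypes.tsv")
  pp <- file.path(dir, "populations.tsv")
  tp <- file.path(dir, "truth.json")
  write_genotype_table(sim$dataset, gp)
  utils::write.table(sim$dataset$populations, pp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  tr$locus_origin <- NULL # bulky; reproducible from params$seed
  writeLines(jsonlite::toJSON(unclass(tr), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tp)
  invisible(c(gp, pp, tp))
}
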