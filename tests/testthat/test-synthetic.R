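test_that("simulation is deterministic under its seed", {
  p <- sim_params(101, n_populations = 4, isolates_per_population = 8,
                  missing_rate = 0.05, mating_typed_rate = 0.8)
  s1 <- simulate_dataset(p)
  s2 <- simulate_dataset(p)
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$truth$role, s2$truth$role)
  s3 <- simulate_dataset(sim_params(102, n_populations = 4,
                                    isolates_per_population = 8))
  expect_false(identical(s1$dataset$str, s3$dataset$str))
})

test_that("emitted datasets are valid and truth is consistent", {
  sim <- simulate_dataset(sim_params(7, n_populations = 5,
                                     isolates_per_population = c(4, 6, 8,
                                                                 10, 12),
                                     missing_rate = 0.03))
  d <- sim$dataset
  expect_s3_class(d, "mlg_dataset")
  expect_identical(n_isolates(d), 40L)
  expect_identical(nrow(d$populations), 5L)
  expect_identical(ncol(d$str), 20L)
  expect_identical(ncol(d$mlst), 6L)
  expect_identical(length(sim$truth$cluster_of_population), 5L)
  expect_identical(length(sim$truth$role), 40L)
  expect_true(all(sim$truth$role %in%
                    c("founder", "clone", "recombinant")))
  # realized genotype counts cover every assigned isolate
  gt <- assign_genotypes(d, "STR")
  expect_identical(sum(sim$truth$realized_genotype_counts),
                   sum(!is.na(gt$assignments)))
  # the 19-population preset mirrors the bundled sampling design
  preset <- sim_params(1)
  expect_identical(sum(preset$isolates_per_population), 239L)
  expect_identical(preset$n_populations, 19L)
})

test_that("simulated files round-trip through the standard readers", {
  sim <- simulate_dataset(sim_params(3, n_populations = 3,
                                     isolates_per_population = 6))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  d2 <- read_genotype_table(
    file.path(dir, "genotypes.tsv"),
    str_loci = colnames(sim$dataset$str),
    mlst_loci = colnames(sim$dataset$mlst),
    populations_file = file.path(dir, "populations.tsv"))
  expect_identical(unname(d2$str), unname(sim$dataset$str))
  expect_identical(unname(d2$mlst), unname(sim$dataset$mlst))
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_identical(truth$params$seed, 3L)
})

test_that("full recombination drives rBarD to zero", {
  set.seed(1)
  vals <- vapply(1:12, function(k) {
    sim <- simulate_dataset(sim_params(1000 + k, n_populations = 1,
                                       isolates_per_population = 200,
                                       n_str_loci = 10, n_mlst_loci = 0,
                                       recombination_rate = 1,
                                       hybrid_fraction = 0))
    index_of_association(sim$dataset, "STR", n_perm = 0)$r_bar_d
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("mean rBarD decreases with the recombination rate", {
  rates <- c(0, 0.25, 0.5, 1)
  means <- vapply(rates, function(rr) {
    mean(vapply(1:15, function(k) {
      sim <- simulate_dataset(sim_params(2000 + 17 * k, n_populations = 1,
                                         isolates_per_population = 60,
                                         n_str_loci = 10, n_mlst_loci = 0,
                                         recombination_rate = rr,
                                         hybrid_fraction = 0,
                                         clone_p = 0.3))
      index_of_association(sim$dataset, "STR", n_perm = 0)$r_bar_d
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0.02)) # non-increasing up to noise
  expect_gt(means[1], means[4] + 0.1)  # and clearly so end to end
})

test_that("PhiPT rises with cluster divergence and vanishes without it", {
  grid <- c(0, 0.5, 1, 2, 4)
  means <- vapply(grid, function(dv) {
    mean(vapply(1:12, function(k) {
      sim <- simulate_dataset(sim_params(3000 + 31 * k,
                                         n_populations = 4,
                                         isolates_per_population = 15,
                                         n_str_loci = 10,
                                         n_mlst_loci = 0,
                                         divergence = dv,
                                         recombination_rate = 1,
                                         hybrid_fraction = 0))
      d <- sim$dataset
      g <- genotype_distance(d, "STR")
      amova_phipt(g, setNames(d$isolates$population, d$isolates$id),
                  n_perm = 0)$phi_pt_raw
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(means[1]), 0.02)
  expect_gt(suppressWarnings(cor(grid, means, method = "spearman")), 0.9)
})

test_that("hybrids fall between the cluster centroids on PCoA axis 1", {
  hits <- vapply(1:30, function(k) {
    sim <- simulate_dataset(sim_params(4000 + 7 * k, n_populations = 4,
                                       isolates_per_population = 15,
                                       n_str_loci = 15, n_mlst_loci = 0,
                                       divergence = 3,
                                       recombination_rate = 0,
                                       hybrid_fraction = 0.25))
    d <- sim$dataset
    hy <- sim$truth$is_hybrid[d$isolates$id]
    if (sum(hy) < 2 || sum(!hy) < 2) return(NA)
    pc <- suppressWarnings(pcoa(genotype_distance(d, "STR"), k = 1))
    ax <- pc$coordinates[, 1]
    cl <- sim$truth$cluster_of_population[d$isolates$population]
    cent <- tapply(ax[!hy], cl[!hy], mean)
    if (length(cent) < 2) return(NA)
    between <- function(v) v > min(cent) & v < max(cent)
    mean(between(ax[hy])) > mean(between(ax[!hy]))
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.5)
})
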