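test_that("genotype distance equals a brute-force mismatch count", {
  m <- rbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 6), c(2, 2, 3, 5, 6),
             c(1, 1, 1, 1, 1))
  d <- toy_dataset(m)
  g <- genotype_distance(d, "STR")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_identical(unname(g[i, j]), sum(m[i, ] != m[j, ]))
  }
  expect_true(all(diag(g) == 0))
  expect_identical(unname(g), unname(t(g)))
  # missing calls are pairwise-complete
  m2 <- rbind(c(1, NA), c(2, 2), c(1, 2))
  g2 <- genotype_distance(toy_dataset(m2), "STR")
  expect_identical(unname(g2[1, 2]), 1L)
  expect_identical(unname(g2[1, 3]), 0L)
  # a pair with no comparable locus is an error
  m3 <- rbind(c(1, NA), c(NA, 1))
  expect_error(genotype_distance(toy_dataset(m3), "STR"),
               "pairwise-complete")
})

test_that("AMOVA attains PhiPT = 1 on fully partitioned data", {
  iso <- data.frame(id = sprintf("i%d", 1:10),
                    population = rep(c("A", "B"), each = 5))
  m <- rbind(matrix(1L, 5, 4), matrix(2L, 5, 4))
  d <- mlg_dataset(iso, str = m)
  g <- genotype_distance(d, "STR")
  memb <- setNames(iso$population, iso$id)
  a <- amova_phipt(g, memb, n_perm = 199, seed = 3)
  expect_equal(a$phi_pt, 1)
  expect_equal(a$pct_among + a$pct_within, 100, tolerance = 0.1)
  expect_lte(a$p_value, 0.05)
  # identical isolates: degenerate, PhiPT defined as 0 with warning
  d0 <- mlg_dataset(iso, str = matrix(7L, 10, 4))
  g0 <- genotype_distance(d0, "STR")
  expect_warning(a0 <- amova_phipt(g0, memb, n_perm = 0), "no molecular")
  expect_equal(a0$phi_pt, 0)
})

test_that("AMOVA permutation p is invariant to distance rescaling", {
  sim <- simulate_dataset(sim_params(9, n_populations = 3,
                                     isolates_per_population = 8,
                                     n_mlst_loci = 0))
  d <- sim$dataset
  g <- genotype_distance(d, "STR")
  memb <- setNames(d$isolates$population, d$isolates$id)
  a1 <- amova_phipt(g, memb, n_perm = 99, seed = 12)
  a2 <- amova_phipt(3 * g, memb, n_perm = 99, seed = 12)
  expect_equal(a1$phi_pt, a2$phi_pt)
  expect_equal(a1$p_value, a2$p_value)
})

test_that("pairwise PhiPT equals per-pair AMOVA and is symmetric", {
  sim <- simulate_dataset(sim_params(21, n_populations = 3,
                                     isolates_per_population = 7,
                                     n_mlst_loci = 0, divergence = 2))
  d <- sim$dataset
  g <- genotype_distance(d, "STR")
  memb <- setNames(d$isolates$population, d$isolates$id)
  pw <- pairwise_phipt(g, memb, n_perm = 0)
  pops <- unique(memb)
  expect_identical(sum(upper.tri(pw$phi_pt)), 3L) # P(P-1)/2 entries
  expect_identical(pw$phi_pt, t(pw$phi_pt))
  for (a in 1:2) for (b in (a + 1):3) {
    idx <- memb %in% pops[c(a, b)]
    ref <- amova_phipt(g[idx, idx], memb[idx], n_perm = 0)
    expect_equal(pw$phi_pt[pops[a], pops[b]], ref$phi_pt)
  }
})

test_that("Nei distance matches the pooled-locus formula", {
  # two populations, two loci, two isolates per population
  iso <- data.frame(id = c("a", "b", "c", "d"),
                    population = c("X", "X", "Y", "Y"))
  m <- rbind(c(1L, 1L), c(1L, 2L), c(1L, 1L), c(2L, 2L))
  d <- mlg_dataset(iso, str = m)
  D <- nei_distance(d, "STR")
  # hand evaluation: px(L1)=(1,0), py(L1)=(.5,.5); px(L2)=py(L2)=(.5,.5)
  jxy <- (1 * 0.5 + 0 * 0.5) + (0.5 * 0.5 + 0.5 * 0.5)
  jx <- (1^2 + 0^2) + (0.5^2 + 0.5^2)
  jy <- (0.5^2 + 0.5^2) + (0.5^2 + 0.5^2)
  expect_equal(unname(D["X", "Y"]), -log(jxy / sqrt(jx * jy)))
  expect_identical(unname(diag(D)), c(0, 0))
  # identical spectra give 0
  d2 <- mlg_dataset(iso, str = rbind(c(1L, 1L), c(2L, 2L),
                                     c(1L, 1L), c(2L, 2L)))
  expect_equal(unname(nei_distance(d2, "STR")["X", "Y"]), 0)
  # fully disjoint alleles: infinite and flagged
  d3 <- mlg_dataset(iso, str = rbind(c(1L, 1L), c(1L, 1L),
                                     c(2L, 2L), c(2L, 2L)))
  expect_warning(D3 <- nei_distance(d3, "STR"), "no alleles")
  expect_identical(unname(D3["X", "Y"]), Inf)
  expect_identical(attr(D3, "infinite_pairs"), 1L)
})

test_that("great-circle distances honour the 6371 km sphere", {
  same <- geographic_distance(data.frame(abbrev = c("a", "b"),
                                         lat = c(10, 10),
                                         lon = c(20, 20)))
  expect_equal(unname(same["a", "b"]), 0)
  anti <- geographic_distance(data.frame(abbrev = c("a", "b"),
                                         lat = c(0, 0),
                                         lon = c(0, 180)))
  expect_equal(unname(anti["a", "b"]), pi * 6371, tolerance = 1e-6)
  quarter <- geographic_distance(data.frame(abbrev = c("a", "b"),
                                            lat = c(0, 0),
                                            lon = c(0, 90)))
  expect_equal(unname(quarter["a", "b"]), 10007.5, tolerance = 0.1)
  expect_error(geographic_distance(data.frame(abbrev = "a",
                                              lat = NA, lon = 1)),
               "missing coordinates")
})

test_that("Mantel r is 1 for identical and affine-related matrices", {
  set.seed(8)
  x <- matrix(runif(25), 5, 5); x <- x + t(x); diag(x) <- 0
  dimnames(x) <- list(letters[1:5], letters[1:5])
  m1 <- mantel_test(x, x, n_perm = 99, seed = 1)
  expect_equal(m1$r, 1)
  m2 <- mantel_test(x, 2 * x + 3, n_perm = 0)
  expect_equal(m2$r, 1)
  expect_error(mantel_test(x, matrix(1, 5, 5) - diag(5), n_perm = 0),
               "constant")
  # non-finite entries excluded pairwise
  xinf <- x; xinf[1, 2] <- xinf[2, 1] <- Inf
  m3 <- mantel_test(x, xinf, n_perm = 0)
  expect_identical(m3$n_excluded_pairs, 1L)
  expect_gt(m3$r, 0.99)
})

test_that("Mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(13)
  p <- matrix(runif(30), 10, 3)
  q <- p + matrix(rnorm(30, sd = 0.3), 10, 3)
  d1 <- as.matrix(dist(p)); d2 <- as.matrix(dist(q))
  dimnames(d1) <- dimnames(d2) <- list(letters[1:10], letters[1:10])
  ours <- mantel_test(d1, d2, n_perm = 999, seed = 5)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.05)
})

test_that("PCoA recovers simple geometric configurations", {
  # collinear points: one axis explains everything
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  p <- pcoa(d, k = 2)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  p3 <- suppressWarnings(pcoa(d3, k = 2))
  eig <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_identical(length(eig), 2L)
  expect_equal(eig[1], eig[2], tolerance = 1e-9)
  # two tight, well-separated clusters split on axis 1
  set.seed(4)
  pts <- c(rnorm(6, 0, 0.05), rnorm(6, 10, 0.05))
  pc <- pcoa(as.matrix(dist(pts)), k = 1)
  sgn <- sign(pc$coordinates[, 1])
  expect_identical(length(unique(sgn[1:6])), 1L)
  expect_identical(length(unique(sgn[7:12])), 1L)
  expect_true(all(sgn[1:6] != sgn[7:12]))
})
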