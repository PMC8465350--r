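test_that("genotype tables round-trip through TSV exactly", {
  d <- toy_dataset(rbind(c(1L, 5L, NA), c(2L, 5L, 7L), c(1L, NA, 7L)),
                   populations = c("A", "A", "B"),
                   mating_type = c("mat1-1", "mat1-2", NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(d, path)
  d2 <- read_genotype_table(path)
  expect_identical(unname(d2$str), unname(d$str))
  expect_identical(d2$isolates$id, d$isolates$id)
  expect_identical(d2$isolates$mating_type, d$isolates$mating_type)
  # write -> read -> write is byte-stable
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(d2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed input is rejected with informative errors", {
  expect_error(
    mlg_dataset(data.frame(id = c("x", "x"), population = "P"),
                str = matrix(1L, 2, 2)),
    "duplicated isolate")
  # row with one allele call too few names the offending isolate
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tpopulation\tL1\tL2",
               "good\tP1\t1\t2",
               "bad\tP1\t1"), path)
  expect_error(read_genotype_table(path), "bad")
  # wrong-size allele matrix
  expect_error(
    mlg_dataset(data.frame(id = c("a", "b"), population = "P"),
                str = matrix(1L, 3, 2)),
    "2 isolates")
  # unknown mating-type token becomes unknown, with a warning
  expect_warning(
    d <- mlg_dataset(data.frame(id = "a", population = "P",
                                mating_type = "MAT-A"),
                     str = matrix(1L, 1, 1)),
    "mating-type")
  expect_true(is.na(d$isolates$mating_type))
})

test_that("zero-as-missing flag and population metadata join work", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tpopulation\tL1\tL2",
               "a\tP1\t0\t2",
               "b\tP2\t1\t2"), path)
  d0 <- read_genotype_table(path)
  expect_identical(d0$str["a", "L1"], 0L)
  dz <- read_genotype_table(path, zero_as_missing = TRUE)
  expect_true(is.na(dz$str["a", "L1"]))
  popfile <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("abbrev\tname\tregion\tlat\tlon",
               "P1\tPop one\tWest\t10\t20",
               "P2\tPop two\tEast\t11\t21"), popfile)
  dp <- read_genotype_table(path, populations_file = popfile)
  expect_identical(dp$populations$region,
                   c("West", "East"))
})

test_that("sequence collapse labels haplotypes and counts polymorphism", {
  out <- collapse_sequences_to_alleles(
    list(L1 = c(a = "ACGT", b = "ACGT", c = "ACGA")))
  expect_identical(unname(out$alleles[, "L1"]), c(1L, 1L, 2L))
  expect_identical(out$summary$n_polymorphic, 1L)
  expect_equal(out$summary$prop_polymorphic, 0.25)

  mono <- collapse_sequences_to_alleles(
    list(L1 = c(a = "AAAA", b = "AAAA", c = "AAAA")))
  expect_identical(unname(mono$alleles[, "L1"]), c(1L, 1L, 1L))
  expect_identical(mono$summary$n_polymorphic, 0L)

  expect_error(
    collapse_sequences_to_alleles(list(L1 = c(a = "ACGT", b = "ACG"))),
    "lengths differ")
  expect_warning(
    out2 <- collapse_sequences_to_alleles(
      list(L1 = c(a = "ACGT"), L2 = c(a = "AC", b = "AC"))),
    "missing from FASTA")
  expect_true(is.na(out2$alleles["b", "L1"]))
})

test_that("a six-locus panel totalling 2106 sites with 125 polymorphic gives the expected overall proportion", {
  lens <- c(465, 420, 380, 184, 342, 315)
  polys <- c(20, 25, 30, 5, 34, 11)
  stopifnot(sum(lens) == 2106, sum(polys) == 125)
  seqs <- lapply(seq_along(lens), function(k) {
    s1 <- strrep("A", lens[k])
    s2 <- paste0(strrep("C", polys[k]), strrep("A", lens[k] - polys[k]))
    c(a = s1, b = s2, c = s1)
  })
  names(seqs) <- paste0("g", seq_along(seqs))
  out <- collapse_sequences_to_alleles(seqs)
  expect_identical(attr(out$summary, "total_length"), 2106L)
  expect_identical(attr(out$summary, "total_polymorphic"), 125L)
  prop <- attr(out$summary, "total_polymorphic") /
    attr(out$summary, "total_length")
  expect_equal(round(prop, 4), 0.0594, tolerance = 1e-8)
})

test_that("genotype assignment groups identical profiles in order of first appearance", {
  d <- toy_dataset(rbind(c(1, 1), c(2, 2), c(1, 1), c(2, 3), c(2, 2)))
  gt <- assign_genotypes(d, "STR")
  expect_identical(unname(gt$assignments), c(1L, 2L, 1L, 3L, 2L))
  expect_identical(gt$n_genotypes, 3L)
  # all-identical profiles collapse to a single genotype
  d1 <- toy_dataset(matrix(5L, 6, 3))
  expect_identical(assign_genotypes(d1, "STR")$n_genotypes, 1L)
})

test_that("genotype partition is stable under isolate permutation", {
  set.seed(11)
  sim <- simulate_dataset(sim_params(11, n_populations = 3,
                                     isolates_per_population = 12,
                                     n_mlst_loci = 0))
  d <- sim$dataset
  gt <- assign_genotypes(d, "STR")
  for (k in 1:3) {
    o <- sample(n_isolates(d))
    gt2 <- assign_genotypes(subset_isolates(d, o), "STR")
    expect_identical(partition_of(gt2), partition_of(gt))
  }
})

test_that("missing-call policies behave as documented", {
  d <- toy_dataset(rbind(c(1, 1), c(1, NA), c(1, 1), c(2, 2)))
  gt <- assign_genotypes(d, "STR")
  expect_identical(gt$excluded, "i02")
  expect_true(is.na(gt$assignments[["i02"]]))
  expect_identical(gt$n_genotypes, 2L)
  gm <- assign_genotypes(d, "STR", missing_policy = "match_any")
  expect_identical(length(gm$excluded), 0L)
  # the wildcard profile joins the first compatible genotype
  expect_identical(gm$assignments[["i02"]], gm$assignments[["i01"]])
})

test_that("clonal correction keeps first members, is idempotent, and orders by scope", {
  sim <- simulate_dataset(sim_params(5, n_populations = 4,
                                     isolates_per_population = 15,
                                     n_mlst_loci = 0, clone_p = 0.3))
  d <- sim$dataset
  gt <- assign_genotypes(d, "STR")
  cw <- clonal_correct(d, gt, "within_population")
  cg <- clonal_correct(d, gt, "global")
  expect_lte(n_isolates(cg), n_isolates(cw))
  expect_lte(n_isolates(cw), n_isolates(d))
  expect_identical(n_isolates(cg),
                   assign_genotypes(d, "STR")$n_genotypes)
  # idempotence
  gt_w <- assign_genotypes(cw, "STR")
  expect_identical(n_isolates(clonal_correct(cw, gt_w)), n_isolates(cw))
  # clone-free data unchanged
  du <- toy_dataset(rbind(c(1, 1), c(1, 2), c(2, 1)))
  gu <- assign_genotypes(du, "STR")
  expect_identical(n_isolates(clonal_correct(du, gu)), 3L)
})

test_that("the bundled genotype-distribution fixture reproduces the published membership structure", {
  d <- fixture_from_table3()
  expect_identical(n_isolates(d), 239L)
  expect_identical(nrow(d$populations), 19L)
  gt <- assign_genotypes(d, "MLST")
  expect_identical(gt$n_genotypes, 59L)
  sizes <- sort(vapply(gt$members, length, integer(1)),
                decreasing = TRUE)
  expect_identical(unname(sizes[1]), 71L)
  expect_identical(n_isolates(clonal_correct(d, gt)), 100L)
  expect_identical(n_isolates(clonal_correct(d, gt, "global")), 59L)
  # the single-genotype population keeps its 14 clonal members
  jil <- d$isolates$population == "JiL"
  expect_identical(sum(jil), 14L)
  expect_identical(length(unique(gt$assignments[jil])), 1L)
})
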