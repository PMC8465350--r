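# small in-code fixtures shared across tests

toy_dataset <- function(profiles, populations = NULL, system = "str",
                        mating_type = NULL) {
  m <- as.matrix(profiles)
  n <- nrow(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("L", seq_len(ncol(m)))
  iso <- data.frame(id = sprintf("i%02d", seq_len(n)),
                    population = populations %||% rep("P1", n))
  if (!is.null(mating_type)) iso$mating_type <- mating_type
  args <- list(iso)
  args[[system]] <- m
  do.call(mlg_dataset, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# membership partition of a genotype table, as a canonical sorted list
partition_of <- function(table) {
  p <- lapply(table$members, sort)
  unname(p[order(vapply(p, `[`, character(1), 1L))])
}

# brute-force minimum spanning weight by enumerating all edge subsets of
# size n-1 (feasible for <= 7 nodes); independent oracle for Kruskal
brute_force_mst_weight <- function(d) {
  n <- nrow(d)
  pr <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (pick in utils::combn(nrow(pr), n - 1L, simplify = FALSE)) {
    e <- pr[pick, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (k in seq_len(nrow(e))) {
      ru <- find(e[k, 1]); rv <- find(e[k, 2])
      if (ru == rv) { ok <- FALSE; break }
      parent[ru] <- rv
    }
    if (ok) best <- min(best, sum(d[e]))
  }
  best
}

# printed per-population genotypic diversities (GeJ_YunN row is a known
# typo in the source table and is excluded where relevant)
table3_printed_diversity <- c(
  HuB = 0.904, HeN = 0.786, ZheJ = 0.900, NeiM = 0.667, ShanX = 0.662,
  JiL = 0, QingH = 0.956, XinJ1 = 0, XinJ2 = 0, GuangD = 0.700,
  GuangX = 0.754, HaiN = 0.775, Dianchi_YunN = 0.628, GeJ_YunN = 0.286,
  YiM_YunN = 0.848, HeiJ_YunN = 0.981, GuiZ = 0.722, SiC = 0.385,
  Tibet = 0.667)
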