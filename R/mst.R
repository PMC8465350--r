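## Kruskal with deterministic tie-breaking: edges sorted by
## (distance, min node rank, max node rank); `rank` must be an
## input-order-invariant total order over the nodes
kruskal_mst <- function(d, rank = seq_len(nrow(d))) {
  n <- nrow(d)
  pr <- pair_index(n)
  w <- d[pr]
  lo <- pmin(rank[pr[, 1]], rank[pr[, 2]])
  hi <- pmax(rank[pr[, 1]], rank[pr[, 2]])
  o <- order(w, lo, hi)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(pr))
  for (e in o) {
    if (!is.finite(w[e])) next
    ru <- find(pr[e, 1]); rv <- find(pr[e, 2])
    if (ru != rv) {
      parent[ru] <- rv
      keep[e] <- TRUE
    }
  }
  out <- cbind(pr[keep, , drop = FALSE], w = w[keep])
  out[order(w[keep], lo[keep], hi[keep]), , drop = FALSE]
}

edge_class <- function(d) {
  cut(d, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
      labels = c("ONE", "TWO", "THREE", "FOUR_PLUS"))
}

#' Minimum spanning tree of multilocus genotypes
#'
#' Nodes are multilocus genotypes (one representative profile each —
#' identical across members by construction), weighted by member count and
#' annotated with population and mating-type composition. Edge weights are
#' allele mismatch counts between representative profiles; the tree is
#' built by Kruskal's algorithm with edges sorted by distance and then by
#' the lexicographic order of the endpoint profiles, so equal-weight ties
#' resolve deterministically and independently of isolate input order.
#' Edges are classed ONE / TWO / THREE / FOUR_PLUS by
#' difference count. If the missing-data policy leaves isolate pairs
#' without comparable loci a spanning forest is returned with a warning.
#'
#' @param table A `genotype_table`.
#' @param dataset The `mlg_dataset` the table was built on.
#' @param system Marker system (defaults to the table's system).
#' @return Object of class `mlg_mst`: `nodes` (data frame: genotype,
#'   n_members, populations, mating types), `edges` (data frame: g1, g2,
#'   distance, class), `total_weight`.
#' @export
#' @examples
#' d <- fixture_from_table3()
#' g <- build_mst(assign_genotypes(d, "MLST"), d)
#' nrow(g$edges) # 58 = 59 genotypes - 1
build_mst <- function(table, dataset, system = table$system) {
  if (table$n_genotypes < 2L) stop("need >= 2 genotypes")
  m <- system_matrix(dataset, system)
  first_ids <- vapply(table$members, `[`, character(1), 1L)
  reps <- m[first_ids, , drop = FALSE]
  gids <- as.integer(names(table$members))
  d <- profile_mismatch(reps)
  comp <- attr(d, "complete")
  dm <- matrix(as.numeric(d), nrow(d), ncol(d))
  dm[comp == 0L] <- Inf
  diag(dm) <- 0

  # tie-break on the lexicographic order of representative profiles so
  # the tree does not depend on isolate input order
  prof_key <- apply(reps, 1L, function(x)
    paste(sprintf("%06d", ifelse(is.na(x), 0L, x)), collapse = ","))
  edges <- kruskal_mst(dm, rank = rank(prof_key, ties.method = "first"))
  if (nrow(edges) < table$n_genotypes - 1L) {
    warning("graph is disconnected; returning a spanning forest")
  }
  pop_of <- stats::setNames(dataset$isolates$population,
                            dataset$isolates$id)
  mt_of <- stats::setNames(dataset$isolates$mating_type,
                           dataset$isolates$id)
  compose <- function(v) {
    t <- table(v[!is.na(v)])
    paste(names(t), as.integer(t), sep = ":", collapse = ";")
  }
  nodes <- data.frame(
    genotype = gids,
    n_members = vapply(table$members, length, integer(1)),
    populations = vapply(table$members,
                         function(ids) compose(pop_of[ids]), character(1)),
    mating_types = vapply(table$members,
                          function(ids) compose(mt_of[ids]), character(1)),
    row.names = NULL)
  edf <- data.frame(g1 = gids[edges[, 1]], g2 = gids[edges[, 2]],
                    distance = as.integer(edges[, "w"]))
  edf$class <- as.character(edge_class(edf$distance))
  structure(list(nodes = nodes, edges = edf,
                 total_weight = sum(edf$distance), system = system),
            class = "mlg_mst")
}

#' @export
print.mlg_mst <- function(x, ...) {
  cat("<mlg_mst> ", nrow(x$nodes), " genotypes, ", nrow(x$edges),
      " edges, total weight ", x$total_weight, "\n", sep = "")
  print(table(factor(x$edges$class,
                     levels = c("ONE", "TWO", "THREE", "FOUR_PLUS"))))
  invisible(x)
}

#' Convert a genotype MST to an igraph object
#'
#' @param x An `mlg_mst`.
#' @return An undirected `igraph` graph with node/edge attributes.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "mlg_mst"))
  v <- x$nodes
  v$name <- as.character(v$genotype)
  e <- data.frame(from = as.character(x$edges$g1),
                  to = as.character(x$edges$g2),
                  distance = x$edges$distance,
                  class = x$edges$class)
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = v[, c("name", "n_members",
                                                 "populations",
                                                 "mating_types")])
}

#' Export a genotype MST
#'
#' `write_mst_graphml()` and `write_mst_dot()` write standard graph
#' formats; `write_mst_tables()` writes the edge list and node attribute
#' TSVs.
#'
#' @param x An `mlg_mst`.
#' @param path Output path (for `write_mst_tables()`, a path prefix:
#'   `<prefix>_edges.tsv` and `<prefix>_nodes.tsv` are written).
#' @return Invisibly, the path(s) written.
#' @export
write_mst_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(path)
}

#' @rdname write_mst_graphml
#' @export
write_mst_dot <- function(x, path) {
  style <- c(ONE = "bold", TWO = "solid", THREE = "dashed",
             FOUR_PLUS = "dotted")
  lines <- c("graph mst {",
             sprintf("  %d [label=\"%d (n=%d)\"];",
                     x$nodes$genotype, x$nodes$genotype,
                     x$nodes$n_members),
             sprintf("  %d -- %d [label=%d, style=%s];",
                     x$edges$g1, x$edges$g2, x$edges$distance,
                     style[x$edges$class]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mst_graphml
#' @export
write_mst_tables <- function(x, path) {
  ep <- paste0(path, "_edges.tsv")
  np <- paste0(path, "_nodes.tsv")
  utils::write.table(x$edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$nodes, np, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ep, np))
}
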