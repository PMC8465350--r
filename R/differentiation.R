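#' Pairwise multilocus genotype distance
#'
#' `d(i, j)` is the number of pairwise-complete loci (both calls
#' non-missing) at which the two isolates carry different allele labels —
#' a simple categorical mismatch count, the haploid analogue of the binary
#' distance used by distance-based AMOVA.
#'
#' @param dataset An `mlg_dataset`.
#' @param system `"STR"`, `"MLST"`, or `"COMBINED"`.
#' @return Symmetric integer matrix with zero diagonal, labelled by
#'   isolate id.
#' @export
genotype_distance <- function(dataset, system = "STR") {
  m <- system_matrix(dataset, system)
  d <- profile_mismatch(m)
  comp <- attr(d, "complete")
  if (any(comp[upper.tri(comp)] == 0L)) {
    bad <- which(comp == 0L & upper.tri(comp), arr.ind = TRUE)[1, ]
    stop("isolates ", rownames(m)[bad[1]], " and ", rownames(m)[bad[2]],
         " share no pairwise-complete locus")
  }
  attr(d, "complete") <- NULL
  d
}

## mismatch count matrix over the rows of an allele matrix; attaches the
## per-pair count of pairwise-complete loci
profile_mismatch <- function(m) {
  n <- nrow(m)
  diff <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  comp <- matrix(0L, n, n)
  for (L in seq_len(ncol(m))) {
    v <- m[, L]
    ok <- !is.na(v)
    both <- outer(ok, ok, "&")
    ne <- outer(v, v, "!=")
    ne[!both] <- FALSE
    diff <- diff + ne
    comp <- comp + both
  }
  storage.mode(diff) <- "integer"
  attr(diff, "complete") <- comp
  diff
}

## within-group half sums of squared distances, divided by group size
ss_within_groups <- function(d2, membership) {
  groups <- split(seq_along(membership), membership)
  sum(vapply(groups, function(idx)
    sum(d2[idx, idx]) / 2 / length(idx), numeric(1)))
}

#' Distance-based AMOVA with PhiPT
#'
#' One-level analysis of molecular variance on squared pairwise distances
#' (Excoffier-style): total and within-population sums of squares are
#' computed from the squared distance matrix, variance components follow
#' from the mean squares with the usual unequal-sample-size coefficient
#' `n0`, and `PhiPT = var_among / (var_among + var_within)` estimates the
#' among-population share of molecular variance. Significance is assessed
#' by permuting isolate-to-population labels; the p-value uses the
#' `+1`-corrected one-sided count of permuted PhiPT values at least as
#' large as observed. A negative among-population component is truncated
#' to zero for `phi_pt` (the untruncated estimate is kept as
#' `phi_pt_raw`).
#'
#' @param dist Symmetric distance matrix labelled by isolate id.
#' @param membership Named character vector: population per isolate
#'   (names must match the distance labels), or an unnamed vector in the
#'   same order.
#' @param n_perm Number of label permutations (0 skips the test).
#' @param seed Optional integer seed for the permutations.
#' @return Object of class `amova_result`.
#' @export
#' @examples
#' d <- fixture_from_table3()
#' g <- genotype_distance(d, "MLST")
#' amova_phipt(g, setNames(d$isolates$population, d$isolates$id),
#'             n_perm = 99, seed = 1)
amova_phipt <- function(dist, membership, n_perm = 999, seed = NULL) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (!is.null(names(membership))) {
    membership <- membership[rownames(dist)]
    if (anyNA(membership)) stop("membership missing for some isolates")
  }
  stopifnot(length(membership) == n)
  membership <- as.character(membership)
  sizes <- table(membership)
  if (any(sizes == 0)) stop("population(s) with zero isolates")
  P <- length(sizes)
  if (P < 2L) stop("need >= 2 populations")

  d2 <- dist^2
  ss_total <- sum(d2) / 2 / n
  phipt_of <- function(memb) {
    ss_within <- ss_within_groups(d2, memb)
    ss_among <- ss_total - ss_within
    df_among <- P - 1L
    df_within <- n - P
    var_within <- ss_within / df_within
    n0 <- (n - sum(sizes^2) / n) / df_among
    var_among_raw <- (ss_among / df_among - var_within) / n0
    c(ss_within = ss_within, ss_among = ss_among,
      var_within = var_within, var_among_raw = var_among_raw)
  }

  obs <- phipt_of(membership)
  var_within <- obs[["var_within"]]
  var_among_raw <- obs[["var_among_raw"]]
  var_among <- max(0, var_among_raw)
  tot <- var_among + var_within
  degenerate <- tot <= 0
  if (degenerate) {
    warning("no molecular variance; PhiPT defined as 0")
    phi <- 0
    phi_raw <- 0
  } else {
    phi <- var_among / tot
    phi_raw <- var_among_raw / (var_among_raw + var_within)
  }

  p_value <- NA_real_
  if (n_perm > 0 && !degenerate) {
    perm_phi <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        pm <- phipt_of(sample(membership))
        va <- max(0, pm[["var_among_raw"]])
        t2 <- va + pm[["var_within"]]
        if (t2 <= 0) 0 else va / t2
      }, numeric(1))
    })
    p_value <- (1 + sum(perm_phi >= phi)) / (1 + n_perm)
  }

  structure(list(
    df_among = P - 1L, df_within = n - P,
    ss_among = obs[["ss_among"]], ss_within = obs[["ss_within"]],
    var_among = var_among, var_among_raw = var_among_raw,
    var_within = var_within,
    phi_pt = phi, phi_pt_raw = phi_raw,
    pct_among = if (degenerate) 0 else 100 * var_among / tot,
    pct_within = if (degenerate) 100 else 100 * var_within / tot,
    p_value = p_value, n_permutations = as.integer(n_perm),
    n = n, n_populations = P), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result> PhiPT =", signif(x$phi_pt, 4))
  if (!is.na(x$p_value)) cat(", p =", signif(x$p_value, 3),
                             sprintf("(%d perms)", x$n_permutations))
  cat("\n  among:", sprintf("df=%d SS=%.3f var=%.4f (%.0f%%)",
                            x$df_among, x$ss_among, x$var_among,
                            x$pct_among), "\n")
  cat("  within:", sprintf("df=%d SS=%.3f var=%.4f (%.0f%%)",
                           x$df_within, x$ss_within, x$var_within,
                           x$pct_within), "\n")
  invisible(x)
}

#' Pairwise population PhiPT matrix
#'
#' [amova_phipt()] applied to every pair of populations. P-values are
#' reported raw (uncorrected).
#'
#' @inheritParams amova_phipt
#' @return List with `phi_pt` and `p_value` (symmetric population
#'   matrices; diagonal 0 and NA respectively).
#' @export
pairwise_phipt <- function(dist, membership, n_perm = 999, seed = NULL) {
  dist <- as.matrix(dist)
  if (!is.null(names(membership))) membership <- membership[rownames(dist)]
  pops <- unique(membership)
  P <- length(pops)
  phi <- matrix(0, P, P, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (a in seq_len(P - 1L)) {
    for (b in seq((a + 1L), P)) {
      idx <- membership %in% pops[c(a, b)]
      res <- amova_phipt(dist[idx, idx, drop = FALSE], membership[idx],
                         n_perm = n_perm,
                         seed = if (is.null(seed)) NULL
                                else stage_seed(seed, paste(a, b)))
      phi[a, b] <- phi[b, a] <- res$phi_pt
      pv[a, b] <- pv[b, a] <- res$p_value
    }
  }
  list(phi_pt = phi, p_value = pv)
}

#' Nei's (1972) standard genetic distance between populations
#'
#' Per-population allele frequencies are computed at each locus of the
#' chosen system; the normalized identity pools loci,
#' `I = J_xy / sqrt(J_x J_y)` with `J` summed over loci and alleles, and
#' `D = -ln(I)`. Population pairs sharing no allele at any locus have
#' infinite distance and are flagged.
#'
#' @param dataset An `mlg_dataset` with at least two populations.
#' @param system Marker system.
#' @return Symmetric matrix over populations, possibly containing `Inf`;
#'   attribute `infinite_pairs` counts such pairs.
#' @export
nei_distance <- function(dataset, system = "STR") {
  m <- system_matrix(dataset, system)
  pops <- dataset$populations$abbrev
  if (length(pops) < 2L) stop("need >= 2 populations")
  pop_of <- dataset$isolates$population
  # per-locus frequency tables with a common allele basis
  freq <- lapply(seq_len(ncol(m)), function(L) {
    tab <- table(factor(pop_of[!is.na(m[, L])], levels = pops),
                 m[!is.na(m[, L]), L])
    sweep(unclass(tab), 1L, pmax(rowSums(tab), 1L), "/")
  })
  P <- length(pops)
  D <- matrix(0, P, P, dimnames = list(pops, pops))
  n_inf <- 0L
  for (a in seq_len(P - 1L)) {
    for (b in seq((a + 1L), P)) {
      jxy <- sum(vapply(freq, function(f) sum(f[a, ] * f[b, ]), numeric(1)))
      jx <- sum(vapply(freq, function(f) sum(f[a, ]^2), numeric(1)))
      jy <- sum(vapply(freq, function(f) sum(f[b, ]^2), numeric(1)))
      if (jxy == 0) {
        D[a, b] <- D[b, a] <- Inf
        n_inf <- n_inf + 1L
      } else {
        D[a, b] <- D[b, a] <- max(0, -log(jxy / sqrt(jx * jy)))
      }
    }
  }
  if (n_inf > 0) {
    warning(n_inf, " population pair(s) share no alleles: distance Inf")
  }
  attr(D, "infinite_pairs") <- n_inf
  D
}

#' Great-circle distances between populations
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param populations Data frame with columns `abbrev`, `lat`, `lon`
#'   (e.g. the `populations` element of an `mlg_dataset`).
#' @return Symmetric matrix of distances in kilometres.
#' @export
geographic_distance <- function(populations) {
  if (inherits(populations, "mlg_dataset")) {
    populations <- populations$populations
  }
  miss <- is.na(populations$lat) | is.na(populations$lon)
  if (any(miss)) {
    stop("missing coordinates for population(s): ",
         paste(populations$abbrev[miss], collapse = ", "))
  }
  xy <- cbind(populations$lon, populations$lat)
  P <- nrow(xy)
  D <- matrix(0, P, P,
              dimnames = list(populations$abbrev, populations$abbrev))
  for (a in seq_len(P - 1L)) {
    D[a, (a + 1L):P] <- geosphere::distHaversine(
      xy[a, , drop = FALSE], xy[(a + 1L):P, , drop = FALSE],
      r = 6371000) / 1000
  }
  D + t(D)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance by
#' jointly permuting rows and columns of the second matrix. Non-finite
#' entries (e.g. infinite genetic distances) are excluded pairwise from
#' the correlation, with their count reported.
#'
#' @param d1,d2 Distance matrices with identical labels and order.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default; positive association, the
#'   isolation-by-distance direction) or `"two.sided"`.
#' @return Object of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`, `n_excluded_pairs`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(identical(dim(d1), dim(d2)))
  n <- nrow(d1)
  if (n < 3L) stop("Mantel test needs >= 3 objects")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("distance matrices have different labels")
  }
  ut <- upper.tri(d1)
  finite <- is.finite(d1) & is.finite(d2)
  n_excl <- sum(ut & !finite)
  r_of <- function(m2) {
    keep <- ut & is.finite(d1) & is.finite(m2)
    x <- d1[keep]; y <- m2[keep]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("constant distances: Mantel r undefined")
    }
    stats::cor(x, y)
  }
  r_obs <- r_of(d2)
  p_value <- NA_real_
  if (n_perm > 0) {
    perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      o <- sample(n)
      r_of(d2[o, o])
    }, numeric(1)))
    p_value <- if (alternative == "greater") {
      (1 + sum(perm_r >= r_obs)) / (1 + n_perm)
    } else {
      (1 + sum(abs(perm_r) >= abs(r_obs))) / (1 + n_perm)
    }
  }
  structure(list(r = r_obs, p_value = p_value,
                 n_permutations = as.integer(n_perm),
                 n_excluded_pairs = n_excl,
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("<mantel_result> r =", signif(x$r, 4))
  if (!is.na(x$p_value)) cat(", p =", signif(x$p_value, 3))
  if (x$n_excluded_pairs > 0) cat(" (", x$n_excluded_pairs,
                                  " non-finite pairs excluded)", sep = "")
  cat("\n")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix (double-centred
#' `-d^2/2`). Negative eigenvalues are dropped with a warning; explained
#' proportions are relative to the positive eigenvalues.
#'
#' @param dist Distance matrix.
#' @param k Number of axes requested (truncated, with a warning, when
#'   fewer positive eigenvalues exist).
#' @return List of class `pcoa_result`: `coordinates` (n x k matrix),
#'   `eigenvalues`, `explained` (proportion per returned axis).
#' @export
pcoa <- function(dist, k = 2) {
  stopifnot(k >= 1)
  d <- as.matrix(dist)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = min(k, nrow(d) - 1L),
                    eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  if (any(eig < -sqrt(.Machine$double.eps) * max(abs(eig)))) {
    warning("negative eigenvalues dropped (non-Euclidean distances)")
  }
  coords <- fit$points
  if (ncol(coords) > length(pos)) {
    coords <- coords[, seq_along(pos), drop = FALSE]
  }
  if (ncol(coords) < k) {
    warning("only ", ncol(coords), " positive axes available; truncated")
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = eig,
                 explained = pos[seq_len(ncol(coords))] / sum(pos)),
            class = "pcoa_result")
}
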