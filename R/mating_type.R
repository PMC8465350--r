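#' Mating-type idiomorph summary and 1:1 goodness-of-fit test
#'
#' Counts the `mat1-1` and `mat1-2` idiomorphs (heterothallic fungi need
#' opposite idiomorphs to mate, so a sexually active population is
#' expected near 1:1), reports the `mat1-2 : mat1-1` ratio, and tests the
#' 1:1 hypothesis with a 1-df chi-square goodness-of-fit (no continuity
#' correction). Isolates of unknown mating type are excluded from the
#' test denominator.
#'
#' @param dataset An `mlg_dataset` with at least one typed isolate, or a
#'   length-2 numeric vector of counts `c(n_mat1_1, n_mat1_2)`.
#' @return Object of class `mating_type_summary`: `n_mat1_1`, `n_mat1_2`,
#'   `n_unknown`, `ratio` (`n_mat1_2 / n_mat1_1`), `chi_square`,
#'   `p_value`, `per_population` (data frame, `NULL` when raw counts were
#'   supplied).
#' @export
#' @examples
#' mating_type_summary(c(84, 113)) # ratio 1.3 (1 d.p.), chi-sq 4.27
mating_type_summary <- function(dataset) {
  per_pop <- NULL
  if (inherits(dataset, "mlg_dataset")) {
    mt <- dataset$isolates$mating_type
    n1 <- sum(mt == "mat1-1", na.rm = TRUE)
    n2 <- sum(mt == "mat1-2", na.rm = TRUE)
    nu <- sum(is.na(mt))
    tab <- table(dataset$isolates$population,
                 factor(mt, levels = c("mat1-1", "mat1-2")),
                 useNA = "always")
    tab <- tab[rownames(tab) %in% dataset$populations$abbrev, ,
               drop = FALSE]
    per_pop <- data.frame(population = rownames(tab),
                          n_mat1_1 = as.integer(tab[, "mat1-1"]),
                          n_mat1_2 = as.integer(tab[, "mat1-2"]),
                          n_unknown = as.integer(tab[, 3]),
                          row.names = NULL)
  } else {
    stopifnot(is.numeric(dataset), length(dataset) == 2L)
    n1 <- dataset[1]; n2 <- dataset[2]; nu <- 0L
  }
  if (n1 + n2 == 0) stop("no isolates with known mating type")
  test <- stats::chisq.test(c(n1, n2), p = c(0.5, 0.5), correct = FALSE)
  structure(list(n_mat1_1 = n1, n_mat1_2 = n2, n_unknown = nu,
                 ratio = if (n1 > 0) n2 / n1 else Inf,
                 chi_square = unname(test$statistic),
                 p_value = unname(test$p.value),
                 per_population = per_pop),
            class = "mating_type_summary")
}

#' @export
print.mating_type_summary <- function(x, ...) {
  cat("<mating_type_summary> mat1-1:", x$n_mat1_1,
      " mat1-2:", x$n_mat1_2, " unknown:", x$n_unknown, "\n")
  cat("  ratio 1:", format(round(x$ratio, 1), nsmall = 1),
      "  chi-square ", signif(x$chi_square, 4),
      " (p = ", signif(x$p_value, 3), ")\n", sep = "")
  invisible(x)
}
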