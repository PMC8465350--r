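`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage-specific seed from a master seed
#'
#' Mixes a master seed with a stage name so that toggling one analysis stage
#' on or off does not shift the random stream consumed by the others. The
#' result is always a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' stage_seed(42, "amova")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 2147483587
  as.integer((abs(seed) + h) %% 2147483587 + 1)
}

## population variance: divide by N, not N - 1 (pair-distance convention
## used throughout the linkage statistics)
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

## upper-triangle (i < j) index pairs of an n x n matrix, as a 2-column matrix
pair_index <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  j <- rep.int(seq_len(n), rep.int(n, n))
  i <- rep.int(seq_len(n), n)
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

#' Write a labelled square matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## deterministic RNG scope: set seed if non-NULL without touching the
## caller's stream otherwise
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}
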