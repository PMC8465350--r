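#' Collapse aligned sequences to haplotype alleles
#'
#' For sequence-typed loci the working "allele" is the whole-locus
#' haplotype: identical aligned sequence strings at a locus receive the
#' same integer allele label (labels ordered by first appearance). A
#' per-locus polymorphism summary counts aligned columns with at least two
#' distinct non-gap states.
#'
#' @param seqs_by_locus Named list, one element per locus; each element a
#'   named character vector of aligned sequences keyed by isolate id (or a
#'   FASTA file path, read via Biostrings when available).
#' @param isolate_ids Character vector fixing the isolate order of the
#'   returned allele matrix. Defaults to the union of ids seen, in order of
#'   first appearance. An isolate absent from a locus gets a missing call,
#'   with a warning.
#' @param gap_chars Characters ignored when counting polymorphic columns.
#' @return List with `alleles` (integer matrix, isolates x loci) and
#'   `summary` (data frame: locus, aligned length, number of alleles,
#'   polymorphic column count, proportion polymorphic).
#' @export
#' @examples
#' out <- collapse_sequences_to_alleles(
#'   list(L1 = c(a = "ACGT", b = "ACGT", c = "ACGA")))
#' out$alleles[, "L1"]   # 1 1 2
#' out$summary$n_polymorphic  # 1
collapse_sequences_to_alleles <- function(seqs_by_locus,
                                          isolate_ids = NULL,
                                          gap_chars = c("-", "N", "n", ".")) {
  stopifnot(is.list(seqs_by_locus), length(seqs_by_locus) > 0L,
            !is.null(names(seqs_by_locus)))
  seqs_by_locus <- lapply(seqs_by_locus, function(s) {
    if (is.character(s) && length(s) == 1L && file.exists(s)) {
      s <- read_fasta(s)
    }
    stopifnot(is.character(s), !is.null(names(s)))
    toupper(s)
  })
  if (is.null(isolate_ids)) {
    isolate_ids <- unique(unlist(lapply(seqs_by_locus, names),
                                 use.names = FALSE))
  }

  loci <- names(seqs_by_locus)
  alleles <- matrix(NA_integer_, nrow = length(isolate_ids),
                    ncol = length(loci),
                    dimnames = list(isolate_ids, loci))
  summ <- data.frame(locus = loci, aligned_length = NA_integer_,
                     n_alleles = NA_integer_, n_polymorphic = NA_integer_,
                     prop_polymorphic = NA_real_)

  for (k in seq_along(loci)) {
    s <- seqs_by_locus[[k]]
    lens <- nchar(s)
    if (length(unique(lens)) > 1L) {
      stop("locus ", loci[k], ": aligned sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    extra <- setdiff(names(s), isolate_ids)
    if (length(extra)) {
      stop("locus ", loci[k], ": sequence id(s) not in the dataset: ",
           paste(extra, collapse = ", "))
    }
    absent <- setdiff(isolate_ids, names(s))
    if (length(absent)) {
      warning("locus ", loci[k], ": ", length(absent),
              " isolate(s) missing from FASTA; missing calls assigned")
    }
    lab <- match(s, unique(s)) # first-appearance order
    alleles[names(s), k] <- lab

    colmat <- do.call(rbind, strsplit(s, "", fixed = TRUE))
    poly <- apply(colmat, 2L, function(col) {
      states <- unique(col[!col %in% gap_chars])
      length(states) >= 2L
    })
    summ$aligned_length[k] <- lens[1]
    summ$n_alleles[k] <- length(unique(s))
    summ$n_polymorphic[k] <- sum(poly)
    summ$prop_polymorphic[k] <- sum(poly) / lens[1]
  }
  attr(summ, "total_length") <- sum(summ$aligned_length)
  attr(summ, "total_polymorphic") <- sum(summ$n_polymorphic)
  list(alleles = alleles, summary = summ)
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over `Biostrings::readBStringSet()`.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA files requires the Biostrings package")
  }
  s <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
}
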