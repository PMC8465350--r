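#' Analysis run configuration
#'
#' Bundles inputs and options for [run_analysis()]. Group definitions
#' (e.g. regions or clades) must cover every population or be omitted;
#' they drive the per-group linkage-disequilibrium report.
#'
#' @param dataset An `mlg_dataset` (e.g. from [read_genotype_table()],
#'   [simulate_dataset()], or a fixture constructor).
#' @param system Marker system for genotype-level stages.
#' @param clone_correct `"off"`, `"population"`, or `"global"`.
#' @param n_perm Permutations for AMOVA / Mantel / linkage tests.
#' @param seed Master seed; required whenever `n_perm > 0`. Every random
#'   stage consumes a sub-seed derived from it and the stage name.
#' @param groups Optional named character vector mapping population
#'   abbreviations to group labels.
#' @param pairwise Also compute the pairwise PhiPT matrix (slower).
#' @param out_dir Optional output directory; when given, report tables
#'   are written there.
#' @return List of class `run_config`.
#' @export
run_config <- function(dataset, system = "STR",
                       clone_correct = c("off", "population", "global"),
                       n_perm = 999, seed = NULL, groups = NULL,
                       pairwise = FALSE, out_dir = NULL) {
  stopifnot(inherits(dataset, "mlg_dataset"))
  clone_correct <- match.arg(clone_correct)
  if (n_perm > 0 && is.null(seed)) {
    stop("a seed is required whenever permutations are requested")
  }
  if (!is.null(groups)) {
    pops <- dataset$populations$abbrev
    unknown <- setdiff(names(groups), pops)
    if (length(unknown)) {
      stop("group map names unknown population(s): ",
           paste(unknown, collapse = ", "))
    }
    uncovered <- setdiff(pops, names(groups))
    if (length(uncovered)) {
      stop("group map must cover all populations; missing: ",
           paste(uncovered, collapse = ", "))
    }
  }
  structure(list(dataset = dataset, system = toupper(system),
                 clone_correct = clone_correct,
                 n_perm = as.integer(n_perm), seed = seed,
                 groups = groups, pairwise = pairwise,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis chain
#'
#' Orchestrates genotype assignment, optional clonal correction,
#' diversity accounting, AMOVA/PhiPT (and optionally the pairwise
#' matrix), Nei distance, Mantel isolation-by-distance (when population
#' coordinates exist), PCoA, the linkage-disequilibrium and
#' compatibility tests (overall and per group), the genotype minimum
#' spanning tree, and the mating-type summary. A failing stage is
#' recorded under `$errors` and does not abort independent stages. When
#' `out_dir` is set, report tables, a JSON summary, and a reproducibility
#' manifest are written.
#'
#' @param config A [run_config()] object.
#' @return List of class `run_report` with one element per stage.
#' @export
#' @examples
#' d <- fixture_from_table3()
#' rep <- run_analysis(run_config(d, system = "MLST", n_perm = 49,
#'                                seed = 1))
#' rep$amova$phi_pt
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  d <- config$dataset
  report <- list(errors = list())
  seed_for <- function(stage) {
    if (is.null(config$seed)) NULL else stage_seed(config$seed, stage)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  gt <- stage("genotypes", assign_genotypes(d, config$system))
  if (is.null(gt)) {
    report$config <- config
    class(report) <- "run_report"
    return(report)
  }
  report$genotypes <- gt

  d_an <- d
  if (config$clone_correct != "off") {
    d_an <- stage("clonal_correction",
                  clonal_correct(d, gt,
                                 scope = if (config$clone_correct ==
                                             "population")
                                   "within_population" else "global"))
    if (is.null(d_an)) d_an <- d
    gt_an <- assign_genotypes(d_an, config$system)
  } else {
    gt_an <- gt
  }
  report$n_analysed <- n_isolates(d_an)

  report$locus_diversity <-
    stage("locus_diversity", locus_diversity_summary(d, config$system))
  report$allele_summary <-
    stage("allele_summary", private_alleles(d, config$system))
  report$genotype_diversity <-
    stage("genotype_diversity", genotype_diversity_table(d, gt))
  report$genotype_frequency <-
    stage("genotype_frequency", genotype_frequency_summary(gt, d))

  memb <- stats::setNames(d_an$isolates$population, d_an$isolates$id)
  gd <- stage("distance", genotype_distance(d_an, config$system))
  if (!is.null(gd)) {
    report$amova <- stage("amova",
                          amova_phipt(gd, memb, n_perm = config$n_perm,
                                      seed = seed_for("amova")))
    if (config$pairwise) {
      report$pairwise_phipt <-
        stage("pairwise_phipt",
              pairwise_phipt(gd, memb, n_perm = config$n_perm,
                             seed = seed_for("pairwise_phipt")))
    }
    report$pcoa <- stage("pcoa", pcoa(gd, k = 2))
  }

  nd <- stage("nei_distance", nei_distance(d_an, config$system))
  report$nei_distance <- nd
  if (!is.null(nd) && !anyNA(d_an$populations$lat) &&
      nrow(d_an$populations) >= 3) {
    geo <- stage("geographic_distance",
                 geographic_distance(d_an$populations))
    if (!is.null(geo)) {
      report$mantel <- stage("mantel",
                             mantel_test(geo, nd, n_perm = config$n_perm,
                                         seed = seed_for("mantel")))
    }
  }

  report$linkage <- stage("linkage",
                          index_of_association(d_an, config$system,
                                               n_perm = config$n_perm,
                                               seed = seed_for("linkage")))
  report$compatibility <- stage("compatibility",
                                prc(d_an, config$system,
                                    n_perm = config$n_perm,
                                    seed = seed_for("compatibility")))
  if (!is.null(config$groups)) {
    report$group_linkage <- stage("group_linkage", {
      glab <- config$groups[d_an$isolates$population]
      rows <- lapply(unique(glab), function(g) {
        sub <- subset_isolates(d_an, glab == g)
        la <- tryCatch(index_of_association(
          sub, config$system, n_perm = config$n_perm,
          seed = seed_for(paste0("linkage_", g))),
          error = function(e) NULL)
        pc <- tryCatch(prc(sub, config$system, n_perm = config$n_perm,
                           seed = seed_for(paste0("prc_", g))),
                       error = function(e) NULL)
        data.frame(group = g, n = n_isolates(sub),
                   prc = if (is.null(pc)) NA else pc$prc,
                   prc_p = if (is.null(pc)) NA else pc$p_value,
                   r_bar_d = if (is.null(la)) NA else la$r_bar_d,
                   r_bar_d_p = if (is.null(la)) NA else la$p_value)
      })
      do.call(rbind, rows)
    })
  }

  report$mst <- stage("mst", build_mst(gt_an, d_an, config$system))
  report$mating_types <- stage("mating_types", mating_type_summary(d))
  report$conflicts <- stage("conflicts",
                            shared_genotype_mating_conflicts(gt, d))

  report$manifest <- list(
    package_version = as.character(utils::packageVersion("mlgpop")),
    system = config$system, clone_correct = config$clone_correct,
    n_perm = config$n_perm, seed = config$seed,
    n_isolates = n_isolates(d), n_analysed = report$n_analysed,
    groups = as.list(config$groups %||% list()))

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report$config <- config
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> system=", x$manifest$system, ", ",
      x$manifest$n_isolates, " isolates (", x$manifest$n_analysed,
      " analysed)\n", sep = "")
  done <- setdiff(names(x), c("errors", "config", "manifest"))
  cat("  stages:", paste(done, collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("  failed:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

## write the report bundle as TSV/JSON files
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$locus_diversity)) {
    wt(report$locus_diversity, "locus_diversity.tsv")
  }
  if (!is.null(report$allele_summary)) {
    wt(report$allele_summary$pop_totals, "allele_totals.tsv")
  }
  if (!is.null(report$genotype_diversity)) {
    wt(report$genotype_diversity, "genotype_diversity.tsv")
  }
  if (!is.null(report$genotype_frequency)) {
    wt(report$genotype_frequency, "genotype_frequency.tsv")
  }
  if (!is.null(report$group_linkage)) {
    wt(report$group_linkage, "group_linkage.tsv")
  }
  if (!is.null(report$nei_distance)) {
    write_matrix_tsv(report$nei_distance,
                     file.path(dir, "nei_distance.tsv"))
  }
  if (!is.null(report$pairwise_phipt)) {
    write_matrix_tsv(report$pairwise_phipt$phi_pt,
                     file.path(dir, "pairwise_phipt.tsv"))
    write_matrix_tsv(report$pairwise_phipt$p_value,
                     file.path(dir, "pairwise_phipt_p.tsv"))
  }
  if (!is.null(report$pcoa)) {
    coords <- data.frame(id = rownames(report$pcoa$coordinates),
                         report$pcoa$coordinates)
    wt(coords, "pcoa_coordinates.tsv")
  }
  if (!is.null(report$mst)) {
    write_mst_tables(report$mst, file.path(dir, "mst"))
    write_mst_dot(report$mst, file.path(dir, "mst.dot"))
  }
  scalar <- list(
    amova = if (!is.null(report$amova)) unclass(report$amova),
    mantel = if (!is.null(report$mantel)) unclass(report$mantel),
    linkage = if (!is.null(report$linkage)) unclass(report$linkage),
    compatibility = if (!is.null(report$compatibility)) {
      c <- unclass(report$compatibility)
      c$pairwise_flags <- NULL
      c
    },
    mating_types = if (!is.null(report$mating_types)) {
      m <- unclass(report$mating_types)
      m$per_population <- NULL
      m
    },
    conflicts = report$conflicts,
    errors = report$errors,
    manifest = report$manifest)
  writeLines(jsonlite::toJSON(scalar, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE),
             file.path(dir, "report.json"))
  invisible(dir)
}
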