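#' Run the full typing workflow over a cohort
#'
#' Executes iterative typing (classical pass, then non-classical pass) for
#' every individual, quantifies expression against each individual's called
#' alleles, and collects a reproducible run manifest.  Novel alleles
#' discovered in one individual enter the shared cohort catalogue before
#' the remaining individuals are typed; individuals are processed in sorted
#' id order, so the result does not depend on input ordering.  A strict
#' per-individual isolation mode is available for comparison.
#'
#' @param reads_by_individual named list of read data frames (or FASTQ
#'   paths, loaded with [read_fastq()]).
#' @param cat the starting [allele_catalogue()].
#' @param config a [typing_config()].
#' @param isolate discover novel alleles per individual without sharing?
#' @return list of class `typing_run` with `calls` (per-individual genotype
#'   data frames), `expression` (per-individual `expression_table`s),
#'   `catalogue` (the extended cohort catalogue), `profiles` and `manifest`.
#' @export
run_pipeline <- function(reads_by_individual, cat,
                         config = typing_config(), isolate = FALSE) {
  stopifnot(length(reads_by_individual) > 0L,
            !is.null(names(reads_by_individual)))
  inds <- sort(names(reads_by_individual))
  cohort <- cat
  calls <- list()
  expr <- list()
  profiles <- list()
  audits <- list()
  for (ind in inds) {
    reads <- reads_by_individual[[ind]]
    if (is.character(reads)) reads <- read_fastq(reads)
    base_cat <- if (isolate) cat else cohort
    res <- run_iterative_typing(reads, base_cat, config,
                                individual_id = ind)
    if (!isolate) cohort <- res$catalogue
    calls[[ind]] <- res$call
    profiles[[ind]] <- res$profiles
    audits[[ind]] <- res$audit
    expr[[ind]] <- if (length(res$counts)) {
      expression_proportions(res$counts, res$catalogue, individual_id = ind)
    } else {
      expression_proportions(numeric(0), res$catalogue,
                             individual_id = ind)
    }
  }
  # one settling pass: individuals typed before a later discovery get
  # re-called against the final cohort catalogue
  if (!isolate) {
    grew <- nrow(cohort$alleles) > nrow(cat$alleles)
    if (grew) {
      for (ind in inds) {
        reads <- reads_by_individual[[ind]]
        if (is.character(reads)) reads <- read_fastq(reads)
        res <- run_iterative_typing(reads, cohort, config,
                                    individual_id = ind)
        cohort <- res$catalogue
        calls[[ind]] <- res$call
        profiles[[ind]] <- res$profiles
        expr[[ind]] <- if (length(res$counts)) {
          expression_proportions(res$counts, res$catalogue,
                                 individual_id = ind)
        } else {
          expression_proportions(numeric(0), res$catalogue,
                                 individual_id = ind)
        }
      }
    }
  }
  final_cat <- if (isolate) cat else cohort
  manifest <- list(
    tool = paste0("mhctyper ",
                  as.character(utils::packageVersion("mhctyper"))),
    config = unclass(config),
    catalogue_version_in = cat$version_tag,
    catalogue_version_out = final_cat$version_tag,
    n_alleles_in = nrow(cat$alleles),
    n_alleles_out = nrow(final_cat$alleles),
    individuals = inds,
    novel_alleles = setdiff(final_cat$alleles$allele_id,
                            cat$alleles$allele_id),
    audit = audits)
  structure(list(calls = calls, expression = expr, catalogue = final_cat,
                 profiles = profiles, manifest = manifest),
            class = "typing_run")
}

#' @export
print.typing_run <- function(x, ...) {
  cat("typing_run: ", length(x$calls), " individuals, ",
      nrow(x$catalogue$alleles), " catalogue alleles (",
      length(x$manifest$novel_alleles), " novel)\n", sep = "")
  invisible(x)
}

#' Write a run manifest as JSON
#'
#' @param run a `typing_run` from [run_pipeline()] (or a manifest list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  manifest <- if (inherits(run, "typing_run")) run$manifest else run
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write all reports of a typing run
#'
#' Emits the genotype TSV, the wide expression TSV, the extended catalogue
#' FASTA and the JSON manifest into a directory.
#'
#' @param run a `typing_run`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_run_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             catalogue = file.path(dir, "catalogue.fasta"),
             manifest = file.path(dir, "manifest.json"))
  write_genotype_report(run$calls, paths[["genotypes"]])
  write_expression_table(run$expression, paths[["expression"]])
  write_catalogue(run$catalogue, paths[["catalogue"]])
  write_manifest(run, paths[["manifest"]])
  invisible(paths)
}
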