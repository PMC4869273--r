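#' Final quantification alignment against an individual's called alleles
#'
#' Re-aligns the reads at zero mismatches against only the alleles called in
#' the individual, and distributes multi-mapping reads under the chosen
#' policy (default fractional, which conserves total read mass exactly).
#' Mates are counted individually.
#'
#' @param reads read data frame of the individual.
#' @param called_cat an [allele_catalogue()] restricted to the called
#'   alleles (see [subset_catalogue()] usage in [run_iterative_typing()]).
#' @param policy multi-mapping policy (see [assign_reads()]).
#' @param seed seed for the `"random"` policy.
#' @param k index k-mer length.
#' @return named numeric vector of per-allele read counts (real-valued
#'   under the fractional policy), including zeros.
#' @export
final_alignment_counts <- function(reads, called_cat, policy = "fractional",
                                   seed = 1L, k = 15L) {
  stopifnot(inherits(called_cat, "allele_catalogue"))
  if (nrow(called_cat$alleles) == 0L) {
    stop("empty called-allele set: nothing to quantify against")
  }
  reads <- as_reads(reads)
  index <- build_index(called_cat, k)
  hits <- align_reads(reads, index, 0L, "best_only")
  asg <- assign_reads(hits, policy, seed = seed)
  count_by_allele(asg, called_cat$alleles$allele_id)
}

#' Within-class expression proportions
#'
#' Normalises per-allele read counts separately within the classical and
#' within the non-classical alleles of one individual, mirroring the two
#' within-class report tables.  A class with zero total reads yields `NA`
#' proportions (undefined, not 0/0).
#'
#' @param counts named numeric vector of per-allele counts.
#' @param cat an [allele_catalogue()] assigning each counted allele a class.
#' @param individual_id identifier recorded in the table.
#' @param length_normalise divide counts by allele length before
#'   normalising (off by default: the report semantics are raw read-count
#'   ratios, and allele lengths within a class are nearly equal).
#' @return data frame of class `expression_table`: `individual_id`,
#'   `allele_id`, `gene_label`, `class_kind`, `raw_count`, `proportion`.
#' @export
expression_proportions <- function(counts, cat, individual_id = "sample",
                                   length_normalise = FALSE) {
  ids <- names(counts) %||% character(0)
  stopifnot(all(ids %in% cat$alleles$allele_id))
  info <- cat$alleles[match(ids, cat$alleles$allele_id), , drop = FALSE]
  x <- as.numeric(counts)
  if (length_normalise && length(x)) {
    x <- x / unname(nchar(cat$sequences[ids]))
  }
  prop <- rep(NA_real_, length(x))
  for (kind in unique(info$class_kind)) {
    sel <- info$class_kind == kind
    tot <- sum(x[sel])
    if (tot > 0) prop[sel] <- x[sel] / tot
  }
  out <- data.frame(individual_id = rep(individual_id, length(x)),
                    allele_id = ids, gene_label = info$gene_label,
                    class_kind = info$class_kind,
                    raw_count = as.numeric(counts), proportion = prop,
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Write a cohort expression table as TSV
#'
#' Wide layout mirroring the within-class report tables: rows are
#' (gene, allele), one column per individual, cells are proportions
#' rendered with 3 decimal places, blank where the allele was not called.
#'
#' @param tables a list of `expression_table` data frames (one per
#'   individual), or one combined data frame.
#' @param path output path.
#' @return the wide data frame, invisibly.
#' @export
write_expression_table <- function(tables, path) {
  if (is.data.frame(tables)) tables <- list(tables)
  long <- do.call(rbind, tables)
  inds <- unique(long$individual_id)
  key <- unique(long[, c("class_kind", "gene_label", "allele_id")])
  key <- key[order(key$class_kind, key$gene_label, key$allele_id), ,
             drop = FALSE]
  wide <- key
  for (ind in inds) {
    sub <- long[long$individual_id == ind, , drop = FALSE]
    v <- sub$proportion[match(key$allele_id, sub$allele_id)]
    wide[[ind]] <- ifelse(is.na(v), "", sprintf("%.3f", v))
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(wide)
}
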