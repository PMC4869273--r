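#' Typing run configuration
#'
#' Collects every tunable of the typing pipeline with its default.
#'
#' @param k seed k-mer length of the aligner index.
#' @param max_mismatch_exact mismatch bound of the strict calling alignment.
#' @param max_mismatch_relaxed mismatch bound of the relaxed discovery
#'   alignment (best stratum only).
#' @param min_depth minimum per-base depth for a base to count as covered.
#'   The default 2 requires two independent zero-mismatch reads per base:
#'   at finite depth a single sequencing-error read that reverts a variant
#'   base to the reference otherwise fabricates complete coverage at
#'   exactly the discriminating position (calling the parent of a novel
#'   allele, or validating a partial reconstruction).  `min_depth = 1` is
#'   the literal presence criterion; at the deep coverage the method is
#'   designed for the two coincide.
#' @param gap_max maximum length of the single tolerated uncovered interval
#'   when proposing novel-allele parents ("fully covered except a single
#'   region < 5 bp", i.e. at most 4 bases).
#' @param min_support minimum reads carrying an alternative base for a
#'   pileup variant.
#' @param min_fraction minimum fraction of the pileup carrying the
#'   alternative base.
#' @param min_link minimum fragments jointly observing two variants for a
#'   phasing edge (and, in repulsion, for an anti-edge).
#' @param min_overlap minimum read overlap during de novo contig extension.
#' @param min_contig minimum accepted de novo contig length.
#' @param branch_frac fraction of extension votes at which a second branch
#'   makes the extension ambiguous.
#' @param iteration_cap abort bound on discovery iterations.
#' @param count_policy multi-mapping policy of the final quantification
#'   alignment (`"fractional"`, `"all"` or `"random"`).
#' @param lab_tag laboratory tag used in generated novel-allele ids.
#' @param seed seed for any randomised policy.
#' @return a list of class `typing_config`.
#' @export
typing_config <- function(k = 15L, max_mismatch_exact = 0L,
                          max_mismatch_relaxed = 3L, min_depth = 2L,
                          gap_max = 4L, min_support = 3L, min_fraction = 0.2,
                          min_link = 2L, min_overlap = 25L, min_contig = 200L,
                          branch_frac = 0.25, iteration_cap = 20L,
                          count_policy = "fractional", lab_tag = "FBN",
                          seed = 1L) {
  structure(list(k = as.integer(k),
                 max_mismatch_exact = as.integer(max_mismatch_exact),
                 max_mismatch_relaxed = as.integer(max_mismatch_relaxed),
                 min_depth = as.integer(min_depth),
                 gap_max = as.integer(gap_max),
                 min_support = as.integer(min_support),
                 min_fraction = min_fraction, min_link = as.integer(min_link),
                 min_overlap = as.integer(min_overlap),
                 min_contig = as.integer(min_contig),
                 branch_frac = branch_frac,
                 iteration_cap = as.integer(iteration_cap),
                 count_policy = count_policy, lab_tag = lab_tag,
                 seed = as.integer(seed)),
            class = "typing_config")
}

#' Per-base coverage profiles from read placements
#'
#' Depth at position `i` of an allele is the number of assigned reads whose
#' placement overlaps `i`.  Uncovered intervals are the maximal 0-based
#' half-open intervals with depth below `min_depth`.
#'
#' @param assignments data frame of placements with columns `allele_id`,
#'   `offset`, `width` (e.g. hits from [align_reads()]).
#' @param cat the [allele_catalogue()] the placements refer to.
#' @param min_depth depth below which a base counts as uncovered.
#' @return named list (one entry per catalogue allele) of
#'   `coverage_profile` lists with fields `allele_id`, `depth` (integer
#'   vector) and `uncovered` (two-column matrix of half-open intervals).
#' @export
compute_coverage <- function(assignments, cat, min_depth = 1L) {
  stopifnot(inherits(cat, "allele_catalogue"))
  lens <- nchar(cat$sequences)
  if (nrow(assignments)) {
    if (any(assignments$offset < 0L) ||
        any(assignments$offset + assignments$width >
            lens[assignments$allele_id])) {
      stop("read placement out of allele bounds")
    }
  }
  by_allele <- split(seq_len(nrow(assignments)), assignments$allele_id)
  profs <- lapply(cat$alleles$allele_id, function(id) {
    L <- unname(lens[[id]])
    rows <- by_allele[[id]]
    depth <- integer(L)
    if (!is.null(rows)) {
      starts <- assignments$offset[rows] + 1L
      ends <- assignments$offset[rows] + assignments$width[rows]
      delta <- tabulate(starts, L + 1L) - tabulate(ends + 1L, L + 1L)
      depth <- cumsum(delta)[seq_len(L)]
    }
    structure(list(allele_id = id, depth = depth,
                   uncovered = runs_true(depth < min_depth)),
              class = "coverage_profile")
  })
  stats::setNames(profs, cat$alleles$allele_id)
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile ", x$allele_id, ": length ", length(x$depth),
      ", mean depth ", round(mean(x$depth), 1), ", ", nrow(x$uncovered),
      " uncovered interval(s)\n", sep = "")
  invisible(x)
}

fully_covered <- function(profile) nrow(profile$uncovered) == 0L

#' Does a coverage profile qualify as a novel-allele parent candidate?
#'
#' A profile qualifies when it is fully covered, or uncovered in exactly one
#' maximal interval of at most `gap_max` bases (the "fully covered except a
#' single region < 5 bp" rule, read literally as one interval of <= 4 nt).
#'
#' @param profile a `coverage_profile`.
#' @param gap_max maximum tolerated length of the single uncovered interval.
#' @return logical.
#' @export
candidate_from_profile <- function(profile, gap_max = 4L) {
  u <- profile$uncovered
  nrow(u) == 0L ||
    (nrow(u) == 1L && (u[1L, "end"] - u[1L, "start"]) <= gap_max)
}

#' Call alleles by complete zero-mismatch coverage
#'
#' Aligns reads at the strict mismatch bound (default 0) with the `"all"`
#' multi-mapping policy and calls exactly those alleles whose entire
#' sequence is covered at depth `>= min_depth`.
#'
#' @param reads read data frame (`read_id`, `mate`, `sequence`).
#' @param cat an [allele_catalogue()].
#' @param config a [typing_config()].
#' @param index optional pre-built index over `cat` (rebuilt when `NULL`).
#' @return list with `call` (data frame: `allele_id`, `gene_label`,
#'   `class_kind`, `stage`, `read_count`, `mean_depth`), `profiles` and the
#'   raw `hits`.
#' @export
call_alleles_exact <- function(reads, cat, config = typing_config(),
                               index = NULL) {
  reads <- as_reads(reads)
  if (is.null(index)) index <- build_index(cat, config$k)
  hits <- align_reads(reads, index, config$max_mismatch_exact, "all_valid")
  asg <- assign_reads(hits, "all")
  profiles <- compute_coverage(asg, cat, config$min_depth)
  called <- names(profiles)[vapply(profiles, fully_covered, logical(1))]
  info <- cat$alleles[match(called, cat$alleles$allele_id), , drop = FALSE]
  call <- data.frame(
    allele_id = called,
    gene_label = info$gene_label,
    class_kind = info$class_kind,
    stage = ifelse(info$provenance == "database", "exact", "novel"),
    read_count = vapply(called, function(id)
      sum(asg$allele_id == id), numeric(1)),
    mean_depth = vapply(called, function(id)
      mean(profiles[[id]]$depth), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(call) <- NULL
  list(call = call, profiles = profiles, hits = hits)
}

#' Propose parent alleles for novel-allele discovery
#'
#' Aligns at the relaxed mismatch bound (best stratum only, `"all"` policy)
#' and returns the not-yet-called alleles whose relaxed profile is fully
#' covered or uncovered in a single interval of at most `gap_max` bases.
#' Classical candidates are reported before non-classical ones (the
#' classical genes are processed first), then by descending mean depth.
#'
#' @param reads read data frame.
#' @param cat an [allele_catalogue()].
#' @param already_called character vector of allele ids to exclude.
#' @param config a [typing_config()].
#' @param index optional pre-built index over `cat`.
#' @return list with `candidates` (data frame: `allele_id`, `class_kind`,
#'   `mean_depth`, `n_gaps`), the relaxed-stratum `hits` and `profiles`.
#' @export
find_novel_candidates <- function(reads, cat, already_called = character(),
                                  config = typing_config(), index = NULL) {
  reads <- as_reads(reads)
  if (is.null(index)) index <- build_index(cat, config$k)
  hits <- align_reads(reads, index, config$max_mismatch_relaxed, "best_only")
  asg <- assign_reads(hits, "all")
  profiles <- compute_coverage(asg, cat, config$min_depth)
  ok <- vapply(profiles, candidate_from_profile, logical(1),
               gap_max = config$gap_max)
  ids <- names(profiles)[ok]
  ids <- setdiff(ids, already_called)
  info <- cat$alleles[match(ids, cat$alleles$allele_id), , drop = FALSE]
  cand <- data.frame(
    allele_id = ids, class_kind = info$class_kind,
    mean_depth = vapply(ids, function(id)
      mean(profiles[[id]]$depth), numeric(1)),
    n_gaps = vapply(ids, function(id)
      nrow(profiles[[id]]$uncovered), numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(cand$class_kind != "classical", -cand$mean_depth,
               cand$allele_id)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, hits = hits, profiles = profiles)
}

#' Iterative allele typing with novel-allele discovery
#'
#' The calling core: alternates complete-coverage calling with novel-allele
#' discovery until no further allele is added, processing classical genes to
#' closure before non-classical genes.  Each iteration (per class pass)
#' performs: (1) strict-coverage calling; (2) relaxed-alignment candidate
#' detection; (3) variant-based reconstruction against each candidate
#' parent (pileup, phasing, substitution, validation); (4) a de novo pass
#' over reads carrying recurrent k-mers absent from the catalogue; (5)
#' extension of the catalogue with every validated novel allele.  A final
#' strict alignment against only the called alleles yields per-allele read
#' counts for quantification.
#'
#' @param reads read data frame for one individual.
#' @param cat the (cohort) [allele_catalogue()].
#' @param config a [typing_config()].
#' @param individual_id identifier recorded on the genotype call.
#' @return list with `call` (genotype data frame as in
#'   [call_alleles_exact()], plus `individual_id` and the catalogue version),
#'   `catalogue` (possibly extended), `counts` (final per-allele read
#'   counts), `profiles` of the final call, and `audit` (per-iteration log
#'   of candidates and accepted/rejected novel alleles).
#' @export
run_iterative_typing <- function(reads, cat, config = typing_config(),
                                 individual_id = "sample") {
  reads <- as_reads(reads)
  audit <- list()
  if (nrow(reads) == 0L) {
    return(list(call = cbind(individual_id = character(0),
                             call_alleles_exact(reads, cat, config)$call),
                catalogue = cat, counts = numeric(0), profiles = list(),
                audit = audit))
  }
  for (phase in c("classical", "nonclassical")) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > config$iteration_cap) {
        stop("iteration cap (", config$iteration_cap,
             ") exceeded in ", phase, " pass for ", individual_id)
      }
      index <- build_index(cat, config$k)
      exact <- call_alleles_exact(reads, cat, config, index = index)
      called <- exact$call$allele_id
      fc <- find_novel_candidates(reads, cat, called, config, index = index)
      cand <- fc$candidates[fc$candidates$class_kind == phase, , drop = FALSE]
      # variant inspection also covers already-called alleles: a novel
      # allele whose parent is itself called (co-expressed, or covered by
      # a mosaic of relatives) surfaces as recurrent pileup variants on
      # the called allele
      called_phase <- exact$call$allele_id[exact$call$class_kind == phase]
      # inspect freshly reconstructed alleles before database alleles:
      # a variant recurring on a just-built allele continues that
      # haplotype's reconstruction, whereas relatives only pick up
      # bleed-through variants via conserved-window ties
      prov <- cat$alleles$provenance[match(called_phase,
                                           cat$alleles$allele_id)]
      called_phase <- called_phase[order(prov == "database")]
      parents <- unique(c(cand$allele_id, called_phase))
      added <- character(0)
      rejected <- list()
      for (parent_id in parents) {
        # once something was accepted this iteration, defer called-allele
        # inspection to the next iteration: only after re-alignment are
        # the accepted allele's reads explained, and a variant counts
        # only when unexplained by every identified allele
        if (length(added) && parent_id %in% called_phase) next
        disc <- discover_from_parent(parent_id, fc$hits, reads, cat, config)
        rejected <- c(rejected, disc$rejected)
        for (seqn in disc$accepted) {
          res <- add_novel_allele(cat, seqn, parent_id = parent_id,
                                  lab_tag = config$lab_tag)
          cat <- res$catalogue
          added <- c(added, res$allele_id)
        }
      }
      # de novo pass on reads unexplained by the (possibly extended)
      # catalogue, accepted in the pass matching their protein features
      dn <- denovo_pass(reads, cat, fc$hits, phase, config)
      cat <- dn$catalogue
      added <- c(added, dn$added)
      rejected <- c(rejected, dn$rejected)
      audit[[length(audit) + 1L]] <- list(
        phase = phase, iteration = iter, called = called,
        candidates = parents, accepted = added,
        rejected = rejected)
      if (length(added) == 0L) break
    }
  }
  final <- call_alleles_exact(reads, cat, config)
  call <- final$call
  counts <- numeric(0)
  if (nrow(call)) {
    counts <- final_alignment_counts(
      reads, subset_catalogue(cat, call$allele_id),
      policy = config$count_policy, seed = config$seed, k = config$k)
    call$read_count <- unname(counts[call$allele_id])
  }
  call <- cbind(individual_id = rep(individual_id, nrow(call)), call,
                catalogue_version = rep(cat$version_tag, nrow(call)),
                stringsAsFactors = FALSE)
  list(call = call, catalogue = cat, counts = counts,
       profiles = final$profiles[call$allele_id], audit = audit)
}

# catalogue restricted to `ids`, order preserved
subset_catalogue <- function(cat, ids) {
  stopifnot(all(ids %in% cat$alleles$allele_id))
  out <- cat
  out$alleles <- cat$alleles[match(ids, cat$alleles$allele_id), ,
                             drop = FALSE]
  rownames(out$alleles) <- NULL
  out$sequences <- cat$sequences[ids]
  out
}

#' Write a genotype report as TSV
#'
#' @param calls genotype data frame(s) from [run_iterative_typing()] (or a
#'   list thereof, concatenated).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_report <- function(calls, path) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, calls)
  }
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
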