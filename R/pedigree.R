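#' Pedigrees and SNP matrices
#'
#' A pedigree is a data frame with columns `individual_id`, `sire_id`,
#' `dam_id` (NA for founders) and a free-text `group_label`.  A SNP matrix
#' is a data frame with columns `snp_id`, `chrom`, `pos` and one genotype
#' column per individual, coded `"AA"`, `"AB"`, `"BB"` or `NA`.
#'
#' @param ped a candidate pedigree data frame.
#' @return the validated pedigree (invisibly errors otherwise).
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("individual_id", "sire_id", "dam_id") %in% names(ped)))
  if (anyDuplicated(ped$individual_id)) {
    stop("duplicate individual_id in pedigree")
  }
  # no individual may be its own ancestor
  parent_of <- function(id) {
    r <- ped[ped$individual_id == id, , drop = FALSE]
    if (!nrow(r)) return(character(0))
    stats::na.omit(c(r$sire_id, r$dam_id))
  }
  for (id in ped$individual_id) {
    seen <- character(0)
    frontier <- parent_of(id)
    while (length(frontier)) {
      if (id %in% frontier) stop(id, " is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  ped
}

founder_ids <- function(ped) {
  ped$individual_id[is.na(ped$sire_id) & is.na(ped$dam_id)]
}

#' Read/write pedigree TSV
#'
#' @param path TSV path with columns `individual_id`, `sire_id`, `dam_id`,
#'   `group_label`.
#' @return data frame (read) or `path` invisibly (write).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write SNP matrix TSV
#'
#' @param path TSV path with columns `snp_id`, `chrom`, `pos` and one
#'   genotype column per individual.
#' @return data frame (read) or `path` invisibly (write).
#' @export
read_snp_matrix <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
}

#' @rdname read_snp_matrix
#' @param m SNP matrix data frame.
#' @export
write_snp_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

snp_individuals <- function(m) {
  setdiff(names(m), c("snp_id", "chrom", "pos"))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic marker: the probability of each
#' possible heterozygote count given the observed allele counts is
#' enumerated and the p-value is the summed probability of all outcomes no
#' more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb observed genotype counts.
#' @return the exact p-value (1 for degenerate inputs).
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  na <- 2L * n_aa + n_ab
  nb <- 2L * n_bb + n_ab
  rare <- min(na, nb)
  hets <- seq(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- (nb - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  if (is.na(p_obs)) stop("inconsistent genotype counts")
  sum(p[p <= p_obs * (1 + 1e-9)])
}

genotype_counts <- function(g) {
  c(n_aa = sum(g == "AA", na.rm = TRUE), n_ab = sum(g == "AB", na.rm = TRUE),
    n_bb = sum(g == "BB", na.rm = TRUE))
}

#' Filter SNPs by region and quality control
#'
#' Retains SNPs inside the target region that pass call rate, minor allele
#' frequency and Hardy-Weinberg filters, mirroring chip quality control.
#' The HWE exact test runs on founders only, to avoid the family structure
#' of the offspring; call rate and MAF use all individuals.
#'
#' @param m SNP matrix data frame.
#' @param region numeric length-2 `(start_bp, end_bp)`, inclusive.
#' @param ped pedigree used to identify founders (all individuals are
#'   treated as founders when `NULL`).
#' @param call_rate_min,maf_min,hwe_p_min strict lower thresholds (a SNP
#'   passes when its value is strictly greater).
#' @return the filtered SNP matrix (with a warning when empty).
#' @export
filter_snps <- function(m, region, ped = NULL, call_rate_min = 0.98,
                        maf_min = 0.05, hwe_p_min = 0.001) {
  stopifnot(region[1] < region[2])
  inds <- snp_individuals(m)
  founders <- if (is.null(ped)) inds else intersect(founder_ids(ped), inds)
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (m$pos[i] < region[1] || m$pos[i] > region[2]) next
    g <- unlist(m[i, inds], use.names = FALSE)
    cr <- mean(!is.na(g))
    if (!(cr > call_rate_min)) next
    cnt <- genotype_counts(g)
    na <- 2 * cnt["n_aa"] + cnt["n_ab"]
    nb <- 2 * cnt["n_bb"] + cnt["n_ab"]
    tot <- na + nb
    maf <- if (tot > 0) min(na, nb) / tot else 0
    if (!(maf > maf_min)) next
    gf <- unlist(m[i, founders], use.names = FALSE)
    cf <- genotype_counts(gf)
    p <- hwe_exact_test(cf[["n_aa"]], cf[["n_ab"]], cf[["n_bb"]])
    if (!(p > hwe_p_min)) next
    keep[i] <- TRUE
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no SNP passed the filters")
  out
}

snp_alleles <- function(g) {
  switch(g, AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"),
         stop("unknown genotype code: ", g))
}

#' Mendelian-consistency check of MHC genotypes and SNPs
#'
#' For multi-allele MHC genotypes (haplotype-free mode) an offspring allele
#' found in neither parent's called set is a violation; when a
#' `haplotype_assignment` is supplied, an offspring whose set is not the
#' union of one paternal and one maternal haplotype is additionally flagged.
#' For biallelic SNPs, standard trio inconsistencies (no assignment of one
#' allele from each parent explains the offspring) are reported.  Offspring
#' with a single genotyped parent are checked against that parent only.
#'
#' @param ped pedigree data frame.
#' @param genotypes named list: per individual, the character vector of
#'   called allele ids.
#' @param snps optional SNP matrix data frame for trio checks.
#' @param haplotypes optional haplotype assignment from
#'   [derive_haplotypes()].
#' @return data frame of violations: `individual_id`, `type`, `detail`
#'   (zero rows when fully consistent).
#' @export
check_mendelian <- function(ped, genotypes, snps = NULL, haplotypes = NULL) {
  validate_pedigree(ped)
  out <- list()
  note <- function(ind, type, detail) {
    out[[length(out) + 1L]] <<- data.frame(individual_id = ind, type = type,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ped))) {
    ind <- ped$individual_id[i]
    sire <- ped$sire_id[i]
    dam <- ped$dam_id[i]
    if (is.na(sire) && is.na(dam)) next
    g <- genotypes[[ind]]
    if (is.null(g)) next
    parents <- character(0)
    if (!is.na(sire) && !is.null(genotypes[[sire]])) {
      parents <- c(parents, genotypes[[sire]])
    }
    if (!is.na(dam) && !is.null(genotypes[[dam]])) {
      parents <- c(parents, genotypes[[dam]])
    }
    if (length(parents)) {
      orphan <- setdiff(g, parents)
      for (a in orphan) {
        note(ind, "mhc_allele",
             paste0("allele ", a, " absent from both parents (possible ",
                    "genotyping error or recombination)"))
      }
    }
    if (!is.null(haplotypes) && haplotypes$status == "ok" &&
        !is.na(sire) && !is.na(dam) &&
        identical(sire, haplotypes$sire_id) &&
        identical(dam, haplotypes$dam_id)) {
      ok <- FALSE
      for (p in haplotypes$paternal) {
        for (m in haplotypes$maternal) {
          if (setequal(g, union(p, m))) ok <- TRUE
        }
      }
      if (!ok) {
        note(ind, "mhc_haplotype",
             paste("allele set is not a union of one paternal and one",
                   "maternal haplotype"))
      }
    }
  }
  if (!is.null(snps)) {
    inds <- snp_individuals(snps)
    for (i in seq_len(nrow(ped))) {
      ind <- ped$individual_id[i]
      sire <- ped$sire_id[i]
      dam <- ped$dam_id[i]
      if (!ind %in% inds) next
      has_s <- !is.na(sire) && sire %in% inds
      has_d <- !is.na(dam) && dam %in% inds
      if (!has_s && !has_d) next
      for (r in seq_len(nrow(snps))) {
        go <- snps[r, ind]
        if (is.na(go)) next
        ao <- snp_alleles(go)
        compatible <- FALSE
        gs <- if (has_s) snps[r, sire] else NA
        gd <- if (has_d) snps[r, dam] else NA
        from_s <- if (has_s && !is.na(gs)) unique(snp_alleles(gs)) else
          c("A", "B")
        from_d <- if (has_d && !is.na(gd)) unique(snp_alleles(gd)) else
          c("A", "B")
        for (x in from_s) {
          for (y in from_d) {
            if (setequal_multi(c(x, y), ao)) compatible <- TRUE
          }
        }
        if (!compatible) {
          note(ind, "snp",
               paste0(snps$snp_id[r], ": offspring ", go, " from ",
                      if (has_s) gs else "?", " x ",
                      if (has_d) gd else "?"))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(individual_id = character(0), type = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# multiset equality of two length-2 allele vectors
setequal_multi <- function(x, y) {
  identical(sort(x), sort(y))
}

#' Derive parental MHC haplotypes within a full-sib family
#'
#' Exhaustively searches the 2-partitions of the sire's and the dam's
#' called allele sets for assignments under which every full sib's allele
#' set equals the union of one paternal and one maternal haplotype.  The
#' unique consistent assignment (up to within-parent label swap) is
#' returned; several co-optimal assignments are flagged `"unresolvable"`
#' (e.g. under-determined families), and absence of any consistent
#' assignment returns a violation report.  Duplicated genes are supported:
#' a haplotype may carry more than one allele of a gene, and per-haplotype
#' gene copy counts are reported.
#'
#' @param ped pedigree data frame; the full-sib family is the set of
#'   offspring sharing `sire_id` and `dam_id`.
#' @param genotypes named list of called allele sets, including both
#'   parents.
#' @param sire_id,dam_id the parents (inferred when the pedigree contains
#'   exactly one full-sib family).
#' @param max_alleles refuse exhaustive search above this parent set size.
#' @return list with `status` (`"ok"`, `"unresolvable"` or
#'   `"inconsistent"`), `sire_id`, `dam_id`, `paternal` and `maternal`
#'   (lists of two allele sets, P1/P2 and M1/M2), `offspring` (data frame
#'   of per-offspring haplotype labels), `gene_copies` (per-haplotype gene
#'   copy counts) and `n_solutions`.
#' @export
derive_haplotypes <- function(ped, genotypes, sire_id = NULL, dam_id = NULL,
                              max_alleles = 20L) {
  validate_pedigree(ped)
  fam <- ped[!is.na(ped$sire_id) & !is.na(ped$dam_id), , drop = FALSE]
  if (is.null(sire_id)) {
    key <- paste(fam$sire_id, fam$dam_id)
    top <- names(sort(table(key), decreasing = TRUE))[1L]
    sire_id <- strsplit(top, " ")[[1]][1]
    dam_id <- strsplit(top, " ")[[1]][2]
  }
  offs <- fam$individual_id[fam$sire_id == sire_id & fam$dam_id == dam_id]
  offs <- offs[offs %in% names(genotypes)]
  if (length(offs) < 2L) stop("need at least 2 genotyped full sibs")
  s_set <- genotypes[[sire_id]]
  d_set <- genotypes[[dam_id]]
  if (is.null(s_set) || is.null(d_set)) {
    stop("both parents must be genotyped")
  }
  if (length(s_set) > max_alleles || length(d_set) > max_alleles) {
    stop("parent allele set exceeds ", max_alleles,
         " alleles; exhaustive haplotype search refused")
  }
  parts <- function(set) {
    # all 2-partitions, canonical: first allele always in haplotype 1
    n <- length(set)
    if (n == 0L) return(list(list(character(0), character(0))))
    lapply(seq_len(2^(n - 1)) - 1L, function(code) {
      inh1 <- c(TRUE, as.logical(bitwAnd(bitwShiftR(code,
                                                    seq_len(n - 1) - 1L),
                                         1L)))
      list(set[inh1], set[!inh1])
    })
  }
  gsets <- lapply(genotypes[offs], unique)
  # Necessary per-offspring conditions prune each parent's partitions
  # independently before the joint search: the transmitted half must be a
  # subset of the offspring set, and must contain every offspring allele
  # found in this parent only.  Bitmask-vectorised, so large parent sets
  # stay tractable.
  prune_parts <- function(set, other_set) {
    n <- length(set)
    if (n == 0L) return(list(list(character(0), character(0))))
    full <- bitwShiftL(1L, n) - 1L
    q <- bitwOr(bitwShiftL(seq_len(2^(n - 1)) - 1L, 1L), 1L)
    keep <- rep(TRUE, length(q))
    for (S in gsets) {
      allow <- sum(bitwShiftL(1L, which(set %in% S) - 1L))
      need <- sum(bitwShiftL(1L,
                             which(set %in% setdiff(S, other_set)) - 1L))
      compq <- bitwXor(full, q)
      ok1 <- bitwAnd(need, bitwXor(full, q)) == 0L &
        bitwAnd(q, bitwXor(full, allow)) == 0L
      ok2 <- bitwAnd(need, q) == 0L &
        bitwAnd(compq, bitwXor(full, allow)) == 0L
      keep <- keep & (ok1 | ok2)
      if (!any(keep)) break
    }
    lapply(q[keep], function(code) {
      inh1 <- as.logical(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L))
      list(set[inh1], set[!inh1])
    })
  }
  small <- (length(s_set) + length(d_set)) <= 12L
  if (small) {
    # full enumeration keeps best-scoring diagnostics for tiny families
    sp <- parts(s_set)
    dp <- parts(d_set)
  } else {
    sp <- prune_parts(s_set, d_set)
    dp <- prune_parts(d_set, s_set)
    if (!length(sp) || !length(dp)) {
      return(list(status = "inconsistent", sire_id = sire_id,
                  dam_id = dam_id, paternal = NULL, maternal = NULL,
                  offspring = data.frame(individual_id = offs,
                                         paternal = NA_character_,
                                         maternal = NA_character_,
                                         stringsAsFactors = FALSE),
                  gene_copies = NULL, n_solutions = 0L,
                  n_consistent_offspring = 0L))
    }
  }
  solutions <- list()
  best_score <- -1L
  for (P in sp) {
    for (M in dp) {
      labels <- matrix(NA_character_, length(offs), 2)
      score <- 0L
      for (o in seq_along(offs)) {
        found <- FALSE
        for (i in 1:2) {
          for (j in 1:2) {
            if (setequal(gsets[[o]], union(P[[i]], M[[j]]))) {
              labels[o, ] <- c(paste0("P", i), paste0("M", j))
              found <- TRUE
              break
            }
          }
          if (found) break
        }
        if (found) score <- score + 1L
      }
      if (score > best_score) {
        best_score <- score
        solutions <- list()
      }
      if (score == best_score) {
        solutions[[length(solutions) + 1L]] <-
          list(paternal = P, maternal = M, labels = labels)
      }
    }
  }
  consistent <- best_score == length(offs)
  # collapse solutions identical up to within-parent label swap
  canon <- function(sol) {
    key <- function(h) paste(sort(h), collapse = ",")
    paste(sort(c(key(sol$paternal[[1]]), key(sol$paternal[[2]]))),
          sort(c(key(sol$maternal[[1]]), key(sol$maternal[[2]]))),
          collapse = "|")
  }
  uniq <- !duplicated(vapply(solutions, canon, character(1)))
  solutions <- solutions[uniq]
  sol <- solutions[[1L]]
  status <- if (!consistent) "inconsistent"
  else if (length(solutions) > 1L) "unresolvable" else "ok"
  gene_copies <- lapply(c(sol$paternal, sol$maternal), function(h) {
    if (!length(h)) return(table(character(0)))
    table(parse_gene_label(h))
  })
  names(gene_copies) <- c("P1", "P2", "M1", "M2")
  list(status = status, sire_id = sire_id, dam_id = dam_id,
       paternal = sol$paternal, maternal = sol$maternal,
       offspring = data.frame(individual_id = offs,
                              paternal = sol$labels[, 1],
                              maternal = sol$labels[, 2],
                              stringsAsFactors = FALSE),
       gene_copies = gene_copies, n_solutions = length(solutions),
       n_consistent_offspring = best_score)
}

#' Track parental SNP haplotypes through a family
#'
#' For every SNP at which a parent is heterozygous, the allele transmitted
#' to each offspring is inferred (using the other parent's genotype to
#' resolve ambiguity); the per-parent patterns over informative SNPs are
#' concatenated into flank haplotype labels, which partition the offspring
#' into transmission classes comparable with the MHC haplotype classes.
#'
#' @param m filtered SNP matrix (see [filter_snps()]).
#' @param ped pedigree data frame.
#' @param sire_id,dam_id the family's parents (inferred as in
#'   [derive_haplotypes()] when `NULL`).
#' @return list with `informative` (SNP ids informative for each parent),
#'   `offspring` (data frame: `individual_id`, `paternal_class`,
#'   `maternal_class` -- `NA` when uninformative) and the per-class allele
#'   `patterns`.  Classes are labelled `P1`/`P2` and `M1`/`M2` in order of
#'   first appearance.
#' @export
snp_haplotype_tracking <- function(m, ped, sire_id = NULL, dam_id = NULL) {
  validate_pedigree(ped)
  fam <- ped[!is.na(ped$sire_id) & !is.na(ped$dam_id), , drop = FALSE]
  if (is.null(sire_id)) {
    key <- paste(fam$sire_id, fam$dam_id)
    top <- names(sort(table(key), decreasing = TRUE))[1L]
    sire_id <- strsplit(top, " ")[[1]][1]
    dam_id <- strsplit(top, " ")[[1]][2]
  }
  offs <- fam$individual_id[fam$sire_id == sire_id & fam$dam_id == dam_id]
  inds <- snp_individuals(m)
  offs <- intersect(offs, inds)
  transmitted <- function(parent, other) {
    # matrix SNP x offspring of alleles transmitted by `parent`
    t_mat <- matrix(NA_character_, nrow(m), length(offs))
    info <- logical(nrow(m))
    for (r in seq_len(nrow(m))) {
      gp <- m[r, parent]
      if (is.na(gp) || gp != "AB") next
      go_other <- if (other %in% inds) m[r, other] else NA
      for (o in seq_along(offs)) {
        go <- m[r, offs[o]]
        if (is.na(go)) next
        ao <- snp_alleles(go)
        if (ao[1] == ao[2]) {
          t_mat[r, o] <- ao[1]          # homozygote: transmitted allele clear
        } else if (!is.na(go_other) && go_other != "AB") {
          oth <- unique(snp_alleles(go_other))
          t_mat[r, o] <- setdiff(ao, oth)  # other parent fixes one allele
        }
      }
      info[r] <- any(!is.na(t_mat[r, ]))
    }
    list(mat = t_mat[info, , drop = FALSE], snps = m$snp_id[info])
  }
  classify <- function(tr, prefix) {
    if (nrow(tr$mat) == 0L) {
      return(list(classes = rep(NA_character_, length(offs)),
                  patterns = list()))
    }
    # at parent-heterozygous SNPs the two parental chromosomes differ, so
    # any overlapping informative position decides whether two offspring
    # inherited the same chromosome; transmission classes are the
    # connected components of the pairwise-agreement graph
    informative <- apply(tr$mat, 2, function(v) any(!is.na(v)))
    comp <- seq_along(offs)
    for (i in seq_along(offs)) {
      for (j in seq_along(offs)) {
        if (i >= j || !informative[i] || !informative[j]) next
        both <- !is.na(tr$mat[, i]) & !is.na(tr$mat[, j])
        if (any(both) && all(tr$mat[both, i] == tr$mat[both, j])) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
    classes <- rep(NA_character_, length(offs))
    patterns <- list()
    for (cc in unique(comp[informative])) {
      members <- which(comp == cc & informative)
      pat <- apply(tr$mat[, members, drop = FALSE], 1, function(row) {
        u <- unique(row[!is.na(row)])
        if (length(u) == 1L) u else NA_character_
      })
      patterns[[length(patterns) + 1L]] <- pat
      classes[members] <- paste0(prefix, length(patterns))
    }
    if (length(patterns) > 2L) {
      warning("more than two ", prefix,
              " flank classes: recombination or genotyping error")
    }
    names(patterns) <- paste0(prefix, seq_along(patterns))
    list(classes = classes, patterns = patterns)
  }
  tp <- transmitted(sire_id, dam_id)
  tm <- transmitted(dam_id, sire_id)
  if (nrow(tp$mat) == 0L && nrow(tm$mat) == 0L) {
    warning("no informative SNP in the family")
  }
  cp <- classify(tp, "P")
  cm <- classify(tm, "M")
  list(informative = list(paternal = tp$snps, maternal = tm$snps),
       offspring = data.frame(individual_id = offs,
                              paternal_class = cp$classes,
                              maternal_class = cm$classes,
                              stringsAsFactors = FALSE),
       patterns = list(paternal = cp$patterns, maternal = cm$patterns))
}
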