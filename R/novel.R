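#' Consistent pileup variants against a candidate parent allele
#'
#' Builds per-position base counts from best-stratum read placements on one
#' parent allele and emits a variant wherever an alternative base is carried
#' by at least `min_support` reads and at least `min_fraction` of the
#' pileup.  This automates the visual variant inspection step of the
#' typing workflow.
#'
#' @param parent_id allele the hits refer to.
#' @param hits best-stratum hit data frame (any alleles; filtered to
#'   `parent_id` internally).
#' @param reads read data frame the hits came from.
#' @param cat the [allele_catalogue()].
#' @param min_support minimum reads supporting the alternative base.
#' @param min_fraction minimum supported fraction of the pileup depth.
#' @return data frame of variants: `parent_allele_id`, 0-based `position`,
#'   `ref`, `alt`, `support_reads`, `pileup_depth`, `support_fraction`.
#' @export
pileup_variants <- function(parent_id, hits, reads, cat, min_support = 3L,
                            min_fraction = 0.2) {
  reads <- as_reads(reads)
  parent_seq <- unname(cat$sequences[[parent_id]])
  h <- hits[hits$allele_id == parent_id, , drop = FALSE]
  empty <- data.frame(parent_allele_id = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      support_reads = integer(0), pileup_depth = integer(0),
                      support_fraction = numeric(0), stringsAsFactors = FALSE)
  if (nrow(h) == 0L) return(empty)
  pc <- subset_catalogue(cat, parent_id)
  depth <- compute_coverage(h, pc)[[parent_id]]$depth
  mm <- h[h$mismatches > 0L, , drop = FALSE]
  if (nrow(mm) == 0L) return(empty)
  seqs <- stats::setNames(reads$sequence, paste(reads$read_id, reads$mate))
  obs_pos <- integer(0)
  obs_alt <- character(0)
  for (i in seq_len(nrow(mm))) {
    s <- unname(seqs[[paste(mm$read_id[i], mm$mate[i])]])
    if (mm$orientation[i] == "reverse_complement") s <- revcomp(s)
    d <- cpp_mismatch_positions(s, parent_seq, mm$offset[i])
    obs_pos <- c(obs_pos, d$position)
    obs_alt <- c(obs_alt, d$alt)
  }
  tab <- table(paste(obs_pos, obs_alt, sep = ":"))
  key <- strsplit(names(tab), ":", fixed = TRUE)
  pos <- vapply(key, function(x) as.integer(x[1]), integer(1))
  alt <- vapply(key, `[`, character(1), 2L)
  support <- as.integer(tab)
  dep <- depth[pos + 1L]
  frac <- ifelse(dep > 0L, support / dep, 0)
  keep <- which(support >= min_support & frac >= min_fraction & alt != "N")
  if (!length(keep)) return(empty)
  out <- data.frame(parent_allele_id = parent_id, position = pos[keep],
                    ref = substring(parent_seq, pos[keep] + 1L,
                                    pos[keep] + 1L),
                    alt = alt[keep], support_reads = support[keep],
                    pileup_depth = dep[keep],
                    support_fraction = frac[keep], stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-fragment variant observations: for every fragment (read pair or
# unpaired read) and every variant position covered by one of its
# placements on the parent, the observed state "alt"/"ref"/"other".
fragment_observations <- function(variants, hits, reads, parent_id, cat) {
  reads <- as_reads(reads)
  parent_seq <- unname(cat$sequences[[parent_id]])
  h <- hits[hits$allele_id == parent_id, , drop = FALSE]
  if (nrow(h) == 0L || nrow(variants) == 0L) return(list())
  # one placement per mate: fewest mismatches, then leftmost
  ord <- order(h$read_id, h$mate, h$mismatches, h$offset)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(paste(h$read_id, h$mate)), , drop = FALSE]
  seqs <- stats::setNames(reads$sequence, paste(reads$read_id, reads$mate))
  obs_by_frag <- split(seq_len(nrow(h)), h$read_id)
  lapply(obs_by_frag, function(rows) {
    state <- stats::setNames(rep(NA_character_, nrow(variants)),
                             as.character(variants$position))
    for (r in rows) {
      s <- unname(seqs[[paste(h$read_id[r], h$mate[r])]])
      if (h$orientation[r] == "reverse_complement") s <- revcomp(s)
      off <- h$offset[r]
      w <- h$width[r]
      inwin <- which(variants$position >= off & variants$position < off + w)
      for (v in inwin) {
        base <- substring(s, variants$position[v] - off + 1L,
                          variants$position[v] - off + 1L)
        state[v] <- if (base == variants$alt[v]) "alt"
        else if (base == variants$ref[v]) "ref" else "other"
      }
    }
    state
  })
}

#' Phase pileup variants into candidate haplotypes
#'
#' Builds a co-occurrence graph over the variants of one parent allele: an
#' edge joins two variants jointly observed in the alternative state on at
#' least `min_link` fragments (single reads or mate pairs); an anti-edge
#' joins variants observed in repulsion (one alt, one ref) on at least
#' `min_link` fragments.  Connected components under edges become phased
#' variant sets; a component whose members also carry anti-edge evidence
#' against each other is flagged ambiguous rather than silently merged.
#'
#' @param variants variant data frame from [pileup_variants()].
#' @param hits best-stratum hits on the parent allele.
#' @param reads read data frame.
#' @param cat the [allele_catalogue()].
#' @param min_link minimum joint fragments for an edge/anti-edge.
#' @return list of phased sets, each a list with `parent_allele_id`,
#'   `variants` (rows of `variants`, positions strictly increasing),
#'   `linking_evidence` and `ambiguous`.  The pairwise `links`/`anti`
#'   matrices are attached as attributes.
#' @export
phase_variants <- function(variants, hits, reads, cat, min_link = 2L) {
  if (nrow(variants) == 0L) return(structure(list(), links = NULL))
  parent_id <- variants$parent_allele_id[1L]
  obs <- fragment_observations(variants, hits, reads, parent_id, cat)
  nv <- nrow(variants)
  links <- matrix(0L, nv, nv)
  anti <- matrix(0L, nv, nv)
  for (state in obs) {
    seen <- which(!is.na(state))
    if (length(seen) < 2L) next
    for (a in seq_along(seen)[-length(seen)]) {
      for (b in seq((a + 1L), length(seen))) {
        i <- seen[a]; j <- seen[b]
        if (state[i] == "alt" && state[j] == "alt") {
          links[i, j] <- links[i, j] + 1L
        } else if ((state[i] == "alt" && state[j] == "ref") ||
                   (state[i] == "ref" && state[j] == "alt")) {
          anti[i, j] <- anti[i, j] + 1L
        }
      }
    }
  }
  links <- links + t(links)
  anti <- anti + t(anti)
  edge <- links >= min_link
  antie <- anti >= min_link
  # connected components under positive edges
  comp <- seq_len(nv)
  repeat {
    changed <- FALSE
    for (i in seq_len(nv)) {
      for (j in seq_len(nv)) {
        if (edge[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sets <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    idx <- idx[order(variants$position[idx])]
    amb <- any(antie[idx, idx, drop = FALSE])
    list(parent_allele_id = parent_id,
         variants = variants[idx, , drop = FALSE],
         linking_evidence = sum(links[idx, idx, drop = FALSE]) / 2,
         ambiguous = amb)
  })
  ord <- order(vapply(sets, function(s) min(s$variants$position), numeric(1)))
  structure(sets[ord], links = links, anti = anti)
}

#' Apply a phased variant set to its parent sequence
#'
#' Substitutions only: the candidate has the parent's length.
#'
#' @param parent_seq parent cDNA sequence (or an allele id with `cat`).
#' @param phased one phased set from [phase_variants()], or a variant data
#'   frame.
#' @param cat optional [allele_catalogue()] to resolve an allele id.
#' @return the candidate sequence.
#' @export
reconstruct_variant_allele <- function(parent_seq, phased, cat = NULL) {
  if (!is.null(cat)) parent_seq <- unname(cat$sequences[[parent_seq]])
  v <- if (is.data.frame(phased)) phased else phased$variants
  stopifnot(nrow(v) >= 1L, !anyDuplicated(v$position))
  s <- strsplit(parent_seq, "")[[1]]
  stopifnot(all(s[v$position + 1L] == v$ref))
  s[v$position + 1L] <- v$alt
  paste(s, collapse = "")
}

#' Validate a candidate novel allele
#'
#' A candidate is accepted iff (a) its sequence is distinct from every
#' catalogue allele, (b) a zero-mismatch re-alignment of the reads covers
#' the candidate completely, and (c) its translation yields an open reading
#' frame, or -- for a non-classical assignment -- the candidate shows the
#' documented non-classical features (early stop codon or a VPI/IPI/VLIK
#' transmembrane motif).
#'
#' @param candidate_seq candidate cDNA sequence.
#' @param cat the current [allele_catalogue()].
#' @param reads read data frame of the individual.
#' @param class_kind intended class of the candidate.
#' @param config a [typing_config()].
#' @return list with `accept` (logical), `reason` (`"ok"`, `"duplicate"`,
#'   `"incomplete coverage"` or `"no ORF / no non-classical features"`) and
#'   the `protein_report`.
#' @export
validate_novel <- function(candidate_seq, cat, reads,
                           class_kind = "classical",
                           config = typing_config()) {
  reads <- as_reads(reads)
  report <- translate_allele(candidate_seq)
  dup <- which(cat$sequences == candidate_seq)
  if (length(dup)) {
    return(list(accept = FALSE,
                reason = paste0("duplicate (", names(cat$sequences)[dup[1]],
                                ")"),
                protein_report = report))
  }
  tmp <- allele_catalogue("candidate", candidate_seq,
                          class_kind = class_kind)
  idx <- build_index(tmp, config$k)
  hits <- align_reads(reads, idx, config$max_mismatch_exact, "all_valid")
  prof <- compute_coverage(assign_reads(hits, "all"), tmp,
                           config$min_depth)[["candidate"]]
  if (!fully_covered(prof)) {
    return(list(accept = FALSE, reason = "incomplete coverage",
                protein_report = report))
  }
  features_ok <- report$has_orf ||
    (class_kind == "nonclassical" &&
       (report$early_stop || report$tm_motif != "none"))
  if (!features_ok) {
    return(list(accept = FALSE,
                reason = "no ORF / no non-classical features",
                protein_report = report))
  }
  list(accept = TRUE, reason = "ok", protein_report = report)
}

# Variant-based discovery against one candidate parent: pileup, phasing,
# then candidate sequences from anti-edge-free unions of phased components,
# tried smallest-first so that a variant set already explained by an
# accepted allele is not re-combined (parsimony).
discover_from_parent <- function(parent_id, hits, reads, cat, config) {
  variants <- pileup_variants(parent_id, hits, reads, cat,
                              config$min_support, config$min_fraction)
  accepted <- character(0)
  rejected <- list()
  if (nrow(variants) == 0L) {
    return(list(accepted = accepted, rejected = rejected))
  }
  sets <- phase_variants(variants, hits, reads, cat, config$min_link)
  anti <- attr(sets, "anti")
  amb <- vapply(sets, `[[`, logical(1), "ambiguous")
  for (s in sets[amb]) {
    rejected[[length(rejected) + 1L]] <-
      list(parent = parent_id, reason = "ambiguous phasing",
           positions = s$variants$position)
  }
  sets <- sets[!amb]
  if (!length(sets)) return(list(accepted = accepted, rejected = rejected))
  vrows <- lapply(sets, function(s) match(s$variants$position,
                                          variants$position))
  compat <- function(subset_idx) {
    rows <- unlist(vrows[subset_idx])
    all(anti[rows, rows] < config$min_link)
  }
  explained <- logical(length(sets))
  class_kind <- cat$alleles$class_kind[cat$alleles$allele_id == parent_id]
  max_size <- min(length(sets), 6L)
  for (size in seq_len(max_size)) {
    open <- which(!explained)
    if (length(open) < size) break
    for (sub in utils::combn(open, size, simplify = FALSE)) {
      if (any(explained[sub])) next
      if (size > 1L && !compat(sub)) next
      v <- do.call(rbind, lapply(sets[sub], `[[`, "variants"))
      v <- v[order(v$position), , drop = FALSE]
      if (anyDuplicated(v$position)) next
      cand <- reconstruct_variant_allele(unname(cat$sequences[[parent_id]]),
                                         v)
      val <- validate_novel(cand, cat, reads, class_kind, config)
      if (val$accept) {
        accepted <- c(accepted, cand)
        explained[sub] <- TRUE
        # extend in-loop so later duplicates are rejected
        cat$sequences <- c(cat$sequences,
                           stats::setNames(cand, paste0(".cand",
                                                        length(accepted))))
      } else {
        rejected[[length(rejected) + 1L]] <-
          list(parent = parent_id, reason = val$reason,
               positions = v$position)
      }
    }
  }
  list(accepted = accepted, rejected = rejected)
}

#' Assemble a novel allele de novo by greedy overlap extension
#'
#' Starting from a seed read carrying recurrent unexplained sequence, the
#' contig is extended base by base in both directions.  At every step the
#' reads overlapping the contig terminus by at least `min_overlap` exact
#' bases vote on the next base; extension stops when no read overlaps, and
#' fails when a second branch gains appreciable support.  This mirrors
#' reading the novel allele directly off assembled reads, mate by mate and
#' overlap by overlap.
#'
#' @param seed_reads character vector of seed read sequences (the first one
#'   starts the contig).
#' @param all_reads read data frame (or character vector) to assemble from;
#'   in the pipeline this is the set of reads unexplained by the catalogue.
#' @param min_overlap minimum exact overlap for a read to vote.
#' @param min_contig minimum contig length for success.
#' @param branch_frac second-branch vote fraction above which the extension
#'   is ambiguous.
#' @param max_length safety bound on contig growth.
#' @return list with `status` (`"ok"`, `"ambiguous"` or `"fragmentary"`) and
#'   `contig`.
#' @export
assemble_de_novo <- function(seed_reads, all_reads, min_overlap = 25L,
                             min_contig = 200L, branch_frac = 0.25,
                             max_length = 100000L) {
  if (is.data.frame(all_reads)) all_reads <- all_reads$sequence
  stopifnot(length(seed_reads) >= 1L)
  pool <- c(all_reads, revcomp(all_reads))
  pool <- pool[nchar(pool) > min_overlap]
  # overlap map: every min_overlap-mer of every pooled read
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(pool)) {
    s <- pool[i]
    np <- nchar(s) - min_overlap + 1L
    kms <- substring(s, seq_len(np), seq_len(np) + min_overlap - 1L)
    for (p in seq_len(np)) {
      key <- kms[p]
      env[[key]] <- c(env[[key]], i * 1000L + p)  # read index and position
    }
  }
  vote_next <- function(contig) {
    key <- substring(contig, nchar(contig) - min_overlap + 1L,
                     nchar(contig))
    entries <- env[[key]]
    if (is.null(entries)) return(NULL)
    ridx <- entries %/% 1000L
    rpos <- entries %% 1000L
    nxt <- substring(pool[ridx], rpos + min_overlap, rpos + min_overlap)
    nxt[nzchar(nxt)]
  }
  extend_right <- function(contig) {
    repeat {
      if (nchar(contig) > max_length) return(list(contig = contig,
                                                  status = "ok"))
      votes <- vote_next(contig)
      if (is.null(votes) || !length(votes)) {
        return(list(contig = contig, status = "ok"))
      }
      tab <- sort(table(votes), decreasing = TRUE)
      if (length(tab) > 1L) {
        second <- as.integer(tab[2L])
        if (second >= 2L && second / sum(tab) >= branch_frac) {
          return(list(contig = contig, status = "ambiguous"))
        }
      }
      contig <- paste0(contig, names(tab)[1L])
    }
  }
  contig <- seed_reads[1L]
  r <- extend_right(contig)
  if (r$status == "ambiguous") {
    return(list(status = "ambiguous", contig = r$contig))
  }
  l <- extend_right(revcomp(r$contig))
  if (l$status == "ambiguous") {
    return(list(status = "ambiguous", contig = revcomp(l$contig)))
  }
  contig <- revcomp(l$contig)
  if (nchar(contig) < min_contig) {
    return(list(status = "fragmentary", contig = contig))
  }
  list(status = "ok", contig = contig)
}

# De novo discovery pass: seed on k-mers absent from the catalogue that
# recur in >= min_support unexplained reads, assemble, validate, and add
# contigs whose protein features match the current class pass.
denovo_pass <- function(reads, cat, relaxed_hits, phase, config) {
  added <- character(0)
  rejected <- list()
  reads <- as_reads(reads)
  aligned <- unique(paste(relaxed_hits$read_id, relaxed_hits$mate))
  un <- reads[!paste(reads$read_id, reads$mate) %in% aligned, , drop = FALSE]
  if (nrow(un) < config$min_support) {
    return(list(catalogue = cat, added = added, rejected = rejected))
  }
  index <- build_index(cat, config$k)
  k <- config$k
  repeat {
    # recurrent catalogue-absent k-mers among still-unexplained reads
    seqs <- un$sequence
    canon <- function(km) pmin(km, revcomp(km))
    km_by_read <- lapply(seqs, function(s) {
      np <- nchar(s) - k + 1L
      if (np < 1L) return(character(0))
      unique(canon(substring(s, seq_len(np), seq_len(np) + k - 1L)))
    })
    tab <- table(unlist(km_by_read))
    tab <- tab[as.integer(tab) >= config$min_support]
    if (!length(tab)) break
    tab <- sort(tab, decreasing = TRUE)
    absent <- names(tab)[vapply(names(tab), function(km) {
      nrow(cpp_index_lookup(index$ptr, km)) == 0L &&
        nrow(cpp_index_lookup(index$ptr, revcomp(km))) == 0L
    }, logical(1))]
    if (!length(absent)) break
    seed_km <- absent[[1L]]
    carries <- vapply(km_by_read, function(x) seed_km %in% x, logical(1))
    seed_reads <- seqs[carries]
    # extension walks through every read of the individual (overlaps and
    # mates), not just unexplained ones: reads from low-divergence
    # stretches of the novel allele align to the parent yet still belong
    # to the contig
    asm <- assemble_de_novo(seed_reads, reads, config$min_overlap,
                            config$min_contig, config$branch_frac)
    if (asm$status != "ok") {
      rejected[[length(rejected) + 1L]] <-
        list(parent = NA_character_, reason = paste("de novo", asm$status))
      break
    }
    # strand of the contig is arbitrary: accept whichever orientation
    # passes protein validation
    accepted_now <- FALSE
    for (cand in c(asm$contig, revcomp(asm$contig))) {
      rep <- translate_allele(cand)
      kind <- if (rep$early_stop || rep$tm_motif != "none") "nonclassical"
      else "classical"
      if (kind != phase) next
      val <- validate_novel(cand, cat, reads, kind, config)
      if (val$accept) {
        res <- add_novel_allele(cat, cand, parent_id = NULL,
                                lab_tag = config$lab_tag, class_kind = kind)
        cat <- res$catalogue
        added <- c(added, res$allele_id)
        index <- build_index(cat, config$k)
        accepted_now <- TRUE
        break
      }
    }
    if (!accepted_now) {
      rejected[[length(rejected) + 1L]] <-
        list(parent = NA_character_,
             reason = paste("de novo contig rejected or out of phase"))
      break
    }
    # drop reads explained by the extended catalogue and continue seeding
    h <- align_reads(un, index, config$max_mismatch_relaxed, "best_only")
    expl <- unique(paste(h$read_id, h$mate))
    un <- un[!paste(un$read_id, un$mate) %in% expl, , drop = FALSE]
    if (nrow(un) < config$min_support) break
  }
  list(catalogue = cat, added = added, rejected = rejected)
}

#' Write a variant report as TSV
#'
#' @param variants data frame from [pileup_variants()], optionally with a
#'   `phase_set` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_report <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
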