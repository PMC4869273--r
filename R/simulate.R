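#' Simulation configuration
#'
#' Defaults emulate the sequencing design and haplotype structure the
#' typing method assumes: 61-nt paired-end reads, ~1.1-kb class I cDNA
#' alleles, classical genes 1-6 and non-classical genes NC1-NC5 with
#' copy-number-variable haplotypes (2-3 classical and 2-5 non-classical
#' gene copies per haplotype), co-dominant unequal allele expression and a
#' substitution-only sequencing error model.
#'
#' @param n_genes_classical,n_genes_nonclassical gene counts per class.
#' @param alleles_per_gene database alleles simulated per gene.
#' @param allele_length cDNA length in nt.
#' @param divergence per-base substitution probability of an allele
#'   relative to its gene's ancestral sequence.
#' @param nc_feature_prob probability that a non-classical allele carries a
#'   characteristic feature (early stop codon or transmembrane motif).
#' @param nc_motif_prob given a feature, probability of a motif (vs early
#'   stop).
#' @param copies_classical,copies_nonclassical inclusive ranges of gene
#'   copies per haplotype and class.
#' @param read_length read length in nt (61-cycle sequencing).
#' @param fragment_mean,fragment_sd fragment length distribution in nt.
#' @param error_rate per-base substitution sequencing error probability.
#' @param n_pairs read pairs per individual.
#' @param dirichlet_conc concentration of the symmetric Dirichlet from
#'   which per-individual expression weights are drawn.
#' @param share_weights share the expression weight vector across
#'   individuals with an identical genotype (emulating the cross-individual
#'   consistency of allele-level expression).
#' @param decoy_fraction fraction of extra random (non-MHC) read pairs,
#'   exercising the contract that unaligned reads are ignored.
#' @param seed master seed: fixed seed implies byte-identical outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes_classical = 6L, n_genes_nonclassical = 5L,
                       alleles_per_gene = 4L, allele_length = 1100L,
                       divergence = 0.02, nc_feature_prob = 1,
                       nc_motif_prob = 0.5, copies_classical = c(2L, 3L),
                       copies_nonclassical = c(2L, 5L), read_length = 61L,
                       fragment_mean = 200, fragment_sd = 30,
                       error_rate = 0.003, n_pairs = 20000L,
                       dirichlet_conc = 5, share_weights = FALSE,
                       decoy_fraction = 0, seed = 1L) {
  stopifnot(read_length <= fragment_mean, error_rate >= 0, error_rate <= 1,
            divergence >= 0, divergence <= 1)
  structure(as.list(environment()), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# random open reading frame of `len` nt: ATG + non-stop codons + final stop,
# plus 0-2 trailing bases so the total length is exactly `len`
random_orf <- function(len) {
  ncod <- len %/% 3L
  stopifnot(ncod >= 3L)
  pool <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  pool <- setdiff(pool, STOP_CODONS)
  body <- sample(pool, ncod - 2L, replace = TRUE)
  tail_len <- len - 3L * ncod
  tail <- if (tail_len > 0) {
    paste(sample(BASES, tail_len, replace = TRUE), collapse = "")
  } else ""
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L), tail)
}

# in-frame positions (0-based) that must not be touched to preserve the
# allele's reading-frame structure and class features
protected_positions <- function(seq) {
  len <- nchar(seq)
  ncod <- len %/% 3L
  prot <- c(0:2, (3L * (ncod - 1L)):(3L * ncod - 1L))  # start + final codon
  rep_ <- translate_allele(seq)
  if (rep_$early_stop) {
    # protect the premature stop codon
    aa_len <- nchar(rep_$aa_sequence)
    prot <- c(prot, (3L * aa_len):(3L * aa_len + 2L))
  }
  if (rep_$tm_motif != "none") {
    at <- as.integer(regexpr(rep_$tm_motif, rep_$aa_sequence,
                             fixed = TRUE)) - 1L
    span <- nchar(rep_$tm_motif)
    prot <- c(prot, (3L * at):(3L * (at + span) - 1L))
  }
  unique(prot[prot < len])
}

has_premature_stop <- function(seq, skip_aa = integer(0)) {
  ncod <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  stops <- which(codons %in% STOP_CODONS)
  stops <- setdiff(stops, c(ncod, skip_aa))
  length(stops) > 0L
}

# apply exactly n substitutions outside protected positions, never creating
# a new in-frame premature stop codon (existing early stops stay protected)
mutate_sequence <- function(seq, n, protected = protected_positions(seq),
                            max_tries = 200L) {
  len <- nchar(seq)
  rep0 <- translate_allele(seq)
  skip <- if (rep0$early_stop) nchar(rep0$aa_sequence) + 1L else integer(0)
  free <- setdiff(seq_len(len) - 1L, protected)
  stopifnot(length(free) >= n)
  for (try in seq_len(max_tries)) {
    pos <- sample(free, n)
    s <- strsplit(seq, "")[[1]]
    for (p in pos) {
      s[p + 1L] <- sample(setdiff(BASES, s[p + 1L]), 1L)
    }
    cand <- paste(s, collapse = "")
    if (!has_premature_stop(cand, skip)) {
      return(list(sequence = cand, positions = sort(pos)))
    }
  }
  stop("could not place ", n, " substitutions without a premature stop")
}

#' Simulate an MHC class I allele catalogue
#'
#' Generates, per gene, an ancestral ORF and derives database alleles from
#' it by seeded substitutions at the configured divergence.  Non-classical
#' alleles receive an early stop codon or a VPI/IPI/VLIK transmembrane
#' motif with probability `nc_feature_prob`, so that they always pass the
#' non-classical feature check of [translate_allele()].  Deterministic
#' under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `catalogue` (an [allele_catalogue()]) and `truth`
#'   (ancestral sequences and the config).
#' @export
simulate_catalogue <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    ids <- character(0)
    seqs <- character(0)
    kinds <- character(0)
    genes <- c(as.character(seq_len(cfg$n_genes_classical)),
               if (cfg$n_genes_nonclassical > 0L)
                 paste0("NC", seq_len(cfg$n_genes_nonclassical)))
    kind_of <- rep(c("classical", "nonclassical"),
                   c(cfg$n_genes_classical, cfg$n_genes_nonclassical))
    ancestors <- stats::setNames(vector("list", length(genes)), genes)
    for (gi in seq_along(genes)) {
      anc <- random_orf(cfg$allele_length)
      if (kind_of[gi] == "nonclassical") {
        anc <- add_nc_feature(anc, cfg)
      }
      ancestors[[gi]] <- anc
      for (ai in seq_len(cfg$alleles_per_gene)) {
        for (try in 1:50) {
          n <- stats::rbinom(1L, nchar(anc), cfg$divergence)
          n <- max(n, 1L)
          cand <- mutate_sequence(anc, n)$sequence
          if (!cand %in% seqs) break
          if (try == 50) stop("allele collision: divergence too low")
        }
        ids <- c(ids, sprintf("BoLA-%s*%05d", genes[gi], ai * 100L + 1L))
        seqs <- c(seqs, cand)
        kinds <- c(kinds, kind_of[gi])
      }
    }
    cat <- allele_catalogue(ids, seqs, class_kind = kinds,
                            version_tag = "sim-v1")
    list(catalogue = cat, truth = list(ancestors = ancestors, config = cfg))
  })
}

# give a non-classical ancestral ORF its characteristic feature
add_nc_feature <- function(seq, cfg) {
  if (stats::runif(1) >= cfg$nc_feature_prob) return(seq)
  ncod <- nchar(seq) %/% 3L
  s <- strsplit(seq, "")[[1]]
  if (stats::runif(1) < cfg$nc_motif_prob) {
    # transmembrane motif near the 3' end (around 85 % of the protein)
    motif <- sample(c("VPI", "IPI", "VLIK"), 1L)
    codons <- switch(motif, VPI = c("GTT", "CCT", "ATT"),
                     IPI = c("ATT", "CCT", "ATT"),
                     VLIK = c("GTT", "CTT", "ATT", "AAA"))
    at <- floor(ncod * 0.85)  # 1-based codon index
    nt <- unlist(strsplit(codons, ""))
    s[(3L * (at - 1L) + 1L):(3L * (at - 1L) + length(nt))] <- nt
  } else {
    at <- floor(ncod * 0.6)
    s[(3L * (at - 1L) + 1L):(3L * at)] <- strsplit(
      sample(STOP_CODONS, 1L), "")[[1]]
  }
  paste(s, collapse = "")
}

#' Spawn novel alleles withheld from the public catalogue
#'
#' Each novel allele is a catalogue parent with `k` substitutions, `k`
#' drawn from `substitutions_range` (small `k` is visible to the relaxed
#' aligner; large `k` exercises the de novo assembly path).  Substitutions
#' preserve the parent's reading-frame structure and class features.
#'
#' @param cat an [allele_catalogue()].
#' @param n_novel number of novel alleles.
#' @param substitutions_range integer vector of admissible `k`.
#' @param seed seed.
#' @param parents optional parent allele ids (sampled when `NULL`).
#' @param positions optional list of fixed 0-based substitution positions
#'   per novel allele (overrides `substitutions_range`).
#' @return list with `novel` (data frame: `novel_id`, `parent_id`,
#'   `class_kind`, `n_substitutions`, `positions`) and `sequences` (named
#'   character, withheld from the catalogue).
#' @export
spawn_novel_alleles <- function(cat, n_novel, substitutions_range = 1:3,
                                seed = 1L, parents = NULL,
                                positions = NULL) {
  stopifnot(nrow(cat$alleles) > 0L, n_novel >= 1L)
  if (any(substitutions_range < 1L)) {
    stop("substitutions_range must be >= 1: zero substitutions would ",
         "duplicate the parent")
  }
  with_seed(seed, {
    if (is.null(parents)) {
      parents <- sample(cat$alleles$allele_id, n_novel,
                        replace = n_novel > nrow(cat$alleles))
    }
    stopifnot(length(parents) == n_novel)
    seqs <- character(0)
    rows <- list()
    for (i in seq_len(n_novel)) {
      pseq <- unname(cat$sequences[[parents[i]]])
      kind <- cat$alleles$class_kind[cat$alleles$allele_id == parents[i]]
      prot <- protected_positions(pseq)
      for (try in 1:100) {
        if (!is.null(positions)) {
          pos <- positions[[i]]
          stopifnot(!any(pos %in% prot))
          s <- strsplit(pseq, "")[[1]]
          for (p in pos) s[p + 1L] <- sample(setdiff(BASES, s[p + 1L]), 1L)
          cand <- paste(s, collapse = "")
          rep0 <- translate_allele(pseq)
          skip <- if (rep0$early_stop) nchar(rep0$aa_sequence) + 1L
          else integer(0)
          if (has_premature_stop(cand, skip)) next
        } else {
          k <- if (length(substitutions_range) == 1L) substitutions_range
          else sample(substitutions_range, 1L)
          m <- mutate_sequence(pseq, k, prot)
          cand <- m$sequence
          pos <- m$positions
        }
        if (!cand %in% c(cat$sequences, seqs)) break
        if (try == 100) stop("could not spawn a distinct novel allele")
      }
      nid <- paste0(parents[i], "|nov", i)
      seqs <- c(seqs, stats::setNames(cand, nid))
      rows[[i]] <- data.frame(novel_id = nid, parent_id = parents[i],
                              class_kind = kind,
                              n_substitutions = length(pos),
                              positions = paste(pos, collapse = ","),
                              stringsAsFactors = FALSE)
    }
    list(novel = do.call(rbind, rows), sequences = seqs)
  })
}

#' Simulate a two-generation family with MHC haplotypes and SNP flanks
#'
#' Builds founder haplotypes with per-class gene copy counts drawn from the
#' configured ranges (gene duplications allowed), assigns each full-sib and
#' half-sib offspring one haplotype per parent uniformly, and simulates a
#' biallelic SNP flank panel phased with the founder chromosomes (default:
#' seven SNPs in the class I region of bovine chromosome 23).
#'
#' @param pool named character vector of allele sequences available to
#'   haplotypes (catalogue sequences, possibly plus withheld novel ones).
#' @param cat the [allele_catalogue()] that assigns classes (novel truth
#'   alleles may be absent: their class comes from `extra_classes`).
#' @param cfg a [sim_config()].
#' @param n_fullsib,n_halfsib offspring counts (half sibs share the sire).
#' @param extra_classes named character vector of classes for pool entries
#'   not in the catalogue.
#' @param n_snps SNP flank panel size.
#' @param snp_region bp range of the simulated SNP positions.
#' @param must_include allele ids that must be placed on some transmitted
#'   founder haplotype (e.g. withheld novel alleles).
#' @return list with `pedigree`, `haplotypes` (per founder, two allele-id
#'   sets), `genotypes` (named list of allele sets, founders included),
#'   `transmissions` (data frame of inherited haplotype indices),
#'   `snp` (SNP matrix data frame) and `snp_phase` (founder chromosome
#'   alleles).
#' @export
simulate_family <- function(pool, cat, cfg = sim_config(), n_fullsib = 8L,
                            n_halfsib = 3L, extra_classes = character(0),
                            n_snps = 7L,
                            snp_region = c(27545231, 30222836),
                            must_include = character(0)) {
  class_of <- function(ids) {
    out <- cat$alleles$class_kind[match(ids, cat$alleles$allele_id)]
    out[is.na(out)] <- extra_classes[ids[is.na(out)]]
    out
  }
  with_seed(cfg$seed + 1L, {
    ids <- names(pool)
    classical <- ids[class_of(ids) == "classical"]
    nonclassical <- ids[class_of(ids) == "nonclassical"]
    used <- character(0)
    draw_haplotype <- function(force = character(0)) {
      n_c <- sample(cfg$copies_classical[1]:cfg$copies_classical[2], 1L)
      n_n <- sample(cfg$copies_nonclassical[1]:cfg$copies_nonclassical[2],
                    1L)
      avail_c <- setdiff(classical, used)
      avail_n <- setdiff(nonclassical, used)
      fc <- intersect(force, classical)
      fn <- intersect(force, nonclassical)
      # haplotypes are drawn disjoint across founders (so that families
      # are identifiable); copy counts are capped by the remaining pool
      take_c <- min(max(0L, n_c - length(fc)), length(setdiff(avail_c, fc)))
      take_n <- min(max(0L, n_n - length(fn)), length(setdiff(avail_n, fn)))
      h <- c(fc, sample(setdiff(avail_c, fc), take_c),
             fn, sample(setdiff(avail_n, fn), take_n))
      used <<- c(used, h)
      h
    }
    n_dams <- 1L + (n_halfsib > 0L)
    founders <- c("SIRE", paste0("DAM", seq_len(n_dams)))
    haplos <- list()
    # withheld novel alleles ride on the first haplotype of each parent,
    # which every offspring can inherit
    forced <- split(must_include,
                    rep_len(founders, length.out = length(must_include)))
    for (f in founders) {
      haplos[[f]] <- list(draw_haplotype(forced[[f]] %||% character(0)),
                          draw_haplotype())
    }
    ped <- data.frame(individual_id = founders,
                      sire_id = NA_character_, dam_id = NA_character_,
                      group_label = "founder", stringsAsFactors = FALSE)
    genotypes <- lapply(haplos, function(h) union(h[[1]], h[[2]]))
    trans <- list()
    offspring <- character(0)
    add_offspring <- function(id, dam, group) {
      si <- sample(1:2, 1L)
      di <- sample(1:2, 1L)
      genotypes[[id]] <<- union(haplos[["SIRE"]][[si]], haplos[[dam]][[di]])
      ped <<- rbind(ped, data.frame(individual_id = id, sire_id = "SIRE",
                                    dam_id = dam, group_label = group,
                                    stringsAsFactors = FALSE))
      trans[[id]] <<- data.frame(individual_id = id, sire_chrom = si,
                                 dam_id = dam, dam_chrom = di,
                                 stringsAsFactors = FALSE)
      offspring <<- c(offspring, id)
    }
    for (i in seq_len(n_fullsib)) {
      add_offspring(sprintf("F2_%02d", i), "DAM1", "fullsib")
    }
    for (i in seq_len(n_halfsib)) {
      add_offspring(sprintf("HS_%02d", i), "DAM2", "halfsib")
    }
    # SNP flank panel phased with the founder chromosomes; re-drawn until
    # both DAM1-family parents are informative somewhere
    pos <- sort(snp_region[1] +
                  sample.int(snp_region[2] - snp_region[1] + 1L,
                             n_snps) - 1L)
    repeat {
      phase <- lapply(founders, function(f) {
        list(sample(c("A", "B"), n_snps, replace = TRUE),
             sample(c("A", "B"), n_snps, replace = TRUE))
      })
      names(phase) <- founders
      het_s <- any(phase[["SIRE"]][[1]] != phase[["SIRE"]][[2]])
      het_d <- any(phase[["DAM1"]][[1]] != phase[["DAM1"]][[2]])
      if (het_s && het_d) break
    }
    geno_code <- function(a1, a2) {
      ifelse(a1 == a2, paste0(a1, a2),
             ifelse(a1 < a2, paste0(a1, a2), paste0(a2, a1)))
    }
    snp <- data.frame(snp_id = sprintf("rs%07d", seq_len(n_snps) * 101L),
                      chrom = "BTA23", pos = pos, stringsAsFactors = FALSE)
    for (f in founders) {
      snp[[f]] <- geno_code(phase[[f]][[1]], phase[[f]][[2]])
    }
    for (id in offspring) {
      tr <- trans[[id]]
      a1 <- phase[["SIRE"]][[tr$sire_chrom]]
      a2 <- phase[[tr$dam_id]][[tr$dam_chrom]]
      snp[[id]] <- geno_code(a1, a2)
    }
    list(pedigree = ped, haplotypes = haplos, genotypes = genotypes,
         transmissions = do.call(rbind, trans), snp = snp,
         snp_phase = phase)
  })
}

#' Draw per-individual expression weights
#'
#' Symmetric Dirichlet over the individual's alleles; individuals with an
#' identical genotype share one weight vector when `cfg$share_weights`.
#'
#' @param genotypes named list of allele-id sets.
#' @param cfg a [sim_config()].
#' @param seed seed (defaults to the config seed).
#' @return named list of named weight vectors summing to 1.
#' @export
simulate_weights <- function(genotypes, cfg = sim_config(),
                             seed = cfg$seed + 2L) {
  with_seed(seed, {
    cache <- list()
    lapply(genotypes, function(g) {
      g <- sort(g)
      key <- paste(g, collapse = "|")
      if (cfg$share_weights && !is.null(cache[[key]])) {
        return(cache[[key]])
      }
      x <- stats::rgamma(length(g), shape = cfg$dirichlet_conc)
      w <- stats::setNames(x / sum(x), g)
      if (cfg$share_weights) cache[[key]] <<- w
      w
    })
  })
}

#' Simulate paired-end reads from one individual's expressed alleles
#'
#' Fragments are drawn from the alleles with probability proportional to
#' the expression weights; both 61-nt mates are read from the fragment
#' ends, mate 2 reverse-complemented; substitution errors are applied at
#' the configured rate; qualities are constant.  Fragments longer than the
#' source allele are truncated to it (and counted in `n_truncated`).
#'
#' @param weights named weight vector over the individual's alleles.
#' @param pool named character vector resolving allele ids to sequences.
#' @param cfg a [sim_config()].
#' @param seed seed.
#' @param individual_id prefix of the generated read ids.
#' @param n_pairs number of pairs (defaults to `cfg$n_pairs`).
#' @return list with `reads` (data frame: `read_id`, `mate`, `sequence`),
#'   `truth` (data frame of source allele, fragment coordinates and mate
#'   offsets/orientations) and `n_truncated`.
#' @export
simulate_reads <- function(weights, pool, cfg = sim_config(), seed = 1L,
                           individual_id = "sample", n_pairs = cfg$n_pairs) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, all(names(weights) %in%
                                                names(pool)))
  rl <- cfg$read_length
  with_seed(seed, {
    empty <- data.frame(read_id = character(0), mate = character(0),
                        sequence = character(0), stringsAsFactors = FALSE)
    if (n_pairs == 0L) {
      return(list(reads = empty, truth = data.frame(), n_truncated = 0L))
    }
    n_decoy <- round(n_pairs * cfg$decoy_fraction)
    src <- sample(names(weights), n_pairs, replace = TRUE, prob = weights)
    lens <- nchar(pool[src])
    flen <- pmax(rl, round(stats::rnorm(n_pairs, cfg$fragment_mean,
                                        cfg$fragment_sd)))
    trunc <- flen > lens
    flen <- pmin(flen, lens)
    # fragmentation of whole cDNA molecules: fragments at the molecule
    # termini are truncated (raw starts may overhang the 5' end, raw ends
    # the 3' end), so terminal bases are covered at near-interior depth --
    # the regime the complete-coverage criterion assumes
    raw <- floor(stats::runif(n_pairs) * (lens + flen - 2 * rl + 1)) -
      (flen - rl)                              # 0-based, may be negative
    start <- pmax(raw, 0L)
    fend <- pmin(raw + flen, lens)
    flen <- fend - start
    frag <- substring(pool[src], start + 1L, start + flen)
    m1 <- substring(frag, 1L, rl)
    m2 <- revcomp(substring(frag, flen - rl + 1L, flen))
    add_errors <- function(seqs) {
      if (cfg$error_rate == 0) return(seqs)
      n <- length(seqs)
      nerr <- stats::rbinom(n, rl, cfg$error_rate)
      idx <- which(nerr > 0L)
      for (i in idx) {
        s <- strsplit(seqs[i], "")[[1]]
        at <- sample.int(rl, nerr[i])
        for (p in at) s[p] <- sample(setdiff(BASES, s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
      }
      seqs
    }
    m1 <- add_errors(m1)
    m2 <- add_errors(m2)
    ids <- sprintf("%s_frag%06d", individual_id, seq_len(n_pairs))
    reads <- data.frame(read_id = rep(ids, 2L),
                        mate = rep(c("1", "2"), each = n_pairs),
                        sequence = c(m1, m2), stringsAsFactors = FALSE)
    truth <- data.frame(read_id = rep(ids, 2L),
                        mate = rep(c("1", "2"), each = n_pairs),
                        allele_id = rep(unname(src), 2L),
                        offset = c(start, start + flen - rl),
                        orientation = rep(c("forward",
                                            "reverse_complement"),
                                          each = n_pairs),
                        stringsAsFactors = FALSE)
    if (n_decoy > 0L) {
      decoy <- vapply(seq_len(2L * n_decoy), function(i)
        paste(sample(BASES, rl, replace = TRUE), collapse = ""),
        character(1))
      dids <- sprintf("%s_decoy%06d", individual_id, seq_len(n_decoy))
      reads <- rbind(reads,
                     data.frame(read_id = rep(dids, 2L),
                                mate = rep(c("1", "2"), each = n_decoy),
                                sequence = decoy, stringsAsFactors = FALSE))
    }
    list(reads = reads, truth = truth, n_truncated = sum(trunc))
  })
}

#' Write the full truth set of a simulation as JSON
#'
#' @param truth any list of simulation ground truth (genotypes, weights,
#'   novel sequences, transmissions ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
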