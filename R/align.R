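#' Build a k-mer index over an allele catalogue
#'
#' Exhaustive k-mer to location map over the forward strand of every allele
#' sequence (reads are reverse-complemented during alignment instead).
#' K-mers containing `N` are not indexed; since `N` always counts as a
#' mismatch, pigeonhole seeding is unaffected.
#'
#' @param cat an [allele_catalogue()].
#' @param k seed length (default 15; small k is admitted for toy
#'   catalogues but inflates the candidate load on realistic ones).
#' @return a `kmer_index` object.
#' @export
build_index <- function(cat, k = 15L) {
  stopifnot(inherits(cat, "allele_catalogue"), k >= 4L, k <= 32L,
            nrow(cat$alleles) > 0L)
  ptr <- cpp_build_index(unname(cat$sequences), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 allele_ids = cat$alleles$allele_id,
                 allele_len = unname(nchar(cat$sequences)),
                 catalogue_version = cat$version_tag),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k=", x$k, ", ", length(x$allele_ids), " alleles, ",
      format(cpp_index_nkeys(x$ptr), big.mark = ","), " distinct k-mers [",
      x$catalogue_version, "]\n", sep = "")
  invisible(x)
}

#' Look up one k-mer in an index
#'
#' @param index a `kmer_index`.
#' @param kmer a single k-mer string.
#' @return data frame of `allele_id` and 0-based `position` of every
#'   occurrence.
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  m <- cpp_index_lookup(index$ptr, kmer)
  data.frame(allele_id = index$allele_ids[m[, 1L]], position = m[, 2L],
             stringsAsFactors = FALSE)
}

#' Number of distinct k-mers in an index
#'
#' @param index a `kmer_index`.
#' @return the count of distinct indexed k-mers.
#' @export
index_nkeys <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_index_nkeys(index$ptr)
}

as_reads <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = names(reads) %||%
                          paste0("read", seq_along(reads)),
                        mate = "unpaired", sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads),
            all(c("read_id", "mate", "sequence") %in% names(reads)))
  reads
}

#' Align reads end-to-end against an indexed catalogue
#'
#' Ungapped, end-to-end alignment with a bounded mismatch count, in both
#' orientations.  Candidate loci come from `max_mismatches + 1`
#' non-overlapping seed k-mers (pigeonhole principle: at least one seed of a
#' valid alignment is exact), then each candidate is verified by full-length
#' Hamming comparison; reads shorter than `(max_mismatches + 1) * k` fall
#' back to an exhaustive scan.  `N` in read or reference counts as a
#' mismatch.
#'
#' @param reads data frame with columns `read_id`, `mate`, `sequence`
#'   (a named character vector of sequences is also accepted).
#' @param index a `kmer_index` from [build_index()].
#' @param max_mismatches maximum Hamming distance per read (0 replicates the
#'   strict calling alignment; 3 the relaxed discovery alignment).
#' @param stratum `"all_valid"` returns every hit within the bound;
#'   `"best_only"` returns only hits tied at the minimum observed mismatch
#'   count for each read.
#' @return data frame of hits: `read_id`, `mate`, `allele_id`, `offset`
#'   (0-based start on the allele, half-open placement), `orientation`
#'   (`"forward"`/`"reverse_complement"`), `mismatches`, `width`.
#' @export
align_reads <- function(reads, index, max_mismatches = 0L,
                        stratum = c("all_valid", "best_only")) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(index, "kmer_index"))
  reads <- as_reads(reads)
  if (nrow(reads) == 0L) return(empty_hits())
  useq <- unique(reads$sequence)
  h <- cpp_align_batch(index$ptr, useq, as.integer(max_mismatches),
                       stratum == "best_only")
  if (!length(h$read)) return(empty_hits())
  per_u <- split(seq_along(h$read), h$read)
  key <- match(reads$sequence, useq)
  hl <- vector("list", length(useq))
  hl[as.integer(names(per_u))] <- per_u
  nh <- lengths(hl)[key]
  rows <- unlist(hl[key], use.names = FALSE)
  data.frame(read_id = rep(reads$read_id, nh), mate = rep(reads$mate, nh),
             allele_id = index$allele_ids[h$allele[rows]],
             offset = h$offset[rows],
             orientation = c("forward", "reverse_complement")[
               h$orient[rows] + 1L],
             mismatches = h$mismatches[rows],
             width = nchar(rep(reads$sequence, nh)),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(read_id = character(0), mate = character(0),
             allele_id = character(0), offset = integer(0),
             orientation = character(0), mismatches = integer(0),
             width = integer(0), stringsAsFactors = FALSE)
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one sequence.
#'
#' @param sequence a single read sequence.
#' @param index a `kmer_index`.
#' @param max_mismatches,stratum see [align_reads()].
#' @param read_id,mate identifiers recorded on the hits.
#' @return hit data frame as in [align_reads()].
#' @export
align_read <- function(sequence, index, max_mismatches = 0L,
                       stratum = c("all_valid", "best_only"),
                       read_id = "read1", mate = "unpaired") {
  align_reads(data.frame(read_id = read_id, mate = mate, sequence = sequence,
                         stringsAsFactors = FALSE),
              index, max_mismatches, stratum)
}

#' Align a mate pair
#'
#' In `"independent"` mode (the default, used for coverage and calling) the
#' two mates are aligned separately and no pairing constraint is applied.
#' In `"constrained"` mode, additionally reports `pair_links`: hit pairs on
#' the same allele in opposite orientations whose implied fragment length
#' falls within `fragment_bounds` (used for variant phasing).
#'
#' @param r1,r2 single-row read data frames (or single sequences) sharing a
#'   read id.
#' @param index a `kmer_index`.
#' @param max_mismatches per-read mismatch bound.
#' @param pairing `"independent"` or `"constrained"`.
#' @param fragment_bounds numeric length-2: admissible implied fragment
#'   lengths (inclusive).
#' @param stratum hit stratum, as in [align_reads()].
#' @return list with `hits1`, `hits2` and `pair_links` (data frame with
#'   `allele_id`, offsets of both mates and implied `fragment_length`).
#' @export
align_pair <- function(r1, r2, index, max_mismatches = 0L,
                       pairing = c("independent", "constrained"),
                       fragment_bounds = c(61, 1000),
                       stratum = c("best_only", "all_valid")) {
  pairing <- match.arg(pairing)
  stratum <- match.arg(stratum)
  if (is.character(r1)) r1 <- data.frame(read_id = "pair1", mate = "1",
                                         sequence = r1,
                                         stringsAsFactors = FALSE)
  if (is.character(r2)) r2 <- data.frame(read_id = "pair1", mate = "2",
                                         sequence = r2,
                                         stringsAsFactors = FALSE)
  stopifnot(identical(r1$read_id, r2$read_id))
  h1 <- align_reads(r1, index, max_mismatches, stratum)
  h2 <- align_reads(r2, index, max_mismatches, stratum)
  links <- pair_links(h1, h2, fragment_bounds)
  if (pairing == "independent") links <- links[0, , drop = FALSE]
  list(hits1 = h1, hits2 = h2, pair_links = links)
}

# concordant links between two mates' hit tables (same allele, opposite
# orientation, implied fragment length within bounds)
pair_links <- function(h1, h2, fragment_bounds = c(61, 1000)) {
  out <- data.frame(allele_id = character(0), offset1 = integer(0),
                    offset2 = integer(0), fragment_length = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(h1) == 0L || nrow(h2) == 0L) return(out)
  ij <- expand.grid(i = seq_len(nrow(h1)), j = seq_len(nrow(h2)))
  same <- h1$allele_id[ij$i] == h2$allele_id[ij$j] &
    h1$orientation[ij$i] != h2$orientation[ij$j]
  ij <- ij[same, , drop = FALSE]
  if (nrow(ij) == 0L) return(out)
  fwd1 <- h1$orientation[ij$i] == "forward"
  lo <- ifelse(fwd1, h1$offset[ij$i], h2$offset[ij$j])
  hi <- ifelse(fwd1, h2$offset[ij$j] + h2$width[ij$j],
               h1$offset[ij$i] + h1$width[ij$i])
  flen <- hi - lo
  keep <- flen >= fragment_bounds[1] & flen <= fragment_bounds[2]
  data.frame(allele_id = h1$allele_id[ij$i[keep]],
             offset1 = h1$offset[ij$i[keep]], offset2 = h2$offset[ij$j[keep]],
             fragment_length = flen[keep], stringsAsFactors = FALSE)
}

#' Distribute multi-mapping reads over tied alleles
#'
#' Takes per-read best-stratum hits and attaches an assignment weight:
#' policy `"all"` gives every tied allele weight 1 (used for coverage-based
#' calling, where a read supports every allele it matches), `"fractional"`
#' gives `1/t` to each of `t` tied alleles (deterministic quantification
#' default) and `"random"` picks one tied allele uniformly under `seed`.
#'
#' @param hits hit data frame from [align_reads()], already restricted to
#'   each read's best stratum.
#' @param policy `"all"`, `"fractional"` or `"random"`.
#' @param seed integer seed for the `"random"` policy.
#' @return `hits` with a `weight` column (rows dropped for `"random"`
#'   non-chosen placements).
#' @export
assign_reads <- function(hits, policy = c("all", "fractional", "random"),
                         seed = 1L) {
  if (is.character(policy) && length(policy) == 1L &&
      !policy %in% c("all", "fractional", "random")) {
    stop("unknown assignment policy: ", policy)
  }
  policy <- match.arg(policy)
  key <- paste(hits$read_id, hits$mate, sep = "\r")
  if (policy == "all") {
    hits$weight <- rep(1, nrow(hits))
    return(hits)
  }
  if (policy == "fractional") {
    t <- ave(rep(1, nrow(hits)), key, FUN = sum)
    hits$weight <- if (nrow(hits)) 1 / t else numeric(0)
    return(hits)
  }
  if (nrow(hits) == 0L) {
    hits$weight <- numeric(0)
    return(hits)
  }
  # random: one tied allele per read, uniformly, reproducible under seed
  idx <- with_seed(seed, {
    grp <- split(seq_len(nrow(hits)), key)
    vapply(grp, function(g) if (length(g) == 1L) g else
      g[sample.int(length(g), 1L)], integer(1))
  })
  hits <- hits[sort(unname(idx)), , drop = FALSE]
  rownames(hits) <- NULL
  hits$weight <- 1
  hits
}

#' Per-allele read counts from weighted assignments
#'
#' @param assignments hit data frame with a `weight` column, from
#'   [assign_reads()].
#' @param allele_ids alleles to report (defaults to those observed).
#' @return named numeric vector of summed weights per allele.
#' @export
count_by_allele <- function(assignments, allele_ids = NULL) {
  if (is.null(allele_ids)) allele_ids <- sort(unique(assignments$allele_id))
  out <- stats::setNames(numeric(length(allele_ids)), allele_ids)
  if (nrow(assignments)) {
    s <- tapply(assignments$weight, assignments$allele_id, sum)
    out[names(s)] <- as.numeric(s)
  }
  out
}

#' Export hits as SAM
#'
#' Minimal single-end SAM against the catalogue as reference: one `@SQ` line
#' per allele, `NM` tag carrying the mismatch count, flag 0/16 for
#' forward/reverse placements.
#'
#' @param hits hit data frame from [align_reads()].
#' @param reads the read data frame the hits came from.
#' @param cat the [allele_catalogue()] used as reference.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, reads, cat, path) {
  reads <- as_reads(reads)
  seqs <- stats::setNames(reads$sequence, paste(reads$read_id, reads$mate))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", cat$alleles$allele_id, "\tLN:",
                  nchar(cat$sequences)))
  rseq <- unname(seqs[paste(hits$read_id, hits$mate)])
  rev <- hits$orientation == "reverse_complement"
  rseq[rev] <- revcomp(rseq[rev])
  body <- if (nrow(hits)) {
    paste(hits$read_id, ifelse(rev, 16L, 0L), hits$allele_id,
          hits$offset + 1L, 255L, paste0(hits$width, "M"), "*", 0L, 0L,
          rseq, "*", paste0("NM:i:", hits$mismatches), sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
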