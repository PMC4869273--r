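# Independent brute-force alignment oracle: exhaustive Hamming scan over
# every allele, offset and orientation, written against integer codes and
# deliberately sharing no code path with the package's seeded aligner.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# precompute per-allele sliding-window integer matrices for read width w
oracle_prep <- function(seqs, w) {
  lapply(seqs, function(s) {
    si <- utf8ToInt(s)
    L <- length(si)
    if (L < w) return(NULL)
    noff <- L - w + 1L
    matrix(si[outer(seq_len(w) - 1L, seq_len(noff) - 1L, "+") + 1L],
           nrow = w)
  })
}

N_INT <- utf8ToInt("N")

# all hits of one read (both orientations) with <= maxmm mismatches
oracle_align <- function(read, seqs, maxmm, best_only = FALSE,
                         prep = NULL) {
  w <- nchar(read)
  if (is.null(prep)) prep <- oracle_prep(seqs, w)
  out <- list()
  for (orient in c("forward", "reverse_complement")) {
    r <- if (orient == "forward") read else oracle_revcomp(read)
    ri <- utf8ToInt(r)
    for (a in seq_along(seqs)) {
      sm <- prep[[a]]
      if (is.null(sm)) next
      bad <- sm != ri | sm == N_INT | ri == N_INT
      mm <- colSums(bad)
      hit <- which(mm <= maxmm)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          allele_id = names(seqs)[a], offset = hit - 1L,
          orientation = orient, mismatches = as.integer(mm[hit]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(allele_id = character(0), offset = integer(0),
                      orientation = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  if (best_only) res <- res[res$mismatches == min(res$mismatches), ,
                            drop = FALSE]
  res[order(res$allele_id, res$offset, res$orientation), , drop = FALSE]
}

# canonical form of a package hit table for comparison with the oracle
hits_canonical <- function(h) {
  h <- h[, c("allele_id", "offset", "orientation", "mismatches")]
  h <- h[order(h$allele_id, h$offset, h$orientation), , drop = FALSE]
  rownames(h) <- NULL
  h
}
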