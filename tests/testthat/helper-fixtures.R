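# Shared fixture builders (everything is generated in code; no data files).

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny catalogue of random alleles (no ORF structure; for aligner tests)
random_catalogue <- function(n_alleles, len, seed = 1) {
  set.seed(seed)
  seqs <- replicate(n_alleles, random_dna(len))
  allele_catalogue(sprintf("AL%02d", seq_len(n_alleles)), seqs)
}

# all error-free reads of width w tiling a sequence at the given stride
tile_reads <- function(seq, w = 61L, stride = 10L, prefix = "t") {
  L <- nchar(seq)
  starts <- unique(c(seq(1L, L - w + 1L, by = stride), L - w + 1L))
  data.frame(read_id = sprintf("%s%04d", prefix, seq_along(starts)),
             mate = "unpaired",
             sequence = substring(seq, starts, starts + w - 1L),
             stringsAsFactors = FALSE)
}

# substitute given 1-based positions of a sequence with a different base
substitute_at <- function(seq, pos1) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos1) {
    s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  }
  paste(s, collapse = "")
}

with_seed_local <- function(seed, code) {
  old <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

empty_placements <- function() {
  data.frame(allele_id = character(0), offset = integer(0),
             width = integer(0), stringsAsFactors = FALSE)
}

empty_reads <- function() {
  data.frame(read_id = character(0), mate = character(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

# default simulator scale used across unit tests: small but structured
test_sim_config <- function(...) {
  sim_config(n_genes_classical = 3L, n_genes_nonclassical = 2L,
             alleles_per_gene = 3L, allele_length = 600L, ...)
}
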