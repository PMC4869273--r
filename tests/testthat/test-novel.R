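# constructed pileup scenario: reads tiling a parent, a subset carrying
# alternative bases at chosen positions
make_parent_reads <- function(parent, alt_positions0 = integer(0),
                              alt_every = 2L, w = 61L, stride = 6L) {
  reads <- tile_reads(parent, w = w, stride = stride)
  variant_seq <- if (length(alt_positions0)) {
    substitute_at(parent, alt_positions0 + 1L)
  } else parent
  alt_rows <- seq_len(nrow(reads)) %% alt_every == 0L
  L <- nchar(parent)
  starts <- unique(c(seq(1L, L - w + 1L, by = stride), L - w + 1L))
  reads$sequence[alt_rows] <- substring(variant_seq, starts[alt_rows],
                                        starts[alt_rows] + w - 1L)
  list(reads = reads, variant_seq = variant_seq)
}

test_that("pileup emits variants only above support and fraction thresholds", {
  cat. <- random_catalogue(2, 400, seed = 201)
  parent <- cat.$sequences[["AL01"]]
  idx <- build_index(cat.)

  # concordant reads: no variant
  r0 <- tile_reads(parent, stride = 6)
  h0 <- align_reads(r0, idx, 3L, "best_only")
  v0 <- pileup_variants("AL01", h0, r0, cat.)
  expect_equal(nrow(v0), 0L)

  # half the reads carry an alternative base at position 120
  mk <- make_parent_reads(parent, 120L, alt_every = 2L)
  h <- align_reads(mk$reads, idx, 3L, "best_only")
  v <- pileup_variants("AL01", h, mk$reads, cat.)
  expect_equal(v$position, 120L)
  expect_equal(v$ref, substr(parent, 121, 121))
  expect_equal(v$alt, substr(mk$variant_seq, 121, 121))
  expect_gte(v$support_fraction, 0.2)
  expect_true(v$support_reads >= 3L)

  # a single discordant read among deep coverage is rejected as noise
  deep <- tile_reads(parent, stride = 2, prefix = "d")
  one <- data.frame(read_id = "noise", mate = "unpaired",
                    sequence = substitute_at(substr(parent, 100, 160), 21),
                    stringsAsFactors = FALSE)
  rn <- rbind(deep, one)
  hn <- align_reads(rn, idx, 3L, "best_only")
  vn <- pileup_variants("AL01", hn, rn, cat.)
  expect_equal(nrow(vn), 0L)
})

test_that("variants co-occurring on fragments phase into one set", {
  cat. <- random_catalogue(2, 400, seed = 211)
  parent <- cat.$sequences[["AL01"]]
  idx <- build_index(cat.)
  mk <- make_parent_reads(parent, c(150L, 180L), alt_every = 2L)
  h <- align_reads(mk$reads, idx, 3L, "best_only")
  v <- pileup_variants("AL01", h, mk$reads, cat.)
  expect_equal(v$position, c(150L, 180L))
  sets <- phase_variants(v, h, mk$reads, cat.)
  expect_equal(length(sets), 1L)
  expect_equal(sets[[1]]$variants$position, c(150L, 180L))
  expect_false(sets[[1]]$ambiguous)
  expect_gte(sets[[1]]$linking_evidence, 2)
})

test_that("variants in repulsion phase into distinct sets, never merged", {
  cat. <- random_catalogue(2, 400, seed = 221)
  parent <- cat.$sequences[["AL01"]]
  idx <- build_index(cat.)
  # sibling alleles: A carries alt at 150, B at 180; reads alternate
  sibA <- substitute_at(parent, 151)
  sibB <- substitute_at(parent, 181)
  ra <- tile_reads(sibA, stride = 6, prefix = "a")
  rb <- tile_reads(sibB, stride = 6, prefix = "b")
  reads <- rbind(ra, rb)
  h <- align_reads(reads, idx, 3L, "best_only")
  v <- pileup_variants("AL01", h, reads, cat.)
  expect_equal(v$position, c(150L, 180L))
  sets <- phase_variants(v, h, reads, cat.)
  expect_equal(length(sets), 2L)
  expect_equal(vapply(sets, function(s) nrow(s$variants), integer(1)),
               c(1L, 1L))
  expect_false(any(vapply(sets, `[[`, logical(1), "ambiguous")))

  expect_equal(length(phase_variants(v[0, ], h, reads, cat.)), 0L)
})

test_that("variant application reconstructs the expected sequence", {
  v1 <- data.frame(parent_allele_id = "P", position = 1L, ref = "A",
                   alt = "C", stringsAsFactors = FALSE)
  expect_equal(reconstruct_variant_allele("AAAA", v1), "ACAA")

  parent <- random_dna(200)
  v2 <- data.frame(parent_allele_id = "P", position = c(10L, 150L),
                   ref = c(substr(parent, 11, 11), substr(parent, 151, 151)),
                   alt = c("N", "N"), stringsAsFactors = FALSE)
  # choose real alternative bases
  v2$alt <- vapply(seq_len(2), function(i)
    setdiff(c("A", "C", "G", "T"), v2$ref[i])[1], character(1))
  rec <- reconstruct_variant_allele(parent, v2)
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                   strsplit(b, "")[[1]]), parent, rec)
  expect_equal(unname(d), 2)
})

test_that("validation enforces distinctness, coverage closure and features", {
  cfg <- test_sim_config(seed = 231, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  cat. <- sim$catalogue
  nov <- spawn_novel_alleles(cat., 1, substitutions_range = 2, seed = 232)
  rr <- simulate_reads(stats::setNames(1, nov$novel$novel_id),
                       c(cat.$sequences, nov$sequences), cfg, seed = 233,
                       n_pairs = 500)
  # the true novel sequence validates with full coverage
  val <- validate_novel(unname(nov$sequences), cat., rr$reads,
                        nov$novel$class_kind)
  expect_true(val$accept)
  # an existing catalogue sequence is a duplicate
  dup <- validate_novel(unname(cat.$sequences[[1]]), cat., rr$reads)
  expect_false(dup$accept)
  expect_match(dup$reason, "duplicate")
  # a sequence with an extra unsupported substitution loses coverage
  wrong <- substitute_at(unname(nov$sequences), 300L)
  val2 <- validate_novel(wrong, cat., rr$reads, nov$novel$class_kind)
  expect_false(val2$accept)
  expect_match(val2$reason, "incomplete coverage")
})

test_that("accepted novel alleles would be called on the same reads", {
  cfg <- test_sim_config(seed = 241, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  cat. <- sim$catalogue
  nov <- spawn_novel_alleles(cat., 1, substitutions_range = 3, seed = 242)
  rr <- simulate_reads(stats::setNames(1, nov$novel$novel_id),
                       c(cat.$sequences, nov$sequences), cfg, seed = 243,
                       n_pairs = 500)
  val <- validate_novel(unname(nov$sequences), cat., rr$reads,
                        nov$novel$class_kind)
  expect_true(val$accept)
  res <- add_novel_allele(cat., unname(nov$sequences),
                          parent_id = nov$novel$parent_id)
  call <- call_alleles_exact(rr$reads, res$catalogue)
  expect_true(res$allele_id %in% call$call$allele_id)
})

test_that("de novo assembly reconstructs a distant allele end-to-end", {
  set.seed(251)
  truth <- random_dna(700)
  # 30x error-free coverage
  reads <- do.call(rbind, lapply(1:3, function(i)
    tile_reads(truth, stride = 7, prefix = paste0("c", i))))
  rc <- sample(nrow(reads), nrow(reads) %/% 2)
  reads$sequence[rc] <- revcomp(reads$sequence[rc])
  seed <- substr(truth, 301, 361)
  asm <- assemble_de_novo(seed, reads)
  expect_equal(asm$status, "ok")
  expect_equal(asm$contig, truth)
})

test_that("de novo assembly fails cleanly without overlaps or on branches", {
  set.seed(261)
  seed <- random_dna(61)
  lonely <- assemble_de_novo(seed, data.frame(read_id = "x", mate = "1",
                                              sequence = random_dna(61)))
  expect_equal(lonely$status, "fragmentary")

  # chimera: two equally supported extensions after a shared core
  core <- random_dna(100)
  armA <- paste0(core, random_dna(120))
  armB <- paste0(core, random_dna(120))
  readsA <- tile_reads(armA, stride = 5, prefix = "A")
  readsB <- tile_reads(armB, stride = 5, prefix = "B")
  asm <- assemble_de_novo(substr(core, 20, 80), rbind(readsA, readsB))
  expect_equal(asm$status, "ambiguous")
})

test_that("typing discovers a de novo allele unreachable by the aligner", {
  cfg <- test_sim_config(seed = 271, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  cat. <- sim$catalogue
  # 40 substitutions: far beyond the relaxed mismatch bound
  nov <- spawn_novel_alleles(cat., 1, substitutions_range = 40, seed = 272)
  g <- c(setdiff(cat.$alleles$allele_id[c(2, 8)], nov$novel$parent_id),
         nov$novel$novel_id)
  w <- stats::setNames(rep(1 / length(g), length(g)), g)
  rr <- simulate_reads(w, c(cat.$sequences, nov$sequences), cfg,
                       seed = 273, n_pairs = 1200)
  res <- run_iterative_typing(rr$reads, cat., individual_id = "dn")
  novel_ids <- setdiff(res$call$allele_id, cat.$alleles$allele_id)
  expect_equal(length(novel_ids), 1L)
  expect_equal(unname(res$catalogue$sequences[novel_ids]),
               unname(nov$sequences))
  row <- res$catalogue$alleles[res$catalogue$alleles$allele_id ==
                                 novel_ids, ]
  expect_equal(row$provenance, "novel_de_novo")
})

test_that("reads from catalogue alleles alone never yield a novel allele", {
  cfg <- test_sim_config(seed = 281, error_rate = 0.005)
  sim <- simulate_catalogue(cfg)
  cat. <- sim$catalogue
  for (s in 1:3) {
    g <- with_seed_local(s, sample(cat.$alleles$allele_id, 4))
    w <- stats::setNames(rep(0.25, 4), g)
    rr <- simulate_reads(w, cat.$sequences, cfg, seed = 300 + s,
                         n_pairs = 1500)
    res <- run_iterative_typing(rr$reads, cat.,
                                individual_id = paste0("s", s))
    expect_equal(nrow(res$catalogue$alleles), nrow(cat.$alleles))
    expect_setequal(res$call$allele_id, g)
  }
})
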