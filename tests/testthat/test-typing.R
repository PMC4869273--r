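test_that("coverage profiles report depth and maximal uncovered intervals", {
  cat. <- random_catalogue(1, 300, seed = 1)
  L <- 300L
  # no reads: one uncovered interval [0, L)
  p0 <- compute_coverage(empty_placements(), cat.)[["AL01"]]
  expect_equal(p0$uncovered, cbind(start = 0L, end = L))

  # overlapping placements [0,30) and [28, L) join to full coverage
  asg <- data.frame(allele_id = "AL01", offset = c(0L, 28L),
                    width = c(30L, L - 28L), stringsAsFactors = FALSE)
  p1 <- compute_coverage(asg, cat.)[["AL01"]]
  expect_equal(nrow(p1$uncovered), 0L)
  expect_equal(p1$depth[29:30], c(2L, 2L))  # 0-based 28,29 overlap twice
  expect_equal(p1$depth[31], 1L)

  # everything but [100,104) covered
  asg2 <- data.frame(allele_id = "AL01", offset = c(0L, 104L),
                     width = c(100L, L - 104L), stringsAsFactors = FALSE)
  p2 <- compute_coverage(asg2, cat.)[["AL01"]]
  expect_equal(p2$uncovered, cbind(start = 100L, end = 104L))

  # out-of-bounds placements are a hard error
  bad <- data.frame(allele_id = "AL01", offset = 290L, width = 20L)
  expect_error(compute_coverage(bad, cat.), "out of allele bounds")
})

test_that("min_depth raises the bar for covered bases", {
  cat. <- random_catalogue(1, 100, seed = 2)
  asg <- data.frame(allele_id = "AL01", offset = c(0L, 0L, 50L),
                    width = c(100L, 50L, 50L), stringsAsFactors = FALSE)
  expect_equal(nrow(compute_coverage(asg, cat., 2L)[["AL01"]]$uncovered),
               0L)
  asg1 <- asg[1, , drop = FALSE]
  expect_equal(nrow(compute_coverage(asg1, cat., 2L)[["AL01"]]$uncovered),
               1L)
})

test_that("complete-coverage calling is strict to the last base", {
  cat. <- random_catalogue(3, 300, seed = 3)
  # single-tiling fixture: depth 1 at the termini, so use the literal
  # presence criterion
  cfg1 <- typing_config(min_depth = 1L)
  a <- cat.$sequences[["AL01"]]
  reads <- tile_reads(a, stride = 20)
  res <- call_alleles_exact(reads, cat., cfg1)
  expect_equal(res$call$allele_id, "AL01")
  expect_equal(res$call$stage, "exact")

  # every base except position 150 covered: not called
  b <- cat.$sequences[["AL02"]]
  left <- tile_reads(substr(b, 1, 150), stride = 10, prefix = "l")
  right <- tile_reads(substr(b, 152, 300), stride = 10, prefix = "r")
  res2 <- call_alleles_exact(rbind(left, right), cat., cfg1)
  expect_false("AL02" %in% res2$call$allele_id)
  expect_equal(res2$profiles[["AL02"]]$uncovered,
               cbind(start = 150L, end = 151L))
})

test_that("calling on a two-allele mixture matches the coverage oracle", {
  cfg <- test_sim_config(seed = 31, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  g <- sim$catalogue$alleles$allele_id[c(2, 8)]
  w <- stats::setNames(c(0.7, 0.3), g)
  rr <- simulate_reads(w, sim$catalogue$sequences, cfg, seed = 32,
                       n_pairs = 2000)
  res <- call_alleles_exact(rr$reads, sim$catalogue)
  expect_setequal(res$call$allele_id, g)
  # oracle: per-base coverage recomputed from brute-force alignments
  seqs <- sim$catalogue$sequences
  prep <- oracle_prep(seqs, 61L)
  sub <- rr$reads[sample.int(nrow(rr$reads), 300), ]
  for (i in seq_len(nrow(sub))) {
    h <- oracle_align(sub$sequence[i], seqs, 0L, prep = prep)
    pkg <- align_read(sub$sequence[i], build_index(sim$catalogue), 0L)
    expect_equal(hits_canonical(pkg)[, 1:3], h[, 1:3],
                 ignore_attr = TRUE)
  }
})

test_that("the single-gap candidate rule is exact at the boundary", {
  prof <- function(gaps) {
    depth <- rep(1L, 500)
    for (g in gaps) depth[g] <- 0L
    structure(list(allele_id = "X", depth = depth,
                   uncovered = mhctyper:::runs_true(depth < 1L)),
              class = "coverage_profile")
  }
  expect_true(candidate_from_profile(prof(list())))          # fully covered
  expect_true(candidate_from_profile(prof(list(101:104))))   # one 4-nt gap
  expect_false(candidate_from_profile(prof(list(101:105))))  # one 5-nt gap
  expect_false(candidate_from_profile(prof(list(101:102, 301:302))))
})

test_that("novel-allele parents are proposed via the relaxed alignment", {
  cfg <- test_sim_config(seed = 41, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  cat. <- sim$catalogue
  nov <- spawn_novel_alleles(cat., 1, substitutions_range = 2, seed = 42)
  parent <- nov$novel$parent_id
  w <- stats::setNames(1, nov$novel$novel_id)
  rr <- simulate_reads(w, c(cat.$sequences, nov$sequences), cfg, seed = 43,
                       n_pairs = 400)
  fc <- find_novel_candidates(rr$reads, cat., character(0))
  expect_true(parent %in% fc$candidates$allele_id)
  # the parent is NOT called at the exact stage
  expect_false(parent %in% call_alleles_exact(rr$reads,
                                              cat.)$call$allele_id)
})

test_that("classical candidates are reported before non-classical ones", {
  cfg <- test_sim_config(seed = 51, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  cat. <- sim$catalogue
  cl <- cat.$alleles$allele_id[cat.$alleles$class_kind == "classical"][1]
  nc <- cat.$alleles$allele_id[cat.$alleles$class_kind ==
                                 "nonclassical"][1]
  w <- stats::setNames(c(0.5, 0.5), c(cl, nc))
  rr <- simulate_reads(w, cat.$sequences, cfg, seed = 52, n_pairs = 600)
  fc <- find_novel_candidates(rr$reads, cat., character(0))
  kinds <- fc$candidates$class_kind
  if (all(c("classical", "nonclassical") %in% kinds)) {
    expect_lt(max(which(kinds == "classical")),
              min(which(kinds == "nonclassical")))
  }
  expect_true(all(c(cl, nc) %in% fc$candidates$allele_id))
})

test_that("iterative typing recovers known plus novel alleles to closure", {
  cfg <- test_sim_config(seed = 61, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  cat. <- sim$catalogue
  nov <- spawn_novel_alleles(cat., 1, substitutions_range = 2, seed = 62)
  g_known <- setdiff(cat.$alleles$allele_id[c(2, 7, 13)],
                     nov$novel$parent_id)
  g <- c(g_known, nov$novel$novel_id)
  w <- stats::setNames(rep(1 / length(g), length(g)), g)
  rr <- simulate_reads(w, c(cat.$sequences, nov$sequences), cfg, seed = 63,
                       n_pairs = 1500)
  res <- run_iterative_typing(rr$reads, cat., individual_id = "ind1")
  # all known alleles recovered, novel reconstructed base-exactly
  expect_true(all(g_known %in% res$call$allele_id))
  novel_ids <- setdiff(res$call$allele_id, cat.$alleles$allele_id)
  expect_equal(length(novel_ids), 1L)
  expect_equal(unname(res$catalogue$sequences[novel_ids]),
               unname(nov$sequences))
  expect_equal(length(res$call$allele_id), length(g))
  # catalogue grew by exactly the novel allele; audit terminates quickly
  expect_equal(nrow(res$catalogue$alleles), nrow(cat.$alleles) + 1L)
  expect_lte(length(res$audit), 6L)
  # soundness: every called allele fully covered in the final profiles
  expect_true(all(vapply(res$profiles, function(p)
    nrow(p$uncovered) == 0L, logical(1))))
})

test_that("typing with zero reads returns an empty call unchanged", {
  cat. <- random_catalogue(3, 300, seed = 71)
  res <- run_iterative_typing(empty_reads(), cat.)
  expect_equal(nrow(res$call), 0L)
  expect_equal(nrow(res$catalogue$alleles), 3L)
})

test_that("a catalogue-complete individual converges in one extra pass", {
  cfg <- test_sim_config(seed = 81, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  g <- sim$catalogue$alleles$allele_id[c(1, 5, 10)]
  w <- stats::setNames(rep(1 / 3, 3), g)
  rr <- simulate_reads(w, sim$catalogue$sequences, cfg, seed = 82,
                       n_pairs = 1200)
  res <- run_iterative_typing(rr$reads, sim$catalogue)
  expect_setequal(res$call$allele_id, g)
  expect_equal(nrow(res$catalogue$alleles), nrow(sim$catalogue$alleles))
  # each class pass runs exactly one iteration that adds nothing
  expect_equal(length(res$audit), 2L)
  expect_true(all(vapply(res$audit, function(a)
    length(a$accepted) == 0L, logical(1))))
})

test_that("genotype reports serialise to TSV", {
  cfg <- test_sim_config(seed = 91, error_rate = 0)
  sim <- simulate_catalogue(cfg)
  g <- sim$catalogue$alleles$allele_id[c(1, 4)]
  rr <- simulate_reads(stats::setNames(c(0.6, 0.4), g),
                       sim$catalogue$sequences, cfg, seed = 92,
                       n_pairs = 600)
  res <- run_iterative_typing(rr$reads, sim$catalogue,
                              individual_id = "cow1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_report(res$call, f)
  back <- read.delim(f)
  expect_setequal(back$allele_id, g)
  expect_equal(unique(back$individual_id), "cow1")
})
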