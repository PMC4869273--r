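# independent exact-test oracle: enumerate heterozygote counts with
# probabilities computed from exact binomial coefficients
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  rare <- min(na, 2 * n - na)
  hets <- seq(rare %% 2, rare, by = 2)
  # conditional on allele counts: P(h) proportional to 2^h/(aa! h! bb!)
  pr <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    exp(h * log(2) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_ab, hets)] * (1 + 1e-9)])
}

test_that("the HWE exact test matches brute-force enumeration", {
  expect_equal(hwe_exact_test(10, 80, 10), oracle_hwe(10, 80, 10))
  set.seed(601)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    g <- as.vector(stats::rmultinom(1, n, c(0.3, 0.45, 0.25)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 oracle_hwe(g[1], g[2], g[3]))
  }
  # strong heterozygote excess is detected
  expect_lt(hwe_exact_test(0, 100, 0), 0.001)
  expect_equal(hwe_exact_test(50, 0, 0), 1)
})

make_snp_matrix <- function() {
  data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
             chrom = "BTA23",
             pos = c(27545231, 28000000, 29000000, 31000000),
             F1 = c("AB", "AA", "AB", "AB"),
             F2 = c("AB", "AA", "AB", "AB"),
             F3 = c("AB", "AA", NA, "AB"),
             F4 = c("AB", "AA", "AB", "AB"),
             stringsAsFactors = FALSE)
}

test_that("SNP filtering applies region, call-rate, MAF and HWE rules", {
  m <- make_snp_matrix()
  region <- c(27545231, 30222836)
  out <- filter_snps(m, region, call_rate_min = 0.9)
  # rs2 monomorphic (MAF 0), rs3 call rate 0.75, rs4 outside region
  expect_equal(out$snp_id, "rs1")
  # idempotence
  expect_identical(filter_snps(out, region, call_rate_min = 0.9), out)
  # everything filtered away warns, does not error
  expect_warning(res <- filter_snps(m[2, ], region), "no SNP passed")
  expect_equal(nrow(res), 0L)
})

test_that("trio SNP inconsistencies and orphan MHC alleles are flagged", {
  ped <- data.frame(individual_id = c("S", "D", "O"),
                    sire_id = c(NA, NA, "S"), dam_id = c(NA, NA, "D"),
                    group_label = "x", stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "rs9", chrom = "c", pos = 1,
                     S = "AA", D = "AA", O = "AB",
                     stringsAsFactors = FALSE)
  geno <- list(S = c("a", "b"), D = c("c", "d"), O = c("a", "c", "zzz"))
  v <- check_mendelian(ped, geno, snps = snps)
  expect_equal(nrow(v), 2L)
  expect_true(any(v$type == "snp" & v$individual_id == "O"))
  expect_true(any(v$type == "mhc_allele" & grepl("zzz", v$detail)))

  # compatible trio and genotypes: clean
  snps_ok <- snps
  snps_ok$O <- "AA"
  geno_ok <- list(S = c("a", "b"), D = c("c", "d"), O = c("a", "c"))
  expect_equal(nrow(check_mendelian(ped, geno_ok, snps = snps_ok)), 0L)
})

test_that("pedigree validation rejects ancestry cycles", {
  bad <- data.frame(individual_id = c("A", "B"),
                    sire_id = c("B", "A"), dam_id = c(NA, NA),
                    group_label = "x", stringsAsFactors = FALSE)
  expect_error(validate_pedigree(bad), "ancestor")
})

test_that("haplotype derivation recovers simulated founder haplotypes", {
  cfg <- test_sim_config(seed = 611)
  sim <- simulate_catalogue(cfg)
  fam <- simulate_family(sim$catalogue$sequences, sim$catalogue, cfg,
                         n_fullsib = 8L, n_halfsib = 0L)
  hap <- derive_haplotypes(fam$pedigree, fam$genotypes)
  expect_equal(hap$status, "ok")
  truth_p <- lapply(fam$haplotypes[["SIRE"]], sort)
  got_p <- lapply(hap$paternal, sort)
  expect_true(setequal(truth_p, got_p))
  truth_m <- lapply(fam$haplotypes[["DAM1"]], sort)
  expect_true(setequal(truth_m, lapply(hap$maternal, sort)))
  # zero Mendelian violations on simulator truth
  v <- check_mendelian(fam$pedigree, fam$genotypes, snps = fam$snp,
                       haplotypes = hap)
  expect_equal(nrow(v), 0L)
})

test_that("haplotype recovery and violation-free transmission hold across seeds", {
  cfg0 <- test_sim_config(seed = 1)
  sim <- simulate_catalogue(cfg0)
  ok <- 0L
  for (s in 1:20) {
    cfg <- test_sim_config(seed = 620 + s)
    fam <- simulate_family(sim$catalogue$sequences, sim$catalogue, cfg,
                           n_fullsib = 8L, n_halfsib = 0L)
    v <- check_mendelian(fam$pedigree, fam$genotypes, snps = fam$snp)
    expect_equal(nrow(v), 0L)
    hap <- derive_haplotypes(fam$pedigree, fam$genotypes)
    expect_equal(hap$status, "ok")
    if (setequal(lapply(fam$haplotypes[["SIRE"]], sort),
                 lapply(hap$paternal, sort))) ok <- ok + 1L
  }
  expect_equal(ok, 20L)
})

test_that("an injected allele swap is always detected", {
  cfg0 <- test_sim_config(seed = 1)
  sim <- simulate_catalogue(cfg0)
  for (s in 1:10) {
    cfg <- test_sim_config(seed = 640 + s)
    fam <- simulate_family(sim$catalogue$sequences, sim$catalogue, cfg,
                           n_fullsib = 6L, n_halfsib = 0L)
    g <- fam$genotypes
    offs <- fam$pedigree$individual_id[fam$pedigree$group_label ==
                                         "fullsib"]
    victim <- with_seed_local(s, sample(offs, 1))
    g[[victim]][1] <- "BoLA-9*99901"  # absent from both parents
    v <- check_mendelian(fam$pedigree, g)
    expect_gte(nrow(v), 1L)
    expect_true(victim %in% v$individual_id)
  }
})

test_that("parents sharing alleles can make sib haplotypes unresolvable", {
  ped <- data.frame(individual_id = c("S", "D", "o1", "o2"),
                    sire_id = c(NA, NA, "S", "S"),
                    dam_id = c(NA, NA, "D", "D"),
                    group_label = c("f", "f", "fullsib", "fullsib"),
                    stringsAsFactors = FALSE)
  geno <- list(S = c("a", "b", "c"), D = c("a", "d", "e"),
               o1 = c("a", "b", "d"), o2 = c("a", "b", "d"))
  hap <- derive_haplotypes(ped, geno)
  expect_equal(hap$status, "unresolvable")
  expect_gt(hap$n_solutions, 1L)
})

test_that("duplicated genes are carried and reported with copy counts", {
  ped <- data.frame(individual_id = c("S", "D", "o1", "o2"),
                    sire_id = c(NA, NA, "S", "S"),
                    dam_id = c(NA, NA, "D", "D"),
                    group_label = c("f", "f", "fullsib", "fullsib"),
                    stringsAsFactors = FALSE)
  # paternal haplotype with three NC2 copies (gene duplication)
  P1 <- c("BoLA-NC2*00101", "BoLA-NC2*00201", "BoLA-NC2*00301")
  P2 <- c("BoLA-1*00101")
  M1 <- c("BoLA-2*00101")
  M2 <- c("BoLA-3*00101")
  geno <- list(S = c(P1, P2), D = c(M1, M2),
               o1 = c(P1, M1), o2 = c(P2, M2))
  hap <- derive_haplotypes(ped, geno)
  expect_equal(hap$status, "ok")
  cp <- vapply(hap$gene_copies, function(tab)
    if ("NC2" %in% names(tab)) as.integer(tab[["NC2"]]) else 0L,
    integer(1))
  expect_true(3L %in% cp)
})

test_that("inconsistent families return a violation report, not a crash", {
  ped <- data.frame(individual_id = c("S", "D", "o1", "o2"),
                    sire_id = c(NA, NA, "S", "S"),
                    dam_id = c(NA, NA, "D", "D"),
                    group_label = c("f", "f", "fullsib", "fullsib"),
                    stringsAsFactors = FALSE)
  geno <- list(S = c("a", "b"), D = c("c", "d"),
               o1 = c("a", "c"), o2 = c("a", "x"))
  hap <- derive_haplotypes(ped, geno)
  expect_equal(hap$status, "inconsistent")
  expect_lt(hap$n_consistent_offspring, 2L)
})

test_that("SNP flank tracking classifies offspring like the MHC haplotypes", {
  cfg0 <- test_sim_config(seed = 1)
  sim <- simulate_catalogue(cfg0)
  for (s in 1:10) {
    cfg <- test_sim_config(seed = 660 + s)
    fam <- simulate_family(sim$catalogue$sequences, sim$catalogue, cfg,
                           n_fullsib = 8L, n_halfsib = 0L)
    # sparse informativeness can split a chromosome class in two, which
    # the function flags; concordance with MHC classes is what matters
    trk <- suppressWarnings(snp_haplotype_tracking(fam$snp, fam$pedigree))
    hap <- derive_haplotypes(fam$pedigree, fam$genotypes)
    stopifnot(hap$status == "ok")
    # no recombination simulated: SNP flank classes and MHC haplotype
    # classes partition the offspring identically (up to labels)
    cmp <- merge(trk$offspring, hap$offspring, by = "individual_id")
    for (side in list(c("paternal_class", "paternal"),
                      c("maternal_class", "maternal"))) {
      got <- cmp[[side[1]]]
      want <- cmp[[side[2]]]
      keep <- !is.na(got)
      if (!any(keep)) next
      map <- table(got[keep], want[keep])
      # each flank class maps to exactly one MHC haplotype label
      expect_true(all(rowSums(map > 0) == 1L))
    }
  }
})

test_that("a family homozygous at every SNP yields no informative flanks", {
  ped <- data.frame(individual_id = c("S", "D", "o1", "o2"),
                    sire_id = c(NA, NA, "S", "S"),
                    dam_id = c(NA, NA, "D", "D"),
                    group_label = c("f", "f", "fullsib", "fullsib"),
                    stringsAsFactors = FALSE)
  m <- data.frame(snp_id = c("rs1", "rs2"), chrom = "c", pos = c(1, 2),
                  S = c("AA", "BB"), D = c("AA", "BB"),
                  o1 = c("AA", "BB"), o2 = c("AA", "BB"),
                  stringsAsFactors = FALSE)
  expect_warning(trk <- snp_haplotype_tracking(m, ped), "no informative")
  expect_true(all(is.na(trk$offspring$paternal_class)))
})

test_that("pedigree and SNP matrices round-trip through TSV", {
  cfg <- test_sim_config(seed = 671)
  sim <- simulate_catalogue(cfg)
  fam <- simulate_family(sim$catalogue$sequences, sim$catalogue, cfg,
                         n_fullsib = 3L, n_halfsib = 1L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(fam$pedigree, f1)
  expect_equal(read_pedigree(f1), fam$pedigree)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_snp_matrix(fam$snp, f2)
  expect_equal(read_snp_matrix(f2), fam$snp)
})
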