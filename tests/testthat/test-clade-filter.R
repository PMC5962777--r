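# The discrimination filter: per-sample frequency arithmetic, the four
# predicate clauses, oracle equivalence, monotonicity and symmetry.

test_that("sample allele frequency is reads/depth with absent alleles at 0", {
  expect_equal(sample_allele_freq(c(T = 24), 25, "T"), 0.96)
  expect_equal(sample_allele_freq(c(A = 18, T = 2), 20, "T"), 0.10)
  expect_equal(sample_allele_freq(c(A = 18), 20, "G"), 0)
  expect_error(sample_allele_freq(c(A = 1), 0, "A"), "undefined")
  # exhaustive small-domain agreement with the closed form
  for (depth in c(1, 7, 20, 50)) {
    for (reads in 0:depth) {
      expect_equal(sample_allele_freq(c(X = reads), depth, "X"), reads / depth)
    }
  }
})

test_that("the filter applies all four clauses on hand-built sites", {
  g <- two_clade_groups(3, 2)
  ins <- c("flor_01", "flor_02", "flor_03"); outs <- c("wine_01", "wine_02")
  mk <- function(dp, t_reads) {
    counts <- lapply(seq_along(dp), function(i) {
      c(dp[i] - t_reads[i], t_reads[i])
    })
    names(counts) <- names(dp)
    make_site_vs("A", "T", dp, counts)
  }
  dp <- setNames(rep(30, 5), c(ins, outs))
  # in-clade 0.95 T, out-clade ~0.97 A -> reported with clade allele T
  vs <- mk(dp, setNames(c(29, 29, 29, 1, 1), names(dp)))
  calls <- call_clade_specific(vs, g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$clade_allele, "T")
  expect_equal(calls$out_alleles, "A")
  # depth rule: one in-clade sample at 19x kills the site
  dp19 <- dp; dp19["flor_02"] <- 19
  vs2 <- mk(dp19, setNames(c(29, 18, 29, 1, 1), names(dp19)))
  expect_equal(nrow(call_clade_specific(vs2, g)), 0)
  # frequency rule: an in-clade sample at 0.8 kills the site
  vs3 <- mk(dp, setNames(c(29, 24, 29, 1, 1), names(dp)))
  expect_equal(nrow(call_clade_specific(vs3, g)), 0)
  # out-clade sample sharing the clade allele kills the site
  vs4 <- mk(dp, setNames(c(29, 29, 29, 29, 1), names(dp)))
  expect_equal(nrow(call_clade_specific(vs4, g)), 0)
})

test_that("no-data samples fail the depth clause even with high depth elsewhere", {
  g <- two_clade_groups(2, 1)
  dp <- setNames(c(30, NA, 30), c("flor_01", "flor_02", "wine_01"))
  counts <- list(flor_01 = c(0, 30), flor_02 = c(NA, NA), wine_01 = c(30, 0))
  vs <- make_site_vs("A", "T", dp, counts)
  expect_equal(nrow(call_clade_specific(vs, g)), 0)
})

test_that("empty or overlapping groups are rejected", {
  g <- two_clade_groups(2, 1)
  vs <- make_site_vs("A", "T",
                     setNames(c(30, 30, 30), c("flor_01", "flor_02", "wine_01")),
                     list(flor_01 = c(0, 30), flor_02 = c(0, 30), wine_01 = c(30, 0)))
  expect_error(group_config(setNames(c("flor", "flor"), c("s1", "s1"))),
               "duplicated")
  ghost <- group_config(setNames(c("flor", "wine"), c("flor_01", "nope")), "flor")
  expect_error(call_clade_specific(vs, ghost), "absent")
})

test_that("the optimized filter matches the brute-force predicate on random sites", {
  set.seed(42)
  g <- two_clade_groups(3, 3)
  ins <- c("flor_01", "flor_02", "flor_03")
  outs <- c("wine_01", "wine_02", "wine_03")
  n_agree <- 0
  n_pass <- 0
  for (rep in 1:1500) {
    s <- random_site(c(ins, outs), 3)
    counts <- lapply(seq_len(ncol(s$ar)), function(j) s$ar[, j])
    names(counts) <- colnames(s$ar)
    vs <- make_site_vs(s$ref, s$alts, s$dp, counts)
    got <- call_clade_specific(vs, g)
    want <- oracle_clade_site(s$ar, s$dp, ins, outs)
    expect_equal(nrow(got) == 1, want$pass)
    if (want$pass) {
      expect_equal(got$clade_allele, want$allele)
      n_pass <- n_pass + 1
    }
    n_agree <- n_agree + 1
  }
  expect_gt(n_pass, 10)  # the sweep exercised the accepting branch
})

test_that("raising thresholds never increases the call count", {
  dir <- withr::local_tempdir()
  sim <- generate_dataset(sim_config(seed = 31, support_noise = 0.05), dir)
  vs <- read_variants(sim$paths$vcf, sim$groups)
  counts_depth <- vapply(c(10, 20, 30, 45, 61), function(d) {
    nrow(call_clade_specific(vs, sim$groups, filter_thresholds(min_depth = d)))
  }, numeric(1))
  expect_true(all(diff(counts_depth) <= 0))
  counts_freq <- vapply(c(0.6, 0.75, 0.9, 0.97, 1), function(f) {
    nrow(call_clade_specific(vs, sim$groups, filter_thresholds(min_group_freq = f)))
  }, numeric(1))
  expect_true(all(diff(counts_freq) <= 0))
})

test_that("swapping clade labels reports the same sites with roles exchanged", {
  dir <- withr::local_tempdir()
  sim <- generate_dataset(sim_config(seed = 32), dir)
  vs <- read_variants(sim$paths$vcf, sim$groups)
  fwd <- call_clade_specific(vs, sim$groups)
  swapped <- group_config(sim$groups$groups, in_clade = "wine")
  rev <- call_clade_specific(vs, swapped)
  expect_equal(rev$pos, fwd$pos)
  expect_true(all(rev$clade_allele != fwd$clade_allele))
  expect_equal(rev$out_alleles, fwd$clade_allele)
})

test_that("every emitted call re-satisfies all predicate clauses post hoc", {
  dir <- withr::local_tempdir()
  sim <- generate_dataset(sim_config(seed = 33, support_noise = 0.05), dir)
  vs <- read_variants(sim$paths$vcf, sim$groups)
  calls <- call_clade_specific(vs, sim$groups)
  ins <- c("flor_01", "flor_02", "flor_03")
  outs <- sprintf("wine_%02d", 1:5)
  for (k in seq_len(nrow(calls))) {
    i <- which(vs$sites$pos == calls$pos[k])
    want <- oracle_clade_site(vs$ar[[i]], vs$dp[i, ], ins, outs)
    expect_true(want$pass)
    expect_equal(want$allele, calls$clade_allele[k])
  }
})

test_that("locus counting maps calls to owning genes or intergenic intervals", {
  gA <- make_gene("geneA", cds = rbind(c(301, 600)), up = 100, dn = 100)
  gB <- make_gene("geneB", cds = rbind(c(2001, 2300)), up = 100, dn = 100)
  genes <- structure(list(geneA = gA, geneB = gB), class = "gene_models")
  set.seed(9)
  genome <- list(chr1 = random_dna(3000))
  mkcalls <- function(pos) {
    ref <- substring(genome$chr1, pos, pos)
    alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
    structure(data.frame(chrom = "chr1", pos = pos, ref = ref, alts = alt,
                         clade_allele = alt, stringsAsFactors = FALSE),
              class = c("clade_calls", "data.frame"))
  }
  # three calls inside geneA -> one locus
  expect_equal(summarize_loci(mkcalls(c(310, 400, 550)), genes, genome)$n_loci, 1)
  # two in geneA, one between the genes (outside windows) -> two loci
  expect_equal(summarize_loci(mkcalls(c(310, 400, 1200)), genes, genome)$n_loci, 2)
  # property: locus count never exceeds call count
  for (rep in 1:20) {
    pos <- sample(2900, sample(1:12, 1))
    res <- summarize_loci(mkcalls(pos), genes, genome)
    expect_lte(res$n_loci, length(pos))
  }
})
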