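# Site selection rules, concatenation, p-distances and neighbor joining.

test_that("tree sites require per-sample majors to pass both bounds and vary", {
  samples <- c("s1", "s2", "s3")
  mk <- function(t_reads, dp = c(30, 30, 30)) {
    counts <- lapply(seq_along(dp), function(i) c(dp[i] - t_reads[i], t_reads[i]))
    names(counts) <- samples
    make_site_vs("A", "T", setNames(dp, samples), counts)
  }
  # all majors A -> invariant -> excluded
  expect_equal(nrow(select_tree_sites(mk(c(1, 1, 1)))$alleles), 0)
  # (A, A, T), all freqs >= 0.9, depth 30 -> retained
  m <- select_tree_sites(mk(c(1, 1, 29)))
  expect_equal(nrow(m$alleles), 1)
  expect_equal(unname(m$alleles[1, ]), c("A", "A", "T"))
  # one sample at 0.8 major frequency -> dropped
  expect_equal(nrow(select_tree_sites(mk(c(1, 6, 29)))$alleles), 0)
  # depth 19 in one sample -> dropped
  expect_equal(nrow(select_tree_sites(mk(c(1, 1, 29), dp = c(30, 19, 30)))$alleles), 0)
})

test_that("retained cells re-satisfy the selection predicates post hoc", {
  dir <- withr::local_tempdir()
  sim <- generate_dataset(sim_config(seed = 71, support_noise = 0.05), dir)
  vs <- read_variants(sim$paths$vcf, sim$groups)
  m <- select_tree_sites(vs)
  expect_gt(nrow(m$alleles), 0)
  for (k in seq_len(nrow(m$alleles))) {
    i <- which(vs$sites$pos == m$sites$pos[k])
    for (s in seq_along(m$samples)) {
      dp <- vs$dp[i, s]
      fr <- vs$ar[[i]][m$alleles[k, s], s] / dp
      expect_gte(dp, 20)
      expect_gte(fr, 0.9)
      expect_equal(fr, max(vs$ar[[i]][, s] / dp))  # truly the major allele
    }
    expect_gte(length(unique(m$alleles[k, ])), 2)
  }
})

test_that("indel sites are dropped under snps_only and dash-encoded otherwise", {
  samples <- c("s1", "s2")
  counts <- list(s1 = c(1, 29), s2 = c(29, 1))
  vs <- make_site_vs("A", "AT", setNames(c(30, 30), samples), counts)
  expect_equal(nrow(select_tree_sites(vs)$alleles), 0)
  m <- select_tree_sites(vs, snps_only = FALSE)
  expect_equal(nrow(m$alleles), 1)
  seqs <- concatenate_snp_matrix(m)
  expect_equal(unname(seqs["s1"]), "-")
  expect_equal(unname(seqs["s2"]), "A")
})

test_that("concatenation yields equal-length pseudo-sequences that round-trip FASTA", {
  dir <- withr::local_tempdir()
  sim <- generate_dataset(sim_config(seed = 72), dir)
  vs <- read_variants(sim$paths$vcf, sim$groups)
  m <- select_tree_sites(vs)
  fa <- file.path(dir, "aln.fa")
  seqs <- concatenate_snp_matrix(m, fasta_path = fa)
  expect_true(all(nchar(seqs) == nrow(m$alleles)))
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(back), m$samples)
  expect_equal(unname(as.character(back)), unname(seqs))
  expect_error(concatenate_snp_matrix(select_tree_sites(make_site_vs(
    "A", "T", c(s1 = 30, s2 = 30), list(s1 = c(29, 1), s2 = c(29, 1))
  ))), "empty")
})

test_that("p-distance equals the brute-force mismatch proportion", {
  m <- structure(list(
    samples = c("s1", "s2", "s3"),
    sites = data.frame(chrom = "chr1", pos = 1:10),
    alleles = cbind(s1 = rep("A", 10),
                    s2 = c(rep("A", 5), rep("T", 5)),
                    s3 = rep("T", 10))
  ), class = "snp_matrix")
  d <- p_distance(m)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 1.0)
  expect_equal(d, t(d))
  set.seed(73)
  am <- matrix(sample(c("A", "C", "G", "T"), 60, replace = TRUE), 20, 3,
               dimnames = list(NULL, c("x", "y", "z")))
  m2 <- structure(list(samples = c("x", "y", "z"),
                       sites = data.frame(chrom = "chr1", pos = 1:20),
                       alleles = am), class = "snp_matrix")
  d2 <- p_distance(m2)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d2[i, j], sum(am[, i] != am[, j]) / 20)
  }
})

test_that("three taxa solve in closed form and a 4-taxon split is recovered", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d3)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))
  # additive ((A,B),(C,D)) distances
  d4 <- matrix(c(0, 2, 7, 7,
                 2, 0, 7, 7,
                 7, 7, 0, 2,
                 7, 7, 2, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- neighbor_joining(d4)
  expect_true(is_clade_monophyletic(tr4, c("A", "B")))
  expect_true(is_clade_monophyletic(tr4, c("C", "D")))
  expect_error(neighbor_joining(d3[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ recovers the topology of random additive matrices (vs ape oracle)", {
  set.seed(74)
  for (rep in 1:25) {
    case <- random_additive_case(sample(6:10, 1))
    tr <- neighbor_joining(case$d)
    expect_setequal(tr$tip.label, case$tree$tip.label)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(case$tree))), 0)
    # independent implementation agrees on the same input
    ref <- ape::nj(case$d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
  }
})

test_that("negative branch lengths are clamped to zero", {
  d <- matrix(c(0, 0.1, 0.4, 0.5,
                0.1, 0, 0.45, 0.55,
                0.4, 0.45, 0, 0.05,
                0.5, 0.55, 0.05, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("flor-analog samples are monophyletic on clade-structured data", {
  for (seed in c(81, 82)) {
    dir <- withr::local_tempdir()
    sim <- generate_dataset(sim_config(seed = seed, support_noise = 0.05), dir)
    vs <- read_variants(sim$paths$vcf, sim$groups)
    tr <- neighbor_joining(p_distance(select_tree_sites(vs)))
    expect_true(is_clade_monophyletic(tr, sprintf("flor_%02d", 1:3)))
  }
})
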