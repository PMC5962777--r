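# Breadth-of-coverage presence/absence, shared/exclusive partitions and the
# strict-inequality novelty rule.

test_that("coverage fraction is breadth over the gene span", {
  gene <- make_gene("geneA", cds = rbind(c(101, 400)))  # 300 bp span
  expect_equal(coverage_fraction(data.frame(start = 101, end = 250), gene), 0.5)
  expect_equal(coverage_fraction(data.frame(start = 101, end = 400), gene), 1.0)
  expect_equal(coverage_fraction(data.frame(start = numeric(0), end = numeric(0)), gene), 0)
  # overlapping intervals are unioned, not double counted
  iv <- data.frame(start = c(101, 150), end = c(200, 260))
  expect_equal(coverage_fraction(iv, gene), 160 / 300)
  expect_error(coverage_fraction(data.frame(start = 50, end = 120), gene), "outside")
})

test_that("random interval sets agree with the per-base bitmap oracle", {
  set.seed(61)
  gene <- make_gene("geneA", cds = rbind(c(1001, 1600)))
  for (rep in 1:50) {
    k <- sample(1:8, 1)
    st <- sample(1001:1590, k, replace = TRUE)
    en <- pmin(st + sample(0:120, k, replace = TRUE), 1600)
    iv <- data.frame(start = st, end = en)
    expect_equal(coverage_fraction(iv, gene), oracle_coverage_fraction(iv, gene))
  }
})

test_that("missing calls use a strict < threshold", {
  fr <- c(geneA = 0.49, geneB = 0.50, geneC = 0.51, geneD = 0)
  expect_setequal(call_missing(fr, 0.5), c("geneA", "geneD"))
  # lowering the threshold never adds missing genes
  for (thr in c(0.5, 0.4, 0.25, 0.1)) {
    expect_true(all(call_missing(fr, thr) %in% call_missing(fr, 0.5)))
  }
  expect_error(call_missing(c(g = 1.2)), "\\[0,1\\]")
  # a second evidence track (assembly coverage) must concur for a missing call
  assembly <- c(geneA = 0.1, geneB = 0.9, geneC = 0.9, geneD = 0.9)
  expect_equal(call_missing(fr, 0.5, confirm_fractions = assembly), "geneA")
})

test_that("shared/exclusive partition matches set algebra", {
  per <- list(s1 = c("a", "b"), s2 = c("a"), s3 = c("a"))
  res <- shared_missing(per)
  expect_equal(res$shared, "a")
  expect_equal(res$exclusive$s1, "b")
  expect_equal(res$exclusive$s2, character(0))
  same <- list(s1 = c("x", "y"), s2 = c("x", "y"))
  res2 <- shared_missing(same)
  expect_setequal(res2$shared, c("x", "y"))
  expect_true(all(lengths(res2$exclusive) == 0))
  expect_error(shared_missing(list(s1 = "a")), ">= 2 strains")
  # |shared| <= min per-strain size, on random sets
  set.seed(62)
  for (rep in 1:20) {
    per_r <- lapply(1:3, function(i) sample(letters, sample(0:10, 1)))
    names(per_r) <- paste0("s", 1:3)
    expect_lte(length(shared_missing(per_r)$shared), min(lengths(per_r)))
  }
})

test_that("planted deletions are recovered exactly from the coverage table", {
  dir <- withr::local_tempdir()
  sim <- generate_dataset(sim_config(seed = 63, n_deleted_genes_clade_a = 4), dir)
  cov <- read_coverage(sim$paths$coverage)
  per_strain <- lapply(split(cov, cov$sample), function(df) {
    call_missing(setNames(df$covered_fraction, df$gene_id))
  })
  flor <- sprintf("flor_%02d", 1:3)
  truth_genes <- sort(unique(sim$truth$deleted_genes$gene_id))
  for (s in flor) expect_equal(per_strain[[s]], truth_genes)
  for (s in sprintf("wine_%02d", 1:5)) expect_equal(per_strain[[s]], character(0))
  res <- shared_missing(per_strain[flor])
  expect_equal(res$shared, truth_genes)
  expect_true(all(lengths(res$exclusive) == 0))
})

test_that("novelty boundary cases follow the strict 70%/80% reading", {
  qlen <- c(q1 = 100, q2 = 100, q3 = 100)
  hit <- function(q, pid, al) {
    data.frame(query_id = q, subject_id = "s", percent_identity = pid,
               alignment_length = al, mismatches = 0, gap_opens = 0,
               q_start = 1, q_end = al, s_start = 1, s_end = al,
               evalue = 1e-5, bit_score = 100, stringsAsFactors = FALSE)
  }
  hits <- rbind(hit("q1", 69, 95),   # identity too low -> novel
                hit("q2", 95, 79),   # coverage too low -> novel
                hit("q3", 71, 81))   # both bounds crossed -> known
  expect_setequal(novel_genes(hits, qlen), c("q1", "q2"))
  # exactly-at-the-bound hits do NOT rescue a candidate ("more than")
  hits_edge <- rbind(hit("q1", 70, 100), hit("q2", 95, 80), hit("q3", 70.1, 80.1))
  expect_setequal(novel_genes(hits_edge, qlen), c("q1", "q2"))
  expect_error(novel_genes(hit("ghost", 99, 99), qlen), "unknown query")
})

test_that("planted novel genes are detected from the emitted hit table", {
  dir <- withr::local_tempdir()
  sim <- generate_dataset(sim_config(seed = 64, n_novel_genes = 3), dir)
  hits <- read_hits(sim$paths$hits)
  q <- florvar:::read_tsv_commented(sim$paths$queries,
                                    col.names = c("gene_id", "length"),
                                    colClasses = c("character", "numeric"))
  novel <- novel_genes(hits, setNames(q$length, q$gene_id))
  expect_setequal(novel, sim$truth$novel_genes$gene_id)
})

test_that("non-reference presence statuses split at 0.95 and 0.5", {
  fr <- c(r1 = 0.98, r2 = 0.3, r3 = 0.7, r4 = 0.95, r5 = 0.4999)
  st <- nonreference_presence(fr)
  expect_equal(unname(st), c("present", "absent", "truncated", "present", "absent"))
  expect_error(nonreference_presence(fr, present_threshold = 0.3,
                                     missing_threshold = 0.5), "must be >=")
})
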