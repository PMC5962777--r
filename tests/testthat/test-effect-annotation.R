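# Effect classification against gene models: worked codon examples, the
# full-CDS translation oracle, strand symmetry, precedence, tabulation and
# the dN/dS count ratio.

# A tiny + strand gene whose first codons are known: build the chromosome
# explicitly so expected codon changes are readable.
fixed_gene_fixture <- function(strand = "+") {
  cds_seq <- "ATGGCTCAACGTTTAGGCTAA"  # M A Q R L G *
  chrom <- paste0(random_dna(100),
                  if (strand == "+") cds_seq else dna_rc(cds_seq),
                  random_dna(100))
  genome <- list(chr1 = chrom)
  gene <- make_gene("geneA", strand = strand, cds = rbind(c(101, 121)),
                    up = 50, dn = 50)
  list(gene = gene, genome = genome)
}

dna_rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

test_that("codon-level worked examples classify as expected on both strands", {
  fx <- fixed_gene_fixture("+")
  genes <- structure(list(geneA = fx$gene), class = "gene_models")
  # GCT -> GCC, both Ala (third position of codon 2 = pos 106)
  expect_equal(classify_variant("chr1", 106, "T", "C", genes, fx$genome)$category,
               "synonymous")
  # CAA -> TAA introduces a stop
  expect_equal(classify_variant("chr1", 107, "C", "T", genes, fx$genome)$category,
               "stop_splice")
  # GCT -> GAT is Ala -> Asp
  expect_equal(classify_variant("chr1", 105, "C", "A", genes, fx$genome)$category,
               "missense")
  # single-base deletion inside the CDS
  del <- classify_variant("chr1", 104, substr(fx$genome$chr1, 104, 105),
                          substr(fx$genome$chr1, 104, 104), genes, fx$genome)
  expect_equal(del$category, "frameshift")
  # 50 bp 5' of the gene with a window covering it
  up <- classify_variant("chr1", 51, substr(fx$genome$chr1, 51, 51), "A",
                         genes, fx$genome, check_ref = FALSE)
  expect_equal(up$category, "upstream")
  # the same codon positions classify identically on the minus strand
  fm <- fixed_gene_fixture("-")
  genes_m <- structure(list(geneA = fm$gene), class = "gene_models")
  # pos 116 on the genome is codon-2 third base read on the minus strand
  ref <- substr(fm$genome$chr1, 116, 116)  # complement of T in GCT
  expect_equal(ref, "A")
  expect_equal(classify_variant("chr1", 116, "A", "G", genes_m, fm$genome)$category,
               "synonymous")
})

test_that("a reference mismatch against the genome is a data error", {
  fx <- fixed_gene_fixture("+")
  genes <- structure(list(geneA = fx$gene), class = "gene_models")
  wrong <- setdiff(c("A", "C", "G", "T"),
                   substr(fx$genome$chr1, 106, 106))[1]
  expect_error(classify_variant("chr1", 106, wrong, "C", genes, fx$genome),
               "mismatch")
  expect_error(classify_variant("chrX", 106, "T", "C", genes, fx$genome),
               "absent")
})

test_that("classification agrees with the full-CDS translation oracle", {
  set.seed(101)
  n_checked <- 0
  for (rep in 1:40) {
    fx <- random_gene_fixture()
    genes <- structure(list(geneA = fx$gene), class = "gene_models")
    map <- florvar:::cds_map(fx$gene, fx$genome)
    for (k in 1:8) {
      j <- sample(length(map$gpos), 1)
      pos <- map$gpos[j]
      ref <- substr(fx$genome$chr1, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- primary_category(classify_variant("chr1", pos, ref, alt, genes, fx$genome))
      want <- oracle_classify_substitution(fx$gene, fx$genome, pos, ref, alt)
      expect_equal(got$category, want)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 320)
})

test_that("intron interiors, splice edges and windows classify by geometry", {
  gene <- make_gene("geneA", cds = rbind(c(101, 160), c(201, 400)),
                    up = 50, dn = 50)
  genes <- structure(list(geneA = gene), class = "gene_models")
  set.seed(5)
  genome <- list(chr1 = random_dna(600))
  cls <- function(pos) {
    ref <- substr(genome$chr1, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    primary_category(classify_variant("chr1", pos, ref, alt, genes, genome))$category
  }
  expect_equal(cls(180), "intron")
  expect_equal(cls(161), "stop_splice")  # first 2 nt of the intron
  expect_equal(cls(162), "stop_splice")
  expect_equal(cls(199), "stop_splice")  # last 2 nt
  expect_equal(cls(75), "upstream")
  expect_equal(cls(430), "downstream")
  expect_equal(cls(520), "intergenic")
})

test_that("reverse-complementing the genome leaves every category unchanged", {
  set.seed(77)
  for (rep in 1:10) {
    fx <- random_gene_fixture()
    genes <- structure(list(geneA = fx$gene), class = "gene_models")
    L <- nchar(fx$genome$chr1)
    map <- florvar:::cds_map(fx$gene, fx$genome)
    j <- sample(length(map$gpos), 1)
    pos <- map$gpos[j]
    ref <- substr(fx$genome$chr1, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- primary_category(classify_variant("chr1", pos, ref, alt, genes, fx$genome))
    # mirror the world: flip genome, strand and coordinates
    genome_rc <- list(chr1 = dna_rc(fx$genome$chr1))
    cds_rc <- cbind(L - fx$gene$cds[, 2] + 1, L - fx$gene$cds[, 1] + 1)
    gene_rc <- make_gene("geneA", strand = if (fx$gene$strand == "+") "-" else "+",
                         cds = cds_rc, up = 50, dn = 50)
    genes_rc <- structure(list(geneA = gene_rc), class = "gene_models")
    rev <- primary_category(classify_variant("chr1", L - pos + 1,
                                             dna_rc(ref), dna_rc(alt),
                                             genes_rc, genome_rc))
    expect_equal(rev$category, fwd$category)
  }
})

test_that("primary category follows severity then lexicographic gene id", {
  recs <- data.frame(
    gene_id = c("geneB", "geneA"),
    category = c("upstream", "missense"),
    detail = "", stringsAsFactors = FALSE
  )
  expect_equal(primary_category(recs)$gene_id, "geneA")
  expect_equal(primary_category(recs)$category, "missense")
  recs2 <- data.frame(gene_id = c("geneB", "geneA"),
                      category = c("upstream", "downstream"),
                      detail = "", stringsAsFactors = FALSE)
  expect_equal(primary_category(recs2)$category, "upstream")
  tie <- data.frame(gene_id = c("geneB", "geneA"),
                    category = c("upstream", "upstream"),
                    detail = "", stringsAsFactors = FALSE)
  expect_equal(primary_category(tie)$gene_id, "geneA")
  one <- recs[1, , drop = FALSE]
  expect_equal(primary_category(one), one)
  expect_error(primary_category(recs[0, ]), "at least one")
})

test_that("category tabulation partitions any record set", {
  expect_equal(attr(tabulate_categories(data.frame(category = character(0))), "total"), 0L)
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(0:200, 1)
    eff <- data.frame(category = sample(CATEGORY_LEVELS, n, replace = TRUE))
    tab <- tabulate_categories(eff)
    expect_equal(sum(unclass(tab)), n)
    expect_equal(attr(tab, "total"), n)
  }
})

test_that("dN/dS is the raw missense/synonymous count ratio with flags", {
  expect_equal(round(dn_ds(c(missense = 982, synonymous = 583)), 2), 1.68)
  expect_equal(dn_ds(c(missense = 5, synonymous = 5)), 1)
  expect_identical(dn_ds(c(missense = 3, synonymous = 0)), Inf)
  expect_true(is.nan(dn_ds(c(missense = 0, synonymous = 0))))
  tab <- tabulate_categories(
    data.frame(category = rep(c("missense", "synonymous"), c(4, 2)))
  )
  expect_equal(dn_ds(tab), 2)
})
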