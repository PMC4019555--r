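# Coordinate model and flat-file round trips.

test_that("joined CDS locations become ordered exon lists with derived introns", {
  seq <- rand_dna(400)
  path <- withr::local_tempfile(fileext = ".gb")
  toy_genbank(path, seq, list(
    list(key = "CDS", location = "join(1..100,201..300)",
         qualifiers = c('/gene="toy"'))))
  ann <- read_annotated_genome(path, "genbank")
  expect_length(ann$genes, 1)
  gm <- ann$genes[[1]]
  expect_length(gm$exons, 2)
  expect_equal(gm$coding_length, 200L)
  expect_length(gm$introns, 1)
  expect_equal(interval_length(gm$introns[[1]]$interval, 400L), 100L)
  expect_equal(gm$introns[[1]]$interval$start, 101L)
  expect_equal(gm$introns[[1]]$interval$end, 200L)
})

test_that("minus-strand joined locations come out in transcription order", {
  seq <- rand_dna(400)
  path <- withr::local_tempfile(fileext = ".gb")
  toy_genbank(path, seq, list(
    list(key = "CDS", location = "complement(join(50..100,201..250))",
         qualifiers = c('/gene="neg"'))))
  gm <- read_annotated_genome(path, "genbank")$genes[[1]]
  expect_equal(gm$strand, "-")
  # 5' exon of a minus-strand gene is the genomically rightmost one
  expect_equal(gm$exons[[1]]$start, 201L)
  expect_equal(gm$exons[[2]]$start, 50L)
  expect_equal(gm$span$start, 50L)
  expect_equal(gm$span$end, 250L)
})

test_that("a CDS joined across the origin wraps as a single gene", {
  seq <- rand_dna(160)
  path <- withr::local_tempfile(fileext = ".gb")
  toy_genbank(path, seq, list(
    list(key = "CDS", location = "join(150..160,1..30)",
         qualifiers = c('/gene="wrap"'))))
  gm <- read_annotated_genome(path, "genbank")$genes[[1]]
  expect_length(gm$exons, 1)
  expect_true(gm$exons[[1]]$wraps_origin)
  # brute-force position count across the origin: 150..160 plus 1..30
  expect_equal(gm$coding_length, length(c(150:160, 1:30)))
  expect_equal(gm$coding_length, 41L)
  # and the spliced sequence stitches across the origin
  expect_equal(interval_sequence(read_annotated_genome(path, "genbank")$genome,
                                 gm$exons[[1]]),
               paste0(substr(seq, 150, 160), substr(seq, 1, 30)))
})

test_that("a feature beyond sequence length on a linear record errors", {
  seq <- rand_dna(100)
  path <- withr::local_tempfile(fileext = ".gb")
  toy_genbank(path, seq, list(
    list(key = "CDS", location = "40..120", qualifiers = c('/gene="bad"'))),
    circular = FALSE)
  expect_error(read_annotated_genome(path, "genbank"), "exceeds sequence length")
})

test_that("malformed coordinates name the offending feature", {
  seq <- rand_dna(100)
  path <- withr::local_tempfile(fileext = ".gb")
  toy_genbank(path, seq, list(
    list(key = "CDS", location = "join(10..x)", qualifiers = c('/gene="oops"'))))
  expect_error(read_annotated_genome(path, "genbank"), "oops")
})

test_that("tRNA features yield anticodon records with correct locus lengths", {
  seq <- rand_dna(200)
  path <- withr::local_tempfile(fileext = ".gb")
  toy_genbank(path, seq, list(
    list(key = "tRNA", location = "20..91",
         qualifiers = c('/gene="tRNA-Ile"',
                        '/anticodon="(pos:52..54,aa:Ile,seq:gat)"'))))
  ann <- read_annotated_genome(path, "genbank")
  expect_length(ann$trnas, 1)
  tr <- ann$trnas[[1]]
  expect_equal(tr$anticodon, "GAU")
  expect_equal(interval_length(tr$locus, 200L), 72L)
})

test_that("EMBL flat files parse equivalently to GenBank", {
  seq <- rand_dna(300)
  path <- withr::local_tempfile(fileext = ".embl")
  writeLines(c(
    "ID   TOY; SV 1; circular; genomic DNA; STD; UNC; 300 BP.",
    "FH   Key             Location/Qualifiers",
    "FT   CDS             join(10..60,101..160)",
    'FT                   /gene="toy"',
    "SQ   Sequence 300 BP;",
    paste("    ", tolower(seq)),
    "//"), path)
  ann <- read_annotated_genome(path, "embl")
  expect_equal(ann$genome$length, 300L)
  expect_true(ann$genome$circular)
  expect_equal(ann$genes[[1]]$coding_length, 111L)
})

test_that("GFF3 round trip preserves coordinates, strand and exon structure", {
  set.seed(31)
  L <- 5000L
  genome <- circular_genome("toy", rand_dna(L))
  genes <- list(
    gene_model("a", "protein",
               list(feature_interval(101, 400, "+"),
                    feature_interval(501, 700, "+")), "+",
               genome_length = L, stop_codon = "TAA"),
    gene_model("b", "protein",
               list(feature_interval(2001, 2300, "-"),
                    feature_interval(1201, 1500, "-")), "-",
               genome_length = L, stop_codon = "TAG"),
    gene_model("t", "tRNA", list(feature_interval(3000, 3071, "+")), "+",
               genome_length = L),
    # wrapped single-exon gene across the origin
    gene_model("w", "protein",
               list(feature_interval(4801, 100, "+", wraps_origin = TRUE)),
               "+", genome_length = L, stop_codon = "TAA"))
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gff <- file.path(dir, "g.gff3")
  write_genome_fasta(genome, fa)
  write_annotation(genes, gff, "gff3", genome = genome)
  back <- read_annotated_genome(gff, "gff3", fasta = fa)
  expect_length(back$genes, length(genes))
  nm <- vapply(back$genes, function(g) g$name, "")
  for (g in genes) {
    g2 <- back$genes[[match(g$name, nm)]]
    expect_equal(g2$strand, g$strand)
    expect_equal(length(g2$exons), length(g$exons))
    for (j in seq_along(g$exons)) {
      expect_equal(g2$exons[[j]]$start, g$exons[[j]]$start)
      expect_equal(g2$exons[[j]]$end, g$exons[[j]]$end)
      expect_equal(g2$exons[[j]]$wraps_origin, g$exons[[j]]$wraps_origin)
    }
    expect_equal(g2$coding_length, g$coding_length)
  }
})

test_that("BED output is 0-based half-open with exon blocks", {
  L <- 2000L
  gm <- gene_model("atp6-like", "protein",
                   list(feature_interval(1, 777, "+")), "+",
                   genome_length = L, stop_codon = "TAA")
  path <- withr::local_tempfile(fileext = ".bed")
  write_annotation(list(gm), path, "bed",
                   genome = circular_genome("g", rand_dna(L)))
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.integer(f[2]), 0L)     # 1-based 1 -> 0-based 0
  expect_equal(as.integer(f[3]), 777L)
  expect_equal(f[6], "+")
  expect_equal(as.integer(f[10]), 1L)
})

test_that("newick round trip preserves topology and branch lengths", {
  # two-leaf base case
  t2 <- ape::read.tree(text = "(A:0.1,B:0.2);")
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t2, p)
  expect_equal(readLines(p), "(A:0.1,B:0.2);")
  # random multifurcating-capable case
  set.seed(5)
  tr <- ape::rtree(8)
  write_newick(tr, p)
  back <- ape::read.tree(p)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  co1 <- ape::cophenetic.phylo(tr); co2 <- ape::cophenetic.phylo(back)
  expect_lt(max(abs(co1 - co2[rownames(co1), colnames(co1)])), 1e-9)
})

test_that("genome rotation preserves gene lengths and circular distances", {
  spec <- small_spec(duplication = list(enabled = FALSE),
                     repeat_families = list(n_families = 0))
  tr <- generate_genome(spec, seed = 2)
  L <- tr$genome$length
  rot <- rotate_truth(tr, 4321L)
  len0 <- vapply(tr$genes, function(g) g$coding_length, 0L)
  len1 <- vapply(rot$genes, function(g) g$coding_length, 0L)
  expect_equal(len1, len0)
  mid <- function(gs) vapply(gs, function(g)
    mitofeatures:::interval_midpoint(g$span, L), 0L)
  m0 <- mid(tr$genes); m1 <- mid(rot$genes)
  d0 <- outer(m0, m0, function(a, b) pmin(abs(a - b), L - abs(a - b)))
  d1 <- outer(m1, m1, function(a, b) pmin(abs(a - b), L - abs(a - b)))
  expect_equal(d1, d0)
})
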