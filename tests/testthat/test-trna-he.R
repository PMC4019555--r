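# Wobble decoding, unassigned codons, HE similarity vs. locus distance.

test_that("wobble rules expand anticodons to their codon sets", {
  # wobble U reads all four third-position bases
  expect_setequal(wobble_decodes("UGC"), c("GCA", "GCU", "GCG", "GCC"))
  # wobble G reads C or U
  expect_setequal(wobble_decodes("GAA"), c("UUC", "UUU"))
  # A and C pair Watson-Crick only
  expect_equal(wobble_decodes("CAU"), "AUG")
  expect_equal(wobble_decodes("CCA"), "UGG")
  expect_equal(wobble_decodes("AAU"), "AUU")
  # the reassignment flag turns a CAU anticodon into an AUA reader
  expect_equal(wobble_decodes("CAU", ile_cau_reassignment = TRUE), "AUA")
  expect_error(wobble_decodes("XYZ"), "RNA triplet")
})

test_that("the published 28-tRNA set decodes everything except AUA and UGA", {
  recs <- phlebia_anticodon_records()
  expect_length(recs, 28)
  usage <- count_codons("ATGTTT")
  no_flag <- decoding_check(recs, usage, ile_cau_reassignment = FALSE)
  expect_setequal(no_flag$undecodable, c("AUA", "UGA"))
  flagged <- decoding_check(recs, usage, ile_cau_reassignment = TRUE)
  expect_equal(flagged$undecodable, "UGA")
  expect_match(flagged$reassignment_notes, "AUA")
  # decodable and undecodable partition the sense codons of code 4
  expect_equal(sort(c(flagged$decodable, flagged$undecodable)),
               sort(chartr("T", "U", setdiff(
                 names(Biostrings::getGeneticCode("4")), c("TAA", "TAG")))))
})

test_that("codons used but undecodable are flagged with their counts", {
  recs <- phlebia_anticodon_records()
  # UUU is read both by tRNA-Phe (GAA, wobble G) and by the wobble-U
  # tRNA-Leu (UAA reads UUN); both must go before UUU becomes undecodable
  recs <- Filter(function(r) !r$anticodon %in% c("GAA", "UAA"), recs)
  usage <- count_codons(strrep("TTT", 7))
  rep_ <- decoding_check(recs, usage, ile_cau_reassignment = TRUE)
  expect_true("UUU" %in% rep_$undecodable)
  expect_equal(rep_$undecodable_used$conserved_count[
    rep_$undecodable_used$codon == "UUU"], 7L)
})

test_that("codons present only outside conserved ORFs become unassigned candidates", {
  recs <- phlebia_anticodon_records()
  conserved <- count_codons("ATGTTTAAA")
  other <- count_codons(paste0("CGG", "CGG", "AGG"))
  rep_ <- decoding_check(recs, conserved, other)
  expect_setequal(rep_$unassigned_candidates$codon[
    rep_$unassigned_candidates$other_count > 0], c("CGG", "AGG"))
  expect_equal(rep_$unassigned_candidates$other_count[
    rep_$unassigned_candidates$codon == "CGG"], 2L)
})

test_that("pairwise identity is exact on gap-free cases", {
  d1 <- he_domain_record("GIY-YIG", paste0(strrep("A", 4), strrep("LMNPQ", 4)),
                         feature_interval(100, 171))
  # identical sequences align at 100%
  m <- pairwise_identity(list(d1, d1))
  expect_equal(unname(m[1, 2]), 100)
  # single substitution in an equal-length pair: 75% over 4 columns...
  a <- he_domain_record("GIY-YIG", "AAAAAAAAAAAA", feature_interval(1, 36))
  b <- he_domain_record("GIY-YIG", "AAAAAATAAAAA", feature_interval(40, 75))
  m2 <- pairwise_identity(list(a, b))
  expect_equal(unname(m2[1, 2]), 100 * 11 / 12)
  expect_equal(m2, t(m2))
})

test_that("family identity summaries match brute-force recomputation", {
  set.seed(15)
  aas <- Biostrings::AA_STANDARD
  doms <- lapply(1:4, function(i)
    he_domain_record("LAGLIDADG1",
                     paste(sample(aas, 40, TRUE), collapse = ""),
                     feature_interval(i * 1000, i * 1000 + 119)))
  m <- pairwise_identity(doms)
  ut <- m[upper.tri(m)]
  # independent recomputation of min/max/mean from the same alignments
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(doms[[i]]$aa_sequence),
      Biostrings::AAString(doms[[j]]$aa_sequence),
      type = "global",
      substitutionMatrix = mitofeatures:::aa_identity_matrix(),
      gapOpening = 5, gapExtension = 1)
    vals <- c(vals, 100 * Biostrings::nmatch(aln) /
                nchar(as.character(Biostrings::alignedPattern(aln))))
  }
  expect_equal(sort(ut), sort(vals))
  expect_equal(c(min(ut), max(ut), mean(ut)),
               c(min(vals), max(vals), mean(vals)))
})

test_that("domain length outside the plausible band errors", {
  expect_error(he_domain_record("GIY-YIG", "SHORT", feature_interval(1, 15)),
               "10-600")
})

test_that("circular locus distances wrap and are bounded by L/2", {
  mk <- function(s, e) he_domain_record("GIY-YIG", strrep("ACDEF", 8),
                                        feature_interval(s, e))
  L <- 1000L
  # midpoints 1 and L: circular distance 1
  d <- circular_distance_matrix(list(mk(1, 1), mk(L, L)), L)
  expect_equal(unname(d[1, 2]), 1L)
  d2 <- circular_distance_matrix(list(mk(10, 10), mk(110, 110)), L)
  expect_equal(unname(d2[1, 2]), 100L)
  set.seed(21)
  doms <- lapply(sample(L, 12), function(p) mk(p, p))
  dm <- circular_distance_matrix(doms, L)
  expect_lte(max(dm), L %/% 2)
  expect_equal(dm, t(dm))
  # rotation invariance
  doms_rot <- lapply(doms, function(dd) {
    p <- mitofeatures:::canon_pos(dd$locus$start + 333L, L)
    mk(p, p)
  })
  expect_equal(unname(circular_distance_matrix(doms_rot, L)), unname(dm))
  # triangle inequality on the circle
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12)
    expect_lte(dm[i, j], dm[i, k] + dm[k, j])
})

test_that("Pearson correlation matches the textbook formula on a hand dataset", {
  # 4 loci -> 6 pairs; build matrices whose upper triangles carry the vectors
  sim <- matrix(0, 4, 4); dist <- matrix(0, 4, 4)
  x <- c(12, 25, 31, 44, 58, 69); y <- c(80, 62, 59, 41, 30, 18)
  sim[upper.tri(sim)] <- x; sim <- sim + t(sim)
  dist[upper.tri(dist)] <- y; dist <- dist + t(dist)
  res <- correlate_similarity_distance(sim, dist, "pearson", "none")
  n <- 6
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$n_pairs, 6L)
  t_stat <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_stat), n - 2),
               tolerance = 1e-12)
})

test_that("perfect linear relation gives r = 1 with a tiny p-value", {
  sim <- matrix(0, 5, 5); dist <- matrix(0, 5, 5)
  v <- 1:10
  sim[upper.tri(sim)] <- v; sim <- sim + t(sim)
  dist[upper.tri(dist)] <- 3 * v + 2; dist <- dist + t(dist)
  res <- correlate_similarity_distance(sim, dist, "pearson")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-9)
})

test_that("degenerate constant input yields a no-result, not NaN", {
  sim <- matrix(5, 4, 4); diag(sim) <- 0
  dist <- matrix(0, 4, 4); dist[upper.tri(dist)] <- 1:6
  dist <- dist + t(dist)
  res <- correlate_similarity_distance(sim, dist)
  expect_true(is.na(res$r))
  expect_match(res$note, "degenerate")
  expect_no_error(print(res))
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(30)
  sim <- matrix(0, 5, 5); dist <- matrix(0, 5, 5)
  v1 <- runif(10); v2 <- runif(10)
  sim[upper.tri(sim)] <- v1; sim <- sim + t(sim)
  dist[upper.tri(dist)] <- v2; dist <- dist + t(dist)
  r1 <- correlate_similarity_distance(sim, dist, "spearman")$r
  r2 <- correlate_similarity_distance(exp(sim * 3), dist, "spearman")$r
  expect_equal(r2, r1, tolerance = 1e-12)
})

test_that("log transform admits zero similarities", {
  sim <- matrix(0, 4, 4)
  sim[upper.tri(sim)] <- c(0, 2, 5, 8, 12, 20); sim <- sim + t(sim)
  dist <- matrix(0, 4, 4)
  dist[upper.tri(dist)] <- c(60, 50, 40, 30, 20, 10); dist <- dist + t(dist)
  res <- correlate_similarity_distance(sim, dist, "pearson", "log")
  expect_false(is.na(res$r))
  expect_equal(res$transform, "log")
})

test_that("Mantel permutation p-value is seeded and sensible", {
  set.seed(12)
  n <- 8
  pos <- sort(runif(n))
  sim <- -as.matrix(stats::dist(pos)); diag(sim) <- 0
  dist <- as.matrix(stats::dist(pos))
  r1 <- correlate_similarity_distance(sim, dist, "pearson",
                                      mantel_permutations = 199, seed = 5)
  r2 <- correlate_similarity_distance(sim, dist, "pearson",
                                      mantel_permutations = 199, seed = 5)
  expect_identical(r1$mantel_p, r2$mantel_p)
  expect_lt(r1$mantel_p, 0.05)   # perfectly anti-correlated structure
  expect_equal(r1$r, -1, tolerance = 1e-12)
})

test_that("too few pairs is an explicit insufficient-data signal", {
  sim <- matrix(0, 2, 2); dist <- matrix(0, 2, 2)
  expect_error(correlate_similarity_distance(sim, dist), "insufficient")
})
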