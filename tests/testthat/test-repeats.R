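# Repeat discovery, clustering, inverted duplication, coverage.

test_that("a planted exact direct repeat is found with identity 1", {
  set.seed(1)
  S <- rand_dna(100)
  g <- circular_genome("t", paste0(rand_dna(300), S, rand_dna(400), S,
                                   rand_dna(300)))
  pr <- self_compare(g)
  direct <- Filter(function(p) p$orientation == "direct", pr)
  expect_gte(length(direct), 1)
  hit <- direct[[which.max(vapply(direct, function(p) p$length, 0L))]]
  expect_gte(hit$identity, 1 - 1e-12)
  expect_gte(hit$length, 100L)
  expect_lte(abs(hit$interval_a$start - 301L), 3L)
  expect_lte(abs(hit$interval_b$start - 801L), 3L)
})

test_that("a planted inverted repeat is found in inverted orientation", {
  set.seed(2)
  S <- rand_dna(100)
  g <- circular_genome("t", paste0(rand_dna(300), S, rand_dna(400), rc(S),
                                   rand_dna(300)))
  pr <- self_compare(g)
  inv <- Filter(function(p) p$orientation == "inverted", pr)
  expect_gte(length(inv), 1)
  hit <- inv[[which.max(vapply(inv, function(p) p$length, 0L))]]
  expect_gte(hit$length, 100L)
  expect_gte(hit$identity, 1 - 1e-12)
})

test_that("parameter validation rejects bad search settings", {
  g <- circular_genome("t", rand_dna(500))
  expect_error(self_compare(g, seed_k = 5), "seed_k")
  expect_error(self_compare(g, min_len = 8), "min_len")
  expect_error(self_compare(g, min_identity = 1.2), "min_identity")
})

test_that("reported hits match direct recomputation from the sequence", {
  spec <- small_spec(duplication = list(enabled = FALSE),
                     repeat_families = list(n_families = 3,
                                            members_per_family = 3))
  tr <- generate_genome(spec, seed = 13)
  found <- self_compare(tr$genome, seed_k = 9)
  expect_gt(length(found), 0)
  S <- tr$genome$residues
  for (fp in found) {
    sa <- substr(S, fp$interval_a$start, fp$interval_a$end)
    sb <- substr(S, fp$interval_b$start, fp$interval_b$end)
    if (fp$orientation == "inverted") sb <- rc(sb)
    expect_equal(nchar(sa), fp$length)
    expect_equal(mean(strsplit(sa, "")[[1]] == strsplit(sb, "")[[1]]),
                 fp$identity, tolerance = 1e-12)
  }
})

test_that("planted families at 85% identity are recovered accurately", {
  spec <- small_spec(duplication = list(enabled = FALSE),
                     repeat_families = list(n_families = 4,
                                            members_per_family = 3,
                                            identity = 0.85))
  tr <- generate_genome(spec, seed = 42)
  found <- self_compare(tr$genome, seed_k = 9)
  m <- match_planted_repeats(tr$repeats, found)
  expect_gte(m$recall, 0.95)
  expect_lte(m$max_identity_error, 0.02)
})

test_that("brute-force oracle agrees on small genomes", {
  set.seed(33)
  S1 <- rand_dna(70); S2 <- rand_dna(45)
  seqs <- paste0(rand_dna(300), S1, rand_dna(400), S2, rand_dna(250), S1,
                 rand_dna(300), S2, rand_dna(200))
  g <- circular_genome("t", seqs, circular = FALSE)
  oracle <- brute_force_exact_repeats(seqs, 30L)
  found <- self_compare(g, min_len = 30L, orientation = "direct")
  # every maximal exact repeat the oracle finds is contained in a reported
  # hit...
  for (r in seq_len(nrow(oracle))) {
    covered <- any(vapply(found, function(p)
      p$interval_a$start <= oracle$a_start[r] &&
      p$interval_a$end >= oracle$a_end[r] &&
      p$interval_b$start <= oracle$b_start[r] &&
      p$interval_b$end >= oracle$b_end[r], NA))
    expect_true(covered, label = sprintf("oracle repeat %d covered", r))
  }
  # ...and every reported hit contains an oracle-listed exact core
  for (p in found) {
    has_core <- any(oracle$a_start >= p$interval_a$start - 5 &
                    oracle$a_end <= p$interval_a$end + 5 &
                    oracle$b_start >= p$interval_b$start - 5 &
                    oracle$b_end <= p$interval_b$end + 5)
    expect_true(has_core)
  }
})

test_that("hits crossing the origin are found on circular genomes", {
  set.seed(14)
  S <- rand_dna(120)
  # copy 1 plain, copy 2 straddling the origin
  body <- paste0(rand_dna(500), S, rand_dna(1000))
  tail_len <- 60L
  g <- circular_genome("t", paste0(
    substr(S, tail_len + 1L, 120), body,
    substr(S, 1L, tail_len)))
  pr <- self_compare(g)
  wrapped <- Filter(function(p)
    p$interval_a$wraps_origin || p$interval_b$wraps_origin, pr)
  expect_gte(length(wrapped), 1)
  expect_gte(max(vapply(wrapped, function(p) p$length, 0L)), 120L)
})

test_that("self-comparison of the reverse complement mirrors the pairs", {
  spec <- small_spec(duplication = list(enabled = FALSE),
                     repeat_families = list(n_families = 3,
                                            members_per_family = 2))
  tr <- generate_genome(spec, seed = 27)
  L <- tr$genome$length
  f1 <- self_compare(tr$genome, seed_k = 9)
  f2 <- self_compare(circular_genome("rc", rc(tr$genome$residues)),
                     seed_k = 9)
  expect_equal(length(f1), length(f2))
  key <- function(p, L, mirror) {
    ivs <- list(p$interval_a, p$interval_b)
    coords <- lapply(ivs, function(iv) {
      if (mirror) sort(c(L - iv$start + 1L, L - iv$end + 1L))
      else c(iv$start, iv$end)
    })
    coords <- coords[order(vapply(coords, `[`, 0L, 1))]
    paste(p$orientation, paste(unlist(coords), collapse = "_"))
  }
  k1 <- sort(vapply(f1, key, "", L = L, mirror = FALSE))
  k2 <- sort(vapply(f2, key, "", L = L, mirror = TRUE))
  expect_equal(k2, k1)
})

test_that("greedy clustering groups identical members at every level", {
  set.seed(3)
  S <- rand_dna(50)
  g <- circular_genome("t", paste0(rand_dna(200), S, rand_dna(300), S,
                                   rand_dna(300), S, rand_dna(200)))
  pr <- self_compare(g, orientation = "direct")
  cl <- cluster_repeats(pr, g)
  for (lv in names(cl)) {
    # one cluster per level; the same copy may enter under slightly
    # different extents from different pairs, so members >= copies
    expect_equal(length(cl[[lv]]), 1, label = lv)
    expect_gte(length(cl[[lv]][[1]]$members), 3)
  }
})

test_that("cascaded cut-offs merge at 0.75 and split at 0.80", {
  set.seed(44)
  motifA <- rand_dna(80)
  # family B: 22% diverged from A (cross-identity ~0.78); members within a
  # family differ by ~3%
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(v), k)
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  motifB <- mutate(motifA, 18)
  a1 <- motifA; a2 <- mutate(motifA, 2)
  b1 <- motifB; b2 <- mutate(motifB, 2)
  g <- circular_genome("t", paste0(
    rand_dna(150), a1, rand_dna(150), a2, rand_dna(150),
    b1, rand_dna(150), b2, rand_dna(150)))
  # verify the constructed identities by brute-force alignment
  idy <- function(x, y) mitofeatures:::align_identity(x, y)
  expect_gte(idy(a1, a2), 0.9); expect_gte(idy(b1, b2), 0.9)
  expect_lt(idy(a1, b1), 0.80); expect_gte(idy(a1, b1), 0.75)
  members <- list(
    feature_interval(151, 230), feature_interval(381, 460),
    feature_interval(611, 690), feature_interval(841, 920))
  pairs <- list(
    repeat_pair(members[[1]], members[[2]], "direct", 0.97, 80),
    repeat_pair(members[[3]], members[[4]], "direct", 0.97, 80),
    repeat_pair(members[[1]], members[[3]], "direct", 0.78, 80))
  cl <- cluster_repeats(pairs, g)
  expect_equal(length(cl$cutoff_0.75), 1)
  expect_equal(length(cl$cutoff_0.8), 2)
  expect_equal(length(cl$cutoff_0.9), 2)
})

test_that("cluster counts are non-increasing as the cut-off decreases", {
  spec <- small_spec(duplication = list(enabled = FALSE),
                     repeat_families = list(n_families = 4,
                                            members_per_family = 3))
  tr <- generate_genome(spec, seed = 50)
  pr <- self_compare(tr$genome, seed_k = 9)
  cl <- cluster_repeats(pr, tr$genome)
  n <- vapply(cl, length, 0L)
  expect_true(all(diff(n) >= 0))       # 0.75 <= 0.80 <= 0.90 cluster counts
  expect_error(cluster_repeats(pr, tr$genome, cutoffs = c(0.9, 0.8)),
               "increasing")
  expect_equal(cluster_repeats(list(), tr$genome),
               setNames(rep(list(list()), 3),
                        c("cutoff_0.75", "cutoff_0.8", "cutoff_0.9")))
})

test_that("every cluster member aligns to its representative at the cut-off", {
  spec <- small_spec(duplication = list(enabled = FALSE),
                     repeat_families = list(n_families = 3,
                                            members_per_family = 3))
  tr <- generate_genome(spec, seed = 61)
  pr <- self_compare(tr$genome, seed_k = 9)
  cl <- cluster_repeats(pr, tr$genome)
  for (lv in names(cl)) for (cc in cl[[lv]]) {
    rep_seq <- interval_sequence(tr$genome, cc$representative)
    for (m in cc$members) {
      expect_gte(mitofeatures:::align_identity(
        interval_sequence(tr$genome, m), rep_seq), cc$cutoff_level)
    }
  }
})

test_that("planted inverted duplication is recovered at exact boundaries", {
  spec <- synthetic_genome_spec(
    length_bp = 25000,
    genes = data.frame(name = c("g1", "g2"),
                       feature_class = c("protein", "protein"),
                       coding_bp = c(900, 1200), n_introns = c(1, 0),
                       strand = c("+", "-"), stringsAsFactors = FALSE),
    duplication = list(length_bp = 6076, n_edits = 3),
    repeat_families = list(n_families = 0))
  tr <- generate_genome(spec, seed = 42)
  dd <- find_inverted_duplication(tr$genome)
  expect_length(dd, 1)
  d <- dd[[1]]
  expect_equal(d$region_1$start, tr$duplication$region_1$start)
  expect_equal(d$region_1$end, tr$duplication$region_1$end)
  expect_equal(d$region_2$start, tr$duplication$region_2$start)
  expect_equal(d$region_2$end, tr$duplication$region_2$end)
  expect_equal(nrow(d$mismatches), 3)
  expect_setequal(d$mismatches$class,
                  c("substitution", "insertion", "deletion"))
})

test_that("a duplication planted across the origin is still recovered", {
  spec <- synthetic_genome_spec(
    length_bp = 25000,
    genes = data.frame(name = c("g1", "g2"),
                       feature_class = c("protein", "protein"),
                       coding_bp = c(900, 1200), n_introns = c(1, 0),
                       strand = c("+", "-"), stringsAsFactors = FALSE),
    duplication = list(length_bp = 4000, n_edits = 3),
    repeat_families = list(n_families = 0))
  tr0 <- generate_genome(spec, seed = 7)
  tr <- rotate_truth(tr0, tr0$duplication$region_2$start + 1500L)
  expect_true(tr$duplication$region_2$wraps_origin)
  dd <- find_inverted_duplication(tr$genome)
  expect_length(dd, 1)
  d <- dd[[1]]
  expect_equal(d$region_1$start, tr$duplication$region_1$start)
  expect_equal(d$region_2$start, tr$duplication$region_2$start)
  expect_equal(d$region_2$end, tr$duplication$region_2$end)
  expect_equal(nrow(d$mismatches), 3)
})

test_that("palindrome-free random sequence yields no duplication report", {
  set.seed(9)
  g <- circular_genome("t", rand_dna(12000))
  expect_length(find_inverted_duplication(g), 0)
})

test_that("repeat coverage merges overlaps and respects the partition", {
  L <- 1000L
  g <- circular_genome("t", rand_dna(L))
  pairs <- list(repeat_pair(feature_interval(1, 100),
                            feature_interval(51, 150), "direct", 1, 100))
  cov <- repeat_coverage(pairs, list(), g)
  expect_equal(cov$total_bp, 150L)
  expect_equal(cov$total_fraction, 0.15)
  expect_equal(cov$intergenic_fraction, 0.15)
  # order invariance
  pairs2 <- rev(pairs)
  expect_equal(repeat_coverage(pairs2, list(), g), cov)
})

test_that("repeats planted only in spacers give zero coding coverage", {
  spec <- small_spec(duplication = list(enabled = FALSE),
                     repeat_families = list(n_families = 3,
                                            members_per_family = 3))
  tr <- generate_genome(spec, seed = 70)
  cov <- repeat_coverage(tr$repeats, tr$genes, tr$genome)
  expect_equal(cov$coding_bp, 0L)
  expect_gt(cov$intergenic_bp, 0L)
})
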