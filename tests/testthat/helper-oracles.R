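# Shared fixtures and independent oracles used across the suite.

# random DNA of a given GC content
rand_dna <- function(n, gc = 0.31) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Independent brute-force oracle: all maximal exact direct repeat pairs of
# length >= min_len on a LINEAR sequence, by scanning every diagonal for
# match runs. O(n^2), for small fixtures only.
brute_force_exact_repeats <- function(s, min_len) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(b)
  out <- list()
  for (d in seq_len(n - 1L)) {
    v <- b[seq_len(n - d)] == b[(1L + d):n]
    r <- rle(v)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_len) {
        i <- pos[k]
        out[[length(out) + 1L]] <- c(a_start = i, a_end = i + r$lengths[k] - 1L,
                                     b_start = i + d,
                                     b_end = i + d + r$lengths[k] - 1L)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# fraction of iv1 covered by iv2 (non-wrapping intervals)
interval_cov <- function(iv1, iv2) {
  s <- max(iv1$start, iv2$start); e <- min(iv1$end, iv2$end)
  max(0, e - s + 1) / (iv1$end - iv1$start + 1)
}

# match planted repeat pairs against reported ones; returns recall and the
# largest |reported - planted| identity among matched pairs
match_planted_repeats <- function(truth_pairs, found_pairs,
                                  min_side_cov = 0.8) {
  rec <- 0L; max_err <- 0
  for (tp in truth_pairs) {
    ok <- FALSE
    for (fp in found_pairs) {
      if (fp$orientation != tp$orientation) next
      o1 <- min(interval_cov(tp$interval_a, fp$interval_a),
                interval_cov(tp$interval_b, fp$interval_b))
      o2 <- min(interval_cov(tp$interval_a, fp$interval_b),
                interval_cov(tp$interval_b, fp$interval_a))
      if (max(o1, o2) >= min_side_cov) {
        ok <- TRUE
        max_err <- max(max_err, abs(fp$identity - tp$identity))
        break
      }
    }
    rec <- rec + ok
  }
  list(recall = rec / max(1L, length(truth_pairs)), max_identity_error = max_err)
}

# minimal GenBank record writer for parser tests
toy_genbank <- function(path, seq, features, circular = TRUE) {
  lines <- c(sprintf("LOCUS       TOY       %d bp    DNA     %s   UNA",
                     nchar(seq), if (circular) "circular" else "linear"),
             "FEATURES             Location/Qualifiers")
  for (f in features) {
    lines <- c(lines, sprintf("     %-16s%s", f$key, f$location))
    for (q in f$qualifiers)
      lines <- c(lines, sprintf("                     %s", q))
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1, nchar(seq), by = 60))
    lines <- c(lines, sprintf("%9d %s", i,
                              tolower(substr(seq, i, min(i + 59, nchar(seq))))))
  lines <- c(lines, "//")
  writeLines(lines, path)
  path
}

# small synthetic spec used by several tests (kept identical across files so
# genomes are comparable)
small_spec <- function(...) {
  args <- list(
    length_bp = 15000,
    genes = data.frame(name = c("g1", "g2"),
                       feature_class = c("protein", "protein"),
                       coding_bp = c(900, 1200), n_introns = c(1, 1),
                       strand = c("+", "-"), stringsAsFactors = FALSE),
    intron_len_range = c(200L, 800L),   # keep spacer budget for repeats
    duplication = list(length_bp = 2500L),
    repeat_families = list(n_families = 3L, members_per_family = 3L))
  user <- list(...)
  args[names(user)] <- user
  do.call(synthetic_genome_spec, args)
}

# circular distance between positions
circ_dist <- function(a, b, L) {
  d <- abs(a - b)
  min(d, L - d)
}

codon_split_for_test <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}
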