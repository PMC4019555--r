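# Dispersed/inverted repeat discovery by genome self-comparison, greedy
# identity clustering with cascaded cut-offs, inverted-duplication detection,
# and repeat coverage accounting.
#
# Discovery is an exact k-mer seed + ungapped X-drop extension, in the style
# of a blastn self-search: seeds on the forward strand for direct repeats and
# against the reverse complement for inverted ones. Circular genomes are
# searched on a doubled sequence so hits may cross the origin; coordinates
# are canonicalized back onto the circle and symmetric duplicates removed.
# Filtering is by identity and length; a Karlin-Altschul style E-value is
# attached for reporting only.

#' Construct a repeat pair
#'
#' @param interval_a,interval_b [feature_interval()]s of the two copies
#'   (canonical order: `interval_a` starts first).
#' @param orientation `"direct"` or `"inverted"`.
#' @param identity fraction of matching columns in (0, 1].
#' @param length alignment length in bp.
#' @param evalue optional E-value-like score (reporting only).
#' @export
repeat_pair <- function(interval_a, interval_b, orientation, identity,
                        length, evalue = NA_real_) {
  structure(list(interval_a = interval_a, interval_b = interval_b,
                 orientation = orientation, identity = identity,
                 length = as.integer(length), evalue = evalue),
            class = "repeat_pair")
}

#' @export
print.repeat_pair <- function(x, ...) {
  cat(sprintf("<repeat_pair> %s %d..%d ~ %d..%d, %d bp, %.1f%% identity\n",
              x$orientation, x$interval_a$start, x$interval_a$end,
              x$interval_b$start, x$interval_b$end, x$length,
              100 * x$identity))
  invisible(x)
}

# Karlin-Altschul-like expectation for an ungapped DNA hit (+1/-2 scoring)
evalue_like <- function(matches, mismatches, search_space) {
  lambda <- 1.28; K <- 0.46
  s <- matches - 2 * mismatches
  K * search_space * exp(-lambda * s)
}

# --- seed + extend engine on plain character vectors ------------------------

# ungapped X-drop extension of a seed match between vectors a (at i..i+k-1)
# and b (at j..j+k-1); returns trimmed 1-based bounds and match count.
# A mild mismatch penalty (1) keeps mismatch-dense repeat ends inside the
# reported hit; a harsher one (2) trims to sharper maximal boundaries.
xdrop_extend <- function(a, b, i, j, k, xdrop = 20L, max_len = Inf,
                         mismatch = 1L) {
  score <- k; best <- k
  # right extension
  ri <- i + k - 1L; rj <- j + k - 1L
  bri <- ri; brj <- rj
  while (ri < length(a) && rj < length(b) && (bri - i + 1L) < max_len) {
    ri <- ri + 1L; rj <- rj + 1L
    score <- score + if (a[ri] == b[rj] && a[ri] != "N") 1L else -mismatch
    if (score > best) { best <- score; bri <- ri; brj <- rj }
    if (score <= best - xdrop) break
  }
  # left extension
  score <- best
  li <- i; lj <- j; bli <- i; blj <- j
  while (li > 1L && lj > 1L && (bri - bli + 1L) < max_len) {
    li <- li - 1L; lj <- lj - 1L
    score <- score + if (a[li] == b[lj] && a[li] != "N") 1L else -mismatch
    if (score > best) { best <- score; bli <- li; blj <- lj }
    if (score <= best - xdrop) break
  }
  len <- bri - bli + 1L
  nm <- sum(a[bli:bri] == b[blj:brj] & a[bli:bri] != "N")
  list(ai = bli, aj = bri, bi = blj, bj = brj, len = len, matches = nm)
}

# Trim hit ends whose outermost `w`-window is inconsistent with the hit's
# own core identity (a 3-sigma binomial outlier with a variance floor), then
# make both ends land on a match. This removes low-identity chance
# excursions into the flanks while leaving mismatch-dense but statistically
# ordinary repeat ends alone -- a fixed threshold close to the repeat's true
# identity would clip genuine ends and bias reported identities upward.
refine_ends <- function(a, b, ext, w = 16L) {
  m <- a[ext$ai:ext$aj] == b[ext$bi:ext$bj] & a[ext$ai:ext$aj] != "N"
  n <- length(m)
  core <- if (n >= 4L * w) mean(m[(n %/% 4L):(3L * n %/% 4L)]) else mean(m)
  sdw <- sqrt(max(core * (1 - core), 0.05 * 0.95) / w)
  thr <- max(0.5, core - 3 * sdw)
  lo <- 1L; hi <- n
  while (hi - lo + 1L >= w && mean(m[lo:(lo + w - 1L)]) < thr) lo <- lo + 1L
  while (hi - lo + 1L >= w && mean(m[(hi - w + 1L):hi]) < thr) hi <- hi - 1L
  while (lo <= hi && !m[lo]) lo <- lo + 1L
  while (hi >= lo && !m[hi]) hi <- hi - 1L
  if (lo > hi) return(NULL)
  list(ai = ext$ai + lo - 1L, aj = ext$ai + hi - 1L,
       bi = ext$bi + lo - 1L, bj = ext$bi + hi - 1L,
       len = hi - lo + 1L, matches = sum(m[lo:hi]))
}

# positions of every k-mer, bucketed, ambiguous k-mers dropped
kmer_buckets <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kms <- substring(s, starts, starts + k - 1L)
  keep <- !grepl("N", kms, fixed = TRUE)
  split(starts[keep], kms[keep])
}

# raw ungapped hits between character sequences sa and sb (already doubled
# for circular searches); self = TRUE when sa and sb are the same molecule
# in the same orientation (suppresses the trivial diagonal)
raw_hits <- function(sa, sb, seed_k, min_len, min_identity, xdrop = 20L,
                     self_diag_period = NA_integer_, max_len = Inf,
                     mismatch = 1L) {
  a <- chars(sa); b <- chars(sb)
  ba <- kmer_buckets(sa, seed_k)
  bb <- if (identical(sa, sb)) ba else kmer_buckets(sb, seed_k)
  shared <- intersect(names(ba), names(bb))
  hits <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (km in shared) {
    pa <- ba[[km]]; pb <- bb[[km]]
    for (i in pa) for (j in pb) {
      if (identical(sa, sb) && j <= i) next
      d <- j - i
      if (!is.na(self_diag_period) && d %% self_diag_period == 0L) next
      dkey <- paste0(d, ":", (i %/% 64L))
      # cheap skip: if a previous hit on this diagonal covered this seed
      cov <- get0(paste0("d", d), envir = seen)
      if (!is.null(cov) && any(i >= cov[, 1] & i <= cov[, 2])) next
      ext <- xdrop_extend(a, b, i, j, seed_k, xdrop, max_len, mismatch)
      assign(paste0("d", d),
             rbind(cov, c(ext$ai, ext$aj)), envir = seen)
      # remove residual low-identity chance excursions from the hit ends
      ext <- refine_ends(a, b, ext)
      if (is.null(ext) || ext$len < min_len) next
      idy <- ext$matches / ext$len
      if (idy < min_identity) next
      hits[[length(hits) + 1L]] <-
        c(ai = ext$ai, aj = ext$aj, bi = ext$bi, bj = ext$bj,
          len = ext$len, matches = ext$matches)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(ai = integer(0), aj = integer(0), bi = integer(0),
                      bj = integer(0), len = integer(0),
                      matches = integer(0)))
  df <- as.data.frame(do.call(rbind, hits))
  unique(df)
}

# map a doubled-coordinate interval back onto the circle
fold_interval <- function(s, e, L, circular) {
  if (!circular) return(feature_interval(s, e))
  cs <- canon_pos(s, L); ce <- canon_pos(e, L)
  feature_interval(cs, ce, wraps_origin = cs > ce)
}

interval_key <- function(iv) paste(iv$start, iv$end, iv$wraps_origin, sep = "_")

# numeric ordering for canonical pair orientation
interval_before <- function(a, b) {
  a$start < b$start || (a$start == b$start && a$end < b$end)
}

#' Discover dispersed and inverted repeats by genome self-comparison
#'
#' @param genome a [circular_genome()].
#' @param seed_k exact seed length (>= 8; default 11).
#' @param min_len minimum reported hit length in bp (default 30).
#' @param min_identity minimum identity fraction in (0, 1] (default 0.75).
#' @param orientation `"both"`, `"direct"` or `"inverted"`.
#' @param xdrop X-drop extension cut-off in score units.
#' @return list of [repeat_pair()]; symmetric duplicates and the trivial
#'   full-length self-hit are removed, hits may cross the origin.
#' @export
self_compare <- function(genome, seed_k = 11L, min_len = 30L,
                         min_identity = 0.75, orientation = c("both",
                         "direct", "inverted"), xdrop = 20L) {
  orientation <- match.arg(orientation)
  if (seed_k < 8L) stop("seed_k must be >= 8")
  if (min_len < seed_k) stop("min_len must be >= seed_k")
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  L <- genome$length
  S <- genome$residues
  S2 <- if (genome$circular) paste0(S, S) else S
  space <- as.numeric(L)^2
  out <- list()
  seen <- character(0)
  add_pair <- function(iva, ivb, orient, len, matches) {
    # canonical order + duplicate suppression
    if (interval_key(iva) == interval_key(ivb)) return(invisible())
    if (interval_before(ivb, iva)) { tmp <- iva; iva <- ivb; ivb <- tmp }
    key <- paste(orient, interval_key(iva), interval_key(ivb))
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- repeat_pair(
      iva, ivb, orient, matches / len, len,
      evalue_like(matches, len - matches, space))
  }
  if (orientation %in% c("both", "direct")) {
    df <- raw_hits(S2, S2, seed_k, min_len, min_identity, xdrop,
                   self_diag_period = if (genome$circular) L else NA_integer_,
                   max_len = L, mismatch = 2L)
    for (r in seq_len(nrow(df))) {
      if (df$ai[r] > L) next                          # anchor in first copy
      add_pair(fold_interval(df$ai[r], df$aj[r], L, genome$circular),
               fold_interval(df$bi[r], df$bj[r], L, genome$circular),
               "direct", df$len[r], df$matches[r])
    }
  }
  if (orientation %in% c("both", "inverted")) {
    R <- revcomp_chr(S)
    R2 <- if (genome$circular) paste0(R, R) else R
    df <- raw_hits(S2, R2, seed_k, min_len, min_identity, xdrop,
                   max_len = L, mismatch = 2L)
    for (r in seq_len(nrow(df))) {
      if (df$ai[r] > L) next
      iva <- fold_interval(df$ai[r], df$aj[r], L, genome$circular)
      # revcomp coordinate p maps to genome position L - canon(p) + 1
      gs <- canon_pos(L - canon_pos(df$bj[r], L) + 1L, L)
      ge <- canon_pos(L - canon_pos(df$bi[r], L) + 1L, L)
      ivb <- feature_interval(gs, ge, wraps_origin = gs > ge)
      add_pair(iva, ivb, "inverted", df$len[r], df$matches[r])
    }
  }
  out
}

# --- greedy identity clustering --------------------------------------------

align_identity <- function(s1, s2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1), Biostrings::DNAString(s2), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / cols
}

#' Greedy longest-first clustering of repeat intervals with cascaded cut-offs
#'
#' CD-HIT style greedy incremental clustering of the repeat copies: member
#' intervals are sorted by length descending (ties by start, then end); each
#' joins the first cluster whose representative it matches at or above the
#' cut-off identity, otherwise it founds a new cluster. The cascade
#' re-clusters each level's clusters at the next, stricter cut-off, so the
#' cluster count is non-increasing as the cut-off decreases.
#'
#' @param pairs list of [repeat_pair()] from [self_compare()].
#' @param genome the [circular_genome()] the intervals refer to (sequences
#'   are needed for identity computation).
#' @param cutoffs ascending identity cut-offs applied in cascade
#'   (default `c(0.75, 0.80, 0.90)`).
#' @return named list, one element per cut-off level, each a list of
#'   clusters; a cluster is a list with `members` (list of
#'   [feature_interval()]), `representative` (the longest member) and
#'   `cutoff_level`.
#' @export
cluster_repeats <- function(pairs, genome, cutoffs = c(0.75, 0.80, 0.90)) {
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly increasing in cascade order")
  members <- list()
  keys <- character(0)
  for (p in pairs) for (iv in list(p$interval_a, p$interval_b)) {
    k <- interval_key(iv)
    if (!k %in% keys) { keys <- c(keys, k); members[[length(members) + 1L]] <- iv }
  }
  if (length(members) == 0L)
    return(stats::setNames(rep(list(list()), length(cutoffs)),
                           paste0("cutoff_", cutoffs)))
  L <- genome$length
  lens <- vapply(members, interval_length, 0L, genome_length = L)
  ord <- order(-lens, vapply(members, function(iv) iv$start, 0L),
               vapply(members, function(iv) iv$end, 0L))
  members <- members[ord]
  seqs <- vapply(members, function(iv) interval_sequence(genome, iv), "")

  greedy <- function(idx, cutoff) {
    clusters <- list()
    for (i in idx) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        rep_i <- clusters[[ci]]$rep_idx
        if (align_identity(seqs[i], seqs[rep_i]) >= cutoff) {
          clusters[[ci]]$idx <- c(clusters[[ci]]$idx, i)
          placed <- TRUE; break
        }
      }
      if (!placed)
        clusters[[length(clusters) + 1L]] <- list(rep_idx = i, idx = i)
    }
    clusters
  }

  levels <- list()
  current <- list(list(idx = seq_along(members)))   # one pot, pre-cascade
  for (co in cutoffs) {
    nxt <- list()
    for (cl in current) nxt <- c(nxt, greedy(cl$idx, co))
    levels[[paste0("cutoff_", co)]] <- lapply(nxt, function(cl)
      list(members = members[cl$idx],
           representative = members[[cl$rep_idx]],
           cutoff_level = co))
    current <- nxt
  }
  levels
}

# --- inverted duplication ---------------------------------------------------

#' Detect large inverted duplications (mirror regions)
#'
#' Finds the longest near-identical reverse-complement region pairs by
#' chaining collinear inverted self-comparison hits (indels in the
#' duplication split ungapped hits onto adjacent anti-diagonals) and then
#' aligning the two regions to produce an explicit mismatch list, with
#' substitutions and indels classified separately.
#'
#' @param genome a [circular_genome()].
#' @param min_len minimum duplication length in bp (default 1000).
#' @param seed_k seed length for the underlying search.
#' @param band maximum anti-diagonal drift (bp) when chaining hits across
#'   indels.
#' @param max_gap maximum unaligned gap (bp) between chained hits.
#' @return list of reports, each with `region_1`, `region_2`
#'   ([feature_interval()]s, region_1 on the plus strand), `length_bp`
#'   (inclusive length of region_1) and `mismatches` (data frame with
#'   `position` on the forward strand of region_1 or, for region-2-only
#'   bases, the nearest flanking position; `base_1`, `base_2`, `class` in
#'   substitution/insertion/deletion).
#' @export
find_inverted_duplication <- function(genome, min_len = 1000L, seed_k = 13L,
                                      band = 100L, max_gap = 500L) {
  L <- genome$length
  S <- genome$residues
  S2 <- if (genome$circular) paste0(S, S) else S
  R <- revcomp_chr(S)
  R2 <- if (genome$circular) paste0(R, R) else R
  seg_min <- max(as.integer(min_len %/% 8L), 2L * seed_k)
  df <- raw_hits(S2, R2, seed_k, seg_min, 0.85, xdrop = 30L, max_len = L,
                 mismatch = 2L)
  if (nrow(df) == 0L) return(list())
  # chain on near-constant diagonal: both coordinates advance together in
  # (forward, reverse-complement) space, so bi - ai drifts only at indels
  df$anti <- df$bi - df$ai
  df <- df[order(df$ai), , drop = FALSE]
  used <- rep(FALSE, nrow(df))
  chains <- list()
  for (r in order(-df$len)) {
    if (used[r]) next
    idx <- r; used[r] <- TRUE
    repeat {
      cur_a <- range(df$ai[idx], df$aj[idx])
      cur_anti <- stats::median(df$anti[idx])
      cand <- which(!used & abs(df$anti - cur_anti) <= band &
                      df$ai <= cur_a[2] + max_gap &
                      df$aj >= cur_a[1] - max_gap)
      if (length(cand) == 0L) break
      used[cand] <- TRUE
      idx <- c(idx, cand)
    }
    chains[[length(chains) + 1L]] <- idx
  }
  out <- list()
  seen <- character(0)
  for (idx in chains) {
    a0 <- min(df$ai[idx]); a1 <- max(df$aj[idx])
    b0 <- min(df$bi[idx]); b1 <- max(df$bj[idx])
    if ((a1 - a0 + 1L) < min_len) next
    iva <- fold_interval(a0, a1, L, genome$circular)
    gs <- canon_pos(L - canon_pos(b1, L) + 1L, L)
    ge <- canon_pos(L - canon_pos(b0, L) + 1L, L)
    ivb <- feature_interval(gs, ge, wraps_origin = gs > ge)
    if (interval_key(iva) == interval_key(ivb)) next
    if (interval_before(ivb, iva)) { tmp <- iva; iva <- ivb; ivb <- tmp }
    key <- paste(interval_key(iva), interval_key(ivb))
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- inverted_duplication_report(genome, iva, ivb)
  }
  # drop reports wholly contained in a larger one (origin-split images of
  # the same duplication chain onto different diagonals of the doubled
  # sequence and would otherwise be reported twice)
  if (length(out) > 1L) {
    msk <- function(iv) {
      m <- logical(L); m[interval_positions(iv, L)] <- TRUE; m
    }
    m1 <- lapply(out, function(d) msk(d$region_1))
    m2 <- lapply(out, function(d) msk(d$region_2))
    within <- function(a, b) !any(a & !b)
    keep <- rep(TRUE, length(out))
    ord <- order(-vapply(out, function(d) d$length_bp, 0L))
    for (ii in seq_along(ord)) for (jj in seq_along(ord)) {
      if (ii == jj) next
      big <- ord[ii]; small <- ord[jj]
      if (!keep[big] || !keep[small]) next
      if (out[[small]]$length_bp > out[[big]]$length_bp) next
      if ((within(m1[[small]], m1[[big]]) && within(m2[[small]], m2[[big]])) ||
          (within(m1[[small]], m2[[big]]) && within(m2[[small]], m1[[big]])))
        keep[small] <- FALSE
    }
    out <- out[keep]
  }
  out
}

# align region_1 (+) against revcomp(region_2) and classify every difference
inverted_duplication_report <- function(genome, iva, ivb) {
  s1 <- interval_sequence(genome, iva)
  iv2m <- feature_interval(ivb$start, ivb$end, "-", ivb$wraps_origin)
  s2 <- interval_sequence(genome, iv2m)           # revcomp of region 2
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1), Biostrings::DNAString(s2), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  p <- chars(as.character(Biostrings::alignedPattern(aln)))
  q <- chars(as.character(Biostrings::alignedSubject(aln)))
  L <- genome$length
  pos1 <- 0L
  mm <- list()
  for (k in seq_along(p)) {
    if (p[k] != "-") pos1 <- pos1 + 1L
    if (p[k] == q[k]) next
    gpos <- canon_pos(iva$start + max(pos1, 1L) - 1L, L)
    cls <- if (p[k] == "-") "insertion"            # extra base in region 2
           else if (q[k] == "-") "deletion"        # base absent from region 2
           else "substitution"
    mm[[length(mm) + 1L]] <- data.frame(
      position = gpos, base_1 = p[k], base_2 = q[k], class = cls,
      stringsAsFactors = FALSE)
  }
  mismatches <- if (length(mm)) do.call(rbind, mm) else
    data.frame(position = integer(0), base_1 = character(0),
               base_2 = character(0), class = character(0))
  identity <- Biostrings::nmatch(aln) / length(p)
  structure(list(region_1 = iva, region_2 = ivb,
                 length_bp = interval_length(iva, L),
                 identity = identity, mismatches = mismatches),
            class = "inverted_duplication_report")
}

#' @export
print.inverted_duplication_report <- function(x, ...) {
  cat(sprintf("<inverted_duplication> %d..%d ~ %d..%d (inverted), %d bp, %.3f identity, %d difference(s)\n",
              x$region_1$start, x$region_1$end, x$region_2$start,
              x$region_2$end, x$length_bp, x$identity, nrow(x$mismatches)))
  invisible(x)
}

#' Repeat coverage of the genome by annotation category
#'
#' Projects the union of all repeat intervals onto the genome (overlaps
#' merged) and intersects it with the coding/intronic/intergenic partition.
#' All fractions are of total genome length.
#'
#' @param pairs list of [repeat_pair()].
#' @param genes list of [gene_model()] defining the partition.
#' @param genome the [circular_genome()].
#' @return list with `total_bp`, `total_fraction`, and per-category bp and
#'   fractions (`coding_bp`, `intronic_bp`, `intergenic_bp`, ...).
#' @export
repeat_coverage <- function(pairs, genes, genome) {
  L <- genome$length
  mask <- logical(L)
  for (p in pairs) for (iv in list(p$interval_a, p$interval_b))
    mask[interval_positions(iv, L)] <- TRUE
  cat <- integer(L)
  for (gm in genes) for (ir in gm$introns)
    cat[interval_positions(ir$interval, L)] <- 1L
  for (gm in genes) for (ex in gm$exons)
    cat[interval_positions(ex, L)] <- 2L
  list(total_bp = sum(mask),
       total_fraction = sum(mask) / L,
       coding_bp = sum(mask & cat == 2L),
       coding_fraction = sum(mask & cat == 2L) / L,
       intronic_bp = sum(mask & cat == 1L),
       intronic_fraction = sum(mask & cat == 1L) / L,
       intergenic_bp = sum(mask & cat == 0L),
       intergenic_fraction = sum(mask & cat == 0L) / L)
}
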