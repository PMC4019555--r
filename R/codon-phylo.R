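# Codon-usage tabulation, codon-on-codon distances, neighbor joining, CAI,
# and positional GC content.

# the 64 codons in a fixed lexicographic order (DNA alphabet)
ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                    c("T", "C", "A", "G"), paste0),
                              c("T", "C", "A", "G"), paste0))

sense_codons <- function(code_table = "4") {
  code <- Biostrings::getGeneticCode(code_table)
  names(code)[code != "*"]
}

#' Tabulate codon usage over a set of coding sequences
#'
#' Counts codons over the concatenation of in-frame coding sequences. Codons
#' containing an ambiguous base (N) are skipped and counted in an ambiguity
#' tally rather than attributed to any codon.
#'
#' @param cds_set character vector of coding sequences (DNA), each with
#'   length divisible by 3 after applying `frame`.
#' @param taxon label for the table.
#' @param frame 1-based reading-frame offset (1 = first base).
#' @return object of class `codon_usage`: list with `taxon`, `counts` (named
#'   integer vector over the 64 codons), `ambiguous` (skipped codon count).
#' @examples
#' u <- count_codons("ATGTTTTTC")
#' u$counts[c("ATG", "TTT", "TTC")]
#' @export
count_codons <- function(cds_set, taxon = "cds_set", frame = 1L) {
  counts <- stats::setNames(integer(64), ALL_CODONS)
  ambiguous <- 0L
  for (s in cds_set) {
    s <- toupper(s)
    if (frame > 1L) s <- substring(s, frame)
    s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    if (nchar(s) == 0L) next
    cod <- codon_split(s)
    bad <- grepl("[^ACGT]", cod)
    ambiguous <- ambiguous + sum(bad)
    tab <- table(cod[!bad])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(taxon = taxon, counts = counts, ambiguous = ambiguous),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %s: %d codons counted (%d ambiguous skipped)\n",
              x$taxon, sum(x$counts), x$ambiguous))
  invisible(x)
}

#' Relative codon frequencies of a usage table
#'
#' Global relative frequencies (codon count / total over the included codon
#' set), not within-family RSCU. Stop codons are excluded by default since
#' protein-coding usage analyses concern sense codons.
#'
#' @param usage a [count_codons()] table.
#' @param include `"sense"` (default) or `"all"` (all 64 codons).
#' @param code_table NCBI genetic code id used to define sense codons.
#' @return named numeric vector summing to 1 (when any included codon was
#'   observed).
#' @export
codon_frequencies <- function(usage, include = c("sense", "all"),
                              code_table = "4") {
  include <- match.arg(include)
  keys <- if (include == "sense") sense_codons(code_table) else ALL_CODONS
  cnt <- usage$counts[keys]
  tot <- sum(cnt)
  if (tot == 0) stop("empty codon usage table: no included codons observed")
  cnt / tot
}

#' Within-family synonymous codon fractions
#'
#' For each amino-acid family, the fraction each synonymous codon contributes
#' to the family total (e.g. the share of TGT among Cys codons).
#'
#' @inheritParams codon_frequencies
#' @return data frame with columns `codon`, `amino_acid`, `count`, `fraction`
#'   (NA for families never observed).
#' @export
synonymous_fractions <- function(usage, code_table = "4") {
  code <- Biostrings::getGeneticCode(code_table)
  keys <- sense_codons(code_table)
  aa <- code[keys]
  cnt <- usage$counts[keys]
  fam_tot <- tapply(cnt, aa, sum)
  data.frame(codon = keys, amino_acid = unname(aa), count = unname(cnt),
             fraction = unname(ifelse(fam_tot[aa] > 0, cnt / fam_tot[aa], NA)),
             stringsAsFactors = FALSE)
}

#' Codon-on-codon RMSD distance between two usage tables
#'
#' The root mean squared difference of relative codon frequencies:
#' `sqrt(mean((f_a - f_b)^2))` over the included codon set. A metric on
#' frequency vectors.
#'
#' @param a,b [count_codons()] tables over the same codon key set.
#' @inheritParams codon_frequencies
#' @return non-negative scalar.
#' @export
rmsd_distance <- function(a, b, include = c("sense", "all"),
                          code_table = "4") {
  include <- match.arg(include)
  fa <- codon_frequencies(a, include, code_table)
  fb <- codon_frequencies(b, include, code_table)
  sqrt(mean((fa - fb)^2))
}

#' Sum-of-squared-differences distance between two usage tables
#'
#' As [rmsd_distance()] but the plain sum of squared frequency differences
#' (no mean, no square root); on a key set of size `m`,
#' `ssd = m * rmsd^2`.
#'
#' @inheritParams rmsd_distance
#' @return non-negative scalar.
#' @export
sum_squared_distance <- function(a, b, include = c("sense", "all"),
                                 code_table = "4") {
  include <- match.arg(include)
  fa <- codon_frequencies(a, include, code_table)
  fb <- codon_frequencies(b, include, code_table)
  sum((fa - fb)^2)
}

#' Pairwise codon-usage distance matrix for a set of taxa
#'
#' @param usages list of [count_codons()] tables (taxon labels must be
#'   unique).
#' @param method `"rmsd"` or `"ssd"`.
#' @inheritParams codon_frequencies
#' @return symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
codon_distance_matrix <- function(usages, method = c("rmsd", "ssd"),
                                  include = c("sense", "all"),
                                  code_table = "4") {
  method <- match.arg(method); include <- match.arg(include)
  taxa <- vapply(usages, function(u) u$taxon, "")
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  n <- length(usages)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  f <- if (method == "rmsd") rmsd_distance else sum_squared_distance
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- f(usages[[i]], usages[[j]], include, code_table)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomerative algorithm: at each step the pair minimising
#' the Q-criterion `Q_ij = (n-2) d_ij - r_i - r_j` is joined, with branch
#' lengths from the standard three-point formulas. Deterministic: among
#' equal-Q pairs the lexicographically smallest (sorted) taxon-name pair is
#' joined. Negative branch lengths are clamped to zero with the deficit
#' transferred to the sister branch; the raw (unclamped) lengths are kept in
#' the `raw_edge_length` attribute of the returned tree.
#'
#' @param d symmetric non-negative distance matrix with taxon dimnames and a
#'   zero diagonal (at least 3 taxa).
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")

  labels <- rownames(d)           # newick fragment per active node
  tipname <- rownames(d)          # smallest contained tip, for tie-breaking
  fmt <- function(x) sprintf("%.17g", x)
  clamp <- function(bi, bj) {
    raw <- c(bi, bj)
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    list(bi = max(bi, 0), bj = max(bj, 0), raw = raw)
  }
  raw_lengths <- list()

  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      nm <- sort(c(tipname[ij[1]], tipname[ij[2]]))
      paste(nm, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1]; j <- pick[2]
    dij <- d[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    cl <- clamp(bi, bj)
    raw_lengths[[length(raw_lengths) + 1L]] <-
      c(stats::setNames(cl$raw, c(tipname[i], tipname[j])))
    new_lab <- sprintf("(%s:%s,%s:%s)", labels[i], fmt(cl$bi),
                       labels[j], fmt(cl$bj))
    new_tip <- min(tipname[i], tipname[j])
    dnew <- (d[i, ] + d[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    labels <- c(labels[keep], new_lab)
    tipname <- c(tipname[keep], new_tip)
    rownames(d) <- colnames(d) <- tipname
  }

  # terminal 3-star: closed-form branch lengths
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  bs <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 labels[1], fmt(bs[1]), labels[2], fmt(bs[2]),
                 labels[3], fmt(bs[3]))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw_edge_length") <- raw_lengths
  tree
}

#' Codon Adaptation Index of an open reading frame
#'
#' Sharp-Li CAI: each reference codon gets a relative adaptiveness
#' `w(c) = count(c) / max count within its synonymous family`; the CAI of an
#' ORF is the geometric mean of `w` over its codons, excluding stop codons
#' and single-codon families (Met, Trp under the standard code). Codons with
#' zero reference count receive the pseudo-adaptiveness
#' `w = 0.5 / (family max count)` so a single unused codon cannot collapse
#' the index to zero. Reference families entirely unobserved are excluded
#' with a warning.
#'
#' @param orf coding sequence (DNA string, length divisible by 3).
#' @param reference a [count_codons()] table of the reference gene set.
#' @param code_table NCBI genetic code id defining synonymous families.
#' @return scalar in (0, 1].
#' @examples
#' ref <- count_codons(c(strrep("TTT", 3), "TTC"))  # Phe 3:1
#' compute_cai("TTTTTC", ref)                       # sqrt(1/3)
#' @export
compute_cai <- function(orf, reference, code_table = "4") {
  orf <- toupper(orf)
  if (nchar(orf) %% 3 != 0) stop("ORF length must be divisible by 3")
  code <- Biostrings::getGeneticCode(code_table)
  keys <- sense_codons(code_table)
  aa <- code[keys]
  fam_sizes <- table(aa)
  multi <- names(fam_sizes)[fam_sizes > 1L]       # skip single-codon families
  cnt <- reference$counts[keys]
  w <- stats::setNames(rep(NA_real_, length(keys)), keys)
  excluded_fams <- character(0)
  for (fam in multi) {
    idx <- which(aa == fam)
    mx <- max(cnt[idx])
    if (mx == 0) { excluded_fams <- c(excluded_fams, fam); next }
    wf <- cnt[idx] / mx
    wf[wf == 0] <- 0.5 / mx
    w[idx] <- wf
  }
  if (length(excluded_fams) > 0L)
    warning("reference families with zero counts excluded from CAI: ",
            paste(excluded_fams, collapse = ", "))
  cod <- codon_split(orf)
  wv <- w[cod]
  wv <- wv[!is.na(wv)]        # drops stops, single-codon and excluded families
  if (length(wv) == 0L) stop("no CAI-informative codons in ORF")
  exp(mean(log(wv)))
}

#' Positional GC content of a coding-sequence set
#'
#' GC percentage overall and at each codon position over the concatenated
#' in-frame coding sequences. Ambiguous bases (N) are excluded from both
#' numerator and denominator.
#'
#' @param cds_set character vector of coding sequences, lengths divisible
#'   by 3.
#' @return named numeric vector (percent): `gc_overall`, `gc1`, `gc2`, `gc3`.
#' @export
positional_gc <- function(cds_set) {
  s <- toupper(paste(cds_set, collapse = ""))
  if (nchar(s) %% 3 != 0) stop("total coding length must be divisible by 3")
  b <- chars(s)
  pos <- rep_len(1:3, length(b))
  ok <- b %in% c("A", "C", "G", "T")
  gc <- b %in% c("G", "C")
  pct <- function(sel) 100 * sum(gc[sel & ok]) / sum(sel & ok)
  c(gc_overall = 100 * sum(gc[ok]) / sum(ok),
    gc1 = pct(pos == 1L), gc2 = pct(pos == 2L), gc3 = pct(pos == 3L))
}
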