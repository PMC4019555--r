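# tRNA wobble decoding sufficiency, unassigned-codon detection, and
# homing-endonuclease domain similarity vs. circular locus distance.

RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

#' Codons decoded by a tRNA anticodon under mitochondrial wobble rules
#'
#' Pairing is Watson-Crick at codon positions 1 and 2 (anticodon positions 3
#' and 2). At the wobble position (anticodon position 1 / codon position 3):
#' a wobble U pairs with all four bases, a wobble G pairs with C or U, and A
#' and C pair only Watson-Crick. With `ile_cau_reassignment = TRUE` a CAU
#' anticodon is treated as an edited/modified isoleucine anticodon reading
#' AUA (the lysidine-type reassignment inferred for fungal mitochondria)
#' instead of AUG.
#'
#' @param anticodon RNA triplet, 5'->3'.
#' @param ile_cau_reassignment treat a CAU anticodon as tRNA-Ile reading AUA.
#' @return character vector of RNA codons (5'->3').
#' @examples
#' wobble_decodes("UGC")  # Ala: GCA GCU GCG GCC
#' wobble_decodes("GAA")  # Phe: UUC UUU
#' @export
wobble_decodes <- function(anticodon, ile_cau_reassignment = FALSE) {
  anticodon <- toupper(chartr("T", "U", anticodon))
  if (!grepl("^[ACGU]{3}$", anticodon))
    stop("anticodon must be an RNA triplet over {A,C,G,U}")
  if (anticodon == "CAU" && ile_cau_reassignment) return("AUA")
  a <- chars(anticodon)
  c1 <- RNA_COMP[a[3]]; c2 <- RNA_COMP[a[2]]
  third <- switch(a[1],
    U = c("A", "G", "C", "U"),       # wobble U reads all four
    G = c("C", "U"),                 # wobble G reads C or U
    A = "U",
    C = "G")
  paste0(c1, c2, third)
}

dna_codon <- function(rna) chartr("U", "T", rna)
rna_codon <- function(dna) chartr("T", "U", dna)

#' Decoding sufficiency check for a tRNA set
#'
#' Applies [wobble_decodes()] to every anticodon record, optionally treating
#' one CAU anticodon annotated as isoleucine as an edited tRNA-Ile reading
#' AUA, and compares the decodable codon set against the sense codons of the
#' configured genetic code and their observed usage. Codons used in the
#' conserved coding sequences but decodable by no tRNA are flagged; codons
#' absent from conserved coding sequences but present elsewhere are listed as
#' unassigned candidates (suggesting no functional decoding tRNA is needed).
#'
#' @param anticodons list of [anticodon_record()].
#' @param conserved_usage [count_codons()] table over conserved coding
#'   sequences.
#' @param other_usage [count_codons()] table over the remaining ORF space
#'   (may be `NULL`).
#' @param ile_cau_reassignment apply the CAU->Ile reassignment to anticodon
#'   records whose amino acid is isoleucine.
#' @param code_table NCBI genetic code id (default `"4"`).
#' @return object of class `decoding_report`: `decodable` and `undecodable`
#'   RNA codon sets (their union is the sense codons of the code),
#'   `undecodable_used` (data frame of undecodable codons with nonzero
#'   conserved usage), `unassigned_candidates` (data frame), and
#'   `reassignment_notes`.
#' @export
decoding_check <- function(anticodons, conserved_usage, other_usage = NULL,
                           ile_cau_reassignment = TRUE, code_table = "4") {
  notes <- character(0)
  decodable <- character(0)
  for (rec in anticodons) {
    is_ile <- grepl("^(I|Ile)", rec$amino_acid, ignore.case = TRUE)
    flag <- ile_cau_reassignment && rec$anticodon == "CAU" && is_ile
    if (flag)
      notes <- c(notes, sprintf(
        "CAU anticodon at %d..%d treated as edited tRNA-Ile reading AUA",
        rec$locus$start, rec$locus$end))
    decodable <- union(decodable, wobble_decodes(rec$anticodon, flag))
  }
  sense <- rna_codon(sense_codons(code_table))
  decodable <- intersect(decodable, sense)
  undecodable <- setdiff(sense, decodable)
  und_counts <- conserved_usage$counts[dna_codon(undecodable)]
  undecodable_used <- data.frame(
    codon = undecodable[und_counts > 0],
    conserved_count = unname(und_counts[und_counts > 0]),
    stringsAsFactors = FALSE)
  unassigned <- data.frame(codon = character(0), other_count = integer(0))
  if (!is.null(other_usage)) {
    zero_cons <- sense[conserved_usage$counts[dna_codon(sense)] == 0]
    oc <- other_usage$counts[dna_codon(zero_cons)]
    unassigned <- data.frame(codon = zero_cons[oc > 0],
                             other_count = unname(oc[oc > 0]),
                             stringsAsFactors = FALSE)
  }
  structure(list(decodable = sort(decodable),
                 undecodable = sort(undecodable),
                 undecodable_used = undecodable_used,
                 unassigned_candidates = unassigned,
                 reassignment_notes = notes,
                 code_table = code_table),
            class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report> %d/%d sense codons decodable (code %s)\n",
              length(x$decodable),
              length(x$decodable) + length(x$undecodable), x$code_table))
  if (nrow(x$undecodable_used) > 0L)
    cat("  used but undecodable:",
        paste(x$undecodable_used$codon, collapse = " "), "\n")
  if (nrow(x$unassigned_candidates) > 0L)
    cat("  unassigned candidates:",
        paste(x$unassigned_candidates$codon, collapse = " "), "\n")
  invisible(x)
}

#' Construct a homing-endonuclease domain record
#'
#' @param family `"LAGLIDADG1"`, `"LAGLIDADG2"` or `"GIY-YIG"`.
#' @param aa_sequence core catalytic domain amino-acid sequence.
#' @param locus genomic [feature_interval()] of the encoding region; its
#'   midpoint is the reference point for locus distances.
#' @export
he_domain_record <- function(family = c("LAGLIDADG1", "LAGLIDADG2",
                                        "GIY-YIG"), aa_sequence, locus) {
  family <- match.arg(family)
  aa_sequence <- toupper(aa_sequence)
  n <- nchar(aa_sequence)
  if (n < 10L || n > 600L)
    stop("domain length out of the plausible 10-600 aa band: ", n)
  structure(list(family = family, aa_sequence = aa_sequence, locus = locus,
                 length_aa = n),
            class = "he_domain_record")
}

aa_identity_matrix <- function() {
  alpha <- c(Biostrings::AA_STANDARD, "X", "*", "-")
  m <- matrix(-1, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- 1
  m
}

#' Pairwise percent identity of homing-endonuclease domains
#'
#' Global (Needleman-Wunsch) pairwise alignment with match +1, mismatch -1,
#' gap opening 5 and gap extension 1 (costs); identity is matches divided by
#' alignment columns including gap columns, times 100.
#'
#' @param domains list of [he_domain_record()] (>= 2).
#' @return symmetric percent-identity matrix with 100 on the diagonal.
#' @export
pairwise_identity <- function(domains) {
  n <- length(domains)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  nm <- paste0(vapply(domains, function(d) d$family, ""), "_",
               seq_len(n))
  m <- matrix(100, n, n, dimnames = list(nm, nm))
  if (n < 2L) return(m)
  sub <- aa_identity_matrix()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(domains[[i]]$aa_sequence),
      Biostrings::AAString(domains[[j]]$aa_sequence),
      type = "global", substitutionMatrix = sub,
      gapOpening = 5, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    m[i, j] <- m[j, i] <- 100 * Biostrings::nmatch(aln) / cols
  }
  m
}

interval_midpoint <- function(iv, L) {
  len <- interval_length(iv, L)
  canon_pos(iv$start + (len - 1L) %/% 2L, L)
}

#' Circular locus distance matrix for domain records
#'
#' Distances between the genomic midpoints of the encoding loci on the
#' circle: `d(i,j) = min(|m_i - m_j|, L - |m_i - m_j|)`, bounded above by
#' `floor(L/2)`.
#'
#' @param domains list of [he_domain_record()].
#' @param genome_length circular genome length L.
#' @return symmetric integer matrix of bp distances.
#' @export
circular_distance_matrix <- function(domains, genome_length) {
  mids <- vapply(domains, function(d)
    interval_midpoint(d$locus, genome_length), 0L)
  n <- length(mids)
  dm <- abs(outer(mids, mids, "-"))
  dm <- pmin(dm, genome_length - dm)
  dimnames(dm) <- list(paste0("d", seq_len(n)), paste0("d", seq_len(n)))
  dm
}

#' Correlate domain similarity with circular locus distance
#'
#' Vectorizes the `n(n-1)/2` off-diagonal pairs of both matrices and applies
#' Pearson (t-distribution p-value) or Spearman correlation. An optional
#' `log(x + 1)` transform normalizes the similarity scores (the `+ 1` admits
#' 0% identities). Because matrix pairs are not independent, a seeded Mantel
#' permutation p-value can be computed alongside the classical one.
#'
#' @param sim similarity matrix (e.g. [pairwise_identity()]).
#' @param dist distance matrix of the same shape (e.g.
#'   [circular_distance_matrix()]).
#' @param method `"pearson"` or `"spearman"`.
#' @param transform `"none"` or `"log"` (applied to the similarity vector).
#' @param mantel_permutations number of Mantel permutations (0 to skip).
#' @param seed seed for the permutations.
#' @return object of class `correlation_result`: `method`, `r`, `p_value`,
#'   `n_pairs`, `transform`, and `mantel_p` (NA when not requested). A
#'   degenerate (constant) vector yields `r = NA` with a note instead of NaN
#'   propagation.
#' @export
correlate_similarity_distance <- function(sim, dist,
                                          method = c("pearson", "spearman"),
                                          transform = c("none", "log"),
                                          mantel_permutations = 0L,
                                          seed = 1L) {
  method <- match.arg(method); transform <- match.arg(transform)
  sim <- as.matrix(sim); dist <- as.matrix(dist)
  if (!all(dim(sim) == dim(dist)))
    stop("similarity and distance matrices must have the same shape")
  n <- nrow(sim)
  if (n * (n - 1) / 2 < 3)
    stop("insufficient data: need at least 3 off-diagonal pairs")
  ut <- upper.tri(sim)
  x <- sim[ut]; y <- dist[ut]
  if (transform == "log") x <- log(x + 1)
  res <- list(method = method, transform = transform,
              n_pairs = sum(ut), r = NA_real_, p_value = NA_real_,
              mantel_p = NA_real_, note = NULL)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    res$note <- "degenerate input: constant vector, correlation undefined"
    class(res) <- "correlation_result"
    return(res)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  res$r <- unname(ct$estimate)
  res$p_value <- ct$p.value
  if (mantel_permutations > 0L) {
    obs <- abs(stats::cor(x, y, method = method))
    perm_r <- numeric(mantel_permutations)
    perms <- local({ set.seed(seed); lapply(seq_len(mantel_permutations),
                                            function(i) sample.int(n)) })
    for (i in seq_len(mantel_permutations)) {
      p <- perms[[i]]
      xs <- sim[p, p][ut]
      if (transform == "log") xs <- log(xs + 1)
      perm_r[i] <- abs(stats::cor(xs, y, method = method))
    }
    res$mantel_p <- (1 + sum(perm_r >= obs)) / (mantel_permutations + 1)
  }
  class(res) <- "correlation_result"
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  if (is.na(x$r)) {
    cat("<correlation_result> undefined:", x$note %||% "no result", "\n")
  } else {
    cat(sprintf("<correlation_result> %s r = %.3f (p = %.4g, n_pairs = %d%s%s)\n",
                x$method, x$r, x$p_value, x$n_pairs,
                if (x$transform == "log") ", log-transformed similarity" else "",
                if (!is.na(x$mantel_p))
                  sprintf(", Mantel p = %.4g", x$mantel_p) else ""))
  }
  invisible(x)
}
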