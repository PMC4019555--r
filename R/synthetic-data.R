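# Seeded synthetic circular mitochondrial genomes with full ground truth.
#
# The generator emulates the architecture of a large fungal mtDNA: a
# conserved protein/rRNA/tRNA gene set split by long introns, AT-rich
# intergenic spacers seeded with short dispersed/inverted repeat families, a
# multi-kbp inverted duplication differing at a configurable number of
# sites, and a strand-asymmetric base composition producing a detectable
# G-over-C skew flip at the planted replication origin and terminus. All
# coordinates are laid out deterministically before any residue is drawn, so
# a seed fully determines the output.

#' Specification for a synthetic circular mitochondrial genome
#'
#' Defaults mirror a large Agaricomycotina-type mtDNA: 156,348 bp at 31.1%
#' GC, the conserved gene complement with its published coding lengths and
#' intron counts, intron lengths of 0.2-3.4 kbp, a 6,076 bp inverted
#' duplication differing at 3 sites, short (<= 200 nt) dispersed and
#' inverted repeat families in the intergenic spacers, and a G/C skew
#' architecture with the origin just upstream of the first gene.
#'
#' @param length_bp genome length (default 156348).
#' @param gc_fraction overall GC target for genic sequence (default 0.311).
#' @param genes data frame with columns `name`, `feature_class`
#'   (protein/rRNA/tRNA), `coding_bp`, `n_introns`, `strand`; defaults to
#'   the conserved mitochondrial set of [phlebia_gene_table()].
#' @param intron_len_range intron length range in bp (default c(200, 3400)).
#' @param duplication list: `enabled`, `length_bp` (region-1 length),
#'   `n_edits`, `edit_classes` (recycled over edits; default one
#'   substitution, one insertion, one deletion as observed in real mirror
#'   regions).
#' @param repeat_families list: `n_families`, `members_per_family`,
#'   `member_len_range` (<= 200 nt), `identity` (target pairwise identity),
#'   `inverted_fraction` (fraction of families planted in inverted
#'   orientation).
#' @param skew list: `enabled`, `amplitude` (G excess over C among G+C
#'   positions of non-coding sequence on the leading segment; default 0.25,
#'   an asymmetry strong enough that the cumulative-skew extremum localizes
#'   the origin to about one smoothing window, as a skew plot readable at
#'   ~1 kb resolution implies), `ori_pos` (default: 500 bp before the end
#'   of the circle), `ter_pos` (default antipodal).
#' @param spacer_at_enrichment factor by which intergenic/intronic AT is
#'   enriched relative to genic sequence (default 1.3).
#' @param code_table NCBI genetic code id for CDS sampling (default "4").
#' @return object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(length_bp = 156348L,
                                  gc_fraction = 0.311,
                                  genes = NULL,
                                  intron_len_range = c(200L, 3400L),
                                  duplication = list(),
                                  repeat_families = list(),
                                  skew = list(),
                                  spacer_at_enrichment = 1.3,
                                  code_table = "4") {
  if (is.null(genes)) genes <- default_synthetic_genes()
  dup <- utils::modifyList(list(enabled = TRUE, length_bp = 6076L,
                                n_edits = 3L,
                                edit_classes = c("substitution", "insertion",
                                                 "deletion")),
                           duplication)
  reps <- utils::modifyList(list(n_families = 5L, members_per_family = 4L,
                                 member_len_range = c(150L, 200L),
                                 identity = 0.85,
                                 inverted_fraction = 0.4),
                            repeat_families)
  sk <- utils::modifyList(list(enabled = TRUE, amplitude = 0.25,
                               ori_pos = NULL, ter_pos = NULL), skew)
  structure(list(length_bp = as.integer(length_bp),
                 gc_fraction = gc_fraction, genes = genes,
                 intron_len_range = as.integer(intron_len_range),
                 duplication = dup, repeat_families = reps, skew = sk,
                 spacer_at_enrichment = spacer_at_enrichment,
                 code_table = code_table),
            class = "synthetic_genome_spec")
}

# conserved fungal mitochondrial gene complement used as the default layout
default_synthetic_genes <- function() {
  tb <- phlebia_gene_table()
  it <- phlebia_intron_table()
  n_int <- vapply(tb$gene, function(g) sum(it$gene == g), 0L)
  data.frame(name = tb$gene,
             feature_class = tb$feature_class,
             coding_bp = tb$coding_bp,
             n_introns = unname(n_int),
             strand = tb$strand,
             stringsAsFactors = FALSE)
}

# AT-rich codon sampling table over the sense codons of the code: W-ending
# codons preferred, mirroring strongly AT-biased mitochondrial usage
default_codon_weights <- function(code_table = "4", gc_fraction = 0.311) {
  keys <- sense_codons(code_table)
  bw <- c(A = (1 - gc_fraction) / 2, T = (1 - gc_fraction) / 2,
          G = gc_fraction / 2, C = gc_fraction / 2)
  w <- vapply(keys, function(k) prod(bw[chars(k)]), 0)
  w / sum(w)
}

#' Generate a synthetic genome with ground truth
#'
#' Deterministic under `seed`. Coding sequences are sampled from an AT-rich
#' codon table and are stop-free under the configured code except for the
#' terminal TAA; the inverted duplication is inserted as the reverse
#' complement of its template with exactly the requested edits; repeat
#' family members are planted in intergenic spacers; strand-asymmetric base
#' composition in non-coding sequence switches at the planted origin and
#' terminus. The two residues flanking each duplication copy are forced to
#' break reverse-complement pairing so the planted boundaries are also the
#' maximal extent of the duplication.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param seed integer seed.
#' @return object of class `synthetic_truth`: `genome`, `genes` (list of
#'   [gene_model()]), `trnas`, `repeats` (list of planted [repeat_pair()]),
#'   `duplication` (`NULL` or list with `region_1`, `region_2`, `edits`),
#'   `ori_pos`, `ter_pos`, `composition` (bp per category), `spec`, `seed`.
#' @export
generate_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(as.integer(seed))
  L <- spec$length_bp
  g <- spec$genes
  n_g <- nrow(g)

  ## ---- layout (pure arithmetic, before any residue) ----
  exon_lens <- vector("list", n_g); intron_lens <- vector("list", n_g)
  for (i in seq_len(n_g)) {
    k <- g$n_introns[i]
    cb <- g$coding_bp[i]
    base <- cb %/% (k + 1L); rem <- cb %% (k + 1L)
    el <- rep(base, k + 1L)
    if (rem > 0L) el[seq_len(rem)] <- el[seq_len(rem)] + 1L
    exon_lens[[i]] <- el
    intron_lens[[i]] <- if (k > 0L)
      sample(spec$intron_len_range[1]:spec$intron_len_range[2], k,
             replace = TRUE) else integer(0)
  }
  spans <- vapply(seq_len(n_g), function(i)
    sum(exon_lens[[i]]) + sum(intron_lens[[i]]), 0)

  dup <- spec$duplication
  dup_on <- isTRUE(dup$enabled)
  ins_n <- del_n <- 0L
  edit_classes <- character(0)
  if (dup_on) {
    edit_classes <- rep(dup$edit_classes, length.out = dup$n_edits)
    ins_n <- sum(edit_classes == "insertion")
    del_n <- sum(edit_classes == "deletion")
  }
  dup_len1 <- if (dup_on) dup$length_bp else 0L
  dup_len2 <- if (dup_on) dup$length_bp + ins_n - del_n else 0L

  base_spacer <- 200L
  budget <- L - sum(spans) - n_g * base_spacer -
    (dup_len1 + dup_len2 + if (dup_on) 2L * 200L else 0L)
  if (budget < 0L)
    stop("infeasible packing: requested features exceed genome length")
  extra <- as.vector(stats::rmultinom(1L, budget, rep(1, n_g)))
  spacer_lens <- base_spacer + extra
  host1 <- max(1L, n_g %/% 4L); host2 <- max(2L, (3L * n_g) %/% 4L)
  if (dup_on) {
    spacer_lens[host1] <- spacer_lens[host1] + dup_len1 + 200L
    spacer_lens[host2] <- spacer_lens[host2] + dup_len2 + 200L
  }

  pos <- 1L
  gene_start <- integer(n_g); spacer_start <- integer(n_g)
  for (i in seq_len(n_g)) {
    gene_start[i] <- pos
    pos <- pos + as.integer(spans[i])
    spacer_start[i] <- pos
    pos <- pos + spacer_lens[i]
  }
  stopifnot(pos - 1L == L)

  dup_truth <- NULL
  if (dup_on) {
    r1s <- spacer_start[host1] + 100L
    r2s <- spacer_start[host2] + 100L
    dup_truth <- list(r1 = c(r1s, r1s + dup_len1 - 1L),
                      r2 = c(r2s, r2s + dup_len2 - 1L))
  }

  ## ---- skew architecture ----
  # default flip points sit at spacer midpoints: the composition switch is
  # only expressed in non-coding sequence, and real replication
  # origins/termini lie intergenic; a flip point inside a gene would be
  # unlocatable by construction
  sk <- spec$skew
  spacer_mid <- spacer_start + spacer_lens %/% 2L
  ori_pos <- as.integer(sk$ori_pos %||% spacer_mid[n_g])
  ter_target <- canon_pos(ori_pos + L %/% 2L, L)
  ter_default <- spacer_mid[which.min(vapply(spacer_mid, function(p) {
    d <- abs(p - ter_target); min(d, L - d) }, 0))]
  ter_pos <- as.integer(sk$ter_pos %||% ter_default)
  on_leading <- function(p) {
    # TRUE on [ori, ter): the G-rich leading segment
    if (ori_pos <= ter_pos) p >= ori_pos & p < ter_pos
    else p >= ori_pos | p < ter_pos
  }
  amp <- if (isTRUE(sk$enabled)) sk$amplitude else 0

  gc_nc <- spec$gc_fraction / spec$spacer_at_enrichment
  rand_noncoding <- function(start, len) {
    if (len == 0L) return(character(0))
    p <- canon_pos(start:(start + len - 1L), L)
    lead <- on_leading(p)
    pg <- ifelse(lead, gc_nc / 2 * (1 + amp), gc_nc / 2 * (1 - amp))
    pc <- gc_nc - pg
    u <- stats::runif(len)
    ifelse(u < pg, "G",
           ifelse(u < gc_nc, "C",
                  ifelse(u < gc_nc + (1 - gc_nc) / 2, "A", "T")))
  }

  codon_w <- default_codon_weights(spec$code_table, spec$gc_fraction)
  keys <- names(codon_w)
  rand_cds <- function(coding_bp) {
    nc <- coding_bp %/% 3L
    cods <- sample(keys, nc - 1L, replace = TRUE, prob = codon_w)
    paste0(paste(cods, collapse = ""), "TAA")
  }
  rand_rna_gene <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - spec$gc_fraction) / 2,
                          spec$gc_fraction / 2, spec$gc_fraction / 2,
                          (1 - spec$gc_fraction) / 2)), collapse = "")
  }

  ## ---- sequence assembly ----
  seqv <- character(L)
  genes_out <- vector("list", n_g)
  for (i in seq_len(n_g)) {
    el <- exon_lens[[i]]; il <- intron_lens[[i]]
    cb <- g$coding_bp[i]
    strand <- g$strand[i]
    coding <- if (g$feature_class[i] == "protein") rand_cds(cb)
              else rand_rna_gene(cb)
    # cut the spliced sequence into exon pieces (transcription order)
    pieces <- character(length(el)); off <- 0L
    for (j in seq_along(el)) {
      pieces[j] <- substr(coding, off + 1L, off + el[j])
      off <- off + el[j]
    }
    # lay out genomically: plus strand = transcription order, minus = reversed
    gpos <- gene_start[i]
    order_idx <- if (strand == "+") seq_along(el) else rev(seq_along(el))
    exiv <- vector("list", length(el))
    for (j in order_idx) {
      exon_seq <- if (strand == "+") pieces[j] else revcomp_chr(pieces[j])
      e_end <- gpos + el[j] - 1L
      seqv[gpos:e_end] <- chars(exon_seq)
      exiv[[j]] <- feature_interval(gpos, e_end, strand)
      gpos <- e_end + 1L
      jj <- if (strand == "+") j else j - 1L     # intron after this exon?
      if (jj >= 1L && jj <= length(il)) {
        i_end <- gpos + il[jj] - 1L
        seqv[gpos:i_end] <- rand_noncoding(gpos, il[jj])
        gpos <- i_end + 1L
      }
    }
    genes_out[[i]] <- gene_model(
      g$name[i], g$feature_class[i], exiv, strand, genome_length = L,
      stop_codon = if (g$feature_class[i] == "protein") "TAA" else
        NA_character_)
  }
  for (i in seq_len(n_g)) {
    s <- spacer_start[i]
    seqv[s:(s + spacer_lens[i] - 1L)] <- rand_noncoding(s, spacer_lens[i])
  }

  ## ---- inverted duplication ----
  edits <- NULL
  if (dup_on) {
    r1 <- dup_truth$r1; r2 <- dup_truth$r2
    src <- paste(seqv[r1[1]:r1[2]], collapse = "")
    ed_pos <- sort(sample(50L:(dup_len1 - 50L), dup$n_edits))
    edits <- data.frame(position = r1[1] + ed_pos - 1L,
                        src_offset = ed_pos, class = edit_classes,
                        stringsAsFactors = FALSE)
    tmp <- chars(src)
    out <- character(0); prev <- 1L
    for (e in seq_len(nrow(edits))) {
      p <- edits$src_offset[e]
      out <- c(out, tmp[prev:(p - 1L)])
      cls <- edits$class[e]
      if (cls == "substitution") {
        out <- c(out, sample(setdiff(c("A", "C", "G", "T"), tmp[p]), 1L))
      } else if (cls == "insertion") {
        out <- c(out, tmp[p], sample(c("A", "C", "G", "T"), 1L))
      } else {                                   # deletion: drop the base
      }
      prev <- p + 1L
    }
    out <- c(out, tmp[prev:length(tmp)])
    stopifnot(length(out) == dup_len2)
    seqv[r2[1]:r2[2]] <- chars(revcomp_chr(paste(out, collapse = "")))
    # force the flanks to break reverse-complement pairing: a base can never
    # pair with its equal, so copying the partner flank ends extension there
    seqv[r2[2] + 1L] <- seqv[r1[1] - 1L]
    seqv[r2[2] + 2L] <- seqv[r1[1] - 2L]
    seqv[r2[1] - 1L] <- seqv[r1[2] + 1L]
    seqv[r2[1] - 2L] <- seqv[r1[2] + 2L]
  }

  ## ---- repeat families in spacers ----
  rp <- spec$repeat_families
  planted <- list()
  if (rp$n_families > 0L && rp$members_per_family > 1L) {
    # free sub-intervals of spacers (duplication regions excluded)
    free <- list()
    for (i in seq_len(n_g)) {
      s0 <- spacer_start[i]; s1 <- s0 + spacer_lens[i] - 1L
      if (dup_on && i == host1) s0 <- dup_truth$r1[2] + 10L
      if (dup_on && i == host2) s0 <- dup_truth$r2[2] + 10L
      if (s1 - s0 > 20L) free[[length(free) + 1L]] <- c(s0 + 5L, s1 - 5L)
    }
    mlr <- rp$member_len_range
    e_rate <- (1 - rp$identity) / 2
    fam_seqs <- list(); fam_locs <- list(); fam_orient <- character(0)
    for (f in seq_len(rp$n_families)) {
      mlen <- sample(mlr[1]:mlr[2], 1L)
      motif <- paste(sample(c("A", "C", "G", "T"), mlen, replace = TRUE),
                     collapse = "")
      inverted <- stats::runif(1) < rp$inverted_fraction
      members <- list(); locs <- list()
      for (m in seq_len(rp$members_per_family)) {
        mv <- chars(motif)
        nmut <- stats::rbinom(1L, mlen, e_rate)
        # diverge interior positions only, keeping member termini exact --
        # the conserved-ends structure of mobile-element-derived repeats;
        # this also makes the planted extent of each copy sharply defined
        interior <- 11L:(mlen - 10L)
        nmut <- min(nmut, length(interior))
        if (nmut > 0L) {
          mp <- sample(interior, nmut)
          mv[mp] <- vapply(mv[mp], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        }
        mseq <- paste(mv, collapse = "")
        # inverted families: odd members forward, even members revcomp
        flip <- inverted && (m %% 2L == 0L)
        placed <- FALSE
        for (fi in sample(seq_along(free))) {
          fr <- free[[fi]]
          if (fr[2] - fr[1] + 1L >= mlen + 10L) {
            start <- fr[1] + 5L
            end <- start + mlen - 1L
            seqv[start:end] <- chars(if (flip) revcomp_chr(mseq) else mseq)
            # sharpen the planted boundary: give each member a distinct
            # flanking dinucleotide code over {A,C}; distinct codes mismatch
            # in direct comparisons and their reverse complements ({T,G})
            # mismatch in inverted ones, so extension ends at the boundary
            if (m <= 4L) {
              code <- list(c("A", "A"), c("A", "C"),
                           c("C", "A"), c("C", "C"))[[m]]
              seqv[c(start - 2L, start - 1L)] <- code
              seqv[c(end + 1L, end + 2L)] <- rev(code)
            }
            # dispersed elements: keep >= 250 bp of spacer between planted
            # copies; X-drop extension cannot bridge that much near-random
            # sequence, so neighbours are never merged into tandem hits
            free[[fi]] <- c(end + 250L, fr[2])
            locs[[m]] <- list(iv = feature_interval(start, end),
                              flipped = flip)
            members[[m]] <- mseq
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("infeasible packing: no spacer room for repeat family member")
      }
      fam_seqs[[f]] <- members; fam_locs[[f]] <- locs
      fam_orient <- c(fam_orient, if (inverted) "inverted" else "direct")
    }
    # planted truth: every within-family pair with its realized identity
    for (f in seq_along(fam_locs)) {
      locs <- fam_locs[[f]]
      for (a in seq_len(length(locs) - 1L)) for (b in (a + 1L):length(locs)) {
        sa <- paste(seqv[locs[[a]]$iv$start:locs[[a]]$iv$end], collapse = "")
        sb <- paste(seqv[locs[[b]]$iv$start:locs[[b]]$iv$end], collapse = "")
        orient <- if (locs[[a]]$flipped == locs[[b]]$flipped) "direct"
                  else "inverted"
        sb_cmp <- if (orient == "inverted") revcomp_chr(sb) else sb
        idy <- mean(chars(sa) == chars(sb_cmp))
        planted[[length(planted) + 1L]] <- repeat_pair(
          locs[[a]]$iv, locs[[b]]$iv, orient, idy,
          nchar(sa))
      }
    }
  }

  genome <- circular_genome(sprintf("synthetic_mt_seed%d", as.integer(seed)),
                            paste(seqv, collapse = ""))

  ## ---- tRNA anticodon records for tRNA-class genes ----
  trna_tb <- phlebia_trna_table()
  trnas <- list()
  ti <- 0L
  for (i in seq_len(n_g)) {
    if (g$feature_class[i] != "tRNA") next
    ti <- ti %% nrow(trna_tb) + 1L
    trnas[[length(trnas) + 1L]] <- anticodon_record(
      trna_tb$amino_acid[ti], trna_tb$anticodon[ti], genes_out[[i]]$span)
  }

  comp <- genome_composition(genome, genes_out)
  dup_out <- if (dup_on) list(
    region_1 = feature_interval(dup_truth$r1[1], dup_truth$r1[2]),
    region_2 = feature_interval(dup_truth$r2[1], dup_truth$r2[2]),
    length_bp = dup_len1, edits = edits) else NULL

  structure(list(genome = genome, genes = genes_out, trnas = trnas,
                 repeats = planted, duplication = dup_out,
                 ori_pos = if (isTRUE(sk$enabled)) ori_pos else NA_integer_,
                 ter_pos = if (isTRUE(sk$enabled)) ter_pos else NA_integer_,
                 composition = comp, spec = spec, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d bp, %d genes, %d planted repeat pairs%s, seed %d\n",
              x$genome$length, length(x$genes), length(x$repeats),
              if (!is.null(x$duplication)) sprintf(", %d bp inverted duplication",
                                                   x$duplication$length_bp)
              else "", x$seed))
  invisible(x)
}

#' Rotate a synthetic genome and its entire ground truth
#'
#' Shifts the sequence origin by `k` (position `k + 1` becomes position 1)
#' and remaps every truth coordinate accordingly. Used for rotation
#' equivariance properties and for planting features across the origin.
#'
#' @param truth a [generate_genome()] result.
#' @param k rotation offset in bp (0 <= k < length).
#' @return a `synthetic_truth` with identical content at shifted
#'   coordinates.
#' @export
rotate_truth <- function(truth, k) {
  L <- truth$genome$length
  k <- as.integer(k %% L)
  if (k == 0L) return(truth)
  S <- truth$genome$residues
  genome <- circular_genome(truth$genome$id,
                            paste0(substr(S, k + 1L, L), substr(S, 1L, k)))
  sh <- function(p) canon_pos(p - k, L)
  shiv <- function(iv) {
    s <- sh(iv$start); e <- sh(iv$end)
    feature_interval(s, e, iv$strand, wraps_origin = s > e)
  }
  genes <- lapply(truth$genes, function(gm) {
    exons <- lapply(gm$exons, shiv)
    introns <- lapply(gm$introns, function(ir) {
      ir$interval <- shiv(ir$interval); ir })
    gm2 <- gene_model(gm$name, gm$feature_class, exons, gm$strand,
                      genome_length = L, stop_codon = gm$stop_codon,
                      introns = introns)
    gm2
  })
  trnas <- lapply(truth$trnas, function(tr) {
    tr$locus <- shiv(tr$locus); tr })
  reps <- lapply(truth$repeats, function(p) {
    p$interval_a <- shiv(p$interval_a); p$interval_b <- shiv(p$interval_b); p })
  dup <- truth$duplication
  if (!is.null(dup)) {
    dup$region_1 <- shiv(dup$region_1)
    dup$region_2 <- shiv(dup$region_2)
    if (!is.null(dup$edits)) dup$edits$position <- sh(dup$edits$position)
  }
  out <- truth
  out$genome <- genome; out$genes <- genes; out$trnas <- trnas
  out$repeats <- reps; out$duplication <- dup
  if (!is.na(truth$ori_pos)) out$ori_pos <- sh(truth$ori_pos)
  if (!is.na(truth$ter_pos)) out$ter_pos <- sh(truth$ter_pos)
  out
}

#' Write a synthetic truth bundle to a directory
#'
#' Emits `genome.fa`, `annotation.gff3`, and plain-text truth tables
#' (`repeats.tsv`, `duplication.tsv`, `landmarks.tsv`, `partition.tsv`).
#' Re-reading with [read_truth()] reproduces the written truth.
#'
#' @param truth a [generate_genome()] result.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_annotation(truth$genes, file.path(dir, "annotation.gff3"), "gff3",
                   genome = truth$genome, trnas = truth$trnas)
  rp <- do.call(rbind, lapply(truth$repeats, function(p) data.frame(
    a_start = p$interval_a$start, a_end = p$interval_a$end,
    b_start = p$interval_b$start, b_end = p$interval_b$end,
    orientation = p$orientation, identity = p$identity,
    length = p$length)))
  if (is.null(rp)) rp <- data.frame(a_start = integer(0), a_end = integer(0),
                                    b_start = integer(0), b_end = integer(0),
                                    orientation = character(0),
                                    identity = numeric(0),
                                    length = integer(0))
  utils::write.table(rp, file.path(dir, "repeats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dup <- truth$duplication
  dd <- if (!is.null(dup)) data.frame(
    r1_start = dup$region_1$start, r1_end = dup$region_1$end,
    r2_start = dup$region_2$start, r2_end = dup$region_2$end,
    length_bp = dup$length_bp, n_edits = nrow(dup$edits)) else
    data.frame(r1_start = integer(0), r1_end = integer(0),
               r2_start = integer(0), r2_end = integer(0),
               length_bp = integer(0), n_edits = integer(0))
  utils::write.table(dd, file.path(dir, "duplication.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lm <- data.frame(ori_pos = truth$ori_pos, ter_pos = truth$ter_pos)
  utils::write.table(lm, file.path(dir, "landmarks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cp <- truth$composition
  pt <- data.frame(category = c("coding", "intronic", "intergenic"),
                   bp = c(cp$coding_bp, cp$intronic_bp, cp$intergenic_bp))
  utils::write.table(pt, file.path(dir, "partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a synthetic truth bundle written by [write_truth()]
#'
#' @param dir directory containing the bundle.
#' @return list with `genome`, `genes`, `trnas`, `repeats` (data frame),
#'   `duplication` (data frame), `landmarks`, `partition`.
#' @export
read_truth <- function(dir) {
  ann <- read_annotated_genome(file.path(dir, "annotation.gff3"), "gff3",
                               fasta = file.path(dir, "genome.fa"))
  list(genome = ann$genome, genes = ann$genes, trnas = ann$trnas,
       repeats = utils::read.delim(file.path(dir, "repeats.tsv")),
       duplication = utils::read.delim(file.path(dir, "duplication.tsv")),
       landmarks = utils::read.delim(file.path(dir, "landmarks.tsv")),
       partition = utils::read.delim(file.path(dir, "partition.tsv")))
}
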