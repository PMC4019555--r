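# Published annotation tables of the Phlebia radiata mitochondrial genome
# (EMBL HE613568 / NCBI NC_020148), shipped as plain-text fixtures. These
# carry the printed gene spans, coding lengths, stop codons, per-intron
# lengths with homing-endonuclease associations, and the tRNA loci with
# anticodons -- the inputs for table replays and the default architecture of
# the synthetic generator.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "mitofeatures")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)   # pre-install
  p
}

#' Published conserved gene table of the P. radiata mtDNA
#'
#' One row per conserved protein/rRNA gene: genomic span, strand, coding
#' length, stop codon, and the printed coding-density / protein-length /
#' intron-mean values used for replay checks.
#'
#' @return data frame.
#' @export
phlebia_gene_table <- function() {
  utils::read.delim(extdata_path("phlebia_radiata_genes.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published per-intron lengths and homing-endonuclease associations
#'
#' @return data frame with columns `gene`, `ordinal`, `length_bp`,
#'   `he_label`.
#' @export
phlebia_intron_table <- function() {
  utils::read.delim(extdata_path("phlebia_radiata_introns.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published tRNA gene table of the P. radiata mtDNA
#'
#' All 28 tRNA loci with anticodons (RNA, 5'->3'), coordinates, strand and
#' printed length.
#'
#' @return data frame.
#' @export
phlebia_trna_table <- function() {
  utils::read.delim(extdata_path("phlebia_radiata_trnas.tsv"),
                    stringsAsFactors = FALSE)
}

#' Gene models reconstructed from the published tables
#'
#' Builds [gene_model()] objects from the published spans, coding lengths
#' and per-intron lengths. The published tables fully determine each gene's
#' span, coding length and ordered intron lengths; the exact exon boundaries
#' within a span are not printed, so exons are laid out synthetically
#' (coding sequence split evenly between the published introns, in
#' transcription order). All span/coding/intron-derived statistics are
#' exactly those of the published annotation.
#'
#' @param genome_length circular genome length (default 156348 bp).
#' @return list of [gene_model()].
#' @export
phlebia_gene_models <- function(genome_length = 156348L) {
  tb <- phlebia_gene_table()
  it <- phlebia_intron_table()
  out <- vector("list", nrow(tb))
  for (i in seq_len(nrow(tb))) {
    g <- tb[i, ]
    il <- it$length_bp[it$gene == g$gene]
    he <- it$he_label[it$gene == g$gene]
    k <- length(il)
    base <- g$coding_bp %/% (k + 1L); rem <- g$coding_bp %% (k + 1L)
    el <- rep(base, k + 1L)
    if (rem > 0L) el[seq_len(rem)] <- el[seq_len(rem)] + 1L
    # interleave exon/intron lengths in transcription order, then place
    # genomically from the published span boundary
    piece_len <- integer(0)
    for (j in seq_len(k + 1L)) {
      piece_len <- c(piece_len, el[j])
      if (j <= k) piece_len <- c(piece_len, il[j])
    }
    stopifnot(sum(piece_len) == g$end - g$start + 1L)
    exons <- list()
    if (g$strand == "+") {
      cur <- g$start
      for (j in seq_along(piece_len)) {
        if (j %% 2L == 1L)
          exons[[length(exons) + 1L]] <-
            feature_interval(cur, cur + piece_len[j] - 1L, "+")
        cur <- cur + piece_len[j]
      }
    } else {
      cur <- g$end
      for (j in seq_along(piece_len)) {
        if (j %% 2L == 1L)
          exons[[length(exons) + 1L]] <-
            feature_interval(cur - piece_len[j] + 1L, cur, "-")
        cur <- cur - piece_len[j]
      }
    }
    gm <- gene_model(g$gene, g$feature_class, exons, g$strand,
                     genome_length = genome_length,
                     stop_codon = if (is.na(g$stop_codon)) NA_character_
                                  else g$stop_codon)
    for (j in seq_along(gm$introns)) gm$introns[[j]]$he_label <- he[j]
    out[[i]] <- gm
  }
  out
}

#' Anticodon records from the published tRNA table
#'
#' @return list of [anticodon_record()].
#' @export
phlebia_anticodon_records <- function() {
  tb <- phlebia_trna_table()
  lapply(seq_len(nrow(tb)), function(i)
    anticodon_record(tb$amino_acid[i], tb$anticodon[i],
                     feature_interval(tb$start[i], tb$end[i], tb$strand[i])))
}
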