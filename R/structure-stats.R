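# Gene-architecture accounting and genome composition partitioning.

#' Per-gene structure report
#'
#' Derives the standard architecture statistics of an annotated mitochondrial
#' gene: genomic span, coding length, protein length, intron count and total,
#' and coding-sequence density (percentage of the span that is exonic).
#' Rounding is half-up to the precision conventionally printed in genome
#' reports: densities to 1 decimal, intron means to the nearest integer.
#'
#' The protein-length convention is that the annotated stop codon is included
#' in the coding length but not in the protein, so
#' `protein_aa = coding_bp/3 - 1` when a stop codon is annotated.
#'
#' @param gene a [gene_model()].
#' @return a one-row data frame with columns `gene`, `span_bp`, `coding_bp`,
#'   `protein_aa`, `intron_count`, `intron_total_bp`, `intron_mean_bp`,
#'   `coding_density` (percent, 1 decimal), `stop_codon`.
#' @examples
#' gm <- gene_model("atp6", "protein",
#'                  list(feature_interval(36924, 37700, "+")), "+",
#'                  genome_length = 156348, stop_codon = "TAA")
#' gene_structure(gm)
#' @export
gene_structure <- function(gene) {
  L <- gene$genome_length
  span_bp <- interval_length(gene$span, L)
  coding_bp <- gene$coding_length
  if (gene$feature_class == "protein" && coding_bp %% 3 != 0)
    stop(sprintf("gene '%s': coding length %d not divisible by 3",
                 gene$name, coding_bp))
  protein_aa <- if (gene$feature_class == "protein") {
    if (!is.na(gene$stop_codon)) coding_bp %/% 3L - 1L else coding_bp %/% 3L
  } else NA_integer_
  n_int <- length(gene$introns)
  intron_total <- if (n_int > 0L)
    sum(vapply(gene$introns, function(ir)
      interval_length(ir$interval, L), 0L)) else 0L
  intron_mean <- if (n_int > 0L)
    as.integer(round_half_up(intron_total / n_int)) else NA_integer_
  data.frame(
    gene = gene$name,
    span_bp = span_bp,
    coding_bp = coding_bp,
    protein_aa = protein_aa,
    intron_count = n_int,
    intron_total_bp = intron_total,
    intron_mean_bp = intron_mean,
    coding_density = round_half_up(100 * coding_bp / span_bp, 1),
    stop_codon = gene$stop_codon,
    stringsAsFactors = FALSE)
}

#' Structure report for a set of genes
#'
#' @param genes list of [gene_model()].
#' @return data frame with one [gene_structure()] row per gene.
#' @export
structure_table <- function(genes) {
  do.call(rbind, lapply(genes, gene_structure))
}

#' Intron length summary for one gene
#'
#' @param gene a [gene_model()] with at least one intron.
#' @return list with `total_bp` (sum of intron lengths) and `mean_bp`
#'   (total/count, rounded half-up to the nearest integer).
#' @export
intron_summary <- function(gene) {
  if (length(gene$introns) == 0L)
    stop(sprintf("gene '%s' has no introns; intron summary undefined",
                 gene$name))
  lens <- vapply(gene$introns, function(ir)
    interval_length(ir$interval, gene$genome_length), 0L)
  list(total_bp = sum(lens),
       mean_bp = as.integer(round_half_up(sum(lens) / length(lens))))
}

#' Genome composition breakdown
#'
#' Assigns every genomic position to exactly one primary category by the
#' precedence conserved-coding > intronic > intergenic (overlapping genes --
#' e.g. a start codon sharing a base with the upstream stop -- are counted
#' once). An optional layer of additional ORFs is reported on top without
#' disturbing the partition.
#'
#' @param genome a [circular_genome()].
#' @param genes list of [gene_model()]; exons count as conserved coding,
#'   the gaps between them as intronic.
#' @param extra_orfs optional list of [feature_interval()] reported as a
#'   non-partition overlay.
#' @return list with bp and fraction per category; `coding_bp + intronic_bp +
#'   intergenic_bp` always equals the genome length.
#' @export
genome_composition <- function(genome, genes, extra_orfs = list()) {
  L <- genome$length
  cat <- integer(L)                       # 0 intergenic, 1 intronic, 2 coding
  for (gm in genes) {
    for (ir in gm$introns)
      cat[interval_positions(ir$interval, L)] <-
        pmax(cat[interval_positions(ir$interval, L)], 1L)
  }
  for (gm in genes) {
    for (ex in gm$exons)
      cat[interval_positions(ex, L)] <- 2L
  }
  orf_mask <- logical(L)
  for (iv in extra_orfs) orf_mask[interval_positions(iv, L)] <- TRUE
  coding <- sum(cat == 2L); intronic <- sum(cat == 1L)
  intergenic <- L - coding - intronic
  list(coding_bp = coding, intronic_bp = intronic, intergenic_bp = intergenic,
       significant_orf_bp = sum(orf_mask),
       coding_fraction = coding / L, intronic_fraction = intronic / L,
       intergenic_fraction = intergenic / L,
       genome_bp = L)
}

#' Translate a coding sequence
#'
#' Splices the exons, reverse complementing minus-strand genes, and
#' translates under the requested NCBI genetic code. The trailing stop codon
#' is removed from the returned protein; internal stops are reported as an
#' attached warning record (codon positions), never silently translated.
#'
#' @param gene a protein-class [gene_model()].
#' @param genome the [circular_genome()] the gene lies on.
#' @param code_table NCBI genetic code id as a string; `"4"` is the mold /
#'   protozoan / coelenterate mitochondrial code in which UGA reads Trp.
#' @return character protein string; attribute `internal_stops` holds the
#'   1-based codon positions of any internal stop under the code.
#' @examples
#' g <- circular_genome("t", "ATGTTTTAA", circular = FALSE)
#' gm <- gene_model("toy", "protein", list(feature_interval(1, 9, "+")), "+",
#'                  genome_length = 9, stop_codon = "TAA")
#' translate_cds(gm, g)  # "MF"
#' @export
translate_cds <- function(gene, genome, code_table = "4") {
  cds <- paste(vapply(gene$exons, function(e)
    interval_sequence(genome, e), ""), collapse = "")
  if (nchar(cds) %% 3 != 0)
    stop(sprintf("gene '%s': coding length %d not divisible by 3",
                 gene$name, nchar(cds)))
  code <- Biostrings::getGeneticCode(code_table)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), genetic.code = code,
    if.fuzzy.codon = "X"))
  n <- nchar(aa)
  trailing_stop <- substr(aa, n, n) == "*"
  prot <- if (trailing_stop) substr(aa, 1L, n - 1L) else aa
  internal <- which(chars(prot) == "*")
  if (length(internal) > 0L)
    warning(sprintf("gene '%s': internal stop codon(s) at codon position(s) %s under code %s",
                    gene$name, paste(internal, collapse = ", "), code_table))
  attr(prot, "internal_stops") <- internal
  prot
}
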