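# Circular genome model, feature intervals, gene models, and flat-file I/O.
#
# External coordinates are 1-based inclusive (GenBank/EMBL convention).
# Internal arithmetic uses explicit wrap handling on the circle; a feature
# crossing the sequence origin is a single interval with wraps_origin = TRUE,
# never two sub-intervals. In GFF3/BED output, a wrapped feature is written
# with end = end + genome length (the convention for circular molecules, so
# start < end always holds in the file); on input an end exceeding the
# sequence length is folded back and flagged.

#' Construct a circular genome
#'
#' The coordinate authority for every other module: a DNA residue string over
#' \{A,C,G,T,N\} with circular topology. Any 1-based position `p` maps to the
#' canonical position `((p-1) mod length) + 1`.
#'
#' @param id record identifier.
#' @param residues single character string of residues (case-insensitive).
#' @param circular logical; circular topology (default `TRUE`).
#' @return an object of class `circular_genome` with fields `id`, `residues`,
#'   `length`, `circular`.
#' @examples
#' g <- circular_genome("toy", "ACGTACGTAC")
#' g$length
#' @export
circular_genome <- function(id, residues, circular = TRUE) {
  residues <- toupper(as.character(residues))
  if (nchar(residues) == 0L) stop("genome must contain at least one residue")
  if (grepl("[^ACGTN]", residues))
    stop("residues must be over {A,C,G,T,N}")
  structure(
    list(id = as.character(id), residues = residues,
         length = nchar(residues), circular = isTRUE(circular)),
    class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a feature interval
#'
#' 1-based inclusive genomic interval on a (possibly circular) genome.
#' `wraps_origin = TRUE` marks a feature crossing the sequence origin, whose
#' span is `(L - start + 1) + end` on a genome of length `L`.
#'
#' @param start,end 1-based inclusive bounds.
#' @param strand `"+"` or `"-"`.
#' @param wraps_origin does the interval cross the origin?
#' @return object of class `feature_interval`.
#' @export
feature_interval <- function(start, end, strand = "+", wraps_origin = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L)
    stop("interval bounds must be positive integers")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!wraps_origin && end < start)
    stop("end < start on a non-wrapping interval")
  structure(list(start = start, end = end, strand = strand,
                 wraps_origin = isTRUE(wraps_origin)),
            class = "feature_interval")
}

#' Span of a feature interval in bp
#'
#' @param interval a [feature_interval()].
#' @param genome_length genome length, required when the interval wraps.
#' @return integer span (always >= 1).
#' @export
interval_length <- function(interval, genome_length = NULL) {
  if (interval$wraps_origin) {
    if (is.null(genome_length)) stop("genome_length needed for wrapped interval")
    (genome_length - interval$start + 1L) + interval$end
  } else {
    interval$end - interval$start + 1L
  }
}

# genomic positions covered by an interval, ascending along the forward strand
interval_positions <- function(interval, genome_length) {
  if (interval$wraps_origin) {
    c(seq.int(interval$start, genome_length), seq.int(1L, interval$end))
  } else {
    seq.int(interval$start, interval$end)
  }
}

#' Extract the sequence of a feature interval
#'
#' Wrapped intervals are stitched across the origin; minus-strand intervals
#' are reverse complemented so the returned string reads 5'->3' on the coding
#' strand of the feature.
#'
#' @param genome a [circular_genome()].
#' @param interval a [feature_interval()].
#' @return character DNA string.
#' @export
interval_sequence <- function(genome, interval) {
  L <- genome$length
  if (interval$start > L || interval$end > L) {
    if (!genome$circular)
      stop(sprintf("interval %d..%d exceeds sequence length %d on a linear record",
                   interval$start, interval$end, L))
  }
  s <- if (interval$wraps_origin) {
    paste0(substr(genome$residues, interval$start, L),
           substr(genome$residues, 1L, interval$end))
  } else {
    substr(genome$residues, interval$start, interval$end)
  }
  if (interval$strand == "-") revcomp_chr(s) else s
}

#' Construct an intron record
#'
#' @param ordinal 1-based intron index in transcription order.
#' @param interval genomic [feature_interval()] of the intron.
#' @param intron_type `"groupI"`, `"groupII"` or `"uncertain"`.
#' @param he_label homing-endonuclease association label:
#'   `"GIY-YIG"`, `"LAGLIDADG1"`, `"LAGLIDADG2"`, `"RT"` or `"none"`.
#' @export
intron_record <- function(ordinal, interval,
                          intron_type = c("uncertain", "groupI", "groupII"),
                          he_label = c("none", "GIY-YIG", "LAGLIDADG1",
                                       "LAGLIDADG2", "RT")) {
  intron_type <- match.arg(intron_type)
  he_label <- match.arg(he_label)
  structure(list(ordinal = as.integer(ordinal), interval = interval,
                 intron_type = intron_type, he_label = he_label),
            class = "intron_record")
}

# introns between transcription-consecutive exons, as genomic intervals
introns_from_exons <- function(exons, strand, genome_length) {
  n <- length(exons)
  if (n < 2L) return(list())
  L <- genome_length
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    if (strand == "+") {
      gs <- canon_pos(exons[[i]]$end + 1L, L)
      ge <- canon_pos(exons[[i + 1L]]$start - 1L, L)
    } else {
      gs <- canon_pos(exons[[i + 1L]]$end + 1L, L)
      ge <- canon_pos(exons[[i]]$start - 1L, L)
    }
    out[[i]] <- intron_record(i, feature_interval(
      gs, ge, strand, wraps_origin = gs > ge))
  }
  out
}

#' Construct a gene model
#'
#' A named feature with ordered exons, strand and class. Exons are given in
#' transcription direction (for minus-strand genes, descending genomic
#' coordinates). Introns are derived from the gaps between consecutive exons
#' unless supplied explicitly (e.g. to attach intron types and
#' homing-endonuclease labels).
#'
#' @param name gene name (e.g. `"cox1"`).
#' @param feature_class `"protein"`, `"rRNA"` or `"tRNA"`.
#' @param exons list of [feature_interval()] in transcription order.
#' @param strand `"+"` or `"-"`; must match the exon strands.
#' @param genome_length genome length, needed when the gene wraps the origin.
#' @param stop_codon annotated stop triplet (DNA alphabet) or `NA`.
#' @param introns optional list of [intron_record()]; derived when `NULL`.
#' @return object of class `gene_model` with derived fields `span`
#'   (a [feature_interval()]) and `coding_length`.
#' @examples
#' gm <- gene_model("atp6", "protein",
#'                  list(feature_interval(36924, 37700, "+")), "+",
#'                  genome_length = 156348, stop_codon = "TAA")
#' gm$coding_length
#' @export
gene_model <- function(name, feature_class = c("protein", "rRNA", "tRNA"),
                       exons, strand, genome_length = NULL,
                       stop_codon = NA_character_, introns = NULL) {
  feature_class <- match.arg(feature_class)
  if (length(exons) == 0L) stop("gene must have at least one exon")
  if (!all(vapply(exons, function(e) e$strand, "") == strand))
    stop(sprintf("gene '%s': exon strands disagree with gene strand", name))
  wraps <- any(vapply(exons, function(e) e$wraps_origin, NA))
  if ((wraps || length(exons) > 1L) && is.null(genome_length))
    stop("genome_length required for multi-exon or wrapped genes")
  L <- genome_length
  coding_length <- sum(vapply(exons, interval_length, 0L,
                              genome_length = L))
  if (is.null(introns)) introns <- introns_from_exons(exons, strand, L)
  if (length(introns) != length(exons) - 1L)
    stop(sprintf("gene '%s': intron count must equal exon count - 1", name))
  # span: 5'-most exon start to 3'-most exon end in transcription direction
  first <- exons[[1L]]; last <- exons[[length(exons)]]
  if (strand == "+") { ss <- first$start; se <- last$end }
  else               { ss <- last$start;  se <- first$end }
  span <- feature_interval(ss, se, strand,
                           wraps_origin = ss > se ||
                             (wraps && length(exons) == 1L))
  structure(list(name = as.character(name), feature_class = feature_class,
                 exons = exons, strand = strand,
                 stop_codon = toupper(stop_codon),
                 introns = introns, span = span,
                 coding_length = as.integer(coding_length),
                 genome_length = L),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s): span %d..%d%s, %d exon(s), coding %d bp\n",
              x$name, x$feature_class, x$strand, x$span$start, x$span$end,
              if (x$span$wraps_origin) " (wraps origin)" else "",
              length(x$exons), x$coding_length))
  invisible(x)
}

#' Construct a tRNA anticodon record
#'
#' @param amino_acid 1- or 3-letter amino-acid code the tRNA carries.
#' @param anticodon RNA triplet, 5'->3' (over A, C, G, U).
#' @param locus genomic [feature_interval()] of the tRNA gene.
#' @export
anticodon_record <- function(amino_acid, anticodon, locus) {
  anticodon <- toupper(anticodon)
  if (!grepl("^[ACGU]{3}$", anticodon))
    stop("anticodon must be an RNA triplet over {A,C,G,U}")
  structure(list(amino_acid = as.character(amino_acid),
                 anticodon = anticodon, locus = locus),
            class = "anticodon_record")
}

## ---------------------------------------------------------------------------
## Flat-file input

#' Read an annotated genome
#'
#' Parses a GenBank or EMBL flat file, or a GFF3 annotation with its FASTA
#' sequence, into the package's genome model. All features are converted to
#' 1-based inclusive coordinates; features crossing the origin of a circular
#' record are flagged `wraps_origin`; joined CDS locations become ordered exon
#' lists; tRNA features additionally yield anticodon records.
#'
#' @param path path to the flat file (for `"gff3"`, the GFF3 file).
#' @param dialect one of `"genbank"`, `"embl"`, `"gff3"`.
#' @param fasta for the GFF3 dialect, path to the genome FASTA (defaults to
#'   `path` with extension replaced by `.fa`).
#' @return list with components `genome` ([circular_genome()]), `genes`
#'   (list of [gene_model()]), and `trnas` (list of [anticodon_record()]).
#' @export
read_annotated_genome <- function(path, dialect = c("genbank", "embl", "gff3"),
                                  fasta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
    genbank = read_flatfile(path, "genbank"),
    embl    = read_flatfile(path, "embl"),
    gff3    = read_gff3_genome(path, fasta))
}

# shared GenBank/EMBL feature-table reader (minimal, coordinates owned here)
read_flatfile <- function(path, flavour) {
  lines <- readLines(path, warn = FALSE)
  if (flavour == "genbank") {
    head_line <- grep("^LOCUS", lines, value = TRUE)[1]
    circular <- grepl("circular", head_line, ignore.case = TRUE)
    id <- strsplit(trimws(sub("^LOCUS", "", head_line)), "\\s+")[[1]][1]
    feat_start <- grep("^FEATURES", lines)[1]
    seq_start <- grep("^ORIGIN", lines)[1]
    feat_lines <- lines[(feat_start + 1L):(seq_start - 1L)]
    seq_lines <- lines[(seq_start + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  } else {
    head_line <- grep("^ID", lines, value = TRUE)[1]
    circular <- grepl("circular", head_line, ignore.case = TRUE)
    id <- trimws(strsplit(sub("^ID\\s+", "", head_line), ";")[[1]][1])
    ft <- grep("^FT", lines, value = TRUE)
    feat_lines <- sub("^FT", "  ", ft)         # blank the prefix, keep columns
    seq_start <- grep("^SQ", lines)[1]
    seq_lines <- lines[(seq_start + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  genome <- circular_genome(id, residues, circular = circular)
  feats <- parse_feature_table(feat_lines)
  assemble_models(genome, feats)
}

# split a feature table body into (key, location, qualifiers) records;
# `lines` have the leading record-type columns already removed (21-char indent)
parse_feature_table <- function(lines) {
  feats <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) feats[[length(feats) + 1L]] <<- cur
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    key <- trimws(substr(ln, 1L, 20L))
    rest <- trimws(substring(ln, 21L))
    if (nzchar(key)) {                        # new feature record
      flush()
      cur <- list(key = key, location = rest, qualifiers = character(0))
    } else if (!is.null(cur)) {
      if (startsWith(rest, "/")) {
        cur$qualifiers <- c(cur$qualifiers, rest)
      } else if (length(cur$qualifiers) == 0L) {
        cur$location <- paste0(cur$location, rest)   # continued location
      } else {
        n <- length(cur$qualifiers)
        cur$qualifiers[n] <- paste(cur$qualifiers[n], rest)
      }
    }
  }
  flush()
  feats
}

qualifier_value <- function(feat, name) {
  pat <- paste0("^/", name, "=")
  hit <- grep(pat, feat$qualifiers, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  gsub('^"|"$', "", sub(pat, "", hit[1]))
}

# Parse a GenBank/EMBL location string into strand + ordered segment list.
# Handles complement(), join(), order(), partial markers (< >), and merges a
# segment pair abutting the origin of a circular record into one wrapped
# interval.  Returns exons in transcription order.
parse_location <- function(loc, genome_length, circular, feature_desc = loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    m <- regmatches(p, regexec("^(\\d+)(\\.\\.(\\d+))?$", p))[[1]]
    if (length(m) == 0L)
      stop("malformed coordinates in feature '", feature_desc, "': ", p)
    s <- as.integer(m[2])
    e <- if (nzchar(m[4] %||% "")) as.integer(m[4]) else s
    if (e > genome_length || s > genome_length) {
      if (!circular)
        stop(sprintf("feature '%s' exceeds sequence length %d on a linear record",
                     feature_desc, genome_length))
      s <- canon_pos(s, genome_length); e <- canon_pos(e, genome_length)
    }
    c(s, e)
  })
  # merge (x..L, 1..y) pairs into a single origin-wrapping segment
  merged <- list()
  i <- 1L
  while (i <= length(segs)) {
    s <- segs[[i]]
    if (i < length(segs) && s[2] == genome_length && segs[[i + 1L]][1] == 1L &&
        circular) {
      merged[[length(merged) + 1L]] <- c(s[1], segs[[i + 1L]][2], 1L)
      i <- i + 2L
    } else {
      merged[[length(merged) + 1L]] <- c(s, 0L)
      i <- i + 1L
    }
  }
  exons <- lapply(merged, function(m)
    feature_interval(m[1], m[2], strand, wraps_origin = m[3] == 1L))
  if (strand == "-") exons <- rev(exons)      # transcription order
  list(strand = strand, exons = exons)
}

# turn parsed flat-file features into gene models and anticodon records
assemble_models <- function(genome, feats) {
  genes <- list(); trnas <- list()
  class_of <- c(CDS = "protein", rRNA = "rRNA", tRNA = "tRNA")
  for (f in feats) {
    if (!f$key %in% names(class_of)) next
    name <- qualifier_value(f, "gene")
    if (is.na(name)) name <- qualifier_value(f, "product")
    if (is.na(name)) name <- f$key
    pl <- parse_location(f$location, genome$length, genome$circular, name)
    stop_codon <- NA_character_
    if (f$key == "CDS") {
      cds <- paste(vapply(pl$exons, function(e)
        interval_sequence(genome, e), ""), collapse = "")
      if (nchar(cds) %% 3 == 0 && nchar(cds) >= 3)
        stop_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
    }
    gm <- gene_model(name, class_of[[f$key]], pl$exons, pl$strand,
                     genome_length = genome$length, stop_codon = stop_codon)
    genes[[length(genes) + 1L]] <- gm
    if (f$key == "tRNA") {
      aa <- sub("^tRNA-", "", name)
      anti <- qualifier_value(f, "anticodon")
      if (!is.na(anti)) {
        m <- regmatches(anti, regexec("seq:([acgtuACGTU]{3})", anti))[[1]]
        anti <- if (length(m)) toupper(chartr("Tt", "Uu", m[2])) else NA_character_
      }
      if (!is.na(anti))
        trnas[[length(trnas) + 1L]] <-
          anticodon_record(aa, anti, gm$span)
    }
  }
  list(genome = genome, genes = genes, trnas = trnas)
}

## ---------------------------------------------------------------------------
## GFF3 + FASTA

read_gff3_genome <- function(path, fasta = NULL) {
  if (is.null(fasta))
    fasta <- paste0(tools::file_path_sans_ext(path), ".fa")
  if (!file.exists(fasta)) stop("genome FASTA not found: ", fasta)
  dna <- Biostrings::readDNAStringSet(fasta)
  id <- sub("\\s.*$", "", names(dna)[1])
  circular <- grepl("circular", names(dna)[1], ignore.case = TRUE)
  genome <- circular_genome(id, as.character(dna[[1]]), circular = circular)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  md$Parent <- vapply(S4Vectors::mcols(gr)$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  L <- genome$length

  fold <- function(s, e) {
    # an end beyond L encodes an origin-wrapping feature on a circular record
    if (e > L) {
      if (!genome$circular)
        stop(sprintf("feature %d..%d exceeds sequence length %d on a linear record",
                     s, e, L))
      feature_interval(s, e - L, wraps_origin = TRUE)
    } else feature_interval(s, e)
  }

  genes <- list(); trnas <- list()
  gene_rows <- md[md$type == "gene", , drop = FALSE]
  for (i in seq_len(nrow(gene_rows))) {
    grow <- gene_rows[i, ]
    kids <- md[!is.na(md$Parent) & md$Parent == grow$ID &
                 md$type %in% c("CDS", "exon"), , drop = FALSE]
    if (nrow(kids) == 0L) kids <- grow
    strand <- as.character(grow$strand)
    ord <- if ("exon_order" %in% names(kids) && !anyNA(kids$exon_order)) {
      order(as.integer(kids$exon_order))
    } else if (strand == "+") order(kids$start) else order(-kids$start)
    kids <- kids[ord, , drop = FALSE]
    exons <- lapply(seq_len(nrow(kids)), function(j) {
      iv <- fold(kids$start[j], kids$end[j])
      feature_interval(iv$start, iv$end, strand, iv$wraps_origin)
    })
    fclass <- if ("feature_class" %in% names(grow) && !is.na(grow$feature_class))
      grow$feature_class else "protein"
    stopc <- if ("stop_codon" %in% names(grow) && !is.na(grow$stop_codon))
      grow$stop_codon else NA_character_
    gm <- gene_model(grow$Name %||% grow$ID, fclass, exons, strand,
                     genome_length = L, stop_codon = stopc)
    # re-attach intron metadata if present
    irows <- md[!is.na(md$Parent) & md$Parent == grow$ID &
                  md$type == "intron", , drop = FALSE]
    if (nrow(irows) > 0L && nrow(irows) == length(gm$introns)) {
      iord <- order(as.integer(irows$ordinal))
      irows <- irows[iord, , drop = FALSE]
      for (j in seq_len(nrow(irows))) {
        gm$introns[[j]]$intron_type <- irows$intron_type[j] %||% "uncertain"
        gm$introns[[j]]$he_label <- irows$he_label[j] %||% "none"
      }
    }
    genes[[length(genes) + 1L]] <- gm
    if (fclass == "tRNA" && "anticodon" %in% names(grow) &&
        !is.na(grow$anticodon)) {
      aa <- sub("^tRNA-", "", gm$name)
      trnas[[length(trnas) + 1L]] <-
        anticodon_record(aa, grow$anticodon, gm$span)
    }
  }
  list(genome = genome, genes = genes, trnas = trnas)
}

## ---------------------------------------------------------------------------
## Output

#' Write gene annotations
#'
#' GFF3 is the canonical interchange dialect: genes are written as
#' `gene` records with `CDS` (protein) or `exon` (RNA) children carrying an
#' `exon_order` attribute (transcription order), plus `intron` children with
#' type and homing-endonuclease labels. BED output is 0-based half-open
#' (BED12 with exon blocks). Origin-wrapping features are written with
#' `end = end + L`.
#'
#' @param genes list of [gene_model()].
#' @param path output path.
#' @param dialect `"gff3"` or `"bed"`.
#' @param genome optional [circular_genome()]; its id and length are used for
#'   the sequence-region header (defaults taken from the first gene).
#' @param trnas optional list of [anticodon_record()] to attach anticodons.
#' @return invisibly, the path written.
#' @export
write_annotation <- function(genes, path, dialect = c("gff3", "bed"),
                             genome = NULL, trnas = list()) {
  dialect <- match.arg(dialect)
  L <- if (!is.null(genome)) genome$length else genes[[1]]$genome_length
  seqid <- if (!is.null(genome)) genome$id else "genome"
  unfold <- function(iv) {
    if (iv$wraps_origin) c(iv$start, iv$end + L) else c(iv$start, iv$end)
  }
  anti_for <- function(gm) {
    for (tr in trnas)
      if (tr$locus$start == gm$span$start && tr$locus$end == gm$span$end)
        return(tr$anticodon)
    NA_character_
  }
  if (dialect == "gff3") {
    out <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqid, L))
    for (gm in genes) {
      sp <- unfold(gm$span)
      gid <- paste0("gene:", gm$name, ":", gm$span$start)
      attrs <- sprintf("ID=%s;Name=%s;feature_class=%s", gid, gm$name,
                       gm$feature_class)
      if (!is.na(gm$stop_codon))
        attrs <- paste0(attrs, ";stop_codon=", gm$stop_codon)
      if (gm$feature_class == "tRNA") {
        ac <- anti_for(gm)
        if (!is.na(ac)) attrs <- paste0(attrs, ";anticodon=", ac)
      }
      out <- c(out, paste(seqid, "mitofeatures", "gene", sp[1], sp[2], ".",
                          gm$strand, ".", attrs, sep = "\t"))
      ctype <- if (gm$feature_class == "protein") "CDS" else "exon"
      for (j in seq_along(gm$exons)) {
        ep <- unfold(gm$exons[[j]])
        out <- c(out, paste(seqid, "mitofeatures", ctype, ep[1], ep[2], ".",
                            gm$strand, if (ctype == "CDS") "0" else ".",
                            sprintf("ID=%s.e%d;Parent=%s;exon_order=%d",
                                    gid, j, gid, j), sep = "\t"))
      }
      for (ir in gm$introns) {
        ip <- unfold(ir$interval)
        out <- c(out, paste(seqid, "mitofeatures", "intron", ip[1], ip[2], ".",
                            gm$strand, ".",
                            sprintf("ID=%s.i%d;Parent=%s;ordinal=%d;intron_type=%s;he_label=%s",
                                    gid, ir$ordinal, gid, ir$ordinal,
                                    ir$intron_type, ir$he_label), sep = "\t"))
      }
    }
    writeLines(out, path)
  } else {
    out <- character(0)
    for (gm in genes) {
      sp <- unfold(gm$span)
      exs <- lapply(gm$exons, unfold)
      exs <- exs[order(vapply(exs, `[`, 0, 1))]
      sizes <- vapply(exs, function(e) e[2] - e[1] + 1L, 0)
      starts <- vapply(exs, function(e) e[1] - sp[1], 0)
      out <- c(out, paste(seqid, sp[1] - 1L, sp[2], gm$name, 0L, gm$strand,
                          sp[1] - 1L, sp[2], "0,0,0", length(exs),
                          paste0(paste(sizes, collapse = ","), ","),
                          paste0(paste(starts, collapse = ","), ","),
                          sep = "\t"))
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Write a FASTA sequence file for a circular genome
#'
#' @param genome a [circular_genome()].
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  header <- sprintf("%s %s", genome$id,
                    if (genome$circular) "circular" else "linear")
  dna <- Biostrings::DNAStringSet(genome$residues)
  names(dna) <- header
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

#' Write a phylogenetic tree in newick format
#'
#' Thin wrapper over [ape::write.tree()]; the emitted string parses back to an
#' identical topology with branch lengths preserved to full precision.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
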