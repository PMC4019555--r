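# One-shot orchestration of all analysis stages with a machine-readable
# manifest. Stages are independent after input parsing: a failing stage is
# recorded in the manifest and the remaining stages still run.

default_run_config <- function() {
  list(
    input = list(gff3 = NULL, fasta = NULL, genbank = NULL, embl = NULL),
    out_dir = "mitofeatures_run",
    seed = 1L,
    code_table = "4",
    skew = list(window_bp = 1000L, step_bp = 100L, n_null = 499L,
                quantile = 0.95),
    repeats = list(seed_k = 11L, min_len = 30L, min_identity = 0.75,
                   orientation = "both", cutoffs = c(0.75, 0.80, 0.90),
                   cluster = TRUE),
    duplication = list(min_len = 1000L),
    cai = list(reference_genes = NULL),
    he = list(domains_fasta = NULL, loci_tsv = NULL,
              mantel_permutations = 999L))
}

#' Run the complete feature-analysis pipeline
#'
#' Parses the annotated genome, then runs every analysis stage and writes
#' per-stage TSV/newick/JSON artifacts plus a JSON manifest with parameter
#' provenance. The run is fully reproducible from the config and inputs: all
#' randomness (skew null replicates, Mantel permutations) derives from
#' `config$seed`, and the manifest contains no timestamps.
#'
#' @param config a config list (see `default_run_config` fields), or the
#'   path to a YAML file with the same structure. Minimal usage supplies
#'   `input$gff3` + `input$fasta` (or `input$genbank` / `input$embl`) and
#'   `out_dir`.
#' @return the manifest, invisibly; written as `manifest.json` in the output
#'   directory.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_run_config(), config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(tool = "mitofeatures",
                   version = as.character(utils::packageVersion("mitofeatures")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("input", "out_dir"))],
                   stages = list(), outputs = character(0))
  note <- function(stage, status, outputs = character(0), message = NULL) {
    manifest$stages[[stage]] <<- list(status = status,
                                      outputs = as.list(outputs),
                                      message = message)
    manifest$outputs <<- c(manifest$outputs, outputs)
  }
  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) note(stage, "failed", message = conditionMessage(res))
    res
  }
  path_of <- function(f) file.path(out_dir, f)

  ## input parsing (everything else depends on it)
  ann <- if (!is.null(config$input$genbank)) {
    read_annotated_genome(config$input$genbank, "genbank")
  } else if (!is.null(config$input$embl)) {
    read_annotated_genome(config$input$embl, "embl")
  } else if (!is.null(config$input$gff3)) {
    read_annotated_genome(config$input$gff3, "gff3",
                          fasta = config$input$fasta)
  } else stop("config$input must name a genbank, embl, or gff3 (+fasta) input")
  genome <- ann$genome; genes <- ann$genes; trnas <- ann$trnas
  protein_genes <- Filter(function(g) g$feature_class == "protein", genes)

  ## structure stage
  run_stage("structure", function() {
    st <- structure_table(genes)
    utils::write.table(st, path_of("structure.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    comp <- genome_composition(genome, genes)
    cdf <- data.frame(category = c("coding", "intronic", "intergenic"),
                      bp = c(comp$coding_bp, comp$intronic_bp,
                             comp$intergenic_bp),
                      fraction = c(comp$coding_fraction,
                                   comp$intronic_fraction,
                                   comp$intergenic_fraction))
    utils::write.table(cdf, path_of("composition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("structure", "ok", c("structure.tsv", "composition.tsv"))
  })

  ## codon usage, positional GC, CAI
  run_stage("codon", function() {
    cds <- vapply(protein_genes, function(g)
      paste(vapply(g$exons, function(e) interval_sequence(genome, e), ""),
            collapse = ""), "")
    if (length(cds) == 0L) { note("codon", "skipped",
                                  message = "no protein genes"); return() }
    usage <- count_codons(cds, taxon = genome$id)
    sf <- synonymous_fractions(usage, config$code_table)
    utils::write.table(sf, path_of("codon_usage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pg <- positional_gc(cds)
    utils::write.table(data.frame(metric = names(pg), percent = unname(pg)),
                       path_of("positional_gc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ref_names <- config$cai$reference_genes %||%
      vapply(protein_genes, function(g) g$name, "")
    ref_cds <- cds[vapply(protein_genes, function(g) g$name, "") %in% ref_names]
    ref <- count_codons(ref_cds, taxon = "reference")
    cai <- vapply(seq_along(protein_genes), function(i)
      compute_cai(cds[i], ref, config$code_table), 0)
    utils::write.table(
      data.frame(gene = vapply(protein_genes, function(g) g$name, ""),
                 cai = cai),
      path_of("cai.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    note("codon", "ok",
         c("codon_usage.tsv", "positional_gc.tsv", "cai.tsv"))
  })

  ## codon-usage phylogeny across taxa, when several CDS sets are supplied
  run_stage("phylo", function() {
    taxa <- config$codon_taxa
    if (is.null(taxa) || length(taxa) < 3L) {
      note("phylo", "skipped",
           message = "needs >= 3 taxon CDS FASTA files in codon_taxa")
      return()
    }
    usages <- lapply(names(taxa), function(nm) {
      dna <- Biostrings::readDNAStringSet(taxa[[nm]])
      count_codons(as.character(dna), taxon = nm)
    })
    dm <- codon_distance_matrix(usages, method = "rmsd",
                                code_table = config$code_table)
    utils::write.table(dm, path_of("distance_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
    tree <- neighbor_joining(dm)
    write_newick(tree, path_of("tree.nwk"))
    note("phylo", "ok", c("distance_matrix.tsv", "tree.nwk"))
  })

  ## skew profile and replication landmarks
  run_stage("skew", function() {
    prof <- windowed_skew(genome, config$skew$window_bp,
                          config$skew$step_bp)
    write_skew_tsv(prof, path_of("skew.tsv"))
    lm <- call_replication_landmarks(prof, n_null = config$skew$n_null,
                                     quantile = config$skew$quantile,
                                     seed = config$seed)
    lmdf <- data.frame(
      called = lm$called,
      ori_start = if (lm$called) lm$ori$start else NA,
      ori_end = if (lm$called) lm$ori$end else NA,
      ter_start = if (lm$called) lm$ter$start else NA,
      ter_end = if (lm$called) lm$ter$end else NA,
      range = lm$range, null_threshold = lm$null_threshold)
    utils::write.table(lmdf, path_of("landmarks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("skew", "ok", c("skew.tsv", "landmarks.tsv"),
         message = if (!lm$called) "no significant skew: landmark no-call")
  })

  ## repeats, clusters, duplication, coverage
  run_stage("repeats", function() {
    rp <- config$repeats
    pairs <- self_compare(genome, rp$seed_k, rp$min_len, rp$min_identity,
                          rp$orientation)
    pdf <- do.call(rbind, lapply(pairs, function(p) data.frame(
      a_start = p$interval_a$start, a_end = p$interval_a$end,
      b_start = p$interval_b$start, b_end = p$interval_b$end,
      orientation = p$orientation, identity = p$identity,
      length = p$length, evalue = p$evalue)))
    if (is.null(pdf)) pdf <- data.frame()
    utils::write.table(pdf, path_of("repeats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outs <- "repeats.tsv"
    if (isTRUE(rp$cluster) && length(pairs) > 0L) {
      cl <- cluster_repeats(pairs, genome, rp$cutoffs)
      cdf <- do.call(rbind, lapply(names(cl), function(lv)
        do.call(rbind, lapply(seq_along(cl[[lv]]), function(ci) {
          mem <- cl[[lv]][[ci]]$members
          data.frame(level = lv, cluster = ci,
                     start = vapply(mem, function(iv) iv$start, 0L),
                     end = vapply(mem, function(iv) iv$end, 0L))
        }))))
      utils::write.table(cdf %||% data.frame(), path_of("clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- c(outs, "clusters.tsv")
    }
    dups <- find_inverted_duplication(genome,
                                      min_len = config$duplication$min_len)
    ddf <- do.call(rbind, lapply(dups, function(d) data.frame(
      r1_start = d$region_1$start, r1_end = d$region_1$end,
      r2_start = d$region_2$start, r2_end = d$region_2$end,
      length_bp = d$length_bp, identity = d$identity,
      n_differences = nrow(d$mismatches))))
    if (is.null(ddf)) ddf <- data.frame()
    utils::write.table(ddf, path_of("duplication.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cov <- repeat_coverage(pairs, genes, genome)
    utils::write.table(
      data.frame(metric = names(unlist(cov)), value = unlist(cov)),
      path_of("repeat_coverage.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    note("repeats", "ok", c(outs, "duplication.tsv", "repeat_coverage.tsv"))
  })

  ## tRNA decoding sufficiency
  run_stage("decoding", function() {
    if (length(trnas) == 0L) {
      note("decoding", "skipped", message = "annotation carries no tRNAs")
      return()
    }
    cds <- vapply(protein_genes, function(g)
      paste(vapply(g$exons, function(e) interval_sequence(genome, e), ""),
            collapse = ""), "")
    usage <- count_codons(cds, taxon = "conserved")
    rep_ <- decoding_check(trnas, usage, code_table = config$code_table)
    jsonlite::write_json(
      list(decodable = rep_$decodable, undecodable = rep_$undecodable,
           undecodable_used = rep_$undecodable_used,
           unassigned_candidates = rep_$unassigned_candidates,
           reassignment_notes = rep_$reassignment_notes),
      path_of("decoding.json"), auto_unbox = TRUE, pretty = TRUE)
    note("decoding", "ok", "decoding.json")
  })

  ## homing-endonuclease similarity vs. locus distance
  run_stage("he", function() {
    he <- config$he
    if (is.null(he$domains_fasta) || is.null(he$loci_tsv)) {
      note("he", "skipped", message = "no HE domain inputs supplied")
      return()
    }
    aa <- Biostrings::readAAStringSet(he$domains_fasta)
    loci <- utils::read.delim(he$loci_tsv, stringsAsFactors = FALSE)
    doms <- lapply(seq_along(aa), function(i)
      he_domain_record(loci$family[i], as.character(aa[[i]]),
                       feature_interval(loci$start[i], loci$end[i])))
    fams <- split(seq_along(doms),
                  vapply(doms, function(d) d$family, ""))
    res <- list()
    for (fam in names(fams)) {
      idx <- fams[[fam]]
      if (length(idx) < 3L) next
      sim <- pairwise_identity(doms[idx])
      dd <- circular_distance_matrix(doms[idx], genome$length)
      method <- if (fam == "LAGLIDADG2") "spearman" else "pearson"
      transform <- if (fam == "LAGLIDADG1") "log" else "none"
      cr <- correlate_similarity_distance(
        sim, dd, method, transform,
        mantel_permutations = he$mantel_permutations, seed = config$seed)
      res[[fam]] <- list(method = cr$method, transform = cr$transform,
                         r = cr$r, p_value = cr$p_value,
                         mantel_p = cr$mantel_p, n_pairs = cr$n_pairs)
    }
    jsonlite::write_json(res, path_of("he_correlation.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    note("he", "ok", "he_correlation.json")
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       null = "null")
  invisible(manifest)
}
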