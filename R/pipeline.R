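PILUS_CONFIG_KEYS <- c(
  "c_term_window", "max_intergenic_gap", "n_flank", "stem_min",
  "loop_min", "loop_max", "allow_gu", "terminator_window", "dg_cutoff",
  "pseudocount", "background", "min_run", "efficiency")

#' Pipeline configuration
#'
#' All tunable parameters of the annotation pipeline with their
#' defaults.  Unknown keys are rejected so configuration typos fail
#' loudly.
#'
#' @param ... named overrides of the defaults (see source for the
#'   full key set: \code{c_term_window} 50 aa, \code{max_intergenic_gap}
#'   500 nt, \code{n_flank} 2 genes, hairpin \code{stem_min} 8 /
#'   \code{loop_min} 3 / \code{loop_max} 10 / \code{allow_gu} TRUE,
#'   \code{terminator_window} 150 nt, \code{dg_cutoff} -12 kcal/mol,
#'   PSSM \code{pseudocount} 1 and \code{background} 1/20,
#'   pseudogene \code{min_run} 8 nt, qPCR \code{efficiency} 2).
#' @return named list of class \code{"pilusConfig"}.
#' @export
pilusConfig <- function(...) {
  cfg <- list(
    c_term_window = 50, max_intergenic_gap = 500, n_flank = 2,
    stem_min = 8, loop_min = 3, loop_max = 10, allow_gu = TRUE,
    terminator_window = 150, dg_cutoff = -12, pseudocount = 1,
    background = 1 / 20, min_run = 8, efficiency = 2)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), PILUS_CONFIG_KEYS)
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown config key(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "pilusConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of config overrides.
#' @return a \code{\link{pilusConfig}}.
#' @export
readPilusConfig <- function(path) {
  do.call(pilusConfig, yaml::read_yaml(path))
}

# flatten one locus for the TSV report
lociTsvRow <- function(locus) {
  m <- locus@members
  term <- locus@terminator
  hgt <- locus@hgt
  data.frame(
    locus_id = locus@locusId, contig = locus@contigId,
    start = locus@start, end = locus@end, strand = locus@strand,
    completeness = locus@completeness, n_members = nrow(m),
    major = paste(m$gene_id[m$role == "MAJOR_PILIN"], collapse = ","),
    minors = paste(m$gene_id[m$role == "MINOR_PILIN"], collapse = ","),
    sortase = paste(m$gene_id[m$role == "SORTASE_C"], collapse = ","),
    pseudogene_members = paste(m$gene_id[m$pseudogene], collapse = ","),
    flanking_mobile_elements =
      paste(locus@flankingMobileElements, collapse = ","),
    terminator_dg = if (is.null(term)) NA_real_ else term$delta_g,
    terminator_distance = if (is.null(term)) NA_integer_
      else term$distance_from_locus_end,
    gc_delta = if (is.null(hgt)) NA_real_ else hgt$gc_delta,
    rscu_distance = if (is.null(hgt)) NA_real_ else hgt$rscu_distance,
    stringsAsFactors = FALSE)
}

lociReportEntry <- function(locus) {
  m <- locus@members
  list(
    locus_id = locus@locusId, contig = locus@contigId,
    start = locus@start, end = locus@end, strand = locus@strand,
    completeness = locus@completeness,
    members = lapply(seq_len(nrow(m)), function(i) list(
      gene_id = m$gene_id[i], role = m$role[i], start = m$start[i],
      end = m$end[i], strand = m$strand[i],
      pseudogene = m$pseudogene[i])),
    flanking_mobile_elements = as.list(locus@flankingMobileElements),
    terminator = if (is.null(locus@terminator)) NULL
      else as.list(locus@terminator),
    hgt = locus@hgt)
}

#' Annotate pilus gene clusters in a genome
#'
#' Full pipeline: classify every annotated CDS with the motif grammar,
#' assemble candidate loci, then attach flanking mobile elements,
#' terminator calls and HGT metrics to each locus.  Zero loci is a
#' valid result, not an error.  Output (when \code{out_dir} is given):
#' \code{loci.gff3}, \code{loci.tsv} and \code{report.json}; the
#' report carries no timestamps, so identical inputs and config give
#' byte-identical output.
#'
#' @param fasta genome FASTA path, or a named \code{DNAStringSet}.
#' @param gff GFF3 path, or a \code{GRanges} as from
#'   \code{\link{readGff3}}.
#' @param config a \code{\link{pilusConfig}}.
#' @param out_dir optional output directory.
#' @return list: \code{loci} (list of \code{\linkS4class{PilusLocus}}
#'   with evidence attached), \code{classA} (isolated sortase
#'   candidate gene_ids), \code{calls} (per-gene classification),
#'   \code{report} (the report.json structure as a list).
#' @export
annotateGenome <- function(fasta, gff, config = pilusConfig(),
                           out_dir = NULL) {
  contigs <- if (is.character(fasta)) readFasta(fasta, "DNA") else fasta
  genes <- if (is.character(gff)) readGff3(gff, contigs) else gff
  pssms <- defaultPssms(config$pseudocount, config$background)
  calls <- classifyPilins(genes, pssms,
                          c_term_window = config$c_term_window,
                          min_run = config$min_run)
  found <- findLoci(calls, genes,
                    max_intergenic_gap = config$max_intergenic_gap)
  loci <- lapply(found$loci, function(locus) {
    locus@flankingMobileElements <-
      detectFlankingMobileElements(locus, genes, n_flank = config$n_flank)
    locus@terminator <- callTerminator(
      locus, contigs[[locus@contigId]],
      window = config$terminator_window, dg_cutoff = config$dg_cutoff,
      stem_min = config$stem_min, loop_min = config$loop_min,
      loop_max = config$loop_max, allow_gu = config$allow_gu)
    locus@hgt <- locusHgtMetrics(locus, genes)
    locus
  })
  report <- list(
    schema_version = "1.0",
    tool = "piluscan",
    n_genes = length(genes),
    n_loci = length(loci),
    n_loci_complete =
      sum(vapply(loci, locusCompleteness, character(1)) == "complete"),
    n_loci_partial =
      sum(vapply(loci, locusCompleteness, character(1)) == "partial"),
    loci = lapply(loci, lociReportEntry),
    class_a_sortase_candidates = as.list(found$classA))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (length(loci)) {
      member_ids <- unlist(lapply(loci, function(l) l@members$gene_id))
      roles <- unlist(lapply(loci, function(l) l@members$role))
      sel <- genes[match(member_ids, S4Vectors::mcols(genes)$gene_id)]
      S4Vectors::mcols(sel)$role <- roles
      writeGff3(sel, file.path(out_dir, "loci.gff3"))
      tsv <- do.call(rbind, lapply(loci, lociTsvRow))
    } else {
      writeLines("##gff-version 3", file.path(out_dir, "loci.gff3"))
      tsv <- lociTsvRow(new("PilusLocus", locusId = "x", contigId = "x",
        members = S4Vectors::DataFrame(gene_id = character(),
          role = character(), start = integer(), end = integer(),
          strand = character(), pseudogene = logical()),
        start = 1L, end = 1L, strand = "+", completeness = "partial",
        flankingMobileElements = character(), terminator = NULL,
        hgt = NULL))[0, ]
    }
    utils::write.table(tsv, file.path(out_dir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  list(loci = loci, classA = found$classA, calls = calls, report = report)
}
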