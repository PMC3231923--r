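#' Flag a candidate transcriptional-slippage pseudogene
#'
#' A gene is flagged when its CDS contains a single-nucleotide
#' homopolymer run of at least \code{min_run} bases \emph{and} there is
#' corroborating evidence: an internal stop in the translation, or a
#' product annotation mentioning a pilin/fimbrial protein.  This
#' targets frame-shifted pilin genes whose expression may be rescued by
#' transcriptional slippage along the run (the motivating case is a
#' nine-guanine stretch).
#'
#' @param cds_nt nucleotide CDS string.
#' @param product product annotation text.
#' @param protein optional pre-computed translation; when \code{NULL}
#'   the CDS is translated up to its last full codon.
#' @param min_run minimum qualifying run length, default 8.
#' @return list with \code{flag} (logical), and for flagged genes
#'   \code{base}, \code{start} (1-based CDS position), \code{length} of
#'   the longest qualifying run, plus \code{evidence}
#'   (\code{"internal_stop"} and/or \code{"product"}).
#' @export
flagPseudogeneFrameshift <- function(cds_nt, product = "", protein = NULL,
                                     min_run = 8) {
  no <- list(flag = FALSE, base = NA_character_, start = NA_integer_,
             length = NA_integer_, evidence = character())
  if (is.null(cds_nt) || is.na(cds_nt) || !nchar(cds_nt)) return(no)
  r <- rle(strsplit(toupper(cds_nt), "")[[1]])
  qual <- which(r$lengths >= min_run & r$values %in% c("A", "C", "G", "T"))
  if (!length(qual)) return(no)
  if (is.null(protein)) {
    nt <- substring(cds_nt, 1, nchar(cds_nt) - nchar(cds_nt) %% 3L)
    protein <- if (nchar(nt) >= 3L) translateCds(nt) else ""
  }
  evidence <- character()
  if (hasInternalStop(protein)) evidence <- c(evidence, "internal_stop")
  if (length(product) && !is.na(product) &&
      grepl("pilin|fimbrial", product, ignore.case = TRUE))
    evidence <- c(evidence, "product")
  if (!length(evidence)) return(no)
  best <- qual[which.max(r$lengths[qual])]
  run_start <- if (best == 1L) 1L else sum(r$lengths[seq_len(best - 1L)]) + 1L
  list(flag = TRUE, base = r$values[best], start = as.integer(run_start),
       length = as.integer(r$lengths[best]), evidence = evidence)
}

#' Assemble classified genes into candidate pilus loci
#'
#' Greedy left-to-right chaining, per contig, of genes whose role is
#' not \code{NONE}: a chain extends while the intergenic gap to the
#' next role-carrying gene is at most \code{max_intergenic_gap}.
#' Chains satisfying the canonical composition (exactly one major
#' pilin, 0-2 minor pilins, exactly one class C sortase, one strand)
#' become \code{complete} loci; chains containing at least one pilin
#' but violating composition are reported as \code{partial}, never
#' dropped.  Chains consisting only of sortases are not loci: their
#' genes are returned as housekeeping (class A) sortase candidates.
#'
#' @param calls classification table from \code{\link{classifyPilins}}.
#' @param genes the \code{GRanges} the calls were made on.
#' @param max_intergenic_gap maximum intergenic distance in nt between
#'   consecutive chain members, default 500.
#' @return list with \code{loci} (list of
#'   \code{\linkS4class{PilusLocus}}, IDs \code{pil1, pil2, ...} in
#'   genomic order) and \code{classA} (gene_ids of isolated sortase
#'   candidates).
#' @export
findLoci <- function(calls, genes, max_intergenic_gap = 500) {
  stopifnot(nrow(calls) == length(genes))
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes))
  genes <- genes[ord]
  calls <- calls[ord, , drop = FALSE]
  mc <- S4Vectors::mcols(genes)
  idx <- which(calls$role != "NONE")
  loci <- list()
  classA <- character()
  if (!length(idx))
    return(list(loci = loci, classA = classA))
  ctg <- as.character(GenomicRanges::seqnames(genes))
  st <- GenomicRanges::start(genes)
  en <- GenomicRanges::end(genes)
  strd <- as.character(GenomicRanges::strand(genes))

  # split role genes into proximity chains
  chains <- list(idx[1])
  for (i in idx[-1]) {
    prev <- tail(chains[[length(chains)]], 1)
    gap <- st[i] - en[prev] - 1L
    if (ctg[i] == ctg[prev] && gap <= max_intergenic_gap)
      chains[[length(chains)]] <- c(chains[[length(chains)]], i)
    else chains <- c(chains, list(i))
  }

  k <- 0L
  for (ch in chains) {
    roles <- calls$role[ch]
    if (all(roles == "SORTASE_C")) {
      classA <- c(classA, calls$gene_id[ch])
      next
    }
    k <- k + 1L
    members <- S4Vectors::DataFrame(
      gene_id = calls$gene_id[ch], role = roles,
      start = st[ch], end = en[ch], strand = strd[ch],
      pseudogene = calls$pseudogene[ch])
    complete <- sum(roles == "MAJOR_PILIN") == 1L &&
      sum(roles == "MINOR_PILIN") <= 2L &&
      sum(roles == "SORTASE_C") == 1L &&
      length(unique(strd[ch])) == 1L
    loci[[k]] <- new("PilusLocus",
      locusId = paste0("pil", k),
      contigId = ctg[ch[1]],
      members = members,
      start = min(st[ch]), end = max(en[ch]),
      strand = if (length(unique(strd[ch])) == 1L) strd[ch[1]] else "*",
      completeness = if (complete) "complete" else "partial",
      flankingMobileElements = character(),
      terminator = NULL, hgt = NULL)
  }
  list(loci = loci, classA = classA)
}

#' Detect mobile-element annotations flanking a locus
#'
#' Scans up to \code{n_flank} annotated genes on each side of the locus
#' (in genomic order, same contig) for product text matching the
#' mobile-element keyword set; transposon-flanked loci are one of the
#' horizontal-gene-transfer signals reported by the pipeline.
#'
#' @param locus a \code{\linkS4class{PilusLocus}}.
#' @param genes all annotated genes (\code{GRanges}).
#' @param n_flank genes to inspect on each side, default 2.
#' @param keywords case-insensitive keyword set.
#' @return character vector of matching gene_ids (possibly empty).
#' @export
detectFlankingMobileElements <- function(locus, genes, n_flank = 2,
    keywords = c("transposase", "insertion sequence", "IS element",
                 "integrase", "mobile element")) {
  mc <- S4Vectors::mcols(genes)
  same <- as.character(GenomicRanges::seqnames(genes)) == locus@contigId
  genes <- genes[same]
  mc <- S4Vectors::mcols(genes)
  o <- order(GenomicRanges::start(genes))
  genes <- genes[o]; mc <- mc[o, , drop = FALSE]
  member_pos <- which(mc$gene_id %in% locus@members$gene_id)
  if (!length(member_pos)) return(character())
  lo <- min(member_pos); hi <- max(member_pos)
  up <- if (lo > 1L) seq(max(1L, lo - n_flank), lo - 1L) else integer()
  down <- if (hi < length(genes))
    seq(hi + 1L, min(length(genes), hi + n_flank)) else integer()
  flank_idx <- c(up, down)
  if (!length(flank_idx)) return(character())
  pat <- paste(keywords, collapse = "|")
  hit <- grepl(pat, mc$product[flank_idx], ignore.case = TRUE)
  mc$gene_id[flank_idx][hit]
}
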