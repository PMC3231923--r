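#' G+C content of a nucleotide sequence
#'
#' N bases are excluded from the denominator, so the value reflects
#' only called bases.
#'
#' @param seq nucleotide string (or \code{DNAString}).
#' @return percent G+C in [0, 100].
#' @examples
#' gcContent("ATGC")    # 50
#' gcContent("ATNNGC")  # 50 — N excluded
#' @export
gcContent <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!nchar(seq)) stop("empty sequence")
  b <- strsplit(seq, "")[[1]]
  gc <- sum(b %in% c("G", "C"))
  at <- sum(b %in% c("A", "T"))
  if (gc + at == 0L) stop("sequence contains no called (A/C/G/T) bases")
  100 * gc / (gc + at)
}

# the 59 informative codons: sense codons of the bacterial code minus
# the single-codon families (ATG/Met, TGG/Trp)
informativeCodons <- function() {
  code <- Biostrings::getGeneticCode("11")
  sense <- code[code != "*"]
  fam_size <- table(sense)
  keep <- names(sense)[sense %in% names(fam_size)[fam_size > 1L]]
  sort(keep)
}

# count in-frame codons over a set of CDS strings
countCodons <- function(cds) {
  codons <- unlist(lapply(cds, function(s) {
    s <- toupper(s)
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) return(character())
    substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  }))
  tab <- table(factor(codons, levels = informativeCodons()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon \eqn{c} in a synonymous family of size \eqn{n_{fam}},
#' \deqn{RSCU(c) = n_{fam} \cdot \frac{n_c + \alpha}{\sum_{c' \in fam} (n_{c'} + \alpha)}}
#' with pseudocount \eqn{\alpha = 0.5} per codon, so empty families are
#' defined (every codon there gets RSCU 1).  Stop codons and the
#' single-codon families (Met, Trp) are excluded, leaving 59
#' informative codons.
#'
#' @param genes \code{GRanges} with a \code{cds} metadata column, or a
#'   character vector of CDS strings.
#' @param alpha per-codon pseudocount, default 0.5.
#' @return named numeric vector of 59 RSCU values.
#' @export
rscu <- function(genes, alpha = 0.5) {
  cds <- if (is.character(genes)) genes else S4Vectors::mcols(genes)$cds
  if (!length(cds)) stop("empty gene list")
  counts <- countCodons(cds)
  if (sum(counts) == 0L) stop("no complete codons in input")
  code <- Biostrings::getGeneticCode("11")
  aa <- code[names(counts)]
  out <- numeric(length(counts))
  names(out) <- names(counts)
  for (a in unique(aa)) {
    fam <- names(counts)[aa == a]
    tot <- sum(counts[fam] + alpha)
    out[fam] <- length(fam) * (counts[fam] + alpha) / tot
  }
  out
}

#' Codon usage bias distance between two gene sets
#'
#' Mean absolute difference of the two RSCU vectors over the 59
#' informative codons.  Symmetric, nonnegative, and zero exactly when
#' the two usages coincide.
#'
#' @param locus_genes,genome_genes inputs as accepted by
#'   \code{\link{rscu}}.
#' @param alpha pseudocount passed to \code{\link{rscu}}.
#' @return nonnegative scalar.
#' @export
codonBiasDistance <- function(locus_genes, genome_genes, alpha = 0.5) {
  r1 <- rscu(locus_genes, alpha)
  r2 <- rscu(genome_genes, alpha)
  mean(abs(r1 - r2))
}

#' Horizontal-gene-transfer metrics for a locus
#'
#' Locus G+C is computed over the concatenated member CDSs and
#' compared with the genome baseline, taken as all annotated CDSs
#' (coding regions, not raw contig sequence).  \code{gc_delta} is in
#' percentage points (locus minus genome); the codon-usage distance is
#' \code{\link{codonBiasDistance}} between locus and genome gene sets.
#'
#' @param locus a \code{\linkS4class{PilusLocus}}.
#' @param genes all annotated genes (\code{GRanges} with \code{cds}).
#' @return named list: \code{locus_gc}, \code{genome_gc},
#'   \code{gc_delta}, \code{rscu_distance}, \code{n_codons_locus}.
#' @export
locusHgtMetrics <- function(locus, genes) {
  mc <- S4Vectors::mcols(genes)
  member <- mc$gene_id %in% locus@members$gene_id
  if (!any(member)) stop("locus members not found among genes")
  locus_cds <- mc$cds[member]
  genome_cds <- mc$cds
  locus_gc <- gcContent(paste(locus_cds, collapse = ""))
  genome_gc <- gcContent(paste(genome_cds, collapse = ""))
  list(
    locus_gc = locus_gc,
    genome_gc = genome_gc,
    gc_delta = locus_gc - genome_gc,
    rscu_distance = codonBiasDistance(locus_cds, genome_cds),
    n_codons_locus = sum(nchar(locus_cds) %/% 3L)
  )
}
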