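# shared fixtures and independent oracles, built in code

# build a gene GRanges by hand from parallel vectors
mkGenes <- function(contig_id, start, end, strand, gene_id, product,
                    cds, protein = NULL) {
  if (is.null(protein))
    protein <- vapply(cds, function(x) {
      x <- substring(x, 1, nchar(x) - nchar(x) %% 3)
      if (nchar(x) >= 3) translateCds(x) else ""
    }, character(1), USE.NAMES = FALSE)
  GenomicRanges::GRanges(
    seqnames = contig_id,
    ranges = IRanges::IRanges(start, end),
    strand = strand,
    gene_id = gene_id, product = product, cds = cds, protein = protein,
    internal_stop = vapply(protein, hasInternalStop, logical(1),
                           USE.NAMES = FALSE),
    length_ok = nchar(cds) %% 3 == 0)
}

# brute-force PSSM window scorer, independent of scanPssm internals:
# a plain double loop over windows and positions
bruteForceWindowScores <- function(protein, pssm) {
  aa_order <- rownames(scoreMatrix(pssm))
  M <- scoreMatrix(pssm)
  w <- motifWidth(pssm)
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars) - w + 1
  if (n < 1) return(numeric(0))
  out <- numeric(n)
  for (s in seq_len(n)) {
    tot <- 0
    for (p in seq_len(w)) {
      row <- match(chars[s + p - 1], aa_order)
      tot <- if (is.na(row)) NA_real_ else tot + M[row, p]
    }
    out[s] <- tot
  }
  out
}

# brute-force inverted-repeat finder: tests every (loop start, loop
# length) placement directly with its own pairing code
brutePairs <- function(a, b, allow_gu = TRUE) {
  ok <- paste0(a, b) %in% c("AT", "TA", "GC", "CG")
  if (allow_gu) ok <- ok | paste0(a, b) %in% c("GT", "TG")
  ok
}

bruteForceHairpins <- function(seq, stem_min = 8, loop_min = 3,
                               loop_max = 10, allow_gu = TRUE) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  rows <- list()
  for (l in loop_min:loop_max) {
    for (s in seq_len(max(0, n - l + 1))) {
      stem <- 0
      while (s - stem - 1 >= 1 && s + l + stem <= n &&
             brutePairs(b[s - stem - 1], b[s + l + stem], allow_gu))
        stem <- stem + 1
      if (stem < stem_min) next
      if (l - 2 >= loop_min && brutePairs(b[s], b[s + l - 1], allow_gu))
        next
      rows[[length(rows) + 1]] <-
        c(start = s - stem, end = s + l - 1 + stem,
          stem_len = stem, loop_len = l)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), loop_len = integer()))
  df <- as.data.frame(do.call(rbind, rows))
  df[order(df$start, df$end), , drop = FALSE]
}

# reverse-complement a whole synthetic genome: contig flipped, gene
# coordinates mirrored, strands swapped; cds/protein stay attached
revCompGenome <- function(genome) {
  ctg <- names(genome$contigs)[1]
  L <- nchar(as.character(genome$contigs[[ctg]]))
  contigs <- Biostrings::DNAStringSet(
    stats::setNames(revComp(as.character(genome$contigs[[ctg]])), ctg))
  gr <- genome$genes
  new_start <- L - GenomicRanges::end(gr) + 1
  new_end <- L - GenomicRanges::start(gr) + 1
  flipped <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                    "-", "+")
  mc <- S4Vectors::mcols(gr)
  genes <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    ranges = IRanges::IRanges(new_start, new_end), strand = flipped)
  S4Vectors::mcols(genes) <- mc
  genes <- genes[order(GenomicRanges::start(genes))]
  list(contigs = contigs, genes = genes, L = L)
}

# a neutral background-like protein guaranteed motif-free
NEUTRAL_PROTEIN <- paste0(
  "MSTNDEQRHEW", strrep("DENQSTHRDE", 20), "WSTDNEHQ")
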