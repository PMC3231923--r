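#' Read a FASTA file of contigs or proteins
#'
#' Sequences are uppercased; in nucleotide mode U is converted to T so
#' RNA-style input is tolerated.  Record order is preserved and IDs are
#' taken as the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @param type \code{"DNA"} for contigs (default) or \code{"AA"} for
#'   proteins.
#' @return a \code{DNAStringSet} or \code{AAStringSet}, named by record ID.
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">c1", "acgtn", ">c2", "TTGACA"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA record ID(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (type == "DNA") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x a named \code{XStringSet} or named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("all records must be named before writing FASTA")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Translate a CDS under a bacterial genetic code
#'
#' The terminal stop codon (if present) is removed; internal stops are
#' retained as \code{"*"} so downstream pseudogene logic can see them.
#' Codons made ambiguous by N translate to \code{"X"}.
#'
#' @param cds_nt nucleotide CDS string, length divisible by 3.
#' @param table NCBI genetic code id (default \code{"11"}, bacteria).
#' @return protein string.
#' @examples
#' translateCds("ATGAAATAA")  # "MK"
#' translateCds("ATGTAAAAA")  # "M*K" — internal stop retained
#' @export
translateCds <- function(cds_nt, table = "11") {
  cds_nt <- toupper(gsub("U", "T", cds_nt, fixed = TRUE))
  n <- nchar(cds_nt)
  if (n == 0L) stop("empty CDS")
  if (n %% 3L != 0L)
    stop("CDS length (", n, ") not divisible by 3")
  code <- geneticCodeCached(as.character(table))
  codons <- substring(cds_nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    # ambiguity codes: resolve where unambiguous, else X
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_nt),
      genetic.code = Biostrings::getGeneticCode(as.character(table)),
      if.fuzzy.codon = "solve"))
    return(sub("\\*$", "", aa))
  }
  aa <- paste(aa, collapse = "")
  sub("\\*$", "", aa)
}

# per-session cache of plain codon -> amino-acid lookup vectors
.codeCache <- new.env(parent = emptyenv())
geneticCodeCached <- function(table) {
  got <- get0(table, envir = .codeCache)
  if (is.null(got)) {
    got <- Biostrings::getGeneticCode(table)
    assign(table, got, envir = .codeCache)
  }
  got
}

#' Does a protein carry an internal stop?
#'
#' @param protein protein string as returned by \code{\link{translateCds}}.
#' @return logical.
#' @export
hasInternalStop <- function(protein) {
  grepl("*", protein, fixed = TRUE)
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read CDS gene records from a GFF3 annotation
#'
#' Imports the CDS features of a GFF3 file, extracts each CDS from its
#' contig (reverse-complemented for minus-strand genes), applies the
#' declared phase, and translates under genetic code \code{table}.
#' Coordinates stay 1-based inclusive as in GFF3.  Multi-segment CDSs
#' (two CDS features sharing an ID) are outside the bacterial scope of
#' this package and raise an error.
#'
#' @param path path to GFF3 file.
#' @param contigs named \code{DNAStringSet} of the genome contigs.
#' @param table NCBI genetic code id, default \code{"11"}.
#' @return a \code{GRanges} sorted by contig and start with metadata
#'   columns \code{gene_id}, \code{product}, \code{cds} (nucleotide
#'   string), \code{protein}, \code{internal_stop} and \code{length_ok}
#'   (FALSE flags a CDS whose length is not divisible by 3; it is
#'   translated up to the last full codon, never dropped).
#' @export
readGff3 <- function(path, contigs, table = "11") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  mc <- S4Vectors::mcols(gr)
  ids <- if ("locus_tag" %in% colnames(mc) && !all(is.na(mc$locus_tag)))
    as.character(mc$locus_tag) else as.character(mc$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("every CDS needs an ID or locus_tag attribute")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("multi-segment CDS unsupported (duplicated ID): ",
         paste(dup, collapse = ", "))
  product <- if ("product" %in% colnames(mc))
    as.character(mc$product) else rep(NA_character_, length(gr))
  product[is.na(product)] <- ""
  phase <- if ("phase" %in% colnames(mc)) as.integer(mc$phase)
    else rep(0L, length(gr))
  phase[is.na(phase)] <- 0L

  contig_id <- as.character(GenomicRanges::seqnames(gr))
  missing_ctg <- setdiff(unique(contig_id), names(contigs))
  if (length(missing_ctg))
    stop("GFF3 refers to contig(s) absent from FASTA: ",
         paste(missing_ctg, collapse = ", "))

  n <- length(gr)
  cds <- protein <- character(n)
  internal_stop <- length_ok <- logical(n)
  for (i in seq_len(n)) {
    ctg <- contigs[[contig_id[i]]]
    s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
    if (s < 1L || e > length(ctg))
      stop("CDS ", ids[i], " (", s, "..", e,
           ") outside contig ", contig_id[i], " bounds")
    nt <- as.character(Biostrings::subseq(ctg, s, e))
    if (as.character(GenomicRanges::strand(gr))[i] == "-") nt <- revComp(nt)
    if (phase[i] > 0L) nt <- substring(nt, phase[i] + 1L)
    length_ok[i] <- nchar(nt) %% 3L == 0L
    nt_tr <- if (length_ok[i]) nt
      else substring(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
    cds[i] <- nt
    protein[i] <- if (nchar(nt_tr) >= 3L) translateCds(nt_tr, table) else ""
    internal_stop[i] <- hasInternalStop(protein[i])
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = ids, product = product, cds = cds, protein = protein,
    internal_stop = internal_stop, length_ok = length_ok)
  gr <- gr[order(contig_id, GenomicRanges::start(gr))]
  gr
}

#' Write gene records back to GFF3
#'
#' Inverse of \code{\link{readGff3}} for round-trip testing and for
#' emitting called loci (source column \code{"piluscan"}).
#'
#' @param gr \code{GRanges} with at least \code{gene_id} metadata;
#'   \code{product} is written when present.
#' @param path output path.
#' @param type feature type column, default \code{"CDS"}.
#' @param source source column, default \code{"piluscan"}.
#' @return the path, invisibly.
#' @export
writeGff3 <- function(gr, path, type = "CDS", source = "piluscan") {
  mc <- S4Vectors::mcols(gr)
  attrs <- paste0("ID=", mc$gene_id, ";locus_tag=", mc$gene_id)
  if ("product" %in% colnames(mc))
    attrs <- paste0(attrs, ";product=", mc$product)
  if ("role" %in% colnames(mc))
    attrs <- paste0(attrs, ";role=", mc$role)
  lines <- paste(
    as.character(GenomicRanges::seqnames(gr)), source,
    if (length(type) == 1L) rep(type, length(gr)) else type,
    GenomicRanges::start(gr), GenomicRanges::end(gr), ".",
    as.character(GenomicRanges::strand(gr)), "0", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
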