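# ---- low-level seeded sequence helpers -------------------------------

BASES <- c("A", "C", "G", "T")

# n random codons at per-base G+C probability `gc`, stop codons rejected
randomCodons <- function(n, gc) {
  if (gc <= 0 || gc >= 1)
    stop("infeasible G+C target: ", gc, " (need 0 < gc < 1)")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draw <- function(k) {
    m <- matrix(sample(BASES, 3 * k, replace = TRUE, prob = p),
                ncol = 3, byrow = TRUE)
    paste0(m[, 1], m[, 2], m[, 3])
  }
  out <- draw(n)
  repeat {
    bad <- out %in% c("TAA", "TAG", "TGA")
    if (!any(bad)) break
    out[bad] <- draw(sum(bad))
  }
  out
}

randomSpacer <- function(len, gc) {
  if (len == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
}

# codons per amino acid under the bacterial code (no stops)
aaCodonTable <- local({
  code <- Biostrings::getGeneticCode("11")
  sense <- code[code != "*"]
  split(names(sense), sense)
})

# reverse-translate a peptide segment (no stop codon), choosing
# synonymous codons with weights exp(lambda * gc_count); lambda solved
# by bisection so the expected G+C matches `gc` (clamped when the
# target is unreachable for the fixed residues)
reverseTranslate <- function(protein, gc) {
  aa <- strsplit(protein, "")[[1]]
  cods <- aaCodonTable[aa]
  if (anyNA(names(cods))) stop("protein contains non-standard residues")
  gc_counts <- lapply(cods, function(cc)
    vapply(strsplit(cc, ""), function(b) sum(b %in% c("G", "C")), numeric(1)))
  expected_gc <- function(lambda) {
    tot <- 0
    for (g in gc_counts) {
      w <- exp(lambda * g)
      tot <- tot + sum(w * g) / sum(w)
    }
    tot / (3 * length(aa))
  }
  lo <- -20; hi <- 20
  if (expected_gc(lo) >= gc) lambda <- lo
  else if (expected_gc(hi) <= gc) lambda <- hi
  else {
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (expected_gc(mid) < gc) lo <- mid else hi <- mid
    }
    lambda <- (lo + hi) / 2
  }
  codons <- mapply(function(cc, g) {
    w <- exp(lambda * g)
    if (length(cc) == 1L) cc else sample(cc, 1L, prob = w)
  }, cods, gc_counts)
  paste(codons, collapse = "")
}

randomProtein <- function(n_res, first_m = TRUE) {
  body <- paste(sample(AMINO_ACIDS, n_res, replace = TRUE), collapse = "")
  if (first_m) paste0("M", substring(body, 2)) else body
}

BACKGROUND_PRODUCTS <- c(
  "hypothetical protein", "ABC transporter permease",
  "ribosomal protein", "DNA polymerase III subunit",
  "glycoside hydrolase", "two-component system response regulator",
  "elongation factor", "sugar kinase", "aminotransferase",
  "cell division protein", "peptidase", "oxidoreductase")

# ---- genome container -------------------------------------------------

makeGeneGRanges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig_id,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    gene_id = df$gene_id, product = df$product, cds = df$cds,
    protein = df$protein, internal_stop = df$internal_stop,
    length_ok = df$length_ok)
}

grToDf <- function(gr) {
  mc <- as.data.frame(S4Vectors::mcols(gr), stringsAsFactors = FALSE)
  cbind(data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE), mc)
}

# one background CDS: returns list(cds, protein); the protein is
# rejection-screened so it can never classify as pilin or sortase
backgroundCds <- function(n_codons, gc) {
  repeat {
    cds <- paste0("ATG",
                  paste(randomCodons(n_codons - 2L, gc), collapse = ""))
    cds <- paste0(cds, sample(c("TAA", "TAG", "TGA"), 1L))
    prot <- translateCds(cds)
    if (!grepl("LP.TG", prot) && !grepl("TL.TC", prot) &&
        !hasInternalStop(prot))
      return(list(cds = cds, protein = prot))
  }
}

#' Generate a synthetic annotated bacterial genome
#'
#' Background CDSs are drawn codon-by-codon at a target per-base G+C,
#' separated by random intergenic spacers, with neutral product
#' annotations.  Background proteins are rejection-screened to contain
#' no LPxTG core and no sortase catalytic motif, so motif-scanning
#' false-positive tests are meaningful.  Fully deterministic given the
#' seed.
#'
#' @param n_genes number of background genes (>= 10).
#' @param mean_gene_len mean CDS length in nt, default 900.
#' @param genome_gc target per-base G+C fraction, default 0.60.
#' @param seed RNG seed (required).
#' @param contig_id contig name, default \code{"chr1"}.
#' @param intergenic range of intergenic spacer lengths, default
#'   \code{c(50, 250)}.
#' @return a \code{list} of class \code{"synthGenome"}: \code{contigs}
#'   (named \code{DNAStringSet}), \code{genes} (\code{GRanges} with the
#'   same metadata layout as \code{\link{readGff3}}), \code{truth}
#'   (generation parameters and, after \code{\link{plantLocus}},
#'   planted-locus ground truth).
#' @export
generateGenome <- function(n_genes = 200, mean_gene_len = 900,
                           genome_gc = 0.60, seed, contig_id = "chr1",
                           intergenic = c(50, 250)) {
  if (missing(seed)) stop("seed is required")
  if (n_genes < 10L) stop("n_genes must be >= 10")
  if (genome_gc <= 0 || genome_gc >= 1)
    stop("infeasible G+C target: ", genome_gc)
  withSeed(seed, {
    mean_codons <- max(50L, round(mean_gene_len / 3))
    parts <- character(0)
    pos <- 0L
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      sp_len <- sample(intergenic[1]:intergenic[2], 1L)
      sp <- randomSpacer(sp_len, genome_gc)
      n_cod <- max(50L, stats::rpois(1L, mean_codons))
      g <- backgroundCds(n_cod, genome_gc)
      strand <- sample(c("+", "-"), 1L)
      placed <- if (strand == "-") revComp(g$cds) else g$cds
      start <- pos + sp_len + 1L
      end <- start + nchar(g$cds) - 1L
      parts <- c(parts, sp, placed)
      pos <- end
      rows[[i]] <- data.frame(
        contig_id = contig_id, start = start, end = end, strand = strand,
        gene_id = sprintf("SYN_%04d", i),
        product = sample(BACKGROUND_PRODUCTS, 1L),
        cds = g$cds, protein = g$protein,
        internal_stop = FALSE, length_ok = TRUE,
        stringsAsFactors = FALSE)
    }
    tail_sp <- randomSpacer(sample(intergenic[1]:intergenic[2], 1L),
                            genome_gc)
    contig <- paste(c(parts, tail_sp), collapse = "")
    df <- do.call(rbind, rows)
    contigs <- Biostrings::DNAStringSet(stats::setNames(contig, contig_id))
    structure(list(
      contigs = contigs,
      genes = makeGeneGRanges(df),
      truth = list(seed = seed, n_genes = n_genes,
                   genome_gc = genome_gc, loci = list())),
      class = "synthGenome")
  })
}

#' @export
print.synthGenome <- function(x, ...) {
  cat("synthetic genome:", sum(Biostrings::width(x$contigs)), "nt on",
      length(x$contigs), "contig(s),", length(x$genes), "genes,",
      length(x$truth$loci), "planted locus/loci\n")
  invisible(x)
}

#' Specification of a pilus locus to plant
#'
#' Defaults mirror the canonical architecture under study: a major
#' pilin (Sec signal + pilin motif + E-box + CWSS, motif instances
#' drawn verbatim from the packaged published set), two minor pilins
#' (Sec + CWSS only), one class C sortase carrying the TLxTC catalytic
#' motif under a neutral product annotation, transposase genes
#' immediately flanking the cluster, a GC-rich hairpin terminator 40 nt
#' downstream, and a locus G+C shifted +9 percentage points from the
#' genome background.
#'
#' @param n_minor minor pilins, 0-2, default 2.
#' @param locus_gc_shift percentage points added to the genome G+C for
#'   locus codons, default +9.
#' @param plant_terminator plant a 3' hairpin, default TRUE.
#' @param terminator_stem,terminator_loop hairpin geometry, defaults
#'   12 bp / 4 nt.
#' @param plant_transposase_flanks default TRUE.
#' @param plant_slippage_pseudogene plant a frameshifted pilin-like
#'   pseudogene with a 9-G run downstream of the cluster, default FALSE.
#' @param intergenic_gap gap between locus genes in nt, default 50.
#' @param terminator_offset nt between locus end and hairpin, default 40.
#' @return list of class \code{"locusSpec"}.
#' @export
locusSpec <- function(n_minor = 2, locus_gc_shift = 9,
                      plant_terminator = TRUE, terminator_stem = 12,
                      terminator_loop = 4,
                      plant_transposase_flanks = TRUE,
                      plant_slippage_pseudogene = FALSE,
                      intergenic_gap = 50, terminator_offset = 40) {
  if (!n_minor %in% 0:2) stop("n_minor must be 0, 1 or 2")
  structure(list(
    n_minor = n_minor, locus_gc_shift = locus_gc_shift,
    plant_terminator = plant_terminator,
    terminator_stem = terminator_stem, terminator_loop = terminator_loop,
    plant_transposase_flanks = plant_transposase_flanks,
    plant_slippage_pseudogene = plant_slippage_pseudogene,
    intergenic_gap = intergenic_gap,
    terminator_offset = terminator_offset), class = "locusSpec")
}

# assemble a gene from alternating segments: fixed peptides are
# reverse-translated at `gc`, free segments are drawn as codons at
# `gc` and translated, so body amino-acid composition follows the
# codon model (as in a gene acquired from a donor genome at that G+C)
segGene <- function(segments, gc) {
  cds <- character(length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    cds[i] <- if (s$type == "fixed") reverseTranslate(s$aa, gc)
      else paste(randomCodons(s$n, gc), collapse = "")
  }
  cds <- paste0(paste(cds, collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  list(cds = cds, protein = translateCds(cds))
}

fixedSeg <- function(aa) list(type = "fixed", aa = aa)
freeSeg <- function(n) list(type = "free", n = n)

# hydrophobic Sec h-region / membrane anchor; A/L/V keep the Kyte-
# Doolittle window mean well above the detector cutoff
hydrophobicStretch <- function(n) {
  paste(sample(c("L", "A", "V"), n, replace = TRUE, prob = c(2, 1, 1)),
        collapse = "")
}

# major pilin: Sec signal + pilin motif + E-box + CWSS + membrane
# anchor, motif instances drawn verbatim from the packaged table
synthMajorGene <- function(gc) {
  tab <- pilinMotifTable()
  row <- tab[sample.int(nrow(tab), 1L), ]
  repeat {
    g <- segGene(list(
      fixedSeg(paste0("MKKR", hydrophobicStretch(12))),
      freeSeg(110), fixedSeg(row$pilin_motif),
      freeSeg(80), fixedSeg(row$ebox),
      freeSeg(10), fixedSeg(row$cwss),
      fixedSeg(paste0(hydrophobicStretch(15), "RRK"))), gc)
    # no homopolymer run: a pilin-annotated gene with a long run would
    # look like a slippage pseudogene candidate
    if (!grepl("TL.TC", g$protein) && !hasInternalStop(g$protein) &&
        !grepl("A{8}|C{8}|G{8}|T{8}", g$cds))
      return(g)
  }
}

synthMinorGene <- function(gc, pssms) {
  tab <- pilinMotifTable()
  row <- tab[sample.int(nrow(tab), 1L), ]
  repeat {
    g <- segGene(list(
      fixedSeg(paste0("MRKK", hydrophobicStretch(12))),
      freeSeg(120), fixedSeg(row$cwss),
      fixedSeg(paste0(hydrophobicStretch(15), "KRR"))), gc)
    if (grepl("TL.TC", g$protein) || hasInternalStop(g$protein) ||
        grepl("A{8}|C{8}|G{8}|T{8}", g$cds)) next
    # a minor must not carry a full major motif set by accident
    has_pilin <- nrow(scanPssm(g$protein, pssms$pilin)) > 0
    has_ebox <- nrow(scanPssm(g$protein, pssms$ebox)) > 0
    if (!(has_pilin && has_ebox)) return(g)
  }
}

synthSortaseGene <- function(gc) {
  repeat {
    g <- segGene(list(fixedSeg("M"), freeSeg(130), fixedSeg("TLVTC"),
                      freeSeg(144)), gc)
    if (!grepl("LP.TG", g$protein) && !hasInternalStop(g$protein))
      return(g)
  }
}

# frameshifted pilin-like CDS with a 9-G slippage run and an internal
# stop downstream of the shift
synthPseudogeneCds <- function(gc) {
  repeat {
    cds <- paste0("ATG", paste(randomCodons(60, gc), collapse = ""),
                  "GGGGGGGGG",
                  sample(c("A", "C", "T"), 1L),
                  paste(randomCodons(60, gc), collapse = ""))
    cds <- substring(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
    cds <- paste0(cds, "TAA")
    prot <- translateCds(cds)
    if (hasInternalStop(prot) && !grepl("LP.TG", prot) &&
        !grepl("TL.TC", prot))
      return(cds)
  }
}

# GC-rich perfect hairpin: stem bases ~80% G/C, Watson-Crick closed
synthHairpin <- function(stem_len, loop_len) {
  stem5 <- paste(sample(BASES, stem_len, replace = TRUE,
                        prob = c(0.1, 0.4, 0.4, 0.1)), collapse = "")
  loop <- paste(sample(c("T", "C", "A"), loop_len, replace = TRUE),
                collapse = "")
  paste0(stem5, loop, revComp(stem5))
}

#' Plant a pilus locus into a synthetic genome
#'
#' Inserts, on the plus strand at a seeded position between background
#' genes: optional upstream transposase, the major pilin,
#' \code{n_minor} minor pilins, the sortase, then (downstream of the
#' cluster) the optional terminator hairpin, optional slippage
#' pseudogene and optional downstream transposase.  Locus proteins are
#' reverse-translated at the shifted G+C.  Downstream background gene
#' coordinates are shifted accordingly and full ground truth is
#' appended to \code{genome$truth$loci}.
#'
#' @param genome a \code{\link{generateGenome}} result.
#' @param spec a \code{\link{locusSpec}}.
#' @param seed RNG seed (required).
#' @return the modified genome.
#' @export
plantLocus <- function(genome, spec = locusSpec(), seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(genome, "synthGenome"))
  withSeed(seed, {
    pssms <- defaultPssms()
    gc_bg <- genome$truth$genome_gc
    # plant the shift relative to the realized background-CDS G+C, the
    # baseline the HGT metrics are computed against
    bg_cds <- S4Vectors::mcols(genome$genes)$cds[
      !grepl("^PIL", S4Vectors::mcols(genome$genes)$gene_id)]
    gc_realized_bg <- gcContent(paste(bg_cds, collapse = "")) / 100
    gc_locus <- min(0.95, max(0.05,
      gc_realized_bg + spec$locus_gc_shift / 100))
    gap <- spec$intergenic_gap
    df <- grToDf(genome$genes)
    ctg_id <- names(genome$contigs)[1]
    contig <- as.character(genome$contigs[[ctg_id]])
    on_ctg <- which(df$contig_id == ctg_id)
    # anchor after a background gene, 4+ genes from contig ends and
    # from any previously planted locus
    planted_pos <- which(grepl("^PIL", df$gene_id))
    near_planted <- unique(unlist(lapply(planted_pos, function(p)
      (p - 4L):(p + 4L))))
    cand <- on_ctg[seq(4L, length(on_ctg) - 4L)]
    cand <- setdiff(cand, near_planted)
    cand <- cand[!grepl("^PIL", df$gene_id[cand])]
    if (!length(cand)) stop("no insertion slot left on contig")
    anchor <- sample(cand, 1L)
    insert_at <- df$end[anchor] + 2L   # leave 1 nt of original spacer

    k <- length(genome$truth$loci) + 1L
    idbase <- sprintf("PIL%d", k)
    new_rows <- list()
    seq_parts <- character()
    offset <- 0L                        # length of block built so far
    add_gene <- function(cds, protein, product, gene_id, role) {
      start <- insert_at + offset + gap
      end <- start + nchar(cds) - 1L
      seq_parts <<- c(seq_parts, randomSpacer(gap, gc_bg), cds)
      offset <<- offset + gap + nchar(cds)
      new_rows[[length(new_rows) + 1L]] <<- data.frame(
        contig_id = ctg_id, start = start, end = end, strand = "+",
        gene_id = gene_id, product = product, cds = cds,
        protein = protein,
        internal_stop = hasInternalStop(protein), length_ok = TRUE,
        stringsAsFactors = FALSE)
      c(gene_id = gene_id, role = role)
    }

    # generate member genes, calibrating the working G+C so the
    # realized member-CDS G+C hits the planted target (fixed motif
    # segments respond less than 1:1 to the codon-level target)
    gc_work <- gc_locus
    for (it in 1:6) {
      gene_set <- c(
        list(major = synthMajorGene(gc_work)),
        if (spec$n_minor >= 1)
          stats::setNames(
            lapply(seq_len(spec$n_minor),
                   function(m) synthMinorGene(gc_work, pssms)),
            paste0("minor", seq_len(spec$n_minor))),
        list(sortase = synthSortaseGene(gc_work)))
      realized <- gcContent(paste(vapply(gene_set, `[[`, "", "cds"),
                                  collapse = "")) / 100
      if (abs(realized - gc_locus) < 0.001) break
      gc_work <- min(0.95, max(0.05, gc_work + (gc_locus - realized)))
    }

    members <- list()
    transposases <- character()
    if (spec$plant_transposase_flanks) {
      g <- backgroundCds(120L, gc_bg)
      add_gene(g$cds, g$protein, "transposase", paste0(idbase, "_tnpU"),
               "FLANK")
      transposases <- c(transposases, paste0(idbase, "_tnpU"))
    }
    members <- c(members, list(add_gene(
      gene_set$major$cds, gene_set$major$protein, "major pilin subunit",
      paste0(idbase, "_fimA"), "MAJOR_PILIN")))
    locus_start <- new_rows[[length(new_rows)]]$start
    if (spec$n_minor >= 1) {
      for (m in seq_len(spec$n_minor)) {
        g <- gene_set[[paste0("minor", m)]]
        members <- c(members, list(add_gene(
          g$cds, g$protein, "minor pilin subunit",
          sprintf("%s_fim%s", idbase, c("B", "Q")[m]), "MINOR_PILIN")))
      }
    }
    members <- c(members, list(add_gene(
      gene_set$sortase$cds, gene_set$sortase$protein,
      "hypothetical protein", paste0(idbase, "_srtA"), "SORTASE_C")))
    locus_end <- new_rows[[length(new_rows)]]$end

    terminator_truth <- NULL
    if (spec$plant_terminator) {
      hp <- synthHairpin(spec$terminator_stem, spec$terminator_loop)
      pre <- paste0(randomSpacer(spec$terminator_offset - 2L, 0.3), "AA")
      seq_parts <- c(seq_parts, pre, hp, "AA")
      hp_start <- locus_end + nchar(pre) + 1L
      terminator_truth <- list(
        start = as.integer(hp_start),
        end = as.integer(hp_start + nchar(hp) - 1L),
        stem_len = as.integer(spec$terminator_stem),
        loop_len = as.integer(spec$terminator_loop),
        distance_from_locus_end = as.integer(nchar(pre)))
      offset <- offset + nchar(pre) + nchar(hp) + 2L
    }
    pseudogene_id <- NULL
    if (spec$plant_slippage_pseudogene) {
      cds <- synthPseudogeneCds(gc_locus)
      prot_tr <- translateCds(cds)
      add_gene(cds, prot_tr, "fimbrial subunit (frameshifted)",
               paste0(idbase, "_fimX"), "PSEUDOGENE")
      pseudogene_id <- paste0(idbase, "_fimX")
    }
    if (spec$plant_transposase_flanks) {
      g <- backgroundCds(120L, gc_bg)
      add_gene(g$cds, g$protein, "IS3 family transposase",
               paste0(idbase, "_tnpD"), "FLANK")
      transposases <- c(transposases, paste0(idbase, "_tnpD"))
    }

    block <- paste(seq_parts, collapse = "")
    contig <- paste0(substring(contig, 1L, insert_at - 1L), block,
                     substring(contig, insert_at))
    shift <- nchar(block)
    move <- df$contig_id == ctg_id & df$start >= insert_at
    df$start[move] <- df$start[move] + shift
    df$end[move] <- df$end[move] + shift
    # ground truth of previously planted loci moves with the insertion
    genome$truth$loci <- lapply(genome$truth$loci, function(l) {
      if (l$contig_id == ctg_id && l$start >= insert_at) {
        l$start <- l$start + as.integer(shift)
        l$end <- l$end + as.integer(shift)
        if (!is.null(l$terminator)) {
          l$terminator$start <- l$terminator$start + as.integer(shift)
          l$terminator$end <- l$terminator$end + as.integer(shift)
        }
      }
      l
    })
    df <- rbind(df, do.call(rbind, new_rows))
    df <- df[order(df$contig_id, df$start), , drop = FALSE]

    contigs_chr <- as.character(genome$contigs)
    contigs_chr[[ctg_id]] <- contig
    genome$contigs <- Biostrings::DNAStringSet(contigs_chr)
    genome$genes <- makeGeneGRanges(df)
    mem_df <- do.call(rbind, lapply(members, function(m)
      data.frame(gene_id = m[["gene_id"]], role = m[["role"]],
                 stringsAsFactors = FALSE)))
    genome$truth$loci[[k]] <- list(
      locus_id = idbase, contig_id = ctg_id, anchor_gene = anchor,
      start = as.integer(locus_start), end = as.integer(locus_end),
      strand = "+",
      members = mem_df, gc_shift = spec$locus_gc_shift,
      terminator = terminator_truth, transposase_flanks = transposases,
      pseudogene = pseudogene_id)
    genome
  })
}

#' Write a synthetic genome to FASTA + GFF3 + truth JSON
#'
#' @param genome a \code{"synthGenome"}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, default \code{"genome"}.
#' @return named list of the three paths.
#' @export
writeGenome <- function(genome, dir, prefix = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fna"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  truth <- file.path(dir, paste0(prefix, ".truth.json"))
  writeFasta(genome$contigs, fa)
  writeGff3(genome$genes, gff, source = "piluscan-synth")
  jsonlite::write_json(genome$truth, truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(fasta = fa, gff3 = gff, truth = truth)
}

#' Simulate sequence evolution under the K2P model along a tree
#'
#' The root sequence is uniform over A/C/G/T; each branch applies the
#' Kimura two-parameter substitution process with
#' transition/transversion rate ratio \code{kappa}, using the exact
#' closed-form transition probabilities for the branch length
#' (expected substitutions per site).
#'
#' @param tree \code{ape::phylo} with nonnegative branch lengths (or a
#'   newick string).
#' @param root_len sequence length in nt.
#' @param kappa transition/transversion rate ratio, > 0, default 2.
#' @param seed RNG seed (required).
#' @return named character vector of aligned sequences, one per tip.
#' @export
evolveAlignment <- function(tree, root_len, kappa = 2, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (kappa <= 0) stop("kappa must be > 0")
  withSeed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    seqs[[root]] <- sample.int(4L, root_len, replace = TRUE)
    beta <- 1 / (kappa + 2)
    alpha <- kappa / (kappa + 2)
    ts_partner <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T (A C G T = 1..4)
    tv_opts <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
    mutate <- function(x, d) {
      p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) -
        0.5 * exp(-2 * (alpha + beta) * d)
      p_tv <- 0.25 - 0.25 * exp(-4 * beta * d)   # each of the two
      u <- stats::runif(length(x))
      out <- x
      is_ts <- u < p_ts
      is_tv1 <- !is_ts & u < p_ts + p_tv
      is_tv2 <- !is_ts & !is_tv1 & u < p_ts + 2 * p_tv
      out[is_ts] <- ts_partner[x[is_ts]]
      for (b in 1:4) {
        sel1 <- is_tv1 & x == b
        sel2 <- is_tv2 & x == b
        out[sel1] <- tv_opts[[b]][1]
        out[sel2] <- tv_opts[[b]][2]
      }
      out
    }
    # preorder edge traversal from the root
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      from <- ord$edge[e, 1]; to <- ord$edge[e, 2]
      seqs[[to]] <- mutate(seqs[[from]], ord$edge.length[e])
    }
    out <- vapply(seq_len(ntip), function(i)
      paste(BASES[seqs[[i]]], collapse = ""), character(1))
    stats::setNames(out, tree$tip.label)
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Per gene a baseline Ct is drawn once; for each condition the sample
#' Ct is \eqn{baseline - \log_E(RQ) + N(0, \sigma)} per replicate,
#' where RQ is the planted fold for target genes and 1 for reference
#' genes and the calibrator condition.
#'
#' @param folds data.frame with columns \code{gene}, \code{condition},
#'   \code{fold} (> 0) for the target genes.
#' @param reference_genes default \code{c("atpD","tufA","rpoB","ldh")}.
#' @param calibrator calibrator condition, default \code{"glucose"}.
#' @param sigma Ct noise SD in cycles, >= 0, default 0.2.
#' @param efficiency amplification efficiency, default 2.
#' @param n_replicates replicates per gene/condition, default 3.
#' @param seed RNG seed (required).
#' @return a validated \code{\link{ctTable}} with attribute
#'   \code{"planted_folds"}.
#' @export
simulateCt <- function(folds,
                       reference_genes = c("atpD", "tufA", "rpoB", "ldh"),
                       calibrator = "glucose", sigma = 0.2,
                       efficiency = 2, n_replicates = 3, seed) {
  if (missing(seed)) stop("seed is required")
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(folds$fold <= 0)) stop("planted folds must be > 0")
  withSeed(seed, {
    genes <- unique(c(folds$gene, reference_genes))
    conditions <- unique(c(calibrator, folds$condition))
    baseline <- stats::setNames(stats::runif(length(genes), 18, 24), genes)
    rows <- list()
    for (g in genes) {
      for (cond in conditions) {
        rq <- 1
        if (cond != calibrator && g %in% folds$gene) {
          hit <- folds$fold[folds$gene == g & folds$condition == cond]
          if (length(hit)) rq <- hit[1]
        }
        ct0 <- baseline[[g]] - log(rq, base = efficiency)
        for (r in seq_len(n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, condition = cond, replicate = r,
            ct = ct0 + stats::rnorm(1, 0, sigma),
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- ctTable(do.call(rbind, rows), reference_genes, calibrator)
    attr(tab, "planted_folds") <- folds
    tab
  })
}
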