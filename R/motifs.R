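#' Packaged pilin hallmark motif instances
#'
#' The 16 published major-pilin motif instances bundled with the
#' package: for each protein a 6-residue cell wall sorting signal
#' (CWSS, LPxTG core), a 10-residue pilin motif (conserved terminal
#' lysine in 15/16 instances) and a 12-residue E-box (conserved
#' glutamic acid at position 5).  These train the default PSSMs and
#' seed the synthetic-genome generator.
#'
#' @return data.frame with columns \code{strain}, \code{orf},
#'   \code{cwss}, \code{pilin_motif}, \code{ebox}.
#' @export
pilinMotifTable <- function() {
  path <- system.file("extdata", "pilin_motifs.tsv", package = "piluscan",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build a position-specific scoring matrix from motif instances
#'
#' Column score for amino acid \eqn{a} at position \eqn{p} is
#' \deqn{\ln\frac{(n_{ap}+\alpha)/(N+20\alpha)}{b}}
#' with pseudocount \eqn{\alpha} (default 1) and uniform background
#' \eqn{b = 1/20}.  The default reporting threshold is the minimum
#' self-score of the training instances, so every training instance
#' scores at or above threshold by construction.
#'
#' @param instances character vector of >= 2 equal-width amino-acid
#'   strings over the 20 standard residues.
#' @param kind motif label, e.g. \code{"CWSS"}.
#' @param pseudocount \eqn{\alpha}, default 1.
#' @param background per-residue background frequency \eqn{b},
#'   default 1/20.
#' @param threshold reporting threshold; default is the minimum
#'   training-instance self-score.
#' @return a \code{\linkS4class{MotifPSSM}}.
#' @examples
#' tab <- pilinMotifTable()
#' buildPssm(tab$cwss, kind = "CWSS")
#' @export
buildPssm <- function(instances, kind = "MOTIF", pseudocount = 1,
                      background = 1 / 20, threshold = NULL) {
  instances <- toupper(instances)
  if (length(instances) < 2L) stop("need at least 2 training instances")
  w <- unique(nchar(instances))
  if (length(w) != 1L)
    stop("ragged instance widths: ", paste(w, collapse = ", "))
  chars <- strsplit(instances, "")
  bad <- setdiff(unique(unlist(chars)), AMINO_ACIDS)
  if (length(bad))
    stop("non-standard amino acid(s) in instances: ",
         paste(bad, collapse = ", "))
  N <- length(instances)
  counts <- matrix(0L, nrow = 20L, ncol = w,
                   dimnames = list(AMINO_ACIDS, NULL))
  for (inst in chars)
    for (p in seq_len(w))
      counts[inst[p], p] <- counts[inst[p], p] + 1L
  freq <- (counts + pseudocount) / (N + 20 * pseudocount)
  scores <- log(freq / background)
  obj <- new("MotifPSSM", kind = kind, width = as.integer(w),
             scores = scores, threshold = 0,
             instances = instances, pseudocount = pseudocount,
             background = background)
  obj@threshold <- if (is.null(threshold)) min(selfScores(obj)) else threshold
  validObject(obj)
  obj
}

# total score of each training instance against its own PSSM
selfScores <- function(pssm) {
  vapply(strsplit(pssm@instances, ""), function(aa) {
    sum(pssm@scores[cbind(match(aa, AMINO_ACIDS), seq_along(aa))])
  }, numeric(1))
}

# highest-scoring residue per column
pssmConsensus <- function(pssm) {
  paste(AMINO_ACIDS[apply(pssm@scores, 2, which.max)], collapse = "")
}

#' Default pilin-motif PSSMs trained on the packaged instances
#'
#' @inheritParams buildPssm
#' @return named list with elements \code{cwss}, \code{pilin},
#'   \code{ebox}.
#' @export
defaultPssms <- function(pseudocount = 1, background = 1 / 20) {
  tab <- pilinMotifTable()
  list(
    cwss  = buildPssm(tab$cwss, "CWSS", pseudocount, background),
    pilin = buildPssm(tab$pilin_motif, "PILIN", pseudocount, background),
    ebox  = buildPssm(tab$ebox, "EBOX", pseudocount, background)
  )
}

# score every window of `protein` against `pssm`; windows containing a
# non-standard residue (X, internal stop, ...) score NA and never match
pssmWindowScores <- function(protein, pssm) {
  aa <- strsplit(protein, "")[[1]]
  L <- length(aa)
  w <- pssm@width
  if (L < w) return(numeric(0))
  idx <- match(aa, AMINO_ACIDS)           # NA for non-standard residues
  nwin <- L - w + 1L
  sc <- numeric(nwin)
  for (p in seq_len(w))
    sc <- sc + pssm@scores[cbind(idx[p:(p + nwin - 1L)], p)]
  sc
}

# motif-kind-specific conserved-residue check
motifAnchorOk <- function(kind, seq) {
  aa <- strsplit(seq, "")[[1]]
  switch(kind,
    CWSS  = identical(aa[4:5], c("T", "G")),
    PILIN = aa[length(aa)] == "K",
    EBOX  = aa[5] == "E",
    TRUE)
}

#' Scan a protein with a motif PSSM
#'
#' Every eligible window is scored; windows containing a non-standard
#' residue (including \code{X} and internal-stop \code{*}) never match.
#' Hits at or above the PSSM threshold are returned sorted by
#' descending score, ties broken by smaller start.
#'
#' @param protein amino-acid string.
#' @param pssm a \code{\linkS4class{MotifPSSM}}.
#' @param region_constraint optional \code{c(min_start, max_start)}
#'   limiting eligible 1-based window starts.
#' @param threshold override of the PSSM threshold.
#' @return data.frame with columns \code{kind}, \code{start},
#'   \code{end}, \code{matched_seq}, \code{score}, \code{anchor_ok};
#'   zero rows when nothing scores above threshold (a protein shorter
#'   than the motif yields zero rows, not an error).
#' @export
scanPssm <- function(protein, pssm, region_constraint = NULL,
                     threshold = scoreThreshold(pssm)) {
  protein <- toupper(protein)
  sc <- pssmWindowScores(protein, pssm)
  empty <- data.frame(kind = character(), start = integer(),
                      end = integer(), matched_seq = character(),
                      score = numeric(), anchor_ok = logical(),
                      stringsAsFactors = FALSE)
  if (!length(sc)) return(empty)
  starts <- seq_along(sc)
  keep <- !is.na(sc) & sc >= threshold
  if (!is.null(region_constraint)) {
    keep <- keep & starts >= region_constraint[1] &
      starts <= region_constraint[2]
  }
  if (!any(keep)) return(empty)
  starts <- starts[keep]
  sc <- sc[keep]
  ord <- order(-sc, starts)
  starts <- starts[ord]; sc <- sc[ord]
  seqs <- substring(protein, starts, starts + pssm@width - 1L)
  data.frame(
    kind = pssm@kind, start = starts,
    end = starts + pssm@width - 1L, matched_seq = seqs, score = sc,
    anchor_ok = vapply(seqs, motifAnchorOk, logical(1),
                       kind = pssm@kind, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Detect the C-terminal cell wall sorting signal (LPxTG)
#'
#' Returns the best CWSS hit whose start lies within the final
#' \code{c_term_window} residues and whose positions 1, 2, 4, 5 are the
#' hard LPxTG core (position 3 is free), or \code{NULL}.
#'
#' @param protein amino-acid string.
#' @param pssm the CWSS PSSM (default: trained on packaged instances).
#' @param c_term_window size of the C-terminal search window in
#'   residues, default 50.
#' @return one-row hit data.frame (as \code{\link{scanPssm}}) or
#'   \code{NULL}.
#' @export
detectCwss <- function(protein, pssm = defaultPssms()$cwss,
                       c_term_window = 50) {
  L <- nchar(protein)
  lo <- max(1L, L - as.integer(c_term_window) + 1L)
  # the exact LPxTG core plus the positional constraint do the
  # filtering here; the PSSM score only ranks candidate windows, so
  # an unusual x position (absent from the training set) still counts
  hits <- scanPssm(protein, pssm, region_constraint = c(lo, L),
                   threshold = -Inf)
  if (!nrow(hits)) return(NULL)
  core <- substring(hits$matched_seq, 1, 2) == "LP" &
    substring(hits$matched_seq, 4, 5) == "TG"
  hits <- hits[core, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  hits[1, , drop = FALSE]
}

#' Heuristic Sec secretion-signal detector
#'
#' A protein is called Sec-positive when (a) the first 7 residues
#' contain at least one K or R (positively charged n-region) and (b)
#' some window of at least \code{min_window} residues inside the first
#' \code{n_term} residues has mean Kyte-Doolittle hydropathy of at
#' least \code{min_hydropathy} (hydrophobic h-region).  This is a
#' transparent approximation, not a trained signal-peptide predictor.
#'
#' @param protein amino-acid string.
#' @param n_term search depth from the N terminus, default 45.
#' @param min_window minimum hydrophobic window, default 8.
#' @param min_hydropathy mean Kyte-Doolittle cutoff, default 1.5.
#' @return logical.
#' @export
detectSecSignal <- function(protein, n_term = 45, min_window = 8,
                            min_hydropathy = 1.5) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (!length(aa)) return(FALSE)
  if (!any(aa[seq_len(min(7L, length(aa)))] %in% c("K", "R")))
    return(FALSE)
  head_aa <- aa[seq_len(min(n_term, length(aa)))]
  kd <- unname(KD_HYDROPATHY[head_aa])
  kd[is.na(kd)] <- 0
  n <- length(kd)
  if (n < min_window) return(FALSE)
  cs <- c(0, cumsum(kd))
  for (len in min_window:n) {
    means <- (cs[(len + 1):(n + 1)] - cs[1:(n - len + 1)]) / len
    if (any(means >= min_hydropathy)) return(TRUE)
  }
  FALSE
}

#' Class C sortase candidate check
#'
#' A gene passes when its product annotation mentions a sortase, or
#' when its protein carries the catalytic T-L-x-T-C motif at a
#' plausible sortase length (200-550 residues).  Final class C versus
#' class A assignment is contextual: sortases inside an assembled pilus
#' locus are class C candidates, isolated ones class A candidates (see
#' \code{\link{findLoci}}).
#'
#' @param protein amino-acid string.
#' @param product free-text product annotation (may be empty).
#' @param min_len,max_len protein length bounds for the motif branch.
#' @return logical.
#' @export
detectSortaseC <- function(protein, product = "", min_len = 200,
                           max_len = 550) {
  if (length(product) && !is.na(product) &&
      grepl("sortase", product, ignore.case = TRUE))
    return(TRUE)
  L <- nchar(protein)
  L >= min_len && L <= max_len && grepl("TL.TC", protein)
}

#' Classify genes into pilin/sortase roles
#'
#' Role grammar: a gene matching \code{\link{detectSortaseC}} is
#' \code{SORTASE_C} regardless of pilin hits.  A \code{MAJOR_PILIN}
#' needs a C-terminal CWSS, pilin-motif and E-box hits above threshold,
#' and a Sec signal.  A \code{MINOR_PILIN} needs the CWSS and Sec
#' signal without the full major set.  Everything else is \code{NONE}.
#'
#' @param genes \code{GRanges} from \code{\link{readGff3}} (or any
#'   object with \code{gene_id}, \code{product}, \code{protein},
#'   \code{cds} metadata columns).
#' @param pssms list as returned by \code{\link{defaultPssms}}.
#' @param c_term_window CWSS C-terminal window, default 50.
#' @param min_run homopolymer run length for the pseudogene flag,
#'   default 8.
#' @return \code{DataFrame} with one row per gene: \code{gene_id},
#'   \code{role}, \code{sec_signal}, \code{pseudogene},
#'   \code{cwss_score}, \code{pilin_score}, \code{ebox_score}.
#' @export
classifyPilins <- function(genes, pssms = defaultPssms(),
                           c_term_window = 50, min_run = 8) {
  mc <- S4Vectors::mcols(genes)
  n <- length(genes)
  role <- rep("NONE", n)
  sec <- pseud <- logical(n)
  cwss_s <- pilin_s <- ebox_s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    prot <- mc$protein[i]
    prod <- mc$product[i]
    sec[i] <- detectSecSignal(prot)
    cw <- detectCwss(prot, pssms$cwss, c_term_window)
    ph <- scanPssm(prot, pssms$pilin)
    eh <- scanPssm(prot, pssms$ebox)
    if (!is.null(cw)) cwss_s[i] <- cw$score
    if (nrow(ph)) pilin_s[i] <- ph$score[1]
    if (nrow(eh)) ebox_s[i] <- eh$score[1]
    pseud[i] <- flagPseudogeneFrameshift(
      mc$cds[i], product = prod, protein = prot, min_run = min_run)$flag
    if (detectSortaseC(prot, prod)) {
      role[i] <- "SORTASE_C"
    } else if (!is.null(cw) && sec[i]) {
      role[i] <- if (nrow(ph) && nrow(eh)) "MAJOR_PILIN" else "MINOR_PILIN"
    }
  }
  S4Vectors::DataFrame(
    gene_id = mc$gene_id, role = role, sec_signal = sec,
    pseudogene = pseud, cwss_score = cwss_s, pilin_score = pilin_s,
    ebox_score = ebox_s)
}
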