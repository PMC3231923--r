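#' MotifPSSM: position-specific scoring matrix for a pilin hallmark motif
#'
#' Log-odds matrix over the 20 standard amino acids, trained on the
#' packaged motif instances (see \code{\link{pilinMotifTable}}) or on
#' user-supplied instances via \code{\link{buildPssm}}.  Column score for
#' amino acid \eqn{a} at position \eqn{p} is
#' \eqn{\ln(((n_{ap}+\alpha)/(N+20\alpha))/b)} with pseudocount
#' \eqn{\alpha} and background frequency \eqn{b}.  The reporting
#' threshold defaults to the minimum self-score of the training
#' instances, so no training instance is ever missed.
#'
#' @slot kind one of \code{"CWSS"}, \code{"PILIN"}, \code{"EBOX"} (or a
#'   user-chosen label).
#' @slot width motif width in residues.
#' @slot scores 20 x width numeric matrix, rows named by amino acid.
#' @slot threshold minimum total score for a reportable hit.
#' @slot instances character vector of training instances.
#' @slot pseudocount pseudocount used during training.
#' @slot background background amino-acid frequency used during training.
#' @exportClass MotifPSSM
setClass("MotifPSSM",
  representation(
    kind = "character",
    width = "integer",
    scores = "matrix",
    threshold = "numeric",
    instances = "character",
    pseudocount = "numeric",
    background = "numeric"
  )
)

setValidity("MotifPSSM", function(object) {
  msg <- NULL
  if (length(object@kind) != 1L) msg <- c(msg, "kind must be length 1")
  if (length(object@width) != 1L || object@width < 1L)
    msg <- c(msg, "width must be a positive integer")
  if (!identical(rownames(object@scores), AMINO_ACIDS))
    msg <- c(msg, "scores rows must be the 20 standard amino acids")
  if (ncol(object@scores) != object@width)
    msg <- c(msg, "scores must have one column per motif position")
  if (any(nchar(object@instances) != object@width))
    msg <- c(msg, "all training instances must have the motif width")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a finite scalar")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn MotifPSSM motif kind label.
#' @param x,object a \code{MotifPSSM}.
#' @export
setGeneric("motifKind", function(x) standardGeneric("motifKind"))

#' @export
setMethod("motifKind", "MotifPSSM", function(x) x@kind)

#' @describeIn MotifPSSM motif width in residues.
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @export
setMethod("motifWidth", "MotifPSSM", function(x) x@width)

#' @describeIn MotifPSSM 20 x width log-odds score matrix.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @export
setMethod("scoreMatrix", "MotifPSSM", function(x) x@scores)

#' @describeIn MotifPSSM minimum reportable hit score.
#' @export
setGeneric("scoreThreshold", function(x) standardGeneric("scoreThreshold"))

#' @export
setMethod("scoreThreshold", "MotifPSSM", function(x) x@threshold)

setMethod("show", "MotifPSSM", function(object) {
  cat("MotifPSSM of kind", object@kind,
      "| width", object@width,
      "| trained on", length(object@instances), "instances\n")
  cat("  threshold:", format(object@threshold, digits = 4),
      "(min training self-score:",
      format(min(selfScores(object)), digits = 4), ")\n")
  cat("  consensus:", pssmConsensus(object), "\n")
})

#' PilusLocus: an assembled candidate pilus gene cluster
#'
#' Ordered same-neighbourhood genes classified as pilin subunits or
#' class C sortase, with the evidence layers attached by the pipeline.
#' A locus is \emph{complete} when it has exactly one major pilin, zero
#' to two minor pilins, exactly one sortase, and all members on one
#' strand; anything else is reported as \emph{partial}, never dropped.
#'
#' @slot locusId locus identifier, e.g. \code{"pil1"}.
#' @slot contigId contig of origin.
#' @slot members \code{DataFrame} with one row per member gene
#'   (\code{gene_id, role, start, end, strand, pseudogene}).
#' @slot start,end 1-based inclusive genomic span of the member genes.
#' @slot strand locus strand (\code{"+"}, \code{"-"}, or \code{"*"} for
#'   mixed-strand partial chains).
#' @slot completeness \code{"complete"} or \code{"partial"}.
#' @slot flankingMobileElements gene_ids of mobile-element annotations
#'   within the flank window.
#' @slot terminator a one-row \code{data.frame} (terminator hit) or
#'   \code{NULL}.
#' @slot hgt a named list of HGT metrics or \code{NULL}.
#' @exportClass PilusLocus
setClass("PilusLocus",
  representation(
    locusId = "character",
    contigId = "character",
    members = "DataFrame",
    start = "integer",
    end = "integer",
    strand = "character",
    completeness = "character",
    flankingMobileElements = "character",
    terminator = "ANY",
    hgt = "ANY"
  )
)

setValidity("PilusLocus", function(object) {
  msg <- NULL
  need <- c("gene_id", "role", "start", "end", "strand")
  if (!all(need %in% colnames(object@members)))
    msg <- c(msg, paste("members must have columns:",
                        paste(need, collapse = ", ")))
  if (!object@completeness %in% c("complete", "partial"))
    msg <- c(msg, "completeness must be 'complete' or 'partial'")
  if (length(object@start) == 1L && length(object@end) == 1L &&
      object@start > object@end)
    msg <- c(msg, "start must be <= end")
  if (object@completeness == "complete") {
    roles <- object@members$role
    if (sum(roles == "MAJOR_PILIN") != 1L)
      msg <- c(msg, "complete locus needs exactly one MAJOR_PILIN")
    if (sum(roles == "MINOR_PILIN") > 2L)
      msg <- c(msg, "complete locus allows at most two MINOR_PILIN")
    if (sum(roles == "SORTASE_C") != 1L)
      msg <- c(msg, "complete locus needs exactly one SORTASE_C")
    if (length(unique(object@members$strand)) != 1L)
      msg <- c(msg, "complete locus members must share one strand")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PilusLocus locus identifier.
#' @param x,object a \code{PilusLocus}.
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @export
setMethod("locusId", "PilusLocus", function(x) x@locusId)

#' @describeIn PilusLocus member gene table (\code{DataFrame}).
#' @export
setGeneric("locusMembers", function(x) standardGeneric("locusMembers"))

#' @export
setMethod("locusMembers", "PilusLocus", function(x) x@members)

#' @describeIn PilusLocus completeness label.
#' @export
setGeneric("locusCompleteness", function(x) standardGeneric("locusCompleteness"))

#' @export
setMethod("locusCompleteness", "PilusLocus", function(x) x@completeness)

#' @describeIn PilusLocus terminator hit (one-row data.frame) or NULL.
#' @export
setGeneric("locusTerminator", function(x) standardGeneric("locusTerminator"))

#' @export
setMethod("locusTerminator", "PilusLocus", function(x) x@terminator)

#' @describeIn PilusLocus HGT metrics list or NULL.
#' @export
setGeneric("locusHgt", function(x) standardGeneric("locusHgt"))

#' @export
setMethod("locusHgt", "PilusLocus", function(x) x@hgt)

setMethod("show", "PilusLocus", function(object) {
  cat("PilusLocus", object@locusId, "on", object@contigId,
      sprintf("%d..%d (%s), %s\n", object@start, object@end,
              object@strand, object@completeness))
  m <- object@members
  cat(sprintf("  %d members: %s\n", nrow(m),
              paste(sprintf("%s[%s]", m$gene_id, m$role), collapse = " ")))
  if (length(object@flankingMobileElements))
    cat("  mobile-element flanks:",
        paste(object@flankingMobileElements, collapse = ", "), "\n")
  if (!is.null(object@terminator))
    cat(sprintf("  terminator: dG %.1f kcal/mol, %d nt downstream\n",
                object@terminator$delta_g,
                object@terminator$distance_from_locus_end))
  if (!is.null(object@hgt))
    cat(sprintf("  HGT: gc_delta %+.1f pts, RSCU distance %.3f\n",
                object@hgt$gc_delta, object@hgt$rscu_distance))
})
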