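#' Validate a qPCR Ct table
#'
#' @param x data.frame with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{ct}.
#' @param reference_genes genes used for normalization (e.g. atpD,
#'   tufA, rpoB, ldh).
#' @param calibrator calibrator condition every fold change is
#'   expressed against, default \code{"glucose"}.
#' @return the data.frame with attributes \code{reference_genes} and
#'   \code{calibrator} set, invisibly classed \code{"CtTable"}.
#' @export
ctTable <- function(x, reference_genes, calibrator = "glucose") {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(x)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(x$ct)) || any(x$ct <= 0))
    stop("all Ct values must be finite and > 0")
  if (!length(reference_genes))
    stop("at least one reference gene is required")
  missing_ref <- setdiff(reference_genes, x$gene)
  if (length(missing_ref))
    stop("reference gene(s) absent from table: ",
         paste(missing_ref, collapse = ", "))
  no_cal <- setdiff(unique(x$gene),
                    unique(x$gene[x$condition == calibrator]))
  if (length(no_cal))
    stop("no calibrator ('", calibrator, "') rows for gene(s): ",
         paste(no_cal, collapse = ", "))
  attr(x, "reference_genes") <- reference_genes
  attr(x, "calibrator") <- calibrator
  class(x) <- c("CtTable", class(x))
  x
}

#' Read a Ct table from CSV plus a YAML design stanza
#'
#' The YAML file must name \code{reference_genes} and may set
#' \code{calibrator} (default \code{"glucose"}).
#'
#' @param csv path to CSV with columns gene, condition, replicate, ct.
#' @param yaml_path path to the YAML design file.
#' @return a validated \code{\link{ctTable}}.
#' @export
readCtTable <- function(csv, yaml_path) {
  x <- utils::read.csv(csv, stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(yaml_path)
  if (is.null(cfg$reference_genes))
    stop("YAML design must name reference_genes")
  ctTable(x, unlist(cfg$reference_genes),
          calibrator = if (is.null(cfg$calibrator)) "glucose"
                       else cfg$calibrator)
}

#' Relative quantity from mean Ct values
#'
#' \eqn{RQ = E^{(Ct_{calibrator} - Ct_{sample})}} with amplification
#' efficiency \eqn{E} (2 = perfect doubling per cycle).
#'
#' @param ct_calibrator_mean,ct_sample_mean mean Ct of the calibrator
#'   and sample conditions.
#' @param efficiency amplification efficiency in (1, 2], default 2.
#' @return relative quantity (1 = unchanged).
#' @examples
#' relativeQuantity(22, 20)        # 4
#' relativeQuantity(23, 20, 1.9)   # 1.9^3 = 6.859
#' @export
relativeQuantity <- function(ct_calibrator_mean, ct_sample_mean,
                             efficiency = 2) {
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must be in (1, 2]")
  efficiency^(ct_calibrator_mean - ct_sample_mean)
}

#' Multi-reference normalization factor
#'
#' Geometric mean of the reference-gene relative quantities in a
#' sample condition.
#'
#' @param reference_rqs numeric vector of reference-gene RQs.
#' @return the normalization factor.
#' @examples
#' normalizationFactor(c(2, 8))  # 4
#' @export
normalizationFactor <- function(reference_rqs) {
  if (!length(reference_rqs)) stop("need at least one reference RQ")
  if (any(reference_rqs <= 0)) stop("reference RQs must be positive")
  exp(mean(log(reference_rqs)))
}

#' Efficiency-corrected delta-delta-Ct fold changes
#'
#' Replicate Cts are averaged (arithmetic mean) per gene and
#' condition; per-condition target RQs are divided by the geometric
#' mean of the reference-gene RQs in that condition.  Folds are
#' relative to the calibrator condition (1 = unchanged).
#'
#' @param table a \code{\link{ctTable}}.
#' @param efficiency amplification efficiency, default 2.
#' @return data.frame with \code{gene_id}, \code{condition},
#'   \code{fold}, \code{n_replicates}, one row per target gene and
#'   non-calibrator condition.
#' @export
foldChange <- function(table, efficiency = 2) {
  refs <- attr(table, "reference_genes")
  cal <- attr(table, "calibrator")
  if (is.null(refs) || is.null(cal))
    stop("input must be a validated ctTable()")
  mean_ct <- stats::aggregate(ct ~ gene + condition, data = table, FUN = mean)
  n_rep <- stats::aggregate(ct ~ gene + condition, data = table, FUN = length)
  key <- function(g, c) paste(g, c, sep = "\r")
  ct_of <- stats::setNames(mean_ct$ct, key(mean_ct$gene, mean_ct$condition))
  rq <- function(g, cond) {
    cal_ct <- ct_of[[key(g, cal)]]
    if (is.null(cal_ct)) stop("no calibrator rows for gene ", g)
    relativeQuantity(cal_ct, ct_of[[key(g, cond)]], efficiency)
  }
  conds <- setdiff(unique(table$condition), cal)
  targets <- setdiff(unique(table$gene), refs)
  out <- list()
  for (cond in conds) {
    nf <- normalizationFactor(vapply(refs, function(g) {
      if (is.null(ct_of[[key(g, cond)]]))
        stop("reference gene ", g, " has no rows in condition ", cond)
      rq(g, cond)
    }, numeric(1)))
    for (g in targets) {
      if (is.null(ct_of[[key(g, cond)]])) next
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, condition = cond, fold = rq(g, cond) / nf,
        n_replicates = n_rep$ct[n_rep$gene == g & n_rep$condition == cond],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
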