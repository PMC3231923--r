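# Packaged RNA nearest-neighbor stacking parameters (dG37, kcal/mol)
# for Watson-Crick steps, after Xia et al. 1998.  A step is two
# adjacent pairs (p1, p2); pair "AU" means A on the top (coding)
# strand paired to U on the bottom.  Wobble G.U pairs are handled by a
# documented simplification: stack as the corresponding A-type pair
# plus +0.5 kcal/mol per wobble pair in the step.
RNA_NN_STACK <- local({
  base10 <- list(
    c("AU", "AU", -0.93), c("AU", "UA", -1.10), c("UA", "AU", -1.33),
    c("CG", "UA", -2.08), c("CG", "AU", -2.11), c("GC", "UA", -2.24),
    c("GC", "AU", -2.35), c("CG", "GC", -2.36), c("GC", "GC", -3.26),
    c("GC", "CG", -3.42))
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  tab <- new.env(parent = emptyenv())
  for (e in base10) {
    g <- as.numeric(e[3])
    assign(paste(e[1], e[2]), g, envir = tab)
    assign(paste(flip(e[2]), flip(e[1])), g, envir = tab)
  }
  tab
})

# Hairpin loop initiation dG37 (kcal/mol) by loop length, after the
# Turner rules for loops of 3-10 nt.
HAIRPIN_LOOP_INIT <- c(`3` = 5.4, `4` = 5.6, `5` = 5.7, `6` = 5.4,
                       `7` = 6.0, `8` = 5.5, `9` = 6.4, `10` = 6.5)

GU_WOBBLE_PENALTY <- 0.5

# free energy of one stacked step; pairs given as 2-char top+bottom
# RNA strings, wobble allowed
stackEnergy <- function(p1, p2) {
  toA <- function(p) switch(p, GU = "AU", UG = "UA", p)
  n_wobble <- sum(c(p1, p2) %in% c("GU", "UG"))
  key <- paste(toA(p1), toA(p2))
  g <- get0(key, envir = RNA_NN_STACK, ifnotfound = NA_real_)
  if (is.na(g)) stop("no stacking parameter for step ", p1, "/", p2)
  g + n_wobble * GU_WOBBLE_PENALTY
}

# is (a, b) a legal DNA-alphabet pair on the hairpin stem?
basePairs <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu)
    wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  else wc
}

#' Enumerate perfect inverted repeats (hairpin candidates)
#'
#' Exhaustively enumerates perfect hairpin stems: for every loop
#' placement with loop length between \code{loop_min} and
#' \code{loop_max}, the stem is extended outward while bases pair
#' (Watson-Crick, plus G.T wobble when \code{allow_gu}).  Only maximal
#' representations are kept: a candidate whose loop-terminal bases
#' themselves pair (and whose loop could legally shrink) is a
#' non-maximal duplicate of a longer stem and is dropped.  Stems with
#' internal mismatches or bulges are outside this model.
#'
#' @param seq nucleotide string (DNA alphabet; the coding strand).
#' @param stem_min minimum stem length in bp, default 8.
#' @param loop_min,loop_max loop length bounds in nt, defaults 3 and 10.
#' @param allow_gu allow G.T (G.U in RNA) wobble pairs, default TRUE.
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   hairpin span in \code{seq}), \code{stem_len}, \code{loop_len},
#'   \code{stem5}, \code{loop}, \code{stem3}.
#' @export
findInvertedRepeats <- function(seq, stem_min = 8, loop_min = 3,
                                loop_max = 10, allow_gu = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  out <- list()
  if (n >= 2 * stem_min + loop_min) {
    for (l in loop_min:loop_max) {
      for (s in seq_len(n - l + 1L)) {        # loop occupies s..s+l-1
        i <- s - 1L; j <- s + l
        stem <- 0L
        while (i >= 1L && j <= n && basePairs(b[i], b[j], allow_gu)) {
          stem <- stem + 1L; i <- i - 1L; j <- j + 1L
        }
        if (stem < stem_min) next
        # drop non-maximal duplicate of an inner-extended stem
        if (l - 2L >= loop_min && basePairs(b[s], b[s + l - 1L], allow_gu))
          next
        h_start <- s - stem; h_end <- s + l - 1L + stem
        out[[length(out) + 1L]] <- data.frame(
          start = h_start, end = h_end, stem_len = stem, loop_len = l,
          stem5 = substring(seq, h_start, s - 1L),
          loop = substring(seq, s, s + l - 1L),
          stem3 = substring(seq, s + l, h_end),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), loop_len = integer(),
                      stem5 = character(), loop = character(),
                      stem3 = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Hairpin free energy from the packaged nearest-neighbor table
#'
#' \eqn{\Delta G = \sum} stacked-pair terms over adjacent stem pairs
#' plus a loop-initiation term indexed by loop length.  The DNA input
#' is treated as its RNA transcript (T read as U).  Negative values
#' are more stable.
#'
#' @param candidates data.frame from \code{\link{findInvertedRepeats}}
#'   (any subset of rows).
#' @return numeric vector of free energies, kcal/mol.
#' @export
hairpinDeltaG <- function(candidates) {
  vapply(seq_len(nrow(candidates)), function(r) {
    stem5 <- chartr("T", "U", candidates$stem5[r])
    stem3 <- chartr("T", "U", candidates$stem3[r])
    loop_len <- candidates$loop_len[r]
    if (grepl("N", stem5, fixed = TRUE) || grepl("N", stem3, fixed = TRUE))
      stop("stem contains N; free energy undefined")
    k <- nchar(stem5)
    top <- strsplit(stem5, "")[[1]]                  # outermost -> innermost
    bot <- rev(strsplit(stem3, "")[[1]])             # pair partner order
    pairs <- paste0(top, bot)
    g <- 0
    if (k >= 2L)
      for (p in seq_len(k - 1L)) g <- g + stackEnergy(pairs[p], pairs[p + 1L])
    init <- HAIRPIN_LOOP_INIT[as.character(loop_len)]
    if (is.na(init)) stop("no loop-initiation term for loop of ",
                          loop_len, " nt")
    g + unname(init)
  }, numeric(1))
}

#' Call a rho-independent terminator downstream of a locus
#'
#' Searches the coding-strand sequence from the locus 3' end to
#' \code{window} nt downstream for the most stable hairpin at or below
#' \code{dg_cutoff}; ties are broken by smaller distance from the locus
#' end.  A locus at a contig edge is searched over the truncated
#' region and the result is marked \code{truncated}.
#'
#' @param locus a \code{\linkS4class{PilusLocus}} (or any object with
#'   \code{start}, \code{end}, \code{strand} slots).
#' @param contig contig sequence (string or \code{DNAString}).
#' @param window downstream search window in nt, default 150.
#' @param dg_cutoff maximum (least negative) free energy for a call,
#'   default -12 kcal/mol.
#' @param stem_min,loop_min,loop_max,allow_gu hairpin enumeration
#'   parameters, see \code{\link{findInvertedRepeats}}.
#' @return one-row data.frame (\code{start}, \code{end} genomic
#'   1-based, \code{stem_len}, \code{loop_len}, \code{delta_g},
#'   \code{distance_from_locus_end}, \code{truncated}) or \code{NULL}
#'   when no candidate passes the cutoff.
#' @export
callTerminator <- function(locus, contig, window = 150, dg_cutoff = -12,
                           stem_min = 8, loop_min = 3, loop_max = 10,
                           allow_gu = TRUE) {
  contig <- as.character(contig)
  n <- nchar(contig)
  if (locus@strand == "-") {
    from <- max(1L, locus@start - as.integer(window))
    to <- locus@start - 1L
    if (to < from) return(NULL)
    region <- revComp(substring(contig, from, to))
    truncated <- from == 1L && locus@start - window < 1L
  } else {
    from <- locus@end + 1L
    to <- min(n, locus@end + as.integer(window))
    if (to < from) return(NULL)
    region <- substring(contig, from, to)
    truncated <- to == n && locus@end + window > n
  }
  cand <- findInvertedRepeats(region, stem_min, loop_min, loop_max, allow_gu)
  if (!nrow(cand)) return(NULL)
  cand$delta_g <- hairpinDeltaG(cand)
  cand <- cand[cand$delta_g <= dg_cutoff, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand$distance_from_locus_end <- cand$start - 1L
  cand <- cand[order(cand$delta_g, cand$distance_from_locus_end), ,
               drop = FALSE]
  best <- cand[1, , drop = FALSE]
  if (locus@strand == "-") {
    g_end <- locus@start - best$start
    g_start <- locus@start - best$end
  } else {
    g_start <- locus@end + best$start
    g_end <- locus@end + best$end
  }
  data.frame(start = g_start, end = g_end, stem_len = best$stem_len,
             loop_len = best$loop_len, delta_g = best$delta_g,
             distance_from_locus_end = best$distance_from_locus_end,
             truncated = truncated, stringsAsFactors = FALSE,
             row.names = NULL)
}
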