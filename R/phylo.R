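# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# coerce an alignment (named character vector, DNAStringSet or
# character matrix) to a character matrix, rows = taxa
asMsaMatrix <- function(msa) {
  if (is.matrix(msa)) {
    m <- toupper(msa)
  } else {
    seqs <- as.character(msa)
    if (!is.null(names(msa))) names(seqs) <- names(msa)
    seqs <- stats::setNames(toupper(seqs), names(seqs))
    if (is.null(names(seqs)) || any(names(seqs) == ""))
      stop("alignment rows must be named by taxon")
    if (length(unique(nchar(seqs))) != 1L)
      stop("alignment rows must all have equal length")
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named by taxon")
  m
}

#' Read an aligned nucleotide FASTA
#'
#' @param path path to aligned FASTA (rows may contain \code{-} and
#'   \code{N}).
#' @return named \code{DNAStringSet}, all rows equal length.
#' @export
readMsa <- function(path) {
  msa <- readFasta(path, type = "DNA")
  if (length(unique(Biostrings::width(msa))) != 1L)
    stop("alignment rows differ in length: not an MSA")
  msa
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either row has a gap or ambiguity are excluded
#' (pairwise deletion).  With transition proportion \eqn{P} and
#' transversion proportion \eqn{Q} over the remaining sites,
#' \deqn{d = -\tfrac{1}{2}\ln\big((1-2P-Q)\sqrt{1-2Q}\big).}
#' The standard error follows Kimura's variance formula.
#'
#' @param row_i,row_j aligned sequence strings (equal length).
#' @param pair_label optional label used in saturation error messages.
#' @return list with \code{d}, \code{se}, \code{P}, \code{Q},
#'   \code{n_sites}.
#' @examples
#' k2pDistance("AAAA", "AGAA")$d  # -log(0.5)/2 = 0.34657
#' @export
k2pDistance <- function(row_i, row_j, pair_label = NULL) {
  a <- strsplit(toupper(as.character(row_i)), "")[[1]]
  b <- strsplit(toupper(as.character(row_j)), "")[[1]]
  if (length(a) != length(b)) stop("rows differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  lab <- if (is.null(pair_label)) "" else paste0(" (", pair_label, ")")
  if (n == 0L) stop("zero valid sites after pairwise deletion", lab)
  diff <- a != b
  purine <- function(x) x %in% c("A", "G")
  transition <- diff & (purine(a) == purine(b))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturated pair: K2P distance undefined", lab)
  d <- -0.5 * log(w1 * sqrt(w2))
  c1 <- 1 / w1; c2 <- 1 / w2; c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  list(d = d, se = sqrt(max(v, 0)), P = P, Q = Q, n_sites = n)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param msa alignment (named character vector, \code{DNAStringSet}
#'   or character matrix).
#' @return symmetric numeric matrix with zero diagonal, taxa as
#'   dimnames; attribute \code{n_sites} holds the per-pair valid-site
#'   counts.
#' @export
k2pDistanceMatrix <- function(msa) {
  m <- asMsaMatrix(msa)
  taxa <- rownames(m)
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  ns <- matrix(NA_integer_, n, n, dimnames = list(taxa, taxa))
  rows <- apply(m, 1L, paste, collapse = "")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k2pDistance(rows[i], rows[j],
                       pair_label = paste(taxa[i], "vs", taxa[j]))
      d[i, j] <- d[j, i] <- k$d
      ns[i, j] <- ns[j, i] <- k$n_sites
    }
  }
  attr(d, "n_sites") <- ns
  d
}

# quote a taxon label for newick if it contains metacharacters
newickLabel <- function(x) {
  if (grepl("[ ,():;'\\[\\]]", x))
    paste0("'", gsub("'", "''", x), "'") else x
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the rate-corrected Q criterion.  Ties
#' in Q are broken by the lexicographic order of the joined clusters'
#' smallest leaf labels, so the result is deterministic.  Negative
#' branch lengths are clamped to zero; the total clamped amount is
#' recorded in the \code{negative_branch_deficit} attribute.
#'
#' @param d symmetric distance matrix with zero diagonal and taxon
#'   dimnames (at least 3 taxa).
#' @return unrooted \code{ape::phylo} tree.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(d)  # branches 1, 1, 3
#' @export
njTree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  taxa <- rownames(d)
  if (is.null(taxa)) stop("distance matrix needs taxon dimnames")
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  D <- d
  frag <- vapply(taxa, newickLabel, character(1))   # newick fragments
  lab <- taxa                                       # smallest leaf label
  deficit <- 0
  clamp <- function(v) {
    if (v < 0) { deficit <<- deficit + abs(v); 0 } else v
  }
  r <- n
  while (r > 3L) {
    R <- rowSums(D)
    best <- NULL; bestQ <- Inf; bestKey <- NULL
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        q <- (r - 2) * D[i, j] - R[i] - R[j]
        key <- sort(c(lab[i], lab[j]))
        better <- q < bestQ - 1e-12 ||
          (abs(q - bestQ) <= 1e-12 &&
           (key[1] < bestKey[1] ||
            (key[1] == bestKey[1] && key[2] < bestKey[2])))
        if (is.null(best) || better) {
          best <- c(i, j); bestQ <- q; bestKey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    vi <- clamp(vi); vj <- clamp(vj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    newlab <- min(lab[i], lab[j])
    others <- setdiff(seq_len(r), c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], newd),
               c(newd, 0))
    frag <- c(frag[others], newfrag)
    lab <- c(lab[others], newlab)
    r <- r - 1L
  }
  va <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], va, frag[2], vb, frag[3], vc)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_branch_deficit") <- deficit
  tree
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Columns are resampled with replacement; each replicate is run
#' through the same K2P + NJ path as the reference tree.  The support
#' of each internal edge of the reference tree is the percentage of
#' successful replicates containing that bipartition.  Replicates with
#' a saturated pair are skipped (with a warning) and excluded from the
#' denominator.
#'
#' @param msa alignment as accepted by \code{\link{k2pDistanceMatrix}}.
#' @param reps bootstrap replicates, default 1000.
#' @param seed RNG seed (required; the caller's RNG state is restored).
#' @return list: \code{tree} (reference NJ tree with supports as
#'   \code{node.label}), \code{supports} (numeric, percent, one per
#'   internal node), \code{n_used}, \code{n_skipped}.
#' @export
bootstrapSupport <- function(msa, reps = 1000, seed) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (reps < 1L) stop("reps must be >= 1")
  m <- asMsaMatrix(msa)
  ref <- njTree(k2pDistanceMatrix(m))
  boots <- withSeed(seed, {
    lapply(seq_len(reps), function(rep) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tryCatch(njTree(k2pDistanceMatrix(m[, cols, drop = FALSE])),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(boots, is.null, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(n_skipped, " replicate(s) skipped (saturated pair)")
  boots <- boots[ok]
  if (!length(boots)) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- 100 * counts / length(boots)
  ref$node.label <- formatC(supports, format = "fg", digits = 4)
  list(tree = ref, supports = supports,
       n_used = length(boots), n_skipped = n_skipped)
}

#' Write a tree to newick
#'
#' Branch lengths are kept; bootstrap supports (if present) are
#' written as internal-node labels.  The output re-parses to the same
#' tree.
#'
#' @param tree an \code{ape::phylo} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0L)
    stop("not a non-empty phylo tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}
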