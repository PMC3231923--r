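# hand-built call/gene pairs exercise the chaining and composition rules

mkCallRow <- function(gene_id, role) {
  S4Vectors::DataFrame(gene_id = gene_id, role = role,
                       sec_signal = role %in% c("MAJOR_PILIN", "MINOR_PILIN"),
                       pseudogene = FALSE, cwss_score = NA_real_,
                       pilin_score = NA_real_, ebox_score = NA_real_)
}

chainFixture <- function(strands = c("+", "+", "+"), gaps = c(50, 50),
                         roles = c("MAJOR_PILIN", "MINOR_PILIN",
                                   "SORTASE_C")) {
  n <- length(roles)
  len <- 300
  start <- integer(n); start[1] <- 1000
  for (i in seq_len(n - 1))
    start[i + 1] <- start[i] + len + gaps[i]
  genes <- mkGenes("c1", start, start + len - 1, strands,
                   paste0("g", seq_len(n)), rep("x", n),
                   rep(paste0("ATG", strrep("GCT", 98), "TAA"), n))
  calls <- do.call(rbind, lapply(seq_len(n), function(i)
    mkCallRow(paste0("g", i), roles[i])))
  list(calls = calls, genes = genes)
}

test_that("a same-strand chain within the gap forms one complete locus", {
  fx <- chainFixture()
  res <- findLoci(fx$calls, fx$genes)
  expect_length(res$loci, 1)
  loc <- res$loci[[1]]
  expect_identical(locusCompleteness(loc), "complete")
  expect_identical(locusMembers(loc)$gene_id, c("g1", "g2", "g3"))
  expect_identical(res$classA, character(0))
})

test_that("opposite-strand sortase makes the locus partial, not absent", {
  fx <- chainFixture(strands = c("+", "+", "-"))
  res <- findLoci(fx$calls, fx$genes)
  expect_length(res$loci, 1)
  expect_identical(locusCompleteness(res$loci[[1]]), "partial")
})

test_that("gap beyond the limit splits the chain", {
  fx <- chainFixture(gaps = c(50, 501))
  res <- findLoci(fx$calls, fx$genes)
  # pilin pair stays a partial locus; the severed sortase is reported
  # as a housekeeping (class A) candidate
  expect_length(res$loci, 1)
  expect_identical(locusCompleteness(res$loci[[1]]), "partial")
  expect_identical(locusMembers(res$loci[[1]])$gene_id, c("g1", "g2"))
  expect_identical(res$classA, "g3")
  # a wider limit restores one complete locus
  res2 <- findLoci(fx$calls, fx$genes, max_intergenic_gap = 600)
  expect_length(res2$loci, 1)
  expect_identical(locusCompleteness(res2$loci[[1]]), "complete")
})

test_that("an isolated sortase is a class A candidate, not a locus", {
  fx <- chainFixture(roles = c("NONE", "NONE", "SORTASE_C"))
  res <- findLoci(fx$calls, fx$genes)
  expect_length(res$loci, 0)
  expect_identical(res$classA, "g3")
})

test_that("two majors in one chain violate composition -> partial", {
  fx <- chainFixture(roles = c("MAJOR_PILIN", "MAJOR_PILIN", "SORTASE_C"))
  res <- findLoci(fx$calls, fx$genes)
  expect_identical(locusCompleteness(res$loci[[1]]), "partial")
})

test_that("flank scanning respects the gene-count window", {
  # genes: t(ransposase) at positions 1 and 7; locus members 4-5
  n <- 7
  start <- as.integer(seq(1, by = 400, length.out = n))
  prods <- c("IS3 family transposase", "ABC transporter", "ribosomal protein",
             "major pilin subunit", "hypothetical protein",
             "elongation factor", "integrase")
  genes <- mkGenes("c1", start, start + 299, rep("+", n),
                   paste0("g", 1:n), prods,
                   rep(paste0("ATG", strrep("GCT", 98), "TAA"), n))
  members <- S4Vectors::DataFrame(
    gene_id = c("g4", "g5"), role = c("MAJOR_PILIN", "SORTASE_C"),
    start = start[4:5], end = start[4:5] + 299L, strand = c("+", "+"),
    pseudogene = c(FALSE, FALSE))
  locus <- new("PilusLocus", locusId = "pil1", contigId = "c1",
               members = members, start = start[4], end = start[5] + 299L,
               strand = "+", completeness = "complete",
               flankingMobileElements = character(),
               terminator = NULL, hgt = NULL)
  # transposase (g1) is 3 genes upstream, integrase (g7) 2 downstream
  expect_identical(detectFlankingMobileElements(locus, genes, n_flank = 2),
                   "g7")
  expect_setequal(detectFlankingMobileElements(locus, genes, n_flank = 3),
                  c("g1", "g7"))
  # neutral products nearby are never reported
  expect_false("g2" %in% detectFlankingMobileElements(locus, genes, 3))
})

test_that("slippage pseudogene flag needs a long run plus evidence", {
  # 9-G run starting at CDS position 4, internal stop at codon 5
  cds <- paste0("ATT", strrep("G", 9), "TAAAAATAA")
  res <- flagPseudogeneFrameshift(cds)
  expect_true(res$flag)
  expect_identical(res$base, "G")
  expect_identical(res$start, 4L)
  expect_identical(res$length, 9L)
  expect_true("internal_stop" %in% res$evidence)
  # run of 7 is below threshold even with an internal stop
  expect_false(flagPseudogeneFrameshift(
    paste0("ATT", strrep("G", 7), "TATAAAAATAA"))$flag)
  # long run without internal stop or pilin annotation: no flag
  clean <- paste0("ATG", strrep("G", 9), "AAATAA")
  expect_false(flagPseudogeneFrameshift(clean)$flag)
  # ... but a pilin-annotated product is accepted as evidence
  expect_true(flagPseudogeneFrameshift(clean, product = "fimbrial subunit")$flag)
})

test_that("planted loci are recovered exactly, with flanks and roles", {
  for (s in 1:3) {
    g <- generateGenome(n_genes = 40, seed = s)
    g <- plantLocus(g, locusSpec(n_minor = (s %% 3)), seed = 100 + s)
    res <- annotateGenome(g$contigs, g$genes)
    expect_length(res$loci, 1)
    loc <- res$loci[[1]]
    truth <- g$truth$loci[[1]]
    expect_identical(locusCompleteness(loc), "complete")
    expect_identical(locusMembers(loc)$gene_id, truth$members$gene_id)
    expect_identical(locusMembers(loc)$role, truth$members$role)
    expect_setequal(loc@flankingMobileElements, truth$transposase_flanks)
  }
})

test_that("locus calling is invariant under contig reverse complement", {
  g <- generateGenome(n_genes = 40, seed = 21)
  g <- plantLocus(g, locusSpec(), seed = 22)
  fwd <- annotateGenome(g$contigs, g$genes)
  rc <- revCompGenome(g)
  rev <- annotateGenome(rc$contigs, rc$genes)
  expect_length(rev$loci, length(fwd$loci))
  floc <- fwd$loci[[1]]; rloc <- rev$loci[[1]]
  expect_setequal(locusMembers(rloc)$gene_id, locusMembers(floc)$gene_id)
  expect_identical(rloc@strand, "-")
  # coordinates mirror: start' = L - end + 1
  expect_identical(rloc@start, rc$L - floc@end + 1L)
  expect_identical(rloc@end, rc$L - floc@start + 1L)
})

test_that("pseudogene flag fires on the planted gene only", {
  g <- generateGenome(n_genes = 40, seed = 33)
  g <- plantLocus(g, locusSpec(plant_slippage_pseudogene = TRUE), seed = 34)
  calls <- classifyPilins(g$genes)
  flagged <- calls$gene_id[calls$pseudogene]
  expect_identical(flagged, g$truth$loci[[1]]$pseudogene)
})
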