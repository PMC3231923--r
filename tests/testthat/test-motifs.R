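test_that("packaged motif instances have the published widths and anchors", {
  tab <- pilinMotifTable()
  expect_identical(nrow(tab), 16L)
  expect_true(all(nchar(tab$cwss) == 6))
  expect_true(all(nchar(tab$pilin_motif) == 10))
  expect_true(all(nchar(tab$ebox) == 12))
  # LPxTG hard core in every CWSS instance
  expect_true(all(substr(tab$cwss, 1, 2) == "LP"))
  expect_true(all(substr(tab$cwss, 4, 5) == "TG"))
  # glutamic acid at E-box position 5 in every instance
  expect_true(all(substr(tab$ebox, 5, 5) == "E"))
  # terminal lysine of the pilin motif is conserved in 15/16: one
  # published instance ends in T, which is why it is a soft anchor
  expect_identical(sum(substr(tab$pilin_motif, 10, 10) == "K"), 15L)
})

test_that("PSSM column scores follow the stated log-odds formula", {
  p <- defaultPssms()$cwss
  # position 1 is L in all 16 instances: ln((17/36) * 20)
  expect_equal(unname(scoreMatrix(p)["L", 1]),
               log((16 + 1) / (16 + 20) * 20),
               tolerance = 1e-12)
  expect_equal(unname(scoreMatrix(p)["L", 1]), 2.2455, tolerance = 1e-4)
  # zero observations: ln((1/36) * 20)
  expect_equal(unname(scoreMatrix(p)["W", 1]), log(1 / 36 * 20),
               tolerance = 1e-12)
  expect_equal(unname(scoreMatrix(p)["W", 1]), -0.588, tolerance = 1e-3)
  # threshold never exceeds any training self-score
  for (q in defaultPssms()) {
    self <- vapply(strsplit(q@instances, ""), function(aa)
      sum(scoreMatrix(q)[cbind(match(aa, rownames(scoreMatrix(q))),
                               seq_along(aa))]), numeric(1))
    expect_true(all(self >= scoreThreshold(q)))
  }
})

test_that("PSSM building validates input and frequencies scale with N", {
  expect_error(buildPssm(c("AAAA", "AAA")), "ragged")
  expect_error(buildPssm(c("AAAB", "AAAA")), "non-standard")
  expect_error(buildPssm("AAAA"), "at least 2")
  # with no pseudocount, duplicating the training set changes nothing
  ins <- c("LPKTGA", "LPLTGG")
  a <- buildPssm(ins, pseudocount = 0.5)
  b <- buildPssm(rep(ins, 2), pseudocount = 1)  # alpha scaled with N
  expect_equal(scoreMatrix(a), scoreMatrix(b), tolerance = 1e-12)
})

test_that("scanning recovers a published pilin motif in padded context", {
  # Table instance of ORF 1707
  prot <- paste0(strrep("A", 20), "VYSSGSIDMK", strrep("A", 20))
  hits <- scanPssm(prot, defaultPssms()$pilin)
  expect_gt(nrow(hits), 0)
  expect_identical(hits$start[1], 21L)
  expect_identical(hits$matched_seq[1], "VYSSGSIDMK")
  expect_true(hits$anchor_ok[1])
})

test_that("dissimilar and short proteins yield no hits, not errors", {
  expect_identical(nrow(scanPssm(strrep("G", 100), defaultPssms()$pilin)), 0L)
  expect_identical(nrow(scanPssm("AC", defaultPssms()$pilin)), 0L)
})

test_that("scan agrees with a brute-force window scorer", {
  set.seed(31)
  pssms <- defaultPssms()
  for (rep in 1:5) {
    prot <- paste(sample(rownames(scoreMatrix(pssms$cwss)), 60,
                         replace = TRUE), collapse = "")
    for (p in pssms) {
      want <- bruteForceWindowScores(prot, p)
      got <- scanPssm(prot, p, threshold = -Inf)
      expect_identical(nrow(got), length(want))
      expect_equal(got$score[order(got$start)], unname(want),
                   tolerance = 1e-12)
    }
  }
})

test_that("windows crossing non-standard residues never match", {
  p <- defaultPssms()$cwss
  prot <- paste0(strrep("A", 10), "LPKXGA", strrep("A", 10))
  hits <- scanPssm(prot, p, threshold = -Inf)
  expect_false(any(hits$start %in% 9:14))  # windows overlapping the X
})

test_that("CWSS detection needs the C-terminal window and LPxTG core", {
  p <- defaultPssms()$cwss
  hit <- detectCwss(paste0(NEUTRAL_PROTEIN, "LPKTGA",
                           "LLVLLALLGASSTNRRK"), p)
  expect_false(is.null(hit))
  expect_identical(hit$matched_seq, "LPKTGA")
  # same motif at the N terminus of a long protein: fails the window
  expect_null(detectCwss(paste0("LPKTGA", strrep("D", 400)), p))
  # x position of the core is free
  hit2 <- detectCwss(paste0(NEUTRAL_PROTEIN, "LPATGA", "LLVLLAKRR"), p)
  expect_false(is.null(hit2))
  expect_identical(hit2$matched_seq, "LPATGA")
})

test_that("every packaged instance is recovered in neutral context", {
  tab <- pilinMotifTable()
  pssms <- defaultPssms()
  cases <- list(c("cwss", "cwss"), c("pilin_motif", "pilin"),
                c("ebox", "ebox"))
  for (cs in cases) {
    for (inst in tab[[cs[1]]]) {
      prot <- paste0(strrep("A", 30), inst, strrep("A", 30))
      hits <- scanPssm(prot, pssms[[cs[2]]])
      expect_gt(nrow(hits), 0)
      expect_identical(hits$start[1], 31L)
      expect_gte(hits$score[1], scoreThreshold(pssms[[cs[2]]]))
    }
  }
})

test_that("Sec signal heuristic follows its hydropathy definition", {
  expect_true(detectSecSignal(paste0("MKKRLLALLLAVLLGA", strrep("D", 300))))
  expect_false(detectSecSignal(strrep("D", 100)))
  # hydrophobic stretch too deep into the protein
  expect_false(detectSecSignal(paste0("MK", strrep("D", 58),
                                      strrep("L", 20), strrep("D", 100))))
  # no positive charge in the first 7 residues
  expect_false(detectSecSignal(paste0("MDDDDDDD", strrep("L", 12),
                                      strrep("D", 100))))
  # hand check: window of LLALLLAVLL has mean KD (7*3.8+1.8+4.2+1.8)/10
  # = 3.44 >= 1.5, so the example above must pass on that window alone
  expect_true(detectSecSignal("MKKRLLALLLAVLL"))
})

test_that("sortase check uses product keyword or TLxTC at sane length", {
  expect_true(detectSortaseC(strrep("D", 100), "sortase family protein"))
  prot <- paste0("M", strrep("D", 150), "TLVTC", strrep("D", 144))
  expect_true(detectSortaseC(prot, "hypothetical"))
  expect_false(detectSortaseC(paste0("M", strrep("D", 50), "TLVTC",
                                     strrep("D", 44)), "hypothetical"))
  expect_false(detectSortaseC(strrep("D", 100), "hypothetical"))
  # regex oracle: the motif is T-L-any-T-C
  expect_true(grepl("TL.TC", prot))
})

test_that("role classification matches generator ground truth", {
  g <- generateGenome(n_genes = 30, seed = 5)
  g <- plantLocus(g, locusSpec(n_minor = 2), seed = 6)
  calls <- classifyPilins(g$genes)
  truth <- g$truth$loci[[1]]$members
  for (i in seq_len(nrow(truth))) {
    expect_identical(
      calls$role[calls$gene_id == truth$gene_id[i]], truth$role[i])
  }
  # background genes stay NONE
  bg <- !grepl("^PIL", calls$gene_id)
  expect_true(all(calls$role[bg] == "NONE"))
})

test_that("classification is invariant to gene order and contig name", {
  g <- generateGenome(n_genes = 20, seed = 9)
  g <- plantLocus(g, locusSpec(), seed = 10)
  calls1 <- classifyPilins(g$genes)
  perm <- rev(seq_along(g$genes))
  genes2 <- g$genes[perm]
  calls2 <- classifyPilins(genes2)
  expect_identical(calls2$role,
                   calls1$role[match(calls2$gene_id, calls1$gene_id)])
})
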