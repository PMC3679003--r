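# Global alignment, reference-position mapping, opsin annotation, motifs.

test_that("self-alignment reproduces the diagonal substitution score", {
  s <- "MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSMLAAYMFLLIML"
  aln <- globalAlign(s, s)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- get("BLOSUM62", envir = e)
  letters <- strsplit(s, "")[[1]]
  expect_equal(aln$score, sum(sm[cbind(letters, letters)]))
  expect_equal(aln$alignedQuery, s)
  expect_equal(aln$alignedReference, s)
})

test_that("a single deletion produces one reference-track gap", {
  aln <- globalAlign("ACDEFG", "ACEFG")
  expect_equal(nchar(aln$alignedQuery), 6)
  expect_equal(aln$alignedQuery, "ACDEFG")
  expect_equal(lengths(regmatches(aln$alignedReference,
                                  gregexpr("-", aln$alignedReference))), 1)
})

test_that("alignment scores equal an independent quadratic-space checker", {
  set.seed(61)
  for (i in 1:25) {
    q <- randomPeptide(60); r <- randomPeptide(60)
    expect_equal(globalAlign(q, r)$score, slowAlignScore(q, r))
  }
})

test_that("alignment scores equal the reference library implementation", {
  set.seed(62)
  for (i in 1:25) {
    q <- randomPeptide(60); r <- randomPeptide(55)
    ref <- Biostrings::pairwiseAlignment(
      q, r, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(globalAlign(q, r)$score, ref)
  }
})

test_that("reference-position mapping handles identity, offsets, deletions", {
  ref <- as.character(bovineRhodopsin()[[1]])
  # identity: position 296 maps to 296
  aln <- globalAlign(ref, ref)
  expect_equal(mapReferencePosition(aln, 296), 296)
  # N-terminal extension shifts the map by its length
  ext <- paste0("GGGGG", ref)
  expect_equal(mapReferencePosition(globalAlign(ext, ref), 296), 301)
  # deleting the homolog yields the gap sentinel
  del <- paste0(substr(ref, 1, 295), substr(ref, 297, nchar(ref)))
  expect_true(is.na(mapReferencePosition(globalAlign(del, ref), 296)))
  expect_error(mapReferencePosition(aln, 400), "out of range")
  # injective over non-gap columns
  m <- mapReferencePosition(aln, 1:348)
  expect_false(anyDuplicated(m[!is.na(m)]) > 0)
})

test_that("annotation reports Schiff-base and counterion residues", {
  ann <- annotateOpsin(bovineRhodopsin())
  expect_equal(ann@posSchiff, 296L)
  expect_equal(ann@resSchiff, "K")
  expect_true(ann@hasSchiffLysine)
  expect_equal(ann@res113, "E")
  expect_equal(ann@res181, "E")
  # K296A mutant: position still maps, lysine flag drops
  ref <- as.character(bovineRhodopsin()[[1]])
  mut <- ref
  substr(mut, 296, 296) <- "A"
  annMut <- annotateOpsin(mut, id = "k296a")
  expect_equal(annMut@posSchiff, 296L)
  expect_equal(annMut@resSchiff, "A")
  expect_false(annMut@hasSchiffLysine)
  # 10-residue insertion before position 100 shifts the map by 10
  ins <- paste0(substr(ref, 1, 99), "GGSGGSGGSG", substr(ref, 100, 348))
  annIns <- annotateOpsin(ins, id = "ins10")
  expect_equal(annIns@posSchiff, 306L)
  expect_equal(annIns@resSchiff, "K")
})

test_that("single-point substitutions never move the mapped positions", {
  ref <- as.character(bovineRhodopsin()[[1]])
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(63)
  for (i in 1:100) {
    pos <- sample(348, 1)
    mut <- ref
    substr(mut, pos, pos) <- sample(setdiff(aa, substr(ref, pos, pos)), 1)
    aln <- globalAlign(mut, ref)
    expect_equal(mapReferencePosition(aln, c(113, 181, 296)),
                 c(113L, 181L, 296L))
  }
})

test_that("motif scanning is confined to the C-terminal third", {
  ref <- bovineRhodopsin()
  # NPxxY is at 302-306 in the C-terminal third; a pattern matching the
  # N-terminal glycosylation region must not be reported
  ann <- annotateOpsin(ref, motifPatterns = c(npxxy = "NPx[IV]Y",
                                              nterm = "MNGTEG"))
  expect_equal(ann@motifHits$pattern, "npxxy")
  expect_equal(ann@motifHits$start, 302L)
  expect_equal(ann@motifHits$end, 306L)
  expect_error(scanMotifs("ACDEF", c(bad = "A(")), "pattern syntax")
})

test_that("annotation is invariant to the sequence id", {
  seqs <- bovineRhodopsin()
  a <- annotateOpsin(seqs, id = "one")
  b <- annotateOpsin(seqs, id = "completely different description")
  expect_equal(a@posSchiff, b@posSchiff)
  expect_equal(a@score, b@score)
})

test_that("nearest-reference ranking orders references by score", {
  ref <- as.character(bovineRhodopsin()[[1]])
  mut <- ref
  for (p in seq(5, 200, by = 10)) substr(mut, p, p) <- "A"
  refs <- c(identical = ref, mutated = mut)
  out <- nearestReference(ref, refs)
  expect_equal(out$id[1], "identical")
  expect_gt(out$score[1], out$score[2])
})

test_that("sequence validation enforces the residue alphabet", {
  expect_error(validateOpsinSequence("ACDEFB"), "invalid residue")
  expect_error(validateOpsinSequence("ACDEF"), "shorter")
  expect_equal(validateOpsinSequence(strrep("ACDEF", 12)),
               strrep("ACDEF", 12))
})
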