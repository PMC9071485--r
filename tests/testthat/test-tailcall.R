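test_that("3' soft clips are extracted in transcript orientation", {
  body <- strrep("ACGT", 5)
  expect_identical(
    extractSoftClipTail(paste0(body, "AAAAA"), "20M5S", FALSE), "AAAAA")
  # reverse strand: stored sequence is the reverse complement, tail is the
  # leading clip read back through reverse complement
  expect_identical(
    extractSoftClipTail(paste0("TTTTT", body), "5S20M", TRUE), "AAAAA")
  # no soft clip at all
  expect_identical(extractSoftClipTail(body, "20M", FALSE), "")
  # leading clip on a forward read is not a 3' tail
  expect_identical(
    extractSoftClipTail(paste0("GGG", body), "3S20M", FALSE), "")
  # hard clip at the 3' end: sequence unavailable, flagged unusable
  expect_warning(
    res <- extractSoftClipTail(body, "20M4H", FALSE), "hard clip")
  expect_identical(res, "")
  expect_error(extractSoftClipTail(body, "20Q", FALSE), "malformed CIGAR")
  expect_error(extractSoftClipTail(body, "19M5S", FALSE), "query width")
})

test_that("A-tract extension moves the upstream A run and is idempotent", {
  expect_identical(extendATract("GCGAAA", "AAAAA"), "AAAAAAAA")
  expect_identical(extendATract("GACT", "AAAA"), "AAAA")
  expect_identical(extendATract("AAAA", "AA"), "AAAAAA")
  # N interrupts a run
  expect_identical(extendATract("GANAA", "AAA"), "AAAAA")
  # idempotence over a grid of suffix/tail combinations
  suffixes <- c("GCGAAA", "GACT", "AAAA", "TTTA", "GANAA", "")
  tails <- c("AAAA", "AAAAAAAAAA", "AAAATTTT")
  for (s in suffixes) for (tl in tails) {
    once <- extendATract(s, tl)
    # the donated suffix has had its A run removed, so a second pass with
    # the remaining suffix must change nothing
    remaining <- sub("A+$", "", s)
    expect_identical(extendATract(remaining, once), once)
  }
})

test_that("tail classification applies the quality rules in order", {
  expect_identical(classifyTail(strrep("A", 10), 10)$status, "ACCEPTED")
  expect_identical(classifyTail("AACGTGCTAAAA", 10)$status,
                   "REJECTED_LOW_A")
  # exactly 4 As in the first 8 bases passes ('less than 4' fails)
  expect_identical(classifyTail("AAAATTTT", 10)$status, "ACCEPTED")
  expect_identical(classifyTail("", 10)$status, "REJECTED_NO_CLIP")
  # short tails: rule applies to the first min(8, len) bases
  expect_identical(classifyTail("AAAA", 10)$status, "ACCEPTED")
  expect_identical(classifyTail("AAA", 10)$status, "REJECTED_LOW_A")
  # pass filter: >= 7 kept, < 7 filtered, NA passes never filtered
  expect_identical(classifyTail(strrep("A", 10), 7)$status, "ACCEPTED")
  expect_identical(classifyTail(strrep("A", 10), 6)$status,
                   "FILTERED_LOW_PASS")
  expect_identical(classifyTail(strrep("A", 10), NA_integer_)$status,
                   "ACCEPTED")
  expect_identical(
    classifyTail(strrep("A", 10), 6, passFilter = FALSE)$status,
    "ACCEPTED")
  # quality rejection takes precedence over the pass filter
  expect_identical(classifyTail("AAA", 2)$status, "REJECTED_LOW_A")
  # N counts as non-A
  expect_identical(classifyTail("AAANNNNN", 10)$status, "REJECTED_LOW_A")
  expect_error(classifyTail("AAAA$", 10), "A/C/G/T/N")
})

test_that("gene assignment is strand-aware with largest-overlap tie-break", {
  anno <- toyAnnotation()
  reads <- rbind(
    makeRead("inG1", strrep("ACGT", 50), "200M", FALSE, "chr1", 100L),
    # overlaps G1 (ends at 1000) by 50 nt and G2 (901-1300) by 300 nt
    makeRead("larger", strrep("ACGT", 75), "300M", FALSE, "chr1", 950L),
    # wrong strand for G3
    makeRead("wrongStrand", strrep("ACGT", 25), "100M", FALSE, "chr2", 10L),
    makeRead("onG3", strrep("ACGT", 25), "100M", TRUE, "chr2", 10L),
    makeRead("noRef", strrep("ACGT", 25), "100M", FALSE, "chr9", 10L))
  g <- assignToGene(reads, anno)
  expect_identical(g, c("G1", "G2", NA, "G3", NA))
})

test_that("equal-overlap ties resolve to the lexicographically first gene", {
  anno <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1L, 1L), width = 500L),
    strand = "+", gene_id = c("Gb", "Ga"))
  r <- makeRead("r1", strrep("ACGT", 25), "100M", FALSE, "chr1", 50L)
  expect_identical(assignToGene(r, anno), "Ga")
})

test_that("callTails is deterministic and strand-consistent", {
  body <- paste(rep(c("C", "G", "T", "A", "C"), 8), collapse = "")  # 40 nt
  tail <- strrep("A", 30)
  fwd <- makeRead("f", paste0(body, tail), "40M30S", FALSE, "chr1", 100L)
  revseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(body, tail))))
  rev <- makeRead("r", revseq, "30S40M", TRUE, "chr1", 100L)
  cf <- tailCalls(callTails(fwd))
  cr <- tailCalls(callTails(rev))
  expect_identical(cf$tail_seq, cr$tail_seq)
  expect_identical(cf$tail_len, cr$tail_len)
  expect_identical(cf$status, cr$status)
  # identical input, identical output
  expect_identical(tailCalls(callTails(fwd)), cf)
})

test_that("accepted tails are always at least 4 nt", {
  set.seed(11)
  tails <- vapply(1:200, function(i) {
    paste(sample(c("A", "A", "A", "C", "G", "T", "N"), sample(0:12, 1),
                 replace = TRUE), collapse = "")
  }, character(1))
  for (tl in tails) {
    res <- classifyTail(tl, passes = 10L)
    if (res$status == "ACCEPTED") {
      expect_gte(res$tail_len, 4L)
      first8 <- substr(tl, 1, 8)
      nA <- nchar(gsub("[^A]", "", first8))
      expect_gte(nA, 4L)
    }
  }
})

test_that("tail lengths match the brute-force clip-arithmetic oracle", {
  set.seed(42)
  rows <- list(); expected <- integer(0)
  for (i in 1:50) {
    bodyLen <- sample(20:60, 1)
    tailLen <- sample(0:40, 1)
    # body may end in As (exercises A-tract extension)
    body <- paste(sample(c("A", "C", "G", "T"), bodyLen, replace = TRUE),
                  collapse = "")
    tail <- strrep("A", tailLen)
    isRev <- i %% 3 == 0
    lead5 <- sample(0:5, 1)  # 5' clip, must be ignored
    t5 <- paste(sample(c("C", "G", "T"), max(lead5, 1), replace = TRUE),
                collapse = "")
    t5 <- substr(t5, 1, lead5)
    tseq <- paste0(t5, body, tail)
    if (isRev) {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tseq)))
      cigar <- paste0(if (tailLen) paste0(tailLen, "S") else "",
                      bodyLen, "M",
                      if (lead5) paste0(lead5, "S") else "")
    } else {
      seq <- tseq
      cigar <- paste0(if (lead5) paste0(lead5, "S") else "",
                      bodyLen, "M",
                      if (tailLen) paste0(tailLen, "S") else "")
    }
    rows[[i]] <- makeRead(paste0("r", i), seq, cigar, isRev, "chr1", 100L)
    expected[i] <- oracleTailLength(seq, cigar, isRev)
  }
  reads <- do.call(rbind, rows)
  calls <- tailCalls(callTails(reads, passFilter = FALSE))
  expect_identical(calls$tail_len, expected)
})

test_that("gene summaries use the geometric mean and the transcript floor", {
  mk <- function(gene, lens) {
    data.frame(gene_id = gene, tail_len = lens,
               status = "ACCEPTED")
  }
  calls <- rbind(mk("Ga", rep(100, 10)),
                 mk("Gb", c(rep(10, 5), rep(1000, 5))),
                 mk("Gc", rep(50, 9)))
  s <- tailSummary(summarizeGeneTails(calls, minTranscripts = 10))
  expect_setequal(s$gene_id, c("Ga", "Gb"))  # Gc has only 9 transcripts
  expect_equal(s$geom_mean_len[s$gene_id == "Ga"], 100)
  expect_equal(s$geom_mean_len[s$gene_id == "Gb"], 100)  # exp(mean(log))
})

test_that("raising min_passes or min_transcripts never adds calls", {
  sim <- simulateTailedReads(tailSimConfig(nGenes = 20, readsPerGene = 30,
                                           seed = 7))
  nAcc <- function(mp) sum(tailCalls(callTails(
    sim$reads, sim$annotation, minPasses = mp))$status == "ACCEPTED")
  accepted <- vapply(c(1, 5, 10, 15, 20), nAcc, numeric(1))
  expect_true(all(diff(accepted) <= 0))

  calls <- callTails(sim$reads, sim$annotation)
  nSum <- vapply(c(1, 5, 10, 20), function(mt)
    nrow(tailSummary(summarizeGeneTails(calls, minTranscripts = mt))),
    numeric(1))
  expect_true(all(diff(nSum) <= 0))
})

test_that("two-condition comparison is correct on identity and scaling", {
  sim <- simulateTailedReads(tailSimConfig(nGenes = 15, readsPerGene = 40,
                                           errorRate = 0, noTailFrac = 0,
                                           seed = 5))
  calls <- callTails(sim$reads, sim$annotation, passFilter = FALSE)
  s <- summarizeGeneTails(calls)
  cmpId <- compareTailConditions(s, s, calls, calls)
  expect_equal(cmpId@median_A, cmpId@median_B)
  expect_equal(cmpId@per_gene$geom_mean_A, cmpId@per_gene$geom_mean_B)
  expect_equal(colSums(cmpId@bin_fractions), c(A = 1, B = 1))

  # doubling every tail length doubles the medians (geometric mean and
  # median are scale-equivariant)
  cc <- as.data.frame(tailCalls(calls))
  cc$tail_len <- cc$tail_len * 2L
  cc$tail_seq <- strrep("A", cc$tail_len)
  s2 <- summarizeGeneTails(cc)
  calls2 <- new("TailCallSet",
                calls = S4Vectors::DataFrame(cc),
                params = calls@params, audit = calls@audit)
  cmp2 <- compareTailConditions(s, s2, calls, calls2)
  expect_equal(cmp2@median_B, 2 * cmp2@median_A, tolerance = 1e-12)
})
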