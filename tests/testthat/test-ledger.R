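test_that("ledger records sizes that equal actual cardinalities", {
  led <- GeneSetLedger()
  addGeneSet(led, "A", c("a", "b", "c", "c"))  # deduplicated
  addGeneSet(led, "B", c("b", "c", "d"))
  inter <- recordIntersection(led, "AB", "A", "B")
  expect_setequal(inter, c("b", "c"))
  uni <- recordUnion(led, "AuB", "A", "B")
  expect_setequal(uni, c("a", "b", "c", "d"))
  excl <- recordExclusion(led, "AnotB", "A", "B")
  expect_setequal(excl, "a")
  tab <- ledgerTable(led)
  expect_equal(tab$size, unname(setSizes(led)[tab$name]))
})

test_that("degradation-dependent set records the fraction of the cluster", {
  led <- GeneSetLedger()
  addGeneSet(led, "ko_up", c("a", "b", "c"))
  addGeneSet(led, "degraded", c("b", "c", "d"))
  res <- dependentDegradationSet(led, "ko_up", "degraded")
  expect_setequal(res, c("b", "c"))
  detail <- ledgerTable(led)$detail[ledgerTable(led)$name ==
                                      "degradation_dependent"]
  expect_match(detail, "66.7%")
  # disjoint operands give the empty set, fraction 0
  addGeneSet(led, "other", c("x", "y"))
  res0 <- dependentDegradationSet(led, "other", "degraded", name = "none")
  expect_length(res0, 0)
})

test_that("the late-upregulated derivation builds disjoint categories", {
  led <- GeneSetLedger()
  up <- list(
    "6" = c("cont1", "cont2"),
    "12" = c("cont1", "cont2", "noise12"),
    "24" = c("cont1", "cont2", "both1", "only24a", "only24b"),
    "48" = c("cont1", "cont2", "both1", "only48a"))
  res <- deriveGrnLikeSet(led, up, escUp = c("only24b", "unrelated"))
  sizes <- setSizes(led)
  expect_equal(unname(sizes["continuous_up"]), 2L)
  expect_equal(unname(sizes["up_24h_and_48h"]), 1L)
  expect_equal(unname(sizes["up_24h_only"]), 2L)
  expect_equal(unname(sizes["up_48h_only"]), 1L)
  # disjoint union adds exactly; exclusion removes the ESC-up member
  expect_equal(unname(sizes["grn_like_union"]), 2L + 1L + 2L + 1L)
  expect_setequal(res, c("cont1", "cont2", "both1", "only24a", "only48a"))
  # with no ESC-up genes the final set equals the union
  led2 <- GeneSetLedger()
  res2 <- deriveGrnLikeSet(led2, up, escUp = character(0))
  expect_setequal(res2, geneSet(led2, "grn_like_union"))
})

test_that("category sizes 33+120+81+128 combine to a union of 362", {
  # synthetic disjoint categories with the published sizes: up sets built
  # so the categorisation yields exactly those cardinalities
  cont <- paste0("c", 1:33)
  both <- paste0("b", 1:120)
  o24 <- paste0("x", 1:81)
  o48 <- paste0("y", 1:128)
  up <- list("6" = cont, "12" = cont,
             "24" = c(cont, both, o24),
             "48" = c(cont, both, o48))
  led <- GeneSetLedger()
  deriveGrnLikeSet(led, up, escUp = character(0))
  sizes <- setSizes(led)
  expect_equal(unname(sizes[c("continuous_up", "up_24h_and_48h",
                              "up_24h_only", "up_48h_only")]),
               c(33L, 120L, 81L, 128L))
  expect_equal(unname(sizes["grn_like_union"]), 362L)
})

test_that("reference intersection recovers planted members", {
  led <- GeneSetLedger()
  derived <- paste0("g", 1:200)
  addGeneSet(led, "derived", derived)
  planted <- sample(derived, 40)
  reference <- c(planted, paste0("r", 1:60))
  res <- intersectWithReference(led, "derived", reference)
  expect_setequal(res, planted)
  expect_length(res, 40)
  # self-intersection is the identity
  res2 <- intersectWithReference(led, "derived", derived, name = "self")
  expect_setequal(res2, derived)
  expect_warning(intersectWithReference(led, "derived", character(0),
                                        name = "empty"), "empty reference")
})

test_that("ledger JSON round-trips the sets and the log", {
  led <- GeneSetLedger()
  addGeneSet(led, "A", c("a", "b"))
  addGeneSet(led, "B", "b")
  recordIntersection(led, "AB", "A", "B")
  path <- tempfile(fileext = ".json")
  writeLedgerJson(led, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$sets$AB$size, 1)
  expect_equal(obj$sets$AB$genes, "b")
  expect_equal(nrow(obj$log), 3)
})
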