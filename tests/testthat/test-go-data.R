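test_that("parse_obo maps stanzas to term records with is_a parents", {
  ont <- parse_obo(toy_obo_lines())
  expect_s3_class(ont, "go_ontology")
  expect_equal(nrow(ont), 7)
  expect_equal(ont$namespace[ont$term_id == "GO:0000001"], "BP")
  expect_equal(ont$namespace[ont$term_id == "GO:0000010"], "CC")
  expect_equal(ont$namespace[ont$term_id == "GO:0000011"], "MF")
  # child is_a parent is_a root
  expect_equal(ont$parents[[which(ont$term_id == "GO:0000003")]], "GO:0000002")
  expect_equal(ont$parents[[which(ont$term_id == "GO:0000002")]], "GO:0000001")
  expect_setequal(
    ont$parents[[which(ont$term_id == "GO:0000005")]],
    c("GO:0000002", "GO:0000004")
  )
  expect_equal(ont$definition[ont$term_id == "GO:0000001"], "The root process.")
})

test_that("parse_obo handles empty input, aliases, and malformed stanzas", {
  expect_equal(nrow(parse_obo(character())), 0)
  ont <- parse_obo(toy_obo_lines())
  expect_equal(resolve_term_id(ont, "GO:0000099"), "GO:0000005")
  expect_equal(resolve_term_id(ont, c("GO:0000001", "GO:9999999")),
    c("GO:0000001", NA))
  bad_ns <- c("[Term]", "id: GO:1", "namespace: made_up_ontology")
  expect_error(parse_obo(bad_ns), "namespace")
  bad_line <- c("[Term]", "id: GO:1", "this line has no tag")
  expect_error(parse_obo(bad_line), "line")
})

test_that("parse_gaf filters by evidence code and computes t0", {
  ont <- parse_obo(toy_obo_lines())
  rows <- c(
    "!gaf-version: 2.2",
    gaf_row("g1", "GO:0000002", evidence = "IEA"),
    gaf_row("g1", "GO:0000003", evidence = "EXP"),
    gaf_row("g2", "GO:0000002", evidence = "EXP"),
    gaf_row("g2", "GO:0000003", evidence = "EXP"),
    gaf_row("g2", "GO:0000005", evidence = "EXP"),
    gaf_row("g2", "GO:0000004", evidence = "ND"), # ND always dropped
    gaf_row("g3", "GO:0000004", evidence = "EXP", qualifier = "NOT"),
    gaf_row("g3", "GO:0000010", evidence = "EXP", aspect = "C")
  )
  corp <- parse_gaf(rows, ont, include_iea = FALSE)
  expect_equal(length(corp$annotations[["g1"]][["BP"]]), 1)
  corp_iea <- parse_gaf(rows, ont, include_iea = TRUE)
  expect_equal(length(corp_iea$annotations[["g1"]][["BP"]]), 2)
  # IEA+ annotation sets are supersets of IEA- sets, gene by gene
  for (g in corp$genes) {
    for (ns in c("BP", "CC", "MF")) {
      a_minus <- corp$terms[[ns]][corp$annotations[[g]][[ns]]]
      a_plus <- corp_iea$terms[[ns]][corp_iea$annotations[[g]][[ns]]]
      expect_true(all(a_minus %in% a_plus))
    }
  }
  # t0 = max annotation-set size; g2 has 3 BP terms after ND drop
  expect_equal(unname(corp$t0[["BP"]]), 3)
  # NOT-qualified row dropped: g3 keeps only its CC annotation
  expect_equal(length(corp$annotations[["g3"]][["BP"]]), 0)
  expect_equal(length(corp$annotations[["g3"]][["CC"]]), 1)
})

test_that("parse_gaf warns on unknown terms and errors on empty corpora", {
  ont <- parse_obo(toy_obo_lines())
  rows <- c(
    gaf_row("g1", "GO:7777777", evidence = "EXP"),
    gaf_row("g1", "GO:0000002", evidence = "EXP")
  )
  expect_warning(corp <- parse_gaf(rows, ont), "absent")
  expect_equal(length(corp$annotations[["g1"]][["BP"]]), 1)
  only_nd <- gaf_row("g1", "GO:0000002", evidence = "ND")
  expect_error(suppressWarnings(parse_gaf(only_nd, ont)), "No annotation|empty|no annotation rows|survive")
})

test_that("encode_gene pads with index 0 to the fixed length t0", {
  ont <- parse_obo(toy_obo_lines())
  rows <- c(
    gaf_row("g1", "GO:0000002"), gaf_row("g1", "GO:0000003"),
    gaf_row("g2", "GO:0000002"), gaf_row("g2", "GO:0000003"),
    gaf_row("g2", "GO:0000004"), gaf_row("g2", "GO:0000005"),
    gaf_row("g3", "GO:0000001")
  )
  corp <- parse_gaf(rows, ont)
  t0 <- corp$t0[["BP"]]
  enc1 <- encode_gene(corp, "g1", "BP")
  expect_length(enc1, t0)
  expect_equal(enc1[3:4], c(0L, 0L))
  expect_true(all(diff(enc1[enc1 != 0]) > 0)) # ascending real indices
  # gene with exactly t0 terms gets no padding
  enc2 <- encode_gene(corp, "g2", "BP")
  expect_true(all(enc2 != 0))
  # every encoded gene has length t0, and stripping padding recovers the set
  for (g in corp$genes) {
    enc <- encode_gene(corp, g, "BP", strict = FALSE)
    expect_length(enc, t0)
    expect_equal(enc[enc != 0], corp$annotations[[g]][["BP"]])
  }
  expect_error(encode_gene(corp, "g3", "CC"), "strict")
  expect_error(encode_gene(corp, "nope", "BP"), "not in the corpus")
})

test_that("lift_annotations climbs is_a links with roots as fixed points", {
  ont <- parse_obo(toy_obo_lines())
  rows <- c(
    gaf_row("g1", "GO:0000003"), # child -> parent
    gaf_row("g2", "GO:0000001"), # root only
    gaf_row("g3", "GO:0000005") # diamond child -> two parents
  )
  corp <- parse_gaf(rows, ont)
  lifted <- lift_annotations(corp, ont, levels = 1)
  term_of <- function(c, g) c$terms[["BP"]][c$annotations[[g]][["BP"]]]
  expect_equal(term_of(lifted, "g1"), "GO:0000002")
  expect_equal(term_of(lifted, "g2"), "GO:0000001")
  expect_setequal(term_of(lifted, "g3"), c("GO:0000002", "GO:0000004"))
  # grandparents: levels = 2 equals two applications of levels = 1
  lifted2 <- lift_annotations(corp, ont, levels = 2)
  twice <- lift_annotations(lifted, ont, levels = 1)
  for (g in corp$genes) expect_equal(term_of(lifted2, g), term_of(twice, g))
  # root-only corpora are fixed points at any level
  root_corp <- parse_gaf(gaf_row("g2", "GO:0000001"), ont)
  expect_equal(
    term_of(lift_annotations(root_corp, ont, 3), "g2"), "GO:0000001"
  )
  expect_error(lift_annotations(corp, ont, levels = 0), "levels")
})

test_that("annotation corpora round-trip through their text representation", {
  corp <- tiny_corpus()
  dir <- withr::local_tempdir()
  write_annotation_corpus(corp, dir)
  back <- read_annotation_corpus(dir)
  expect_equal(back$genes, corp$genes)
  expect_equal(back$term_index, corp$term_index)
  expect_equal(back$t0, corp$t0)
  expect_equal(back$annotations, corp$annotations)
})
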