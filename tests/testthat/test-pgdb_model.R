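test_that("the shipped three-record fixture parses to the expected model", {
  s <- read_snapshot(fixture_a_path(), "ECOLI", "27.0")
  expect_setequal(names(s$objects), c("TRPA", "TRPA-MONOMER", "PUB-1"))
  expect_equal(names(s$objects$TRPA$slots),
               c("TYPES", "COMMON-NAME", "PRODUCT", "CITATIONS"))
  expect_equal(s$objects$TRPA$classes, "GENE")
  expect_length(s$merges, 0)
})

test_that("an empty file yields an empty snapshot", {
  p <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# header only", ""), p)
  s <- read_snapshot(p, "X", "1")
  expect_length(s$objects, 0)
  expect_length(s$merges, 0)
})

test_that("value-level citation annotations and continuation lines parse", {
  p <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "UNIQUE-ID - OBJ1",
    "TYPES - GENE",
    "COMMENT - a long summary",
    "/that continues here",
    "^CITATIONS - PMID:111",
    "//"), p)
  s <- read_snapshot(p, "X", "1")
  cv <- s$objects$OBJ1$slots$COMMENT[[1]]
  expect_equal(cv$value, "a long summary that continues here")
  expect_equal(cv$annotations$CITATIONS, "PMID:111")
  expect_equal(citations_of(s$objects$OBJ1), "PMID:111")
})

test_that("malformed files raise parse errors naming the offending line", {
  p <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("TYPES - GENE", "//"), p)
  expect_error(read_snapshot(p, "X", "1"), "line 1",
               class = "pgdb_parse_error")
  writeLines(c("UNIQUE-ID - A", "TYPES - GENE", "^CITATIONS - x", "//"), p)
  s <- read_snapshot(p, "X", "1")  # annotation after a slot is fine
  expect_equal(s$objects$A$slots$TYPES[[1]]$annotations$CITATIONS, "x")
  writeLines(c("UNIQUE-ID - A", "^CITATIONS - x", "//"), p)
  expect_error(read_snapshot(p, "X", "1"), "annotation line before",
               class = "pgdb_parse_error")
  writeLines(c("UNIQUE-ID - A", "TYPES - GENE"), p)
  expect_error(read_snapshot(p, "X", "1"), "unterminated",
               class = "pgdb_parse_error")
  writeLines(c("UNIQUE-ID - A", "TYPES - GENE", "//",
               "UNIQUE-ID - A", "TYPES - GENE", "//"), p)
  expect_error(read_snapshot(p, "X", "1"), "duplicate UNIQUE-ID",
               class = "pgdb_integrity_error")
})

test_that("write then read is the identity on the model", {
  s <- read_snapshot(fixture_a_path(), "ECOLI", "27.0")
  p <- write_tmp_snapshot(s)
  expect_true(snapshot_equal(s, read_snapshot(p, "ECOLI", "27.0")))

  for (seed in c(2, 17, 40)) {
    g <- generate_base(n_genes = 10, seed = seed)
    p <- write_tmp_snapshot(g)
    expect_true(snapshot_equal(g, read_snapshot(p, g$database_id, g$version)),
                info = sprintf("round-trip seed %d", seed))
  }
})

test_that("repeated slot values keep their order through a round trip", {
  o <- db_object("X1", "PROTEIN", list(SYNONYMS = c("beta", "alpha")))
  s <- snapshot("X", "1", list(o))
  p <- write_tmp_snapshot(s)
  lines <- readLines(p)
  syn <- grep("^SYNONYMS - ", lines, value = TRUE)
  expect_equal(syn, c("SYNONYMS - beta", "SYNONYMS - alpha"))
  s2 <- read_snapshot(p, "X", "1")
  vals <- vapply(s2$objects$X1$slots$SYNONYMS, `[[`, "", "value")
  expect_equal(vals, c("beta", "alpha"))
})

test_that("merge provenance round-trips via MERGED-FROM slots", {
  s <- snapshot("X", "2", list(
    db_object("B", "PROTEIN", list(`MERGED-FROM` = "A"))))
  expect_equal(s$merges, c(A = "B"))
  p <- write_tmp_snapshot(s)
  expect_equal(read_snapshot(p, "X", "2")$merges, c(A = "B"))
  expect_error(snapshot("X", "2", list(
    db_object("A", "PROTEIN"),
    db_object("B", "PROTEIN", list(`MERGED-FROM` = "A")))),
    "merged-away", class = "pgdb_validation_error")
})

test_that("citation normalization strips qualifiers and is idempotent", {
  expect_equal(normalize_citation("123456:EV-EXP-IDA:xyz"), "123456")
  expect_equal(normalize_citation("PMID:101"), "PMID:101")
  expect_equal(normalize_citation("pmid:101:EV-COMP"), "PMID:101")
  expect_equal(normalize_citation(" [PUB-77] "), "PUB-77")
  tokens <- c("PMID:9", "abc:def", "|frame-1|", "(X:1:2)", "PMID:12:EV",
              "plain", "  padded  ")
  once <- normalize_citation(tokens)
  expect_identical(normalize_citation(once), once)
})

test_that("citations_of unions object- and value-level citations as a set", {
  o <- db_object("G", "GENE")
  expect_length(citations_of(o), 0)
  o2 <- db_object("G", "GENE", list(
    CITATIONS = "PMID:9",
    COMMENT = list(slot_value("text", list(CITATIONS = "PMID:9")))))
  expect_equal(citations_of(o2), "PMID:9")
  o3 <- db_object("G", "GENE", list(CITATIONS = "123456:EV-EXP-IDA:xyz"))
  expect_equal(citations_of(o3), "123456")
})

test_that("adding a citation token anywhere never shrinks citations_of", {
  for (seed in 1:10) {
    s <- generate_base(n_genes = 6, seed = seed)
    id <- names(s$objects)[1 + seed %% length(s$objects)]
    before <- citations_of(s$objects[[id]])
    o <- s$objects[[id]]
    sn <- names(o$slots)[length(o$slots)]
    o$slots[[sn]][[1]]$annotations[["CITATIONS"]] <-
      c(o$slots[[sn]][[1]]$annotations[["CITATIONS"]], sprintf("PMID:%d", 77000 + seed))
    expect_true(all(before %in% citations_of(o)),
                info = sprintf("monotone seed %d", seed))
  }
})

test_that("objects_of_class is direct multi-class membership", {
  s <- read_snapshot(fixture_a_path(), "ECOLI", "27.0")
  expect_equal(objects_of_class(s, "GENE"), "TRPA")
  expect_length(objects_of_class(s, "NO-SUCH-CLASS"), 0)
  s2 <- snapshot("X", "1", list(db_object("C", c("PROTEIN", "COMPLEX"))))
  expect_equal(objects_of_class(s2, "PROTEIN"), "C")
  expect_equal(objects_of_class(s2, "COMPLEX"), "C")
})
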