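test_that("gene closure walks product, complexes, activity, reaction, pathway, regulation", {
  s <- fixture_b()
  cl <- gene_closure(s, "TRPA")
  expect_equal(cl$anchor_id, "TRPA")
  expect_setequal(cl$members,
                  c("TRPA", "TRPA-MONOMER", "TRPAB", "ENZRXN-1", "RXN-1",
                    "PWY-TRP", "REG-1"))
  ## provenance paths start at the anchor and land on their member
  expect_true("TRPA" %in% cl$members)
  for (m in setdiff(cl$members, "TRPA")) {
    path <- cl$provenance[[m]]
    expect_gt(length(path), 0)
    expect_equal(path[[length(path)]]$id, m)
  }
})

test_that("a gene with no product closes over itself only", {
  s <- snapshot("X", "1", list(db_object("G1", "GENE")))
  expect_equal(gene_closure(s, "G1")$members, "G1")
})

test_that("complex-of-complex chains are followed to any depth", {
  objs <- list(db_object("G1", "GENE", list(PRODUCT = "P1")),
               db_object("P1", "PROTEIN", list(`COMPONENT-OF` = "C1")))
  for (k in 1:5) {
    objs <- c(objs, list(db_object(
      sprintf("C%d", k), c("PROTEIN", "COMPLEX"),
      if (k < 5) list(`COMPONENT-OF` = sprintf("C%d", k + 1)) else list())))
  }
  s <- snapshot("X", "1", objs)
  expect_setequal(gene_closure(s, "G1")$members,
                  c("G1", "P1", sprintf("C%d", 1:5)))
})

test_that("pathway closure covers reactions, compounds, enzymes, genes, regulation", {
  s <- fixture_b()
  cl <- pathway_closure(s, "PWY-TRP")
  expect_setequal(cl$members,
                  c("PWY-TRP", "RXN-1", "CPD-L", "CPD-R", "ENZRXN-1",
                    "TRPAB", "TRPA-MONOMER", "TRPA", "REG-1"))
})

test_that("a pathway with no reactions closes over itself only", {
  s <- snapshot("X", "1", list(db_object("PWY-1", "PATHWAY")))
  expect_equal(pathway_closure(s, "PWY-1")$members, "PWY-1")
})

test_that("sub-pathways in the reaction list are expanded recursively", {
  s <- snapshot("X", "1", list(
    db_object("PWY-SUPER", "PATHWAY", list(`REACTION-LIST` = c("RXN-A", "PWY-SUB"))),
    db_object("PWY-SUB", "PATHWAY", list(`REACTION-LIST` = "RXN-B")),
    db_object("RXN-A", "REACTION", list(LEFT = "CPD-1", RIGHT = "CPD-2")),
    db_object("RXN-B", "REACTION", list(LEFT = "CPD-2", RIGHT = "CPD-3")),
    db_object("CPD-1", "COMPOUND"), db_object("CPD-2", "COMPOUND"),
    db_object("CPD-3", "COMPOUND")))
  expect_setequal(pathway_closure(s, "PWY-SUPER")$members,
                  c("PWY-SUPER", "PWY-SUB", "RXN-A", "RXN-B",
                    "CPD-1", "CPD-2", "CPD-3"))
  expect_identical(pathway_closure(s, "PWY-SUPER")$members,
                   oracle_pathway_closure(s, "PWY-SUPER"))
})

test_that("component-of cycles terminate and keep both cycle members", {
  s <- snapshot("X", "1", list(
    db_object("G1", "GENE", list(PRODUCT = "P1")),
    db_object("P1", "PROTEIN", list(`COMPONENT-OF` = "CA")),
    db_object("CA", c("PROTEIN", "COMPLEX"), list(`COMPONENT-OF` = "CB")),
    db_object("CB", c("PROTEIN", "COMPLEX"), list(`COMPONENT-OF` = "CA"))))
  expect_setequal(gene_closure(s, "G1")$members, c("G1", "P1", "CA", "CB"))
})

test_that("unknown anchors raise resolution errors", {
  s <- fixture_b()
  expect_error(gene_closure(s, "NOPE"), class = "pgdb_resolution_error")
  expect_error(pathway_closure(s, "NOPE"), class = "pgdb_resolution_error")
  expect_error(term_members(s, "NOPE", "GO-TERM"),
               class = "pgdb_resolution_error")
})

go_fixture <- function() {
  snapshot("X", "1", list(
    db_object("GO:1", "GO-TERM"),
    db_object("GO:2", "GO-TERM", list(PARENTS = "GO:1")),
    db_object("GO:3", "GO-TERM", list(PARENTS = "GO:1")),
    db_object("GO:4", "GO-TERM", list(PARENTS = c("GO:2", "GO:3"))),
    db_object("G1", "GENE", list(`GO-TERMS` = "GO:2")),
    db_object("G2", "GENE", list(`GO-TERMS` = "GO:3")),
    db_object("G3", "GENE", list(`GO-TERMS` = "GO:4"))))
}

test_that("term membership propagates annotations up the DAG (true path)", {
  s <- go_fixture()
  expect_equal(term_members(s, "GO:4", "GO-TERM"), "G3")
  expect_setequal(term_members(s, "GO:2", "GO-TERM"), c("G1", "G3"))
  expect_setequal(term_members(s, "GO:1", "GO-TERM"), c("G1", "G2", "G3"))
  s2 <- snapshot("X", "1", list(db_object("GO:9", "GO-TERM"),
                                db_object("G1", "GENE")))
  expect_length(term_members(s2, "GO:9", "GO-TERM"), 0)
})

test_that("pathway-class membership follows TYPES chains through PARENTS", {
  s <- snapshot("X", "1", list(
    db_object("PC-ROOT", "PATHWAY-CLASS"),
    db_object("PC-SUB", "PATHWAY-CLASS", list(PARENTS = "PC-ROOT")),
    db_object("PWY-1", c("PATHWAY", "PC-SUB")),
    db_object("PWY-2", c("PATHWAY", "PC-ROOT"))))
  expect_equal(term_members(s, "PC-SUB", "PATHWAY-CLASS"), "PWY-1")
  expect_setequal(term_members(s, "PC-ROOT", "PATHWAY-CLASS"),
                  c("PWY-1", "PWY-2"))
})

test_that("a PARENTS cycle raises an ontology error", {
  s <- snapshot("X", "1", list(
    db_object("GO:1", "GO-TERM", list(PARENTS = "GO:2")),
    db_object("GO:2", "GO-TERM", list(PARENTS = "GO:1")),
    db_object("G1", "GENE", list(`GO-TERMS` = "GO:2"))))
  expect_error(term_members(s, "GO:1", "GO-TERM"),
               class = "pgdb_ontology_error")
})

test_that("closures equal the naive fixed-point oracle on random fixtures", {
  for (seed in 1:12) {
    s <- generate_base(n_genes = 4 + seed, n_pathways = 2 + seed %% 3,
                       n_terms = 5, seed = seed)
    for (g in utils::head(objects_of_class(s, "GENE"), 3))
      expect_identical(gene_closure(s, g)$members, oracle_gene_closure(s, g),
                       info = sprintf("gene %s seed %d", g, seed))
    for (p in utils::head(objects_of_class(s, "PATHWAY"), 2))
      expect_identical(pathway_closure(s, p)$members,
                       oracle_pathway_closure(s, p),
                       info = sprintf("pathway %s seed %d", p, seed))
  }
})

test_that("adding a relation edge never removes closure members", {
  s <- fixture_b()
  before <- gene_closure(s, "TRPA")$members
  o <- s$objects$TRPAB
  o$slots[["CATALYZES"]] <- c(o$slots[["CATALYZES"]], list(slot_value("ENZRXN-2")))
  s2 <- snapshot("ECOLI", "1.1", c(s$objects[names(s$objects) != "TRPAB"],
                                   list(o),
                                   list(db_object("ENZRXN-2",
                                                  "ENZYMATIC-REACTION"))))
  after <- gene_closure(s2, "TRPA")$members
  expect_true(all(before %in% after))
  expect_true("ENZRXN-2" %in% after)
})
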