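reg1 <- function(kind, target, mode = "NONE", user = "u@x.org", db = "ECOLI") {
  subscribe(empty_registry(), subscription(user, db, kind, target, mode))
}

test_that("typo edits alone never fire, however many there are", {
  s <- fixture_b()
  o <- s$objects$TRPA; o$slots[["COMMON-NAME"]][[1]]$value <- "trpa"
  p <- s$objects[["PWY-TRP"]]
  p$slots[["COMMON-NAME"]][[1]]$value <- "Tryptophan Biosynthesis"
  objs <- s$objects; objs[["TRPA"]] <- o; objs[["PWY-TRP"]] <- p
  s2 <- snapshot("ECOLI", "2.0", objs)
  reg <- subscribe(reg1("GENE", "TRPA"),
                   subscription("u@x.org", "ECOLI", "PATHWAY", "PWY-TRP"))
  expect_length(run_notifications(reg, s, s2), 0)
})

test_that("a new citation on the enzyme complex fires the gene subscription", {
  s <- fixture_b()
  s2 <- with_citation(s, "TRPAB", "PMID:999")
  items <- run_notifications(reg1("GENE", "TRPA"), s, s2)
  expect_length(items, 1)
  expect_equal(items[[1]]$trigger_ids, "TRPAB")
  expect_equal(items[[1]]$new_publications, "PMID:999")
  expect_equal(names(items[[1]]$member_diffs), "TRPAB")
})

test_that("a new citation outside the closure does not fire", {
  s <- fixture_b()
  s2 <- with_citation(s, "CPD-L", "PMID:999")  # compounds are outside a gene closure
  expect_length(run_notifications(reg1("GENE", "TRPA"), s, s2), 0)
  ## but inside the pathway closure, the same edit fires the pathway sub
  expect_length(run_notifications(reg1("PATHWAY", "PWY-TRP"), s, s2), 1)
})

test_that("a brand-new object without citations never triggers", {
  s <- fixture_b()
  objs <- c(s$objects, list(db_object("REG-NEW", "REGULATION", list(
    `REGULATED-ENTITY` = "TRPA-MONOMER"))))
  s2 <- snapshot("ECOLI", "2.0", objs)
  expect_length(run_notifications(reg1("GENE", "TRPA"), s, s2), 0)
  ## the same object with a citation does trigger
  objs2 <- c(s$objects, list(db_object("REG-NEW", "REGULATION", list(
    `REGULATED-ENTITY` = "TRPA-MONOMER", CITATIONS = "PMID:555"))))
  s3 <- snapshot("ECOLI", "2.0", objs2)
  items <- run_notifications(reg1("GENE", "TRPA"), s, s3)
  expect_length(items, 1)
  expect_equal(items[[1]]$trigger_ids, "REG-NEW")
})

go_pair <- function() {
  old <- snapshot("ECOLI", "1.0", list(
    db_object("GO:1", "GO-TERM"),
    db_object("GO:2", "GO-TERM", list(PARENTS = "GO:1")),
    db_object("G1", "GENE", list(`GO-TERMS` = "GO:2", CITATIONS = "PMID:1")),
    db_object("G2", "GENE"),
    db_object("G3", "GENE")))
  list(old = old)
}

test_that("NEW-MEMBERS fires on annotation gains, including via descendants", {
  p <- go_pair()
  objs <- p$old$objects
  o <- objs$G3; o$slots[["GO-TERMS"]] <- list(slot_value("GO:2"))
  objs$G3 <- o
  new <- snapshot("ECOLI", "2.0", objs)
  items <- run_notifications(reg1("GO-TERM", "GO:1", "NEW-MEMBERS"), p$old, new)
  expect_length(items, 1)
  expect_equal(items[[1]]$new_members, "G3")
})

test_that("annotation deletions never fire NEW-MEMBERS", {
  p <- go_pair()
  objs <- p$old$objects
  o <- objs$G1; o$slots[["GO-TERMS"]] <- NULL; objs$G1 <- o
  new <- snapshot("ECOLI", "2.0", objs)
  expect_length(run_notifications(reg1("GO-TERM", "GO:1", "NEW-MEMBERS"),
                                  p$old, new), 0)
  expect_length(run_notifications(reg1("GO-TERM", "GO:2", "NEW-MEMBERS"),
                                  p$old, new), 0)
})

test_that("MEMBER-CHANGES composes the gene criteria over current members", {
  s <- fixture_b()
  objs <- c(s$objects, list(
    db_object("GO:1", "GO-TERM"),
    db_object("GO:2", "GO-TERM", list(PARENTS = "GO:1"))))
  o <- objs$TRPA; o$slots[["GO-TERMS"]] <- list(slot_value("GO:2")); objs$TRPA <- o
  old <- snapshot("ECOLI", "1.0", objs)
  new <- with_citation(old, "TRPAB", "PMID:999")  # enzyme of the member gene
  items <- run_notifications(reg1("GO-TERM", "GO:1", "MEMBER-CHANGES"), old, new)
  expect_length(items, 1)
  expect_equal(items[[1]]$trigger_ids, "TRPAB")
  ## the NEW-MEMBERS mode is silent for the same pair
  expect_length(run_notifications(reg1("GO-TERM", "GO:1", "NEW-MEMBERS"),
                                  old, new), 0)
})

test_that("empty registries, identical releases and self-runs are silent", {
  s <- fixture_b()
  expect_length(run_notifications(empty_registry(), s, s), 0)
  reg <- subscribe(reg1("GENE", "TRPA"),
                   subscription("u@x.org", "ECOLI", "PATHWAY", "PWY-TRP"))
  expect_length(run_notifications(reg, s, s), 0)
  s2 <- with_citation(s, "TRPAB", "PMID:999")
  expect_length(run_notifications(reg, s2, s2), 0)
})

test_that("subscriptions for other databases are skipped", {
  s <- fixture_b()
  s2 <- with_citation(s, "TRPAB", "PMID:999")
  reg <- reg1("GENE", "TRPA", db = "META")
  expect_length(run_notifications(reg, s, s2), 0)
})

test_that("a dangling anchor yields no item (not an error)", {
  s <- fixture_b()
  s2 <- with_citation(s, "TRPAB", "PMID:999")
  items <- run_notifications(reg1("GENE", "NO-SUCH-GENE"), s, s2)
  expect_length(items, 0)
})

test_that("firing agrees exactly with the brute-force oracle over seeds", {
  for (seed in 1:15) {
    old <- generate_base(n_genes = 12 + seed %% 6, n_pathways = 3,
                         n_terms = 6, seed = seed)
    new <- apply_edit_script(old, make_edit_script(old, seed + 1000,
                                                   n_edits = 7))
    reg <- sample_registry(old, seed + 2000, n_users = 3, n_per_user = 4)
    expect_identical(firing_keys(run_notifications(reg, old, new)),
                     oracle_firings(reg, old, new),
                     info = sprintf("seed %d", seed))
  }
})

test_that("adding one more citation edit never unfires a subscription", {
  for (seed in 1:8) {
    old <- generate_base(n_genes = 12, seed = seed)
    new <- apply_edit_script(old, make_edit_script(old, seed + 50, n_edits = 5))
    reg <- sample_registry(old, seed + 90, n_users = 3, n_per_user = 4)
    before <- firing_keys(run_notifications(reg, old, new))
    ## extra citation on an object untouched by the script
    pool <- setdiff(objects_of_class(new, "GENE"), names(diff_snapshot(old, new)$diffs))
    if (!length(pool)) next
    new2 <- with_citation(new, pool[[1]], "PMID:88888")
    after <- firing_keys(run_notifications(reg, old, new2))
    expect_true(all(before %in% after), info = sprintf("seed %d", seed))
  }
})
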