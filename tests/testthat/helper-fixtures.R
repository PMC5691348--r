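## Shared fixtures, built in code.  Tests that need randomness derive all
## of it from explicit seeds so failures reproduce exactly.

options(pgdbwatch.loglevel = "error")

fixture_a_path <- function() {
  system.file("extdata", "fixture-a.dat", package = "pgdbwatch",
              mustWork = TRUE)
}

## Hand-built trpA neighbourhood: gene -> monomer -> complex -> activity
## -> reaction -> pathway, with a regulation object on the complex.
fixture_b <- function() {
  snapshot("ECOLI", "1.0", list(
    db_object("TRPA", "GENE", list(
      `COMMON-NAME` = "trpA", PRODUCT = "TRPA-MONOMER",
      CITATIONS = "PMID:101")),
    db_object("TRPA-MONOMER", "PROTEIN", list(
      GENE = "TRPA", `COMPONENT-OF` = "TRPAB")),
    db_object("TRPAB", c("PROTEIN", "COMPLEX"), list(
      COMPONENTS = "TRPA-MONOMER", CATALYZES = "ENZRXN-1")),
    db_object("ENZRXN-1", "ENZYMATIC-REACTION", list(REACTION = "RXN-1")),
    db_object("RXN-1", "REACTION", list(
      LEFT = "CPD-L", RIGHT = "CPD-R", `IN-PATHWAY` = "PWY-TRP")),
    db_object("PWY-TRP", "PATHWAY", list(
      `COMMON-NAME` = "tryptophan biosynthesis", `REACTION-LIST` = "RXN-1")),
    db_object("REG-1", "REGULATION", list(`REGULATED-ENTITY` = "TRPAB")),
    db_object("CPD-L", "COMPOUND"),
    db_object("CPD-R", "COMPOUND"),
    db_object("PUB-1", "PUBLICATION", list(
      PMID = "101", AUTHORS = "Yanofsky C", YEAR = "1999",
      TITLE = "Tryptophan synthase structure"))
  ))
}

## Copy of a snapshot with one citation token appended to one object.
with_citation <- function(s, id, token) {
  o <- s$objects[[id]]
  sv <- slot_value(token)
  if (is.null(o$slots[["CITATIONS"]])) o$slots[["CITATIONS"]] <- list(sv)
  else o$slots[["CITATIONS"]] <- c(o$slots[["CITATIONS"]], list(sv))
  s$objects[[id]] <- o
  snapshot(s$database_id, "2.0", s$objects)
}

## Markdown link targets appearing in a rendered digest.
md_link_targets <- function(text) {
  m <- gregexpr("\\]\\(([^)]*)\\)", text)
  urls <- regmatches(text, m)[[1]]
  sub("^\\]\\(", "", sub("\\)$", "", urls))
}

nonblank_lines <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines[nzchar(trimws(lines))]
}

write_tmp_snapshot <- function(s) {
  p <- withr::local_tempfile(fileext = ".dat", .local_envir = parent.frame())
  write_snapshot(s, p)
  p
}
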