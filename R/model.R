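## Core model: slot values, database objects, snapshots, citation keys.
##
## A PGDB release is a bag of frame-like records.  Each record has a unique
## id, a list of classes (the values of its TYPES slot), and an ordered
## mapping slot name -> ordered list of values, where every value may carry
## per-value annotations (e.g. a CITATIONS annotation attaching evidence to
## one value rather than to the whole object).

#' Construct a slot value
#'
#' A single value of a slot, optionally carrying per-value annotations such
#' as value-level citations (`annotations = list(CITATIONS = "PMID:101")`).
#'
#' @param value Character scalar; trimmed, must be non-empty.
#' @param annotations Named list mapping an uppercase annotation label to a
#'   character vector of annotation values.
#' @return A `slot_value` list with elements `value` and `annotations`.
#' @export
slot_value <- function(value, annotations = list()) {
  value <- trimws(as.character(value))
  if (length(value) != 1L || is.na(value) || !nzchar(value))
    stop_validation("slot value must be a single non-empty string")
  if (length(annotations)) {
    labs <- names(annotations)
    if (is.null(labs) || any(!nzchar(labs)) || any(labs != toupper(labs)))
      stop_validation("annotation labels must be non-empty and uppercase")
    annotations <- lapply(annotations, as.character)
  } else {
    annotations <- stats::setNames(list(), character(0))
  }
  structure(list(value = value, annotations = annotations),
            class = "slot_value")
}

## Coerce a slot's values to a list of slot_value (accepts plain character).
as_slot_values <- function(x) {
  if (is.character(x)) return(lapply(x, slot_value))
  if (inherits(x, "slot_value")) return(list(x))
  lapply(x, function(v) if (inherits(v, "slot_value")) v else slot_value(v))
}

#' Construct a database object
#'
#' @param id Frame identifier; must match `[A-Za-z0-9._:+-]+`.
#' @param types Character vector of class identifiers (becomes the TYPES
#'   slot); may be omitted if `slots` already contains TYPES.
#' @param slots Named list: slot name -> character vector or list of
#'   [slot_value()]s. Order of slots and of values within a slot is
#'   significant and preserved.
#' @return A `db_object`.
#' @export
db_object <- function(id, types = NULL, slots = list()) {
  if (!grepl("^[A-Za-z0-9._:+-]+$", id))
    stop_validation("invalid object id: %s", id)
  slots <- lapply(slots, as_slot_values)
  if (!is.null(types)) {
    if (!is.null(slots[["TYPES"]]))
      stop_validation("object %s: give classes via types= or slots$TYPES, not both", id)
    slots <- c(list(TYPES = as_slot_values(as.character(types))), slots)
  }
  if (length(slots) == 0L) slots <- stats::setNames(list(), character(0))
  classes <- vapply(slots[["TYPES"]], `[[`, "", "value")
  if (length(classes) == 0L)
    stop_validation("object %s has no TYPES slot (classes must be non-empty)", id)
  structure(list(id = id, classes = classes, slots = slots),
            class = "db_object")
}

## Character vector of value texts for one slot (empty if absent).
slot_values_of <- function(o, slot) {
  vs <- o$slots[[slot]]
  if (is.null(vs)) return(character(0))
  vapply(vs, `[[`, "", "value")
}

display_name <- function(o) {
  nm <- slot_values_of(o, "COMMON-NAME")
  if (length(nm)) nm[[1L]] else o$id
}

#' Construct a snapshot of one database release
#'
#' Merge provenance is carried on surviving objects as a `MERGED-FROM`
#' slot; the snapshot-level `merges` map (merged-away id -> surviving id)
#' is derived from those slots so that it always round-trips through the
#' flatfile serialization.
#'
#' @param database_id Database identifier, e.g. `"ECOLI"`.
#' @param version Release label.
#' @param objects List of [db_object()]s (named or unnamed; names are taken
#'   from the object ids).
#' @return A `pgdb_snapshot` with fields `database_id`, `version`,
#'   `objects` (id -> db_object) and `merges` (named character vector,
#'   old id -> surviving id).
#' @export
snapshot <- function(database_id, version, objects = list()) {
  ids <- vapply(objects, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_validation("duplicate object id: %s", ids[duplicated(ids)][1L])
  names(objects) <- ids
  merges <- character(0)
  for (o in objects) {
    from <- slot_values_of(o, "MERGED-FROM")
    if (length(from))
      merges[from] <- o$id
  }
  if (length(merges)) {
    bad <- intersect(names(merges), ids)
    if (length(bad))
      stop_validation("merged-away id still present in objects: %s", bad[1L])
  }
  structure(list(database_id = database_id, version = version,
                 objects = objects, merges = merges),
            class = "pgdb_snapshot")
}

#' @export
print.pgdb_snapshot <- function(x, ...) {
  cat(sprintf("<pgdb_snapshot %s version %s: %d objects, %d merges>\n",
              x$database_id, x$version, length(x$objects), length(x$merges)))
  invisible(x)
}

#' Normalize a citation token to a citation key
#'
#' Curators attach citations as tokens like `"PMID:101"`,
#' `"123456:EV-EXP-IDA:curator"` or `"[pub-77]"`, where everything after
#' the first `:` is an evidence/provenance qualifier (except in `PMID:` ids,
#' where the digits are part of the key).  The notification trigger is the
#' publication itself, so qualifiers are stripped: surrounding brackets and
#' whitespace removed, uppercased, then truncated at the first `:` unless
#' the token is a `PMID:<digits>` reference.  The function is idempotent.
#'
#' @param tokens Character vector of raw citation tokens.
#' @return Character vector of normalized keys (empty tokens dropped).
#' @export
normalize_citation <- function(tokens) {
  x <- trimws(tokens)
  x <- gsub("^[][()|]+|[][()|]+$", "", x)
  x <- toupper(trimws(x))
  pm <- grepl("^PMID:[0-9]", x)
  x[pm] <- sub("^(PMID:[0-9]+).*$", "\\1", x[pm])
  x[!pm] <- sub(":.*$", "", x[!pm])
  x[nzchar(x)]
}

#' All citation keys attached to an object
#'
#' Union of the object-level `CITATIONS` slot and every value-level
#' `CITATIONS` annotation on any slot, normalized with
#' [normalize_citation()].
#'
#' @param o A [db_object()].
#' @return Sorted character vector of citation keys (possibly empty).
#' @export
citations_of <- function(o) {
  toks <- slot_values_of(o, "CITATIONS")
  for (vs in o$slots) {
    for (v in vs) {
      ann <- v$annotations[["CITATIONS"]]
      if (!is.null(ann)) toks <- c(toks, ann)
    }
  }
  sort(unique(normalize_citation(toks)))
}

#' Object ids belonging directly to a class
#'
#' Direct membership only (an object is in class `X` iff `X` appears in its
#' TYPES slot); ontology expansion is the closure module's job, see
#' [term_members()].
#'
#' @param s A [snapshot()].
#' @param class_id Class identifier, e.g. `"GENE"`.
#' @return Character vector of object ids (snapshot order).
#' @export
objects_of_class <- function(s, class_id) {
  keep <- vapply(s$objects, function(o) class_id %in% o$classes, NA)
  names(s$objects)[keep]
}

## ---- canonical forms (order-insensitive identity used by the diff engine) ----

canonical_sv <- function(v) {
  ann <- v$annotations
  if (length(ann)) {
    ann <- ann[order(names(ann))]
    ann_str <- paste(names(ann),
                     vapply(ann, paste, "", collapse = "\x1d"),
                     sep = "=", collapse = "\x1e")
  } else ann_str <- ""
  paste0(v$value, "\x1f", ann_str)
}

## Canonical string for a whole object: slots as an unordered mapping,
## values within a slot as a multiset (sorted canonical forms).
canonical_object <- function(o) {
  sl <- o$slots
  if (length(sl) == 0L) return(o$id)
  parts <- vapply(seq_along(sl), function(i) {
    paste0(names(sl)[i], ":",
           paste(sort(vapply(sl[[i]], canonical_sv, "")), collapse = "\x1c"))
  }, "")
  paste0(o$id, "\x1b", paste(sort(parts), collapse = "\x1b"))
}

#' Model equality of two snapshots
#'
#' Strict equality: same objects with identical slot order, value order and
#' annotations, and the same merge provenance. Used by round-trip tests.
#'
#' @param a,b Snapshots.
#' @return TRUE or FALSE.
#' @export
snapshot_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("database_id", "objects")],
                   unclass(b)[c("database_id", "objects")])) &&
    identical(sort(names(a$merges)), sort(names(b$merges))) &&
    identical(a$merges[sort(names(a$merges))],
              b$merges[sort(names(b$merges))])
}
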