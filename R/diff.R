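## Release-to-release diffing.  Slots are compared as multisets of
## (value, annotations) pairs -- serialization order is not curation, but
## any textual change, however small, is a difference.  The new-citation
## set of an object is what the significance filter runs on: citations in
## the new release minus citations the object (or anything merged into it)
## already had.

#' Change category for a slot
#'
#' Maps a slot name to the reader-facing category used in digests
#' ("textual summary", "GO term annotations", "regulation", ...). Unmapped
#' slots fall back to the lowercased slot name.
#'
#' @param slot Slot name.
#' @param object_classes Classes of the changed object (reserved for
#'   class-specific category maps; the default map ignores it).
#' @param map Named category map; see `inst/extdata/categories.yaml`.
#' @return Category string.
#' @export
categorize <- function(slot, object_classes = character(0),
                       map = category_map()) {
  map[[slot]] %||% tolower(slot)
}

#' Default slot-to-category map
#' @param path Optional alternative YAML map.
#' @return Named list slot name -> category.
#' @export
category_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "categories.yaml", package = "pgdbwatch",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

## Multiset difference of two lists of slot_value, by canonical form.
## Returns list(added = , removed = ) of display value texts.
sv_multiset_diff <- function(old_vs, new_vs) {
  old_keys <- vapply(old_vs, canonical_sv, "")
  new_keys <- vapply(new_vs, canonical_sv, "")
  old_tab <- table(old_keys)
  new_tab <- table(new_keys)
  added <- character(0); removed <- character(0)
  for (k in union(names(old_tab), names(new_tab))) {
    no <- if (k %in% names(old_tab)) old_tab[[k]] else 0L
    nn <- if (k %in% names(new_tab)) new_tab[[k]] else 0L
    val <- sub("\x1f.*$", "", k)
    if (nn > no) added <- c(added, rep(val, nn - no))
    if (no > nn) removed <- c(removed, rep(val, no - nn))
  }
  list(added = sort(added), removed = sort(removed))
}

#' Diff one object across releases
#'
#' Produces slot-level added/removed value lists and the object's
#' new-citation set.  Merge provenance silences citations: a citation is
#' only "new" if it was absent from the old version of the object *and*
#' from every old object recorded as merged into it, so consolidating
#' redundant objects never looks like new science.
#'
#' @param old,new The object in the old / new release; `NULL` when absent
#'   from that release (not both).
#' @param merges The new snapshot's merge map (old id -> surviving id).
#' @param old_snapshot The old [snapshot()], used to look up citations of
#'   merge sources.
#' @return An `object_diff` (fields `id`, `status` one of
#'   ADDED/REMOVED/MODIFIED/MERGED-AWAY, `slot_diffs`, `new_citations`),
#'   or `NULL` when the versions are identical.
#' @export
diff_object <- function(old, new, merges = character(0),
                        old_snapshot = NULL) {
  if (is.null(old) && is.null(new))
    stop_usage("diff_object: at least one of old/new must be present")
  id <- (new %||% old)$id
  if (!is.null(old) && !is.null(new) &&
      identical(canonical_object(old), canonical_object(new)))
    return(NULL)

  status <- if (is.null(old)) "ADDED"
  else if (is.null(new)) {
    if (id %in% names(merges)) "MERGED-AWAY" else "REMOVED"
  } else "MODIFIED"

  old_slots <- if (is.null(old)) list() else old$slots
  new_slots <- if (is.null(new)) list() else new$slots
  classes <- (new %||% old)$classes
  cmap <- category_map()
  slot_diffs <- list()
  for (sn in union(names(old_slots), names(new_slots))) {
    d <- sv_multiset_diff(old_slots[[sn]] %||% list(),
                          new_slots[[sn]] %||% list())
    if (length(d$added) || length(d$removed)) {
      slot_diffs[[length(slot_diffs) + 1L]] <-
        list(slot = sn, added = d$added, removed = d$removed,
             category = categorize(sn, classes, cmap))
    }
  }

  new_cit <- if (is.null(new)) character(0) else citations_of(new)
  if (length(new_cit)) {
    prior <- if (is.null(old)) character(0) else citations_of(old)
    if (!is.null(old_snapshot)) {
      sources <- names(merges)[merges == id]
      for (src in sources) {
        so <- old_snapshot$objects[[src]]
        if (!is.null(so)) prior <- c(prior, citations_of(so))
      }
    }
    new_cit <- setdiff(new_cit, prior)
  }

  structure(list(id = id, status = status, slot_diffs = slot_diffs,
                 new_citations = sort(new_cit)),
            class = "object_diff")
}

#' Diff two snapshots of the same database
#'
#' Every id in the union of both releases is compared; identical objects
#' are absent from the result.  Ids merged away by the new release get
#' status `MERGED-AWAY` rather than `REMOVED`.
#'
#' @param old,new Snapshots sharing a `database_id`.
#' @return A `snapshot_diff`: `database_id`, `old_version`, `new_version`,
#'   and `diffs` (named list id -> `object_diff`).
#' @export
diff_snapshot <- function(old, new) {
  if (!identical(old$database_id, new$database_id))
    stop_usage("cannot diff releases of different databases (%s vs %s)",
               old$database_id, new$database_id)
  ids <- union(names(old$objects), names(new$objects))
  diffs <- list()
  for (id in ids) {
    d <- diff_object(old$objects[[id]], new$objects[[id]],
                     merges = new$merges, old_snapshot = old)
    if (!is.null(d)) diffs[[id]] <- d
  }
  structure(list(database_id = new$database_id,
                 old_version = old$version, new_version = new$version,
                 diffs = diffs),
            class = "snapshot_diff")
}

#' @export
print.snapshot_diff <- function(x, ...) {
  cat(sprintf("<snapshot_diff %s %s -> %s: %d changed objects>\n",
              x$database_id, x$old_version, x$new_version, length(x$diffs)))
  invisible(x)
}

#' Serialize a snapshot diff to JSON
#'
#' @param d A `snapshot_diff`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diff_json <- function(d, path) {
  out <- list(
    database = d$database_id,
    old_version = d$old_version,
    new_version = d$new_version,
    diffs = lapply(d$diffs, function(od) {
      list(id = od$id, status = od$status,
           new_citations = as.list(od$new_citations),
           slots = lapply(od$slot_diffs, function(sd)
             list(slot = sd$slot, category = sd$category,
                  added = as.list(sd$added), removed = as.list(sd$removed))))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
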