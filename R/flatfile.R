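## Attribute-value flatfile dialect (.dat style), frozen:
##   - "#"-prefixed lines are comments; blank lines are ignored.
##   - A record opens with "UNIQUE-ID - <id>" and closes with a bare "//".
##   - "<SLOT> - <value>" adds a value; repeats append in order.
##   - "^<LABEL> - <value>" annotates the most recent value.
##   - "/<text>" continues the most recent value with " <text>".
## Encoding is UTF-8 with LF newlines; values are compared exactly, so a
## typo fix is a detectable (but non-triggering) difference.

#' Read a database snapshot from an attribute-value flatfile
#'
#' @param path Path to the flatfile.
#' @param database_id Database identifier to stamp on the snapshot.
#' @param version Release label to stamp on the snapshot.
#' @return A [snapshot()]. `MERGED-FROM` slots on surviving objects
#'   populate the snapshot's merge map.
#' @export
read_snapshot <- function(path, database_id, version) {
  if (!file.exists(path)) stop_usage("no such file: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  objects <- vector("list", 256L)
  n_obj <- 0L
  seen <- new.env(parent = emptyenv())

  cur_id <- NULL; cur_start <- 0L
  cur_slots <- NULL        # list slot -> list of slot_value parts
  cur_order <- NULL        # slot names in first-seen order
  last_slot <- NULL        # name of slot owning the most recent value
  last_kind <- NULL        # "slot" or "ann": where a continuation appends
  last_ann <- NULL         # label of the most recent annotation

  finish <- function(lineno) {
    slots <- lapply(cur_order, function(sn) cur_slots[[sn]])
    names(slots) <- cur_order
    obj <- tryCatch(db_object(cur_id, slots = slots), error = function(e) {
      stop_parse("line %d: record %s invalid: %s", lineno, cur_id,
                 conditionMessage(e))
    })
    if (exists(cur_id, envir = seen, inherits = FALSE))
      pgdb_stop("pgdb_integrity_error", "line %d: duplicate UNIQUE-ID %s",
                lineno, cur_id)
    assign(cur_id, TRUE, envir = seen)
    n_obj <<- n_obj + 1L
    if (n_obj > length(objects)) length(objects) <<- 2L * n_obj
    objects[[n_obj]] <<- obj
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    if (ln == "//") {
      if (is.null(cur_id)) stop_parse("line %d: '//' outside a record", i)
      finish(i)
      cur_id <- NULL
      next
    }
    if (startsWith(ln, "^")) {
      if (is.null(cur_id) || is.null(last_slot))
        stop_parse("line %d: annotation line before any slot line", i)
      m <- regmatches(ln, regexec("^\\^([^ ]+) - (.*)$", ln))[[1L]]
      if (length(m) != 3L) stop_parse("line %d: malformed annotation line", i)
      lab <- m[[2L]]; val <- trimws(m[[3L]])
      if (lab != toupper(lab))
        stop_parse("line %d: annotation label must be uppercase: %s", i, lab)
      vs <- cur_slots[[last_slot]]
      k <- length(vs)
      vs[[k]]$annotations[[lab]] <- c(vs[[k]]$annotations[[lab]], val)
      cur_slots[[last_slot]] <- vs
      last_kind <- "ann"; last_ann <- lab
      next
    }
    if (startsWith(ln, "/")) {
      if (is.null(cur_id) || is.null(last_slot))
        stop_parse("line %d: continuation line outside a record", i)
      txt <- substring(ln, 2L)
      vs <- cur_slots[[last_slot]]
      k <- length(vs)
      if (identical(last_kind, "ann")) {
        a <- vs[[k]]$annotations[[last_ann]]
        a[length(a)] <- paste0(a[length(a)], " ", txt)
        vs[[k]]$annotations[[last_ann]] <- a
      } else {
        vs[[k]]$value <- paste0(vs[[k]]$value, " ", txt)
      }
      cur_slots[[last_slot]] <- vs
      next
    }
    m <- regmatches(ln, regexec("^([^ ]+) - (.*)$", ln))[[1L]]
    if (length(m) != 3L) stop_parse("line %d: malformed line: %s", i, ln)
    slot <- m[[2L]]; val <- trimws(m[[3L]])
    if (slot == "UNIQUE-ID") {
      if (!is.null(cur_id))
        stop_parse("line %d: unterminated record %s (new UNIQUE-ID before '//')",
                   i, cur_id)
      cur_id <- val; cur_start <- i
      cur_slots <- list(); cur_order <- character(0)
      last_slot <- NULL; last_kind <- NULL; last_ann <- NULL
      next
    }
    if (is.null(cur_id))
      stop_parse("line %d: slot line outside a record (no UNIQUE-ID first line)", i)
    if (!nzchar(val)) stop_parse("line %d: empty value for slot %s", i, slot)
    sv <- list(value = val, annotations = stats::setNames(list(), character(0)))
    class(sv) <- "slot_value"
    if (is.null(cur_slots[[slot]])) cur_order <- c(cur_order, slot)
    cur_slots[[slot]] <- c(cur_slots[[slot]], list(sv))
    last_slot <- slot; last_kind <- "slot"
  }
  if (!is.null(cur_id))
    stop_parse("line %d: unterminated record %s at end of file", cur_start, cur_id)
  snapshot(database_id, version, objects[seq_len(n_obj)])
}

format_record <- function(o) {
  out <- character(0)
  for (sn in names(o$slots)) {
    for (v in o$slots[[sn]]) {
      out <- c(out, paste0(sn, " - ", v$value))
      for (lab in names(v$annotations))
        out <- c(out,
                 paste0("^", lab, " - ", v$annotations[[lab]]))
    }
  }
  c(paste0("UNIQUE-ID - ", o$id), out, "//")
}

#' Write a snapshot to an attribute-value flatfile
#'
#' Re-reading the emitted file yields a model-equal snapshot (slot order,
#' value order, annotations and merge provenance all preserved); comments
#' in a hand-authored source file are not reproduced.
#'
#' @param s A [snapshot()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snapshot <- function(s, path) {
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    pgdb_stop("pgdb_io_error", "cannot write %s: %s", path, conditionMessage(e)))
  on.exit(close(con))
  hdr <- c(sprintf("# Database: %s", s$database_id),
           sprintf("# Version: %s", s$version))
  body <- unlist(lapply(s$objects, format_record), use.names = FALSE)
  writeLines(c(hdr, body), con, sep = "\n", useBytes = FALSE)
  invisible(path)
}
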