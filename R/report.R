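## Digest rendering.  One report per (user, database) pair, markdown as
## the canonical format with HTML derived from it line by line.  Reports
## are byte-deterministic: all collections are sorted, no timestamps, and
## versions come from snapshot metadata, never the clock.

expand_url <- function(template, db, id) {
  u <- gsub("{db}", db, template, fixed = TRUE)
  gsub("{id}", id, u, fixed = TRUE)
}

check_url_template <- function(template) {
  if (!grepl("{db}", template, fixed = TRUE) ||
      !grepl("{id}", template, fixed = TRUE))
    pgdb_stop("pgdb_config_error",
              "url template must contain {db} and {id} placeholders: %s",
              template)
  template
}

## "AuthorsYear: Title (key)" when a publication object is resolvable,
## else the raw citation key.  pub_ix maps both object ids and PMID:<n>
## keys to publication objects.
publication_index <- function(s) {
  ix <- new.env(parent = emptyenv())
  for (id in objects_of_class(s, "PUBLICATION")) {
    o <- s$objects[[id]]
    assign(toupper(id), o, envir = ix)
    for (pm in slot_values_of(o, "PMID"))
      assign(paste0("PMID:", pm), o, envir = ix)
  }
  ix
}

publication_display <- function(key, pub_ix) {
  o <- pub_ix[[key]]
  if (is.null(o)) return(key)
  authors <- slot_values_of(o, "AUTHORS")
  title <- slot_values_of(o, "TITLE")
  year <- slot_values_of(o, "YEAR")
  if (!length(authors) && !length(title)) return(key)
  paste0(paste(c(authors[1], year[1]), collapse = " "),
         if (length(title)) paste0(": ", title[[1]]) else "",
         " (", key, ")")
}

#' Assemble per-user digests from notification items
#'
#' Groups items by (user, database) -- all of one user's firings for one
#' database always land in a single digest -- and orders items within a
#' report by kind, anchor display name, then id.
#'
#' @param items List of `notification_item`s from [run_notifications()].
#' @param new The new [snapshot()] (display names, publication lookup).
#' @param old_version,new_version Release labels for the report header.
#' @param url_template Object page URL template with `{db}` and `{id}`
#'   placeholders.
#' @param manage_url URL of the subscription-management page.
#' @return List of `pgdb_report`s (possibly empty; reports without items
#'   are never created).
#' @export
build_reports <- function(items, new, old_version, new_version,
                          url_template = "https://example.org/{db}/object/{id}",
                          manage_url = "https://example.org/notifications") {
  check_url_template(url_template)
  if (!length(items)) return(list())
  keys <- vapply(items, function(it) paste(it$user, it$database_id, sep = "\x1f"), "")
  reports <- list()
  for (k in sort(unique(keys))) {
    grp <- items[keys == k]
    disp <- vapply(grp, function(it) {
      o <- new$objects[[it$anchor_id]]
      if (is.null(o)) it$anchor_id else display_name(o)
    }, "")
    kinds <- vapply(grp, `[[`, "", "kind")
    ids <- vapply(grp, `[[`, "", "anchor_id")
    grp <- grp[order(kinds, disp, ids)]
    reports[[length(reports) + 1L]] <- structure(list(
      user = grp[[1L]]$user, database_id = grp[[1L]]$database_id,
      old_version = old_version, new_version = new_version,
      items = grp, url_template = url_template, manage_url = manage_url,
      snapshot = new), class = "pgdb_report")
  }
  reports
}

md_link <- function(text, url) sprintf("[%s](%s)", text, url)

## Member bullet: linked id (only when the object still exists in the new
## release -- merged-away/removed members render as plain text so no link
## dangles), display name, and its change categories.
member_bullet <- function(od, s, url_template, db) {
  o <- s$objects[[od$id]]
  label <- if (is.null(o)) od$id
           else md_link(od$id, expand_url(url_template, db, od$id))
  what <- switch(od$status,
    "MERGED-AWAY" = sprintf("merged into %s", s$merges[[od$id]]),
    "REMOVED" = "removed",
    "ADDED" = "new object",
    paste(sort(unique(vapply(od$slot_diffs, `[[`, "", "category"))),
          collapse = ", "))
  nm <- if (!is.null(o) && display_name(o) != od$id)
    sprintf(" (%s)", display_name(o)) else ""
  sprintf("- %s%s: %s", label, nm, what)
}

#' Render a report
#'
#' Markdown is canonical; HTML is a line-wise translation with identical
#' link targets and visible text.  Rendering is byte-deterministic for a
#' given report.  Member diffs shared between items of one report are
#' listed in full once and cross-referenced afterwards.
#'
#' @param r A `pgdb_report`.
#' @param format `"markdown"` or `"html"`.
#' @return Single string, the rendered digest.
#' @export
render_report <- function(r, format = c("markdown", "html")) {
  format <- match.arg(format)
  s <- r$snapshot; db <- r$database_id
  pub_ix <- publication_index(s)
  lines <- c(
    sprintf("# %s update notifications: release %s to %s",
            db, r$old_version, r$new_version),
    sprintf("For: %s", r$user),
    "")
  rendered <- character(0)
  for (it in r$items) {
    anchor_o <- s$objects[[it$anchor_id]]
    disp <- if (is.null(anchor_o)) it$anchor_id else display_name(anchor_o)
    head <- if (is.null(anchor_o)) disp
            else md_link(disp, expand_url(r$url_template, db, it$anchor_id))
    lines <- c(lines, sprintf("## %s: %s", tolower(it$kind), head))
    if (length(it$new_members))
      lines <- c(lines, sprintf("New members: %s",
                                paste(it$new_members, collapse = ", ")))
    if (length(it$trigger_ids))
      lines <- c(lines, sprintf("Triggered by new citations on: %s",
                                paste(it$trigger_ids, collapse = ", ")))
    fresh <- setdiff(names(it$member_diffs), rendered)
    for (mid in fresh)
      lines <- c(lines, member_bullet(it$member_diffs[[mid]], s,
                                      r$url_template, db))
    dup <- intersect(names(it$member_diffs), rendered)
    if (length(dup))
      lines <- c(lines, sprintf("Also changed (details above): %s",
                                paste(sort(dup), collapse = ", ")))
    rendered <- union(rendered, names(it$member_diffs))
    if (length(it$new_publications))
      lines <- c(lines, sprintf("New publications: %s",
        paste(vapply(it$new_publications, publication_display, "",
                     pub_ix = pub_ix), collapse = "; ")))
    lines <- c(lines, "")
  }
  lines <- c(lines,
             sprintf("Manage or unsubscribe: %s", r$manage_url))
  md <- paste0(paste(lines, collapse = "\n"), "\n")
  if (format == "markdown") md else md_to_html(md)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

## Minimal deterministic markdown -> HTML: headings, bullets, inline links.
md_to_html <- function(md) {
  lines <- strsplit(md, "\n", fixed = TRUE)[[1L]]
  conv <- vapply(lines, function(ln) {
    esc <- html_escape(ln)
    esc <- gsub("\\[([^]]*)\\]\\(([^)]*)\\)", "<a href=\"\\2\">\\1</a>", esc)
    if (startsWith(ln, "## ")) sprintf("<h2>%s</h2>", sub("^## ", "", esc))
    else if (startsWith(ln, "# ")) sprintf("<h1>%s</h1>", sub("^# ", "", esc))
    else if (startsWith(ln, "- ")) sprintf("<li>%s</li>", sub("^- ", "", esc))
    else if (!nzchar(ln)) ""
    else sprintf("<p>%s</p>", esc)
  }, "", USE.NAMES = FALSE)
  paste0("<html><body>\n", paste(conv, collapse = "\n"), "\n</body></html>\n")
}

sanitize_user <- function(user) gsub("[^A-Za-z0-9._-]", "_", user)

#' Write rendered reports plus machine-readable sidecars
#'
#' One `<user>__<database>.md` (or `.html`) per report, plus a `.json`
#' sidecar summarizing the items for downstream tooling and tests.
#'
#' @param reports List from [build_reports()].
#' @param outdir Output directory (created if needed).
#' @param format `"markdown"` or `"html"`.
#' @return Invisibly, character vector of digest file paths.
#' @export
write_reports <- function(reports, outdir, format = c("markdown", "html")) {
  format <- match.arg(format)
  ext <- if (format == "markdown") ".md" else ".html"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in reports) {
    stem <- file.path(outdir, paste0(sanitize_user(r$user), "__", r$database_id))
    path <- paste0(stem, ext)
    writeLines(render_report(r, format), path, sep = "")
    side <- lapply(r$items, function(it) list(
      kind = it$kind, target = it$target_id, mode = it$mode,
      anchor = it$anchor_id,
      triggers = as.list(it$trigger_ids),
      new_members = as.list(it$new_members),
      changed_members = as.list(names(it$member_diffs)),
      new_publications = as.list(it$new_publications)))
    jsonlite::write_json(
      list(user = r$user, database = r$database_id,
           old_version = r$old_version, new_version = r$new_version,
           items = side),
      paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
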