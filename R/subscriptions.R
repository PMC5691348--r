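## Subscription registry.  A registry is a plain data.frame with columns
## user / database / kind / target / mode, one row per subscription, kept
## unique on the full tuple.  TSV persistence keeps the registry diff-able
## and editable in a spreadsheet, which suits curator workflows better
## than JSON.

SUB_KINDS <- c("GENE", "PATHWAY", "GO-TERM", "PATHWAY-CLASS")
TERM_MODES <- c("NEW-MEMBERS", "MEMBER-CHANGES")

#' Construct a subscription
#'
#' Gene and pathway subscriptions have no mode (stored as `"NONE"`);
#' GO-term and pathway-class subscriptions must choose `"NEW-MEMBERS"`
#' (notify when the term gains members) or `"MEMBER-CHANGES"` (apply the
#' gene/pathway change criteria to every current member).
#'
#' @param user Email-like user identifier.
#' @param database Database the target belongs to (targets are always
#'   scoped to one database).
#' @param kind One of `"GENE"`, `"PATHWAY"`, `"GO-TERM"`, `"PATHWAY-CLASS"`.
#' @param target Target object id.
#' @param mode Term mode; defaults to `"NONE"` which is only valid for
#'   gene/pathway kinds.
#' @return One-row registry data.frame.
#' @export
subscription <- function(user, database, kind, target, mode = "NONE") {
  if (!kind %in% SUB_KINDS)
    stop_validation("unknown subscription kind: %s", kind)
  if (kind %in% c("GENE", "PATHWAY")) {
    if (!identical(mode, "NONE"))
      stop_validation("%s subscriptions take no mode (got %s)", kind, mode)
  } else if (!mode %in% TERM_MODES) {
    stop_validation("%s subscriptions need mode NEW-MEMBERS or MEMBER-CHANGES (got %s)",
                    kind, mode)
  }
  if (!nzchar(user) || !nzchar(database) || !nzchar(target))
    stop_validation("user, database and target must be non-empty")
  data.frame(user = user, database = database, kind = kind,
             target = target, mode = mode, stringsAsFactors = FALSE)
}

#' An empty subscription registry
#' @return Zero-row registry data.frame.
#' @export
empty_registry <- function() {
  data.frame(user = character(0), database = character(0),
             kind = character(0), target = character(0),
             mode = character(0), stringsAsFactors = FALSE)
}

sub_key <- function(r) {
  paste(r$user, r$database, r$kind, r$target, r$mode, sep = "\x1f")
}

#' Add a subscription to a registry
#'
#' Idempotent: re-adding an existing entry leaves the registry unchanged.
#'
#' @param r Registry data.frame.
#' @param s A [subscription()] (or any one-row registry).
#' @return Updated registry.
#' @export
subscribe <- function(r, s) {
  s <- subscription(s$user, s$database, s$kind, s$target, s$mode)
  if (sub_key(s) %in% sub_key(r)) return(r)
  rbind(r, s)
}

#' Remove a subscription from a registry
#'
#' Removing an absent entry is a no-op.
#'
#' @inheritParams subscribe
#' @return Updated registry.
#' @export
unsubscribe <- function(r, s) {
  r[sub_key(r) != sub_key(s), , drop = FALSE]
}

#' Subscribe one user to a list of ids in bulk
#'
#' Stand-in for subscribing to the contents of a stored object table:
#' every distinct id becomes one gene or pathway subscription.
#'
#' @param r Registry.
#' @param user,database As in [subscription()].
#' @param kind `"GENE"` or `"PATHWAY"` (term kinds need a mode and are not
#'   bulk-subscribable).
#' @param ids Character vector of target ids; duplicates collapse.
#' @return Updated registry.
#' @export
bulk_subscribe <- function(r, user, database, kind, ids) {
  if (!kind %in% c("GENE", "PATHWAY"))
    stop_validation("bulk subscription requires kind GENE or PATHWAY (got %s)", kind)
  for (id in unique(ids))
    r <- subscribe(r, subscription(user, database, kind, id))
  r
}

#' Load a subscription registry from TSV
#'
#' Expected header: `user<TAB>database<TAB>kind<TAB>target<TAB>mode`, with
#' `-` in the mode column for gene/pathway rows.
#'
#' @param path TSV file path.
#' @return Registry data.frame.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop_usage("no such registry file: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("user", "database", "kind", "target", "mode")
  if (!identical(names(df), need))
    stop_parse("registry %s: expected columns %s", path,
               paste(need, collapse = ", "))
  r <- empty_registry()
  for (i in seq_len(nrow(df))) {
    mode <- if (df$mode[i] == "-") "NONE" else df$mode[i]
    s <- tryCatch(
      subscription(df$user[i], df$database[i], df$kind[i], df$target[i], mode),
      error = function(e)
        stop_validation("registry %s row %d: %s", path, i, conditionMessage(e)))
    r <- subscribe(r, s)
  }
  r
}

#' Save a subscription registry to TSV
#'
#' @param r Registry.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_registry <- function(r, path) {
  out <- r
  out$mode[out$mode == "NONE"] <- "-"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
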