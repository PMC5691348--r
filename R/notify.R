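## The significance filter.  Curators do not make significant changes
## without citing a publication, so a gene or pathway subscription fires
## iff at least one member of its interest closure carries a genuinely new
## citation.  Everything else -- typo fixes, rewordings, merges, deletions,
## annotation removals -- is detectable as a diff but silent.

new_item <- function(sub, anchor_id, trigger_ids, member_diffs,
                     new_publications, new_members = character(0)) {
  structure(list(
    user = sub$user, database_id = sub$database, kind = sub$kind,
    target_id = sub$target, mode = sub$mode, anchor_id = anchor_id,
    trigger_ids = sort(trigger_ids),
    member_diffs = member_diffs[order(names(member_diffs))],
    new_publications = sort(new_publications),
    new_members = sort(new_members)),
    class = "notification_item")
}

#' Evaluate a gene or pathway subscription
#'
#' Computes the subscription's interest closure on the *new* snapshot (the
#' current structure defines the current interests) and fires iff any
#' closure member's diff carries a non-empty new-citation set.  When it
#' fires, all non-trivial diffs of closure members are gathered as
#' evidence -- the citation tells us something significant happened, but
#' not which field change it belongs to, so the digest shows everything.
#'
#' @param sub One-row registry ([subscription()]), kind GENE or PATHWAY.
#' @param old,new The two releases.
#' @param d Their [diff_snapshot()].
#' @param config Relation configuration.
#' @param index Precomputed [snapshot_index()] of `new`.
#' @param cache Optional environment memoizing closures per anchor, so that
#'   overlapping subscriptions (and term modes iterating over members)
#'   never recompute the same closure within one run.
#' @return A `notification_item`, or `NULL` when nothing fired (including
#'   when the anchor no longer exists, which logs a warning).
#' @export
evaluate_gene_or_pathway <- function(sub, old, new, d,
                                     config = relation_config(),
                                     index = snapshot_index(new),
                                     cache = NULL) {
  stopifnot(sub$kind %in% c("GENE", "PATHWAY"))
  if (is.null(new$objects[[sub$target]])) {
    pgdb_log("warn", "subscription target %s absent from release %s of %s%s",
             sub$target, new$version, new$database_id,
             if (sub$target %in% names(new$merges))
               sprintf(" (merged into %s)", new$merges[[sub$target]]) else "")
    return(NULL)
  }
  ckey <- paste0(sub$kind, "\x1f", sub$target)
  cl <- if (!is.null(cache)) cache[[ckey]]
  if (is.null(cl)) {
    cl <- if (sub$kind == "GENE") gene_closure(new, sub$target, config, index)
          else pathway_closure(new, sub$target, config, index)
    if (!is.null(cache)) assign(ckey, cl, envir = cache)
  }
  member_diffs <- d$diffs[intersect(cl$members, names(d$diffs))]
  triggers <- names(member_diffs)[vapply(member_diffs, function(od)
    length(od$new_citations) > 0L, NA)]
  if (!length(triggers)) return(NULL)
  pubs <- unique(unlist(lapply(member_diffs[triggers], `[[`, "new_citations"),
                        use.names = FALSE))
  new_item(sub, sub$target, triggers, member_diffs, pubs)
}

#' Evaluate a GO-term or pathway-class subscription
#'
#' `NEW-MEMBERS` mode fires iff the term gained members between releases
#' (computed under the true-path rule on both snapshots); losing members
#' -- e.g. deletion of an obsolete annotation -- never fires.
#' `MEMBER-CHANGES` mode applies the gene/pathway citation criteria to
#' every current member and fires iff any of them fires, aggregating their
#' closure diffs.
#'
#' @inheritParams evaluate_gene_or_pathway
#' @param old_index Precomputed [snapshot_index()] of `old`.
#' @return A `notification_item` or `NULL`.
#' @export
evaluate_term <- function(sub, old, new, d, config = relation_config(),
                          index = snapshot_index(new),
                          old_index = snapshot_index(old), cache = NULL) {
  stopifnot(sub$kind %in% c("GO-TERM", "PATHWAY-CLASS"))
  in_new <- !is.null(new$objects[[sub$target]])
  in_old <- !is.null(old$objects[[sub$target]])
  if (!in_new && !in_old) {
    pgdb_log("warn", "term %s unknown in both releases of %s",
             sub$target, new$database_id)
    return(NULL)
  }
  tm <- function(s, ix, tag) {
    key <- paste0("TM", tag, "\x1f", sub$kind, "\x1f", sub$target)
    m <- if (!is.null(cache)) cache[[key]]
    if (is.null(m)) {
      m <- term_members(s, sub$target, sub$kind, ix)
      if (!is.null(cache)) assign(key, m, envir = cache)
    }
    m
  }
  members_new <- if (in_new) tm(new, index, "new") else character(0)
  if (sub$mode == "NEW-MEMBERS") {
    members_old <- if (in_old) tm(old, old_index, "old") else character(0)
    gained <- setdiff(members_new, members_old)
    if (!length(gained)) return(NULL)
    gained_diffs <- d$diffs[intersect(gained, names(d$diffs))]
    return(new_item(sub, sub$target, character(0), gained_diffs,
                    character(0), new_members = gained))
  }
  ## MEMBER-CHANGES: each member behaves like its own gene/pathway sub
  member_kind <- if (sub$kind == "GO-TERM") "GENE" else "PATHWAY"
  triggers <- character(0); member_diffs <- list(); pubs <- character(0)
  for (m in members_new) {
    msub <- subscription(sub$user, sub$database, member_kind, m)
    it <- evaluate_gene_or_pathway(msub, old, new, d, config, index, cache)
    if (is.null(it)) next
    triggers <- union(triggers, it$trigger_ids)
    pubs <- union(pubs, it$new_publications)
    member_diffs[names(it$member_diffs)] <- it$member_diffs
  }
  if (!length(triggers)) return(NULL)
  new_item(sub, sub$target, triggers, member_diffs, pubs)
}

#' Evaluate every subscription in a registry against a release pair
#'
#' Entries for other databases are skipped.  Output order is
#' deterministic: user, then kind, then target id.  Comparing a release
#' with itself yields an empty list for any registry.
#'
#' @param reg Registry data.frame.
#' @param old,new Snapshots sharing a `database_id`.
#' @param config Relation configuration.
#' @param d Optional precomputed [diff_snapshot()] (computed if missing).
#' @return List of `notification_item`s.
#' @export
run_notifications <- function(reg, old, new, config = relation_config(),
                              d = NULL) {
  if (!identical(old$database_id, new$database_id))
    stop_usage("snapshots belong to different databases (%s vs %s)",
               old$database_id, new$database_id)
  reg <- reg[reg$database == new$database_id, , drop = FALSE]
  if (!nrow(reg)) return(list())
  reg <- reg[order(reg$user, reg$kind, reg$target, reg$mode), , drop = FALSE]
  if (is.null(d)) d <- diff_snapshot(old, new)
  if (!length(d$diffs)) return(list())
  index <- snapshot_index(new)
  old_index <- NULL
  cache <- new.env(parent = emptyenv())
  items <- list()
  for (i in seq_len(nrow(reg))) {
    sub <- reg[i, , drop = FALSE]
    it <- if (sub$kind %in% c("GENE", "PATHWAY")) {
      evaluate_gene_or_pathway(sub, old, new, d, config, index, cache)
    } else {
      if (is.null(old_index)) old_index <- snapshot_index(old)
      evaluate_term(sub, old, new, d, config, index, old_index, cache)
    }
    if (!is.null(it)) items[[length(items) + 1L]] <- it
  }
  pgdb_log("info", "%d of %d subscriptions fired for %s %s -> %s",
           length(items), nrow(reg), new$database_id,
           old$version, new$version)
  items
}
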