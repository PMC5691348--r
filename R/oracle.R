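## Independent ground-truth oracle.  Everything here is deliberately
## naive: closures by repeat-until-no-growth scans over the whole object
## table, term membership by exhaustive DAG walking, triggering by raw set
## algebra on citation keys.  It shares no code with the closure, diff or
## notify modules, so agreement between the two routes is meaningful
## evidence that the production pipeline is correct.

oracle_new_citations <- function(old, new) {
  out <- list()
  for (id in names(new$objects)) {
    cits <- citations_of(new$objects[[id]])
    if (!length(cits)) next
    prior <- character(0)
    if (!is.null(old$objects[[id]]))
      prior <- citations_of(old$objects[[id]])
    for (src in names(new$merges)[new$merges == id]) {
      so <- old$objects[[src]]
      if (!is.null(so)) prior <- c(prior, citations_of(so))
    }
    fresh <- setdiff(cits, prior)
    if (length(fresh)) out[[id]] <- fresh
  }
  out
}

#' Naive fixed-point gene closure (oracle)
#'
#' Reference implementation by exhaustive re-scanning: apply the relation
#' rules to every member against every object until the member set stops
#' growing.  Used only to validate [gene_closure()].
#'
#' @param s A [snapshot()].
#' @param gene_id Anchor gene id.
#' @return Sorted character vector of member ids.
#' @export
oracle_gene_closure <- function(s, gene_id) {
  members <- gene_id
  repeat {
    grown <- members
    for (m in members) {
      o <- s$objects[[m]]
      if (is.null(o)) next
      if ("GENE" %in% o$classes)
        grown <- c(grown, slot_values_of(o, "PRODUCT"))
      if (any(c("PROTEIN", "COMPLEX") %in% o$classes)) {
        grown <- c(grown, slot_values_of(o, "COMPONENT-OF"))
        grown <- c(grown, slot_values_of(o, "CATALYZES"))
      }
      if ("ENZYMATIC-REACTION" %in% o$classes)
        grown <- c(grown, slot_values_of(o, "REACTION"))
      if ("REACTION" %in% o$classes)
        grown <- c(grown, slot_values_of(o, "IN-PATHWAY"))
    }
    for (id in names(s$objects)) {
      o <- s$objects[[id]]
      if ("REGULATION" %in% o$classes &&
          any(slot_values_of(o, "REGULATED-ENTITY") %in% members))
        grown <- c(grown, id)
      if ("TRANSCRIPTION-UNIT" %in% o$classes &&
          gene_id %in% slot_values_of(o, "GENES"))
        grown <- c(grown, id)
    }
    grown <- intersect(unique(grown), names(s$objects))
    if (length(grown) == length(members)) break
    members <- grown
  }
  sort(members)
}

#' Naive fixed-point pathway closure (oracle)
#'
#' @inheritParams oracle_gene_closure
#' @param pathway_id Anchor pathway id.
#' @return Sorted character vector of member ids.
#' @export
oracle_pathway_closure <- function(s, pathway_id) {
  members <- pathway_id
  repeat {
    grown <- members
    for (m in members) {
      o <- s$objects[[m]]
      if (is.null(o)) next
      if ("PATHWAY" %in% o$classes)
        grown <- c(grown, slot_values_of(o, "REACTION-LIST"))
      if ("REACTION" %in% o$classes)
        grown <- c(grown, slot_values_of(o, "LEFT"),
                   slot_values_of(o, "RIGHT"))
      if ("COMPLEX" %in% o$classes)
        grown <- c(grown, slot_values_of(o, "COMPONENTS"))
      if ("PROTEIN" %in% o$classes)
        grown <- c(grown, slot_values_of(o, "GENE"))
    }
    for (id in names(s$objects)) {
      o <- s$objects[[id]]
      if ("ENZYMATIC-REACTION" %in% o$classes &&
          any(slot_values_of(o, "REACTION") %in% members))
        grown <- c(grown, id)
      if (any(c("PROTEIN", "COMPLEX") %in% o$classes) &&
          any(slot_values_of(o, "CATALYZES") %in% members))
        grown <- c(grown, id)
      if ("REGULATION" %in% o$classes &&
          any(slot_values_of(o, "REGULATED-ENTITY") %in% members))
        grown <- c(grown, id)
    }
    grown <- intersect(unique(grown), names(s$objects))
    if (length(grown) == length(members)) break
    members <- grown
  }
  sort(members)
}

oracle_term_members <- function(s, term_id, kind) {
  node_class <- kind
  annot_slot <- if (kind == "GO-TERM") "GO-TERMS" else "TYPES"
  member_class <- if (kind == "GO-TERM") "GENE" else "PATHWAY"
  if (is.null(s$objects[[term_id]])) return(character(0))
  desc <- term_id
  repeat {
    grown <- desc
    for (id in names(s$objects)) {
      o <- s$objects[[id]]
      if (node_class %in% o$classes &&
          any(slot_values_of(o, "PARENTS") %in% desc))
        grown <- c(grown, id)
    }
    grown <- unique(grown)
    if (length(grown) == length(desc)) break
    desc <- grown
  }
  out <- character(0)
  for (id in names(s$objects)) {
    o <- s$objects[[id]]
    if (member_class %in% o$classes &&
        any(slot_values_of(o, annot_slot) %in% desc))
      out <- c(out, id)
  }
  sort(out)
}

#' Ground-truth firing set for a registry (oracle)
#'
#' For every subscription, decides by brute force whether it must fire for
#' the given release pair: objects with genuinely new citations are found
#' by raw set difference (merge sources subtracted), gene/pathway
#' subscriptions fire iff their naive closure intersects that set, term
#' subscriptions per their mode.  Independent of the production pipeline.
#'
#' @param reg Registry data.frame.
#' @param old,new Release pair.
#' @return Character vector of firing subscription keys
#'   `"user|database|kind|target|mode"`, sorted.
#' @export
oracle_firings <- function(reg, old, new) {
  fresh <- names(oracle_new_citations(old, new))
  fired <- character(0)
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, , drop = FALSE]
    if (r$database != new$database_id) next
    fires <- switch(r$kind,
      "GENE" = !is.null(new$objects[[r$target]]) &&
        length(intersect(oracle_gene_closure(new, r$target), fresh)) > 0L,
      "PATHWAY" = !is.null(new$objects[[r$target]]) &&
        length(intersect(oracle_pathway_closure(new, r$target), fresh)) > 0L,
      {
        m_new <- oracle_term_members(new, r$target, r$kind)
        if (r$mode == "NEW-MEMBERS") {
          m_old <- oracle_term_members(old, r$target, r$kind)
          length(setdiff(m_new, m_old)) > 0L
        } else {
          any(vapply(m_new, function(m) {
            cl <- if (r$kind == "GO-TERM") oracle_gene_closure(new, m)
                  else oracle_pathway_closure(new, m)
            length(intersect(cl, fresh)) > 0L
          }, NA))
        }
      })
    if (isTRUE(fires))
      fired <- c(fired, paste(r$user, r$database, r$kind, r$target, r$mode,
                              sep = "|"))
  }
  sort(unique(fired))
}

#' Firing keys of a notification run, comparable to [oracle_firings()]
#'
#' @param items List of `notification_item`s from [run_notifications()].
#' @return Sorted character vector of `"user|database|kind|target|mode"`.
#' @export
firing_keys <- function(items) {
  sort(unique(vapply(items, function(it)
    paste(it$user, it$database_id, it$kind, it$target_id, it$mode,
          sep = "|"), "")))
}
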