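## Interest closures.  A gene or pathway subscription implicitly covers a
## whole neighbourhood of functionally related objects; the closure module
## materializes that neighbourhood by running a configurable relation set
## to a fixed point, and resolves ontology-term subscriptions (GO terms,
## pathway classes) to their member sets under the true-path rule.

#' Default interest-closure relation configuration
#'
#' Reads the relation sets shipped with the package (see
#' `inst/extdata/relations.yaml`): for genes, product / complex membership
#' (transitive) / catalytic activities / reactions / containing pathways
#' plus regulation and transcription units; for pathways, reaction list
#' (sub-pathways recursive) / substrates / activities / enzymes down to
#' monomers and their genes plus regulation.
#'
#' @param path Optional path to an alternative YAML relation file, for
#'   schemas that use different slot names.
#' @return Nested list keyed by closure type.
#' @export
relation_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "relations.yaml", package = "pgdbwatch",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Build lookup indexes for a snapshot
#'
#' Precomputes class membership and a reverse reference index
#' (slot, value) -> referring object ids so that closure expansion and
#' notification evaluation run in time proportional to the edges touched,
#' not to snapshot size.  Pure function of the snapshot; callers may cache.
#'
#' @param s A [snapshot()].
#' @return List with `by_class` (env: class -> ids) and `ref`
#'   (env: "SLOT\\x1fvalue" -> ids).
#' @export
snapshot_index <- function(s) {
  by_class <- new.env(parent = emptyenv())
  ref <- new.env(parent = emptyenv())
  for (o in s$objects) {
    for (cl in o$classes)
      assign(cl, c(by_class[[cl]], o$id), envir = by_class)
    for (sn in names(o$slots)) {
      for (v in o$slots[[sn]]) {
        key <- paste0(sn, "\x1f", v$value)
        assign(key, c(ref[[key]], o$id), envir = ref)
      }
    }
  }
  list(by_class = by_class, ref = ref)
}

## Worklist fixed point over the configured relation set.  Forward rules
## expand a member's own slots; reverse rules use the reference index to
## find objects pointing at a member.  Cycle-safe because membership is a
## set and each object is enqueued at most once.
closure_expand <- function(s, anchor_id, rules, index = snapshot_index(s)) {
  if (is.null(s$objects[[anchor_id]]))
    stop_resolution("object %s not found in snapshot %s", anchor_id, s$database_id)
  fwd <- rules$forward %||% list()
  rev <- rules$reverse %||% list()
  members <- new.env(parent = emptyenv())
  prov <- list()
  assign(anchor_id, TRUE, envir = members)
  prov[[anchor_id]] <- list()
  queue <- anchor_id
  add <- function(id, from, relation) {
    if (is.null(s$objects[[id]])) return(invisible(NULL))  # dangling ref
    if (!is.null(members[[id]])) return(invisible(NULL))
    assign(id, TRUE, envir = members)
    prov[[id]] <<- c(prov[[from]], list(list(relation = relation, id = id)))
    queue <<- c(queue, id)
    invisible(NULL)
  }
  while (length(queue)) {
    m <- queue[[1L]]; queue <- queue[-1L]
    o <- s$objects[[m]]
    for (r in fwd) {
      if (!any(r$classes %in% o$classes)) next
      for (v in slot_values_of(o, r$slot)) add(v, m, r$slot)
    }
    for (r in rev) {
      if (isTRUE(r$anchor_only) && !identical(m, anchor_id)) next
      hits <- index$ref[[paste0(r$slot, "\x1f", m)]]
      for (h in hits) {
        if (!any(r$classes %in% s$objects[[h]]$classes)) next
        add(h, m, paste0("<-", r$slot))
      }
    }
  }
  ids <- sort(ls(members))
  structure(list(anchor_id = anchor_id, members = ids, provenance = prov[ids]),
            class = "closure_result")
}

#' Interest closure of a gene
#'
#' Fixed point over: gene to product, protein/complex to containing
#' complexes (transitively), catalytic activities, their reactions, and
#' pathways containing those reactions (pathways are included as members
#' but never expanded, so one gene does not transitively cover the
#' database); plus every regulation object whose regulated entity is a
#' member and every transcription unit listing the gene, together with
#' regulation of that unit.
#'
#' @param s A [snapshot()]; the closure reflects this release's structure.
#' @param gene_id Gene object id; must exist in `s`.
#' @param config Relation configuration, see [relation_config()].
#' @param index Optional precomputed [snapshot_index()].
#' @return A `closure_result`: `anchor_id`, sorted `members`, and a
#'   `provenance` path (list of relation/id steps) per member.
#' @export
gene_closure <- function(s, gene_id, config = relation_config(),
                         index = snapshot_index(s)) {
  closure_expand(s, gene_id, config$gene, index)
}

#' Interest closure of a pathway
#'
#' The pathway, its reactions (sub-pathways in the reaction list expanded
#' recursively), the reactions' substrates and products, the activities
#' catalyzing them, the enzymes behind those activities with complexes
#' decomposed transitively to monomers, the monomers' genes, and every
#' regulation object targeting any member.
#'
#' @inheritParams gene_closure
#' @param pathway_id Pathway object id; must exist in `s`.
#' @return A `closure_result`.
#' @export
pathway_closure <- function(s, pathway_id, config = relation_config(),
                            index = snapshot_index(s)) {
  closure_expand(s, pathway_id, config$pathway, index)
}

#' @export
print.closure_result <- function(x, ...) {
  cat(sprintf("<closure of %s: %d members>\n", x$anchor_id, length(x$members)))
  invisible(x)
}

## Descendants of an ontology node (nodes whose PARENTS chain reaches it),
## with cycle detection.  children(t) = nodes of node_class whose PARENTS
## slot names t.
ontology_descendants <- function(s, term_id, node_class, index) {
  state <- new.env(parent = emptyenv())  # 1 = on stack, 2 = done
  out <- character(0)
  walk <- function(t) {
    st <- state[[t]]
    if (identical(st, 1L))
      stop_ontology("cycle in PARENTS hierarchy at %s", t)
    if (identical(st, 2L)) return(invisible(NULL))
    assign(t, 1L, envir = state)
    out <<- c(out, t)
    for (ch in index$ref[[paste0("PARENTS", "\x1f", t)]]) {
      if (!node_class %in% s$objects[[ch]]$classes) next
      walk(ch)
    }
    assign(t, 2L, envir = state)
    invisible(NULL)
  }
  walk(term_id)
  out
}

#' Members of a GO term or pathway class
#'
#' Under the true-path rule an annotation to a term counts for all its
#' ancestors, so membership is computed over the term and every descendant
#' in the is-a DAG: for GO terms, genes whose `GO-TERMS` slot names the
#' term or a descendant; for pathway classes, pathways whose `TYPES` chain
#' reaches the class through `PARENTS` links.
#'
#' @inheritParams gene_closure
#' @param term_id GO-term or pathway-class object id; must exist in `s`.
#' @param kind `"GO-TERM"` or `"PATHWAY-CLASS"`.
#' @return Sorted character vector of member object ids.
#' @export
term_members <- function(s, term_id, kind = c("GO-TERM", "PATHWAY-CLASS"),
                         index = snapshot_index(s)) {
  kind <- match.arg(kind)
  if (is.null(s$objects[[term_id]]))
    stop_resolution("term %s not found in snapshot %s", term_id, s$database_id)
  annot_slot <- if (kind == "GO-TERM") "GO-TERMS" else "TYPES"
  member_class <- if (kind == "GO-TERM") "GENE" else "PATHWAY"
  terms <- ontology_descendants(s, term_id, kind, index)
  hits <- unlist(lapply(terms, function(t)
    index$ref[[paste0(annot_slot, "\x1f", t)]]), use.names = FALSE)
  hits <- unique(hits)
  keep <- vapply(hits, function(id)
    member_class %in% s$objects[[id]]$classes, NA)
  sort(hits[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
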