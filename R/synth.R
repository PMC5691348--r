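## Seeded synthetic PGDB fixtures.  generate_base() builds a schema-valid
## snapshot with connected gene -> product -> complex -> activity ->
## reaction -> pathway chains, regulation, transcription units, a GO DAG
## with gene annotations, a pathway-class tree and publication records.
## make_edit_script()/apply_edit_script() derive a second release from it
## by simulated curation, covering every triggering and every excluded
## edit kind, so the notification pipeline can be validated against ground
## truth computed by the independent oracle (see oracle_firings()).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

EDIT_KINDS <- c("ADD-CITATION", "TYPO", "REWORD-SUMMARY", "MERGE",
                "DELETE-OBJECT", "ADD-GO-ANNOTATION", "REMOVE-GO-ANNOTATION",
                "NEW-OBJECT-WITH-CITATION", "NEW-OBJECT-NO-CITATION")

#' Generate a synthetic base snapshot
#'
#' Emulates the object neighbourhood a real curated PGDB release carries:
#' each gene has a product; products assemble into complexes (nested up to
#' `complex_depth`, with occasional component-of cycles so traversal code
#' is exercised on degenerate graphs); enzymes catalyze activities linked
#' to reactions with substrate compounds; reactions sit in pathways typed
#' against a pathway-class tree, with occasional sub-pathways; genes are
#' annotated into a small GO DAG; transcription units and regulation
#' objects tie back into the graph; publications back the citation tokens.
#' Identifiers are human-readable (`G0001`, `PWY-0002`, `GO:0000003`) so
#' failing comparisons stay debuggable.  The same seed always yields the
#' identical snapshot.
#'
#' @param n_genes,n_pathways,n_terms Positive counts of genes, pathways
#'   and GO terms.
#' @param complex_depth Maximum nesting depth of protein complexes.
#' @param seed Integer seed controlling all randomness.
#' @param database_id,version Snapshot labels.
#' @return A [snapshot()].
#' @export
generate_base <- function(n_genes = 12, complex_depth = 2, n_pathways = 3,
                          n_terms = 6, seed = 1,
                          database_id = "SYNCYC", version = "1.0") {
  stopifnot(n_genes >= 1, n_pathways >= 1, n_terms >= 1, complex_depth >= 1)
  with_seed(seed, {
    objs <- list()
    add <- function(o) objs[[length(objs) + 1L]] <<- o

    n_pubs <- n_genes + 10L
    pub_ids <- sprintf("PUB-%d", 1000L + seq_len(n_pubs))
    pmids <- as.character(1000L + seq_len(n_pubs))
    cite <- function(k) paste0("PMID:", pmids[[k]])
    for (k in seq_len(n_pubs))
      add(db_object(pub_ids[[k]], types = "PUBLICATION", slots = list(
        PMID = pmids[[k]],
        AUTHORS = sprintf("Author%02d A", k),
        YEAR = as.character(1990L + (k %% 30L)),
        TITLE = sprintf("Study %d of the synthetic organism", k))))

    ## GO DAG: term i > 1 gets 1-2 parents among earlier terms
    go_ids <- sprintf("GO:%07d", seq_len(n_terms))
    for (i in seq_len(n_terms)) {
      slots <- list(`COMMON-NAME` = sprintf("process %d", i))
      if (i > 1L) {
        np <- sample(1:min(2L, i - 1L), 1L)
        slots[["PARENTS"]] <- sample(go_ids[seq_len(i - 1L)], np)
      }
      add(db_object(go_ids[[i]], types = "GO-TERM", slots = slots))
    }

    ## pathway-class tree
    n_classes <- max(2L, ceiling(n_pathways / 2L))
    pc_ids <- sprintf("PC-%d", seq_len(n_classes))
    for (i in seq_len(n_classes)) {
      slots <- list(`COMMON-NAME` = sprintf("pathway class %d", i))
      if (i > 1L)
        slots[["PARENTS"]] <- sample(pc_ids[seq_len(i - 1L)], 1L)
      add(db_object(pc_ids[[i]], types = "PATHWAY-CLASS", slots = slots))
    }

    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    prot_ids <- sprintf("P%04d", seq_len(n_genes))

    ## complexes over consecutive protein pairs, then nested chains
    cplx_members <- list()   # complex id -> component ids
    comp_of <- stats::setNames(vector("list", n_genes), prot_ids)
    n_cplx <- n_genes %/% 3L
    cplx_ids <- if (n_cplx) sprintf("CPLX-%04d", seq_len(n_cplx)) else character(0)
    for (j in seq_len(n_cplx)) {
      parts <- prot_ids[c(2L * j - 1L, 2L * j)]
      parts <- parts[!is.na(parts) & parts %in% prot_ids]
      cplx_members[[cplx_ids[[j]]]] <- parts
      for (p in parts) comp_of[[p]] <- c(comp_of[[p]], cplx_ids[[j]])
    }
    super_ids <- character(0)
    if (complex_depth > 1L && n_cplx >= 1L) {
      n_super <- max(0L, n_cplx %/% 2L)
      for (j in seq_len(n_super)) {
        depth_chain <- min(complex_depth - 1L, 1L + (j %% complex_depth))
        base <- cplx_ids[[j]]
        for (dk in seq_len(depth_chain)) {
          sid <- sprintf("CPLX-%04d-L%d", j, dk)
          extra <- sample(prot_ids, 1L)
          cplx_members[[sid]] <- c(base, extra)
          comp_of[[extra]] <- c(comp_of[[extra]], sid)
          cplx_members[[base]] <- cplx_members[[base]]  # unchanged
          comp_of[[base]] <- c(comp_of[[base]] %||% character(0), sid)
          super_ids <- c(super_ids, sid)
          base <- sid
        }
      }
    }
    all_cplx <- names(cplx_members)
    ## occasional component-of cycle between two complexes
    if (length(all_cplx) >= 2L && stats::runif(1) < 0.3) {
      ab <- sample(all_cplx, 2L)
      comp_of[[ab[[1L]]]] <- c(comp_of[[ab[[1L]]]] %||% character(0), ab[[2L]])
      comp_of[[ab[[2L]]]] <- c(comp_of[[ab[[2L]]]] %||% character(0), ab[[1L]])
      cplx_members[[ab[[1L]]]] <- c(cplx_members[[ab[[1L]]]], ab[[2L]])
      cplx_members[[ab[[2L]]]] <- c(cplx_members[[ab[[2L]]]], ab[[1L]])
    }

    ## reactions, activities, compounds, pathways
    n_rxns <- max(1L, round(n_genes * 0.7))
    rxn_ids <- sprintf("RXN-%04d", seq_len(n_rxns))
    enz_ids <- sprintf("ENZRXN-%04d", seq_len(n_rxns))
    n_cpds <- n_rxns + 2L
    cpd_ids <- sprintf("CPD-%04d", seq_len(n_cpds))
    for (x in seq_len(n_cpds))
      add(db_object(cpd_ids[[x]], types = "COMPOUND",
                    slots = list(`COMMON-NAME` = sprintf("compound %d", x))))

    catalysts <- stats::setNames(vector("list", n_rxns), enz_ids)
    catalyze_slots <- list()  # catalyst id -> activities
    pwy_of_rxn <- sample(seq_len(n_pathways), n_rxns, replace = TRUE)
    pwy_ids <- sprintf("PWY-%04d", seq_len(n_pathways))
    for (k in seq_len(n_rxns)) {
      cat_pool <- c(prot_ids, all_cplx)
      cat_id <- sample(cat_pool, 1L)
      catalysts[[k]] <- cat_id
      catalyze_slots[[cat_id]] <- c(catalyze_slots[[cat_id]], enz_ids[[k]])
      lhs <- cpd_ids[[1L + (k - 1L) %% n_cpds]]
      rhs <- cpd_ids[[1L + k %% n_cpds]]
      add(db_object(rxn_ids[[k]], types = "REACTION", slots = list(
        LEFT = lhs, RIGHT = rhs, `IN-PATHWAY` = pwy_ids[[pwy_of_rxn[[k]]]])))
      add(db_object(enz_ids[[k]], types = "ENZYMATIC-REACTION", slots = list(
        REACTION = rxn_ids[[k]],
        CITATIONS = cite(sample.int(n_pubs, 1L)))))
    }

    for (m in seq_len(n_pathways)) {
      rl <- rxn_ids[pwy_of_rxn == m]
      ## occasional nested sub-pathway
      if (m > 1L && stats::runif(1) < 0.4)
        rl <- c(rl, pwy_ids[[sample.int(m - 1L, 1L)]])
      if (!length(rl)) rl <- rxn_ids[[1L + (m - 1L) %% n_rxns]]
      add(db_object(pwy_ids[[m]],
                    types = c("PATHWAY", pc_ids[[1L + (m - 1L) %% n_classes]]),
                    slots = list(
                      `COMMON-NAME` = sprintf("pathway %d", m),
                      `REACTION-LIST` = rl,
                      COMMENT = sprintf("Mini-review of pathway %d.", m),
                      CITATIONS = cite(sample.int(n_pubs, 1L)))))
    }

    ## genes and proteins
    for (i in seq_len(n_genes)) {
      n_go <- sample(0:min(2L, n_terms), 1L)
      slots <- list(
        `COMMON-NAME` = sprintf("gene%03d", i),
        COMMENT = sprintf("Mini-review summary for gene %d.", i),
        PRODUCT = prot_ids[[i]],
        CITATIONS = cite(sample.int(n_pubs, 1L)))
      if (n_go > 0L)
        slots[["GO-TERMS"]] <- sample(go_ids, n_go)
      add(db_object(gene_ids[[i]], types = "GENE", slots = slots))
      pslots <- list(`COMMON-NAME` = sprintf("Protein%03d", i),
                     GENE = gene_ids[[i]])
      if (length(comp_of[[prot_ids[[i]]]]))
        pslots[["COMPONENT-OF"]] <- unique(comp_of[[prot_ids[[i]]]])
      if (length(catalyze_slots[[prot_ids[[i]]]]))
        pslots[["CATALYZES"]] <- catalyze_slots[[prot_ids[[i]]]]
      add(db_object(prot_ids[[i]], types = "PROTEIN", slots = pslots))
    }

    for (cid in all_cplx) {
      cslots <- list(`COMMON-NAME` = paste0("complex ", cid),
                     COMPONENTS = unique(cplx_members[[cid]]))
      if (length(comp_of[[cid]]))
        cslots[["COMPONENT-OF"]] <- unique(comp_of[[cid]])
      if (length(catalyze_slots[[cid]]))
        cslots[["CATALYZES"]] <- catalyze_slots[[cid]]
      add(db_object(cid, types = c("PROTEIN", "COMPLEX"), slots = cslots))
    }

    ## transcription units and regulation
    n_tus <- max(1L, ceiling(n_genes / 4L))
    tu_ids <- sprintf("TU-%04d", seq_len(n_tus))
    for (t in seq_len(n_tus))
      add(db_object(tu_ids[[t]], types = "TRANSCRIPTION-UNIT", slots = list(
        GENES = sample(gene_ids, min(length(gene_ids), sample(1:3, 1L))))))
    n_regs <- max(1L, ceiling(n_genes / 3L))
    reg_targets <- c(prot_ids, all_cplx, tu_ids, pwy_ids)
    for (rix in seq_len(n_regs)) {
      slots <- list(`REGULATED-ENTITY` = sample(reg_targets, 1L))
      if (stats::runif(1) < 0.7)
        slots[["CITATIONS"]] <- cite(sample.int(n_pubs, 1L))
      add(db_object(sprintf("REG-%04d", rix), types = "REGULATION",
                    slots = slots))
    }

    snapshot(database_id, version, objs)
  })
}

## ---- edit scripts ------------------------------------------------------

#' Draw a random curation edit script for a snapshot
#'
#' Samples `n_edits` edits of the requested kinds with pairwise-distinct
#' primary targets (a conflicting script, e.g. delete-then-retype one
#' object, is rejected by [apply_edit_script()]).  Fresh citations use
#' PMIDs from 9000 upward so they can never collide with base citations.
#'
#' @param s Base [snapshot()].
#' @param seed Integer seed.
#' @param kinds Subset of the edit-kind taxonomy to draw from.
#' @param n_edits Number of edits.
#' @return An `edit_script` (fields `seed`, `edits`).
#' @export
make_edit_script <- function(s, seed, kinds = EDIT_KINDS, n_edits = 6) {
  stopifnot(all(kinds %in% EDIT_KINDS))
  with_seed(seed, {
    ids_of <- function(cl) objects_of_class(s, cl)
    closure_pool <- unique(c(ids_of("GENE"), ids_of("PROTEIN"), ids_of("COMPLEX"),
                             ids_of("ENZYMATIC-REACTION"), ids_of("REACTION"),
                             ids_of("PATHWAY"), ids_of("REGULATION")))
    named_pool <- closure_pool[vapply(closure_pool, function(id)
      length(slot_values_of(s$objects[[id]], "COMMON-NAME")) > 0L, NA)]
    commented <- closure_pool[vapply(closure_pool, function(id)
      length(slot_values_of(s$objects[[id]], "COMMENT")) > 0L, NA)]
    genes <- ids_of("GENE")
    terms <- ids_of("GO-TERM")
    regs <- ids_of("REGULATION")
    used <- character(0)
    pick <- function(pool, n = 1L) {
      pool <- setdiff(pool, used)
      if (length(pool) < n) return(NULL)
      got <- if (length(pool) == 1L) pool else sample(pool, n)
      used <<- c(used, got)
      got
    }
    edits <- list()
    pmid_next <- 9000L
    newobj_next <- 1L
    for (e in seq_len(n_edits)) {
      kind <- if (length(kinds) == 1L) kinds else sample(kinds, 1L)
      ed <- switch(kind,
        "ADD-CITATION" = {
          t <- pick(closure_pool); if (is.null(t)) next
          pmid_next <- pmid_next + 1L
          list(kind = kind, target = t,
               payload = list(citation = paste0("PMID:", pmid_next),
                              placement = sample(c("slot", "annotation"), 1L),
                              evidence = stats::runif(1) < 0.5))
        },
        "TYPO" = {
          t <- pick(named_pool); if (is.null(t)) next
          list(kind = kind, target = t, payload = list())
        },
        "REWORD-SUMMARY" = {
          t <- pick(commented); if (is.null(t)) next
          list(kind = kind, target = t, payload = list())
        },
        "MERGE" = {
          t <- pick(regs, 2L); if (is.null(t)) next
          list(kind = kind, target = t[[2L]],
               payload = list(absorbed = t[[1L]]))
        },
        "DELETE-OBJECT" = {
          t <- pick(regs); if (is.null(t)) next
          list(kind = kind, target = t, payload = list())
        },
        "ADD-GO-ANNOTATION" = {
          g <- pick(genes); if (is.null(g)) next
          free <- setdiff(terms, slot_values_of(s$objects[[g]], "GO-TERMS"))
          if (!length(free)) next
          list(kind = kind, target = g,
               payload = list(term = if (length(free) == 1L) free
                              else sample(free, 1L)))
        },
        "REMOVE-GO-ANNOTATION" = {
          annotated <- genes[vapply(genes, function(g)
            length(slot_values_of(s$objects[[g]], "GO-TERMS")) > 0L, NA)]
          g <- pick(annotated); if (is.null(g)) next
          have <- slot_values_of(s$objects[[g]], "GO-TERMS")
          list(kind = kind, target = g,
               payload = list(term = if (length(have) == 1L) have
                              else sample(have, 1L)))
        },
        "NEW-OBJECT-WITH-CITATION" = ,
        "NEW-OBJECT-NO-CITATION" = {
          anchor <- sample(c(ids_of("PROTEIN"), ids_of("GENE")), 1L)
          pmid_next <- pmid_next + 1L
          id <- sprintf("REG-NEW-%04d", newobj_next)
          newobj_next <- newobj_next + 1L
          used <<- c(used, id)
          list(kind = kind, target = id,
               payload = list(regulated = anchor,
                              citation = if (kind == "NEW-OBJECT-WITH-CITATION")
                                paste0("PMID:", pmid_next) else NULL))
        })
      if (!is.null(ed)) edits[[length(edits) + 1L]] <- ed
    }
    structure(list(seed = seed, edits = edits), class = "edit_script")
  })
}

## in-place helpers on a plain named list of db_object
ed_append_value <- function(objs, id, slot, value, annotations = list()) {
  o <- objs[[id]]
  sv <- slot_value(value, annotations)
  if (is.null(o$slots[[slot]])) o$slots[[slot]] <- list(sv)
  else o$slots[[slot]] <- c(o$slots[[slot]], list(sv))
  objs[[id]] <- o
  objs
}

ed_remove_value <- function(objs, id, slot, value) {
  o <- objs[[id]]
  vs <- o$slots[[slot]]
  keep <- vapply(vs, function(v) v$value != value, NA)
  ## drop exactly one occurrence
  if (any(!keep)) keep[which(!keep)[-1L]] <- TRUE
  if (!any(keep)) o$slots[[slot]] <- NULL else o$slots[[slot]] <- vs[keep]
  objs[[id]] <- o
  objs
}

ed_scrub_references <- function(objs, dead_id) {
  for (id in names(objs)) {
    o <- objs[[id]]
    changed <- FALSE
    for (sn in names(o$slots)) {
      if (sn %in% c("TYPES", "MERGED-FROM")) next  # provenance may point at dead ids
      vs <- o$slots[[sn]]
      keep <- vapply(vs, function(v) v$value != dead_id, NA)
      if (!all(keep)) {
        o$slots[[sn]] <- if (any(keep)) vs[keep] else NULL
        changed <- TRUE
      }
    }
    if (changed) objs[[id]] <- o
  }
  objs
}

#' Apply an edit script to a snapshot
#'
#' Produces the "new release": the base snapshot with every edit applied.
#' A script touching one object with two edits (or editing a deleted
#' object) is rejected.
#'
#' @param old Base [snapshot()].
#' @param script An `edit_script` from [make_edit_script()].
#' @param version Version label for the new release.
#' @return A [snapshot()].
#' @export
apply_edit_script <- function(old, script, version = "2.0") {
  targets <- vapply(script$edits, `[[`, "", "target")
  absorbed <- unlist(lapply(script$edits, function(e) e$payload$absorbed))
  prim <- c(targets, absorbed)
  if (anyDuplicated(prim))
    pgdb_stop("pgdb_script_error", "conflicting edits on object %s",
              prim[duplicated(prim)][1L])
  objs <- old$objects
  for (e in script$edits) {
    t <- e$target
    if (!startsWith(e$kind, "NEW-OBJECT") && is.null(objs[[t]]))
      pgdb_stop("pgdb_script_error", "edit target %s does not exist", t)
    objs <- switch(e$kind,
      "ADD-CITATION" = {
        tok <- e$payload$citation
        if (isTRUE(e$payload$evidence)) tok <- paste0(tok, ":EV-EXP-IDA")
        if (e$payload$placement == "annotation" &&
            length(objs[[t]]$slots[["COMMENT"]])) {
          o <- objs[[t]]
          o$slots[["COMMENT"]][[1L]]$annotations[["CITATIONS"]] <-
            c(o$slots[["COMMENT"]][[1L]]$annotations[["CITATIONS"]], tok)
          objs[[t]] <- o
          objs
        } else ed_append_value(objs, t, "CITATIONS", tok)
      },
      "TYPO" = {
        o <- objs[[t]]
        v <- o$slots[["COMMON-NAME"]][[1L]]$value
        flipped <- paste0(toupper(substr(v, 1L, 1L)), substring(v, 2L))
        if (flipped == v)
          flipped <- paste0(tolower(substr(v, 1L, 1L)), substring(v, 2L))
        o$slots[["COMMON-NAME"]][[1L]]$value <- flipped
        objs[[t]] <- o
        objs
      },
      "REWORD-SUMMARY" = {
        o <- objs[[t]]
        o$slots[["COMMENT"]][[1L]]$value <-
          paste(o$slots[["COMMENT"]][[1L]]$value, "(revised wording)")
        objs[[t]] <- o
        objs
      },
      "MERGE" = {
        src <- e$payload$absorbed
        so <- objs[[src]]; to <- objs[[t]]
        for (sn in names(so$slots)) {
          if (sn == "TYPES") next
          have <- vapply(to$slots[[sn]] %||% list(), canonical_sv, "")
          for (v in so$slots[[sn]]) {
            if (canonical_sv(v) %in% have) next
            to$slots[[sn]] <- c(to$slots[[sn]] %||% list(), list(v))
          }
        }
        to$slots[["MERGED-FROM"]] <- c(to$slots[["MERGED-FROM"]] %||% list(),
                                       list(slot_value(src)))
        objs[[t]] <- to
        objs[[src]] <- NULL
        ed_scrub_references(objs, src)
      },
      "DELETE-OBJECT" = {
        objs[[t]] <- NULL
        ed_scrub_references(objs, t)
      },
      "ADD-GO-ANNOTATION" = ed_append_value(objs, t, "GO-TERMS", e$payload$term),
      "REMOVE-GO-ANNOTATION" = ed_remove_value(objs, t, "GO-TERMS",
                                               e$payload$term),
      "NEW-OBJECT-WITH-CITATION" = ,
      "NEW-OBJECT-NO-CITATION" = {
        slots <- list(`REGULATED-ENTITY` = e$payload$regulated)
        if (!is.null(e$payload$citation))
          slots[["CITATIONS"]] <- e$payload$citation
        objs[[t]] <- db_object(t, types = "REGULATION", slots = slots)
        objs
      })
  }
  snapshot(old$database_id, version, objs)
}

#' Build a registry covering every subscription kind for a snapshot
#'
#' Spreads subscriptions of all four kinds (and both term modes) over
#' `n_users` users, anchored on randomly chosen objects of the snapshot.
#'
#' @param s A [snapshot()].
#' @param seed Integer seed.
#' @param n_users Number of users.
#' @param n_per_user Approximate subscriptions per user.
#' @return Registry data.frame.
#' @export
sample_registry <- function(s, seed, n_users = 3, n_per_user = 4) {
  with_seed(seed, {
    genes <- objects_of_class(s, "GENE")
    pwys <- objects_of_class(s, "PATHWAY")
    terms <- objects_of_class(s, "GO-TERM")
    pcs <- objects_of_class(s, "PATHWAY-CLASS")
    r <- empty_registry()
    for (u in seq_len(n_users)) {
      user <- sprintf("user%d@example.org", u)
      for (j in seq_len(n_per_user)) {
        kind <- sample(SUB_KINDS, 1L)
        target <- switch(kind,
          "GENE" = sample(genes, 1L), "PATHWAY" = sample(pwys, 1L),
          "GO-TERM" = sample(terms, 1L), "PATHWAY-CLASS" = sample(pcs, 1L))
        mode <- if (kind %in% c("GENE", "PATHWAY")) "NONE"
                else sample(TERM_MODES, 1L)
        r <- subscribe(r, subscription(user, s$database_id, kind, target, mode))
      }
    }
    r
  })
}
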