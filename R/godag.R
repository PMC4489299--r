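# Gene Ontology DAG: OBO parsing, ancestor closure, confidence
# propagation and per-protein merging of annotation sets.
#
# Annotation semantics follow the GO consortium convention: annotation
# on a term implies annotation on all its is_a and part_of ancestors, so
# confidence scores are pushed to every ancestor, each term keeping the
# maximum score it receives.  Propagation never crosses namespaces.

OBO_NAMESPACES <- c(molecular_function = "MFO",
                    biological_process = "BPO",
                    cellular_component = "CCO")

#' Parse an OBO 1.2 ontology file
#'
#' Loads term stanzas with their `is_a` and `relationship: part_of`
#' edges, maps `alt_id`s to primary ids and flags obsolete terms.
#' Edges whose endpoints lie in different namespaces are dropped.
#' The graph is validated to be acyclic.
#'
#' @param path OBO file.
#' @return an object of class `GODag` with elements `terms` (data frame
#'   `id`, `name`, `namespace`, `obsolete`), `parents` (named list,
#'   child id to parent ids), `alt` (named vector alt id to primary id)
#'   and `roots` (named by namespace).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- names <- namespaces <- character(0)
  obsolete <- logical(0)
  parents <- list()
  alt <- character(0)
  other_starts <- which(startsWith(lines, "[") & lines != "[Term]")
  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[k] + 1L
    to <- bounds[k + 1L] - 1L
    nxt <- other_starts[other_starts > stanza_starts[k]]
    if (length(nxt) && nxt[1] <= to) to <- nxt[1] - 1L
    if (to < from) next
    block <- lines[from:to]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "",
               grep(paste0("^", key, ": "), block, value = TRUE))
      sub(" *!.*$", "", v)
    }
    id <- get1("id")
    if (length(id) == 0L) next
    id <- id[1]
    nm <- get1("name")
    ns <- get1("namespace")
    if (length(ns) == 0L) {
      stop("term ", id, " has no namespace")
    }
    ids <- c(ids, id)
    names <- c(names, if (length(nm)) nm[1] else "")
    namespaces <- c(namespaces, ns[1])
    obsolete <- c(obsolete, any(grepl("^is_obsolete: *true", block)))
    isa <- get1("is_a")
    rel <- grep("^relationship: *part_of ", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", rel))
    parents[[id]] <- unique(c(isa, po))
    for (a in get1("alt_id")) alt[a] <- id
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in ", path)
  nsmap <- unname(OBO_NAMESPACES[namespaces])
  nsmap[is.na(nsmap)] <- namespaces[is.na(nsmap)]
  terms <- data.frame(id = ids, name = names, namespace = nsmap,
                      obsolete = obsolete, stringsAsFactors = FALSE)
  # drop edges to unknown terms or across namespaces
  ns_of <- stats::setNames(terms$namespace, terms$id)
  parents <- stats::setNames(lapply(ids, function(id) {
    p <- parents[[id]]
    p <- p[p %in% ids]
    p[ns_of[p] == ns_of[id]]
  }), ids)

  edge_df <- do.call(rbind, lapply(ids, function(id) {
    if (length(parents[[id]]) == 0L) return(NULL)
    cbind(id, parents[[id]])
  }))
  if (!is.null(edge_df) && nrow(edge_df) > 0L) {
    g <- igraph::graph_from_edgelist(edge_df, directed = TRUE)
    if (!igraph::is_dag(g)) {
      stop("ontology graph contains a cycle; not a valid DAG")
    }
  }
  root_ids <- ids[lengths(parents) == 0L & !obsolete]
  roots <- stats::setNames(root_ids, ns_of[root_ids])
  structure(list(terms = terms, parents = parents, alt = alt,
                 roots = roots, memo = new.env(parent = emptyenv())),
            class = "GODag")
}

#' @export
print.GODag <- function(x, ...) {
  cat(sprintf("GODag: %d terms (%s), %d roots\n", nrow(x$terms),
              paste(unique(x$terms$namespace), collapse = ", "),
              length(x$roots)))
  invisible(x)
}

# Resolve an id through the alt_id map; NA if unknown.
resolve_term <- function(dag, term) {
  if (term %in% x_ids(dag)) return(term)
  if (term %in% names(dag$alt)) return(unname(dag$alt[term]))
  NA_character_
}

x_ids <- function(dag) dag$terms$id

#' Ancestors of a term
#'
#' Transitive closure over `is_a` and `part_of` parents, excluding the
#' term itself; memoized per DAG.
#'
#' @param dag a `GODag`.
#' @param term term id (alt ids resolve to their primary id).
#' @return character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, term) {
  id <- resolve_term(dag, term)
  if (is.na(id)) stop("unknown term: ", term)
  memo_get(dag, id)
}

memo_get <- function(dag, id) {
  if (!is.null(dag$memo[[id]])) return(dag$memo[[id]])
  acc <- character(0)
  frontier <- dag$parents[[id]]
  while (length(frontier)) {
    acc <- union(acc, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier],
                                      use.names = FALSE)), acc)
  }
  dag$memo[[id]] <- acc
  acc
}

# ---------------------------------------------------------------------------
# Annotation sets

#' Construct an annotation set
#'
#' A mapping term id -> confidence in \[0, 1\], with provenance (the
#' families that contributed each term).
#'
#' @param scores named numeric vector of confidences in \[0, 1\].
#' @param provenance named list term -> character vector of family ids,
#'   or a single family id applied to all terms.
#' @return an object of class `AnnotationSet`.
#' @export
annotation_set <- function(scores = numeric(0), provenance = list()) {
  if (length(scores)) {
    stopifnot(!is.null(names(scores)),
              all(scores >= 0 & scores <= 1))
  }
  if (is.character(provenance) && length(provenance) == 1L) {
    provenance <- stats::setNames(
      replicate(length(scores), provenance, simplify = FALSE),
      names(scores))
  }
  structure(list(scores = scores, provenance = provenance),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d terms\n", length(x$scores)))
  if (length(x$scores)) {
    o <- order(-x$scores)
    for (k in utils::head(o, 10)) {
      cat(sprintf("  %s %.3f\n", names(x$scores)[k], x$scores[k]))
    }
    if (length(x$scores) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Propagate confidences up the GO DAG
#'
#' Every annotated term pushes its confidence to all of its ancestors;
#' each term keeps the maximum score it receives, and original scores
#' never decrease.  Terms unknown to the DAG, and obsolete terms, are
#' dropped with a warning.  Propagation stays within each namespace by
#' construction of the DAG edges.
#'
#' @param annotations an `AnnotationSet` (or named numeric vector).
#' @param dag a `GODag`.
#' @return the propagated `AnnotationSet`.
#' @export
propagate_annotations <- function(annotations, dag) {
  if (!inherits(annotations, "AnnotationSet")) {
    annotations <- annotation_set(annotations)
  }
  scores <- annotations$scores
  prov <- annotations$provenance
  if (length(scores) == 0L) return(annotation_set())
  obs <- stats::setNames(dag$terms$obsolete, dag$terms$id)
  keep <- logical(length(scores))
  ids <- character(length(scores))
  for (k in seq_along(scores)) {
    id <- resolve_term(dag, names(scores)[k])
    if (is.na(id)) {
      warning("dropping term unknown to the ontology: ", names(scores)[k])
    } else if (obs[[id]]) {
      warning("dropping obsolete term: ", id)
    } else {
      keep[k] <- TRUE
      ids[k] <- id
    }
  }
  scores <- stats::setNames(scores[keep], ids[keep])
  prov <- stats::setNames(prov[which(keep)], ids[keep])
  out <- numeric(0)
  out_prov <- list()
  for (k in seq_along(scores)) {
    t <- names(scores)[k]
    fams <- if (!is.null(prov[[t]])) prov[[t]] else character(0)
    for (target in c(t, go_ancestors(dag, t))) {
      if (!(target %in% names(out)) || out[[target]] < scores[[k]]) {
        out[target] <- scores[[k]]
      }
      out_prov[[target]] <- union(out_prov[[target]], fams)
    }
  }
  annotation_set(out, out_prov)
}

#' Merge per-domain annotation sets into one nonredundant set
#'
#' Each term retains its highest confidence score across the inputs;
#' provenance is unioned.  Merging is associative and commutative.
#'
#' @param sets list of `AnnotationSet`.
#' @return the merged `AnnotationSet`.
#' @export
merge_annotations <- function(sets) {
  scores <- numeric(0)
  prov <- list()
  for (s in sets) {
    if (!inherits(s, "AnnotationSet")) s <- annotation_set(s)
    for (t in names(s$scores)) {
      if (!(t %in% names(scores)) || scores[[t]] < s$scores[[t]]) {
        scores[t] <- s$scores[[t]]
      }
      prov[[t]] <- union(prov[[t]], s$provenance[[t]])
    }
  }
  annotation_set(scores, prov)
}

#' Export an annotation set as a data frame, TSV or JSON
#'
#' @param aset an `AnnotationSet`.
#' @param dag optional `GODag` for namespaces.
#' @param path optional output path ending in `.tsv` or `.json`.
#' @return data frame (term, namespace, confidence, families), sorted
#'   by descending confidence then term id.
#' @export
annotation_table <- function(aset, dag = NULL, path = NULL) {
  terms <- names(aset$scores)
  if (length(terms) == 0L) {
    out <- data.frame(term = character(0), namespace = character(0),
                      confidence = numeric(0), families = character(0))
    if (!is.null(path)) {
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      return(invisible(out))
    }
    return(out)
  }
  ns <- if (is.null(dag)) rep(NA_character_, length(terms)) else {
    vapply(terms, function(t) {
      id <- resolve_term(dag, t)
      if (is.na(id)) NA_character_
      else dag$terms$namespace[match(id, dag$terms$id)]
    }, character(1))
  }
  fams <- vapply(terms, function(t) {
    paste(sort(aset$provenance[[t]]), collapse = ",")
  }, character(1))
  out <- data.frame(term = terms, namespace = ns,
                    confidence = unname(aset$scores),
                    families = unname(fams), stringsAsFactors = FALSE)
  out <- out[order(-out$confidence, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(out, path, dataframe = "rows",
                           auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    return(invisible(out))
  }
  out
}
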