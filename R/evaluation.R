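# CAFA-style benchmark evaluation: rollback-set helpers, sequence
# identity filtering, BLAST-like and flat-family baseline predictors,
# and precision-recall curves with Fmax.

#' Construct a benchmark set
#'
#' @param true_terms named list, protein id -> character vector of true
#'   GO term ids (must be ancestor-closed within one namespace; roots
#'   are removed here).
#' @param namespace one of MFO, BPO, CCO.
#' @param dag a `GODag`, used to close the truth over ancestors and to
#'   drop root terms (CAFA convention).
#' @param sequences optional named character vector of protein sequences.
#' @return an object of class `BenchmarkSet`.
#' @export
benchmark_set <- function(true_terms, namespace = "MFO", dag = NULL,
                          sequences = NULL) {
  if (!is.null(dag)) {
    true_terms <- lapply(true_terms, function(ts) {
      closed <- unique(c(ts, unlist(lapply(ts, function(t)
        go_ancestors(dag, t)), use.names = FALSE)))
      setdiff(closed, dag$roots)
    })
  }
  if (any(lengths(true_terms) == 0L)) {
    stop("every benchmark protein needs a non-empty truth set")
  }
  structure(list(true_terms = true_terms, namespace = namespace,
                 sequences = sequences), class = "BenchmarkSet")
}

#' Rollback benchmark construction from two annotation snapshots
#'
#' Given annotation tables at an earlier and a later database snapshot,
#' returns the ids annotated in the later snapshot but carrying no
#' annotation in the earlier one -- the proteins whose functions were
#' learned in between and can therefore serve as blind prediction
#' targets.
#'
#' @param earlier,later data frames with columns `sequence_id`,
#'   `term_id` (GAF-like, as read by [read_annotation_tsv()]).
#' @return character vector of benchmark protein ids.
#' @export
rollback_targets <- function(earlier, later) {
  setdiff(unique(later$sequence_id), unique(earlier$sequence_id))
}

#' Remove queries too similar to annotated database sequences
#'
#' Drops every query whose maximum pairwise sequence identity to any
#' database sequence exceeds `cutoff`, so that remaining targets cannot
#' be annotated by trivial close-homolog transfer.  Identity is
#' computed from a global (Needleman-Wunsch, BLOSUM62) alignment as
#' matches divided by alignment length including internal gaps
#' (`denominator = "alignment"`), or by the shorter sequence length
#' (`denominator = "shorter"`).
#'
#' @param queries named character vector of query sequences.
#' @param annotated_db named character vector of database sequences.
#' @param cutoff identity threshold in (0, 1], default 0.5.
#' @param denominator identity denominator convention.
#' @return the retained queries (named character vector).
#' @export
identity_filter <- function(queries, annotated_db, cutoff = 0.5,
                            denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  stopifnot(cutoff > 0, cutoff <= 1)
  if (length(annotated_db) == 0L) {
    warning("empty annotated database; returning all queries")
    return(queries)
  }
  pid_type <- if (denominator == "alignment") "PID1" else "PID3"
  keep <- vapply(queries, function(q) {
    for (d in annotated_db) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(d),
        type = "global", substitutionMatrix = blosum62_matrix(),
        gapOpening = 10, gapExtension = 0.5)
      if (Biostrings::pid(aln, type = pid_type) / 100 > cutoff) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  queries[keep]
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' BLAST-style top-hit annotation transfer baseline
#'
#' Finds the best local pairwise alignment (Smith-Waterman, BLOSUM62)
#' of the query against the annotated database and transfers all of the
#' top hit's terms at confidence exactly 1, then propagates up the DAG.
#' Mimics naive annotation transfer from the top BLAST hit.
#'
#' @param query amino-acid string.
#' @param db_seqs named character vector of database sequences.
#' @param db_annotations named list, sequence id -> character vector of
#'   GO term ids.
#' @param dag a `GODag`.
#' @return propagated `AnnotationSet` (empty when no hit scores > 0).
#' @export
blast_baseline <- function(query, db_seqs, db_annotations, dag) {
  if (length(db_seqs) == 0L) return(annotation_set())
  scores <- vapply(db_seqs, function(d) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(d),
      type = "local", substitutionMatrix = blosum62_matrix(),
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
  }, numeric(1))
  annotated <- names(db_seqs)[lengths(db_annotations[names(db_seqs)]) > 0L]
  scores <- scores[names(scores) %in% annotated]
  if (length(scores) == 0L || max(scores) <= 0) return(annotation_set())
  top <- names(scores)[which.max(scores)]
  terms <- db_annotations[[top]]
  raw <- annotation_set(stats::setNames(rep(1, length(terms)), terms),
                        paste0("blast:", top))
  suppressWarnings(propagate_annotations(raw, dag))
}

#' Collapse a library to one flat family per superfamily
#'
#' Pools the members and annotations of all functional families sharing
#' a superfamily into a single family per superfamily, emulating flat
#' (non-subclassified) family resources such as Pfam or CDD.  Term
#' frequencies are recomputed over the pooled annotated members, so a
#' term confined to one subfamily is diluted in proportion to that
#' subfamily's share of annotated members.  Alignments must share the
#' same width within a superfamily (true for the synthetic libraries).
#'
#' @param library a `FamilyLibrary`.
#' @return a new `FamilyLibrary` with one family per superfamily (HMMs
#'   not yet built; run [build_library()]).
#' @export
collapse_to_superfamilies <- function(library) {
  sfs <- split(library$families,
               vapply(library$families, `[[`, character(1),
                      "superfamily_id"))
  fams <- lapply(names(sfs), function(sf) {
    group <- sfs[[sf]]
    widths <- unique(unlist(lapply(group, function(f) nchar(f$alignment))))
    if (length(widths) != 1L) {
      stop("cannot pool superfamily ", sf,
           ": member alignments have different widths")
    }
    aln <- unlist(unname(lapply(group, `[[`, "alignment")))
    ann <- do.call(rbind, lapply(group, function(f) {
      rows <- lapply(names(f$alignment), function(sid) {
        terms <- c(f$member_annotations[[sid]], f$ec_annotations[[sid]])
        if (!length(terms)) return(NULL)
        data.frame(sequence_id = sid, term_id = terms,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
    build_funfam(sf, sf, aln, ann)
  })
  family_library(fams)
}

#' Flat-family baseline prediction for one query
#'
#' Same pipeline as [annotate_sequence()] but run over a library
#' collapsed to one family per superfamily, modelling flat-family
#' comparators (Pfam/CDD-style annotation transfer).
#'
#' @param query amino-acid string.
#' @param flat_library built `FamilyLibrary` from
#'   [collapse_to_superfamilies()] + [build_library()].
#' @param dag a `GODag`.
#' @param ... passed to [annotate_sequence()].
#' @return the query's merged, propagated `AnnotationSet`.
#' @export
flat_family_baseline <- function(query, flat_library, dag, ...) {
  annotate_sequence(query, flat_library, dag, ...)$protein_annotations
}

#' CAFA-style precision-recall curve and Fmax
#'
#' For each threshold `t` on a uniform grid over \[0, 1\]:
#' precision(t) is averaged over proteins with at least one prediction
#' scoring >= t, of the fraction of predicted terms (>= t) that are
#' true; recall(t) is averaged over *all* benchmark proteins, of the
#' fraction of true terms predicted at >= t.  `Fmax` is the maximum
#' harmonic mean over thresholds (0/0 treated as 0).  Ontology root
#' terms are excluded from both predictions and truth.
#'
#' @param predictions named list, protein id -> `AnnotationSet` or named
#'   numeric score vector (propagated).
#' @param benchmark a `BenchmarkSet`.
#' @param n_thresholds grid size (default 101: 0.00, 0.01, ..., 1.00).
#' @param dag optional `GODag` used to drop root terms.
#' @return a `PRCurve`: `thresholds` (descending), `precision`,
#'   `recall`, `fmax`.
#' @export
precision_recall <- function(predictions, benchmark, n_thresholds = 101L,
                             dag = NULL) {
  stopifnot(inherits(benchmark, "BenchmarkSet"))
  ids <- names(benchmark$true_terms)
  if (length(ids) == 0L) stop("empty benchmark")
  roots <- if (is.null(dag)) character(0) else unname(dag$roots)
  pred_scores <- lapply(ids, function(id) {
    p <- predictions[[id]]
    s <- if (inherits(p, "AnnotationSet")) p$scores
         else if (is.null(p)) numeric(0) else p
    s[!(names(s) %in% roots)]
  })
  truth <- lapply(benchmark$true_terms, function(ts) setdiff(ts, roots))
  thresholds <- seq(1, 0, length.out = n_thresholds)
  pr <- rc <- numeric(n_thresholds)
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    rec_all <- numeric(length(ids))
    n_pred <- 0L
    prec_sum <- 0
    for (i in seq_along(ids)) {
      P_i <- names(pred_scores[[i]])[pred_scores[[i]] >= t]
      T_i <- truth[[i]]
      hit <- length(intersect(P_i, T_i))
      if (length(P_i) > 0L) {
        n_pred <- n_pred + 1L
        prec_sum <- prec_sum + hit / length(P_i)
      }
      rec_all[i] <- if (length(T_i)) hit / length(T_i) else 0
    }
    pr[k] <- if (n_pred > 0L) prec_sum / n_pred else NA_real_
    rc[k] <- mean(rec_all)
  }
  f <- ifelse(is.na(pr) | (pr + rc) == 0, 0, 2 * pr * rc / (pr + rc))
  structure(list(thresholds = thresholds, precision = pr, recall = rc,
                 fmax = max(f)), class = "PRCurve")
}

#' @export
print.PRCurve <- function(x, ...) {
  cat(sprintf("PRCurve: %d thresholds, Fmax = %.3f\n",
              length(x$thresholds), x$fmax))
  invisible(x)
}

#' Write a precision-recall curve as TSV
#'
#' @param curve a `PRCurve`.
#' @param path output TSV (threshold, precision, recall).
#' @export
pr_table <- function(curve, path = NULL) {
  out <- data.frame(threshold = curve$thresholds,
                    precision = curve$precision,
                    recall = curve$recall)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
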