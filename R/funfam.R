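# Functional-family (FunFam) objects and the family library.
#
# A FunFam is one functional family inside a domain superfamily: a
# multiple sequence alignment of member domains, per-member GO and EC
# annotations, GO/EC term frequencies over the annotated members, and an
# E-value inclusion threshold (the worst self-scan E-value of any
# member, computed once the family HMM is calibrated).

#' Construct a functional family (FunFam)
#'
#' Builds a FunFam from an alignment and member annotations, computing
#' GO and EC term frequencies over the annotated members.  The E-value
#' inclusion threshold is left unset until the family HMM has been built
#' and calibrated (see [compute_inclusion_threshold()]).
#'
#' @param family_id unique family identifier (used as file stem).
#' @param superfamily_id identifier of the parent superfamily (opaque
#'   label, e.g. a CATH-style dotted code).
#' @param alignment named character vector of aligned member sequences
#'   (uppercase amino acids plus `-` gaps), all the same length.
#' @param annotations optional data frame with columns `sequence_id` and
#'   `term_id` (`GO:...` or `EC:...`), one row per assignment, or `NULL`.
#' @return an object of class `FunFam`.
#' @examples
#' ff <- build_funfam("f1", "1.10.10.10",
#'                    c(s1 = "MKVL", s2 = "MKVI"),
#'                    data.frame(sequence_id = "s1", term_id = "GO:0000003"))
#' ff$term_frequencies
#' @export
build_funfam <- function(family_id, superfamily_id, alignment,
                         annotations = NULL) {
  if (length(alignment) == 0L) {
    stop("alignment is empty: a family needs at least one member")
  }
  if (is.null(names(alignment)) || anyNA(names(alignment)) ||
      any(names(alignment) == "")) {
    stop("alignment sequences must be named by sequence id")
  }
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: rows have lengths ",
         paste(sort(unique(widths)), collapse = ", "))
  }
  if (anyDuplicated(names(alignment))) {
    stop("duplicate sequence ids in alignment")
  }
  alignment <- toupper(alignment)

  member_annotations <- stats::setNames(
    replicate(length(alignment), character(0), simplify = FALSE),
    names(alignment))
  ec_annotations <- member_annotations
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    stopifnot(all(c("sequence_id", "term_id") %in% names(annotations)))
    unknown <- setdiff(annotations$sequence_id, names(alignment))
    if (length(unknown)) {
      stop("annotations reference sequences absent from the alignment: ",
           paste(unknown, collapse = ", "))
    }
    is_ec <- startsWith(annotations$term_id, "EC:")
    for (k in seq_len(nrow(annotations))) {
      sid <- annotations$sequence_id[k]
      tid <- annotations$term_id[k]
      if (is_ec[k]) {
        ec_annotations[[sid]] <- union(ec_annotations[[sid]], tid)
      } else {
        member_annotations[[sid]] <- union(member_annotations[[sid]], tid)
      }
    }
  }

  ff <- structure(list(
    family_id = as.character(family_id),
    superfamily_id = as.character(superfamily_id),
    alignment = alignment,
    member_annotations = member_annotations,
    ec_annotations = ec_annotations,
    inclusion_threshold = NA_real_,
    term_frequencies = numeric(0),
    ec_frequencies = numeric(0)
  ), class = "FunFam")
  ff$term_frequencies <- annotation_frequencies(ff)
  ff$ec_frequencies <- annotation_frequencies(ff, what = "ec")
  ff
}

#' @export
print.FunFam <- function(x, ...) {
  cat(sprintf("FunFam %s (superfamily %s): %d members, width %d\n",
              x$family_id, x$superfamily_id, length(x$alignment),
              nchar(x$alignment[[1]])))
  cat(sprintf("  %d GO terms, %d EC numbers; inclusion threshold: %s\n",
              length(x$term_frequencies), length(x$ec_frequencies),
              if (is.na(x$inclusion_threshold)) "unset"
              else format(x$inclusion_threshold, digits = 3)))
  invisible(x)
}

#' Annotation frequencies of a family
#'
#' Frequency of each term among the *annotated* members of the family:
#' members carrying no annotation of the requested kind are excluded
#' from the denominator.  Returns an empty vector when no member is
#' annotated.
#'
#' @param funfam a `FunFam`.
#' @param what `"go"` (default) or `"ec"`.
#' @return named numeric vector of frequencies in (0, 1].
#' @export
annotation_frequencies <- function(funfam, what = c("go", "ec")) {
  what <- match.arg(what)
  ann <- if (what == "go") funfam$member_annotations else funfam$ec_annotations
  annotated <- ann[lengths(ann) > 0L]
  if (length(annotated) == 0L) return(numeric(0))
  counts <- table(unlist(annotated, use.names = FALSE))
  freqs <- as.numeric(counts) / length(annotated)
  stats::setNames(freqs, names(counts))
}

#' Compute a family's E-value inclusion threshold
#'
#' The inclusion threshold is the maximum (worst) E-value obtained when
#' each member sequence of the family is scanned against the family's
#' own HMM.  Query matches at or below this threshold are accepted as
#' family members downstream.
#'
#' @param funfam a `FunFam`.
#' @param scanner function `(sequence, sequence_id)` returning the
#'   member's self-scan E-value (see [build_library()], which wires
#'   this to the family's calibrated HMM; the id argument lets a
#'   jackknifing scanner exclude the member from the model).
#' @return the `FunFam` with `inclusion_threshold` set.
#' @export
compute_inclusion_threshold <- function(funfam, scanner) {
  seqs <- gsub("[-.]", "", funfam$alignment)
  evs <- vapply(names(seqs), function(sid) scanner(seqs[[sid]], sid),
                numeric(1))
  if (anyNA(evs) || any(evs <= 0)) {
    stop("scanner returned an invalid E-value for family ",
         funfam$family_id)
  }
  funfam$inclusion_threshold <- max(evs)
  funfam
}

#' Per-column conservation scores of a family alignment
#'
#' Normalized sum-of-pairs substitution similarity per column, in the
#' spirit of Valdar-style conservation scoring: every residue pair
#' contributes `max(0, M[a,b] / sqrt(M[a,a] * M[b,b]))` under BLOSUM62,
#' so identical residues contribute 1; any pair involving a gap
#' contributes 0.  A gap-free invariant column scores exactly 1.
#'
#' @param funfam a `FunFam` with at least two members.
#' @return numeric vector with one score in \[0, 1\] per column.
#' @export
conservation_scores <- function(funfam) {
  n <- length(funfam$alignment)
  if (n < 2L) stop("conservation scores need at least 2 sequences")
  mat <- do.call(rbind, strsplit(funfam$alignment, "", fixed = TRUE))
  sim <- blosum_similarity()
  apply(mat, 2L, function(col) {
    total <- 0
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        ra <- col[a]; rb <- col[b]
        if (is_gap(ra) || is_gap(rb)) next
        ia <- match(ra, AA20); ib <- match(rb, AA20)
        if (is.na(ia) || is.na(ib)) next
        total <- total + sim[ia, ib]
      }
    }
    total / (n * (n - 1) / 2)
  })
}

# Normalized BLOSUM62 similarity over the 20 standard residues,
# sim(a,b) = max(0, M[a,b]/sqrt(M[a,a] M[b,b])) so the diagonal is 1.
blosum_similarity <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA20, AA20]
    d <- sqrt(diag(m))
    s <- m / outer(d, d)
    s[s < 0] <- 0
    s[s > 1] <- 1          # guard floating error on the diagonal
    cache <<- s
    s
  }
})

# ---------------------------------------------------------------------------
# Family library

#' Assemble a family library
#'
#' @param families list of `FunFam` objects with unique family ids.
#' @return a `FamilyLibrary`: families indexed by id, plus `db_size`
#'   (the number of families, used as the E-value search-space size).
#' @export
family_library <- function(families) {
  ids <- vapply(families, function(f) f$family_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate family ids in library")
  structure(list(
    families = stats::setNames(families, ids),
    hmms = NULL,
    db_size = length(families)
  ), class = "FamilyLibrary")
}

#' @export
print.FamilyLibrary <- function(x, ...) {
  cat(sprintf("FamilyLibrary: %d families (%s)\n", x$db_size,
              if (is.null(x$hmms)) "HMMs not built"
              else "HMMs built and calibrated"))
  invisible(x)
}

#' Read an aligned FASTA file as a named character vector
#'
#' @param path aligned FASTA file, one family per file.
#' @return named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aln), names(aln))
}

#' Read a GAF-like annotation table
#'
#' Two tab-separated columns, `sequence_id` and `term_id` (`GO:NNNNNNN`
#' or `EC:N.N.N.N`), one row per assignment; lines starting with `#` are
#' ignored.
#'
#' @param path TSV file path.
#' @return data frame with columns `sequence_id`, `term_id`.
#' @export
read_annotation_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(sequence_id = character(0), term_id = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("annotation file ", path, ": expected 2 tab-separated columns ",
         "at line ", bad[1])
  }
  data.frame(sequence_id = vapply(parts, `[[`, character(1), 1L),
             term_id = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Read a family library from a manifest
#'
#' The manifest is a tab-separated table with columns `family_id`,
#' `superfamily_id`, `alignment_path`, `annotation_path` (paths relative
#' to the manifest's directory); `#` lines are ignored.
#'
#' @param manifest_path manifest TSV path.
#' @return a `FamilyLibrary` (HMMs not yet built).
#' @export
read_family_library <- function(manifest_path) {
  base <- dirname(manifest_path)
  man <- utils::read.delim(manifest_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  needed <- c("family_id", "superfamily_id", "alignment_path",
              "annotation_path")
  if (!all(needed %in% names(man))) {
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  }
  fams <- lapply(seq_len(nrow(man)), function(k) {
    aln <- read_alignment_fasta(file.path(base, man$alignment_path[k]))
    ann_path <- file.path(base, man$annotation_path[k])
    ann <- if (file.exists(ann_path)) read_annotation_tsv(ann_path) else NULL
    build_funfam(man$family_id[k], man$superfamily_id[k], aln, ann)
  })
  family_library(fams)
}

#' Write a family library as alignment/annotation files plus manifest
#'
#' @param library a `FamilyLibrary`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_family_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(library$families, function(ff) {
    aln_file <- paste0(ff$family_id, ".aln.fasta")
    ann_file <- paste0(ff$family_id, ".ann.tsv")
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(ff$alignment), file.path(dir, aln_file))
    lines <- c("# sequence_id\tterm_id", unlist(lapply(
      names(ff$alignment), function(sid) {
        terms <- c(ff$member_annotations[[sid]], ff$ec_annotations[[sid]])
        if (length(terms)) paste(sid, terms, sep = "\t") else character(0)
      })))
    writeLines(lines, file.path(dir, ann_file))
    data.frame(family_id = ff$family_id,
               superfamily_id = ff$superfamily_id,
               alignment_path = aln_file, annotation_path = ann_file,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man_path)
}
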