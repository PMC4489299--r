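# End-to-end pipeline: build the scannable library (HMMs, calibration,
# inclusion thresholds), then FASTA in -> scan -> threshold filter ->
# MDA resolution -> annotation transfer -> DAG propagation -> merge.

#' Build a scannable family library
#'
#' For every family: build its profile HMM from the alignment, calibrate
#' Gumbel E-value parameters on seeded background sequences, then scan
#' each member against the family HMM and store the worst (maximum)
#' self-scan E-value as the family's inclusion threshold.
#'
#' With `threshold_mode = "jackknife"` (the default) each member is
#' scored against the family HMM re-estimated *without* that member
#' (E-values on the full model's calibration).  In-sample self-scans
#' are optimistically biased when a family has only a handful of
#' members -- every member's residues sit in the emission counts -- so
#' the in-sample maximum under-estimates the E-value a genuine new
#' family member attains and rejects it.  The jackknifed scan removes
#' that bias; the plain in-sample scan is available as
#' `threshold_mode = "self"` and is the natural choice when families
#' are large.  Either way every member's own self-scan E-value stays at
#' or below the stored threshold.
#'
#' @param library a `FamilyLibrary` (e.g. from [read_family_library()]),
#'   or a path to a manifest TSV.
#' @param n_random background sequences per family for calibration.
#' @param calib_length background sequence length.
#' @param seed base RNG seed; each family derives its own sub-seed.
#' @param threshold_mode `"jackknife"` (default) or `"self"`, see above.
#' @return the `FamilyLibrary` with `hmms` built and calibrated and
#'   every family's `inclusion_threshold` set.
#' @export
build_library <- function(library, n_random = 200L, calib_length = 150L,
                          seed = 1L,
                          threshold_mode = c("jackknife", "self")) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.character(library)) library <- read_family_library(library)
  stopifnot(inherits(library, "FamilyLibrary"))
  db <- library$db_size
  hmms <- list()
  fam_ids <- names(library$families)
  for (k in seq_along(fam_ids)) {
    fid <- fam_ids[k]
    fam <- library$families[[fid]]
    hmm <- build_profile_hmm(fam)
    hmm <- calibrate_evalue(hmm, n_random = n_random,
                            length = calib_length,
                            seed = (seed + 7L * k) %% .Machine$integer.max)
    scanner <- function(s, sid) {
      model <- hmm
      if (threshold_mode == "jackknife" && length(fam$alignment) >= 2L) {
        loo <- tryCatch(build_profile_hmm(fam$alignment[
          names(fam$alignment) != sid], family_id = fid),
          error = function(e) NULL)
        if (!is.null(loo)) {
          loo$gumbel_lambda <- hmm$gumbel_lambda
          loo$gumbel_mu <- hmm$gumbel_mu
          model <- loo
        }
      }
      hmm_evalue(model, viterbi_local(model, s)$bit_score, db)
    }
    library$families[[fid]] <- compute_inclusion_threshold(fam, scanner)
    hmms[[fid]] <- hmm
  }
  library$hmms <- hmms
  library
}

#' Annotate one protein sequence
#'
#' Runs the full pipeline on a single query: scan against the library,
#' keep matches passing their family's inclusion threshold, resolve the
#' multidomain architecture, transfer each matched family's GO term
#' frequencies as confidence scores, propagate them up the GO DAG and
#' merge the per-domain sets into a nonredundant per-protein set (each
#' term keeping its highest confidence).  EC numbers are reported per
#' domain with their family frequencies but are never propagated.
#'
#' @param sequence amino-acid string.
#' @param library built `FamilyLibrary` (see [build_library()]).
#' @param dag a `GODag`.
#' @param query_id identifier for the report.
#' @param prefilter report-level E-value cutoff passed to
#'   [scan_sequence()].
#' @param overlap_slack residues of boundary overlap tolerated between
#'   retained matches during architecture resolution; overlapping
#'   residues are trimmed from the weaker match, so the reported MDA is
#'   always disjoint.  Local alignment ends wobble a few residues, so a
#'   strict zero tolerance discards genuinely adjacent or nested
#'   domains.
#' @return an `AnnotationReport`: `query_id`, `mda`, `per_domain`
#'   (family id -> propagated `AnnotationSet`), `protein_annotations`
#'   (merged set), `ec_table` (family id -> EC frequencies) and
#'   `no_significant_match` flag.
#' @export
annotate_sequence <- function(sequence, library, dag,
                              query_id = "query", prefilter = 10,
                              overlap_slack = 5L) {
  if (grepl("[^A-Za-z]", sequence)) {
    stop("sequence for ", query_id, " contains non-residue characters")
  }
  hits <- scan_sequence(sequence, library, query_id = query_id,
                        prefilter = prefilter)
  annotate_matches(hits, library, dag, query_id = query_id,
                   overlap_slack = overlap_slack)
}

#' Annotate a query from a pre-computed match list
#'
#' Runs the post-scan stages of the pipeline (inclusion-threshold
#' filter, architecture resolution, annotation transfer, propagation,
#' merge) on matches obtained elsewhere -- e.g. parsed from a HMMER3
#' `--domtblout` file with [parse_domtblout()].
#'
#' @param matches list of `DomainMatch` on one query.
#' @param library `FamilyLibrary` with inclusion thresholds.
#' @param dag a `GODag`.
#' @param query_id identifier for the report.
#' @param overlap_slack see [annotate_sequence()].
#' @return an `AnnotationReport`.
#' @export
annotate_matches <- function(matches, library, dag, query_id = "query",
                             overlap_slack = 5L) {
  matches <- filter_significant(matches, library)
  mda <- resolve_mda(matches, slack = overlap_slack)
  mda$query_id <- query_id
  per_domain <- list()
  ec_table <- list()
  for (m in mda$matches) {
    fam <- library$families[[m$family_id]]
    raw <- annotation_set(fam$term_frequencies, fam$family_id)
    per_domain[[m$family_id]] <-
      suppressWarnings(propagate_annotations(raw, dag))
    ec_table[[m$family_id]] <- fam$ec_frequencies
  }
  structure(list(
    query_id = query_id,
    mda = mda,
    per_domain = per_domain,
    protein_annotations = merge_annotations(per_domain),
    ec_table = ec_table,
    no_significant_match = length(mda$matches) == 0L
  ), class = "AnnotationReport")
}

#' @export
print.AnnotationReport <- function(x, ...) {
  cat(sprintf("AnnotationReport for %s\n", x$query_id))
  if (x$no_significant_match) {
    cat("  no significant match\n")
    return(invisible(x))
  }
  print(x$mda)
  cat(sprintf("  %d GO terms on the protein (top shown)\n",
              length(x$protein_annotations$scores)))
  print(x$protein_annotations)
  invisible(x)
}

#' Annotate every sequence in a FASTA file
#'
#' @param fasta_path FASTA file with unique record ids.
#' @param library built `FamilyLibrary`.
#' @param dag a `GODag`.
#' @param out_dir optional directory; when given, writes
#'   `mda.tsv`, `annotations.tsv` and `annotations.json` there.
#' @param ... passed to [annotate_sequence()].
#' @return list of `AnnotationReport` in input order.
#' @export
annotate_fasta <- function(fasta_path, library, dag, out_dir = NULL, ...) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  }
  reports <- lapply(seq_along(seqs), function(k) {
    annotate_sequence(as.character(seqs[[k]]), library, dag,
                      query_id = ids[k], ...)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    mda_table(lapply(reports, `[[`, "mda"),
              file.path(out_dir, "mda.tsv"), library = library)
    rows <- do.call(rbind, lapply(reports, function(rep) {
      tab <- annotation_table(rep$protein_annotations, dag)
      if (nrow(tab) == 0L) return(NULL)
      cbind(query = rep$query_id, tab)
    }))
    if (is.null(rows)) {
      rows <- data.frame(query = character(0), term = character(0),
                         namespace = character(0), confidence = numeric(0),
                         families = character(0))
    }
    utils::write.table(rows, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, report_to_list),
      file.path(out_dir, "annotations.json"),
      auto_unbox = TRUE, digits = NA)
  }
  reports
}

#' Write a built library (families, profiles, thresholds) to a directory
#'
#' Alongside the family alignment/annotation files and manifest (see
#' [write_family_library()]), stores each family's calibrated profile
#' HMM as JSON lines and an `inclusion_thresholds.tsv` table, so a
#' built library can be reloaded without recomputation.
#'
#' @param library built `FamilyLibrary`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_built_library <- function(library, dir) {
  if (is.null(library$hmms)) stop("library HMMs not built")
  write_family_library(library, dir)
  for (fid in names(library$hmms)) {
    write_hmm_jsonl(library$hmms[[fid]],
                    file.path(dir, paste0(fid, ".hmm.jsonl")))
  }
  thr <- data.frame(
    family_id = names(library$families),
    inclusion_threshold = vapply(library$families, `[[`, numeric(1),
                                 "inclusion_threshold"))
  utils::write.table(thr, file.path(dir, "inclusion_thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a built library written by [write_built_library()]
#'
#' @param dir directory containing the manifest, profile and threshold
#'   files.
#' @return a built `FamilyLibrary` ready for [annotate_sequence()].
#' @export
read_built_library <- function(dir) {
  lib <- read_family_library(file.path(dir, "manifest.tsv"))
  thr <- utils::read.delim(file.path(dir, "inclusion_thresholds.tsv"))
  hmms <- list()
  for (fid in names(lib$families)) {
    hmms[[fid]] <- read_hmm_jsonl(file.path(dir,
                                            paste0(fid, ".hmm.jsonl")))
    k <- match(fid, thr$family_id)
    if (is.na(k)) stop("no inclusion threshold stored for family ", fid)
    lib$families[[fid]]$inclusion_threshold <- thr$inclusion_threshold[k]
  }
  lib$hmms <- hmms
  lib
}

# Plain-list rendering of a report for JSON output.
report_to_list <- function(rep) {
  list(
    query_id = rep$query_id,
    no_significant_match = rep$no_significant_match,
    mda = lapply(rep$mda$matches, function(m) {
      list(family = m$family_id, segments = format_segments(m$segments),
           evalue = m$evalue, bit_score = m$bit_score)
    }),
    annotations = as.list(rep$protein_annotations$scores),
    ec = rep$ec_table
  )
}
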