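# Profile HMM construction, local Viterbi scanning, Gumbel E-value
# calibration, HMMER3 domtblout ingestion and alignment rendering.
#
# The profile model is a simplified single-hit Plan7: per-node match,
# insert and delete states, no multi-hit J state.  Repeated and
# discontinuous domains are recovered by (a) splitting a Viterbi path at
# long insert runs and (b) re-running Viterbi with previously matched
# residues masked (up to 4 iterations).  Scores are log2-odds bits
# against a uniform 1/20 residue background; insert states emit the
# background and score 0 bits.

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Build a simplified profile HMM from a family alignment
#'
#' Alignment columns with gap fraction below 0.5 become match nodes
#' (HMMER convention).  Match emissions are column residue counts with a
#' Laplace pseudocount of 1 over the 20 standard residues; transitions
#' are counted from each row's observed match/insert/delete state path,
#' also with pseudocount 1.  Construction is deterministic.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, or a `FunFam`.
#' @param family_id id stored on the model (defaults to the FunFam's).
#' @return an object of class `ProfileHMM`.
#' @export
build_profile_hmm <- function(alignment, family_id = "profile") {
  if (inherits(alignment, "FunFam")) {
    family_id <- alignment$family_id
    alignment <- alignment$alignment
  }
  if (length(alignment) == 0L) stop("empty alignment")
  widths <- unique(nchar(alignment))
  if (length(widths) != 1L) stop("ragged alignment")
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  n_rows <- nrow(mat)
  gap_frac <- colMeans(matrix(is_gap(mat), nrow = n_rows))
  is_match_col <- gap_frac < 0.5
  K <- sum(is_match_col)
  if (K == 0L) stop("alignment has no match columns (all columns >= 50% gaps)")

  # Emissions: per match node, residue counts + pseudocount 1 over 20.
  node_of_col <- cumsum(is_match_col)
  emis <- matrix(1, nrow = K, ncol = 20,
                 dimnames = list(NULL, AA20))
  for (col in which(is_match_col)) {
    j <- node_of_col[col]
    res <- mat[, col]
    res <- res[!is_gap(res)]
    idx <- match(res, AA20)
    idx <- idx[!is.na(idx)]
    for (i in idx) emis[j, i] <- emis[j, i] + 1
  }
  emis <- emis / rowSums(emis)

  # Transitions: walk each row's state sequence and count events per
  # node.  States: M_j / D_j at match columns, I_j at insert columns
  # carrying a residue (attached to the previous match node).
  counts <- matrix(1, nrow = K, ncol = 7,
                   dimnames = list(NULL, TRANS_NAMES))
  for (r in seq_len(n_rows)) {
    prev_state <- NULL   # c(state, node)
    for (col in seq_len(ncol(mat))) {
      ch <- mat[r, col]
      if (is_match_col[col]) {
        st <- if (is_gap(ch)) "D" else "M"
        nd <- node_of_col[col]
      } else {
        if (is_gap(ch)) next
        st <- "I"
        nd <- node_of_col[col]      # 0 before first match node
        if (nd == 0L) next          # N-terminal inserts are free ends
      }
      if (!is.null(prev_state)) {
        key <- paste0(prev_state[1], st)
        from_node <- as.integer(prev_state[2])
        if (key %in% TRANS_NAMES && from_node >= 1L && from_node <= K) {
          counts[from_node, key] <- counts[from_node, key] + 1
        }
      }
      prev_state <- c(st, nd)
    }
  }
  trans <- counts
  norm_block <- function(cols) {
    block <- counts[, cols, drop = FALSE]
    block / rowSums(block)
  }
  trans[, c("MM", "MI", "MD")] <- norm_block(c("MM", "MI", "MD"))
  trans[, c("IM", "II")] <- norm_block(c("IM", "II"))
  trans[, c("DM", "DD")] <- norm_block(c("DM", "DD"))

  structure(list(
    family_id = family_id,
    n_nodes = K,
    match_emissions = log(emis),
    insert_emissions = log(rep(1 / 20, 20)),
    transitions = log(trans),
    match_columns = which(is_match_col),
    gumbel_lambda = NA_real_,
    gumbel_mu = NA_real_
  ), class = "ProfileHMM")
}

#' @export
print.ProfileHMM <- function(x, ...) {
  cat(sprintf("ProfileHMM %s: %d match nodes, %s\n", x$family_id,
              x$n_nodes,
              if (is.na(x$gumbel_lambda)) "uncalibrated"
              else sprintf("Gumbel(lambda=%.3f, mu=%.2f)",
                           x$gumbel_lambda, x$gumbel_mu)))
  invisible(x)
}

# log2-odds match emission scores vs the uniform background.
match_log_odds <- function(hmm) {
  (hmm$match_emissions - log(1 / 20)) / log(2)
}

#' Local Viterbi alignment of a sequence to a profile HMM
#'
#' Finds the best-scoring local alignment with free start/end on both
#' the sequence and the model.  The bit score is
#' `log2 P(path, subsequence | model) / P(subsequence | background)`.
#' Tie-breaking prefers Match over Insert over Delete predecessors and
#' is fully deterministic.  Residues outside the 20-letter alphabet are
#' scored as a uniform-emission wildcard.
#'
#' @param hmm a `ProfileHMM`.
#' @param sequence amino-acid string.
#' @param mask optional integer positions that no state may emit
#'   (used for iterative multi-hit scanning).
#' @return list with `bit_score`, `path` (data frame `state` in
#'   M/I/D, `seq_pos`, `node`), and `segment` = c(start, end) query
#'   residue bounds (1-based inclusive).
#' @export
viterbi_local <- function(hmm, sequence, mask = NULL) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L) {
    stop("sequence must be a non-empty amino-acid string")
  }
  codes <- aa_encode(sequence)
  if (!is.null(mask) && length(mask)) codes[mask] <- -1L
  res <- .viterbi_local_cpp(match_log_odds(hmm),
                            hmm$transitions / log(2), codes)
  if (!is.finite(res$score)) {
    return(list(bit_score = -Inf,
                path = data.frame(state = character(0),
                                  seq_pos = integer(0), node = integer(0)),
                segment = NULL))
  }
  path <- as.data.frame(res$path)
  path$state <- c("M", "I", "D")[path$state]
  emit <- path$seq_pos[path$state != "D"]
  list(bit_score = res$score, path = path,
       segment = c(min(emit), max(emit)))
}

# Split a Viterbi path at insert runs longer than `split_insert`
# residues: each split yields a separate query segment, giving a
# discontinuous match whose bridged insertion is not part of any
# segment.  Returns list of sub-paths (data frames).
split_path_at_inserts <- function(path, split_insert = 20L) {
  run <- rle(path$state)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  cut_after <- integer(0)
  long_ins <- which(run$values == "I" & run$lengths > split_insert)
  pieces <- list()
  last <- 1L
  for (k in long_ins) {
    pieces[[length(pieces) + 1L]] <- path[last:(starts[k] - 1L), , drop = FALSE]
    last <- ends[k] + 1L
  }
  pieces[[length(pieces) + 1L]] <- path[last:nrow(path), , drop = FALSE]
  # trim leading/trailing non-match rows introduced by the cuts
  lapply(pieces, function(p) {
    m <- which(p$state == "M")
    p[m[1]:m[length(m)], , drop = FALSE]
  })
}

# Re-score a (contiguous) sub-path: emission log2-odds of its match
# states plus the log2 transition costs between consecutive rows.
# Entry/exit are free, matching the local alignment convention.
score_subpath <- function(hmm, codes, path) {
  lo <- match_log_odds(hmm)
  tr <- hmm$transitions / log(2)
  total <- 0
  for (r in seq_len(nrow(path))) {
    if (path$state[r] == "M") {
      code <- codes[path$seq_pos[r]]
      if (code > 0) total <- total + lo[path$node[r], code]
    }
    if (r > 1L) {
      key <- paste0(path$state[r - 1L], path$state[r])
      from <- if (path$state[r - 1L] == "I") path$node[r - 1L]
              else if (key %in% c("MI", "II")) path$node[r - 1L]
              else path$node[r] - 1L
      total <- total + tr[from, match(key, TRANS_NAMES)]
    }
  }
  total
}

#' Fit a Gumbel distribution to a sample of scores
#'
#' Method-of-moments fit of the extreme-value law used for E-values:
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda` with
#' Euler's constant gamma.
#'
#' @param scores numeric vector of scores.
#' @return list with `lambda` and `mu`.
#' @export
fit_gumbel <- function(scores) {
  s <- stats::sd(scores)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate score distribution: zero variance, cannot calibrate")
  }
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649015329 / lambda
  list(lambda = lambda, mu = mu)
}

#' Calibrate E-values for a profile HMM
#'
#' Scores `n_random` i.i.d. uniform-background sequences of the given
#' length with local Viterbi and fits a Gumbel law to the scores by the
#' method of moments, storing `(lambda, mu)` on the model.
#'
#' @param hmm a `ProfileHMM`.
#' @param n_random number of background sequences (>= 100).
#' @param length background sequence length.
#' @param seed RNG seed for the background sample.
#' @return the calibrated `ProfileHMM`.
#' @export
calibrate_evalue <- function(hmm, n_random = 200L, length = 150L,
                             seed = 1L) {
  if (n_random < 100L) stop("calibration needs n_random >= 100")
  scores <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      viterbi_local(hmm, random_aa(length))$bit_score
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  hmm$gumbel_lambda <- fit$lambda
  hmm$gumbel_mu <- fit$mu
  hmm
}

#' E-value of a bit score under a calibrated model
#'
#' `E = db_size * (1 - exp(-exp(-lambda * (score - mu))))`, the expected
#' number of random sequences scoring at least as well in a search over
#' `db_size` families; strictly decreasing in the score.
#'
#' @param hmm calibrated `ProfileHMM`.
#' @param bit_score Viterbi bit score.
#' @param db_size number of families searched (>= 1).
#' @return E-value.
#' @export
hmm_evalue <- function(hmm, bit_score, db_size = 1) {
  if (is.na(hmm$gumbel_lambda)) {
    stop("HMM ", hmm$family_id, " is not calibrated; run calibrate_evalue()")
  }
  stopifnot(db_size >= 1)
  p <- -expm1(-exp(-hmm$gumbel_lambda * (bit_score - hmm$gumbel_mu)))
  db_size * p
}

# ---------------------------------------------------------------------------
# Domain matches and scanning

#' Construct a domain match
#'
#' One scored match of a family HMM to a query region, possibly spanning
#' several disjoint segments (a discontinuous domain).
#'
#' @param query_id,family_id identifiers.
#' @param bit_score,evalue score and E-value of the match.
#' @param segments two-column matrix of (start, end) 1-based inclusive
#'   query intervals, disjoint and sorted.
#' @param hmm_span c(first_node, last_node) covered on the model.
#' @return an object of class `DomainMatch`.
#' @export
domain_match <- function(query_id, family_id, bit_score, evalue,
                         segments, hmm_span = c(NA_integer_, NA_integer_)) {
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) == 0L) stop("a match needs at least one segment")
  if (any(segments[, 1] > segments[, 2])) stop("segment start > end")
  o <- order(segments[, 1])
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1L &&
      any(segments[-1L, 1] <= segments[-nrow(segments), 2])) {
    stop("segments of one match must be pairwise disjoint")
  }
  if (!is.na(evalue) && evalue <= 0) stop("E-value must be positive")
  structure(list(query_id = query_id, family_id = family_id,
                 bit_score = bit_score, evalue = evalue,
                 segments = segments, hmm_span = as.integer(hmm_span)),
            class = "DomainMatch")
}

#' @export
print.DomainMatch <- function(x, ...) {
  cat(sprintf("DomainMatch %s ~ %s: %s, bits=%.1f, E=%.3g\n",
              x$query_id, x$family_id, format_segments(x$segments),
              x$bit_score, x$evalue))
  invisible(x)
}

format_segments <- function(segments) {
  paste(sprintf("%d-%d", segments[, 1], segments[, 2]), collapse = ",")
}

parse_segments <- function(txt) {
  parts <- strsplit(strsplit(txt, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

match_coverage <- function(m) sum(m$segments[, 2] - m$segments[, 1] + 1L)

#' Scan a query sequence against a family library
#'
#' Runs local Viterbi against every family HMM, iterating with matched
#' residues masked (up to `max_hits` rounds) so that repeated and
#' discontinuous domains are found; a Viterbi path bridging a long
#' insertion (> `split_insert` residues) is split into a discontinuous
#' match.  Per family, the best match by E-value is kept; matches with
#' E-value above `prefilter` are dropped (the decisive filter, the
#' family inclusion threshold, is applied downstream by
#' [filter_significant()]).
#'
#' @param sequence query amino-acid string.
#' @param library `FamilyLibrary` with built, calibrated HMMs (see
#'   [build_library()]).
#' @param query_id id recorded on the matches.
#' @param prefilter report-level E-value cutoff (default 10).
#' @param max_hits maximum masked re-scan iterations per family.
#' @param split_insert insert-run length (residues) above which a path
#'   is split into a discontinuous match.
#' @return list of `DomainMatch`, sorted by ascending E-value.
#' @export
scan_sequence <- function(sequence, library, query_id = "query",
                          prefilter = 10, max_hits = 4L,
                          split_insert = 20L) {
  if (is.null(library$hmms)) {
    stop("library HMMs not built; run build_library() first")
  }
  if (library$db_size == 0L) return(list())
  codes <- aa_encode(sequence)
  matches <- list()
  for (fid in names(library$hmms)) {
    hmm <- library$hmms[[fid]]
    fam_matches <- scan_one_family(hmm, sequence, codes, query_id,
                                   library$db_size, prefilter, max_hits,
                                   split_insert)
    fam_matches <- merge_family_matches(fam_matches, hmm = hmm,
                                        db_size = library$db_size)
    if (length(fam_matches)) {
      evs <- vapply(fam_matches, `[[`, numeric(1), "evalue")
      matches[[length(matches) + 1L]] <- fam_matches[[which.min(evs)]]
    }
  }
  evs <- vapply(matches, `[[`, numeric(1), "evalue")
  matches[order(evs)]
}

scan_one_family <- function(hmm, sequence, codes, query_id, db_size,
                            prefilter, max_hits, split_insert) {
  out <- list()
  mask <- integer(0)
  for (iter in seq_len(max_hits)) {
    vit <- viterbi_local(hmm, sequence, mask = mask)
    if (!is.finite(vit$bit_score)) break
    pieces <- split_path_at_inserts(vit$path, split_insert)
    if (length(pieces) > 1L) {
      # discontinuous: score segments individually, bridge is free
      seg_scores <- vapply(pieces, function(p) score_subpath(hmm, codes, p),
                           numeric(1))
      keep <- seg_scores > 0
      if (!any(keep)) break
      pieces <- pieces[keep]
      bit <- sum(seg_scores[keep])
    } else {
      bit <- vit$bit_score
    }
    ev <- hmm_evalue(hmm, bit, db_size)
    if (ev > prefilter) break
    segs <- t(vapply(pieces, function(p) {
      emit <- p$seq_pos[p$state != "D"]
      c(min(emit), max(emit))
    }, integer(2)))
    span <- c(min(vit$path$node), max(vit$path$node))
    out[[length(out) + 1L]] <- domain_match(
      query_id, hmm$family_id, bit, ev, segs, span)
    mask <- unique(c(mask, unlist(apply(segs, 1L, function(s)
      seq.int(s[1], s[2]), simplify = FALSE))))
    if (length(mask) >= length(codes)) break
  }
  out
}

# Merge same-family matches from different masked iterations when
# their model spans and sequence order are compatible: one match lies
# after the other on both the query and the model, with at most
# `node_slack` nodes of model overlap (local alignment ends wobble a
# few nodes at a split point).  The result is one discontinuous match
# whose bit score is the sum of the parts (the bridged insertion is
# free) and whose E-value is recomputed from that summed score -- a
# discontinuous domain is a single hit, scored as such.  Matches are
# attached in order of significance so weak spurious hits cannot
# pre-empt a genuine split-domain merge.
merge_family_matches <- function(matches, hmm = NULL, db_size = 1,
                                 node_slack = 5L) {
  if (length(matches) < 2L) return(matches)
  follows <- function(a, b) {
    # TRUE if b continues a on both the query and the model
    !anyNA(a$hmm_span) && !anyNA(b$hmm_span) &&
      b$hmm_span[1] > a$hmm_span[2] - node_slack &&
      b$hmm_span[2] > a$hmm_span[2] &&
      b$segments[1, 1] > a$segments[nrow(a$segments), 2]
  }
  evs <- vapply(matches, `[[`, numeric(1), "evalue")
  matches <- matches[order(evs)]
  merged <- list(matches[[1]])
  for (m in matches[-1L]) {
    attached <- FALSE
    for (k in seq_along(merged)) {
      prev <- merged[[k]]
      if (follows(prev, m) || follows(m, prev)) {
        bits <- prev$bit_score + m$bit_score
        ev <- if (is.null(hmm)) min(prev$evalue, m$evalue)
              else hmm_evalue(hmm, bits, db_size)
        merged[[k]] <- domain_match(
          prev$query_id, prev$family_id, bits, ev,
          rbind(prev$segments, m$segments),
          range(c(prev$hmm_span, m$hmm_span)))
        attached <- TRUE
        break
      }
    }
    if (!attached) merged[[length(merged) + 1L]] <- m
  }
  merged
}

# ---------------------------------------------------------------------------
# HMMER3 domtblout ingestion

#' Parse a HMMER3 `--domtblout` file into domain matches
#'
#' One `DomainMatch` per domain row, using the envelope coordinates
#' (`env from`/`env to`) as the segment and the independent E-value
#' (`i-Evalue`) as the match E-value; `#` lines are skipped.
#'
#' @param path domtblout file.
#' @return list of `DomainMatch`.
#' @export
parse_domtblout <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  out <- list()
  for (ln in which(keep)) {
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 22L) {
      stop("domtblout parse error at line ", ln, ": expected >= 22 ",
           "columns, got ", length(f))
    }
    ieval <- suppressWarnings(as.numeric(f[13]))
    bits <- suppressWarnings(as.numeric(f[14]))
    coords <- suppressWarnings(as.integer(f[c(16, 17, 20, 21)]))
    if (is.na(ieval) || is.na(bits) || anyNA(coords)) {
      stop("domtblout parse error at line ", ln,
           ": non-numeric score/E-value/coordinate field")
    }
    out[[length(out) + 1L]] <- domain_match(
      query_id = f[4], family_id = f[1], bit_score = bits,
      evalue = ieval, segments = matrix(coords[3:4], ncol = 2),
      hmm_span = coords[1:2])
  }
  out
}

# ---------------------------------------------------------------------------
# Serialization: JSON-lines profile dialect (not HMMER .hmm format)

#' Write a profile HMM as JSON lines
#'
#' Line 1 is a header object (family id, node count, calibration);
#' each further line is one node with its emission and transition
#' probabilities (linear scale).
#'
#' @param hmm a `ProfileHMM`.
#' @param path output file.
#' @export
write_hmm_jsonl <- function(hmm, path) {
  header <- list(family_id = hmm$family_id, n_nodes = hmm$n_nodes,
                 gumbel_lambda = hmm$gumbel_lambda,
                 gumbel_mu = hmm$gumbel_mu,
                 alphabet = paste(AA20, collapse = ""),
                 match_columns = hmm$match_columns)
  lines <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                            na = "null")
  for (j in seq_len(hmm$n_nodes)) {
    node <- list(node = j,
                 match = unname(exp(hmm$match_emissions[j, ])),
                 trans = as.list(stats::setNames(
                   exp(hmm$transitions[j, ]), TRANS_NAMES)))
    lines <- c(lines, jsonlite::toJSON(node, auto_unbox = TRUE,
                                       digits = NA))
  }
  writeLines(lines, path)
}

#' Read a profile HMM from the JSON-lines dialect
#'
#' @param path file written by [write_hmm_jsonl()].
#' @return a `ProfileHMM`.
#' @export
read_hmm_jsonl <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  K <- header$n_nodes
  if (length(lines) != K + 1L) stop("truncated profile file: ", path)
  emis <- matrix(NA_real_, nrow = K, ncol = 20,
                 dimnames = list(NULL, AA20))
  trans <- matrix(NA_real_, nrow = K, ncol = 7,
                  dimnames = list(NULL, TRANS_NAMES))
  for (j in seq_len(K)) {
    node <- jsonlite::fromJSON(lines[j + 1L])
    emis[node$node, ] <- node$match
    trans[node$node, ] <- unlist(node$trans[TRANS_NAMES])
  }
  structure(list(
    family_id = header$family_id, n_nodes = K,
    match_emissions = log(emis),
    insert_emissions = log(rep(1 / 20, 20)),
    transitions = log(trans),
    match_columns = header$match_columns,
    gumbel_lambda = if (is.null(header$gumbel_lambda)) NA_real_
                    else header$gumbel_lambda,
    gumbel_mu = if (is.null(header$gumbel_mu)) NA_real_
                else header$gumbel_mu
  ), class = "ProfileHMM")
}

# ---------------------------------------------------------------------------
# Alignment rendering

#' Render a Viterbi alignment as text
#'
#' Three-line rendering in the style of profile-search reports: model
#' consensus on top, a match line (`|` identity with the consensus, `+`
#' positive log-odds score, space otherwise), and the query with insert
#' residues in lowercase and deletions as `-`; 1-based query coordinates
#' at the line ends.
#'
#' @param hmm the `ProfileHMM` scored against.
#' @param sequence the query sequence.
#' @param path alignment path from [viterbi_local()] on the same inputs.
#' @return character string (three lines joined by newlines).
#' @export
render_alignment <- function(hmm, sequence, path) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (nrow(path) == 0L) stop("empty alignment path")
  if (max(path$seq_pos) > length(chars)) {
    stop("path is inconsistent with the sequence (position out of range)")
  }
  cons_res <- AA20[apply(hmm$match_emissions, 1L, which.max)]
  lo <- match_log_odds(hmm)
  cons <- qry <- mid <- character(nrow(path))
  for (r in seq_len(nrow(path))) {
    st <- path$state[r]; i <- path$seq_pos[r]; j <- path$node[r]
    if (st == "M") {
      cons[r] <- cons_res[j]
      qry[r] <- chars[i]
      code <- match(chars[i], AA20)
      mid[r] <- if (!is.na(code) && chars[i] == cons_res[j]) "|"
                else if (!is.na(code) && lo[j, code] > 0) "+"
                else " "
    } else if (st == "I") {
      cons[r] <- "."
      qry[r] <- tolower(chars[i])
      mid[r] <- " "
    } else {
      cons[r] <- cons_res[j]
      qry[r] <- "-"
      mid[r] <- " "
    }
  }
  emit <- path$seq_pos[path$state != "D"]
  from <- min(emit); to <- max(emit)
  pad <- function(x) formatC(x, width = 6)
  paste(
    paste0("model ", pad(path$node[1]), " ",
           paste(cons, collapse = ""), " ", path$node[nrow(path)]),
    paste0("      ", pad(""), " ", paste(mid, collapse = "")),
    paste0("query ", pad(from), " ", paste(qry, collapse = ""), " ", to),
    sep = "\n")
}
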