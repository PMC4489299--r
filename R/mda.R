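# Multidomain-architecture resolution: collapse the per-family match
# list for one query into a single mutually consistent set of domain
# assignments, after applying each family's E-value inclusion threshold.

#' Keep matches that pass their family's inclusion threshold
#'
#' A match is significant when its E-value is at or below the inclusion
#' threshold of the matched family (the worst self-scan E-value of any
#' family member).  Accepting equality means the member that attains the
#' family maximum is itself accepted.
#'
#' @param matches list of `DomainMatch`.
#' @param library `FamilyLibrary` whose families carry computed
#'   inclusion thresholds.
#' @return the significant matches, in their original order.
#' @export
filter_significant <- function(matches, library) {
  keep <- vapply(matches, function(m) {
    fam <- library$families[[m$family_id]]
    if (is.null(fam)) {
      stop("match references unknown family ", m$family_id)
    }
    if (is.na(fam$inclusion_threshold)) {
      stop("family ", m$family_id, " has no inclusion threshold; ",
           "run build_library() first")
    }
    m$evalue <= fam$inclusion_threshold
  }, logical(1))
  matches[keep]
}

# TRUE if any segment of a overlaps any segment of b (closed intervals,
# sharing `slack` or fewer residues tolerated when slack > 0).
matches_overlap <- function(a, b, slack = 0L) {
  for (i in seq_len(nrow(a$segments))) {
    for (j in seq_len(nrow(b$segments))) {
      ov <- min(a$segments[i, 2], b$segments[j, 2]) -
            max(a$segments[i, 1], b$segments[j, 1]) + 1L
      if (ov > slack) return(TRUE)
    }
  }
  FALSE
}

#' Resolve the multidomain architecture of one query
#'
#' Selects the subset of matches that maximizes total residue coverage
#' subject to pairwise non-overlap of all segments.  Ties are broken by
#' lower combined E-value product, then lexicographically by family id.
#' Single-segment inputs are solved exactly by weighted-interval
#' scheduling DP; when discontinuous matches are present an exhaustive
#' subset search is used for up to `max_exhaustive` candidates, beyond
#' which a greedy fall-back by ascending E-value is applied with a
#' warning.
#'
#' @param matches list of `DomainMatch` on one query, already
#'   significance-filtered.
#' @param slack residues of overlap tolerated between two retained
#'   matches (default 0: sharing even one residue conflicts).
#' @param max_exhaustive candidate cap for the exhaustive search.
#' @return an `MDA`: retained matches ordered by first segment start,
#'   plus total residue coverage.
#' @export
resolve_mda <- function(matches, slack = 0L, max_exhaustive = 20L) {
  if (length(matches) == 0L) {
    return(structure(list(query_id = NA_character_, matches = list(),
                          coverage = 0L), class = "MDA"))
  }
  qids <- unique(vapply(matches, `[[`, character(1), "query_id"))
  if (length(qids) != 1L) stop("matches span several queries: ",
                               paste(qids, collapse = ", "))
  discontinuous <- any(vapply(matches, function(m) nrow(m$segments) > 1L,
                              logical(1)))
  chosen <-
    if (!discontinuous) {
      resolve_wis(matches, slack)
    } else if (length(matches) <= max_exhaustive) {
      resolve_exhaustive(matches, slack)
    } else {
      warning("more than ", max_exhaustive, " candidate matches with ",
              "discontinuous segments; falling back to greedy ",
              "resolution by ascending E-value")
      resolve_greedy(matches, slack)
    }
  if (slack > 0L) chosen <- trim_boundary_overlaps(chosen)
  starts <- vapply(chosen, function(m) m$segments[1, 1], integer(1))
  chosen <- chosen[order(starts)]
  structure(list(query_id = qids, matches = chosen,
                 coverage = sum(vapply(chosen, match_coverage, integer(1)))),
            class = "MDA")
}

# When a positive slack admitted small boundary overlaps between
# retained matches, trim the overlapping residues from the weaker
# (higher E-value) match so the reported architecture is strictly
# disjoint.  Segments trimmed to nothing are dropped.
trim_boundary_overlaps <- function(chosen) {
  if (length(chosen) < 2L) return(chosen)
  evs <- vapply(chosen, `[[`, numeric(1), "evalue")
  ord <- order(evs)   # strongest first; earlier matches own contested residues
  for (a in seq_along(ord)[-length(ord)]) {
    for (b in (a + 1L):length(ord)) {
      strong <- chosen[[ord[a]]]
      weak <- chosen[[ord[b]]]
      if (is.null(weak) || is.null(strong)) next
      segs <- weak$segments
      keep <- rep(TRUE, nrow(segs))
      for (i in seq_len(nrow(segs))) {
        for (j in seq_len(nrow(strong$segments))) {
          s <- strong$segments[j, ]
          if (segs[i, 1] >= s[1] && segs[i, 2] <= s[2]) {
            keep[i] <- FALSE
          } else if (segs[i, 1] >= s[1] && segs[i, 1] <= s[2]) {
            segs[i, 1] <- s[2] + 1L
          } else if (segs[i, 2] >= s[1] && segs[i, 2] <= s[2]) {
            segs[i, 2] <- s[1] - 1L
          }
        }
      }
      segs <- segs[keep & segs[, 1] <= segs[, 2], , drop = FALSE]
      chosen[ord[b]] <- if (nrow(segs) == 0L) list(NULL) else
        list(domain_match(weak$query_id, weak$family_id, weak$bit_score,
                          weak$evalue, segs, weak$hmm_span))
    }
  }
  Filter(Negate(is.null), chosen)
}

#' @export
print.MDA <- function(x, ...) {
  cat(sprintf("MDA for %s: %d domains, %d residues covered\n",
              x$query_id, length(x$matches), x$coverage))
  for (m in x$matches) {
    cat(sprintf("  %s %s E=%.3g\n", m$family_id,
                format_segments(m$segments), m$evalue))
  }
  invisible(x)
}

# Solution value for tie-breaking: coverage (max), then E-value product
# (min, compared as sum of logs), then sorted family-id string (min).
solution_key <- function(matches) {
  list(coverage = sum(vapply(matches, match_coverage, integer(1))),
       log_e = sum(vapply(matches, function(m) log(m$evalue), numeric(1))),
       fams = paste(sort(vapply(matches, `[[`, character(1), "family_id")),
                    collapse = "|"))
}

better_solution <- function(a, b) {
  ka <- solution_key(a); kb <- solution_key(b)
  if (ka$coverage != kb$coverage) return(ka$coverage > kb$coverage)
  if (abs(ka$log_e - kb$log_e) > 1e-12) return(ka$log_e < kb$log_e)
  ka$fams < kb$fams
}

# Exact weighted-interval scheduling over single-segment matches.
resolve_wis <- function(matches, slack = 0L) {
  ends <- vapply(matches, function(m) m$segments[1, 2], integer(1))
  ord <- order(ends)
  matches <- matches[ord]
  n <- length(matches)
  # best[[i + 1]] = best solution among the first i matches
  best <- vector("list", n + 1L)
  best[[1L]] <- list()
  for (i in seq_len(n)) {
    skip <- best[[i]]
    # p(i): last match (in end order) whose interval is compatible with
    # match i, i.e. overlaps it by at most `slack` residues
    start_i <- matches[[i]]$segments[1, 1]
    j <- 0L
    for (k in seq_len(i - 1L)) {
      if (matches[[k]]$segments[1, 2] < start_i + slack) j <- k
    }
    take <- c(best[[j + 1L]], matches[i])
    best[[i + 1L]] <- if (better_solution(take, skip)) take else skip
  }
  best[[n + 1L]]
}

# Exhaustive subset search with conflict pruning (discontinuous case).
resolve_exhaustive <- function(matches, slack = 0L) {
  n <- length(matches)
  best <- list()
  recurse <- function(i, chosen) {
    if (i > n) {
      if (length(chosen) && better_solution(chosen, best)) best <<- chosen
      return(invisible(NULL))
    }
    m <- matches[[i]]
    ok <- !any(vapply(chosen, function(c) matches_overlap(c, m, slack),
                      logical(1)))
    if (ok) recurse(i + 1L, c(chosen, list(m)))
    recurse(i + 1L, chosen)
  }
  recurse(1L, list())
  best
}

# Greedy fall-back: accept by ascending E-value when compatible.
resolve_greedy <- function(matches, slack = 0L) {
  evs <- vapply(matches, `[[`, numeric(1), "evalue")
  chosen <- list()
  for (m in matches[order(evs)]) {
    ok <- !any(vapply(chosen, function(c) matches_overlap(c, m, slack),
                      logical(1)))
    if (ok) chosen[[length(chosen) + 1L]] <- m
  }
  chosen
}

#' Export MDAs as a tab-separated table
#'
#' Columns: query, family, superfamily (if a library is given),
#' segments as `s1-e1,s2-e2`, E-value.
#'
#' @param mdas an `MDA` or list of `MDA`.
#' @param path output TSV path, or `NULL` to return the data frame.
#' @param library optional `FamilyLibrary` for superfamily lookup.
#' @return the data frame, invisibly when written to a file.
#' @export
mda_table <- function(mdas, path = NULL, library = NULL) {
  if (inherits(mdas, "MDA")) mdas <- list(mdas)
  rows <- lapply(mdas, function(mda) {
    if (length(mda$matches) == 0L) return(NULL)
    do.call(rbind, lapply(mda$matches, function(m) {
      sf <- if (!is.null(library) && !is.null(library$families[[m$family_id]]))
        library$families[[m$family_id]]$superfamily_id else NA_character_
      data.frame(query = mda$query_id, family = m$family_id,
                 superfamily = sf, segments = format_segments(m$segments),
                 evalue = m$evalue, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query = character(0), family = character(0),
                      superfamily = character(0), segments = character(0),
                      evalue = numeric(0))
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
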