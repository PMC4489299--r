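# Seeded synthetic fixtures: toy ontologies, functional-family
# libraries with subfamily structure, and query sets with known ground
# truth.  Every artifact is byte-identical under a fixed seed, so the
# whole pipeline is testable offline against constructed truth.
#
# The generator emulates the structure of a domain-superfamily
# resource: each superfamily descends from one ancestral random
# sequence; each subfamily (functional family) derives a consensus from
# the ancestor by seeded mutation at twice the member rate, then
# members by mutating the consensus at the member rate.  Each subfamily
# is annotated with a distinct leaf GO term (its functional signature)
# plus a term shared across its superfamily; synthetic domains are
# ungapped and equal-length, so member stacks are valid alignments.

#' Simulation configuration
#'
#' @param seed integer seed driving every random choice.
#' @param n_superfamilies number of superfamilies.
#' @param subfamilies_per_superfamily functional families per
#'   superfamily.
#' @param members_per_subfamily aligned member sequences per family.
#' @param domain_length residues per synthetic domain.
#' @param mutation_rate per-site substitution rate for members in
#'   \[0, 0.5\]; subfamily consensi diverge from the superfamily
#'   ancestor at twice this rate.
#' @param annotated_fraction fraction of members carrying annotations,
#'   in (0, 1\].
#' @param dag_depth,dag_branching shape of the toy ontology tree.
#' @param held_out_per_subfamily single-domain test queries generated
#'   per subfamily (excluded from the alignments).
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L, n_superfamilies = 2L,
                       subfamilies_per_superfamily = 2L,
                       members_per_subfamily = 5L,
                       domain_length = 80L, mutation_rate = 0.05,
                       annotated_fraction = 0.8,
                       dag_depth = 4L, dag_branching = 2L,
                       held_out_per_subfamily = 5L) {
  cfg <- list(seed = as.integer(seed),
              n_superfamilies = as.integer(n_superfamilies),
              subfamilies_per_superfamily =
                as.integer(subfamilies_per_superfamily),
              members_per_subfamily = as.integer(members_per_subfamily),
              domain_length = as.integer(domain_length),
              mutation_rate = mutation_rate,
              annotated_fraction = annotated_fraction,
              dag_depth = as.integer(dag_depth),
              dag_branching = as.integer(dag_branching),
              held_out_per_subfamily = as.integer(held_out_per_subfamily))
  with(cfg, {
    stopifnot(n_superfamilies >= 1, subfamilies_per_superfamily >= 1,
              members_per_subfamily >= 1, domain_length >= 1,
              mutation_rate >= 0, mutation_rate <= 0.5,
              annotated_fraction > 0, annotated_fraction <= 1,
              dag_depth >= 2, dag_branching >= 1,
              held_out_per_subfamily >= 1)
  })
  structure(cfg, class = "SimulationConfig")
}

#' Generate a toy GO DAG and write it as OBO 1.2
#'
#' Builds a single-namespace (molecular_function) tree of the requested
#' depth and branching factor, then gives each non-root term a second
#' parent with probability 0.2, drawn from terms strictly closer to the
#' root (so the graph stays acyclic).
#'
#' @param config a `SimulationConfig`.
#' @param path output OBO path.
#' @return list with `dag` (parsed `GODag`), `path`, and
#'   `terms_by_depth` (list of term id vectors, depth 1 = root).
#' @export
make_toy_dag <- function(config, path = tempfile(fileext = ".obo")) {
  levels <- list("GO:0000001")
  counter <- 1L
  parents <- list()
  with_seed(config$seed + 101L, {
    for (d in 2:config$dag_depth) {
      prev <- levels[[d - 1L]]
      ids <- character(0)
      for (p in prev) {
        for (b in seq_len(config$dag_branching)) {
          counter <- counter + 1L
          id <- sprintf("GO:%07d", counter)
          parents[[id]] <- p
          ids <- c(ids, id)
        }
      }
      levels[[d]] <- ids
    }
    # cross-links: second parent from a strictly shallower level
    for (d in 3:config$dag_depth) {
      for (id in levels[[d]]) {
        if (stats::runif(1) < 0.2) {
          shallow <- unlist(levels[seq_len(d - 1L)])
          cand <- setdiff(shallow, parents[[id]])
          if (length(cand)) {
            parents[[id]] <- c(parents[[id]],
                               cand[sample.int(length(cand), 1L)])
          }
        }
      }
    }
  })
  all_ids <- unlist(levels)
  lines <- c("format-version: 1.2",
             "ontology: toy-go", "")
  for (id in all_ids) {
    lines <- c(lines, "[Term]",
               paste0("id: ", id),
               paste0("name: synthetic term ", sub("GO:", "", id)),
               "namespace: molecular_function")
    ps <- parents[[id]]
    if (length(ps)) {
      lines <- c(lines, paste0("is_a: ", ps[1]))
      if (length(ps) > 1L) {
        lines <- c(lines,
                   paste0("relationship: part_of ", ps[-1L]))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  list(dag = parse_obo(path), path = path, terms_by_depth = levels)
}

#' Generate a synthetic family library with subfamily structure
#'
#' See the module header for the generative model.  Each subfamily gets
#' a distinct leaf term of the toy DAG plus a superfamily-level term
#' shared by all subfamilies of its superfamily; both are annotated on
#' the seeded `annotated_fraction` of members (at least one).  Each
#' subfamily also carries a distinct synthetic EC number on the same
#' members.  Files (aligned FASTA + GAF-like TSV per family, manifest)
#' are written when `dir` is given.
#'
#' @param config a `SimulationConfig`.
#' @param toy_dag result of [make_toy_dag()].
#' @param dir optional output directory for the library files.
#' @return list with `library` (a `FamilyLibrary`, HMMs not built),
#'   `consensi` (named list family id -> consensus sequence),
#'   `truth_terms` (family id -> annotated GO terms) and `dir`.
#' @export
simulate_library <- function(config, toy_dag, dir = NULL) {
  levels <- toy_dag$terms_by_depth
  leaves <- levels[[length(levels)]]
  n_sub_total <- config$n_superfamilies * config$subfamilies_per_superfamily
  if (length(leaves) < n_sub_total) {
    stop("toy DAG has ", length(leaves), " leaves but ", n_sub_total,
         " subfamilies need distinct leaf terms; increase dag_depth or ",
         "dag_branching")
  }
  mid <- levels[[2L]]
  if (length(mid) < config$n_superfamilies) {
    stop("toy DAG level 2 has too few terms for per-superfamily terms")
  }
  fams <- list()
  consensi <- list()
  truth_terms <- list()
  with_seed(config$seed + 202L, {
    leaf_pool <- sample(leaves)
    for (sf in seq_len(config$n_superfamilies)) {
      sf_id <- sprintf("sf%02d", sf)
      sf_term <- mid[sf]
      ancestor <- random_aa(config$domain_length)
      for (sub in seq_len(config$subfamilies_per_superfamily)) {
        fam_id <- sprintf("%s.ff%02d", sf_id, sub)
        consensus <- mutate_aa(ancestor, 2 * config$mutation_rate)
        members <- stats::setNames(
          vapply(seq_len(config$members_per_subfamily), function(m)
            mutate_aa(consensus, config$mutation_rate), character(1)),
          sprintf("%s.m%02d", fam_id, seq_len(config$members_per_subfamily)))
        leaf_term <- leaf_pool[(sf - 1L) * config$subfamilies_per_superfamily
                               + sub]
        n_ann <- max(1L, ceiling(config$annotated_fraction *
                                   config$members_per_subfamily))
        ann_members <- names(members)[
          sort(sample.int(length(members), n_ann))]
        ec <- sprintf("EC:1.1.1.%d",
                      (sf - 1L) * config$subfamilies_per_superfamily + sub)
        ann <- do.call(rbind, lapply(ann_members, function(sid) {
          data.frame(sequence_id = sid,
                     term_id = c(leaf_term, sf_term, ec),
                     stringsAsFactors = FALSE)
        }))
        fams[[fam_id]] <- build_funfam(fam_id, sf_id, members, ann)
        consensi[[fam_id]] <- consensus
        truth_terms[[fam_id]] <- c(leaf_term, sf_term)
      }
    }
  })
  library <- family_library(unname(fams))
  if (!is.null(dir)) write_family_library(library, dir)
  list(library = library, consensi = consensi,
       truth_terms = truth_terms, dir = dir)
}

#' Generate query sequences with known ground truth
#'
#' Emits four query classes: (a) held-out single-domain queries (fresh
#' mutants of each subfamily consensus, never part of the alignments),
#' (b) two-domain concatenations of mutants from two different
#' superfamilies, (c) one discontinuous construction -- a domain split
#' in half with a second domain inserted between the halves, and (d)
#' seeded random negatives with empty truth.  The truth table maps each
#' query to its expected families, segments and propagated GO terms.
#'
#' @param config a `SimulationConfig`.
#' @param sim result of [simulate_library()].
#' @param toy_dag result of [make_toy_dag()] (for truth propagation).
#' @param dir optional directory; writes `queries.fasta` and
#'   `truth.tsv` when given.
#' @param n_negatives number of random negative queries.
#' @return list with `queries` (named character vector) and `truth`
#'   (data frame `query_id`, `type`, `families`, `segments`, `terms`).
#' @export
simulate_queries <- function(config, sim, toy_dag, dir = NULL,
                             n_negatives = 5L) {
  dag <- toy_dag$dag
  consensi <- sim$consensi
  fam_ids <- names(consensi)
  L <- config$domain_length
  queries <- character(0)
  truth <- list()
  add <- function(id, seq, type, families, segments, terms) {
    queries[id] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      query_id = id, type = type,
      families = paste(families, collapse = ","),
      segments = paste(segments, collapse = ";"),
      terms = paste(terms, collapse = ","), stringsAsFactors = FALSE)
  }
  propagated <- function(fids) {
    terms <- unique(unlist(sim$truth_terms[fids], use.names = FALSE))
    sort(unique(c(terms, unlist(lapply(terms, function(t)
      go_ancestors(dag, t)), use.names = FALSE))))
  }
  with_seed(config$seed + 303L, {
    # (a) held-out single-domain queries
    for (fid in fam_ids) {
      for (h in seq_len(config$held_out_per_subfamily)) {
        qid <- sprintf("held.%s.q%02d", fid, h)
        add(qid, mutate_aa(consensi[[fid]], config$mutation_rate),
            "held_out", fid, sprintf("1-%d", L), propagated(fid))
      }
    }
    # (b) a two-domain concatenation across superfamilies
    if (length(fam_ids) >= 2L) {
      sfs <- vapply(strsplit(fam_ids, ".", fixed = TRUE), `[[`,
                    character(1), 1L)
      f1 <- fam_ids[1L]
      f2 <- fam_ids[which(sfs != sfs[1L])[1L]]
      if (!is.na(f2)) {
        d1 <- mutate_aa(consensi[[f1]], config$mutation_rate)
        d2 <- mutate_aa(consensi[[f2]], config$mutation_rate)
        add("multi.2dom", paste0(d1, d2), "two_domain", c(f1, f2),
            c(sprintf("1-%d", L), sprintf("%d-%d", L + 1L, 2L * L)),
            propagated(c(f1, f2)))
        # (c) discontinuous: f1 split in half, f2 inserted in between
        half <- L %/% 2L
        a <- mutate_aa(consensi[[f1]], config$mutation_rate)
        b <- mutate_aa(consensi[[f2]], config$mutation_rate)
        seq_disc <- paste0(substr(a, 1L, half), b,
                           substr(a, half + 1L, L))
        add("multi.disc", seq_disc, "discontinuous", c(f1, f2),
            c(sprintf("1-%d,%d-%d", half, half + L + 1L, 2L * L),
              sprintf("%d-%d", half + 1L, half + L)),
            propagated(c(f1, f2)))
      }
    }
    # (d) random negatives
    for (k in seq_len(n_negatives)) {
      add(sprintf("neg.q%02d", k), random_aa(L), "negative",
          character(0), character(0), character(0))
    }
  })
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(queries),
                                file.path(dir, "queries.fasta"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(queries = queries, truth = truth)
}

#' Write domain matches in HMMER3 `--domtblout` format
#'
#' Fixture writer used to exercise [parse_domtblout()]; emits one row
#' per (match, segment) with the fields the parser consumes (target and
#' query names, i-Evalue, domain bit score, hmm and envelope
#' coordinates) and placeholder values elsewhere.
#'
#' @param matches list of `DomainMatch`.
#' @param path output file.
#' @export
write_domtblout <- function(matches, path) {
  lines <- c(paste0("# target name        accession   tlen query name",
                    "           accession   qlen   E-value  score  bias",
                    "   #  of  c-Evalue  i-Evalue  score  bias  from",
                    "    to  from    to  from    to  acc description"),
             "#------------------- ----------")
  for (m in matches) {
    n_seg <- nrow(m$segments)
    for (s in seq_len(n_seg)) {
      lines <- c(lines, paste(
        m$family_id, "-", "100", m$query_id, "-", "200",
        format(m$evalue, digits = 3), format(m$bit_score, digits = 3),
        "0.0", s, n_seg,
        format(m$evalue, digits = 3), format(m$evalue, digits = 3),
        format(m$bit_score, digits = 3), "0.0",
        m$hmm_span[1], m$hmm_span[2],
        m$segments[s, 1], m$segments[s, 2],
        m$segments[s, 1], m$segments[s, 2],
        "0.90", "-"))
    }
  }
  writeLines(lines, path)
}
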