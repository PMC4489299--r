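# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (exhaustive enumeration, direct set
# arithmetic, matrix closure) and share no code with the implementation
# paths they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# -- cached default synthetic pipeline (built once per test run) -----------

.fixture_cache <- new.env()

default_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  cfg <- sim_config(seed = 42)
  td <- make_toy_dag(cfg)
  sim <- simulate_library(cfg, td)
  lib <- build_library(sim$library, seed = 42)
  q <- simulate_queries(cfg, sim, td)
  .fixture_cache$fx <- list(cfg = cfg, td = td, dag = td$dag, sim = sim,
                            lib = lib, q = q)
  .fixture_cache$fx
}

# -- random profile HMMs for DP oracle tests -------------------------------

random_hmm <- function(n_nodes) {
  emis <- t(vapply(seq_len(n_nodes), function(j) {
    p <- stats::runif(20, 0.05, 1)
    p / sum(p)
  }, numeric(20)))
  colnames(emis) <- AA
  trans <- t(vapply(seq_len(n_nodes), function(j) {
    m3 <- stats::runif(3, 0.05, 1); m3 <- m3 / sum(m3)
    i2 <- stats::runif(2, 0.05, 1); i2 <- i2 / sum(i2)
    d2 <- stats::runif(2, 0.05, 1); d2 <- d2 / sum(d2)
    c(m3, i2, d2)
  }, numeric(7)))
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  structure(list(family_id = "rand", n_nodes = n_nodes,
                 match_emissions = log(emis),
                 insert_emissions = log(rep(1 / 20, 20)),
                 transitions = log(trans),
                 match_columns = seq_len(n_nodes),
                 gumbel_lambda = NA_real_, gumbel_mu = NA_real_),
            class = "ProfileHMM")
}

# Exhaustive enumeration of every local alignment path: entry at any
# match cell, extension through all legal M/I/D moves, exit at any
# match state.  Exponential -- only for n_nodes <= 4, |seq| <= 6.
oracle_viterbi <- function(hmm, sequence) {
  codes <- match(strsplit(toupper(sequence), "")[[1]], AA)
  codes[is.na(codes)] <- 0L
  lo <- (hmm$match_emissions - log(1 / 20)) / log(2)
  tr <- hmm$transitions / log(2)
  K <- hmm$n_nodes
  L <- length(codes)
  emit <- function(i, j) if (codes[i] == 0L) 0 else lo[j, codes[i]]
  best <- -Inf
  extend <- function(st, i, j, sc) {
    if (st == 1L) {             # M: may terminate here
      if (sc > best) best <<- sc
      if (i < L && j < K) extend(1L, i + 1L, j + 1L,
                                 sc + tr[j, "MM"] + emit(i + 1L, j + 1L))
      if (i < L) extend(2L, i + 1L, j, sc + tr[j, "MI"])
      if (j < K) extend(3L, i, j + 1L, sc + tr[j, "MD"])
    } else if (st == 2L) {      # I
      if (i < L && j < K) extend(1L, i + 1L, j + 1L,
                                 sc + tr[j, "IM"] + emit(i + 1L, j + 1L))
      if (i < L) extend(2L, i + 1L, j, sc + tr[j, "II"])
    } else {                    # D
      if (i < L && j < K) extend(1L, i + 1L, j + 1L,
                                 sc + tr[j, "DM"] + emit(i + 1L, j + 1L))
      if (j < K) extend(3L, i, j + 1L, sc + tr[j, "DD"])
    }
  }
  for (i in seq_len(L)) {
    for (j in seq_len(K)) extend(1L, i, j, emit(i, j))
  }
  unname(best)
}

# -- weighted-interval-scheduling optimum (coverage only) ------------------

oracle_wis <- function(starts, ends) {
  ord <- order(ends)
  s <- starts[ord]; e <- ends[ord]
  w <- e - s + 1
  n <- length(s)
  opt <- numeric(n + 1L)
  for (i in seq_len(n)) {
    compat <- which(e < s[i])
    p <- if (length(compat)) max(compat) else 0L
    opt[i + 1L] <- max(opt[i], w[i] + opt[p + 1L])
  }
  opt[n + 1L]
}

# -- brute-force precision/recall from the set definitions -----------------

oracle_pr <- function(pred, truth, thresholds) {
  ids <- names(truth)
  out <- lapply(thresholds, function(t) {
    precs <- c(); recs <- c()
    for (id in ids) {
      p <- pred[[id]]
      P <- names(p)[p >= t]
      hit <- sum(P %in% truth[[id]])
      if (length(P)) precs <- c(precs, hit / length(P))
      recs <- c(recs, hit / length(truth[[id]]))
    }
    c(precision = if (length(precs)) mean(precs) else NA_real_,
      recall = mean(recs))
  })
  do.call(rbind, out)
}

# -- matrix-power transitive closure ---------------------------------------

oracle_closure <- function(parents) {
  ids <- names(parents)
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) adj[id, parents[[id]]] <- TRUE
  reach <- adj
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% adj > 0)
  }
  lapply(ids, function(id) ids[reach[id, ]])
}

# -- random toy ontologies --------------------------------------------------

# Random single-namespace DAG written as OBO and parsed back; node i's
# parents are drawn from nodes 1..(i-1), so the graph is acyclic.
random_dag <- function(n_terms, p_second_parent = 0.3) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  for (i in seq_len(n_terms)[-1]) {
    k <- 1L + (stats::runif(1) < p_second_parent && i > 2L)
    parents[[i]] <- sample(ids[seq_len(i - 1L)], min(k, i - 1L))
  }
  path <- tempfile(fileext = ".obo")
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n_terms)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: t", i), "namespace: molecular_function",
               paste0("is_a: ", parents[[i]]), "")
  }
  writeLines(lines, path)
  list(dag = parse_obo(path), parents = parents, ids = ids, path = path)
}

random_scores <- function(ids, n) {
  terms <- sample(ids, n)
  stats::setNames(stats::runif(n), terms)
}
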