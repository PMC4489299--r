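test_that("identity filter removes close homologs", {
  db <- c(d1 = "MKVLATGWQERIHPLNDAKW", d2 = "GWQERIHPLNDAKWMKVLAT")
  # identical to d1: removed at cutoff 0.5
  q_same <- c(q1 = "MKVLATGWQERIHPLNDAKW")
  expect_length(identity_filter(q_same, db, 0.5), 0)

  # nothing in common: retained
  q_diff <- c(q2 = "CCCCCCCCCCFFFFFFFFFF")
  expect_identical(names(identity_filter(q_diff, db, 0.5)), "q2")

  # straddling identities agree with a hand-computed predicate:
  # mutate k of 20 residues -> identity (20 - k) / 20 under an
  # ungapped global alignment
  base <- "MKVLATGWQERIHPLNDAKW"
  withr::with_seed(51, {
    queries <- vapply(c(2, 6, 9, 11, 14, 18), function(k) {
      chars <- strsplit(base, "")[[1]]
      pos <- sample(20, k)
      chars[pos] <- vapply(chars[pos], function(a)
        sample(setdiff(AA, a), 1), character(1))
      paste(chars, collapse = "")
    }, character(1))
  })
  names(queries) <- sprintf("k%02d", c(2, 6, 9, 11, 14, 18))
  kept <- identity_filter(queries, db["d1"], 0.5)
  manual <- queries[(20 - c(2, 6, 9, 11, 14, 18)) / 20 <= 0.5]
  expect_identical(names(kept), names(manual))

  expect_warning(out <- identity_filter(q_same, character(0), 0.5),
                 "empty")
  expect_identical(out, q_same)
})

test_that("rollback targets are the newly annotated proteins", {
  earlier <- data.frame(sequence_id = c("p1", "p2"),
                        term_id = c("GO:1", "GO:2"))
  later <- data.frame(sequence_id = c("p1", "p2", "p3", "p4"),
                      term_id = c("GO:1", "GO:2", "GO:3", "GO:4"))
  expect_setequal(rollback_targets(earlier, later), c("p3", "p4"))
})

test_that("BLAST-style baseline transfers top-hit terms at confidence 1", {
  fx <- default_fixture()
  fid <- names(fx$lib$families)[1]
  fam <- fx$lib$families[[fid]]
  db_seqs <- vapply(fx$lib$families, function(f)
    gsub("-", "", f$alignment[[1]]), character(1))
  names(db_seqs) <- names(fx$lib$families)
  db_ann <- lapply(fx$lib$families, function(f)
    names(f$term_frequencies))

  out <- blast_baseline(db_seqs[[fid]], db_seqs, db_ann, fx$dag)
  expect_true(all(out$scores == 1.0))
  expect_true(all(names(fam$term_frequencies) %in% names(out$scores)))

  expect_length(blast_baseline("MKVL", character(0), list(),
                               fx$dag)$scores, 0)
})

test_that("flat superfamily pooling dilutes subfamily-specific terms", {
  cfg <- sim_config(seed = 8, n_superfamilies = 1,
                    members_per_subfamily = 10, annotated_fraction = 1,
                    held_out_per_subfamily = 1)
  td <- make_toy_dag(cfg)
  sim <- simulate_library(cfg, td)
  lib <- build_library(sim$library, seed = 8)
  flat <- build_library(collapse_to_superfamilies(sim$library), seed = 8)
  expect_identical(flat$db_size, 1L)

  q <- simulate_queries(cfg, sim, td)
  fid <- names(sim$consensi)[1]
  leaf <- sim$truth_terms[[fid]][1]       # subfamily-specific leaf term
  qid <- q$truth$query_id[q$truth$type == "held_out" &
                            q$truth$families == fid][1]
  ff <- annotate_sequence(q$queries[[qid]], lib, td$dag)
  fl <- flat_family_baseline(q$queries[[qid]], flat, td$dag)
  expect_equal(ff$protein_annotations$scores[[leaf]], 1.0)
  expect_equal(fl$scores[[leaf]], 0.5)   # 10 of 20 pooled members

  # shared superfamily-level term undiluted in both
  sf_term <- sim$truth_terms[[fid]][2]
  expect_equal(fl$scores[[sf_term]], 1.0)
})

test_that("flat baseline equals the pipeline when subclassification is trivial", {
  cfg <- sim_config(seed = 13, n_superfamilies = 2,
                    subfamilies_per_superfamily = 1,
                    held_out_per_subfamily = 1)
  td <- make_toy_dag(cfg)
  sim <- simulate_library(cfg, td)
  lib <- build_library(sim$library, seed = 13)
  flat <- build_library(collapse_to_superfamilies(sim$library), seed = 13)
  q <- simulate_queries(cfg, sim, td)
  qid <- q$truth$query_id[q$truth$type == "held_out"][1]
  ff <- annotate_sequence(q$queries[[qid]], lib, td$dag)$protein_annotations
  fl <- flat_family_baseline(q$queries[[qid]], flat, td$dag)
  expect_equal(fl$scores[sort(names(fl$scores))],
               ff$scores[sort(names(ff$scores))])
})

test_that("precision-recall reproduces hand-computed values", {
  # perfect predictor
  truth <- list(p1 = c("a", "b"), p2 = c("a"))
  bm <- benchmark_set(truth, "MFO")
  perfect <- list(p1 = c(a = 1, b = 1), p2 = c(a = 1))
  pr <- precision_recall(perfect, bm, n_thresholds = 11)
  expect_equal(pr$fmax, 1)
  expect_true(all(pr$precision == 1))
  expect_true(all(pr$recall == 1))

  # worked 2-protein example: at t = 1.0, precision 0.5, recall 0.25
  pred <- list(p1 = c(a = 1.0, c = 1.0), p2 = numeric(0))
  pr2 <- precision_recall(pred, bm, n_thresholds = 101)
  at1 <- which(pr2$thresholds == 1)
  expect_equal(pr2$precision[at1], 0.5)
  expect_equal(pr2$recall[at1], 0.25)

  expect_error(precision_recall(perfect, benchmark_set(list(), "MFO")),
               "non-empty|empty")
})

test_that("precision-recall agrees with a brute-force oracle", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      terms <- letters[1:6]
      n_prot <- sample(2:5, 1)
      truth <- lapply(seq_len(n_prot), function(i)
        sample(terms, sample(1:4, 1)))
      names(truth) <- paste0("p", seq_len(n_prot))
      pred <- lapply(truth, function(x) {
        n <- sample(0:5, 1)
        if (n == 0) return(numeric(0))
        stats::setNames(round(stats::runif(n), 2), sample(terms, n))
      })
      bm <- benchmark_set(truth, "MFO")
      pr <- precision_recall(pred, bm, n_thresholds = 21)
      want <- oracle_pr(pred, truth, pr$thresholds)
      expect_equal(pr$precision, unname(want[, "precision"]))
      expect_equal(pr$recall, unname(want[, "recall"]))
      # recall never increases as the threshold rises (thresholds are
      # stored in descending order)
      expect_true(all(diff(pr$recall) >= -1e-12))
    }
  })
})
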