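test_that("profile construction follows the count rules", {
  # single ungapped sequence: one node per residue, peaked emissions
  hmm <- build_profile_hmm(c(s = "MKWDE"))
  expect_identical(hmm$n_nodes, 5L)
  p <- exp(hmm$match_emissions)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_equal(unname(p[1, "M"]), 2 / 21)  # count 1 + pseudocount, over 21
  expect_equal(unname(which.max(p[3, ])), which(colnames(p) == "W"))

  # column with 3 of 4 rows gapped is not a match node
  aln <- c(a = "MA", b = "M-", c = "M-", d = "M-")
  expect_identical(build_profile_hmm(aln)$n_nodes, 1L)

  # counts {A:3} with pseudocount 1 -> P(A) = 4/23
  aln3 <- c(a = "A", b = "A", c = "A")
  expect_equal(unname(exp(build_profile_hmm(aln3)$match_emissions)[1, "A"]),
               4 / 23)

  # transition triplets normalize
  tr <- exp(build_profile_hmm(c(a = "MKVL", b = "MKVL"))$transitions)
  expect_true(all(abs(rowSums(tr[, c("MM", "MI", "MD")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(tr[, c("IM", "II")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(tr[, c("DM", "DD")]) - 1) < 1e-9))

  expect_error(build_profile_hmm(c(a = "--", b = "--", c = "AA")),
               "no match columns")
})

test_that("local Viterbi matches exhaustive path enumeration", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      K <- sample(1:4, 1)
      L <- sample(1:6, 1)
      hmm <- random_hmm(K)
      seq <- paste(sample(c(AA, "X"), L, replace = TRUE,
                          prob = c(rep(1, 20), 0.5)), collapse = "")
      got <- viterbi_local(hmm, seq)$bit_score
      want <- oracle_viterbi(hmm, seq)
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("K=%d seq=%s dp=%g", K, seq, got))
    }
  })
})

test_that("Viterbi recognises members and reduces correctly on one node", {
  fx <- default_fixture()
  fid <- names(fx$lib$hmms)[1]
  hmm <- fx$lib$hmms[[fid]]
  member <- gsub("-", "", fx$lib$families[[fid]]$alignment[[1]])
  self_score <- viterbi_local(hmm, member)$bit_score
  withr::with_seed(5, {
    rand <- paste(sample(AA, nchar(member), replace = TRUE), collapse = "")
  })
  expect_gt(self_score, viterbi_local(hmm, rand)$bit_score)

  # one-node model: best single-residue log-odds, brute-forced
  withr::with_seed(6, h1 <- random_hmm(1))
  seqs <- "WKDYAN"
  lo <- (h1$match_emissions - log(1 / 20)) / log(2)
  codes <- match(strsplit(seqs, "")[[1]], AA)
  expect_equal(viterbi_local(h1, seqs)$bit_score, max(lo[1, codes]))

  expect_error(viterbi_local(h1, ""), "non-empty")
})

test_that("Gumbel calibration is seeded, validated and recoverable", {
  fx <- default_fixture()
  hmm <- build_profile_hmm(fx$lib$families[[1]])
  c1 <- calibrate_evalue(hmm, n_random = 120, length = 90, seed = 7)
  c2 <- calibrate_evalue(hmm, n_random = 120, length = 90, seed = 7)
  expect_identical(c1$gumbel_lambda, c2$gumbel_lambda)
  expect_identical(c1$gumbel_mu, c2$gumbel_mu)

  expect_error(calibrate_evalue(hmm, n_random = 50), "n_random >= 100")
  expect_error(fit_gumbel(rep(3, 200)), "degenerate")

  # parameter recovery from true Gumbel draws
  withr::with_seed(11, {
    draws <- 10 - log(-log(stats::runif(5000))) / 0.7
  })
  fit <- fit_gumbel(draws)
  expect_lt(abs(fit$lambda - 0.7) / 0.7, 0.1)
  expect_lt(abs(fit$mu - 10), 0.5)
})

test_that("E-values follow the Gumbel closed form and are monotone", {
  fx <- default_fixture()
  hmm <- fx$lib$hmms[[1]]
  expect_equal(hmm_evalue(hmm, hmm$gumbel_mu, db_size = 1),
               1 - exp(-1), tolerance = 1e-12)
  expect_lt(hmm_evalue(hmm, hmm$gumbel_mu + 100, 1), 1e-20)
  scores <- seq(hmm$gumbel_mu - 1, hmm$gumbel_mu + 15, length.out = 40)
  evs <- vapply(scores, function(s) hmm_evalue(hmm, s, 4), numeric(1))
  expect_true(all(diff(evs) < 0))
  expect_equal(hmm_evalue(hmm, 12, db_size = 4),
               4 * hmm_evalue(hmm, 12, db_size = 1))

  un <- build_profile_hmm(fx$lib$families[[1]])
  expect_error(hmm_evalue(un, 10), "not calibrated")
})

test_that("scanning recovers members, is deterministic and prefilters", {
  fx <- default_fixture()
  fid <- names(fx$lib$families)[2]
  member <- gsub("-", "", fx$lib$families[[fid]]$alignment[[1]])
  hits <- scan_sequence(member, fx$lib, "m")
  expect_gt(length(hits), 0)
  expect_identical(hits[[1]]$family_id, fid)   # minimal E-value first
  evs <- vapply(hits, `[[`, numeric(1), "evalue")
  expect_true(!is.unsorted(evs))
  expect_true(all(evs <= 10))

  # byte-identical repeat
  hits2 <- scan_sequence(member, fx$lib, "m")
  expect_identical(hits, hits2)

  # empty library
  empty <- build_library(family_library(list()))
  expect_identical(scan_sequence(member, empty), list())

  # seeded random negatives rarely pass inclusion thresholds
  withr::with_seed(21, {
    n_sig <- sum(vapply(1:10, function(i) {
      q <- paste(sample(AA, 80, replace = TRUE), collapse = "")
      length(filter_significant(scan_sequence(q, fx$lib), fx$lib)) > 0
    }, logical(1)))
  })
  expect_identical(n_sig, 0L)
})

test_that("domtblout rows round-trip through the fixture writer", {
  m1 <- domain_match("q1", "famA", 52.1, 1.3e-12,
                     matrix(c(4L, 98L), ncol = 2), c(2L, 91L))
  m2 <- domain_match("q2", "famB", 33.0, 2.5e-6,
                     matrix(c(10L, 80L), ncol = 2), c(1L, 70L))
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(list(m1, m2), path)
  back <- parse_domtblout(path)
  expect_length(back, 2)
  expect_identical(back[[1]]$family_id, "famA")
  expect_identical(back[[1]]$query_id, "q1")
  expect_identical(back[[1]]$segments, m1$segments)
  expect_identical(back[[1]]$hmm_span, m1$hmm_span)
  expect_equal(back[[1]]$evalue, 1.3e-12)
  expect_equal(back[[2]]$bit_score, 33.0)

  # comment-only file
  p2 <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# a comment", "# another"), p2)
  expect_identical(parse_domtblout(p2), list())

  # malformed rows raise errors naming the line
  p3 <- withr::local_tempfile(fileext = ".domtblout")
  writeLines("too few columns here", p3)
  expect_error(parse_domtblout(p3), "line 1")
  p4 <- withr::local_tempfile(fileext = ".domtblout")
  lines <- readLines(path)
  bad <- gsub("1.3e-12", "not-a-number", lines, fixed = TRUE)
  writeLines(bad, p4)
  expect_error(parse_domtblout(p4), "line 3")
})

test_that("profiles serialize to JSON lines and back", {
  fx <- default_fixture()
  hmm <- fx$lib$hmms[[1]]
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_hmm_jsonl(hmm, path)
  back <- read_hmm_jsonl(path)
  expect_identical(back$n_nodes, hmm$n_nodes)
  expect_equal(back$match_emissions, hmm$match_emissions,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$transitions, hmm$transitions,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$gumbel_lambda, hmm$gumbel_lambda)
  # scores agree after a round trip
  seqs <- gsub("-", "", fx$lib$families[[1]]$alignment[[2]])
  expect_equal(viterbi_local(back, seqs)$bit_score,
               viterbi_local(hmm, seqs)$bit_score, tolerance = 1e-9)
})

test_that("alignment rendering marks matches, inserts and deletions", {
  fx <- default_fixture()
  fid <- names(fx$lib$hmms)[1]
  hmm <- fx$lib$hmms[[fid]]
  member <- gsub("-", "", fx$lib$families[[fid]]$alignment[[1]])
  v <- viterbi_local(hmm, member)
  txt <- render_alignment(hmm, member, v$path)
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(lines, 3)
  # coordinates equal the match segment bounds
  expect_match(lines[3], paste0(" ", v$segment[1], " "))
  expect_match(lines[3], paste0(" ", v$segment[2], "$"))
  # a member alignment is overwhelmingly identities
  expect_gt(nchar(gsub("[^|]", "", lines[2])) / nchar(member), 0.6)

  # a path with one deletion renders exactly one "-" in the query line
  path <- data.frame(state = c("M", "D", "M"), seq_pos = c(1L, 1L, 2L),
                     node = 1:3)
  txt2 <- render_alignment(hmm, "MK", path)
  q <- strsplit(txt2, "\n")[[1]][3]
  expect_identical(nchar(gsub("[^-]", "", q)), 1L)

  bad <- data.frame(state = "M", seq_pos = 99L, node = 1L)
  expect_error(render_alignment(hmm, "MK", bad), "inconsistent")
})
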