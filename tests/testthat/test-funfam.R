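test_that("family construction validates alignments and degenerate input", {
  ff <- build_funfam("f1", "sf", c(s1 = "MKVLAT"))
  expect_s3_class(ff, "FunFam")
  expect_length(ff$term_frequencies, 0)
  expect_true(is.na(ff$inclusion_threshold))

  expect_error(build_funfam("f1", "sf", c(a = "MKVLATQRPW", b = "MKVLATQRPWS")),
               "ragged")
  expect_error(build_funfam("f1", "sf", character(0)), "empty")
  expect_error(build_funfam("f1", "sf", c(a = "MKV"),
                            data.frame(sequence_id = "zz",
                                       term_id = "GO:0000001")),
               "absent")
})

test_that("term frequencies count only annotated members", {
  # 5 annotated members: 3 carry X, 1 carries Y
  aln <- setNames(rep("MKVL", 5), paste0("s", 1:5))
  ann <- data.frame(
    sequence_id = c("s1", "s2", "s3", "s4", "s1", "s2", "s3", "s4", "s5"),
    term_id = c(rep("GO:000000X", 3), "GO:000000Y",
                rep("GO:000000Z", 5)))
  ff <- build_funfam("f", "sf", aln, ann)
  expect_equal(ff$term_frequencies[["GO:000000X"]], 0.6)
  expect_equal(ff$term_frequencies[["GO:000000Y"]], 0.2)
  expect_equal(ff$term_frequencies[["GO:000000Z"]], 1.0)

  # unannotated members excluded from the denominator
  aln2 <- setNames(rep("MKVL", 5), paste0("s", 1:5))
  ann2 <- data.frame(sequence_id = c("s1", "s2"),
                     term_id = c("GO:000000X", "GO:000000X"))
  ff2 <- build_funfam("f2", "sf", aln2, ann2)
  expect_equal(ff2$term_frequencies[["GO:000000X"]], 1.0)

  # unanimous
  ann3 <- data.frame(sequence_id = paste0("s", 1:4),
                     term_id = rep("GO:000000X", 4))
  ff3 <- build_funfam("f3", "sf", aln2[1:4], ann3)
  expect_equal(unname(ff3$term_frequencies), 1.0)

  # exact count identity: freq * n_annotated is an integer count
  for (t in names(ff$term_frequencies)) {
    n_carrying <- sum(vapply(ff$member_annotations, function(a) t %in% a,
                             logical(1)))
    n_annotated <- sum(lengths(ff$member_annotations) > 0)
    expect_identical(ff$term_frequencies[[t]] * n_annotated,
                     as.numeric(n_carrying))
  }
})

test_that("EC numbers get frequencies but are kept apart from GO terms", {
  aln <- c(s1 = "MKVL", s2 = "MKVL")
  ann <- data.frame(sequence_id = c("s1", "s1", "s2"),
                    term_id = c("GO:0000002", "EC:1.1.1.1", "EC:1.1.1.1"))
  ff <- build_funfam("f", "sf", aln, ann)
  expect_equal(names(ff$term_frequencies), "GO:0000002")
  expect_equal(ff$ec_frequencies[["EC:1.1.1.1"]], 1.0)
  expect_equal(ff$term_frequencies[["GO:0000002"]], 1.0)  # s2 has no GO
})

test_that("inclusion threshold is the worst member self-scan E-value", {
  aln <- c(a = "MKVLAT", b = "MKVIAT", c = "MKVLCT")
  ff <- build_funfam("f", "sf", aln)
  evs <- c(a = 1e-40, b = 1e-35, c = 1e-12)
  ff <- compute_inclusion_threshold(ff, function(s, sid) evs[[sid]])
  expect_equal(ff$inclusion_threshold, 1e-12)

  # singleton family
  ff1 <- build_funfam("g", "sf", aln[1])
  ff1 <- compute_inclusion_threshold(ff1, function(s, sid) 3.7e-9)
  expect_equal(ff1$inclusion_threshold, 3.7e-9)

  # brute-force oracle: threshold equals an explicit loop over members
  # with a scanner that depends on the sequence content
  scanner <- function(s, sid) 10^(-nchar(gsub("[^M]", "", s)) - 5)
  ff2 <- compute_inclusion_threshold(ff, scanner)
  manual <- max(vapply(names(aln), function(sid)
    scanner(gsub("-", "", aln[[sid]]), sid), numeric(1)))
  expect_equal(ff2$inclusion_threshold, manual)

  expect_error(compute_inclusion_threshold(ff, function(s, sid) NA_real_),
               "invalid")
})

test_that("conservation scores are bounded and reward invariant columns", {
  ff <- build_funfam("f", "sf", c(a = "AC", b = "AC"))
  expect_equal(conservation_scores(ff), c(1, 1))

  expect_error(conservation_scores(build_funfam("g", "sf", c(a = "AC"))),
               "at least 2")

  # 20 distinct residues in one column score strictly below invariant
  aln <- setNames(paste0(AA, "A"), paste0("s", 1:20))
  ff2 <- build_funfam("h", "sf", aln)
  cs <- conservation_scores(ff2)
  expect_lt(cs[1], cs[2])
  expect_equal(cs[2], 1)

  # bounds on a random gapped alignment; gap-free invariant column = 1
  withr::with_seed(9, {
    rows <- vapply(1:6, function(i) {
      chars <- sample(c(AA, "-"), 12, replace = TRUE)
      chars[5] <- "W"
      paste(chars, collapse = "")
    }, character(1))
  })
  ff3 <- build_funfam("k", "sf", setNames(rows, paste0("s", 1:6)))
  cs3 <- conservation_scores(ff3)
  expect_true(all(cs3 >= 0 & cs3 <= 1))
  expect_equal(cs3[5], 1)
})

test_that("family library round-trips through manifest files", {
  fx <- default_fixture()
  dir <- withr::local_tempdir()
  man <- write_family_library(fx$sim$library, dir)
  lib2 <- read_family_library(file.path(dir, "manifest.tsv"))
  expect_setequal(names(lib2$families), names(fx$sim$library$families))
  for (fid in names(lib2$families)) {
    a <- fx$sim$library$families[[fid]]
    b <- lib2$families[[fid]]
    expect_identical(a$alignment, b$alignment)
    expect_identical(a$superfamily_id, b$superfamily_id)
    expect_equal(a$term_frequencies[sort(names(a$term_frequencies))],
                 b$term_frequencies[sort(names(b$term_frequencies))])
    expect_equal(a$ec_frequencies, b$ec_frequencies)
  }
  expect_error(family_library(list(build_funfam("x", "s", c(a = "MK")),
                                   build_funfam("x", "s", c(b = "MK")))),
               "duplicate")
})

test_that("a hand-written gapped alignment builds a family cleanly", {
  path <- system.file("extdata", "gapped_family.aln.fasta",
                      package = "funfamscan")
  aln <- read_alignment_fasta(path)
  ff <- build_funfam("gapped", "sf99", aln)
  cs <- conservation_scores(ff)
  expect_true(all(cs >= 0 & cs <= 1))
  hmm <- build_profile_hmm(ff)
  # mostly-gap columns must not become match nodes
  gap_frac <- colMeans(do.call(rbind, strsplit(aln, "")) == "-")
  expect_identical(hmm$n_nodes, sum(gap_frac < 0.5))
})
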