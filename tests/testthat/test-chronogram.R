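test_that("node ages are branch-length path sums to the leaves", {
  tr <- read_datedist(text = "((A:1.0,B:1.0):1.0,C:2.0);")
  expect_equal(n_samples(tr), 1L)
  ch <- tr$samples[[1L]]
  mrca <- resolve_node(ch, clade_definition("AB", c("A", "B")))
  expect_equal(ch$ages[mrca], 1.0)
  expect_equal(root_age(ch), 2.0)
  expect_equal(ch$ages[1:3], c(0, 0, 0))   # extant tips
})

test_that("datedist parsing: header skipping, empty input, malformed lines, leaf-set mismatch", {
  # a leading non-tree line (e.g. a count) is tolerated
  tr <- read_datedist(text = c("2", "((A:1,B:1):1,C:2);", "((A:2,B:2):1,C:3);"))
  expect_equal(n_samples(tr), 2L)

  expect_error(read_datedist(text = character(0)), class = "hgtclock_empty_trace")
  expect_error(read_datedist(text = "10"), class = "hgtclock_empty_trace")

  err <- tryCatch(read_datedist(text = c("((A:1,B:1):1,C:2);", "((A:1,B:1:1,C;")),
                  hgtclock_parse_error = identity)
  expect_s3_class(err, "hgtclock_parse_error")
  expect_match(conditionMessage(err), "line 2")

  expect_error(read_datedist(text = c("((A:1,B:1):1,C:2);",
                                      "((A:1,X:1):1,C:2);")),
               class = "hgtclock_leafset_mismatch")
})

test_that("non-ultrametric trees are rejected by default and repairable by mean path sums", {
  bad <- "((A:1,B:2):1,C:2);"
  expect_error(read_datedist(text = bad), class = "hgtclock_not_ultrametric")
  tr <- read_datedist(text = bad, on_violation = "repair")
  ch <- tr$samples[[1L]]
  # repaired cherry age = mean of its leaf path sums (1, 2) = 1.5
  mrca <- resolve_node(ch, clade_definition("AB", c("A", "B")))
  expect_equal(ch$ages[mrca], 1.5)
})

test_that("validate_ultrametric reports exactly the perturbed leaf", {
  phy <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  v <- validate_ultrametric(phy)
  expect_equal(v$leaf, "B")
  expect_equal(v$observed_depth, 3)
  expect_equal(v$expected_depth, 2)

  for (seed in 1:5) {
    ch <- random_chronogram(8, seed = seed)
    expect_equal(nrow(validate_ultrametric(ch)), 0L)
    phy <- hgtclock:::as_dated_phylo(ch)
    tol <- 1e-6
    term <- which(phy$edge[, 2L] <= ape::Ntip(phy))
    pick <- term[(seed %% length(term)) + 1L]
    leaf <- phy$tip.label[phy$edge[pick, 2L]]
    phy$edge.length[pick] <- phy$edge.length[pick] +
      10 * tol * root_age(ch)
    v <- validate_ultrametric(phy, tol = tol)
    expect_equal(v$leaf, leaf)
  }
})

test_that("tie and inverted parent/child ages are parse errors", {
  expect_error(read_datedist(text = "((A:1,B:1):0,C:1);"),
               class = "hgtclock_tie_age")
  expect_error(hgtclock:::new_chronogram(
    ape::read.tree(text = "((A:1,B:1):1,C:2);"), c(0, 0, 0, 1, 2)),
    class = "hgtclock_order_violation")
})

test_that("round-trip through the datedist dialect preserves topology and ages", {
  ex <- phototroph_example()
  sim <- simulate_posterior_trace(ex$truth, sd = 40, n = 5, seed = 11)
  f <- tempfile(fileext = ".datedist")
  on.exit(unlink(f), add = TRUE)
  write_datedist(sim$trace, f)
  back <- read_datedist(f)
  expect_equal(n_samples(back), 5L)
  for (i in 1:5) {
    expect_equal(back$samples[[i]]$ages, sim$age_matrix[i, ], tolerance = 1e-9)
    expect_true(all(ape::Ntip(back$samples[[i]]$phy) == 18L))
  }
})

test_that("parse/serialize round-trip preserves ages on many random trees", {
  for (seed in 1:20) {
    ch <- random_chronogram(sample(4:12, 1), seed = 100 + seed)
    line <- write_datedist(chronogram_trace(list(ch)))
    back <- read_datedist(text = line)$samples[[1L]]
    expect_equal(back$ages, ch$ages, tolerance = 1e-9)
    # strict ordering invariant on every parsed chronogram
    e <- back$phy$edge
    expect_true(all(back$ages[e[, 1L]] > back$ages[e[, 2L]]))
  }
})

test_that("crown resolves to the MRCA, stem to its parent, with monophyly enforced", {
  ex <- phototroph_example()
  ch <- ex$truth
  all_tips <- ch$phy$tip.label

  expect_equal(resolve_node(ch, clade_definition("all", all_tips)),
               ape::Ntip(ch$phy) + 1L)
  expect_error(resolve_node(ch, clade_definition("all", all_tips, "stem")),
               class = "hgtclock_no_stem")
  expect_error(resolve_node(ch, clade_definition("bad", c("GSB_1", "ZZZ"))),
               class = "hgtclock_unknown_taxon")

  # stem age is strictly older than crown age wherever both exist
  for (cl in ex$clades) {
    if (cl$selector != "crown") next
    crown <- resolve_node(ch, cl)
    stem <- resolve_node(ch, clade_definition(cl$name, cl$tips, "stem"))
    expect_gt(ch$ages[stem], ch$ages[crown])
  }

  # paraphyletic set: GSB_1 + Bacteroidetes_1 spans Ignavibacteria too
  para <- clade_definition("para", c("GSB_1", "Bacteroidetes_1"))
  expect_error(resolve_node(ch, para), class = "hgtclock_not_monophyletic")
  relaxed <- resolve_node(ch, para, strict = FALSE)
  expect_equal(relaxed, brute_mrca(ch$phy, para$tips))
})

test_that("crown MRCA matches the root-path intersection oracle on random trees", {
  for (seed in 1:15) {
    ch <- random_chronogram(8, seed = 300 + seed)
    tips <- sample(ch$phy$tip.label, sample(2:6, 1))
    got <- resolve_node(ch, clade_definition("x", tips), strict = FALSE)
    expect_equal(got, brute_mrca(ch$phy, tips))
  }
})

test_that("clade_age_trace preserves sample order and matches generator bookkeeping", {
  ex <- phototroph_example()
  sim <- simulate_posterior_trace(ex$truth, sd = 60, n = 40, seed = 7)
  cl <- ex$clades[["Crown GSB"]]
  node <- resolve_node(ex$truth, cl)
  at <- clade_age_trace(sim$trace, cl)
  expect_s3_class(at, "age_trace")
  expect_equal(at$ages, sim$age_matrix[, node])

  err <- tryCatch(
    clade_age_trace(sim$trace, clade_definition("bad", c("GSB_1", "Nessie"))),
    hgtclock_unknown_taxon = identity)
  expect_match(conditionMessage(err), "Nessie")
  expect_match(conditionMessage(err), "sample 1")
})
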