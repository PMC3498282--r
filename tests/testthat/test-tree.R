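# Tree plumbing: parsing, validation, pruning, rescaling, branching times,
# LTT series.

test_that("parse_tree reads Newick and computes crown age from path lengths", {
  tr <- parse_tree("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(crown_age(tr), 2)

  # non-ultrametric input parses; ultrametricity is a separate check
  tr2 <- parse_tree("((A:1,B:1):1,C:2.5);")
  expect_equal(crown_age(tr2), 2.5)
  expect_false(check_ultrametric(tr2))

  # quoted labels and comments
  tr3 <- parse_tree("(('sp one':1,B:1)[a comment]:1,C:2);")
  expect_true("sp one" %in% tr3$tip.label)
})

test_that("parse_tree rejects malformed input with informative errors", {
  expect_error(parse_tree("((A:1,B:1):1,C:2));"), "position")
  expect_error(parse_tree("((A:1,(B:1):1,C:2;"), "unclosed")
  expect_error(parse_tree("((A:1,B:1):1,C:2)"), ";")
  expect_error(parse_tree("((A:1,B):1,C:2);"), "branch length")
  expect_error(parse_tree("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("ultrametricity check uses a relative tolerance on crown age", {
  expect_true(check_ultrametric(parse_tree("((A:1,B:1):1,C:2);"), 1e-6))
  expect_false(check_ultrametric(parse_tree("((A:1,B:1):1,C:2.5);"), 1e-6))
  # deviation 1e-7 on crown 2 is within 1e-6 * 2
  expect_true(check_ultrametric(parse_tree("((A:1,B:1):1,C:2.0000001);"), 1e-6))
})

test_that("pruning to a clade gives the induced ultrametric subtree", {
  tr <- parse_tree("((A:1,B:1):2,(C:2,D:2):1);")
  p <- prune_to_clade(tr, c("A", "B", "C"))
  expect_equal(ape::Ntip(p), 3)
  expect_equal(crown_age(p), 3)
  expect_equal(branching_times(p)$ages, c(3, 1))

  # keeping every tip preserves branching times exactly
  all_kept <- prune_to_clade(tr, tr$tip.label)
  expect_equal(branching_times(all_kept)$ages, branching_times(tr)$ages)

  expect_error(prune_to_clade(tr, c("A", "B", "Z")), "Z")
  expect_error(prune_to_clade(tr, c("A", "B")), "at least 3")
})

test_that("pruned branching times equal brute-force pairwise-MRCA ages", {
  tr <- simulate_yule(n_tips = 20, lambda = 0.15, seed = 42)
  keep <- sort(tr$tip.label)[c(1, 3, 5, 8, 12, 15, 17, 20)]
  got <- branching_times(prune_to_clade(tr, keep))$ages

  # oracle: the induced subtree's internal nodes are exactly the MRCAs of
  # tip pairs drawn from the subset; collect them and read off their ages
  depths <- ape::node.depth.edgelength(tr)
  crown <- max(depths[seq_len(ape::Ntip(tr))])
  idx <- match(keep, tr$tip.label)
  mrcas <- unique(unlist(lapply(seq_along(idx)[-1], function(i)
    sapply(seq_len(i - 1), function(j) ape::getMRCA(tr, c(idx[i], idx[j]))))))
  oracle <- sort(crown - depths[mrcas], decreasing = TRUE)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("rescaling multiplies all branch lengths by target/crown", {
  tr <- parse_tree("((A:1,B:1):1,C:2);")
  r <- rescale_root_age(tr, 11.1)
  expect_equal(crown_age(r), 11.1)
  expect_equal(r$edge.length, tr$edge.length * 5.55)

  expect_equal(rescale_root_age(tr, 2)$edge.length, tr$edge.length)
  back <- rescale_root_age(rescale_root_age(tr, 11.1), 2)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-12)
  expect_error(rescale_root_age(tr, -1), "positive")
})

test_that("branching times are sorted node ages with the crown first", {
  expect_equal(branching_times(parse_tree("((A:1,B:1):1,C:2);"))$ages, c(2, 1))
  expect_equal(branching_times(parse_tree("(((A:1,B:1):1,C:2):1,D:3);"))$ages,
               c(3, 2, 1))

  tr <- simulate_yule(n_tips = 50, lambda = 0.2, seed = 99)
  bt <- branching_times(tr)
  expect_equal(bt$n_tips, 50)
  expect_equal(length(bt$ages), 49)
  expect_equal(bt$crown_age, crown_age(tr))
  # independent oracle: ape's own node-age computation
  expect_equal(bt$ages, sort(unname(ape::branching.times(tr)), decreasing = TRUE),
               tolerance = 1e-10)
})

test_that("branching_times rejects bad trees with explicit errors", {
  expect_error(branching_times(parse_tree("((A:1,B:1):1,C:2.5);")), "deviation")
  expect_error(branching_times(parse_tree("(A:1,B:1,C:1);")), "polytom")
  expect_error(branching_times(parse_tree("(A:1,B:1);")), "at least 3")
  expect_error(as_branching_times(c(2, -1)), "positive")
})

test_that("LTT series is the expected step function", {
  l <- ltt(as_branching_times(c(2, 1)))
  expect_equal(l$age, c(2, 1, 0))
  expect_equal(l$count, c(2, 3, 3))
  expect_equal(l$log_count, log(l$count))

  bt <- branching_times(simulate_yule(n_tips = 17, lambda = 0.3, seed = 5))
  l2 <- ltt(bt)
  expect_equal(l2$count[1], 2)
  expect_equal(l2$count[nrow(l2)], 17)
  expect_true(all(diff(l2$count) >= 0))
  # interval durations partition the crown age
  expect_equal(sum(-diff(l2$age)), bt$crown_age)

  tf <- tempfile(fileext = ".tsv")
  write_ltt_tsv(l2, tf)
  back <- read.delim(tf)
  expect_equal(back$age, l2$age)
  expect_equal(back$count, l2$count)
})

test_that("mean LTT of fixed-crown pure-birth trees matches 2*exp(lambda*t)", {
  lambda <- 0.2; T0 <- 20
  count_at <- function(tr, age) {
    bt <- branching_times(tr)
    2 + sum(bt$ages[-1] > age)
  }
  set.seed(31)
  reps <- 500
  ages_checked <- c(15, 10, 5)
  counts <- matrix(0, reps, length(ages_checked))
  for (r in seq_len(reps)) {
    tr <- simulate_yule(crown_age = T0, lambda = lambda)
    counts[r, ] <- vapply(ages_checked, count_at, numeric(1), tr = tr)
  }
  expected <- 2 * exp(lambda * (T0 - ages_checked))
  # var of N_t for a two-lineage pure birth: 2 e^{lt}(e^{lt} - 1)
  se <- sqrt(2 * exp(lambda * (T0 - ages_checked)) *
               (exp(lambda * (T0 - ages_checked)) - 1) / reps)
  expect_true(all(abs(colMeans(counts) - expected) < 4 * se + 1e-9))
})

test_that("write -> parse round trip preserves branching times", {
  tr <- simulate_yule(n_tips = 10, lambda = 0.2, seed = 3)
  back <- parse_tree(write_newick(tr))
  expect_equal(branching_times(back)$ages, branching_times(tr)$ages,
               tolerance = 1e-9)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
})

test_that("branching times scale linearly under crown-age rescaling", {
  tr <- simulate_yule(n_tips = 15, lambda = 0.25, seed = 8)
  for (target in c(0.5, 11.1, 40)) {
    f <- target / crown_age(tr)
    expect_equal(branching_times(rescale_root_age(tr, target))$ages,
                 f * branching_times(tr)$ages, tolerance = 1e-10)
  }
})
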