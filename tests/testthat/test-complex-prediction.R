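test_that("weighted density matches hand-evaluated cases", {
  tri <- tibble::tibble(protein_a = c("a", "a", "b"),
                        protein_b = c("b", "c", "c"), weight = 0.9)
  expect_equal(subgraph_density(tri, c("a", "b", "c")), 0.9)
  pair <- tibble::tibble(protein_a = "u", protein_b = "v", weight = 0.8)
  expect_equal(subgraph_density(pair, c("u", "v")), 0.8)
  # complete graph with unit weights has the maximal density 1
  k4 <- t(combn(letters[1:4], 2))
  full <- tibble::tibble(protein_a = k4[, 1], protein_b = k4[, 2], weight = 1)
  expect_equal(subgraph_density(full, letters[1:4]), 1)
  expect_error(subgraph_density(tri, "a"), "at least two")
})

test_that("attachment score is the mean weight towards the member set", {
  sub <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("v", "v"),
                        weight = c(0.8, 0.6))
  expect_equal(attach_score(sub, "v", c("a", "b")), 0.7)
  expect_equal(attach_score(sub, "x", c("a", "b")), 0) # no edges at all
  # connected to every member with constant weight w -> score w
  star <- tibble::tibble(protein_a = c("a", "b", "c"),
                         protein_b = "v", weight = 0.55)
  expect_equal(attach_score(star, "v", c("a", "b", "c")), 0.55)
  expect_error(attach_score(sub, "a", c("a", "b")), "must not be a member")
})

test_that("cluster score scales edge weight by neighbourhood overlap", {
  iso <- tibble::tibble(protein_a = "u", protein_b = "v", weight = 0.5)
  expect_equal(cluster_score(iso, "u", "v"), 0.5) # 0.5 * 2*1/2
  tri <- tibble::tibble(protein_a = c("a", "a", "b"),
                        protein_b = c("b", "c", "c"), weight = 0.9)
  expect_equal(cluster_score(tri, "a", "b"), 0.9) # 0.9 * 2*2/4
  expect_error(cluster_score(tri, "a", "x"), "nonzero-weight")
})

test_that("cluster score never exceeds the edge weight", {
  withr::local_seed(41)
  for (rep in 1:10) {
    sub <- random_subnetwork(8, 0.6)
    if (nrow(sub) == 0) next
    for (k in seq_len(nrow(sub))) {
      cs <- cluster_score(sub, sub$protein_a[k], sub$protein_b[k])
      expect_lte(cs, sub$weight[k] + 1e-12)
      expect_gt(cs, 0)
      expect_lt(cs, 1)
    }
  }
})

test_that("core detection reproduces the four-protein hand trace", {
  sub <- trace_subnetwork() # triangle abc (0.9) + pendant edge cd (0.9)
  # seed scores: ab 0.9, ac 0.72, bc 0.72, cd 0.45
  expect_equal(cluster_score(sub, "a", "b"), 0.9)
  expect_equal(cluster_score(sub, "a", "c"), 0.72)
  expect_equal(cluster_score(sub, "b", "c"), 0.72)
  expect_equal(cluster_score(sub, "c", "d"), 0.45)

  # permissive threshold: the top seed grows through c (density 0.9) and d
  # (density 0.6), absorbing every other seed -> one core {a,b,c,d}
  expect_equal(detect_cores(sub, 0.1), list(c("a", "b", "c", "d")))
  # stricter threshold: d is rejected (0.6 < 0.7) and the leftover seed cd
  # shares c with the finished core -> one core {a,b,c}
  expect_equal(detect_cores(sub, 0.7), list(c("a", "b", "c")))
  # no seed can ever reach a threshold of 1 (scores are < 1)
  expect_equal(detect_cores(sub, 1), list())
})

test_that("attachments join by score threshold and keep the core disjoint", {
  sub <- trace_subnetwork()
  cores <- list(c("a", "b", "c"))
  got <- attach_to_cores(sub, cores, attach_thresh = 0.1, timepoint = "T1")
  # attach_score(d) = 0.9 / 3 = 0.3 -> attached at 0.1
  expect_equal(got$attachments[[1]], "d")
  expect_equal(got$members[[1]], c("a", "b", "c", "d"))
  expect_equal(got$size, 4)
  expect_equal(got$density[1], subgraph_density(sub, got$members[[1]]))
  # ... but not at 0.5
  got2 <- attach_to_cores(sub, cores, attach_thresh = 0.5)
  expect_equal(got2$attachments[[1]], character(0))
  # zero-weight (absent) connections never attach, even at threshold 0
  far <- dplyr::bind_rows(sub, tibble::tibble(protein_a = "x",
                                              protein_b = "y",
                                              weight = 0.9))
  got3 <- attach_to_cores(far, list(c("a", "b", "c")), attach_thresh = 0)
  expect_false(any(c("x", "y") %in% got3$members[[1]]))
})

test_that("greedy core growth agrees with the step-by-step oracle", {
  withr::local_seed(43)
  for (rep in 1:15) {
    sub <- random_subnetwork(8, 0.45)
    if (nrow(sub) == 0) next
    th <- sample(c(0.05, 0.2, 0.4), 1)
    cores <- detect_cores(sub, th)
    # disjointness
    all_members <- unlist(cores)
    expect_equal(anyDuplicated(all_members), 0)
    # every core's density meets the threshold in its subnetwork
    for (core in cores) {
      if (length(core) >= 2) {
        expect_gte(subgraph_density(sub, core), th)
      }
    }
    # replay the first core from its top seed with the independent oracle
    if (length(cores) > 0) {
      adj <- dynppi:::build_adjacency(sub)
      scores <- dynppi:::edge_cluster_scores(sub, adj)
      seeds <- which(scores >= th)
      key <- paste(pmin(sub$protein_a, sub$protein_b),
                   pmax(sub$protein_a, sub$protein_b))
      top <- seeds[order(-scores[seeds], key[seeds])][1]
      oracle <- oracle_grow_core(sub, c(sub$protein_a[top],
                                        sub$protein_b[top]), th)
      expect_equal(cores[[1]], oracle)
    }
  }
})

test_that("candidate prediction tags time points and composes per-subnetwork", {
  # empty dynamic network -> no candidates
  empty <- tibble::tibble(timepoint = character(0), protein_a = character(0),
                          protein_b = character(0), weight = numeric(0))
  expect_equal(nrow(predict_candidates(empty)), 0)

  # a single nonzero subnetwork equals detect+attach on it
  sub <- trace_subnetwork()
  dyn <- dplyr::bind_cols(tibble::tibble(timepoint = "T3"), sub)
  cand <- predict_candidates(dyn, complex_thresh = 0.1)
  direct <- attach_to_cores(sub, detect_cores(sub, 0.1), 0.1,
                            timepoint = "T3")
  expect_equal(as.data.frame(cand), as.data.frame(direct))
  expect_equal(cand$timepoint, "T3")
})

test_that("overlap degree matches hand values and is symmetric", {
  expect_equal(overlap_degree(letters[1:3], letters[1:3]), 1)
  expect_equal(overlap_degree(letters[1:3], letters[4:6]), 0)
  expect_equal(overlap_degree(letters[1:3], letters[1:4]), 9 / 12)
  expect_equal(overlap_degree(letters[1:4], letters[1:3]), 9 / 12)
  expect_equal(overlap_degree(letters[1:3], letters[1:4], method = "min"), 1)
  expect_error(overlap_degree(character(0), "a"), "non-empty")
})

test_that("overlap filtering keeps the densest of highly overlapping pairs", {
  cand <- tibble::tibble(
    timepoint = c("T1", "T2"),
    members = list(c("a", "b", "c"), c("a", "b", "c", "d")),
    density = c(0.9, 0.6)
  )
  kept <- filter_overlaps(cand) # overlap 9/12 = 0.75 > 2/3
  expect_equal(nrow(kept), 1)
  expect_equal(kept$members[[1]], c("a", "b", "c"))
  expect_equal(kept$timepoint, "T1")

  # disjoint candidates both survive
  disj <- tibble::tibble(members = list(c("a", "b"), c("x", "y")),
                         density = c(0.5, 0.4))
  expect_equal(nrow(filter_overlaps(disj)), 2)

  # identical candidates from two time points collapse to one
  dup <- tibble::tibble(timepoint = c("T1", "T5"),
                        members = list(c("a", "b", "c"), c("c", "b", "a")),
                        density = c(0.8, 0.7))
  expect_equal(nrow(filter_overlaps(dup)), 1)
  # ... even when the threshold is 1 (strict comparison alone would keep it)
  expect_equal(nrow(filter_overlaps(dup, overlap_thresh = 1)), 1)
})

test_that("no pair of final complexes overlaps above the threshold", {
  withr::local_seed(47)
  cand <- tibble::tibble(
    members = replicate(30, sample(letters[1:12], sample(2:5, 1)),
                        simplify = FALSE),
    density = round(runif(30), 3)
  )
  kept <- filter_overlaps(cand)
  if (nrow(kept) > 1) {
    combos <- combn(nrow(kept), 2)
    for (k in seq_len(ncol(combos))) {
      expect_lte(overlap_degree(kept$members[[combos[1, k]]],
                                kept$members[[combos[2, k]]]), 2 / 3)
    }
  }
})

test_that("end-to-end prediction recovers a planted clique at its time point", {
  # four proteins peaking together at T2 embedded in a 12-point course
  fx <- generate_fixture(fixture_spec(complex_sizes = 4,
                                      active_timepoints = 2,
                                      intra_density = 1, n_background = 0,
                                      seed = 7))
  dyn <- build_dynamic_network(fx$network, fx$expression, quiet = TRUE)
  # exactly one candidate contains the whole planted complex, and it comes
  # from the planted time point
  cand <- predict_candidates(dyn)
  full <- vapply(cand$members, function(m) {
    all(fx$truth$members[[1]] %in% m)
  }, logical(1))
  expect_equal(sum(full), 1)
  expect_equal(cand$timepoint[full], "T2")
  # after overlap filtering the planted complex is still matched: its
  # best-affinity prediction is a (near-)complete subset from the peak
  # window, and recall at the usual match rule is perfect
  pred <- filter_overlaps(cand)
  expect_true(all(unlist(pred$members) %in% fx$truth$members[[1]]))
  best <- max(vapply(pred$members, neighborhood_affinity, numeric(1),
                     fx$truth$members[[1]]))
  expect_gte(best, 0.75)
  ev <- evaluate_complexes(pred, fx$truth)
  expect_equal(ev$recall, 1)
})

test_that("two disjoint planted complexes are recovered with their labels", {
  fx <- generate_fixture(fixture_spec(complex_sizes = c(4, 5),
                                      active_timepoints = c(2, 8),
                                      intra_density = 1, n_background = 0,
                                      noise_sd = 0.15, seed = 13))
  pred <- predict_complexes(fx$network, fx$expression)
  for (i in 1:2) {
    hits <- vapply(pred$members, function(m) {
      neighborhood_affinity(m, fx$truth$members[[i]]) == 1
    }, logical(1))
    expect_equal(sum(hits), 1)
    expect_equal(pred$timepoint[hits], fx$truth$timepoint[i])
  }
})

test_that("empty inputs propagate to empty predictions", {
  net <- ppi_network(data.frame(a = "A", b = "B"))
  m <- matrix(c(5, 5, 5, 9, 1, 1), nrow = 1,
              dimnames = list("Z", paste0("T", 1:6)))
  # network proteins absent from expression -> empty dynamic net -> no output
  pred <- suppressMessages(
    predict_complexes(net, as_expression_matrix(m), quiet = TRUE)
  )
  expect_equal(nrow(pred), 0)
})
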