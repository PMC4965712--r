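test_that("damped sigma thresholds match hand-computed values", {
  expect_equal(sigma_threshold(10, 0, 1), 10)
  expect_equal(sigma_threshold(10, 0, 3), 10)
  expect_equal(sigma_threshold(10, 2, 3), 14.8) # 10 + 6 * (1 - 1/5)
  expect_equal(sigma_threshold(0, 1, 1), 0.5)   # 0 + 1 * (1 - 1/2)
  expect_error(sigma_threshold(0, 1, 4), "must be 1, 2 or 3")
  expect_error(sigma_threshold(0, -1, 1), "non-negative")
  # ordering: thresh_1 <= thresh_2 <= thresh_3, equal only when sd = 0
  for (s in c(0, 0.3, 1, 4)) {
    t123 <- vapply(1:3, function(k) sigma_threshold(2, s, k), numeric(1))
    expect_true(all(diff(t123) >= 0))
    if (s > 0) expect_true(all(diff(t123) > 0))
  }
})

test_that("active probability grades time points into the four levels", {
  # constant row: every value sits EXACTLY at all three thresholds (sd = 0
  # collapses them onto the mean); the inclusive top-tier comparison makes
  # every point 0.99 under the faithful policy
  expect_equal(active_probability(rep(10, 12)), rep(0.99, 12))
  expect_equal(active_probability(rep(10, 12), constant_row_policy = "zero"),
               rep(0, 12))

  # alternating 8/12 row: mean 10, sd ~2.09, damped 1-sigma band ~[11.7,
  # 13.4) -> the 12s grade 0.68 and the 8s are inactive
  row <- rep(c(8, 12), 6)
  p <- active_probability(row)
  expect_equal(p[row == 12], rep(0.68, 6))
  expect_equal(p[row == 8], rep(0, 6))

  # independent tier oracle on random rows
  withr::local_seed(5)
  for (rep in 1:20) {
    row <- round(rnorm(12, mean = 5, sd = runif(1, 0.1, 3)), 3)
    m <- mean(row)
    s <- sd(row)
    damp <- 1 - 1 / (1 + s^2)
    expected <- vapply(row, function(g) {
      if (g >= m + 3 * s * damp) 0.99
      else if (g >= m + 2 * s * damp) 0.95
      else if (g >= m + 1 * s * damp) 0.68
      else 0
    }, numeric(1))
    expect_equal(active_probability(row), expected)
    expect_true(all(active_probability(row) %in% c(0, 0.68, 0.95, 0.99)))
  }
})

test_that("activity edge weight is the product of endpoint levels", {
  expect_equal(activity_edge_weight(0.99, 0.68), 0.6732)
  expect_equal(activity_edge_weight(0.99, 0.99), 0.9801)
  expect_equal(activity_edge_weight(c(0, 0.68, 0.95), 0), c(0, 0, 0))
})

test_that("windowed Pearson matches hand values and stats::cor", {
  expect_equal(windowed_pearson(c(1, 2, 3), c(2, 4, 6), 2), 1)
  expect_equal(windowed_pearson(c(1, 2, 3), c(3, 2, 1), 2), 1) # | -1 |
  expect_equal(windowed_pearson(c(1, 2, 4), c(1, 3, 3), 2),
               24 / sqrt(42 * 24), tolerance = 1e-12)
  expect_equal(round(windowed_pearson(c(1, 2, 4), c(1, 3, 3), 2), 4), 0.7559)
  # zero-variance window -> 0
  expect_equal(windowed_pearson(c(1, 1, 1), c(1, 2, 3), 2), 0)

  # cross-check against stats::cor on random interior windows
  withr::local_seed(3)
  for (rep in 1:20) {
    x <- rnorm(10)
    y <- rnorm(10)
    i <- sample(2:9, 1)
    expect_equal(windowed_pearson(x, y, i),
                 abs(cor(x[(i - 1):(i + 1)], y[(i - 1):(i + 1)])))
  }
  # cyclic wrap at the ends
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(windowed_pearson(x, y, 1),
               abs(cor(x[c(6, 1, 2)], y[c(6, 1, 2)])))
  expect_equal(windowed_pearson(x, y, 6),
               abs(cor(x[c(5, 6, 1)], y[c(5, 6, 1)])))
  # truncation keeps the two in-range points
  expect_equal(windowed_pearson(x, y, 1, window = "truncate"),
               abs(cor(x[1:2], y[1:2])))
  # shift transform maps r = -1 to 0
  expect_equal(windowed_pearson(c(1, 2, 3), c(3, 2, 1), 2,
                                transform = "shift"), 0)
})

test_that("co-expression threshold keeps the boundary and zeroes the rest", {
  expect_equal(coexpression_weight(0.7559, 0.5), 0.7559)
  expect_equal(coexpression_weight(0.3, 0.5), 0)
  expect_equal(coexpression_weight(0.5, 0.5), 0.5) # inclusive boundary
  expect_equal(coexpression_weight(c(0.2, 0.9), 0.5), c(0, 0.9))
})

test_that("fused edge weights chain activity and co-expression", {
  w <- activity_edge_weight(0.99, 0.68) * coexpression_weight(0.756, 0.5)
  expect_equal(round(w, 4), 0.5089)
  expect_equal(activity_edge_weight(0, 0.99) * coexpression_weight(1, 0.5), 0)
})

test_that("dynamic network weights live in [0, 1) and on static edges only", {
  withr::local_seed(17)
  for (rep in 1:5) {
    ne <- random_network_expression(9, n_tp = 6, p = 0.5)
    dyn <- build_dynamic_network(ne$network, ne$expr, quiet = TRUE)
    expect_true(all(dyn$weight > 0))
    expect_true(all(dyn$weight < 0.99^2 + 1e-12))
    static_keys <- paste(ne$network$protein_a, ne$network$protein_b)
    expect_true(all(paste(dyn$protein_a, dyn$protein_b) %in% static_keys))
  }
})

test_that("raising pre_thresh never increases weights or edge counts", {
  withr::local_seed(29)
  ne <- random_network_expression(12, n_tp = 8, p = 0.6)
  grids <- c(0, 0.3, 0.5, 0.7, 0.9)
  dyns <- lapply(grids, function(pt) {
    build_dynamic_network(ne$network, ne$expr, pre_thresh = pt, quiet = TRUE)
  })
  counts <- vapply(dyns, nrow, integer(1))
  expect_true(all(diff(counts) <= 0))
  for (k in seq_len(length(grids) - 1)) {
    lo <- dyns[[k]]
    hi <- dyns[[k + 1]]
    key_lo <- paste(lo$timepoint, lo$protein_a, lo$protein_b)
    key_hi <- paste(hi$timepoint, hi$protein_a, hi$protein_b)
    expect_true(all(key_hi %in% key_lo))
    shared <- match(key_hi, key_lo)
    expect_equal(hi$weight, lo$weight[shared])
  }
})

test_that("proteins missing from the expression matrix never activate", {
  net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  m <- matrix(rnorm(2 * 4, 5), nrow = 2,
              dimnames = list(c("A", "B"), paste0("T", 1:4)))
  expect_message(
    dyn <- build_dynamic_network(net, as_expression_matrix(round(m, 3))),
    "absent from the expression matrix"
  )
  expect_false("C" %in% c(dyn$protein_a, dyn$protein_b))
})

test_that("a protein active at a single time point only contributes there", {
  # one gene peaks at T2 and T5 only; its partner peaks identically, so the
  # pair can appear in subnetworks near those peaks and nowhere else
  n_tp <- 8
  base <- rep(2, n_tp)
  profile <- base
  profile[c(2, 5)] <- 10
  m <- rbind(v1 = profile, v2 = profile + 0.001,
             v3 = rep(c(1, 4), 4))
  colnames(m) <- paste0("T", 1:n_tp)
  net <- ppi_network(data.frame(a = c("v1", "v1"), b = c("v2", "v3")))
  dyn <- build_dynamic_network(net, as_expression_matrix(m), quiet = TRUE)
  act <- active_probability(profile)
  inactive_tps <- paste0("T", which(act == 0))
  touching_v1 <- dyn[dyn$protein_a == "v1" | dyn$protein_b == "v1", ]
  expect_false(any(touching_v1$timepoint %in% inactive_tps))
  expect_true(all(c("T2", "T5") %in% touching_v1$timepoint))
})

test_that("dynamic network serialisation writes per-time-point files", {
  withr::local_seed(31)
  ne <- random_network_expression(6, n_tp = 4, p = 0.8)
  dyn <- build_dynamic_network(ne$network, ne$expr, quiet = TRUE)
  dir <- withr::local_tempdir()
  write_dynamic_network(dyn, dir, header = "stamp")
  expect_true(file.exists(file.path(dir, "dynamic_network.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(all(file.exists(file.path(dir, paste0("subnetwork_",
                                                    timepoints(dyn),
                                                    ".tsv")))))
  combined <- read.delim(file.path(dir, "dynamic_network.tsv"),
                         comment.char = "#")
  expect_equal(nrow(combined), nrow(dyn))
})

test_that("tidiers summarise dynamic networks per time point", {
  withr::local_seed(37)
  ne <- random_network_expression(8, n_tp = 5, p = 0.7)
  dyn <- build_dynamic_network(ne$network, ne$expr, quiet = TRUE)
  td <- tidy(dyn)
  expect_equal(td$timepoint, timepoints(dyn))
  expect_equal(sum(td$n_edges), nrow(dyn))
  g <- glance(dyn)
  expect_equal(g$n_active_edges, nrow(dyn))
  expect_s3_class(autoplot(dyn), "ggplot")
})
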