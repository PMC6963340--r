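test_that("entropy matches direct evaluation of -sum p log2 p", {
  expect_equal(entropy(c(0, 1, 0, 1)), 1.0)
  expect_equal(entropy(rep("a", 7)), 0.0)
  # counts (3, 1): 0.75 log2(4/3) + 0.25 log2 4
  expect_equal(entropy(c("a", "a", "a", "b")), 0.811278, tolerance = 1e-6)
  expect_equal(entropy(c("a", "a", "a", "b")),
               oracle_entropy(c("a", "a", "a", "b")), tolerance = 1e-12)
  expect_error(entropy(integer(0)), "empty")
})

test_that("conditional entropy handles perfect, useless and mixed predictors", {
  y <- c(1, 1, 2, 2)
  expect_equal(conditional_entropy(y, y), 0.0)
  expect_equal(conditional_entropy(y, rep(1, 4)), entropy(y))
  # contingency {(x1: 2a,1b), (x2: 1a,2b)}
  a <- c("a", "a", "b", "a", "b", "b")
  x <- c("x1", "x1", "x1", "x2", "x2", "x2")
  expect_equal(conditional_entropy(a, x), 0.918296, tolerance = 1e-6)
  expect_equal(conditional_entropy(a, x), oracle_conditional_entropy(a, x),
               tolerance = 1e-12)
  expect_error(conditional_entropy(y, c(1, 2)), "length mismatch")
})

test_that("mutual information is symmetric, non-negative and matches the joint-table oracle", {
  # independent uniform pair laid out as a full product table
  u <- rep(c(0, 1), each = 4)
  v <- rep(c(0, 1, 0, 1), 2)
  expect_equal(mutual_information(u, v), 0.0)
  w <- c(1, 2, 1, 2, 3, 3)
  expect_equal(mutual_information(w, w), entropy(w))
  # joint counts {(0,0):5, (0,1):1, (1,0):1, (1,1):5}
  uu <- rep(c(0, 0, 1, 1), c(5, 1, 1, 5))
  vv <- rep(c(0, 1, 0, 1), c(5, 1, 1, 5))
  # direct evaluation: 2 - H(joint) with cell masses (5,1,1,5)/12
  expect_equal(mutual_information(uu, vv), 0.3499776, tolerance = 1e-6)
  expect_equal(mutual_information(uu, vv), oracle_mutual_information(uu, vv),
               tolerance = 1e-12)
  expect_equal(mutual_information(uu, vv), mutual_information(vv, uu),
               tolerance = 1e-12)
})

test_that("information gain spans the degenerate cases and respects its bounds", {
  y <- rep(c(0, 1), each = 50)
  x_sep <- c(rnorm(50, 0, 0.01), rnorm(50, 100, 0.01))
  expect_equal(information_gain(y, x_sep), 1.0, tolerance = 1e-9)
  expect_equal(information_gain(y, rep(3.7, 100)), 0.0)

  withr::with_seed(8, {
    for (i in 1:20) {
      y <- sample(0:2, 60, replace = TRUE)
      x <- rnorm(60)
      ig <- information_gain(y, x)
      bins <- hierovr:::apply_bin_edges(
        x, hierovr:::fit_bin_edges(x, discretization_scheme()))
      expect_gte(ig, 0)
      expect_lte(ig, min(entropy(y), entropy(bins)) + 1e-9)
      # independent contingency-table oracle on the same binning
      expect_equal(ig, oracle_entropy(y) - oracle_conditional_entropy(y, bins),
                   tolerance = 1e-9)
    }
  })
})

test_that("IG ranking is ordered, lexicographically tie-broken and sample-order invariant", {
  withr::with_seed(5, {
    n <- 80
    y <- rep(c(0, 1), each = n / 2)
    X <- cbind(
      perfect = y + rnorm(n, sd = 0.01),
      matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("n", 1:5)))
    )
  })
  r <- rank_by_ig(X, y, top_k = 6L)
  expect_identical(r$feature_ids[1], "perfect")
  expect_true(all(diff(r$scores) <= 1e-12))
  expect_true(all(r$scores <= r$h_class + 1e-9))

  # all-constant features: every score 0 and order is lexicographic
  Xc <- matrix(1, 20, 4, dimnames = list(NULL, c("d", "b", "a", "c")))
  rc <- rank_by_ig(Xc, rep(c(0, 1), 10), top_k = 4L)
  expect_identical(rc$feature_ids, c("a", "b", "c", "d"))
  expect_identical(rc$scores, rep(0, 4))

  perm <- sample(nrow(X))
  r2 <- rank_by_ig(X[perm, ], y[perm], top_k = 6L)
  expect_identical(r2$feature_ids, r$feature_ids)
  expect_equal(r2$scores, r$scores, tolerance = 1e-12)

  expect_warning(rank_by_ig(X, y, top_k = 100L), "available features")
})

test_that("planted markers dominate the IG ranking across seeded replicates", {
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    sim <- simulate_expression(simulation_config(
      class_sizes = c(30L, 30L), n_features = 53L, markers_per_class = 3L,
      seed = 700 + s
    ))
    X <- log_tpm(sim$matrix)
    y <- sim$labels$group
    # with two classes both classes' markers carry the same contrast, so
    # the six planted features compete for the top of one ranking
    mk <- sim$truth$feature_id
    r <- rank_by_ig(X, make_one_vs_rest_labels(y, 1), top_k = 6L)
    if (all(mk %in% r$feature_ids)) hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_rep))
})

test_that("mrmr_score reduces to I(h,c) - H(c) for an empty selected set", {
  withr::with_seed(6, {
    y <- sample(0:1, 40, replace = TRUE)
    Xb <- cbind(f1 = sample(1:3, 40, TRUE), f2 = sample(1:4, 40, TRUE))
  })
  st <- mrmr_state(Xb, y)
  for (f in c("f1", "f2")) {
    expect_equal(mrmr_score(st, f),
                 mutual_information(y, Xb[, f]) - entropy(Xb[, f]),
                 tolerance = 1e-12)
  }
  expect_error(mrmr_score(st, "nope"), "unknown candidate")
})

test_that("a duplicated feature scores below an equally relevant independent one", {
  withr::with_seed(7, {
    y <- rep(0:1, each = 30)
    base <- ifelse(y == 1, sample(2:3, 60, TRUE), sample(1:2, 60, TRUE))
    indep <- ifelse(y == 1, sample(2:3, 60, TRUE), sample(1:2, 60, TRUE))
  })
  Xb <- cbind(f = base, f_copy = base, g = indep)
  st <- mrmr_state(Xb, y)
  st$S <- "f"
  # force equal relevance so only redundancy separates the two candidates
  st$relevance[["g"]] <- st$relevance[["f_copy"]]
  expect_lt(mrmr_score(st, "f_copy"), mrmr_score(st, "g"))
})

test_that("mrmr_score equals brute-force evaluation over all subsets of a 4-feature system", {
  withr::with_seed(9, {
    y <- sample(0:1, 50, replace = TRUE)
    Xb <- sapply(1:4, function(i) sample(1:3, 50, replace = TRUE))
    colnames(Xb) <- paste0("f", 1:4)
  })
  brute_wv <- function(S) {
    m <- length(S)
    W <- sum(outer(S, S, Vectorize(function(i, j)
      oracle_mutual_information(Xb[, i], Xb[, j])))) / m^2
    V <- sum(vapply(S, function(i) oracle_mutual_information(y, Xb[, i]),
                    numeric(1))) / m
    c(W = W, V = V)
  }
  feats <- colnames(Xb)
  for (size in 0:3) {
    for (S in combn(feats, size, simplify = FALSE)) {
      st <- mrmr_state(Xb, y)
      st$S <- S
      for (cand in setdiff(feats, S)) {
        wv <- brute_wv(c(S, cand))
        expect_equal(mrmr_score(st, cand), unname(wv["V"] - wv["W"]),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("incremental mRMR scores equal from-scratch recomputation", {
  withr::with_seed(10, {
    y <- sample(0:1, 60, replace = TRUE)
    Xb <- sapply(1:6, function(i) sample(1:4, 60, replace = TRUE))
    colnames(Xb) <- paste0("f", 1:6)
  })
  st <- mrmr_state(Xb, y)
  st$S <- c("f2", "f5")
  rem <- setdiff(colnames(Xb), st$S)
  inc <- hierovr:::mrmr_scores_incremental(st, rem)
  for (cand in rem) {
    expect_equal(inc[[cand]], mrmr_score(st, cand), tolerance = 1e-9)
  }
})

test_that("the wrapper stops at a single perfectly separating feature", {
  withr::with_seed(11, {
    n <- 60
    y <- rep(0:1, each = n / 2)
    X <- cbind(sep = y * 10 + rnorm(n, sd = 0.05),
               matrix(rnorm(n * 10), n, 10,
                      dimnames = list(NULL, paste0("noise", 1:10))))
  })
  r <- rank_by_ig(X, y, top_k = 11L)
  sel <- mrmr_wrapper_select(X, y, r, selection_config(top_k = 11L), seed = 2)
  expect_identical(sel$selected, "sep")
  expect_equal(sel$accuracy, 1.0)
})

test_that("XOR-style complementary features defeat the greedy wrapper, with rejections on record", {
  withr::with_seed(12, {
    n <- 48
    f1 <- rep(c(0, 0, 1, 1), n / 4)
    f2 <- rep(c(0, 1, 0, 1), n / 4)
    y <- as.integer(xor(f1 > 0, f2 > 0))
    X <- cbind(f1 = f1 + rnorm(n, sd = 0.01), f2 = f2 + rnorm(n, sd = 0.01))
  })
  r <- rank_by_ig(X, y, top_k = 2L)
  expect_warning(
    sel <- mrmr_wrapper_select(X, y, r, selection_config(top_k = 2L), seed = 3),
    "falling back"
  )
  expect_length(sel$selected, 1L)       # the pair is never assembled
  expect_true(any(!sel$trace$accepted)) # the rejections are on record
})

test_that("wrapper selections stay within budget and every acceptance strictly improved accuracy", {
  sim <- small_sim_config(seed = 31) |> simulate_expression()
  X <- log_tpm(sim$matrix)
  y01 <- make_one_vs_rest_labels(sim$labels$group, 2)
  cfg <- selection_config(top_k = 20L, max_features = 4L)
  sel <- suppressWarnings(select_features(X, y01, cfg, seed = 5))
  expect_lte(length(sel$selected), 4L)
  acc_path <- sel$trace$wrapper_accuracy[sel$trace$accepted]
  expect_true(all(diff(c(0, acc_path)) > 0))
})
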