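test_that("already balanced input is returned unchanged", {
  X <- matrix(1:12, 6, 2)
  y <- factor(rep(c("A", "B"), each = 3))
  out <- smote_balance(X, y, balancing_config(seed = 1))
  expect_identical(out$X, X)
  expect_identical(out$y, y)
})

test_that("balancing equalizes every class to the majority count, originals first", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(20 * 3), 20, 3),
               matrix(rnorm(6 * 3, mean = 5), 6, 3),
               matrix(rnorm(3 * 3, mean = -5), 3, 3))
  })
  y <- factor(rep(c("maj", "mid", "min"), times = c(20, 6, 3)))
  out <- suppressWarnings(smote_balance(X, y, balancing_config(seed = 2)))
  expect_equal(unname(table(out$y)), rep(20L, 3), ignore_attr = TRUE)
  expect_equal(nrow(out$X), 3 * 20)
  expect_identical(out$X[1:29, ], X)                 # originals verbatim, first
  expect_identical(as.character(out$y[1:29]), as.character(y))
})

test_that("a minority class with a single member is a balancing error naming it", {
  X <- matrix(rnorm(8), 4, 2)
  y <- factor(c("A", "A", "A", "lonely"))
  expect_error(smote_balance(X, y, balancing_config(seed = 1)),
               "balancing error.*lonely")
})

test_that("synthetic points from a two-point class lie on the closed segment", {
  # minority p=(0,0), q=(1,1); every synthetic point is p + u (q - p)
  X <- rbind(matrix(runif(20, 5, 6), 10, 2), c(0, 0), c(1, 1))
  y <- factor(c(rep("maj", 10), "min", "min"))
  out <- smote_balance(X, y, balancing_config(k_neighbors = 1, seed = 3))
  synth <- out$X[out$y == "min", ][-(1:2), , drop = FALSE]
  expect_equal(nrow(synth), 8)
  expect_equal(synth[, 1], synth[, 2])       # both coordinates equal
  expect_true(all(synth >= 0 & synth <= 1))  # within the segment
})

test_that("synthetic points stay in the convex hull of their class (2-D)", {
  withr::with_seed(8, {
    Xmin <- matrix(runif(10, 0, 1), 5, 2)
    Xmaj <- matrix(runif(60, 10, 11), 30, 2)
  })
  X <- rbind(Xmaj, Xmin)
  y <- factor(rep(c("maj", "min"), times = c(30, 5)))
  out <- smote_balance(X, y, balancing_config(k_neighbors = 3, seed = 4))
  synth <- out$X[out$y == "min", ][-(1:5), , drop = FALSE]
  # hull containment via bounding box + pairwise segment property:
  # each synthetic point is a convex combination of two class points
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    on_some_segment <- FALSE
    for (a in 1:5) for (b in 1:5) {
      if (a == b) next
      d <- Xmin[b, ] - Xmin[a, ]
      t1 <- if (abs(d[1]) > 1e-12) (s[1] - Xmin[a, 1]) / d[1] else NA
      t2 <- if (abs(d[2]) > 1e-12) (s[2] - Xmin[a, 2]) / d[2] else NA
      ts <- stats::na.omit(c(t1, t2))
      if (length(ts) && all(abs(ts - ts[1]) < 1e-8) &&
          ts[1] >= -1e-10 && ts[1] <= 1 + 1e-10) {
        on_some_segment <- TRUE
      }
    }
    expect_true(on_some_segment)
  }
})

test_that("balancing is deterministic in the seed; seeds change rows, not counts", {
  withr::with_seed(13, X <- matrix(rnorm(40), 20, 2))
  y <- factor(rep(c("A", "B"), times = c(14, 6)))
  o1 <- smote_balance(X, y, balancing_config(seed = 7))
  o2 <- smote_balance(X, y, balancing_config(seed = 7))
  o3 <- smote_balance(X, y, balancing_config(seed = 8))
  expect_identical(o1$X, o2$X)
  expect_false(identical(o1$X, o3$X))
  expect_identical(table(o1$y), table(o3$y))
})

test_that("k_neighbors larger than the class is clamped with a warning", {
  X <- matrix(c(0, 0, 1, 1, 2, 2, 50, 50, 51, 51, 52, 52, 53, 53), ncol = 2,
              byrow = TRUE)
  y <- factor(c("min", "min", "min", "maj", "maj", "maj", "maj"))
  expect_warning(out <- smote_balance(X, y, balancing_config(k_neighbors = 5,
                                                             seed = 1)),
                 "clamped")
  expect_equal(sum(out$y == "min"), 4L)
})
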