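# hand-written reference cells used throughout this file
hand_stats <- function(halogen = "BR", class = "O-C",
                       d_q = c(3.3, 3.6), t1_q = c(145, 165),
                       t2_q = c(95, 115)) {
  tibble::tibble(
    halogen = halogen, acceptor_class = class,
    parameter = c("distance", "theta1", "theta2"),
    n = 100L, mean = NA_real_,
    median = c(mean(d_q), mean(t1_q), mean(t2_q)),
    q1 = c(d_q[1], t1_q[1], t2_q[1]),
    q3 = c(d_q[2], t1_q[2], t2_q[2]),
    mad = 1)
}

test_that("the geometric score is the IQR-normalised box distance", {
  # inside the box (edges included): exactly zero
  expect_equal(score_geom(15, 10, 20), 0)
  expect_equal(score_geom(c(10, 20), 10, 20), c(0, 0))
  expect_equal(score_geom(35, 10, 20), 1.5) # whisker endpoint
  expect_equal(score_geom(4, 10, 20), 0.6)  # below-box branch
  expect_error(score_geom(5, 10, 10), "IQR")
  expect_error(score_geom(5, 12, 10), "IQR")

  # piecewise-linear with slope 1/IQR outside, and scale invariant
  v <- seq(0, 40, by = 0.5)
  s <- score_geom(v, 10, 20)
  expect_true(all(s[v >= 10 & v <= 20] == 0))
  expect_equal(diff(s[v > 20]) / 0.5, rep(1 / 10, sum(v > 20) - 1))
  for (k in c(0.1, 3, 250)) {
    expect_equal(score_geom(k * v, k * 10, k * 20), s, tolerance = 1e-12)
  }
})

test_that("classification flips exactly at the box edge and the whisker", {
  expect_equal(classify_halbs(c(0, 1.5, 1.63)),
               c("preferred", "allowed", "outlier"))
  expect_error(classify_halbs(-0.1), "non-negative")
  # sweep across a box [10, 20]: preferred on the box, allowed to the
  # whisker inclusive, outlier strictly beyond
  v <- c(9, 10, 15, 20, 21, 35, 35.0001, 50, 4.999, -5, -5.001)
  cls <- classify_halbs(score_geom(v, 10, 20))
  expect_equal(cls, c("allowed", "preferred", "preferred", "preferred",
                      "allowed", "allowed", "outlier", "outlier", "allowed",
                      "allowed", "outlier"))
})

test_that("HalBS is the maximum per-parameter score, theta2 branch included", {
  # geometry engineered against hand-written quartiles:
  # d 3.4 in [3.3,3.6] -> 0; theta1 175 vs [145,165] -> 0.5; theta2 125 vs
  # [95,115] -> 0.5 etc.
  fx <- fixture_structure("BR", "O-C", d = 3.66, theta1 = 175, theta2 = 123)
  sc <- score_bonds(detect_halogen_bonds(fx$structure), hand_stats())
  expect_equal(sc$score_distance, 0.2, tolerance = 1e-6)
  expect_equal(sc$score_theta1, 0.5, tolerance = 1e-6)
  expect_equal(sc$score_theta2, 0.4, tolerance = 1e-6)
  expect_equal(sc$halbs, 0.5, tolerance = 1e-6)
  expect_equal(sc$classification, "allowed")

  # all parameters inside their boxes -> 0, preferred
  fx0 <- fixture_structure("BR", "O-C", d = 3.45, theta1 = 155, theta2 = 105)
  sc0 <- score_bonds(detect_halogen_bonds(fx0$structure), hand_stats())
  expect_equal(sc0$halbs, 0)
  expect_equal(sc0$classification, "preferred")

  # pi candidate: theta2 undefined, max over two scores only
  pi_stats <- tibble::tibble(
    halogen = "I", acceptor_class = "Phe",
    parameter = c("distance", "theta1"), n = 50L, mean = NA_real_,
    median = c(4.8, 130), q1 = c(4.5, 115), q3 = c(5.1, 145), mad = 1)
  fxp <- fixture_structure("I", "Phe", d = 5.28, theta1 = 175)
  scp <- score_bonds(detect_halogen_bonds(fxp$structure), pi_stats)
  expect_equal(scp$score_distance, 0.3, tolerance = 1e-6)
  expect_equal(scp$score_theta1, 1.0, tolerance = 1e-6)
  expect_true(is.na(scp$score_theta2))
  expect_equal(scp$halbs, 1.0, tolerance = 1e-6)
})

test_that("categories without reference statistics are reported, not dropped", {
  fx <- fixture_structure("I", "Trp", d = 5.0, theta1 = 150)
  sc <- score_bonds(detect_halogen_bonds(fx$structure), reference_stats())
  expect_equal(nrow(sc), 1)
  expect_true(is.na(sc$halbs))
  expect_match(sc$unscored_reason, "I-Trp")
  # unscored bonds never enter the model mean
  expect_equal(summarize_model(sc)$n_bonds, 0)
  expect_true(is.na(summarize_model(sc)$mean_halbs))
})

test_that("HalBS is monotone in each geometric parameter", {
  st <- hand_stats()
  base <- fixture_structure("BR", "O-C", d = 3.45, theta1 = 155, theta2 = 105)
  prev <- -Inf
  for (t1 in seq(155, 100, by = -5)) {
    fx <- fixture_structure("BR", "O-C", d = 3.45, theta1 = t1, theta2 = 105)
    h <- score_bonds(detect_halogen_bonds(fx$structure), st)$halbs
    expect_gte(h, prev)
    prev <- h
  }
})

test_that("best-bond selection minimises HalBS with deterministic ties", {
  fx <- fixture_structure("BR", "O-C", d = 3.45, theta1 = 175, theta2 = 105,
                          extra_acceptors = list(
                            list(kind = "O-C", d = 3.45, theta1 = 155,
                                 theta2 = 105)))
  sc <- score_bonds(detect_halogen_bonds(fx$structure), hand_stats())
  expect_equal(sort(sc$halbs), c(0, 0.5))
  best <- select_best_bond(sc)
  expect_equal(nrow(best), 1)
  expect_equal(best$halbs, 0)

  expect_equal(nrow(select_best_bond(sc[2, ])), 1)

  # tie between an atomic and a pi candidate: atomic wins, then smaller d
  tie <- sc[c(1, 1), ]
  tie$halbs <- 0.7
  tie$acceptor_kind <- c("pi", "atomic")
  tie$d <- c(5, 3.4)
  for (perm in list(1:2, 2:1)) {
    got <- select_best_bond(tie[perm, ])
    expect_equal(got$acceptor_kind, "atomic")
  }
})

test_that("model summaries count scored bonds and average HalBS", {
  df <- tibble::tibble(halbs = c(0.2, 0.4))
  s <- summarize_model(df)
  expect_equal(s$n_bonds, 2)
  expect_equal(s$mean_halbs, 0.3)
  empty <- summarize_model(tibble::tibble(halbs = double()))
  expect_equal(empty$n_bonds, 0)
  expect_true(is.na(empty$mean_halbs))

  set.seed(3)
  vals <- runif(5, 0, 2)
  expect_equal(summarize_model(tibble::tibble(halbs = vals))$mean_halbs,
               sum(vals) / 5)
})

test_that("tidy and glance expose the scored table and its summary", {
  fx <- fixture_structure("BR", "O-C", d = 3.45, theta1 = 155, theta2 = 105)
  sc <- score_bonds(detect_halogen_bonds(fx$structure), hand_stats())
  td <- tidy(sc)
  expect_false(inherits(td, "halbs_scores"))
  expect_equal(nrow(td), nrow(sc))
  gl <- glance(sc)
  expect_equal(gl$n_bonds, 1)
  expect_equal(gl$mean_halbs, sc$halbs)
  expect_s3_class(autoplot(sc), "ggplot")
})
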