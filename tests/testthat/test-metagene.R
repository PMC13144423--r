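track_1chr <- function(fwd, rev = rev(fwd)) {
  signal_track(fwd = list(c1 = as.numeric(fwd)), rev = list(c1 = as.numeric(rev)))
}

test_that("extract_matrix orients rows along transcription", {
  tr <- signal_track(fwd = list(c1 = c(1, 2, 3, 4, 5)),
                     rev = list(c1 = c(1, 2, 3, 4, 5)))
  a_plus <- GRanges("c1", IRanges(3, 3), strand = "+")
  expect_equal(unname(extract_matrix(tr, a_plus, 2, 2)[1, ]), c(1, 2, 3, 4, 5))
  a_minus <- GRanges("c1", IRanges(3, 3), strand = "-")
  expect_equal(unname(extract_matrix(tr, a_minus, 2, 2)[1, ]), c(5, 4, 3, 2, 1))
  expect_identical(colnames(extract_matrix(tr, a_plus, 2, 2)),
                   c("-2", "-1", "0", "1", "2"))
  # out-of-bounds anchors dropped with warning; empty anchors error
  far <- GRanges("c1", IRanges(c(3, 1), width = 1), strand = "+")
  expect_warning(m <- extract_matrix(tr, far, 2, 2), "dropped")
  expect_equal(nrow(m), 1L)
  expect_error(extract_matrix(tr, GRanges(), 2, 2), "empty")
})

test_that("extract_matrix uses the strand-matched vector by default", {
  tr <- signal_track(fwd = list(c1 = c(10, 10, 10, 10, 10)),
                     rev = list(c1 = c(7, 7, 7, 7, 7)))
  a <- GRanges("c1", IRanges(3, 3), strand = c("-"))
  expect_true(all(extract_matrix(tr, a, 1, 1) == 7))
  expect_true(all(extract_matrix(tr, a, 1, 1, strand_select = "fwd") == 10))
})

test_that("column means match a brute-force per-anchor loop", {
  set.seed(51)
  n <- 2000
  tr <- signal_track(fwd = list(c1 = rpois(n, 3) * 1.0),
                     rev = list(c1 = rpois(n, 3) * 1.0))
  pos <- sample(60:(n - 60), 40)
  str <- sample(c("+", "-"), 40, TRUE)
  a <- GRanges("c1", IRanges(pos, width = 1), strand = str)
  m <- extract_matrix(tr, a, 50, 50)
  brute <- matrix(NA_real_, 40, 101)
  for (i in 1:40) {
    v <- if (str[i] == "+") tr$fwd$c1 else tr$rev$c1
    idx <- if (str[i] == "+") (pos[i] - 50):(pos[i] + 50)
           else (pos[i] + 50):(pos[i] - 50)
    brute[i, ] <- v[idx]
  }
  expect_equal(unname(colMeans(m)), unname(colMeans(brute)))
})

test_that("metagene_profile bins column means as documented", {
  m <- matrix(2, nrow = 3, ncol = 10,
              dimnames = list(NULL, as.character(-4:5)))
  p <- metagene_profile(m, 5)
  expect_equal(p$mean, c(2, 2))
  expect_equal(p$n, c(3L, 3L))
  expect_equal(p$bin_center, c(-2, 3))
  # bin_width 1 reduces to raw column means
  set.seed(52)
  m2 <- matrix(runif(60), 6, 10, dimnames = list(NULL, as.character(0:9)))
  p1 <- metagene_profile(m2, 1)
  expect_equal(p1$mean, unname(colMeans(m2)))
  # brute-force binning oracle at width 5
  p5 <- metagene_profile(m2, 5)
  expect_equal(p5$mean, c(mean(m2[, 1:5]), mean(m2[, 6:10])))
  # anchor order invariance
  p_shuffled <- metagene_profile(m2[sample(1:6), ], 5)
  expect_equal(p_shuffled$mean, p5$mean)
})

test_that("flank_test matches a hand-computed Welch statistic", {
  # two anchors, flank 2: values laid out so per-anchor flank means are known
  tr <- signal_track(fwd = list(c1 = c(1, 3, 0, 5, 9, 2, 4, 0, 8, 10)),
                     rev = list(c1 = numeric(10)))
  a <- GRanges("c1", IRanges(c(3, 8), width = 1), strand = "+")
  fc <- flank_test(tr, a, flank = 2)
  up <- c(mean(c(1, 3)), mean(c(2, 4)))
  down <- c(mean(c(5, 9)), mean(c(8, 10)))
  expect_equal(fc$upstream, up)
  expect_equal(fc$downstream, down)
  # Welch by the textbook formula
  se2 <- var(down) / 2 + var(up) / 2
  t_hand <- (mean(down) - mean(up)) / sqrt(se2)
  df_hand <- se2^2 / ((var(down) / 2)^2 / 1 + (var(up) / 2)^2 / 1)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(fc$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(fc$p_value, p_hand, tolerance = 1e-12)
})

test_that("flank_test agrees with an independent Welch implementation on random cohorts", {
  welch <- function(x, y) {
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    list(t = t, p = 2 * pt(-abs(t), df))
  }
  set.seed(53)
  for (rep in 1:20) {
    n <- 3000
    tr <- signal_track(fwd = list(c1 = runif(n)), rev = list(c1 = runif(n)))
    a <- GRanges("c1", IRanges(sample(60:(n - 60), 30), width = 1),
                 strand = sample(c("+", "-"), 30, TRUE))
    fc <- flank_test(tr, a, flank = 50)
    w <- welch(fc$downstream, fc$upstream)
    expect_equal(fc$t_statistic, w$t, tolerance = 1e-9)
    expect_equal(fc$p_value, w$p, tolerance = 1e-9)
  }
})

test_that("flank_test handles degenerate equal flanks and small cohorts", {
  tr <- signal_track(fwd = list(c1 = rep(4, 30)), rev = list(c1 = rep(4, 30)))
  a <- GRanges("c1", IRanges(c(10, 20), width = 1), strand = "+")
  fc <- flank_test(tr, a, flank = 3)
  expect_equal(fc$t_statistic, 0)
  expect_equal(fc$p_value, 1)
  expect_error(flank_test(tr, a[1], flank = 3), "fewer than 2")
})

test_that("max_signal_positions finds the 3'-most maximum, normalized", {
  # spike at the TES of a plus-strand transcript
  v <- numeric(100); v[80] <- 9
  tr <- signal_track(fwd = list(c1 = v), rev = list(c1 = numeric(100)))
  tx <- make_tx("c1", 21, 80, "+")
  expect_equal(as.numeric(max_signal_positions(tr, tx)), 1.0)
  # uniform nonzero signal maps to 1 by the 3'-most tie rule (flagged)
  tru <- signal_track(fwd = list(c1 = rep(1, 100)), rev = list(c1 = rep(1, 100)))
  expect_message(p <- max_signal_positions(tru, tx), "tied")
  expect_equal(as.numeric(p), 1.0)
  # minus strand: maximum at genomic start = TES -> 1
  vm <- numeric(100); vm[21] <- 5
  trm <- signal_track(fwd = list(c1 = numeric(100)), rev = list(c1 = vm))
  txm <- make_tx("c1", 21, 80, "-")
  expect_equal(as.numeric(max_signal_positions(trm, txm)), 1.0)
  # all-zero transcripts skipped with a count
  tx2 <- make_tx("c1", c(21, 90), c(80, 95), "+")
  expect_message(p2 <- max_signal_positions(tr, tx2), "skipped")
  expect_length(p2, 1L)
  expect_equal(attr(p2, "skipped"), 1L)
})

test_that("synthetic 3'-loaded signal concentrates maxima in the top decile", {
  ds <- synth_generate(synth_config(seed = 14, n_transcripts = 100,
                                    chromosome_length = 3e5))
  pos <- suppressMessages(max_signal_positions(ds$signal, ds$transcripts))
  expect_gt(mean(pos > 0.9), 0.9)
})
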