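test_that("find_runs reports maximal runs at or above the length threshold", {
  r <- find_runs("AAATTG", 3)
  expect_equal(r$base, "A"); expect_equal(r$start, 1L); expect_equal(r$length, 3L)
  r2 <- find_runs("AAATTG", 2)
  expect_equal(r2$base, c("A", "T"))
  expect_equal(r2$start, c(1L, 4L))
  expect_equal(r2$length, c(3L, 2L))
  # N breaks runs and never forms one
  r3 <- find_runs("ANAAA", 3)
  expect_equal(r3$base, "A"); expect_equal(r3$start, 3L); expect_equal(r3$length, 3L)
  expect_equal(nrow(find_runs("NNNNN", 2)), 0L)
  expect_equal(nrow(find_runs("", 1)), 0L)
})

test_that("find_runs segments are maximal, disjoint and ordered", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_seq(60, alphabet = c("A", "T", "N"), prob = c(0.45, 0.45, 0.1))
    r <- find_runs(s, 1)
    b <- strsplit(s, "")[[1]]
    expect_true(all(diff(r$start) > 0))
    for (j in seq_len(nrow(r))) {
      span <- r$start[j]:(r$start[j] + r$length[j] - 1)
      expect_true(all(b[span] == r$base[j]))
      if (r$start[j] > 1) expect_false(b[r$start[j] - 1] == r$base[j])
      hi <- r$start[j] + r$length[j]
      if (hi <= length(b)) expect_false(b[hi] == r$base[j])
    }
    # coverage: every base position lies in exactly one reported ACGT run
    expect_equal(sum(r$length), sum(b != "N"))
  }
})

test_that("count_nonoverlapping matches the greedy scan on stated examples", {
  expect_equal(count_nonoverlapping("TTTT", "T", 2), 2L)
  expect_equal(count_nonoverlapping("TTTTT", "T", 2), 2L)
  expect_equal(count_nonoverlapping("TTATT", "T", 3), 0L)
  expect_equal(count_nonoverlapping("TTTTT", "T", 5, mode = "exact"), 1L)
  expect_equal(count_nonoverlapping("TTTTTT", "T", 5, mode = "exact"), 0L)
  expect_error(count_nonoverlapping("TTTT", "T", 1), ">= 2")
})

test_that("count_nonoverlapping equals exhaustive greedy scanning", {
  # independent oracle: walk left to right, consume len matches at a time
  greedy_scan <- function(s, base, len) {
    b <- strsplit(s, "")[[1]]
    n <- 0L; i <- 1L
    while (i + len - 1L <= length(b)) {
      if (all(b[i:(i + len - 1L)] == base)) { n <- n + 1L; i <- i + len }
      else i <- i + 1L
    }
    n
  }
  for (L in 1:12) {
    wins <- all_windows(L, alphabet = c("A", "T"))
    if (length(wins) > 300) { set.seed(L); wins <- sample(wins, 300) }
    for (s in wins) for (len in 2:3) {
      expect_identical(count_nonoverlapping(s, "T", len),
                       greedy_scan(s, "T", len))
    }
  }
})

test_that("window frequencies match a brute-force recount and handle edges", {
  g <- toy_genome(c1 = paste0("AAAA", "GTTTG", "C", "GTTTG", "AAAA"))
  w <- GRanges("c1", IRanges(c(5, 11), width = 5), strand = "+")
  tab <- window_track_frequencies(g, w, lengths = 3, bases = "T")
  expect_equal(tab$frequency[tab$base == "T" & tab$length == 3], 1.0)

  gG <- toy_genome(c1 = strrep("G", 100))
  wG <- GRanges("c1", IRanges(c(1, 21, 41), width = 20), strand = "+")
  tabG <- window_track_frequencies(gG, wG, lengths = 2:4)
  expect_true(all(tabG$frequency[tabG$base != "G"] == 0))

  set.seed(17)
  g2 <- toy_genome(c1 = random_seq(2000))
  st <- sample(1:1960, 30)
  w2 <- GRanges("c1", IRanges(st, width = 40),
                strand = sample(c("+", "-"), 30, replace = TRUE))
  tab2 <- window_track_frequencies(g2, w2, lengths = 2:6)
  seqs <- vapply(seq_along(w2), function(i) {
    s <- substr(as.character(g2[[1]]), st[i], st[i] + 39)
    if (as.character(strand(w2))[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  for (r in seq_len(nrow(tab2))) {
    brute <- sum(vapply(seqs, count_nonoverlapping, integer(1),
                        base = tab2$base[r], len = tab2$length[r]))
    expect_equal(tab2$count[r], brute)
  }
  # out-of-bounds windows dropped with a message
  w3 <- GRanges("c1", IRanges(c(10, 1990), width = 40), strand = "+")
  expect_message(tab3 <- window_track_frequencies(g2, w3, lengths = 2),
                 "dropped")
  expect_equal(tab3$n_windows[1], 1L)
  expect_error(window_track_frequencies(g2, GRanges(), lengths = 2), "empty")
})

test_that("minus-strand window frequencies equal plus-strand on the revcomp genome", {
  set.seed(19)
  s <- random_seq(500)
  g <- toy_genome(c1 = s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  g_rc <- toy_genome(c1 = rc)
  st <- sample(1:460, 10)
  w_minus <- GRanges("c1", IRanges(st, width = 40), strand = "-")
  # same windows on the revcomp genome, mirrored coordinates, plus strand
  st_m <- 500 - (st + 39) + 1
  w_plus <- GRanges("c1", IRanges(st_m, width = 40), strand = "+")
  t1 <- window_track_frequencies(g, w_minus, lengths = 2:5)
  t2 <- window_track_frequencies(g_rc, w_plus, lengths = 2:5)
  expect_equal(t1$count, t2$count)
})

test_that("tes_windows covers TES-19..TES+20 in transcription direction", {
  tx <- make_tx("c1", c(101, 301), c(200, 400), c("+", "-"))
  w <- tes_windows(tx, 40)
  expect_equal(start(w), c(200L - 19L, 301L - 20L))
  expect_equal(end(w), c(200L + 20L, 301L + 19L))
  expect_equal(width(w), c(40L, 40L))
})

test_that("body window sampling is reproducible, in-bounds and uniform", {
  tx <- make_tx("c1", 101, 1100, "+")
  w1 <- sample_body_windows(tx, 40, n_per_transcript = 200, seed = 5)
  w2 <- sample_body_windows(tx, 40, n_per_transcript = 200, seed = 5)
  expect_identical(start(w1), start(w2))
  expect_true(all(start(w1) >= 101 & end(w1) <= 1100))
  # windows centered near the TES are excluded
  centers <- start(w1) + 19
  expect_true(all(abs(centers - 1100) >= 20))

  # transcript exactly one window long: the only window is always returned
  tx1 <- make_tx("c1", 61, 100, "+")
  wo <- sample_body_windows(tx1, 40, seed = 1)
  expect_equal(start(wo), 61L)

  expect_warning(expect_error(
    sample_body_windows(make_tx("c1", 1, 10, "+"), 40, seed = 1)),
    "skipped")

  # approximate uniformity of starts over a long transcript
  big <- sample_body_windows(make_tx("c1", 1, 10000, "+"), 40,
                             n_per_transcript = 1000, seed = 7)
  h <- table(cut(start(big), breaks = seq(0, 10000, by = 1000)))
  p <- suppressWarnings(chisq.test(h[1:9])$p.value)  # last bin TES-truncated
  expect_gt(p, 0.01)
})

test_that("poly-tract anchoring picks the longest qualifying run, leftmost on ties", {
  s <- paste0("AC", "TTTTTT", "GG", "TTTTTTTT", "CA")
  expect_equal(locate_polytract_anchor(s, "T"), 11L)
  expect_true(is.na(locate_polytract_anchor("ACGTACGTTTTTA", "T")))  # max run 4
  s2 <- paste0("A", "TTTTTTT", "GG", "TTTTTTT", "C")
  expect_equal(locate_polytract_anchor(s2, "T"), 2L)
  # exhaustive scan oracle on random sequences
  set.seed(23)
  for (i in 1:25) {
    s3 <- random_seq(80, alphabet = c("A", "T"), prob = c(0.3, 0.7))
    r <- find_runs(s3, 1)
    r <- r[r$base == "T" & r$length >= 6, , drop = FALSE]
    want <- if (nrow(r)) r$start[which.max(r$length)] else NA_integer_
    expect_identical(locate_polytract_anchor(s3, "T"), want)
  }
})
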