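test_that("log_odds_score matches closed forms", {
  # a background-matching (uniform) row contributes 0 bits whatever the base
  u <- pwm("halfflat", rbind(c(1, 0, 0, 0), rep(0.25, 4)),
           background = "uniform")
  expect_equal(log_odds_score(u, "AA"), 2)
  expect_equal(log_odds_score(u, "AC"), 2)
  expect_equal(log_odds_score(u, "AT"), 2)
  # single certain column against uniform background: log2(4) = 2 bits
  p1 <- pwm("a", matrix(c(1, 0, 0, 0), 1, 4), background = "uniform",
            pseudocount = 1e-3)
  expect_equal(log_odds_score(p1, "A"), 2)
  expect_error(log_odds_score(p1, "AA"), "width")
  expect_error(log_odds_score(p1, "N"), "non-ACGT")
})

test_that("window scores equal the independent per-position oracle", {
  set.seed(21)
  for (rep in 1:20) {
    pw <- fix_random_pwm(4)
    win <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = "")
    expect_equal(log_odds_score(pw, win), oracle_window_score(pw, win),
                 tolerance = 1e-12)
  }
  # and scan_crm agrees with scoring every window separately (both strands)
  pw <- fix_random_pwm(5)
  seqs <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
  hits <- scan_crm(pw, seqs, t = -1e9)
  expect_equal(nrow(hits), 2 * (80 - 5 + 1))
  for (k in sample(nrow(hits), 10)) {
    h <- hits[k, ]
    win <- substr(seqs, h$start + 1, h$start + 5)
    if (h$strand == "-") win <- revcomp(win)
    expect_equal(h$score, oracle_window_score(pw, win), tolerance = 1e-12)
    expect_equal(h$q, h$score / pw$s_max, tolerance = 1e-12)
  }
})

test_that("scan_crm finds planted sites and handles edge cases", {
  pw <- fix_pwm_acg()
  # nothing above threshold
  expect_equal(nrow(scan_crm(pw, "TTTTTTTT", t = 3)), 0L)
  # sequence shorter than the motif
  expect_equal(nrow(scan_crm(pw, "AC", t = 0)), 0L)
  # planted consensus at 0-based offset 10 scores s_max, q = 1
  seqs <- paste0(strrep("A", 10), "ACG", strrep("A", 10))
  hits <- scan_crm(pw, seqs, t = pw$s_max - 1e-9)
  expect_equal(hits$start, 10L)
  expect_equal(hits$q, 1, tolerance = 1e-12)
  expect_equal(hits$strand, "+")
  # ambiguous bases: windows skipped, counted
  hits2 <- scan_crm(pw, "ACGNACG", t = 0)
  expect_gt(attr(hits2, "skipped"), 0)
  expect_true(all(hits2$start %in% c(0L, 4L)))
})

test_that("palindromic consensus is reported on both strands at one start", {
  # ACGT is its own reverse complement
  probs <- matrix(0.001 / 3 * 3, 4, 4)
  probs[] <- (1 - 0.97) / 3
  probs[cbind(1:4, 1:4)] <- 0.97
  pal <- pwm("pal", probs, background = "uniform")
  seqs <- paste0("TTTTT", "ACGT", "TTTTT")
  hits <- scan_crm(pal, seqs, t = pal$s_max - 1e-9)
  expect_equal(nrow(hits), 2L)
  expect_equal(unique(hits$start), 5L)
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("q = 1 iff the window is the consensus", {
  set.seed(5)
  pw <- fix_random_pwm(6)
  cons <- pwm_consensus(pw)
  expect_equal(log_odds_score(pw, cons) / pw$s_max, 1, tolerance = 1e-12)
  for (k in 1:10) {
    win <- cons
    i <- sample(6, 1)
    substr(win, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(cons, i, i)), 1)
    expect_lt(log_odds_score(pw, win) / pw$s_max, 1)
  }
})

test_that("raising the threshold never adds sites", {
  set.seed(9)
  pw <- fix_random_pwm(5)
  seqs <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  prev <- Inf
  for (t in c(-5, 0, 2, 4, 6)) {
    n <- nrow(scan_crm(pw, seqs, t = t))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("scanning the reverse complement mirrors sites", {
  set.seed(13)
  pw <- fix_random_pwm(5)
  seqs <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  fwd <- scan_crm(pw, seqs, t = 2)
  rev <- scan_crm(pw, revcomp(seqs), t = 2)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = 120 - 5 - rev$start,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score)
  o1 <- order(fwd$start, fwd$strand)
  o2 <- order(mirrored$start, mirrored$strand)
  expect_equal(fwd$start[o1], mirrored$start[o2])
  expect_equal(fwd$strand[o1], mirrored$strand[o2])
  expect_equal(fwd$score[o1], mirrored$score[o2], tolerance = 1e-12)
})

test_that("build_tfbs_map unions per-TF scans deterministically", {
  sd <- fix_tiny_dataset(seed = 8)
  # zero PWMs: empty site lists
  empty <- build_tfbs_map(sd$crms, list(), warn = FALSE)
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
  # planted sites exactly recovered (generator guarantees exactness)
  map <- build_tfbs_map(sd$crms, sd$pwms, t = 9, warn = FALSE)
  for (id in names(map)) {
    expect_equal(map[[id]]$start, sd$truth$sites[[id]]$start)
    expect_equal(map[[id]]$tf, sd$truth$sites[[id]]$tf)
    expect_false(is.unsorted(map[[id]]$start))
  }
  # determinism
  expect_identical(build_tfbs_map(sd$crms, sd$pwms, t = 9, warn = FALSE), map)
  # duplicate PWM names rejected
  expect_error(build_tfbs_map(sd$crms, list(sd$pwms[[1]], sd$pwms[[1]])),
               "distinct")
  # a CRM with no sites at all warns
  nosite <- sequence_set("bare", strrep("T", 50))
  expect_warning(build_tfbs_map(nosite, list(fix_pwm_acg())), "no predicted")
})
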