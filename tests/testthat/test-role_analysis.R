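test_that("configuration index encoding round trips", {
  for (n in c(1, 3, 8)) for (idx in sample(0:(2^n - 1), min(2^n, 8))) {
    expect_identical(index_from_roles(roles_from_index(idx, n)), as.integer(idx))
  }
  expect_equal(roles_from_index(0, 3), c(-1, -1, -1))
  expect_equal(roles_from_index(7, 3), c(1, 1, 1))
})

test_that("cc_matrix validates its shape and values", {
  pn <- tf_panel(c("a", "b"), c("+", "-"))
  expect_error(cc_matrix(matrix(0, 3, 3), pn), "expected 2\\^2")
  expect_error(cc_matrix(matrix(2, 3, 4), pn), "in \\[-1, 1\\]")
  m <- cc_matrix(matrix(0.5, 3, 4), pn)
  expect_identical(m$configs, 0:3)
})

test_that("smallest_optimal covers match the exhaustive oracle", {
  set.seed(61)
  for (rep in 1:12) {
    ccm <- fix_random_ccm(6, 3, levels = 3)   # 8 configs, many ties
    res <- smallest_optimal(ccm)
    opt <- lapply(seq_len(6), function(i)
      which(ccm$cc[i, ] >= max(ccm$cc[i, ]) - 1e-9))
    oracle <- oracle_min_cover(opt, 8)
    expect_identical(length(res$chosen_configs), length(oracle))
    # the chosen set actually covers every CRM's optimal set
    for (i in seq_len(6))
      expect_true(any((res$chosen_configs + 1L) %in% opt[[i]]))
    # assigned config is optimal for its CRM
    for (i in seq_len(6))
      expect_true((res$per_crm_config[[i]] + 1L) %in% opt[[i]])
  }
})

test_that("smallest_optimal trivial geometries", {
  pn <- tf_panel(c("a", "b"), c("+", "-"))
  # all CRMs share one unique optimum -> cover size 1
  m <- matrix(0, 3, 4); m[, 3] <- 0.9
  res <- smallest_optimal(cc_matrix(m, pn))
  expect_identical(res$chosen_configs, 2L)
  # two CRMs with disjoint singleton optima -> size 2
  m2 <- rbind(c(0.9, 0, 0, 0), c(0, 0.9, 0, 0))
  expect_length(smallest_optimal(cc_matrix(m2, pn))$chosen_configs, 2L)
})

test_that("smallest_optimal applies the epsilon NA rule", {
  pn <- tf_panel(c("a", "b"), c("+", "-"))
  # TF b's bit (columns 0/1 vs 2/3) never changes CC -> NA for b
  m <- rbind(c(0.2, 0.8, 0.2, 0.8))
  res <- smallest_optimal(cc_matrix(m, pn), epsilon = 0.1)
  calls <- res$calls
  expect_identical(calls$role[calls$tf == "b"], NA_character_)
  expect_false(any(calls$strong[calls$tf == "b"]))
  expect_identical(calls$role[calls$tf == "a"], "ACT")
  expect_true(all(calls$strong[calls$tf == "a"]))
})

test_that("best_n matches exhaustive enumeration on random matrices", {
  set.seed(62)
  for (rep in 1:12) {
    ccm <- fix_random_ccm(5, 3)
    for (n in 1:2) {
      res <- best_n(ccm, n)
      oracle <- oracle_best_n(ccm$cc, n)
      expect_equal(attr(res, "total_cc"), oracle$total, tolerance = 1e-12)
      expect_identical(res$chosen_configs, sort(as.integer(oracle$set - 1L)))
    }
  }
})

test_that("best_n trivial identities", {
  set.seed(63)
  ccm <- fix_random_ccm(5, 2)
  # n = 1: the column with maximal column sum
  res1 <- best_n(ccm, 1)
  expect_identical(res1$chosen_configs,
                   as.integer(which.max(colSums(ccm$cc)) - 1L))
  # full set: total equals the sum of row maxima
  res4 <- best_n(ccm, 4)
  expect_equal(attr(res4, "total_cc"), sum(apply(ccm$cc, 1, max)),
               tolerance = 1e-12)
  # monotone in n
  tots <- vapply(1:4, function(n) attr(best_n(ccm, n), "total_cc"),
                 numeric(1))
  expect_true(all(diff(tots) >= -1e-12))
  expect_error(best_n(ccm, 5), "1..4")
  # every call strong
  expect_true(all(best_n(ccm, 2)$calls$strong))
})

test_that("sensitivity matches the exhaustive pair oracle", {
  set.seed(64)
  for (rep in 1:10) {
    ccm <- fix_random_ccm(4, 4)
    res <- sensitivity(ccm, na_threshold = 0.1, strong_threshold = 0.1)
    delta <- oracle_sensitivity_delta(ccm$cc, 4)
    for (ci in 1:4) for (t in 1:4) {
      call <- res$calls[res$calls$crm == ccm$crms[ci] &
                          res$calls$tf == ccm$panel$names[t], ]
      d <- delta[ci, t]
      expect_equal(call$delta_cc, d, tolerance = 1e-12)
      if (abs(d) <= 0.1) {
        expect_identical(call$role, NA_character_)
      } else {
        expect_identical(call$role, if (d > 0) "ACT" else "REP")
        expect_identical(call$strong, abs(d) > 0.1)
      }
    }
  }
})

test_that("sensitivity degenerate and single-TF cases", {
  pn <- tf_panel(c("a", "b"), c("+", "-"))
  # b's bit never matters -> NA everywhere for b
  m <- rbind(c(0.1, 0.7, 0.1, 0.7), c(0.3, 0.2, 0.3, 0.2))
  res <- sensitivity(cc_matrix(m, pn))
  expect_true(all(is.na(res$calls$role[res$calls$tf == "b"])))
  # n = 1 panel: cc(ACT) - cc(REP) = 0.5 -> ACT, strong
  one <- cc_matrix(matrix(c(0.2, 0.7), 1, 2),
                   tf_panel("solo", "+"))
  r1 <- sensitivity(one)
  expect_identical(r1$calls$role, "ACT")
  expect_true(r1$calls$strong)
  expect_equal(r1$calls$delta_cc, 0.5)
})

test_that("summarize_tf_roles applies the theta majority rule", {
  mk <- function(n_act, n_rep, n_na = 0) {
    calls <- data.frame(
      crm = sprintf("c%02d", seq_len(n_act + n_rep + n_na)),
      tf = "x",
      role = c(rep("ACT", n_act), rep("REP", n_rep), rep(NA, n_na)),
      strong = c(rep(TRUE, n_act + n_rep), rep(FALSE, n_na)),
      delta_cc = NA_real_, stringsAsFactors = FALSE)
    dualtf:::method_result("sensitivity", 0L, NULL, calls)
  }
  expect_identical(summarize_tf_roles(mk(10, 0))$role, "+")
  expect_identical(summarize_tf_roles(mk(5, 5))$role, "s")
  expect_identical(summarize_tf_roles(mk(7, 3))$role, "+")   # 0.7 > 2/3
  expect_identical(summarize_tf_roles(mk(2, 1))$role, "s")   # 2/3 not > 2/3
  s0 <- summarize_tf_roles(mk(0, 0, 4))
  expect_identical(s0$role, "s")
  expect_identical(s0$confidence, 0L)
  expect_error(summarize_tf_roles(mk(1, 0), theta = 0.4), "theta")
})

test_that("ensemble_vote takes 2-of-3 majorities and counts support", {
  mk_sum <- function(role, nsa = 2L, nsr = 1L)
    data.frame(tf = c("x", "y"), role = role, n_act = 0L, n_rep = 0L,
               n_strong_act = nsa, n_strong_rep = nsr,
               confidence = 0L, stringsAsFactors = FALSE)
  v <- ensemble_vote(list(mk_sum(c("+", "s")), mk_sum(c("+", "s")),
                          mk_sum(c("-", "s"))))
  expect_identical(v$role, c("+", "s"))
  expect_identical(v$confidence[1], 6L)       # 3 methods x n_strong_act = 2
  v2 <- ensemble_vote(list(mk_sum(c("+", "+")), mk_sum(c("-", "-")),
                           mk_sum(c("s", "s"))))
  expect_identical(v2$role, c("s", "s"))      # three-way disagreement
  expect_error(ensemble_vote(list(mk_sum("+"), mk_sum("+"))), "three")
})

test_that("enrichment_call reproduces the worked p-value examples", {
  # activator set enriched, repressor background, gap > 0.2 -> differential
  e1 <- enrichment_call(0.0, 0.231)
  expect_identical(e1$status_act, "over")
  expect_identical(e1$status_rep, "background")
  expect_true(e1$differential)
  # both over -> not differential
  expect_false(enrichment_call(0.0, 0.0)$differential)
  # gap below delta -> not differential
  e3 <- enrichment_call(0.079, 0.005)
  expect_identical(e3$status_rep, "over")
  expect_false(e3$differential)
  # untested blocks a differential call
  e4 <- enrichment_call(NA, 0.001)
  expect_identical(e4$status_act, "untested")
  expect_false(e4$differential)
  # under-representation threshold
  expect_identical(enrichment_call(0.995, 0.5)$status_act, "under")
  expect_error(enrichment_call(1.2, 0), "\\[0, 1\\]")
})

test_that("bonferroni correction is multiply-and-cap", {
  expect_equal(bonferroni_correct(0.001, 76), 0.076)
  expect_equal(bonferroni_correct(0.5, 76), 1)
})

test_that("build_cc_matrix guards, shapes and determinism", {
  sd <- fix_tiny_dataset(seed = 18)
  ds <- as_crm_dataset(sd, rescan = FALSE)
  sch <- sa_schedule(iterations = 40, repeats = 1, seed = 6)
  ccm <- build_cc_matrix(ds, sch)
  expect_identical(dim(ccm$cc), c(2L, 4L))
  expect_true(all(is.finite(ccm$cc)))
  expect_identical(build_cc_matrix(ds, sch)$cc, ccm$cc)
  big <- tf_panel(paste0("t", 1:11), rep("+", 11))
  ds2 <- ds; ds2$panel <- big
  expect_error(build_cc_matrix(ds2, sch), "guard")
})

test_that("planted-configuration column is the row maximum (noise free)", {
  sd <- fix_tiny_dataset(noise_sd = 0, seed = 25)
  ds <- as_crm_dataset(sd, rescan = FALSE)
  ccm <- build_cc_matrix(ds, sa_schedule(seed = 8))
  planted <- index_from_roles(sd$truth$roles_per_crm[[1]])
  for (i in seq_len(nrow(ccm$cc))) {
    expect_equal(unname(which.max(ccm$cc[i, ])) - 1L, planted)
  }
})
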