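two_tf_params <- function(E_act = c(A = 2, R = 0), E_rep = c(A = 0, R = 1),
                          K = c(A = 2, R = 2), G0 = 0, R0 = 1, d = 100) {
  model_params(K = K, E_act = E_act, E_rep = E_rep, G0 = G0, R0 = R0, d = d)
}

site_row <- function(tf, start, q = 1, width = 8L) {
  n <- length(tf)
  dualtf:::tfbs_frame(tf, start, rep("+", n), rep(width, n),
                      rep(q * 10, n), rep(q, n))
}

test_that("site_occupancy follows the binding isotherm", {
  expect_equal(site_occupancy(1, 0, 5), 0)
  expect_equal(site_occupancy(0.5, 1, 2), 0.5)   # K v q = 1
  expect_equal(site_occupancy(1, 1.5, 2), 0.75)  # K v q = 3
  expect_error(site_occupancy(0, 1, 1), "q must")
  expect_error(site_occupancy(1, -1, 1), "v must")
  # monotone in each argument
  expect_true(all(diff(site_occupancy(seq(0.1, 1, 0.1), 1, 2)) > 0))
  expect_true(all(diff(site_occupancy(1, seq(0, 3, 0.5), 2)) > 0))
})

test_that("total_activation sums quenched activator contributions", {
  p <- two_tf_params()
  roles <- c(A = 1, R = -1)
  conc <- c(A = 1, R = 1)
  expect_equal(total_activation(site_row(character(0), integer(0)),
                                conc, p, roles), 0)
  one_act <- site_row("A", 10)
  f <- site_occupancy(1, 1, 2)
  expect_equal(total_activation(one_act, conc, p, roles), 2 * f)
  # repressor within d fully quenches when E_rep * f_rep = 1
  p2 <- two_tf_params(K = c(A = 2, R = 1e12))   # f_rep ~ 1
  both <- rbind(site_row("A", 10), site_row("R", 50))
  expect_equal(total_activation(both, conc, p2, roles), 0, tolerance = 1e-9)
  # repressor beyond d leaves the activator untouched
  apart <- rbind(site_row("A", 10), site_row("R", 400))
  expect_equal(total_activation(apart, conc, p2, roles),
               2 * site_occupancy(1, 1, 2))
})

test_that("predict_expression applies the logistic gate", {
  axis <- c(10, 20, 30)
  conc <- profile_set(axis, list(A = c(0.5, 0.5, 0.5), R = c(0, 0, 0)))
  p <- two_tf_params()
  roles <- c(A = 1, R = -1)
  # no sites: flat basal rate R0 / (1 + exp(G0))
  flat <- predict_expression(site_row(character(0), integer(0)), conc,
                             two_tf_params(G0 = 1.3), roles)
  expect_equal(unname(flat$profiles[1, ]), rep(1 / (1 + exp(1.3)), 3))
  # hand case: q = 1, K v = 1 -> f = 0.5; E_act = 2 -> Sigma = 1;
  # G0 = 0, R0 = 1 -> R = 1 / (1 + exp(-1))
  pr <- predict_expression(site_row("A", 10), conc, p, roles)
  expect_equal(unname(pr$profiles[1, ]), rep(1 / (1 + exp(-1)), 3),
               tolerance = 1e-12)
  expect_equal(unname(pr$profiles[1, 1]), 0.7311, tolerance = 1e-4)
  # saturation: huge activation drives R -> R0
  psat <- two_tf_params(E_act = c(A = 1e6, R = 0))
  sat <- predict_expression(site_row("A", 10), conc, psat, roles)
  expect_equal(unname(sat$profiles[1, ]), rep(1, 3), tolerance = 1e-9)
  # missing concentration track errors
  expect_error(predict_expression(site_row("Z", 1), conc, p,
                                  c(A = 1, R = -1, Z = 1)),
               "no concentration track")
})

test_that("compiled and reference engines agree on random cases", {
  set.seed(31)
  sd <- fix_tiny_dataset(seed = 12, n_crms = 3)
  ds <- as_crm_dataset(sd, rescan = FALSE)
  tfs <- ds$panel$names
  for (rep in 1:15) {
    p <- model_params(
      K = stats::setNames(exp(runif(2, -2, 3)), tfs),
      E_act = stats::setNames(runif(2, 0, 8), tfs),
      E_rep = stats::setNames(runif(2, 0, 1), tfs),
      G0 = runif(1, -4, 4), R0 = exp(runif(1, -1, 1)),
      d = sample(c(10, 60, 150, 1e6), 1))
    roles <- stats::setNames(sample(c(-1, 1), 2, replace = TRUE), tfs)
    id <- sample(names(ds$crms), 1)
    a <- predict_expression(ds$sites[[id]], ds$concentrations, p, roles,
                            engine = "cpp")
    b <- predict_expression(ds$sites[[id]], ds$concentrations, p, roles,
                            engine = "r")
    expect_equal(a$profiles, b$profiles, tolerance = 1e-12)
  }
})

test_that("model invariants hold", {
  sd <- fix_tiny_dataset(seed = 14)
  ds <- as_crm_dataset(sd, rescan = FALSE)
  p <- sd$truth$spec$params
  roles <- c(A = 1, R = -1)
  id <- names(ds$crms)[1]
  pred <- function(par, conc = ds$concentrations)
    as.numeric(predict_expression(ds$sites[[id]], conc, par, roles)$profiles)
  base <- pred(p)
  # rates live strictly inside (0, R0)
  expect_true(all(base > 0 & base < p$R0))
  # monotone non-decreasing in activator concentration
  up <- ds$concentrations
  up$profiles["A", ] <- up$profiles["A", ] * 1.5
  expect_true(all(pred(p, up) >= base - 1e-12))
  # monotone non-increasing in repressor concentration
  up2 <- ds$concentrations
  up2$profiles["R", ] <- up2$profiles["R", ] * 1.5
  expect_true(all(pred(p, up2) <= base + 1e-12))
  # E_rep = 0 reproduces the repressor-free prediction
  p0 <- p; p0$E_rep[] <- 0
  norep <- ds$sites[[id]][ds$sites[[id]]$tf == "A", ]
  expect_equal(pred(p0),
               as.numeric(predict_expression(norep, ds$concentrations, p,
                                             roles)$profiles),
               tolerance = 1e-12)
  # d larger than the CRM: every repressor quenches every activator
  # (matches the whole-CRM repression limit computed by hand)
  phuge <- p; phuge$d <- 1e9
  s <- ds$sites[[id]]
  manual <- vapply(seq_along(ds$concentrations$axis), function(xi) {
    v <- ds$concentrations$profiles[, xi]
    f <- site_occupancy(s$q, unname(v[s$tf]), unname(p$K[s$tf]))
    act <- which(s$tf == "A"); rep_ <- which(s$tf == "R")
    sig <- sum(vapply(act, function(i)
      p$E_act[["A"]] * f[i] * prod(1 - p$E_rep[["R"]] * f[rep_]),
      numeric(1)))
    p$R0 / (1 + exp(-(sig - p$G0)))
  }, numeric(1))
  expect_equal(pred(phuge), manual, tolerance = 1e-12)
})

test_that("pearson_cc handles perfect, affine and degenerate profiles", {
  ax <- 1:5
  a <- profile_set(ax, list(x = c(1, 3, 2, 5, 4)))
  expect_equal(pearson_cc(a, a), 1)
  b <- profile_set(ax, list(x = -2 * c(1, 3, 2, 5, 4) + 7))
  expect_equal(pearson_cc(a, b), -1)
  konst <- profile_set(ax, list(x = rep(2, 5)))
  expect_warning(cc0 <- pearson_cc(a, konst), "zero-variance")
  expect_equal(cc0, 0)
  other <- profile_set(ax + 1, list(x = 1:5))
  expect_error(pearson_cc(a, other), "different axes")
  # invariant under positive affine transforms of the prediction
  expect_equal(pearson_cc(a, profile_set(ax, list(x = 0.3 * c(1, 3, 2, 5, 4) + 9))),
               1, tolerance = 1e-12)
})

test_that("free-parameter accounting matches both model families", {
  expect_identical(count_free_parameters("reinitz", 1), 4L)
  expect_identical(count_free_parameters("reinitz", 8), 18L)
  expect_identical(count_free_parameters("reinitz", 8, "Hb"), 19L)
  expect_identical(count_free_parameters("reinitz", 8, c("Hb", "Kr")), 20L)
  # Segal count 3n + 3|W| + |C|; 344 printed for n = 8, |C| = 44 implies
  # |W| = 92 summed PWM columns
  expect_identical(count_free_parameters("segal", 8, pwm_total_width = 92,
                                         n_crms = 44), 344L)
  expect_error(count_free_parameters("segal", 8), "requires")
})
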