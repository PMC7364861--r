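test_that("parameter record validates and converts to canonical minutes", {
  p <- hpa_params()
  expect_s3_class(p, "hpa_params")
  expect_equal(p$wC, 0.099 / 1440)          # per-day input stored per-minute
  expect_equal(p$wA, 0.049 / 1440)
  expect_equal(p$w1, 0.17)                  # per-minute input unchanged
  expect_equal(attr(p, "unit"), "min")
  # supplying the same rates in the other unit gives an identical record
  p2 <- hpa_params(w1 = 0.17 * 1440, w2 = 0.035 * 1440, w3 = 0.0086 * 1440,
                   wCRHE = 0.016 * 1440, hormone_rate_unit = "day")
  expect_equal(unclass(p2), unclass(p))
  expect_error(hpa_params(w1 = -1), "strictly positive")
  expect_error(hpa_params(K_GR = 1), "K_GR")
  expect_error(hpa_params(n = 2.5), "positive integer")
})

test_that("packaged default parameter file reproduces the reference set", {
  path <- system.file("extdata", "params_default.json", package = "hpaxis")
  expect_true(nzchar(path))
  expect_equal(unclass(read_params(path)), unclass(hpa_params()))
  # wCE alias for the clearance-modifier rate is accepted
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"wCE": 0.046}', tmp)
  expect_equal(read_params(tmp)$wCR, 0.046 / 1440)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"w9": 1}', bad)
  expect_error(read_params(bad), "unknown parameter")
})

test_that("full-model right-hand side behaves at the stated anchor points", {
  m <- hpa_model("full_mass")
  p <- m$params
  expect_equal(hpa_rhs(m, m$baseline, u = 1), setNames(rep(0, 6), m$layout))
  d4 <- hpa_rhs(m, m$baseline, u = 4)
  expect_equal(d4[["x1"]], 3 * p$w1)
  expect_equal(unname(d4[c("x2", "x3", "C", "A")]), rep(0, 4))
  # absorbing boundary of mass-action growth
  st <- m$baseline
  st["C"] <- 0
  expect_equal(hpa_rhs(m, st, u = 1)[["C"]], 0)
  expect_error(hpa_rhs(m, replace(m$baseline, "x3", -1), u = 1), "x3")
  expect_error(hpa_rhs(m, m$baseline, u = -1), "non-negative")
})

test_that("compiled RHS agrees with an independent pure-R evaluation", {
  withr::local_seed(42)
  p <- hpa_params()
  for (v in c("full_mass", "classic", "gr_resistance", "slow_clearance")) {
    m <- hpa_model(v, p)
    for (rep in 1:20) {
      st <- random_state(m)
      u <- runif(1, 0, 6)
      dose <- sample(c(0, 20), 1)
      expect_equal(hpa_rhs(m, st, u = u, crh_dose = dose),
                   ref_rhs(v, st, p, u, dose),
                   tolerance = 1e-12)
    }
  }
})

test_that("steady state pins CRH and ACTH at baseline and solves cortisol", {
  ss1 <- steady_state(u = 1)
  expect_equal(unlist(ss1[c("x1", "x2", "x3", "C", "A")]),
               c(x1 = 1, x2 = 1, x3 = 1, C = 1, A = 1), tolerance = 1e-9)
  # residual of the full RHS at the returned state (oracle equivalence)
  for (u in c(0.5, 1, 2, 4, 8)) {
    ss <- steady_state(u = u)
    expect_equal(ss$x1, 1)
    expect_equal(ss$x2, 1)
    expect_lt(ss$residual, 1e-10)
  }
  # negligible GR feedback: cortisol and adrenal track the input directly
  ssw <- steady_state(hpa_params(K_GR = 1e6), u = 4)
  expect_equal(ssw$x3, 4, tolerance = 1e-6)
  expect_equal(ssw$A, 4, tolerance = 1e-6)
  expect_equal(ssw$C, 1, tolerance = 1e-6)
  # strong feedback attenuates the cortisol rise
  expect_lt(steady_state(u = 4)$x3, 4)
})

test_that("steady-state cortisol and adrenal mass rise with input and with K_GR", {
  us <- c(0.5, 1, 2, 4, 8)
  x3s <- vapply(us, function(u) steady_state(u = u)$x3, numeric(1))
  expect_true(all(diff(x3s) > 0))
  ks <- c(2, 4, 8, 16)
  x3k <- vapply(ks, function(k) steady_state(hpa_params(K_GR = k), u = 4)$x3,
                numeric(1))
  ak <- vapply(ks, function(k) steady_state(hpa_params(K_GR = k), u = 4)$A,
               numeric(1))
  expect_true(all(diff(x3k) > 0))
  expect_true(all(diff(ak) > 0))
})

test_that("fast quasi-steady state: closed forms, exact mode, and agreement", {
  expect_equal(fast_qss(C = 1, A = 1, u = 1),
               tibble::tibble(x1 = 1, x2 = 1, x3 = 1))
  q <- fast_qss(C = 4, A = 1)
  expect_equal(unlist(q), c(x1 = 0.5, x2 = 2, x3 = 2))
  qe <- fast_qss(C = 1, A = 1, u = 1, mode = "exact")
  expect_equal(unlist(qe), c(x1 = 1, x2 = 1, x3 = 1), tolerance = 1e-9)
  # modes agree within 5% while cortisol stays well below K_GR: the
  # neglected GR deviation is ~(x3/K_GR)^n, i.e. < 4% for x3 <= K_GR/3
  withr::local_seed(7)
  p <- hpa_params()
  for (rep in 1:25) {
    C <- runif(1, 0.3, 2); A <- runif(1, 0.3, 2); u <- runif(1, 0.5, 2)
    ap <- fast_qss(C, A, u, p, mode = "approx")
    ex <- fast_qss(C, A, u, p, mode = "exact")
    if (ex$x3 <= p$K_GR / 3) {
      expect_equal(ap$x3, ex$x3, tolerance = 0.05)
      expect_equal(ap$x2, ex$x2, tolerance = 0.05)
    }
  }
  expect_error(fast_qss(C = -1, A = 1), "strictly positive")
})
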