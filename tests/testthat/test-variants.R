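test_that("variant construction exposes the documented state layouts", {
  expect_equal(hpa_model("full_mass")$layout,
               c("x1", "x2", "x3", "C", "A", "x1E"))
  expect_equal(hpa_model("classic")$layout, c("x1", "x2", "x3", "x1E"))
  expect_equal(hpa_model("gr_resistance")$layout,
               c("x1", "x2", "x3", "x1E", "R"))
  expect_equal(hpa_model("slow_clearance")$layout,
               c("x1", "x2", "x3", "x1E", "CR"))
  expect_error(hpa_model("bogus"), "full_mass.*classic|valid ids")
})

test_that("every variant's baseline state zeroes its right-hand side", {
  for (v in c("full_mass", "classic", "gr_resistance", "slow_clearance",
              "slow_input")) {
    m <- hpa_model(v)
    d <- hpa_rhs(m, m$baseline, u = 1)
    expect_equal(max(abs(d)), 0, tolerance = 1e-14, label = v)
  }
})

test_that("GR-resistance dynamics decline under sustained cortisol", {
  m <- hpa_model("gr_resistance")
  p <- m$params
  # steady resistance at basal cortisol: R* = 1/(1 + lambda x3^2) = 1/2
  st <- m$baseline
  expect_equal(st[["R"]], 0.5)
  expect_equal(hpa_rhs(m, st, u = 1)[["R"]], 0)
  # at x3 -> 0 with R = 1 the production and removal terms cancel
  st2 <- m$baseline
  st2["x3"] <- 1e-8; st2["R"] <- 1
  expect_equal(hpa_rhs(m, st2, u = 1)[["R"]], 0, tolerance = 1e-12)
  # sustained high cortisol pushes R below its basal value (weaker feedback)
  traj <- simulate_hpa(m, protocol_constant(4), t_end = 200)
  last <- traj$data[nrow(traj$data), ]
  expect_lt(last$R, 0.5)
  # long-run R matches 1/(1 + lambda x3^2) at the settled cortisol within 1%
  expect_equal(last$R, 1 / (1 + p$lam * last$x3^2), tolerance = 0.01)
})

test_that("slow-clearance modifier integrates cortisol excess", {
  m <- hpa_model("slow_clearance")
  p <- m$params
  st <- m$baseline
  expect_equal(hpa_rhs(m, st, u = 1), setNames(rep(0, 5), m$layout))
  st["x3"] <- 2
  expect_equal(hpa_rhs(m, st, u = 1)[["CR"]], p$wCR * (2 - 1))
  # CR = 2 halves the effective cortisol removal term
  stA <- m$baseline; stA["CR"] <- 2
  stB <- m$baseline
  dxA <- hpa_rhs(m, stA, u = 1)[["x3"]]
  dxB <- hpa_rhs(m, stB, u = 1)[["x3"]]
  expect_equal(dxA, p$w3 * (1 - 0.5))
  expect_equal(dxB, 0)
})

test_that("classic constant-mass cascade shows no slow adaptation", {
  # held stressor: hormones settle elevated; CRH and ACTH do not adapt
  traj <- simulate_hpa("classic", protocol_constant(4), t_end = 2)
  last <- traj$data[nrow(traj$data), ]
  expect_gt(last$x1, 1.05)
  expect_gt(last$x2, 1.3)
  expect_gt(last$x3, 1.5)
  # after stress ends, all hormones revert within hours
  traj2 <- simulate_hpa("classic", protocol_step(u = 4, start = 0, end = 2),
                        t_end = 2.5)
  sub <- traj2$data[traj2$data$time >= 2.25, ] # six hours after stress end
  expect_true(all(abs(sub$x1 - 1) < 0.01))
  expect_true(all(abs(sub$x2 - 1) < 0.01))
  expect_true(all(abs(sub$x3 - 1) < 0.01))
})

test_that("trajectories from positive initial states stay positive", {
  withr::local_seed(11)
  for (v in c("full_mass", "classic", "gr_resistance", "slow_clearance")) {
    m <- hpa_model(v)
    for (rep in 1:3) {
      init <- random_state(m)
      traj <- simulate_hpa(m, protocol_step(u = 2, start = 0, end = 2),
                           t_end = 5, init = init)
      vals <- as.matrix(traj$data[, setdiff(m$layout, "x1E")])
      expect_true(all(vals > 0), label = paste(v, "positivity"))
    }
  }
})
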