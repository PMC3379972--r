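# GeoSSE: state coding, ODE likelihood, ML, LRT, MCMC, per-area scan.

geo_pars <- function(...) {
  p <- c(sA = 0.3, sB = 0.2, sAB = 0.1, xA = 0.05, xB = 0.05,
         dA = 0.1, dB = 0.1)
  over <- c(...)
  p[names(over)] <- over
  p
}

test_that("tip state coding against a focal area", {
  tips <- tibble::tibble(species = c("s1", "s2", "s3"),
                         range = c("D", "CE", "CD"))
  st <- code_states(tips, "D")
  expect_equal(st$state, c("A", "B", "AB"))
  expect_error(code_states(tips, "Z"), "unknown focal")
})

test_that("branch ODE agrees with an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  set.seed(301)
  p <- geo_pars()
  rhs <- function(t, y, parms) {
    EA <- y[1]; EB <- y[2]; EAB <- y[3]
    DA <- y[4]; DB <- y[5]; DAB <- y[6]
    sA <- p["sA"]; sB <- p["sB"]; sAB <- p["sAB"]
    xA <- p["xA"]; xB <- p["xB"]; dA <- p["dA"]; dB <- p["dB"]
    list(c(
      xA - (sA + dA + xA) * EA + dA * EAB + sA * EA^2,
      xB - (sB + dB + xB) * EB + dB * EAB + sB * EB^2,
      -(sA + sB + sAB + xA + xB) * EAB + xA * EB + xB * EA +
        sA * EA * EAB + sB * EB * EAB + sAB * EA * EB,
      -(sA + dA + xA) * DA + dA * DAB + 2 * sA * DA * EA,
      -(sB + dB + xB) * DB + dB * DAB + 2 * sB * DB * EB,
      -(sA + sB + sAB + xA + xB) * DAB + xA * DB + xB * DA +
        sA * (DA * EAB + DAB * EA) + sB * (DB * EAB + DAB * EB) +
        sAB * (DA * EB + DB * EA)))
  }
  for (rep in 1:5) {
    y0 <- c(runif(3, 0, 0.3), 0, 0, 0)
    y0[3 + sample.int(3, 1)] <- 1
    t <- runif(1, 0.5, 10)
    mine <- rangediv:::geosse_integrate_cpp(y0, t, p)
    ref <- deSolve::ode(y0, c(0, t), rhs, NULL, rtol = 1e-10,
                        atol = 1e-13)[2, -1]
    expect_equal(unname(mine), unname(ref), tolerance = 1e-7)
  }
})

test_that("tip initial conditions encode the sampling fractions", {
  # E(0) = 1 - f per state: a prior-free check through a zero-length tree
  p <- geo_pars()
  f <- c(0.6, 0.8, 0.9)
  y <- rangediv:::geosse_integrate_cpp(c(1 - f, f[1], 0, 0), 0, p)
  expect_equal(y[1:3], 1 - f)
})

test_that("full sampling equals the unadjusted likelihood bit for bit", {
  set.seed(302)
  for (rep in 1:3) {
    sim <- simulate_geosse(geo_pars(), n_tips = 30,
                           seed = 310 + rep)
    p <- geo_pars()
    expect_identical(
      geosse_loglik(sim$tree, sim$states, p, sampling = c(1, 1, 1)),
      geosse_loglik(sim$tree, sim$states, p))
  }
})

test_that("likelihood is symmetric under the A/B label swap", {
  sim <- simulate_geosse(geo_pars(sA = 0.35, sB = 0.15), n_tips = 40,
                         seed = 303)
  p <- geo_pars(sA = 0.35, sB = 0.15, xA = 0.07, xB = 0.02,
                dA = 0.12, dB = 0.05)
  ll <- geosse_loglik(sim$tree, sim$states, p, sampling = c(0.8, 0.9, 1))
  swapped <- c(sA = p[["sB"]], sB = p[["sA"]], sAB = p[["sAB"]],
               xA = p[["xB"]], xB = p[["xA"]],
               dA = p[["dB"]], dB = p[["dA"]])
  st2 <- sim$states
  st2$state <- c(A = "B", B = "A", AB = "AB")[st2$state]
  ll2 <- geosse_loglik(sim$tree, st2, swapped, sampling = c(0.9, 0.8, 1))
  expect_equal(ll, ll2, tolerance = 1e-9)
})

test_that("GeoSSE collapses to the closed-form birth-death likelihood", {
  set.seed(304)
  for (rep in 1:4) {
    lam <- runif(1, 0.1, 0.5); mu <- runif(1, 0, 0.8) * lam
    phy <- simulate_bd_tree(lam, mu, n_tips = sample(10:40, 1),
                            seed = 320 + rep)
    st <- tibble::tibble(species = phy$tip.label, state = "A")
    p <- c(sA = lam, sB = runif(1, 0.05, 0.5), sAB = 0,
           xA = mu, xB = 0, dA = 0, dB = 0)
    expect_equal(geosse_loglik(phy, st, p), bd_loglik(phy, lam, mu),
                 tolerance = 1e-6)
  }
})

test_that("the reduced model never beats the full model and the LRT behaves", {
  sim <- simulate_geosse(geo_pars(sAB = 0.15), n_tips = 60, seed = 305)
  red <- fit_geosse_ml(sim$tree, sim$states, constraint = "no_sab")
  full <- rangediv:::fit_geosse_full_nested(sim$tree, sim$states,
                                            c(1, 1, 1), red)
  expect_gte(full$loglik, red$loglik - 1e-6)
  expect_identical(red$pars[["sAB"]], 0)
  lrt <- lrt_compare(full, red)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1L)
  # chi-square reference values
  f <- full; r <- full
  r$loglik <- f$loglik
  expect_equal(lrt_compare(f, r)$p_value, 1)
  r$loglik <- f$loglik - 3.841 / 2
  expect_equal(lrt_compare(f, r)$p_value, 0.05, tolerance = 1e-3)
  # optimum at least as good as the generating truth
  expect_gte(full$loglik,
             geosse_loglik(sim$tree, sim$states, geo_pars(sAB = 0.15)))
})

test_that("MCMC is reproducible, prior-calibrated and summarizable", {
  sim <- simulate_geosse(geo_pars(), n_tips = 25, seed = 306)
  a <- mcmc_sample(sim$tree, sim$states, model = "no_sab",
                   generations = 200, burnin = 50, seed = 11)
  b <- mcmc_sample(sim$tree, sim$states, model = "no_sab",
                   generations = 200, burnin = 50, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 150) # generations - burnin at thinning 1
  td <- tidy(a)
  expect_true(all(c("term", "mean", "cred_lo", "cred_hi") %in% names(td)))

  # prior-only run recovers the prior means within Monte-Carlo error
  pm <- c(sA = 0.3, sB = 0.2, xA = 0.1, xB = 0.1, dA = 0.15, dB = 0.15)
  pr <- mcmc_sample(sim$tree, sim$states, model = "no_sab",
                    generations = 6000, burnin = 1000, seed = 12,
                    prior_means = pm,
                    start = c(pm[1:2], sAB = 0, pm[3:6]),
                    use_likelihood = FALSE)
  got <- colMeans(as.data.frame(pr)[names(pm)])
  expect_equal(unname(got), unname(pm), tolerance = 0.15)
})

test_that("per-area scan skips degenerate codings and flags asymmetry", {
  sp_areas <- c("A", "B", "C")
  set.seed(307)
  tr <- simulate_bd_tree(0.2, 0, n_tips = 40, seed = 308)
  rngs <- tibble::tibble(
    species = tr$tip.label,
    range = sample(c("A", "B", "AB", "C"), 40, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1)))
  # area C harbours only endemic species relative to itself? build the
  # degenerate case explicitly: every species contains C
  rngs_all_c <- tibble::tibble(species = tr$tip.label, range = "C")
  scan_c <- per_area_scan(tr, rngs_all_c, sp_areas, focal_areas = "C")
  expect_match(scan_c$skipped, "only endemic")
  # unoccupied area skipped
  scan_b <- per_area_scan(tr, rngs_all_c, sp_areas, focal_areas = "B")
  expect_match(scan_b$skipped, "unoccupied")
  # two analysable areas give two full rows
  scan <- per_area_scan(tr, rngs, sp_areas, focal_areas = c("A", "B"))
  expect_equal(nrow(scan), 2)
  expect_true(all(is.na(scan$skipped)))
  expect_true(all(c("sA_full", "sA_nosab", "lrt_p", "d_in_gt_d_out") %in%
                    names(scan)))
})

test_that("inward-biased dispersal is recovered as dB > dA", {
  # focal-area coding of a GeoSSE simulation with dB >> dA
  hits <- 0
  for (rep in 1:5) {
    sim <- simulate_geosse(geo_pars(dA = 0.02, dB = 0.3, sAB = 0),
                           n_tips = 150, seed = 330 + rep)
    fit <- fit_geosse_ml(sim$tree, sim$states, constraint = "no_sab")
    hits <- hits + (fit$pars[["dB"]] > fit$pars[["dA"]])
  }
  expect_gte(hits, 4)
})
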