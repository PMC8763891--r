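test_that("rating statistic: degenerate, field value and monotonicity", {
  expect_equal(rating_statistic(1, 1), 1)
  # Mn near-field parameters: X95 = 1.38 * 1.97^1.645
  expect_equal(rating_statistic(1.38, 1.97), 4.21, tolerance = 1e-3)
  # 42x the Mn OEL: the point estimate sits in the top band
  expect_equal(band_of(rating_statistic(1.38, 1.97), 0.1), 4L)
  gsds <- seq(1, 4, by = 0.25)
  expect_true(all(diff(rating_statistic(1, gsds)) > 0))
  expect_error(rating_statistic(-1, 2), "gm")
  expect_error(rating_statistic(1, 0.5), "gsd")
})

test_that("band edges are inclusive on the upper side", {
  oel <- 1
  expect_equal(band_of(0.004, oel), 0L)
  expect_equal(band_of(0.005, oel), 0L)   # <= 0.005 OEL closes ER0
  expect_equal(band_of(0.0051, oel), 1L)
  expect_equal(band_of(0.05, oel), 1L)
  expect_equal(band_of(0.25, oel), 2L)
  expect_equal(band_of(0.5, oel), 3L)     # <= 0.5 OEL closes ER3
  expect_equal(band_of(0.6, oel), 4L)
  expect_error(band_of(0.1, -1), "oel")
})

test_that("rating scheme validates its configuration", {
  expect_error(rating_scheme(oels = c(Cr = -1)), "positive")
  expect_error(rating_scheme(band_edges = c(0.05, 0.005, 0.25, 0.5)),
               "increasing")
  expect_error(rating_scheme(control_labels = c("a", "b")), "5")
  sch <- rating_scheme()
  expect_equal(sch$action_level_fraction, 0.5)
  expect_equal(length(sch$band_edges), 4)
})

test_that("grid log-likelihood peaks at the normal MLE on the log scale", {
  grid <- param_grid(1, n_gm = 801, n_gsd = 401)
  st <- list(gm = 0.4, gsd = 2, n = 20)
  ll <- grid_loglik(st, grid)
  i <- which.max(ll)
  expect_equal(grid$mu[i], log(0.4), tolerance = 0.01)
  expect_equal(grid$sigma[i], log(2) * sqrt(19 / 20), tolerance = 0.01)
})

test_that("doubling every observation shifts the location only", {
  grid <- param_grid(1)
  st <- list(gm = 0.2, gsd = 1.8, n = 15)
  st2 <- list(gm = 0.4, gsd = 1.8, n = 15)
  ll1 <- grid_loglik(st, grid)
  ll2 <- grid_loglik(st2, grid)
  # profile over sigma is unchanged: max over mu at each sigma is equal
  m1 <- tapply(ll1, grid$sigma, max)
  m2 <- tapply(ll2, grid$sigma, max)
  expect_equal(unname(m1), unname(m2), tolerance = 1e-3)
  # argmax mu moves by ~ln 2 (within one grid step)
  mu_step <- diff(sort(unique(grid$mu))[1:2])
  expect_lt(abs((grid$mu[which.max(ll2)] - grid$mu[which.max(ll1)]) -
                  log(2)), mu_step + 1e-12)
})

test_that("sufficient-statistic likelihood equals the per-observation sum", {
  set.seed(41)
  x <- rlnorm(25, log(0.3), log(1.9))
  s <- lognormal_summary(x)
  st <- list(gm = unname(s["gm"]), gsd = unname(s["gsd"]), n = length(x))
  grid <- param_grid(1, n_gm = 41, n_gsd = 21)
  ll <- grid_loglik(st, grid)
  raw <- vapply(seq_along(grid$mu), function(i) {
    -length(x) * log(grid$sigma[i]) -
      sum((log(x) - grid$mu[i])^2) / (2 * grid$sigma[i]^2)
  }, numeric(1))
  expect_lt(max(abs(ll - raw)) / max(abs(raw)), 1e-9)
})

test_that("prior encodings: uniform mode and large-n concentration", {
  grid <- param_grid(1)
  u <- prior_from_dataset(list(gm = 1, gsd = 2, n = 5), grid,
                          mode = "uniform")
  expect_true(all(abs(u$weights - 1 / length(u$mu)) < 1e-15))
  big <- prior_from_dataset(list(gm = 0.1, gsd = 1.5, n = 1e6), grid)
  expect_gt(max(big$weights), 0.2)  # mass collapses onto few nodes
  deg <- prior_from_dataset(list(gm = 0.1, gsd = 1, n = 25), grid)
  expect_true(attr(deg, "degenerate_gsd"))
  expect_equal(sum(deg$weights), 1, tolerance = 1e-12)
})

test_that("decision charts are normalized and localize a point mass", {
  grid <- param_grid(1)
  # point mass at the node whose X95 is closest to 0.3 * OEL
  stat <- exp(grid$mu + 1.645 * grid$sigma)
  j <- which.min(abs(stat - 0.3))
  grid$weights <- rep(0, length(grid$mu)); grid$weights[j] <- 1
  ch <- decision_chart(grid, 1)
  expect_equal(unname(ch$p), c(0, 0, 0, 1, 0))
  expect_equal(ch$dominant_band, 3L)
  expect_equal(ch$p_exceed_action, 0)
  expect_equal(sum(ch$p), 1, tolerance = 1e-9)
  expect_equal(ch$recommended_control,
               "exposure surveillance/medical surveillance/work practices")
})

test_that("flat prior makes the posterior equal the likelihood chart", {
  grid <- param_grid(0.5)
  pri <- prior_from_dataset(NULL, grid, mode = "uniform")
  trio <- posterior_chart(pri, list(gm = 0.064, gsd = 2.68, n = 18), 0.5)
  expect_equal(unname(trio$posterior$p), unname(trio$likelihood$p),
               tolerance = 1e-12)
})

test_that("overwhelming field data dominates the prior", {
  grid <- param_grid(1)
  pri <- prior_from_dataset(list(gm = 0.01, gsd = 1.2, n = 25), grid)
  st_big <- list(gm = 0.3, gsd = 1.5, n = 1e5)
  trio <- posterior_chart(pri, st_big, 1)
  expect_equal(unname(trio$posterior$p), unname(trio$likelihood$p),
               tolerance = 0.01)
})

test_that("sequential updating matches pooled sufficient statistics", {
  grid <- param_grid(1)
  pri <- prior_from_dataset(list(gm = 0.1, gsd = 1.5, n = 10), grid)
  d1 <- list(gm = 0.2, gsd = 1.8, n = 12)
  d2 <- list(gm = 0.15, gsd = 2.2, n = 8)
  step1 <- posterior_chart(pri, d1, 1)
  g1 <- attr(step1, "posterior_grid")
  step2 <- posterior_chart(g1, d2, 1)
  pooled <- posterior_chart(pri, pool_stats(d1, d2), 1)
  expect_equal(unname(step2$posterior$p), unname(pooled$posterior$p),
               tolerance = 1e-9)
})

test_that("pooled statistics reproduce a direct pooled-sample summary", {
  set.seed(43)
  x1 <- rlnorm(12, log(0.2), log(1.8))
  x2 <- rlnorm(8, log(0.15), log(2.2))
  s1 <- lognormal_summary(x1); s2 <- lognormal_summary(x2)
  pooled <- pool_stats(list(gm = s1[["gm"]], gsd = s1[["gsd"]], n = 12),
                       list(gm = s2[["gm"]], gsd = s2[["gsd"]], n = 8))
  direct <- lognormal_summary(c(x1, x2))
  expect_equal(pooled$gm, unname(direct["gm"]), tolerance = 1e-12)
  expect_equal(pooled$gsd, unname(direct["gsd"]), tolerance = 1e-12)
  expect_equal(pooled$n, 20)
})

test_that("posterior top-band mass is monotone in the field GM", {
  grid <- param_grid(1)
  pri <- prior_from_dataset(list(gm = 0.1, gsd = 1.5, n = 25), grid)
  p4 <- sapply(c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6), function(gm) {
    posterior_chart(pri, list(gm = gm, gsd = 2, n = 18),
                    1)$posterior$p[["ER4"]]
  })
  # exact in the continuum; the discrete grid mixing over sigma can
  # introduce sub-1e-4 wobble at the flat low end
  expect_true(all(diff(p4) >= -1e-4))
  expect_gt(tail(p4, 1), 0.99)
  expect_lt(p4[1], 0.01)
})

test_that("doubling the grid resolution barely moves the charts", {
  st3 <- list(gm = 6.13, gsd = 1.35, n = 25)
  st4 <- list(gm = 5.31, gsd = 1.93, n = 18)
  coarse <- posterior_chart(prior_from_dataset(st3, param_grid(10)),
                            st4, 10)
  fine <- posterior_chart(
    prior_from_dataset(st3, param_grid(10, n_gm = 801, n_gsd = 401)),
    st4, 10)
  for (role in c("prior", "likelihood", "posterior")) {
    expect_lt(max(abs(coarse[[role]]$p - fine[[role]]$p)), 0.005)
  }
})

test_that("the predicted Fe near-field prior concentrates above ER3", {
  pred <- wf_predicted()
  fe <- pred[pred$metal == "Fe" & pred$zone == "NF", ]
  pri <- prior_from_dataset(as.list(fe[, c("gm", "gsd", "n")]),
                            param_grid(10))
  ch <- decision_chart(pri, 10, role = "prior")
  expect_gte(sum(ch$p[c("ER3", "ER4")]), 0.95)
  expect_true(ch$dominant_band %in% 3:4)
})

test_that("category encoding multiplies band probabilities", {
  pred <- list(gm = 0.05, gsd = 1.6, n = 25)
  fld <- list(gm = 0.08, gsd = 1.9, n = 18)
  grid <- param_grid(1)
  pri <- prior_from_dataset(pred, grid)
  trio <- posterior_chart(pri, fld, 1, encoding = "category")
  manual <- trio$prior$p * trio$likelihood$p
  manual <- manual / sum(manual)
  expect_equal(unname(trio$posterior$p), unname(manual), tolerance = 1e-12)
  expect_equal(sum(trio$posterior$p), 1, tolerance = 1e-9)
})

test_that("grid aggregation agrees with the sampling oracle", {
  grid <- param_grid(0.5)
  pri <- prior_from_dataset(list(gm = 0.02, gsd = 1.9, n = 25), grid)
  trio <- posterior_chart(pri, list(gm = 0.064, gsd = 2.68, n = 18), 0.5)
  pg <- attr(trio, "posterior_grid")
  mc <- sample_chart(pg, 0.5, n_draw = 2e5, seed = 51)
  expect_lt(max(abs(mc - trio$posterior$p)), 0.02)
})
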