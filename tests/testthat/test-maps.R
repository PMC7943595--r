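test_that("single-context calibration saturates to the observed proportion", {
  v <- make_variants(n = 100, singleton = rep(c(TRUE, FALSE), c(30, 70)))
  model <- maps_fit(v, make_rates())
  expect_equal(unname(predict(model, "ACG:C>T")), 0.30)
  expect_equal(model$contexts$n, 100)
})

test_that("equal-rate contexts share a common fitted proportion", {
  rates <- make_rates(c("ACG:C>T" = 1e-8, "AAA:A>G" = 1e-8))
  v <- rbind(make_variants(100, "ACG:C>T",
                           singleton = rep(c(TRUE, FALSE), c(20, 80))),
             make_variants(100, "AAA:A>G",
                           singleton = rep(c(TRUE, FALSE), c(40, 60))))
  model <- maps_fit(v, rates)
  expect_equal(unname(predict(model, c("ACG:C>T", "AAA:A>G"))),
               c(0.30, 0.30))
})

test_that("calibration recovers the generating intercept and slope", {
  # per-context singleton proportion generated as p = 0.1 + 5e6 * mu
  set.seed(101)
  keys <- paste0(c("ACA", "ACC", "ACG", "ACT", "AAA", "CAC", "GAT", "TCT"),
                 ":", c(rep("C", 4), "A", "A", "A", "C"), ">",
                 c("T", "T", "T", "T", "G", "G", "C", "G"))
  mu <- seq(2e-9, 9e-8, length.out = length(keys))
  rates <- make_rates(stats::setNames(mu, keys))
  a_true <- 0.1; b_true <- 5e6
  vs <- lapply(seq_along(keys), function(i) {
    n <- 800
    p <- a_true + b_true * mu[i]
    make_variants(n, keys[i], singleton = runif(n) < p)
  })
  model <- maps_fit(do.call(rbind, vs), rates)
  fit <- stats::lm(proportion ~ mu, data = model$contexts,
                   weights = model$contexts$n)
  se <- sqrt(diag(stats::vcov(fit)))
  expect_lt(abs(coef(model)["intercept"] - a_true), 2 * se[1])
  expect_lt(abs(coef(model)["slope"] - b_true), 2 * se[2])
})

test_that("maps_fit errors when a context has no rate", {
  v <- make_variants(10, "CCC:C>G")
  expect_error(maps_fit(v, make_rates()), "CCC:C>G")
})

test_that("maps score is (observed - expected) / n", {
  # single context fitted at 0.4; class with 6 singletons of 10 -> 0.2
  calib <- make_variants(100, singleton = rep(c(TRUE, FALSE), c(40, 60)))
  model <- maps_fit(calib, make_rates())
  class_v <- make_variants(10, singleton = rep(c(TRUE, FALSE), c(6, 4)))
  res <- maps_score(class_v, model)
  expect_equal(res$expected_singletons, 4.0)
  expect_equal(res$maps, 0.2)
  expect_error(maps_score(class_v[0, ], model), "no variants")
})

test_that("the training class scores 0 (weighted-residual identity)", {
  set.seed(7)
  keys <- c("ACG:C>T", "AAA:A>G", "TCT:C>G", "GAT:A>C")
  rates <- make_rates(stats::setNames(c(1e-8, 3e-8, 6e-8, 9e-8), keys))
  v <- do.call(rbind, lapply(seq_along(keys), function(i)
    make_variants(200, keys[i], singleton = runif(200) < 0.3 + i / 20)))
  model <- maps_fit(v, rates)
  expect_lt(abs(maps_score(v, model)$maps), 1e-9)
})

test_that("maps score respects its algebraic bounds", {
  set.seed(8)
  keys <- c("ACG:C>T", "AAA:A>G")
  rates <- make_rates(stats::setNames(c(1e-8, 5e-8), keys))
  calib <- do.call(rbind, lapply(keys, function(k)
    make_variants(300, k, singleton = runif(300) < 0.4)))
  model <- maps_fit(calib, rates)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    v <- make_variants(n, sample(keys, 1), singleton = runif(n) < runif(1))
    res <- maps_score(v, model)
    expect_gte(res$maps, -res$expected_singletons / res$n)
    expect_lte(res$maps, 1 - res$expected_singletons / res$n)
  }
})

test_that("bootstrap CI: degenerate width, determinism, small-n oracle", {
  calib <- make_variants(100, singleton = rep(c(TRUE, FALSE), c(40, 60)))
  model <- maps_fit(calib, make_rates())
  # identical variants -> zero-width interval
  const <- make_variants(20, singleton = rep(TRUE, 20))
  ci <- bootstrap_maps(const, model, n_iter = 200, seed = 1)
  expect_equal(ci[1], ci[2])
  # fixed seed -> identical interval
  cls <- make_variants(30, singleton = rep(c(TRUE, FALSE), 15))
  expect_identical(bootstrap_maps(cls, model, n_iter = 500, seed = 42),
                   bootstrap_maps(cls, model, n_iter = 500, seed = 42))
  # n = 5: exhaustive multinomial resample oracle for the percentiles
  v5 <- make_variants(5, singleton = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  contrib <- as.numeric(v5$singleton) - 0.4
  grid <- expand.grid(rep(list(1:5), 5))
  exact <- sort(apply(grid, 1, function(idx) mean(contrib[idx])))
  oracle_ci <- quantile(exact, c(0.05, 0.95), names = FALSE)
  ci5 <- bootstrap_maps(v5, model, n_iter = 1e5, seed = 9)
  expect_lt(max(abs(ci5 - oracle_ci)), 0.05)
})

test_that("maps p-values: symmetry at the null, floor under separation", {
  calib <- make_variants(200, singleton = rep(c(TRUE, FALSE), 100))
  model <- maps_fit(calib, make_rates())
  cls <- make_variants(300, singleton = rep(c(TRUE, FALSE), 150))
  p_same <- maps_pvalue(cls, cls, model, n_iter = 2000, seed = 3)
  expect_gt(p_same, 0.3)
  expect_lt(p_same, 0.7)
  # complete separation attains the 1/(n_iter+1) floor
  a <- make_variants(100, singleton = rep(TRUE, 100))
  b <- make_variants(100, singleton = rep(FALSE, 100))
  expect_equal(maps_pvalue(a, b, model, n_iter = 999, seed = 4), 1 / 1000)
  expect_error(maps_pvalue(a[0, ], b, model), "non-empty")
})

test_that("context matching reproduces the target histogram exactly", {
  set.seed(11)
  keys <- c("ACG:C>T", "AAA:A>G", "TCT:C>G")
  target <- do.call(rbind, lapply(keys, function(k)
    make_variants(sample(3:12, 1), k)))
  pool <- do.call(rbind, lapply(keys, function(k) make_variants(50, k)))
  for (rep in 1:5) {
    ctrl <- match_by_context(target, pool)
    expect_identical(table(ctrl$context), table(target$context))
  }
  # single-context pool == target context: a plain size-n sample
  t1 <- make_variants(8)
  ctrl1 <- match_by_context(t1, make_variants(100))
  expect_equal(nrow(ctrl1), 8)
  # empty target -> empty control; unmatched context -> error
  expect_equal(nrow(match_by_context(t1[0, ], pool)), 0)
  expect_error(match_by_context(make_variants(3, "CCC:C>G"), pool),
               "CCC:C>G")
  # thin pool: with-replacement fallback warns
  expect_warning(match_by_context(make_variants(10), make_variants(2)),
                 "replacement")
})

test_that("injected singleton excess is recovered monotonically", {
  # deltas on top of a two-context baseline; estimates ordered in delta
  # and close to truth at n = 2000 per class
  set.seed(21)
  keys <- c("ACG:C>T", "AAA:A>G")
  rates <- make_rates(stats::setNames(c(1e-8, 6e-8), keys))
  base <- c(0.35, 0.45)
  calib <- do.call(rbind, lapply(1:2, function(i)
    make_variants(5000, keys[i], singleton = runif(5000) < base[i])))
  model <- maps_fit(calib, rates)
  deltas <- c(0, 0.05, 0.1)
  est <- vapply(deltas, function(d) {
    v <- do.call(rbind, lapply(1:2, function(i)
      make_variants(1000, keys[i], singleton = runif(1000) < base[i] + d)))
    maps_score(v, model)$maps
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(max(abs(est - deltas)), 0.04)
})
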