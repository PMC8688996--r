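test_that("normalization z-scores with sample SD and drops constants", {
  x <- tibble::tibble(a = c(1, 2, 3), b = c(-1, 0, 1) / sd(c(-1, 0, 1)))
  z <- normalize_features(x)
  expect_equal(z$a, c(-1, 0, 1))
  expect_equal(z$b, x$b, tolerance = 1e-12)

  expect_warning(z2 <- normalize_features(cbind(x, k = 5)), "constant")
  expect_named(z2, c("a", "b"))
})

test_that("VIF filtering removes planted collinearity and spares orthogonal designs", {
  set.seed(1)
  n <- 60
  base <- rnorm(n)
  dup <- tibble::tibble(x1 = base, x2 = base, x3 = rnorm(n))
  out <- vif_filter(dup)
  expect_equal(nrow(out$removed), 1L)
  expect_true(out$removed$name %in% c("x1", "x2"))

  ortho <- tibble::as_tibble(as.data.frame(qr.Q(qr(matrix(rnorm(n * 5), n, 5)))))
  out2 <- vif_filter(ortho)
  expect_equal(nrow(out2$removed), 0L)
  expect_equal(ncol(out2$x), 5L)

  # x3 = x1 + x2 + tiny noise among 10 columns: exactly one of the triplet goes
  x <- matrix(rnorm(n * 10), n, 10)
  colnames(x) <- paste0("v", 1:10)
  x[, 3] <- x[, 1] + x[, 2] + rnorm(n, 0, 1e-3)
  out3 <- vif_filter(tibble::as_tibble(as.data.frame(x)))
  expect_equal(nrow(out3$removed), 1L)
  expect_true(out3$removed$name %in% c("v1", "v2", "v3"))

  # passthrough with fewer than two columns
  one <- tibble::tibble(a = rnorm(5))
  expect_identical(vif_filter(one)$x, one)
})

test_that("LASSO selection finds a planted predictor with full weight", {
  set.seed(2)
  n <- 76
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 11), n, 11)))
  names(x) <- paste0("v", 1:11)
  y <- 2 * x$v1
  sel <- lasso_select(x, y)
  expect_equal(sum(sel$weights$weight_pct), 100, tolerance = 1e-6)
  expect_identical(sel$weights$name[1], "v1")
  expect_gt(sel$weights$weight_pct[1], 95)
  expect_true("v1" %in% sel$selected)
})

test_that("LASSO selection stays sparse under a pure-noise response", {
  n_spurious <- vapply(1:100, function(s) {
    set.seed(s)
    x <- tibble::as_tibble(as.data.frame(matrix(rnorm(76 * 20), 76, 20)))
    y <- rnorm(76)
    sel <- suppressWarnings(lasso_select(x, y))
    length(sel$selected)
  }, numeric(1))
  expect_gte(mean(n_spurious <= 2), 0.9)
})

test_that("symmetric planted coefficients share the weight evenly", {
  set.seed(3)
  n <- 200
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 8), n, 8)))
  names(x) <- paste0("v", 1:8)
  y <- x$v1 + x$v2 + rnorm(n, 0, 0.3)
  sel <- lasso_select(x, y)
  w <- sel$weights
  expect_setequal(w$name[w$selected], c("v1", "v2"))
  expect_lt(max(abs(w$weight_pct[w$selected] - 50)), 10)
})

test_that("category contributions sum the selected members per category", {
  set.seed(4)
  n <- 120
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6), n, 6)))
  names(x) <- paste0("v", 1:6)
  y <- x$v1 + x$v2 + 0.8 * x$v3 + rnorm(n, 0, 0.2)
  cats <- c(v1 = "propulsion", v2 = "posture", v3 = "posture",
            v4 = "efficiency", v5 = "duration_rate", v6 = "duration_rate")
  sel <- lasso_select(x, y, categories = cats)
  cc <- sel$category_contrib
  expect_equal(sum(cc$weight_pct_renorm), 100, tolerance = 1e-9)
  sel_w <- sel$weights[sel$weights$selected, ]
  for (k in seq_len(nrow(cc))) {
    expect_equal(cc$weight_pct[k],
                 sum(sel_w$weight_pct[sel_w$category == cc$category[k]]))
  }
})

test_that("over-penalized solutions fall back with a warning", {
  set.seed(5)
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(30 * 5), 30, 5)))
  y <- rnorm(30, 0, 1e-4) + 1e-4 * x[[1]]
  sel <- tryCatch(withCallingHandlers(
    lasso_select(x, y),
    warning = function(w) {
      expect_match(conditionMessage(w), "penalty|fold", ignore.case = TRUE)
      invokeRestart("muffleWarning")
    }), error = function(e) NULL)
  if (!is.null(sel)) expect_gte(length(sel$weights$name), 1)
})

test_that("LOO-CV reproduces a noise-free linear model and rejects pure noise", {
  set.seed(6)
  n <- 40
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 4), n, 4)))
  names(x) <- paste0("v", 1:4)
  y <- 1.5 * x$v1 - 2 * x$v2
  rep1 <- fit_evaluate_loocv(x, y, target = "exact")
  expect_gte(rep1$r2, 0.999)
  expect_lt(rep1$rmse, 0.05)

  r2_noise <- vapply(1:10, function(s) {
    set.seed(100 + s)
    xn <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 4), 40, 4)))
    yn <- rnorm(40)
    suppressWarnings(fit_evaluate_loocv(xn, yn, lambda = "fixed")$r2)
  }, numeric(1))
  expect_lt(mean(r2_noise), 0.05)
})

test_that("LOO-CV recovers the planted determination coefficient", {
  # theoretical R^2 = 5 / (5 + sigma^2) = 0.85 with 5 unit coefficients
  sig <- sqrt(5 * 0.15 / 0.85)
  r2 <- vapply(1:10, function(s) {
    d <- simulate_feature_goal_dataset(n = 76, p = 30, support_size = 5,
                                       coefs = 1, noise_sd = sig, seed = s)
    fit_evaluate_loocv(d$x[d$support], d$y, lambda = "fixed")$r2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.85), 0.08)
})

test_that("relative RMSE is undefined for a centred response", {
  set.seed(8)
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(120), 30, 4)))
  y <- x[[1]] - mean(x[[1]])
  expect_warning(r <- fit_evaluate_loocv(x, y, lambda = "fixed"), "zero")
  expect_true(is.nan(r$rel_rmse))
})

test_that("design assembly scopes candidate variables by target phase", {
  feats <- tibble::tibble(
    lap_id = 1:12,
    `Push.Mean(AccY)` = rnorm(12), `Glid.Duration` = rnorm(12),
    `StPr.KickRate` = rnorm(12), `Swim.StrokeRate` = rnorm(12))
  goals <- tibble::tibble(lap_id = 1:12, t5m = rnorm(12), lap_vavg = rnorm(12),
                          push_vmax = rnorm(12))
  d5 <- assemble_design(feats, goals, "t5m")
  expect_setequal(names(d5$x), c("Push.Mean(AccY)", "Glid.Duration"))
  dl <- assemble_design(feats, goals, "lap_vavg")
  expect_equal(ncol(dl$x), 4L)
  dp <- assemble_design(feats, goals, "push_vmax")
  expect_named(dp$x, "Push.Mean(AccY)")
  expect_error(assemble_design(feats, goals, "unknown_target"), "unknown")

  cyc_feats <- tibble::tibble(lap_id = rep(1:4, each = 250),
                              cycle = rep(1:250, 4),
                              `Cycle.Duration` = rnorm(1000),
                              `Cycle.DPS` = rnorm(1000))
  cyc_goals <- tibble::tibble(lap_id = rep(1:4, each = 250),
                              cycle = rep(1:250, 4), v_avg = rnorm(1000))
  dc <- assemble_design(cyc_feats, cyc_goals, "swim_vavg_cycle")
  expect_equal(nrow(dc$x), 1000L)
  expect_setequal(names(dc$x), c("Cycle.Duration", "Cycle.DPS"))
})

test_that("tidy and glance methods expose the fitted objects", {
  set.seed(9)
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm(76 * 6), 76, 6)))
  names(x) <- paste0("v", 1:6)
  y <- x$v1 + rnorm(76, 0, 0.4)
  sel <- lasso_select(x, y)
  expect_named(tidy(sel), c("name", "weight_pct", "category", "selected"))
  expect_equal(glance(sel)$n_candidates, nrow(tidy(sel)))
  reg <- fit_evaluate_loocv(x, y, target = "demo", lambda = "fixed")
  expect_named(glance(reg), c("target", "n_obs", "r2", "rmse", "rel_rmse"))
  expect_equal(nrow(tidy(reg)), 76)
})
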