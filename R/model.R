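# Association between micro-variables and goal metrics:
# z-scoring, iterative VIF multicollinearity removal, LASSO variable
# selection with relative weights and category contributions, and
# leave-one-out cross-validated LASSO regression.

#' Z-score the feature columns
#'
#' Each numeric column is centred and scaled to unit sample standard
#' deviation; constant columns are dropped with a warning.
#'
#' @param x A tibble or data frame of numeric features.
#' @return A tibble with the same (surviving) columns.
#' @export
normalize_features <- function(x) {
  x <- tibble::as_tibble(x)
  sds <- vapply(x, stats::sd, numeric(1))
  const <- sds < 1e-12 | is.na(sds)
  if (any(const)) {
    warning("dropping constant column(s): ", paste(names(x)[const], collapse = ", "))
    x <- x[!const]
    sds <- sds[!const]
  }
  mus <- vapply(x, mean, numeric(1))
  tibble::as_tibble(purrr::map2(x, seq_along(x), function(col, j) (col - mus[j]) / sds[j]))
}

vif_values <- function(xm) {
  p <- ncol(xm)
  vapply(seq_len(p), function(j) {
    y <- xm[, j]
    tss <- sum((y - mean(y))^2)
    if (tss < 1e-24) return(Inf)
    fit <- stats::.lm.fit(cbind(1, xm[, -j, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor filtering
#'
#' Repeatedly removes the column with the largest VIF (`1 / (1 - R^2)` of
#' that column regressed on the others) until all VIFs are below `threshold`.
#' Ties are broken by column order (first wins). With fewer than two columns
#' the input is passed through.
#'
#' @param x Tibble/data frame of numeric features (typically z-scored).
#' @param threshold VIF threshold, default 10.
#' @return A list with `x` (reduced tibble) and `removed`
#'   (tibble `name`, `vif` in removal order).
#' @export
vif_filter <- function(x, threshold = 10) {
  x <- tibble::as_tibble(x)
  removed <- tibble::tibble(name = character(), vif = numeric())
  if (ncol(x) < 2L) return(list(x = x, removed = removed))
  xm <- as.matrix(x)
  repeat {
    if (ncol(xm) < 2L) break
    v <- vif_values(xm)
    if (max(v) < threshold) break
    j <- which.max(v) # which.max takes the first maximum: ties by column order
    removed <- dplyr::bind_rows(removed,
                                tibble::tibble(name = colnames(xm)[j], vif = v[j]))
    xm <- xm[, -j, drop = FALSE]
  }
  list(x = tibble::as_tibble(as.data.frame(xm)), removed = removed)
}

# explicit 100-value log-spaced penalty grid; glmnet's adaptive path can
# stop early on near-perfect fits, biasing the refits
lambda_path <- function(xm, y, nlambda = 100, ratio = 1e-6) {
  n <- nrow(xm)
  lmax <- max(abs(crossprod(xm, y - mean(y)))) / n
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

coef_at <- function(fit, s) {
  b <- as.numeric(glmnet::coef.glmnet(fit, s = s))[-1]
  b[abs(b) < 1e-10] <- 0
  b
}

#' LASSO variable selection with relative weights
#'
#' Fits a LASSO path (100 log-spaced penalties) with the penalty chosen by
#' 10-fold cross-validation (`lambda.1se`, the parsimonious standard for
#' selection). Each variable's relative weight is its share of the summed
#' absolute coefficients, in percent; variables with weight below
#' `weight_cutoff` (default 5%) are neglected. Category contributions are the
#' sums of the selected members' weights per category, reported both raw and
#' renormalized to 100%.
#'
#' If the chosen penalty zeroes every coefficient, the largest penalty with
#' at least one nonzero coefficient is used instead, with a warning.
#'
#' @param x Standardized feature tibble/matrix (n x p, p >= 2).
#' @param y Response vector.
#' @param categories Named character vector mapping variable names to
#'   categories (e.g. from [micro_variable_catalogue()]); unknown variables
#'   get category `"other"`.
#' @param weight_cutoff Relative-weight cutoff in percent, default 5.
#' @param nfolds CV folds, default 10 (capped at n).
#' @param lambda_rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @return An object of class `swim_selection`.
#' @export
lasso_select <- function(x, y, categories = NULL, weight_cutoff = 5,
                         nfolds = 10, lambda_rule = c("lambda.1se", "lambda.min")) {
  lambda_rule <- match.arg(lambda_rule)
  xm <- as.matrix(x)
  stopifnot(nrow(xm) == length(y), ncol(xm) >= 2L)
  nfolds <- min(nfolds, nrow(xm))
  cv <- glmnet::cv.glmnet(xm, y, alpha = 1, lambda = lambda_path(xm, y),
                          standardize = FALSE, nfolds = nfolds)
  lambda <- cv[[lambda_rule]]
  beta <- coef_at(cv$glmnet.fit, lambda)
  if (all(beta == 0)) {
    nz <- cv$glmnet.fit$df > 0
    if (!any(nz)) stop("LASSO path is empty; response may be constant")
    lambda <- max(cv$glmnet.fit$lambda[nz])
    beta <- coef_at(cv$glmnet.fit, lambda)
    warning("cross-validated penalty zeroed all coefficients; ",
            "falling back to the largest penalty with a nonzero coefficient")
  }
  w <- 100 * abs(beta) / sum(abs(beta))
  cat_of <- function(nm) {
    if (is.null(categories)) return("other")
    out <- unname(categories[nm])
    out[is.na(out)] <- "other"
    out
  }
  weights <- tibble::tibble(
    name = colnames(xm), weight_pct = w, category = cat_of(colnames(xm)),
    selected = w >= weight_cutoff
  ) |>
    dplyr::filter(.data$weight_pct > 0) |>
    dplyr::arrange(dplyr::desc(.data$weight_pct))
  sel <- weights[weights$selected, ]
  contrib <- sel |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(weight_pct = sum(.data$weight_pct), .groups = "drop") |>
    dplyr::mutate(weight_pct_renorm = 100 * .data$weight_pct / sum(.data$weight_pct))
  structure(list(weights = weights, selected = sel$name,
                 category_contrib = contrib, lambda = lambda,
                 lambda_rule = lambda_rule, weight_cutoff = weight_cutoff),
            class = "swim_selection")
}

#' @method print swim_selection
#' @export
print.swim_selection <- function(x, ...) {
  cat(sprintf("<swim_selection: %d of %d variables >= %g%% (lambda = %.4g)>\n",
              length(x$selected), nrow(x$weights), x$weight_cutoff, x$lambda))
  print(x$weights, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.swim_selection <- function(x, ...) x$weights

#' @importFrom generics glance
#' @export
glance.swim_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected), n_candidates = nrow(x$weights),
                 lambda = x$lambda, weight_cutoff = x$weight_cutoff)
}

loo_fit_predict <- function(xm, y, i, lambda_mode, fixed_lambda, nfolds) {
  xtr <- xm[-i, , drop = FALSE]; ytr <- y[-i]
  if (ncol(xm) == 1L) {
    # glmnet needs >= 2 predictors; single-predictor models use OLS
    fit <- stats::lm.fit(cbind(1, xtr), ytr)
    return(sum(c(1, xm[i, ]) * fit$coefficients))
  }
  path <- lambda_path(xtr, ytr)
  if (lambda_mode == "nested") {
    cv <- glmnet::cv.glmnet(xtr, ytr, alpha = 1, standardize = FALSE,
                            lambda = path, nfolds = min(nfolds, nrow(xtr)))
    lam <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(xtr, ytr, alpha = 1, standardize = FALSE,
                          lambda = path)
    lam <- fixed_lambda
  }
  as.numeric(glmnet::predict.glmnet(fit, newx = xm[i, , drop = FALSE], s = lam))
}

#' Leave-one-out cross-validated LASSO regression
#'
#' Each observation is predicted by a LASSO model fitted on all others.
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` on the pooled
#' held-out predictions; `RMSE = sqrt(mean((y - yhat)^2))`;
#' `rel_rmse = 100 * RMSE / mean(y)` (NaN with a warning when `mean(y)` is 0).
#'
#' @param x Standardized features (selected variables), n >= 10 rows.
#' @param y Response.
#' @param target Name of the goal metric (carried into the report).
#' @param lambda `"nested"` (default): the penalty is re-chosen by 10-fold CV
#'   inside every leave-one-out fold, avoiding optimistic bias;
#'   `"fixed"`: one full-data CV choice reused across folds (cheaper for
#'   large n, e.g. the per-cycle target).
#' @param nfolds Inner CV folds, default 10.
#' @return An object of class `swim_regression`.
#' @export
fit_evaluate_loocv <- function(x, y, target = "goal_metric",
                               lambda = c("nested", "fixed"), nfolds = 10) {
  lambda <- match.arg(lambda)
  xm <- as.matrix(x)
  n <- nrow(xm)
  if (n < 10L) stop("leave-one-out evaluation needs at least 10 observations")
  stopifnot(length(y) == n)
  fixed_lambda <- NULL
  if (lambda == "fixed" && ncol(xm) >= 2L) {
    cv <- glmnet::cv.glmnet(xm, y, alpha = 1, standardize = FALSE,
                            lambda = lambda_path(xm, y),
                            nfolds = min(nfolds, n))
    fixed_lambda <- cv$lambda.min
  }
  yhat <- vapply(seq_len(n), function(i) {
    loo_fit_predict(xm, y, i, lambda, fixed_lambda, nfolds)
  }, numeric(1))
  sse <- sum((y - yhat)^2)
  rmse <- sqrt(sse / n)
  r2 <- 1 - sse / sum((y - mean(y))^2)
  if (abs(mean(y)) < 1e-12) {
    warning("mean(y) is zero; relative RMSE undefined")
    rel <- NaN
  } else {
    rel <- 100 * rmse / abs(mean(y))
  }
  structure(list(r2 = r2, rmse = rmse, rel_rmse = rel, n_obs = n,
                 target = target, lambda = lambda,
                 predictions = tibble::tibble(obs = seq_len(n), y = y, yhat = yhat)),
            class = "swim_regression")
}

#' @method print swim_regression
#' @export
print.swim_regression <- function(x, ...) {
  cat(sprintf("<swim_regression %s: n = %d, R2 = %.3f, RMSE = %.4g (%.1f%%)>\n",
              x$target, x$n_obs, x$r2, x$rmse, x$rel_rmse))
  invisible(x)
}

#' @export
tidy.swim_regression <- function(x, ...) x$predictions

#' @export
glance.swim_regression <- function(x, ...) {
  tibble::tibble(target = x$target, n_obs = x$n_obs, r2 = x$r2,
                 rmse = x$rmse, rel_rmse = x$rel_rmse)
}

target_phases <- function(target) {
  switch(target,
         push_vmax = "Push",
         glid_vend = "Glid",
         stpr_vavg = "StPr",
         swim_vavg_phase = "Swim",
         t5m = c("Push", "Glid"),
         t15m = c("Push", "Glid", "StPr"),
         lap_vavg = PHASES,
         swim_vavg_cycle = "Cycle",
         stop("unknown target: ", target))
}

#' Assemble the design matrix and response for a goal metric
#'
#' Restricts the candidate micro-variables to the phases relevant to the
#' target: `push_vmax` uses Push variables, `glid_vend` Glid, `stpr_vavg`
#' StPr, `swim_vavg_phase` Swim, `t5m` Push+Glid, `t15m` Push+Glid+StPr,
#' `lap_vavg` all phases, and `swim_vavg_cycle` the per-cycle variables.
#'
#' @param features Lap-level feature tibble including a `lap_id` column (or
#'   the per-cycle table for `swim_vavg_cycle`).
#' @param goals Goal tibble with `lap_id` and the scalar goal columns;
#'   for the per-cycle target, a tibble with `lap_id`, `cycle`, `v_avg`.
#' @param target One of the eight goal-metric names.
#' @return A list with `x` (feature tibble), `y` (response vector) and
#'   `meta` (key columns).
#' @export
assemble_design <- function(features, goals, target) {
  phases <- target_phases(target)
  pat <- paste0("^(", paste(phases, collapse = "|"), ")\\.")
  cols <- grep(pat, names(features), value = TRUE)
  if (length(cols) == 0L) stop("no candidate variables for target ", target)
  if (identical(target, "swim_vavg_cycle")) {
    joined <- dplyr::inner_join(features, goals, by = c("lap_id", "cycle"))
    y <- joined$v_avg
    meta <- joined[intersect(c("lap_id", "cycle", "swimmer", "trial", "pace"),
                             names(joined))]
  } else {
    stopifnot(target %in% names(goals))
    joined <- dplyr::inner_join(features, goals[c("lap_id", target)], by = "lap_id")
    y <- joined[[target]]
    meta <- joined[intersect(c("lap_id", "swimmer", "trial", "pace"), names(joined))]
  }
  list(x = joined[cols], y = y, meta = meta)
}

#' Select variables and evaluate the regression for one goal metric
#'
#' Chains [normalize_features()], [vif_filter()], [lasso_select()] and
#' [fit_evaluate_loocv()] on the selected variables.
#'
#' @param features Feature tibble with `lap_id` (lap level, or cycle level
#'   for the per-cycle target).
#' @param goals Goal tibble (see [assemble_design()]).
#' @param target Goal-metric name.
#' @param vif_threshold VIF threshold, default 10.
#' @param categories Named category map; defaults to the built-in catalogues.
#' @param loo_lambda `"nested"` or `"fixed"` (see [fit_evaluate_loocv()]).
#' @param weight_cutoff Relative-weight cutoff (%), default 5.
#' @return A list of class `swim_target_report` with elements `target`,
#'   `selection`, `regression`, `removed_vif`.
#' @export
estimate_goal_metric <- function(features, goals, target, vif_threshold = 10,
                                 categories = NULL,
                                 loo_lambda = c("nested", "fixed"),
                                 weight_cutoff = 5) {
  loo_lambda <- match.arg(loo_lambda)
  if (is.null(categories)) {
    cat_tbl <- dplyr::bind_rows(
      micro_variable_catalogue()[c("name", "category")],
      cycle_variable_catalogue()
    )
    categories <- stats::setNames(cat_tbl$category, cat_tbl$name)
  }
  des <- assemble_design(features, goals, target)
  xz <- suppressWarnings(normalize_features(des$x))
  vf <- vif_filter(xz, threshold = vif_threshold)
  sel <- lasso_select(vf$x, des$y, categories = categories,
                      weight_cutoff = weight_cutoff)
  x_sel <- vf$x[sel$selected]
  if (ncol(x_sel) == 0L) x_sel <- vf$x[sel$weights$name[1]]
  reg <- fit_evaluate_loocv(x_sel, des$y, target = target, lambda = loo_lambda)
  structure(list(target = target, selection = sel, regression = reg,
                 removed_vif = vf$removed, n_candidates = ncol(xz)),
            class = "swim_target_report")
}

#' @method print swim_target_report
#' @export
print.swim_target_report <- function(x, ...) {
  cat(sprintf("== %s ==\n", x$target))
  print(x$selection)
  print(x$regression)
  invisible(x)
}

#' Write a target report to JSON
#'
#' @param report A `swim_target_report`.
#' @param path JSON path.
#' @export
write_target_report_json <- function(report, path) {
  sel <- report$selection
  obj <- list(
    target = report$target,
    n_obs = report$regression$n_obs,
    selected = purrr::pmap(
      sel$weights[sel$weights$selected, c("name", "weight_pct", "category")],
      function(name, weight_pct, category) {
        list(name = name, weight_pct = weight_pct, category = category)
      }),
    category_contrib = sel$category_contrib,
    lambda = sel$lambda,
    r2 = report$regression$r2,
    rmse = report$regression$rmse,
    rel_rmse = report$regression$rel_rmse
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
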