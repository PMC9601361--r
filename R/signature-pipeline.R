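# Three-stage feature selection and logistic rad-score models:
#   ICC(2,1) reproducibility filter (> 0.8, two readers)
#   -> Welch two-sample t-test (p < 0.1)
#   -> L1-penalized logistic regression, lambda by 10-fold CV deviance
#   -> backward stepwise elimination under AIC
#   -> unpenalized logistic fit; rad-score = linear predictor.
# Selection always uses training rows only; survivor lists are nested.

#' Temporal cohort split
#'
#' Splits a cohort ordered by acquisition index into training and
#' validation sets: the first `floor(train_fraction * n)` patients train,
#' the remainder validate (a temporal, not random, split).
#'
#' @param cohort list of `dce_study` (or anything with `acquisition_index`).
#' @param train_fraction in (0, 1); default 0.8 (a 4:1 split).
#' @return list with integer vectors `train` and `validation`.
#' @export
split_cohort <- function(cohort, train_fraction = 0.8) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(cohort)
  ord <- order(vapply(cohort, function(s) s$acquisition_index, 0L))
  n_train <- floor(train_fraction * n)
  if (n_train < 1 || n_train >= n) stop("split leaves an empty cohort side")
  list(train = ord[seq_len(n_train)], validation = ord[(n_train + 1):n])
}

#' Two-way single-rater absolute-agreement ICC, i.e. ICC(2,1)
#'
#' @param x,y numeric vectors: the same measurement by two raters on the
#'   same subjects.
#' @return ICC estimate (NA if the ANOVA mean squares are degenerate).
#' @export
icc21 <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(den) || den == 0) return(NA_real_)
  (msr - mse) / den
}

#' ICC reproducibility filter
#'
#' Computes per-feature ICC(2,1) between two readers' feature tables and
#' retains features with ICC strictly above the threshold. Features with
#' undefined ICC (zero variance in both tables) are dropped and flagged.
#'
#' @param table_reader1,table_reader2 matrices with identical dimnames
#'   (subjects x features).
#' @param threshold retention threshold (default 0.8).
#' @return list with `survivors` (character), `icc_values` (named numeric),
#'   `dropped_undefined` (character).
#' @export
icc_filter <- function(table_reader1, table_reader2, threshold = 0.8) {
  stopifnot(all(dim(table_reader1) == dim(table_reader2)),
            identical(colnames(table_reader1), colnames(table_reader2)),
            nrow(table_reader1) >= 2)
  icc <- vapply(seq_len(ncol(table_reader1)), function(j) {
    icc21(table_reader1[, j], table_reader2[, j])
  }, 0)
  names(icc) <- colnames(table_reader1)
  undef <- names(icc)[is.na(icc)]
  keep <- names(icc)[!is.na(icc) & icc > threshold]
  list(survivors = keep, icc_values = icc, dropped_undefined = undef)
}

#' Welch t-test filter
#'
#' Per-feature two-sided Welch two-sample t-test between label groups;
#' retains features with p strictly below `alpha`. A pooled-variance
#' variant is available.
#'
#' @param table numeric matrix (subjects x features).
#' @param labels binary vector (0/1), both classes with >= 2 members.
#' @param alpha retention level (default 0.1).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list with `survivors` and `p_values`.
#' @export
ttest_filter <- function(table, labels, alpha = 0.1, var_equal = FALSE) {
  labels <- as.integer(labels)
  stopifnot(sum(labels == 1) >= 2, sum(labels == 0) >= 2)
  a <- table[labels == 1, , drop = FALSE]
  b <- table[labels == 0, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(se2))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1          # zero variance in both groups, equal means
  names(p) <- colnames(table)
  list(survivors = colnames(table)[p < alpha], p_values = p)
}

#' @noRd
stratified_folds <- function(labels, n_folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' LASSO feature selection
#'
#' L1-penalized logistic regression over the candidate features; lambda is
#' chosen by seeded, stratified 10-fold cross-validation minimizing the
#' binomial deviance (`lambda.min`; `rule = "1se"` selects `lambda.1se`).
#' Survivors are the features with nonzero coefficients at the chosen
#' lambda.
#'
#' @param table standardized feature matrix (subjects x features).
#' @param labels binary vector.
#' @param features candidate feature names (default: all columns).
#' @param n_folds CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @return list with `survivors`, `lambda`, `fit` (the cv.glmnet object).
#' @export
lasso_select <- function(table, labels, features = colnames(table),
                         n_folds = 10, seed = 1L, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("all labels identical")
  stopifnot(length(labels) >= n_folds)
  x <- table[, features, drop = FALSE]
  if (length(features) < 2) {
    # glmnet needs >= 2 columns; a single candidate passes through
    return(list(survivors = features, lambda = 0, fit = NULL))
  }
  foldid <- stratified_folds(labels, n_folds, seed)
  # near-saturated small-lambda path segments can emit convergence
  # warnings; solutions at the relevant lambdas are unaffected
  cvfit <- suppressWarnings(
    glmnet::cv.glmnet(x, labels, family = "binomial",
                      type.measure = "deviance", foldid = foldid,
                      standardize = FALSE))
  lam <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  cf <- as.matrix(stats::coef(cvfit, s = lam))[-1, 1]
  list(survivors = names(cf)[cf != 0], lambda = lam, fit = cvfit)
}

#' @noRd
fit_logistic <- function(table, labels, features) {
  df <- data.frame(.y = as.integer(labels), check.names = FALSE)
  for (f in features) df[[f]] <- table[, f]
  fml <- if (length(features) == 0) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", features), collapse = " + ")))
  suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
}

#' Backward stepwise elimination under AIC
#'
#' Starting from the given features, repeatedly removes the feature whose
#' removal most decreases the AIC of the logistic model (ties broken by
#' dropping the feature with the largest Wald p-value); stops when no
#' removal decreases AIC.
#'
#' @param table standardized feature matrix.
#' @param labels binary vector.
#' @param start_features non-empty character vector of candidates.
#' @return list with `survivors`, `aic_final`, `trace` (data frame of
#'   removals).
#' @export
stepwise_select <- function(table, labels, start_features) {
  stopifnot(length(start_features) >= 1)
  current <- start_features
  fit <- fit_logistic(table, labels, current)
  aic <- stats::AIC(fit)
  trace <- data.frame(removed = character(0), aic = numeric(0))
  repeat {
    if (length(current) == 0) break
    cand <- vapply(current, function(f) {
      stats::AIC(fit_logistic(table, labels, setdiff(current, f)))
    }, 0)
    best <- min(cand)
    if (best >= aic) break
    tied <- names(cand)[abs(cand - best) < 1e-9]
    drop_f <- if (length(tied) > 1) {
      pv <- summary(fit)$coefficients
      wp <- vapply(tied, function(f) {
        row <- match(sprintf("`%s`", f), rownames(pv))
        if (is.na(row)) row <- match(f, rownames(pv))
        if (is.na(row)) 1 else pv[row, 4]
      }, 0)
      tied[which.max(wp)]
    } else tied
    current <- setdiff(current, drop_f)
    fit <- fit_logistic(table, labels, current)
    aic <- stats::AIC(fit)
    trace <- rbind(trace, data.frame(removed = drop_f, aic = aic))
  }
  list(survivors = current, aic_final = aic, trace = trace)
}

#' Fit a logistic rad-score model
#'
#' Unpenalized logistic regression of the labels on the selected features;
#' the rad-score is the linear predictor (intercept + sum of coefficient
#' times feature). Non-convergence or separation is flagged, with the
#' coefficients of the (possibly unstable) fit retained.
#'
#' @param table standardized feature matrix (training rows).
#' @param labels binary training labels.
#' @param features selected feature names (possibly empty ->
#'   intercept-only model).
#' @param scope one of `"intra"`, `"peri"`, `"multi"`.
#' @param endpoint label name, e.g. `"ER"`.
#' @return a `radscore_model`: list with `endpoint`, `scope`, `intercept`,
#'   `coefficients` (named), `converged`, `separation_flag`.
#' @export
fit_radscore <- function(table, labels, features, scope = "intra",
                         endpoint = "ER") {
  fit <- fit_logistic(table, labels, features)
  cf <- stats::coef(fit)
  coefs <- if (length(features) > 0) {
    stats::setNames(cf[-1], features)
  } else stats::setNames(numeric(0), character(0))
  structure(list(endpoint = endpoint, scope = scope,
                 intercept = unname(cf[1]),
                 coefficients = coefs,
                 converged = fit$converged,
                 separation_flag = any(abs(cf) > 15)),
            class = "radscore_model")
}

#' Compute rad-scores from a fitted model
#' @param model a `radscore_model`.
#' @param table standardized feature matrix.
#' @return numeric vector of rad-scores (linear predictor scale).
#' @export
rad_score <- function(model, table) {
  s <- rep(model$intercept, nrow(table))
  if (length(model$coefficients) > 0) {
    s <- s + as.numeric(table[, names(model$coefficients), drop = FALSE] %*%
                          model$coefficients)
  }
  stats::setNames(s, rownames(table))
}

#' Serialize / deserialize a rad-score model as JSON
#' @param model a `radscore_model`.
#' @param path JSON file path.
#' @return `read_radscore_model` returns the model; write returns the path,
#'   invisibly.
#' @export
write_radscore_model <- function(model, path) {
  obj <- unclass(model)
  obj$coefficients <- as.list(obj$coefficients)  # keep names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_radscore_model
#' @export
read_radscore_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  if (is.null(m$coefficients)) m$coefficients <- stats::setNames(numeric(0), character(0))
  structure(m, class = "radscore_model")
}

#' Single-region selection chain: t-test -> LASSO -> stepwise
#'
#' @param table standardized training feature matrix.
#' @param labels binary training labels.
#' @param candidates starting feature names (e.g. ICC survivors of one
#'   region).
#' @param alpha t-test retention level.
#' @param seed seed for LASSO folds.
#' @param lasso_rule `"min"` or `"1se"`.
#' @return list with nested survivor lists per stage plus `p_values`,
#'   `lasso_lambda`, `aic_final`.
#' @export
select_features <- function(table, labels, candidates, alpha = 0.1,
                            seed = 1L, lasso_rule = "min") {
  if (length(candidates) == 0) stop("empty candidate set")
  tt <- ttest_filter(table[, candidates, drop = FALSE], labels, alpha)
  if (length(tt$survivors) == 0) stop("empty candidate set: no feature passes the t-test")
  la <- lasso_select(table, labels, tt$survivors, seed = seed, rule = lasso_rule)
  if (length(la$survivors) == 0) {
    # full shrinkage: fall back to an intercept-only model downstream
    return(list(ttest = tt$survivors, lasso = character(0),
                stepwise = character(0), p_values = tt$p_values,
                lasso_lambda = la$lambda, aic_final = NA_real_))
  }
  st <- stepwise_select(table, labels, la$survivors)
  list(ttest = tt$survivors, lasso = la$survivors, stepwise = st$survivors,
       p_values = tt$p_values, lasso_lambda = la$lambda,
       aic_final = st$aic_final)
}

#' Build the multiregional model
#'
#' Pools the selected intratumoral and peritumoral features (deduplicated),
#' re-runs LASSO and backward stepwise on the pooled set, and fits the
#' multiregional logistic rad-score.
#'
#' @param intra_survivors,peri_survivors character vectors of selected
#'   feature names per region.
#' @param table standardized training feature matrix.
#' @param labels binary training labels.
#' @param seed seed for LASSO folds.
#' @param endpoint label name.
#' @return list with `model` (a `radscore_model`, scope `"multi"`) and
#'   `selection` (`lasso`, `stepwise` survivor lists).
#' @export
build_multiregional <- function(intra_survivors, peri_survivors, table,
                                labels, seed = 1L, endpoint = "ER") {
  pool <- unique(c(intra_survivors, peri_survivors))
  if (length(pool) == 0) stop("empty candidate set for the multiregional model")
  la <- lasso_select(table, labels, pool, seed = seed)
  surv <- la$survivors
  if (length(surv) > 0) {
    st <- stepwise_select(table, labels, surv)
    surv <- st$survivors
  }
  model <- fit_radscore(table, labels, surv, scope = "multi", endpoint = endpoint)
  list(model = model, selection = list(pool = pool, lasso = la$survivors,
                                       stepwise = surv, lambda = la$lambda))
}

#' Run the full selection + modelling procedure for one endpoint
#'
#' Orchestrates, on training rows only: per-region ICC filtering (when
#' reader-2 tables are supplied), t-test, LASSO and stepwise selection,
#' single-region rad-score fits, and the multiregional fusion model.
#' The training-only inputs of each stage are checksummed so leakage of
#' validation rows is externally verifiable.
#'
#' @param table unstandardized `feature_table` for the whole cohort.
#' @param labels binary labels for the whole cohort (e.g. ER status).
#' @param split a [split_cohort()] result.
#' @param reader2_table optional feature table from a second reader's
#'   segmentations (same columns; rows = a subset of patients identified by
#'   rownames) enabling the ICC filter.
#' @param icc_threshold ICC retention threshold.
#' @param alpha t-test retention level.
#' @param seed seed for LASSO fold assignment.
#' @param endpoint label name for bookkeeping.
#' @param lasso_rule `"min"` or `"1se"`.
#' @return list with `models` (intra/peri/multi `radscore_model`s),
#'   `selection` (per-stage survivor lists per region), `scores`
#'   (rad-scores for all rows, per scope), `standardized` table,
#'   `checksums`.
#' @export
run_endpoint <- function(table, labels, split, reader2_table = NULL,
                         icc_threshold = 0.8, alpha = 0.1, seed = 1L,
                         endpoint = "ER", lasso_rule = "min") {
  stopifnot(nrow(table) == length(labels))
  tr <- split$train
  std <- standardize_features(table, tr)
  y_tr <- as.integer(labels[tr])
  x_tr <- std[tr, , drop = FALSE]
  checksums <- list(standardize = rlang::hash(table[tr, , drop = FALSE]),
                    selection = rlang::hash(list(x_tr, y_tr)))

  all_feats <- colnames(table)
  region_candidates <- list(
    intra = grep("^intra_", all_feats, value = TRUE),
    peri = grep("^peri_", all_feats, value = TRUE))
  icc_res <- NULL
  if (!is.null(reader2_table)) {
    ids <- intersect(rownames(reader2_table), rownames(table)[tr])
    stopifnot(length(ids) >= 2)
    icc_res <- icc_filter(table[ids, , drop = FALSE],
                          reader2_table[ids, , drop = FALSE], icc_threshold)
    region_candidates <- lapply(region_candidates, intersect, y = icc_res$survivors)
    checksums$icc <- rlang::hash(list(table[ids, , drop = FALSE],
                                      reader2_table[ids, , drop = FALSE]))
  }

  sel <- list(); models <- list()
  for (rg in c("intra", "peri")) {
    sel[[rg]] <- select_features(x_tr, y_tr, region_candidates[[rg]],
                                 alpha = alpha, seed = seed,
                                 lasso_rule = lasso_rule)
    models[[rg]] <- fit_radscore(x_tr, y_tr, sel[[rg]]$stepwise,
                                 scope = rg, endpoint = endpoint)
  }
  multi <- build_multiregional(sel$intra$stepwise, sel$peri$stepwise,
                               x_tr, y_tr, seed = seed, endpoint = endpoint)
  models$multi <- multi$model
  sel$multi <- multi$selection

  scores <- lapply(models, rad_score, table = std)
  list(models = models, selection = sel, icc = icc_res, scores = scores,
       standardized = std, split = split, checksums = checksums,
       endpoint = endpoint)
}
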