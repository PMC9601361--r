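fake_cohort <- function(n) {
  lapply(seq_len(n), function(i) {
    structure(list(patient_id = sprintf("P%03d", i), acquisition_index = i - 1L),
              class = "dce_study")
  })
}

test_that("the cohort split is temporal and deterministic", {
  sp <- split_cohort(fake_cohort(10), 0.8)
  expect_equal(sp$train, 1:8)
  expect_equal(sp$validation, 9:10)
  expect_equal(lengths(split_cohort(fake_cohort(5), 0.8)),
               c(train = 4L, validation = 1L))
  # reordering the input leaves the split (by acquisition index) unchanged
  coh <- fake_cohort(10)
  shuf <- coh[c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)]
  sp2 <- split_cohort(shuf, 0.8)
  got <- vapply(shuf[sp2$train], function(s) s$acquisition_index, 0L)
  expect_setequal(got, 0:7)
  expect_error(split_cohort(fake_cohort(10), 0.05))
})

test_that("ICC(2,1) matches the two-way ANOVA mean-squares decomposition", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  # independent oracle: mean squares from aov
  d <- data.frame(score = c(x, y),
                  subject = factor(rep(1:6, 2)),
                  rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(score ~ subject + rater, d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expect_equal(icc21(x, y),
               (msr - mse) / (msr + mse + 2 * (msc - mse) / 6))
  expect_equal(icc21(x, x), 1)
})

test_that("the ICC filter retains reproducible features and drops noise", {
  set.seed(3)
  t1 <- matrix(rnorm(30 * 50), 30, 50, dimnames = list(NULL, paste0("f", 1:50)))
  res <- icc_filter(t1, t1)
  expect_setequal(res$survivors, colnames(t1))
  expect_true(all(res$icc_values == 1))
  # an independent second reader: near-zero ICC, nearly everything dropped
  set.seed(4)
  t2 <- matrix(rnorm(30 * 1000), 30, 1000, dimnames = list(NULL, paste0("g", 1:1000)))
  t3 <- matrix(rnorm(30 * 1000), 30, 1000, dimnames = list(NULL, paste0("g", 1:1000)))
  res2 <- icc_filter(t2, t3)
  expect_lt(abs(mean(res2$icc_values)), 0.05)
  expect_lt(length(res2$survivors), 10)
  # zero-variance feature is dropped and flagged
  t4 <- cbind(t1, konst = rep(1, 30))
  res3 <- icc_filter(t4, t4)
  expect_true("konst" %in% res3$dropped_undefined)
  expect_false("konst" %in% res3$survivors)
})

test_that("the Welch filter matches t.test and applies the alpha rule", {
  tab <- cbind(same = rep(5, 8),
               strong = c(0.01, -0.02, 0.005, 0, 1.01, 0.99, 1.02, 1),
               toy = c(1, 2, 3, 4, 3, 4, 5, 6))
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  res <- ttest_filter(tab, labels, alpha = 0.1)
  expect_equal(unname(res$p_values["same"]), 1)
  expect_false("same" %in% res$survivors)
  expect_true("strong" %in% res$survivors)
  # worked two-sample case: t = -2.191, p = 0.071 < 0.1 -> retained
  oracle <- t.test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(unname(res$p_values["toy"]), oracle$p.value)
  expect_true("toy" %in% res$survivors)
  # pooled-variance option agrees with t.test(var.equal = TRUE)
  resp <- ttest_filter(tab, labels, var_equal = TRUE)
  expect_equal(unname(resp$p_values["toy"]),
               t.test(c(1, 2, 3, 4), c(3, 4, 5, 6), var.equal = TRUE)$p.value)
})

test_that("LASSO shrinks fully at the path maximum and recovers planted features", {
  set.seed(6)
  n <- 200
  x <- matrix(rnorm(n * 51), n, 51, dimnames = list(NULL, paste0("v", 1:51)))
  y <- as.integer(plogis(3 * x[, 1]) > runif(n))
  res <- lasso_select(x, y, seed = 1)
  expect_true("v1" %in% res$survivors)
  # full shrinkage at the largest lambda on the path
  cf <- as.matrix(coef(res$fit, s = max(res$fit$lambda)))[-1, 1]
  expect_equal(sum(cf != 0), 0)
  # planted feature recovered across seeds
  hits <- 0
  for (sd in 1:20) {
    set.seed(sd + 100)
    xs <- matrix(rnorm(n * 51), n, 51, dimnames = list(NULL, paste0("v", 1:51)))
    ys <- as.integer(plogis(3 * xs[, 1]) > runif(n))
    hits <- hits + ("v1" %in% lasso_select(xs, ys, seed = sd)$survivors)
  }
  expect_gte(hits, 19)  # >= 95% of 20 seeds
  expect_error(lasso_select(x, rep(1L, n), seed = 1), "identical")
})

test_that("LASSO on pure noise keeps few features", {
  counts <- integer(20)
  for (sd in 1:20) {
    set.seed(sd + 500)
    x <- matrix(rnorm(200 * 100), 200, 100, dimnames = list(NULL, paste0("n", 1:100)))
    y <- rbinom(200, 1, 0.5)
    counts[sd] <- length(lasso_select(x, y, seed = sd)$survivors)
  }
  expect_lte(median(counts), 5)
})

test_that("backward stepwise elimination behaves as an AIC fixed point", {
  set.seed(8)
  n <- 150
  x1 <- rnorm(n)
  y <- as.integer(plogis(2.5 * x1) > runif(n))
  tab <- cbind(inf = x1, dup = x1 + rnorm(n, 0, 0.01), noise = rnorm(n))
  # a single informative feature is retained
  res1 <- stepwise_select(tab, y, "inf")
  expect_equal(res1$survivors, "inf")
  # one of a collinear pair is removed
  res2 <- stepwise_select(tab, y, c("inf", "dup"))
  expect_length(res2$survivors, 1)
  # when no removal improves AIC the input is returned unchanged
  res3 <- stepwise_select(tab, y, res1$survivors)
  expect_equal(res3$survivors, res1$survivors)
  expect_equal(nrow(res3$trace), 0)
  # noise features are eliminated
  res4 <- stepwise_select(tab, y, c("inf", "noise"))
  expect_equal(res4$survivors, "inf")
})

test_that("rad-score models reproduce an independent IRLS logistic fit", {
  tab <- cbind(f1 = c(-1.2, -0.8, -0.3, 0.4, 0.9, 1.5),
               f2 = c(0.3, -0.2, 0.8, -0.5, 0.1, 0.4))
  y <- c(0, 1, 0, 0, 1, 1)   # overlapping classes: finite MLE
  m <- fit_radscore(tab, y, c("f1", "f2"), scope = "intra", endpoint = "ER")
  # hand-rolled IRLS oracle, iterated to convergence
  X <- cbind(1, tab)
  b <- rep(0, 3)
  repeat {
    eta <- as.numeric(X %*% b)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    b_new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  expect_equal(m$intercept, b[1], tolerance = 1e-5)
  expect_equal(unname(m$coefficients), unname(b[-1]), tolerance = 1e-5)
  # rad-score is the linear predictor
  sc <- rad_score(m, tab)
  expect_equal(unname(sc), as.numeric(X %*% b), tolerance = 1e-4)
  # separable single feature gives training AUC 1
  y2 <- as.integer(tab[, "f1"] > 0)
  m2 <- fit_radscore(tab, y2, "f1")
  expect_equal(roc_auc(rad_score(m2, tab), y2)$auc, 1)
  # empty feature set: intercept-only constant score
  m0 <- fit_radscore(tab, y, character(0))
  expect_length(unique(rad_score(m0, tab)), 1)
})

test_that("rad-score models serialize to JSON and back exactly", {
  m <- structure(list(endpoint = "ER", scope = "multi", intercept = -0.731,
                      coefficients = c(intra_msi_glcm_d0_contrast = 1.25,
                                       peri_sep_laws_L5E5_sd = -2.5),
                      converged = TRUE, separation_flag = FALSE),
                 class = "radscore_model")
  p <- withr::local_tempfile(fileext = ".json")
  write_radscore_model(m, p)
  back <- read_radscore_model(p)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$scope, m$scope)
})

test_that("multiregional fusion deduplicates and degrades gracefully", {
  set.seed(12)
  n <- 120
  tab <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, c(paste0("intra_f", 1:3), paste0("peri_f", 1:3))))
  y <- as.integer(plogis(2 * tab[, 1] + 2 * tab[, 4]) > runif(n))
  res <- build_multiregional(c("intra_f1", "intra_f2"), c("peri_f1", "intra_f1"),
                             tab, y, seed = 2)
  expect_false(anyDuplicated(res$selection$pool) > 0)
  expect_true(all(res$selection$stepwise %in% res$selection$pool))
  # empty peri survivors: built from intratumoral candidates alone
  res2 <- build_multiregional("intra_f1", character(0), tab, y, seed = 2)
  expect_true(length(res2$selection$pool) == 1)
  expect_error(build_multiregional(character(0), character(0), tab, y, seed = 2))
})

test_that("run_endpoint keeps survivor lists nested and selects per endpoint", {
  run <- cached_small_run()
  for (rg in c("intra", "peri")) {
    sel <- run$er$selection[[rg]]
    expect_true(all(sel$stepwise %in% sel$lasso))
    expect_true(all(sel$lasso %in% sel$ttest))
    # region scoping: candidates come only from the matching region
    expect_true(all(startsWith(sel$ttest, paste0(rg, "_"))))
  }
  expect_true(all(run$er$selection$multi$stepwise %in%
                    run$er$selection$multi$pool))
  # the t-test stage starts from the ICC survivors
  icc_ok <- run$er$icc$survivors
  expect_true(all(run$er$selection$intra$ttest %in% icc_ok))
  expect_true(all(run$er$selection$peri$ttest %in% icc_ok))
  # ER and PR share the table but select against their own labels
  expect_false(identical(run$er_labels, run$pr_labels))
  expect_false(identical(run$er$selection$intra$p_values,
                         run$pr$selection$intra$p_values))
})

test_that("an empty post-t-test candidate set raises an explicit error", {
  tab <- cbind(a = rep(c(1, 2), 10), b = rep(c(3, 7), 10))
  labels <- rep(c(0, 1), each = 10)
  # both features identical across classes -> p = 1 -> empty candidates
  expect_error(select_features(tab, labels, c("a", "b")), "empty candidate set")
})

test_that("validation rows never influence selection, standardization or fits", {
  run <- cached_small_run()
  tab <- run$table; er <- run$er_labels; sp <- run$split
  # corrupt every validation row and re-run: the fitted models, survivor
  # lists and standardization parameters must be unchanged
  tab2 <- tab
  tab2[sp$validation, ] <- tab2[sp$validation, ] * 13 + 7
  res2 <- run_endpoint(tab2, er, sp, reader2_table = run$reader2,
                       endpoint = "ER", seed = 101)
  expect_identical(run$er$checksums, res2$checksums)
  expect_identical(run$er$selection$intra$stepwise, res2$selection$intra$stepwise)
  expect_identical(run$er$selection$peri$stepwise, res2$selection$peri$stepwise)
  expect_identical(run$er$models$multi$coefficients, res2$models$multi$coefficients)
  expect_identical(attr(run$er$standardized, "center"), attr(res2$standardized, "center"))
  expect_identical(attr(run$er$standardized, "scale"), attr(res2$standardized, "scale"))
  # training scores agree; validation scores differ (inputs changed)
  expect_identical(run$er$scores$multi[sp$train], res2$scores$multi[sp$train])
})
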