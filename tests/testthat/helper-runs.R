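# A small end-to-end pipeline run shared across test files (built once per
# test session). Uses the first-order family so the cohort-level machinery
# is exercised quickly; the full 4980-feature bank is covered by the
# single-case extraction tests.
.run_cache <- new.env(parent = emptyenv())

cached_small_run <- function() {
  if (!is.null(.run_cache$small)) return(.run_cache$small)
  cfg <- synthetic_config(n_patients = 60, seed = 101)
  cohort <- generate_cohort(cfg)
  rois <- lapply(cohort, build_roi_set)
  tab <- build_feature_table(cohort, families = "firstorder", rois_list = rois)
  er <- vapply(cohort, function(s) s$er_label, 0L)
  pr <- vapply(cohort, function(s) s$pr_label, 0L)
  sp <- split_cohort(cohort)
  # simulated second reader on a subset of training cases
  sub <- sp$train[1:15]
  reader2 <- do.call(rbind, lapply(sub, function(i) {
    m2 <- simulate_second_reader(unclass(rois[[i]]$intra) > 0, jitter_px = 1,
                                 seed = 9000 + i)
    core <- structure(m2, region_tag = "intratumoral",
                      class = c("roi_mask", "matrix", "array"))
    peri <- dilate_peritumoral(core, attr(cohort[[i]], "breast_mask"),
                               4, cohort[[i]]$pixel_spacing_mm)
    extract_all_features(cohort[[i]], list(intra = core, peri = peri),
                         families = "firstorder")
  }))
  rownames(reader2) <- vapply(cohort[sub], function(s) s$patient_id, "")
  res_er <- run_endpoint(tab, er, sp, reader2_table = reader2,
                         endpoint = "ER", seed = 101)
  res_pr <- run_endpoint(tab, pr, sp, reader2_table = reader2,
                         endpoint = "PR", seed = 101)
  .run_cache$small <- list(config = cfg, cohort = cohort, table = tab,
                           er_labels = er, pr_labels = pr, split = sp,
                           reader2 = reader2, er = res_er, pr = res_pr)
  .run_cache$small
}
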