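# shared fixtures: a small, fast scenario and a memoised fitted pipeline so
# several tests can share one fit without refitting

tiny_scenario <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(region_size = 60, grid_dim = 10, n_periods = 3,
         n_transects = 8, seg_length = 5, seed = seed),
    list(...))
  do.call(dsm_scenario, args)
}

.fixture_cache <- new.env(parent = emptyenv())

# full small pipeline up to a plain DSM fit (+ detection fit); memoised on args
small_fit <- function(seed = 7, family = "poisson", det_beaufort = -0.12, ...) {
  key <- paste(seed, family, format(det_beaufort), rlang::hash(list(...)))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sc <- tiny_scenario(seed = seed, family = family,
                      det_beaufort = det_beaufort, ...)
  grids <- simulate_covariate_fields(sc)
  sv <- simulate_survey(sc, grids)
  det_form <- if (is.null(det_beaufort)) ~1 else ~beaufort
  det <- fit_detection(sv$observations, truncation = sc$truncation,
                       formula = det_form)
  seg <- attach_counts(sv$segments, sv$observations, "individuals", sc$truncation)
  seg <- segment_area(seg, sc$truncation)
  seg <- predict_p_segments(det, seg)
  seg$offset <- seg$area * seg$p
  mspec <- model_spec(smooth_spec(c("x", "y"), k = 5),
                      smooth_spec("sst", k = 5), family = family)
  fit <- fit_dsm(seg, mspec)
  out <- list(scenario = sc, grids = grids, survey = sv, det = det,
              segments = seg, spec = mspec, fit = fit)
  .fixture_cache[[key]] <- out
  out
}

expect_symmetric_psd <- function(V, tol = 1e-8) {
  expect_equal(V, t(V), tolerance = 1e-10)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(abs(ev)))
}
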