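#' Specification for a paired normothermia/hypothermia perfusion cohort
#'
#' Describes the study design being emulated: each subject is scanned at
#' two visits (normothermic dialysis, NT, 37 C dialysate; therapeutic
#' hypothermia, TH, 32 C dialysate), each at rest and under adenosine
#' stress, giving four perfusion maps per subject. Defaults encode the
#' emulated conditions: 7 subjects, rest median blood flow 133
#' mL/min/100 g with stress/rest ratio 2.04 (the printed group medians
#' 271/133), a rest fractal dimension of 1.30 under NT with a -14%
#' NT-to-TH shift, and a further -6% rest-to-stress FD drop under TH only.
#'
#' @param n_subjects number of subjects, >= 2 (default 7)
#' @param fd_nt_rest target FD at NT rest
#' @param fd_th_rest target FD at TH rest (default `0.86 * fd_nt_rest`,
#'   the -14% cooling effect)
#' @param fd_stress_delta named length-2 numeric, fractional FD change
#'   rest to stress per condition, `c(nt = 0, th = -0.06)`
#' @param bf_rest_median median rest blood flow, mL/min/100 g
#' @param stress_ratio stress/rest mean-flow ratio (> 0)
#' @param bf_th_ratio TH/NT rest-flow ratio (the small, non-significant
#'   cooling effect on mean flow; 125/133 printed)
#' @param between_subject_cv lognormal coefficient of variation of
#'   subject-level rest flow
#' @param fd_subject_sd SD of subject-level FD deviations from the
#'   condition target
#' @param grid_shape,mask_kind map geometry passed to [synth_map_spec()]
#' @param seed integer master seed; per-map seeds are derived from it
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 7, fd_nt_rest = 1.30,
                        fd_th_rest = 0.86 * fd_nt_rest,
                        fd_stress_delta = c(nt = 0, th = -0.06),
                        bf_rest_median = 133, stress_ratio = 271 / 133,
                        bf_th_ratio = 125 / 133,
                        between_subject_cv = 0.12, fd_subject_sd = 0.015,
                        grid_shape = c(168, 168, 16),
                        mask_kind = "lv_shell", seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2")
  if (stress_ratio <= 0) abort("`stress_ratio` must be > 0")
  fds <- c(fd_nt_rest, fd_th_rest,
           fd_nt_rest * (1 + fd_stress_delta[["nt"]]),
           fd_th_rest * (1 + fd_stress_delta[["th"]]))
  if (any(fds < 1 | fds > 1.5))
    abort("all condition FD targets must lie in [1, 1.5]")
  structure(list(n_subjects = as.integer(n_subjects),
                 fd_nt_rest = fd_nt_rest, fd_th_rest = fd_th_rest,
                 fd_stress_delta = fd_stress_delta,
                 bf_rest_median = bf_rest_median,
                 stress_ratio = stress_ratio, bf_th_ratio = bf_th_ratio,
                 between_subject_cv = between_subject_cv,
                 fd_subject_sd = fd_subject_sd,
                 grid_shape = as.integer(grid_shape),
                 mask_kind = mask_kind, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a paired NT/TH perfusion cohort
#'
#' For every subject, generates the four perfusion maps of the emulated
#' design (NT/TH x rest/stress) with subject-level variation around the
#' condition targets, and measures each map with the package's own
#' estimators. Identical spec and seed give identical cohorts.
#'
#' @param spec a [cohort_spec()]
#' @param keep_maps keep the generated [perfusion_map()]s as a list
#'   column (default `TRUE`; drop for lighter summaries)
#' @return a tibble with one row per (subject, condition, state):
#'   `subject`, `condition` ("NT"/"TH"), `state` ("rest"/"stress"),
#'   `fd_target`, `mean_bf_target`, measured `fd` and `mean_bf`, and
#'   (optionally) `map`.
#' @export
generate_cohort <- function(spec, keep_maps = TRUE) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec")
  design <- expand.grid(state = c("rest", "stress"),
                        condition = c("NT", "TH"),
                        subject = seq_len(spec$n_subjects),
                        stringsAsFactors = FALSE)[, 3:1]
  n_maps <- nrow(design)
  draws <- local_seed(spec$seed, {
    list(map_seeds = sample.int(.Machine$integer.max - 1L, n_maps),
         subj_bf = exp(rnorm(spec$n_subjects, 0, spec$between_subject_cv)),
         fd_dev = rnorm(n_maps, 0, spec$fd_subject_sd))
  })
  rows <- vector("list", n_maps)
  for (i in seq_len(n_maps)) {
    subject <- design$subject[i]
    condition <- design$condition[i]
    state <- design$state[i]
    fd_base <- if (condition == "NT") spec$fd_nt_rest else spec$fd_th_rest
    if (state == "stress")
      fd_base <- fd_base * (1 + spec$fd_stress_delta[[tolower(condition)]])
    fd_target <- min(max(fd_base + draws$fd_dev[i], 1.01), 1.49)
    bf <- spec$bf_rest_median * draws$subj_bf[subject]
    if (condition == "TH") bf <- bf * spec$bf_th_ratio
    if (state == "stress") bf <- bf * spec$stress_ratio
    map <- generate_perfusion_map(synth_map_spec(
      grid_shape = spec$grid_shape, mask_kind = spec$mask_kind,
      mean_bf = bf, target_fd = fd_target, seed = draws$map_seeds[i]))
    fd_est <- estimate_fd(map)
    rows[[i]] <- tibble(subject = subject, condition = condition,
                        state = state, fd_target = fd_target,
                        mean_bf_target = bf, fd = fd_est$fd,
                        mean_bf = masked_mean(map),
                        map = if (keep_maps) list(map) else list(NULL))
  }
  out <- bind_rows(rows)
  if (!keep_maps) out$map <- NULL
  out
}
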