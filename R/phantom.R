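#' Ground-truth parameters for a synthetic perfusion phantom
#'
#' Encodes the construction a real subject realizes physiologically: a
#' baseline gray-matter CBF, the infarct-to-contralateral CBF ratio, and the
#' additive noise level. A ratio of 0.6 yields a ground-truth percent CBF
#' difference of exactly -40.
#'
#' @param baseline_cbf Contralateral GM CBF, ml/100 g/min (> 0).
#' @param infarct_ratio Infarct CBF divided by contralateral CBF (>= 0).
#' @param noise_sd Additive Gaussian noise SD within the brain, ml/100 g/min.
#' @param seed Integer RNG seed; identical seed and parameters reproduce the
#'   phantom bit-for-bit.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(baseline_cbf = 50, infarct_ratio = 0.6,
                         noise_sd = 0, seed = 20201001L) {
  if (!is.finite(baseline_cbf) || baseline_cbf <= 0)
    stop("`baseline_cbf` must be positive")
  if (!is.finite(infarct_ratio) || infarct_ratio < 0)
    stop("`infarct_ratio` must be >= 0")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0")
  structure(list(baseline_cbf = baseline_cbf, infarct_ratio = infarct_ratio,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate a synthetic, pre-aligned brain anatomy
#'
#' Builds an ellipsoidal brain mask and a cortical-band gray-matter
#' probability map that are exactly mirror-symmetric about the voxel
#' mid-plane of the left-right axis, plus a unilateral infarct mask confined
#' strictly to one side of that plane (and, optionally, a hematoma nested
#' inside the infarct). Exact symmetry makes the mirrored-mask readout exact
#' by construction, isolating the perfusion statistic from registration
#' error, which this package does not model.
#'
#' The infarct is the set of `lesion_fraction * brain voxels` eligible voxels
#' nearest a randomly jittered lateral seed point; eligibility means inside
#' the brain and strictly lateral of the mid-plane, so containment in one
#' hemisphere is guaranteed. The hematoma, when requested, is the inner 30%
#' of the infarct (nearest the lesion centre).
#'
#' @param grid A [volume_grid()].
#' @param lesion_fraction Fraction of brain voxels the infarct occupies,
#'   in (0, 1). Must fit in one hemisphere.
#' @param with_hematoma Generate a hematoma sub-region inside the infarct?
#' @param seed Integer RNG seed.
#' @return A list of class `anatomy_set` with elements `brain_mask`,
#'   `gm_prob` (array), `infarct_mask`, `hematoma_mask` (all `mask_volume`s
#'   except `gm_prob`) and `grid`.
#' @export
generate_anatomy <- function(grid, lesion_fraction = 0.05,
                             with_hematoma = FALSE, seed = 20201001L) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.finite(lesion_fraction) || lesion_fraction <= 0 || lesion_fraction >= 1)
    stop("`lesion_fraction` must lie in (0, 1)")
  set.seed(as.integer(seed))
  sh <- grid$shape

  # normalized ellipsoidal radius; symmetric in every axis about (N+1)/2
  ax <- lapply(1:3, function(a) (seq_len(sh[a]) - (sh[a] + 1) / 2) / (0.45 * sh[a]))
  rho <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  brain <- rho <= 1
  if (!any(brain)) stop("grid too small to contain a brain mask")

  # cortical band: GM probability peaks at 80% of the brain radius
  gm_prob <- exp(-((rho - 0.8) / 0.18)^2)
  gm_prob[!brain] <- 0
  gm_prob[gm_prob < 1e-4] <- 0

  # eligible voxels: in brain, strictly lateral of the lr mid-plane
  lr <- grid$lr_axis
  half <- floor(sh[lr] / 2)
  lr_index <- slice.index(brain, lr)
  eligible <- brain & lr_index <= half
  target <- max(1L, round(lesion_fraction * sum(brain)))
  if (sum(eligible) < target)
    stop(sprintf("lesion placement failed: %d eligible hemisphere voxels < %d requested",
                 sum(eligible), target))

  # lesion centre: jittered point in the lateral cortical band
  ctr <- (sh + 1) / 2
  ctr[lr] <- half * 0.55
  jitter <- stats::runif(3, -0.05, 0.05) * sh
  jitter[lr] <- 0
  ctr <- ctr + jitter

  idx <- which(eligible, arr.ind = TRUE)
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
  take <- idx[order(d2)[seq_len(target)], , drop = FALSE]
  infarct <- array(0, sh)
  infarct[take] <- 1

  hematoma <- array(0, sh)
  if (isTRUE(with_hematoma)) {
    n_h <- max(1L, round(0.3 * target))
    take_h <- idx[order(d2)[seq_len(n_h)], , drop = FALSE]
    hematoma[take_h] <- 1
  }

  structure(list(
    brain_mask = mask_volume(brain, grid, "brain"),
    gm_prob = gm_prob,
    infarct_mask = mask_volume(infarct, grid, "infarct"),
    hematoma_mask = mask_volume(hematoma, grid, "hematoma"),
    grid = grid
  ), class = "anatomy_set")
}

#' Generate a synthetic CBF field with known infarct/contralateral contrast
#'
#' Constructs a piecewise-constant CBF field: `baseline_cbf` in voxels whose
#' GM probability reaches the readout threshold, `wm_ratio * baseline_cbf`
#' elsewhere in the brain, 0 outside; infarct voxels are scaled by
#' `infarct_ratio`. Piecewise-constant construction makes the masked means
#' exact at zero noise: the downstream percent CBF difference equals
#' 100 * (infarct_ratio - 1) identically. Optional Gaussian noise is added
#' within the brain.
#'
#' @param anatomy An `anatomy_set` from [generate_anatomy()].
#' @param truth A [ground_truth()].
#' @param gm_threshold GM-probability cut that defines "GM-valued" voxels;
#'   keep equal to the readout threshold (default 0.6).
#' @param wm_ratio Non-GM brain CBF as a fraction of baseline (default 0.4).
#' @param ratio_volume Optional 3D array of per-voxel infarct ratios
#'   overriding the scalar `truth$infarct_ratio` inside the infarct (used to
#'   build lesions with spatially varying hypoperfusion).
#' @return 3D CBF array in ml/100 g/min.
#' @export
generate_perfusion <- function(anatomy, truth, gm_threshold = 0.6,
                               wm_ratio = 0.4, ratio_volume = NULL) {
  stopifnot(inherits(anatomy, "anatomy_set"), inherits(truth, "ground_truth"))
  grid <- anatomy$grid
  brain <- anatomy$brain_mask$data > 0
  gm <- anatomy$gm_prob >= gm_threshold
  cbf <- array(0, grid$shape)
  cbf[brain] <- truth$baseline_cbf * ifelse(gm[brain], 1, wm_ratio)
  les <- anatomy$infarct_mask$data > 0
  if (is.null(ratio_volume)) {
    cbf[les] <- cbf[les] * truth$infarct_ratio
  } else {
    check_on_grid(ratio_volume, grid, "ratio_volume")
    cbf[les] <- cbf[les] * ratio_volume[les]
  }
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    cbf[brain] <- cbf[brain] + stats::rnorm(sum(brain), 0, truth$noise_sd)
  }
  cbf
}

#' Forward-generate a pCASL control/label series from a CBF field
#'
#' Exact algebraic inverse of [quantify_cbf()]: the noise-free difference
#' signal is delta-M = CBF * M0 / k with k the consensus-equation scale
#' factor, so quantifying the returned series recovers the input CBF field
#' voxelwise. Independent Gaussian noise is added to each control and label
#' volume, so averaging more pairs reduces quantification error as 1/sqrt(n).
#'
#' @param perfusion 3D CBF array, ml/100 g/min.
#' @param grid The [volume_grid()].
#' @param m0_value Scalar M0 signal (> 0).
#' @param params An [asl_params()].
#' @param n_pairs Number of control/label pairs (>= 1).
#' @param noise_sd SD of additive signal noise per volume (same units as M0).
#' @param seed Integer RNG seed.
#' @return An [asl_series()].
#' @export
generate_asl_series <- function(perfusion, grid, m0_value = 1000,
                                params = asl_params(), n_pairs = 1L,
                                noise_sd = 0, seed = 20201001L) {
  stopifnot(inherits(grid, "volume_grid"), inherits(params, "asl_params"))
  check_on_grid(perfusion, grid, "perfusion")
  if (!is.finite(m0_value) || m0_value <= 0)
    stop("`m0_value` must be strictly positive")
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("`n_pairs` must be >= 1")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  set.seed(as.integer(seed))
  k <- cbf_scale_factor(params)
  dm <- perfusion * m0_value / k
  sh4 <- c(grid$shape, n_pairs)
  control <- array(m0_value, sh4)
  label <- array(rep(m0_value - dm, n_pairs), sh4)
  if (noise_sd > 0) {
    control <- control + array(stats::rnorm(prod(sh4), 0, noise_sd), sh4)
    label <- label + array(stats::rnorm(prod(sh4), 0, noise_sd), sh4)
  }
  m0 <- array(m0_value, grid$shape)
  asl_series(control, label, m0, params, grid)
}

#' Specification of a synthetic clinical cohort
#'
#' The 90-day functional-independence outcome follows a logistic model in
#' percent CBF difference, infarct volume and pre-stroke mRS; all other
#' covariates are drawn independently, so they are true null predictors.
#' Default effect coefficients are the natural logs of odds ratios typical
#' for this setting (about 1.013 per percentage point of CBF difference,
#' 0.991 per ml of infarct, 0.286 per pre-stroke mRS point); default
#' covariate shapes approximate a post-thrombectomy cohort (median age ~74,
#' median infarct ~51 ml, median percent CBF difference ~16).
#'
#' @param n Number of subjects (>= 1).
#' @param coef_intercept,coef_pct_cbf_diff,coef_infarct_volume,coef_pre_stroke_mrs
#'   Coefficients on the logit of functional independence.
#' @param covariates Named list of distribution parameters; see Details in
#'   [generate_cohort()]. Missing entries fall back to defaults.
#' @param n_inadequate_imaging,n_posterior_circulation Number of rows flagged
#'   for exclusion (inadequate/incomplete imaging; posterior-circulation
#'   stroke), for exercising the inclusion filter. Default 0.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        coef_intercept = 1.4,
                        coef_pct_cbf_diff = log(1.013),
                        coef_infarct_volume = log(0.991),
                        coef_pre_stroke_mrs = log(0.286),
                        covariates = list(),
                        n_inadequate_imaging = 0L,
                        n_posterior_circulation = 0L,
                        seed = 20201001L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  defaults <- list(
    age_mean = 73, age_sd = 14, age_range = c(18, 100),
    male_p = 0.45,
    pre_mrs_probs = c(0.60, 0.15, 0.10, 0.08, 0.05, 0.02),  # mRS 0..5
    nihss_mean = 12, nihss_sd = 5,
    aspects_probs = c(0.02, 0.03, 0.06, 0.12, 0.22, 0.30, 0.25),  # 4..10
    etici_probs = c("2a" = 0.04, "2b" = 0.18, "2c" = 0.28, "3" = 0.50),
    ivt_p = 0.42,
    stroke_to_mri_mean = 4, stroke_to_mri_sd = 1.5,
    vol_meanlog = log(51), vol_sdlog = 0.9, vol_max = 400,
    pct_mean = 16, pct_sd = 40,
    ht_probs = c(none = 0.56, HI1 = 0.25, HI2 = 0.09, PH1 = 0.04, PH2 = 0.06),
    sh_given_ht = 0.06,
    risk_p = c(hypertension = 0.70, diabetes = 0.19, smoking = 0.30,
               prior_stroke_tia = 0.21, hyperlipidemia = 0.23,
               atrial_fibrillation = 0.53),
    med_p = c(anticoagulation = 0.32, statin = 0.32, platelet_inhibitor = 0.27)
  )
  defaults[names(covariates)] <- covariates
  if (n_inadequate_imaging + n_posterior_circulation > n)
    stop("exclusion-flag counts exceed cohort size")
  structure(list(
    n = n,
    coef = c(intercept = coef_intercept, pct_cbf_diff = coef_pct_cbf_diff,
             infarct_volume = coef_infarct_volume,
             pre_stroke_mrs = coef_pre_stroke_mrs),
    covariates = defaults,
    n_inadequate_imaging = as.integer(n_inadequate_imaging),
    n_posterior_circulation = as.integer(n_posterior_circulation),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic clinical cohort
#'
#' Draws one subject record per row: demographics, stroke severity and
#' treatment covariates, imaging readouts (infarct volume, percent CBF
#' difference, hypoperfused fraction), hemorrhagic-transformation class, and
#' a 90-day modified Rankin Scale outcome whose dichotomy (functional
#' independence, mRS <= 2) follows the logistic model declared in the
#' [cohort_spec()]. `mrs_90d = 6` encodes death. The `noreflow` column
#' applies the operational classifier (eTICI 2c/3, percent CBF difference
#' < -15, hypoperfused fraction >= 0.5) to the generated readouts.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame`, one row per subject. Column dictionary in
#'   [write_cohort_csv()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  cv <- spec$covariates

  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  age <- round(clip(stats::rnorm(n, cv$age_mean, cv$age_sd), cv$age_range[1], cv$age_range[2]))
  sex <- ifelse(stats::runif(n) < cv$male_p, "M", "F")
  pre_mrs <- sample(0:5, n, replace = TRUE, prob = cv$pre_mrs_probs)
  nihss <- round(clip(stats::rnorm(n, cv$nihss_mean, cv$nihss_sd), 0, 42))
  aspects <- sample(4:10, n, replace = TRUE, prob = cv$aspects_probs)
  etici <- sample(names(cv$etici_probs), n, replace = TRUE, prob = cv$etici_probs)
  ivt <- stats::runif(n) < cv$ivt_p
  s2m <- round(clip(stats::rnorm(n, cv$stroke_to_mri_mean, cv$stroke_to_mri_sd), 1, 10), 1)
  vol <- clip(stats::rlnorm(n, cv$vol_meanlog, cv$vol_sdlog), 0.5, cv$vol_max)
  pct <- stats::rnorm(n, cv$pct_mean, cv$pct_sd)
  hypo_frac <- clip(0.5 - pct / 60 + stats::rnorm(n, 0, 0.1), 0, 1)
  ht <- sample(names(cv$ht_probs), n, replace = TRUE, prob = cv$ht_probs)
  sh <- ht != "none" & stats::runif(n) < cv$sh_given_ht
  risk <- lapply(cv$risk_p, function(p) stats::runif(n) < p)
  med <- lapply(cv$med_p, function(p) stats::runif(n) < p)

  lp <- spec$coef["intercept"] +
    spec$coef["pct_cbf_diff"] * pct +
    spec$coef["infarct_volume"] * vol +
    spec$coef["pre_stroke_mrs"] * pre_mrs
  fi <- stats::runif(n) < stats::plogis(lp)
  mrs90 <- integer(n)
  mrs90[fi] <- sample(0:2, sum(fi), replace = TRUE, prob = c(0.3, 0.4, 0.3))
  mrs90[!fi] <- sample(3:6, sum(!fi), replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.15))

  noreflow <- etici %in% c("2c", "3") & pct < -15 & hypo_frac >= 0.5

  excl <- rep("none", n)
  flagged <- sample.int(n, spec$n_inadequate_imaging + spec$n_posterior_circulation)
  excl[flagged[seq_len(spec$n_inadequate_imaging)]] <- "inadequate_imaging"
  if (spec$n_posterior_circulation > 0)
    excl[flagged[spec$n_inadequate_imaging + seq_len(spec$n_posterior_circulation)]] <-
      "posterior_circulation"

  out <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex,
    pre_stroke_mrs = pre_mrs,
    nihss_admission = nihss,
    aspects = aspects,
    etici = etici,
    etici_2c3 = etici %in% c("2c", "3"),
    iv_thrombolysis = ivt,
    stroke_to_mri_days = s2m,
    infarct_volume_ml = vol,
    percent_cbf_difference = pct,
    hypoperfused_fraction = hypo_frac,
    ht_class = ht,
    sh = sh,
    mrs_90d = mrs90,
    functional_independence = fi,
    noreflow = noreflow,
    exclusion_flag = excl,
    stringsAsFactors = FALSE
  )
  for (nm in names(risk)) out[[nm]] <- risk[[nm]]
  for (nm in names(med)) out[[nm]] <- med[[nm]]
  out
}
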