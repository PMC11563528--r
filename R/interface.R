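#' Write a volume to NIfTI-1
#'
#' One file per volume; the grid's voxel spacing goes into the header
#' `pixdim`. The interslice gap, which NIfTI-1 does not represent, must be
#' re-declared when the volume is read back.
#'
#' @param vol 3D (or 4D) array.
#' @param grid The [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(vol)[1:3], grid$shape))
    stop("volume does not sit on the declared grid")
  im <- RNifti::asNifti(vol)
  RNifti::pixdim(im) <- grid$spacing_mm
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a volume from NIfTI-1, recovering its grid
#'
#' @param path NIfTI file path.
#' @param lr_axis Left-right axis of the stored grid (default 1).
#' @param slice_gap_mm Declared interslice gap (not stored in NIfTI-1).
#' @return List with `data` (array) and `grid` ([volume_grid()]).
#' @export
read_volume <- function(path, lr_axis = 1L, slice_gap_mm = 0) {
  im <- RNifti::readNifti(path)
  arr <- array(as.numeric(im), dim = dim(im))
  grid <- volume_grid(dim(arr)[1:3], RNifti::pixdim(im)[1:3],
                      lr_axis = lr_axis, slice_gap_mm = slice_gap_mm)
  list(data = arr, grid = grid)
}

# internal: 32-bit rolling polynomial hash of the serialized configuration,
# used as a provenance stamp on every output file (not cryptographic)
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Default pipeline configuration for a single subject
#'
#' Collects every tunable the subject-level pipeline uses, with the package
#' defaults: GM threshold 0.6, mean readout statistic, minimum region 10
#' voxels, 15% voxelwise hypoperfusion threshold, consensus ASL constants.
#' All values are echoed into the sidecar log by [run_subject()].
#'
#' @param cbf,control_label,m0 Paths: either a quantified CBF map, or a raw
#'   4D control/label series (first half of the 4th dimension control
#'   volumes, second half the paired label volumes) plus M0.
#' @param infarct,hematoma,gm_prob Paths to the lesion mask, hematoma mask
#'   (optional, NULL for none) and GM probability map.
#' @param etici eTICI grade for the no-reflow classifier.
#' @param gm_threshold,statistic,min_voxels,rel_threshold Readout tunables.
#' @param params An [asl_params()].
#' @param criteria A [noreflow_criteria()].
#' @param lr_axis,slice_gap_mm Grid conventions for files read from disk.
#' @param out_dir Output directory; NULL to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cbf = NULL, control_label = NULL, m0 = NULL,
                            infarct = NULL, hematoma = NULL, gm_prob = NULL,
                            etici = "3",
                            gm_threshold = 0.6,
                            statistic = "mean",
                            min_voxels = 10L,
                            rel_threshold = 0.15,
                            params = asl_params(),
                            criteria = noreflow_criteria(),
                            lr_axis = 1L, slice_gap_mm = 0,
                            out_dir = NULL) {
  structure(list(cbf = cbf, control_label = control_label, m0 = m0,
                 infarct = infarct, hematoma = hematoma, gm_prob = gm_prob,
                 etici = etici, gm_threshold = gm_threshold,
                 statistic = statistic, min_voxels = as.integer(min_voxels),
                 rel_threshold = rel_threshold, params = params,
                 criteria = criteria, lr_axis = as.integer(lr_axis),
                 slice_gap_mm = slice_gap_mm, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the subject-level pipeline
#'
#' Quantifies CBF if a raw series is given (otherwise loads the CBF map),
#' thresholds the GM probability map, excludes the hematoma from the infarct
#' mask, computes the mirrored-mask perfusion readout and the no-reflow
#' classification, and (when `out_dir` is set) writes `readout.json` plus a
#' sidecar `provenance.json` echoing every constant and a hash of the
#' configuration. Deterministic given inputs and configuration.
#'
#' @param config A [pipeline_config()]. Paths may also be in-memory objects:
#'   `cbf` an array, `infarct`/`hematoma`/`gm_prob` arrays, in which case
#'   `grid` must be supplied.
#' @param grid Required when in-memory arrays are passed instead of paths.
#' @return List with `readout` (`perfusion_readout`), `noreflow`
#'   (`noreflow_result`), and `provenance`.
#' @export
run_subject <- function(config, grid = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  load_vol <- function(x, what) {
    if (is.character(x)) {
      v <- read_volume(x, config$lr_axis, config$slice_gap_mm)
      if (is.null(grid)) grid <<- v$grid
      if (!grids_match(v$grid, grid))
        stop(sprintf("grid mismatch: '%s' (%s) does not match the subject grid",
                     what, x))
      v$data
    } else {
      if (is.null(grid)) stop("`grid` is required for in-memory volumes")
      check_on_grid(x, grid, what)
      x
    }
  }

  if (!is.null(config$cbf)) {
    cbf <- load_vol(config$cbf, "cbf")
  } else {
    if (is.null(config$control_label) || is.null(config$m0))
      stop("either `cbf` or both `control_label` and `m0` must be given")
    raw <- if (is.character(config$control_label)) {
      rv <- read_volume(config$control_label, config$lr_axis, config$slice_gap_mm)
      if (is.null(grid)) grid <- rv$grid
      rv$data
    } else config$control_label
    m0 <- load_vol(config$m0, "m0")
    if (is.null(grid)) stop("`grid` could not be established from inputs")
    if (length(dim(raw)) != 4L) stop("`control_label` must be a 4D series")
    np <- dim(raw)[4] / 2
    if (is.na(np) || np != round(np))
      stop("`control_label` must be 4D with an even number of volumes")
    series <- asl_series(raw[, , , seq_len(np), drop = FALSE],
                         raw[, , , np + seq_len(np), drop = FALSE],
                         m0, config$params, grid)
    cbf <- quantify_series(series)
  }

  infarct <- mask_volume(load_vol(config$infarct, "infarct"), grid, "infarct")
  hematoma <- if (is.null(config$hematoma))
    mask_volume(array(0, grid$shape), grid, "hematoma")
  else mask_volume(load_vol(config$hematoma, "hematoma"), grid, "hematoma")
  gm <- threshold_gm(load_vol(config$gm_prob, "gm_prob"), grid,
                     config$gm_threshold)

  readout <- percent_cbf_difference(cbf, infarct, hematoma, gm,
                                    min_voxels = config$min_voxels,
                                    statistic = config$statistic,
                                    rel_threshold = config$rel_threshold)
  nr <- classify_noreflow(readout, config$etici, config$criteria)

  echo <- list(
    gm_threshold = config$gm_threshold, statistic = config$statistic,
    min_voxels = config$min_voxels, rel_threshold = config$rel_threshold,
    asl_params = unclass(config$params),
    noreflow_criteria = unclass(config$criteria),
    lr_axis = config$lr_axis, slice_gap_mm = config$slice_gap_mm,
    units = "ml/100g/min", noreflow_rule = "operationalized criterion")
  prov <- list(config = echo, config_hash = config_hash(echo),
               package_version = as.character(utils::packageVersion("aslperf")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    res <- c(unclass(readout),
             list(is_noreflow = nr$is_noreflow, etici_ok = nr$etici_ok,
                  diff_ok = nr$diff_ok, fraction_ok = nr$fraction_ok,
                  etici = nr$etici, operationalized = TRUE,
                  config_hash = prov$config_hash))
    jsonlite::write_json(res, file.path(config$out_dir, "readout.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(readout = readout, noreflow = nr, provenance = prov)
}

#' Apply the cohort inclusion filters
#'
#' Removes rows flagged for inadequate/incomplete imaging or
#' posterior-circulation stroke and reports the inclusion flow.
#'
#' @param cohort Data frame with an `exclusion_flag` column
#'   ("none", "inadequate_imaging" or "posterior_circulation").
#' @return List with `cohort` (analyzed rows), `n_enrolled`,
#'   `n_inadequate_imaging`, `n_posterior_circulation`, `n_analyzed`.
#' @export
apply_inclusion_filters <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  flag <- if ("exclusion_flag" %in% names(cohort)) cohort$exclusion_flag
          else rep("none", nrow(cohort))
  legal <- c("none", "inadequate_imaging", "posterior_circulation")
  if (!all(flag %in% legal))
    stop("`exclusion_flag` must be one of: ", paste(legal, collapse = ", "))
  keep <- flag == "none"
  list(cohort = cohort[keep, , drop = FALSE],
       n_enrolled = nrow(cohort),
       n_inadequate_imaging = sum(flag == "inadequate_imaging"),
       n_posterior_circulation = sum(flag == "posterior_circulation"),
       n_analyzed = sum(keep))
}

#' Default variable-type declarations for the cohort battery
#'
#' Maps the standard cohort columns to their comparison type; continuous
#' and ordinal variables go to Mann-Whitney, binary ones to Fisher's exact.
#'
#' @return Named character vector.
#' @export
default_variable_types <- function() {
  c(age = "continuous", pre_stroke_mrs = "continuous",
    nihss_admission = "continuous", aspects = "continuous",
    stroke_to_mri_days = "continuous", infarct_volume_ml = "continuous",
    percent_cbf_difference = "continuous",
    etici_2c3 = "binary", iv_thrombolysis = "binary", sh = "binary",
    hypertension = "binary", diabetes = "binary", smoking = "binary",
    prior_stroke_tia = "binary", hyperlipidemia = "binary",
    atrial_fibrillation = "binary", anticoagulation = "binary",
    statin = "binary", platelet_inhibitor = "binary")
}

#' Run the cohort-level pipeline
#'
#' Applies the inclusion filters, compares all declared variables between
#' the two outcome groups (and between the no-reflow subcohort and the
#' rest), then fits the stepwise-forward logistic regression for functional
#' independence using as candidates the continuous/ordinal and binary
#' variables univariately significant at `univariate_p` (or an explicit
#' `candidates` vector). When `out_dir` is set, writes the comparison
#' tables, regression table and a no-reflow summary as CSV/JSON with the
#' configuration hash.
#'
#' @param cohort Data frame (e.g. from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param variables Named type vector; default [default_variable_types()].
#' @param candidates Explicit candidate set for the regression; NULL to use
#'   variables with univariate p below `univariate_p`.
#' @param univariate_p Univariate screening threshold (default 0.05).
#' @param entry_p,removal_p Stepwise thresholds (defaults 0.05 / 0.10).
#' @param out_dir Output directory; NULL to skip writing.
#' @return List with `inclusion`, `comparison_fi`, `comparison_noreflow`,
#'   `regression`, `noreflow_summary`.
#' @export
run_cohort <- function(cohort, variables = default_variable_types(),
                       candidates = NULL, univariate_p = 0.05,
                       entry_p = 0.05, removal_p = 0.10, out_dir = NULL) {
  flow <- apply_inclusion_filters(cohort)
  dat <- flow$cohort
  variables <- variables[names(variables) %in% names(dat)]

  cmp_fi <- compare_groups(dat, "functional_independence", variables)
  cmp_nr <- if (any(dat$noreflow) && any(!dat$noreflow))
    compare_groups(dat, "noreflow", variables) else NULL

  if (is.null(candidates))
    candidates <- cmp_fi$variable[cmp_fi$p_value < univariate_p]
  reg <- if (length(candidates) >= 1L)
    stepwise_logistic(dat, candidates, "functional_independence",
                      entry_p = entry_p, removal_p = removal_p) else NULL

  nr_sum <- list(
    n_noreflow = sum(dat$noreflow), n_analyzed = nrow(dat),
    prevalence_pct = round(100 * mean(dat$noreflow)),
    rule = "operationalized criterion")

  out <- list(inclusion = flow[-1], comparison_fi = cmp_fi,
              comparison_noreflow = cmp_nr, regression = reg,
              noreflow_summary = nr_sum)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    h <- config_hash(list(variables = as.list(variables),
                          candidates = candidates, univariate_p = univariate_p,
                          entry_p = entry_p, removal_p = removal_p))
    utils::write.csv(cmp_fi, file.path(out_dir, "comparison_functional_independence.csv"),
                     row.names = FALSE)
    if (!is.null(cmp_nr))
      utils::write.csv(cmp_nr, file.path(out_dir, "comparison_noreflow.csv"),
                       row.names = FALSE)
    if (!is.null(reg))
      utils::write.csv(odds_ratio_table(reg), file.path(out_dir, "regression.csv"),
                       row.names = FALSE)
    jsonlite::write_json(c(out$inclusion, nr_sum, list(config_hash = h)),
                         file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Write / read a cohort table as CSV
#'
#' UTF-8 CSV with a header row. Column dictionary: `id` subject id; `age`
#' years; `sex` M/F; `pre_stroke_mrs` modified Rankin Scale 0-6 before
#' stroke; `nihss_admission` NIHSS 0-42; `aspects` ASPECTS 0-10; `etici`
#' recanalization grade (0, 1, 2a, 2b, 2c, 3); `etici_2c3` near-complete or
#' complete recanalization; `iv_thrombolysis` intravenous thrombolysis given;
#' `stroke_to_mri_days`; `infarct_volume_ml` hematoma-excluded infarct
#' volume; `percent_cbf_difference` mirrored-mask perfusion statistic;
#' `hypoperfused_fraction` voxelwise relative-hypoperfusion fraction;
#' `ht_class` hemorrhagic transformation (none, HI1, HI2, PH1, PH2); `sh`
#' symptomatic hemorrhage; `mrs_90d` 90-day mRS, 6 = death;
#' `functional_independence` mRS <= 2 at 90 days; `noreflow` operational
#' classifier output; `exclusion_flag` inclusion-filter flag; remaining
#' logical columns are risk-factor / medication flags.
#'
#' @param cohort Data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
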