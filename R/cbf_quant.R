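#' pCASL quantification constants
#'
#' Bundles the constants of the consensus single-compartment quantification
#' model. Label duration and post-label delay default to the acquisition
#' protocol (1800 ms labeling, 2000 ms PLD); labeling efficiency, blood-brain
#' partition coefficient and arterial blood T1 default to the consensus
#' recommendation values for pCASL at 3T (alpha = 0.85, lambda = 0.9 ml/g,
#' T1b = 1650 ms). All are overridable; every value used is echoed by
#' [run_subject()] so the provenance of the constants is auditable.
#'
#' @param label_duration_s Labeling pulse-train duration tau, seconds.
#' @param post_label_delay_s Post-label delay (PLD), seconds.
#' @param labeling_efficiency Labeling efficiency alpha, in (0, 1].
#' @param partition_coefficient Blood-brain partition coefficient lambda, ml/g.
#' @param blood_t1_s Longitudinal relaxation time of arterial blood, seconds.
#' @return An object of class `asl_params`.
#' @export
asl_params <- function(label_duration_s = 1.8,
                       post_label_delay_s = 2.0,
                       labeling_efficiency = 0.85,
                       partition_coefficient = 0.9,
                       blood_t1_s = 1.65) {
  vals <- c(tau = label_duration_s, pld = post_label_delay_s,
            alpha = labeling_efficiency, lambda = partition_coefficient,
            t1b = blood_t1_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all ASL parameters must be strictly positive and finite")
  if (labeling_efficiency > 1)
    stop("`labeling_efficiency` must be <= 1")
  structure(
    list(label_duration_s = label_duration_s,
         post_label_delay_s = post_label_delay_s,
         labeling_efficiency = labeling_efficiency,
         partition_coefficient = partition_coefficient,
         blood_t1_s = blood_t1_s),
    class = "asl_params"
  )
}

#' @export
print.asl_params <- function(x, ...) {
  cat(sprintf(
    "asl_params: tau = %.3g s, PLD = %.3g s, alpha = %.3g, lambda = %.3g ml/g, T1b = %.3g s\n",
    x$label_duration_s, x$post_label_delay_s, x$labeling_efficiency,
    x$partition_coefficient, x$blood_t1_s))
  invisible(x)
}

#' A pCASL control/label series with its M0 reference
#'
#' Control and label volumes come in equal-count pairs (4D arrays with the
#' pair index last); the proton-density M0 volume scales the difference
#' signal into absolute units. The series is assumed motion-corrected and
#' co-registered — the pipeline does not realign.
#'
#' @param control,label 4D arrays, `grid$shape` x n_pairs.
#' @param m0 3D array, positive within the brain.
#' @param params An [asl_params()].
#' @param grid The [volume_grid()].
#' @return An object of class `asl_series`.
#' @export
asl_series <- function(control, label, m0, params, grid) {
  stopifnot(inherits(params, "asl_params"), inherits(grid, "volume_grid"))
  if (length(dim(control)) != 4L || length(dim(label)) != 4L)
    stop("`control` and `label` must be 4D arrays (x, y, z, pair)")
  if (!identical(dim(control), dim(label)))
    stop("control and label series must have identical dimensions (paired)")
  if (!identical(dim(control)[1:3], grid$shape))
    stop("control/label volumes do not sit on the declared grid")
  check_on_grid(m0, grid, "m0")
  if (dim(control)[4] < 1L) stop("at least one control/label pair is required")
  structure(
    list(control = control, label = label, m0 = m0, params = params,
         grid = grid, n_pairs = dim(control)[4]),
    class = "asl_series"
  )
}

#' Average control-minus-label difference signal
#'
#' Voxelwise mean over pairs of (control - label). No outlier rejection is
#' performed before averaging.
#'
#' @param series An [asl_series()].
#' @return 3D array, the mean difference signal (delta-M).
#' @export
average_difference <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  d <- series$control - series$label
  out <- apply(d, 1:3, mean)
  array(out, dim = series$grid$shape)
}

#' Quantify CBF from a difference signal with the consensus model
#'
#' Applies the single-compartment pCASL quantification equation voxelwise:
#'
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta M\,e^{PLD/T_{1b}}}
#'   {2\,\alpha\,T_{1b}\,M_0\,(1 - e^{-\tau/T_{1b}})}}
#'
#' in ml/100 g/min. Voxels with M0 <= 0 cannot be calibrated; they are set to
#' `NA` and their count is reported in the `n_missing` attribute.
#'
#' @param delta_m 3D array, mean control-minus-label signal.
#' @param m0 3D array, proton-density reference.
#' @param params An [asl_params()].
#' @param grid The [volume_grid()] all volumes share.
#' @return 3D array of CBF in ml/100 g/min, with attributes `units`
#'   ("ml/100g/min") and `n_missing` (voxels with non-positive M0).
#' @examples
#' g <- volume_grid(c(2, 2, 2), c(3, 3, 6))
#' m0 <- array(1000, g$shape)
#' cbf <- quantify_cbf(0.01 * m0, m0, asl_params(), g)
#' cbf[1, 1, 1]  # ~97.4 ml/100g/min
#' @export
quantify_cbf <- function(delta_m, m0, params, grid) {
  stopifnot(inherits(params, "asl_params"), inherits(grid, "volume_grid"))
  check_on_grid(delta_m, grid, "delta_m")
  check_on_grid(m0, grid, "m0")
  bad <- !(m0 > 0)
  cbf <- array(NA_real_, dim = grid$shape)
  k <- cbf_scale_factor(params)
  cbf[!bad] <- k * delta_m[!bad] / m0[!bad]
  structure(cbf, units = "ml/100g/min", n_missing = sum(bad))
}

# internal: the scalar factor such that CBF = k * deltaM / M0
cbf_scale_factor <- function(params) {
  with(params, {
    6000 * partition_coefficient * exp(post_label_delay_s / blood_t1_s) /
      (2 * labeling_efficiency * blood_t1_s *
         (1 - exp(-label_duration_s / blood_t1_s)))
  })
}

#' Quantify CBF directly from a control/label series
#'
#' Convenience composition: [average_difference()] then [quantify_cbf()].
#'
#' @param series An [asl_series()].
#' @return 3D CBF array in ml/100 g/min.
#' @export
quantify_series <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  quantify_cbf(average_difference(series), series$m0, series$params, series$grid)
}
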