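#' Fluorescent probe model
#'
#' A probe is characterised by its blinking calibration: `alpha`, the
#' average number of localizations emitted per probe over a full
#' acquisition, and the maximum dark time, the longest frame gap over
#' which localizations are still attributed to the same fluorophore
#' re-blinking. `alpha` is what converts localization counts into
#' molecule counts downstream.
#'
#' @param probe_name label used to look the probe up from configurations.
#' @param alpha mean localizations per probe (>= 1).
#' @param max_dark_time_frames maximum dark time, in frames, for blink
#'   merging (used only by [merge_blinks()]).
#' @param loc_precision_sigma_nm isotropic localization precision (sd of
#'   the Gaussian error added to each emitted localization), in nm.
#' @return An object of class `fluorophore`.
#' @seealso [fluorophore_registry()] for the calibrated probes shipped
#'   with the package.
#' @export
fluorophore <- function(probe_name, alpha, max_dark_time_frames = 50,
                        loc_precision_sigma_nm = 10) {
  stopifnot(is.character(probe_name), length(probe_name) == 1L)
  check_number(alpha, "alpha", lower = 1)
  check_number(max_dark_time_frames, "max_dark_time_frames", lower = 0)
  check_number(loc_precision_sigma_nm, "loc_precision_sigma_nm", lower = 1e-9)
  structure(list(probe_name = probe_name, alpha = alpha,
                 max_dark_time_frames = as.integer(max_dark_time_frames),
                 loc_precision_sigma_nm = loc_precision_sigma_nm),
            class = "fluorophore")
}

#' Calibrated probe registry
#'
#' The assay's calibration constants for the shipped probes: SNA lectin
#' conjugated to AF647 (alpha = 6), anti-tetraspanin antibodies
#' conjugated to AF647 (alpha = 10) or CF568 (alpha = 11), and the
#' anti-ApoE antibody conjugated to AF647 (alpha = 11). Dark time and
#' localization precision are configuration, not calibrated truth, and
#' can be overridden per probe.
#'
#' @param loc_precision_sigma_nm default localization precision applied
#'   to every registry entry.
#' @return Named list of [fluorophore()] objects.
#' @examples
#' fluorophore_registry()[["SNA-AF647"]]$alpha  # 6
#' @export
fluorophore_registry <- function(loc_precision_sigma_nm = 10) {
  probes <- list(
    `SNA-AF647`          = 6,
    `antibody-AF647`     = 10,
    `antibody-CF568`     = 11,
    `ApoE-antibody-AF647` = 11
  )
  out <- lapply(names(probes), function(nm)
    fluorophore(nm, probes[[nm]],
                loc_precision_sigma_nm = loc_precision_sigma_nm))
  names(out) <- names(probes)
  out
}
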