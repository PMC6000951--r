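# broom-style tidiers for the fitted/derived result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an MTF curve
#'
#' @param x An `mtf_curve`.
#' @param ... Unused.
#' @return The frequency/modulation tibble.
#' @export
tidy.mtf_curve <- function(x, ...) x$curve

#' One-row summary of an MTF curve
#'
#' @param x An `mtf_curve`.
#' @param ... Unused.
#' @return Tibble with `f10_lp_mm`, `f10_fit_lp_mm`, `sigma_fit_mm`,
#'   `lsf_fwhm_mm`, `esf_bin_um`.
#' @export
glance.mtf_curve <- function(x, ...) {
  tibble::tibble(f10_lp_mm = x$f10_lp_mm, f10_fit_lp_mm = x$f10_fit_lp_mm,
                 sigma_fit_mm = x$sigma_fit_mm, lsf_fwhm_mm = x$lsf_fwhm_mm,
                 esf_bin_um = x$esf_bin_um)
}

#' Tidy a dose report
#'
#' @param x A `dose_report`.
#' @param ... Unused.
#' @return The per-slab depth/energy/dose profile tibble.
#' @export
tidy.dose_report <- function(x, ...) x$profile

#' One-row summary of a dose report
#'
#' @param x A `dose_report`.
#' @param ... Unused.
#' @return Tibble with `fluence_cm2`, `n_ions`, `mean_dose_ugy`.
#' @export
glance.dose_report <- function(x, ...) {
  tibble::tibble(fluence_cm2 = x$fluence_cm2, n_ions = x$n_ions,
                 mean_dose_ugy = x$mean_dose_gy * 1e6)
}
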