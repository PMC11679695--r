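# Reference-intensity-ratio (corundum number) phase quantification from
# XRD peak intensities, shared by experimental and synthetic workflows.

#' OCP mass fraction from XRD peak intensities
#'
#' RIR (corundum number) quantification of the DCPD -> OCP
#' transformation from the (010) OCP and (020) DCPD peak intensities:
#' `omega = (I010/RIR_OCP) / (I020/RIR_DCPD + I010/RIR_OCP)` with
#' `RIR_DCPD = 1.42` and `RIR_OCP = 0.5`.
#'
#' @param I010_ocp Intensity of the OCP (010) peak (counts, >= 0).
#' @param I020_dcpd Intensity of the DCPD (020) peak (counts, >= 0).
#' @param rir_dcpd,rir_ocp Reference intensity ratios (> 0).
#' @return OCP mass fraction in `[0, 1]`.
#' @examples
#' omega_ocp_from_intensities(100, 100)   # ~0.740
#' @export
omega_ocp_from_intensities <- function(I010_ocp, I020_dcpd,
                                       rir_dcpd = 1.42, rir_ocp = 0.5) {
  if (rir_dcpd <= 0 || rir_ocp <= 0)
    stop("reference intensity ratios must be > 0", call. = FALSE)
  if (any(I010_ocp < 0) || any(I020_dcpd < 0))
    stop("peak intensities must be >= 0", call. = FALSE)
  if (any(I010_ocp == 0 & I020_dcpd == 0))
    stop("phase fraction undefined when both intensities are zero",
         call. = FALSE)
  (I010_ocp / rir_ocp) / (I020_dcpd / rir_dcpd + I010_ocp / rir_ocp)
}
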