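# Ion-interaction corrections: ionic strength, Davies activity
# coefficients, and the empirical ionic-strength correction of pK values.

# charge registry for analytical components; Tris counted as its
# protonated (monovalent cation) form
.component_charges <- c(
  Na = 1L, K = 1L, Mg = 2L, Ca = 2L, Cl = -1L, HCO3 = -1L,
  HPO4 = -2L, H2PO4 = -1L, SO4 = -2L, Tris = 1L, TrisH = 1L
)

#' Ionic strength from analytical totals
#'
#' Classical ionic strength `I = 0.5 * sum(C_i * z_i^2)` over the charged
#' analytical components of a medium, plus an optional buffer cation
#' (protonated Tris counts as a monovalent cation).
#'
#' @param totals Named numeric vector of total concentrations in mM.
#'   Recognised names: `Na`, `K`, `Mg`, `Ca`, `Cl`, `HCO3`, `HPO4`,
#'   `H2PO4`, `SO4`, `Tris`, `TrisH`.
#' @param buffer_cation_mM Additional monovalent buffer cation (mM),
#'   e.g. protonated Tris when it is not part of `totals`.
#' @return Ionic strength in mol/L.
#' @examples
#' ionic_strength(c(Na = 1, Cl = 1))              # 0.001 M
#' ionic_strength(c(Ca = 1, Cl = 2))              # 0.003 M
#' @export
ionic_strength <- function(totals, buffer_cation_mM = 0) {
  if (any(totals < 0) || buffer_cation_mM < 0)
    stop("ionic_strength(): concentrations must be non-negative", call. = FALSE)
  nm <- names(totals)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("ionic_strength(): 'totals' must be a fully named vector", call. = FALSE)
  unknown <- setdiff(nm, names(.component_charges))
  if (length(unknown))
    stop("ionic_strength(): unknown component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  z <- .component_charges[nm]
  (0.5 * sum(totals * z^2) + 0.5 * buffer_cation_mM) / 1000
}

#' Davies activity model
#'
#' Container for the Davies extension of the Debye-Hueckel limiting law.
#' The default constant `A = 0.5231` is the 37 degC value; the model is
#' considered valid for ionic strengths of roughly 0.1-0.3 M.
#'
#' @param A Temperature-dependent Debye-Hueckel constant.
#' @param linear_term Coefficient of the linear `I` term (0.3).
#' @param validity Ionic-strength interval (M) outside which
#'   [davies_log_gamma()] emits a warning.
#' @return An object of class `cap_activity_model`.
#' @export
activity_model <- function(A = 0.5231, linear_term = 0.3,
                           validity = c(0.1, 0.3)) {
  stopifnot(A > 0, length(validity) == 2, validity[1] < validity[2])
  structure(list(A = A, linear_term = linear_term, validity = validity),
            class = "cap_activity_model")
}

#' Davies log activity coefficient
#'
#' `lg gamma = -A * z^2 * (sqrt(I)/(1 + sqrt(I)) - 0.3 * I)`.
#' The charge enters squared (the standard Davies form).
#'
#' @param z Integer ionic charge (sign is irrelevant).
#' @param I Ionic strength in mol/L.
#' @param model An [activity_model()].
#' @param warn Emit a warning when `I` lies outside the model's stated
#'   validity range (default `TRUE`).
#' @return `log10` of the activity coefficient (vectorised over `z`/`I`).
#' @examples
#' 10^davies_log_gamma(2, 0.207)  # ~0.299 at 37 degC
#' @export
davies_log_gamma <- function(z, I, model = activity_model(), warn = TRUE) {
  if (any(I < 0)) stop("ionic strength must be >= 0", call. = FALSE)
  if (warn && any(I < model$validity[1] | I > model$validity[2]))
    warning(sprintf(
      "ionic strength %.3g M outside Davies validity range [%g, %g] M",
      I[which(I < model$validity[1] | I > model$validity[2])[1]],
      model$validity[1], model$validity[2]), call. = FALSE)
  -model$A * z^2 * (sqrt(I) / (1 + sqrt(I)) - model$linear_term * I)
}

#' Ionic-strength correction of a pK value
#'
#' Empirical correction `pK' = pK0 - a*sqrt(I) + b*I` used to move
#' thermodynamic dissociation constants to working ionic strengths
#' (0.15-0.2 M). Provided as a utility for user-supplied constants; the
#' packaged equilibrium table is already conditional at I = 0.15-0.2 M
#' and is used at face value.
#'
#' @param pK0 Thermodynamic (infinite-dilution) pK.
#' @param I Ionic strength in mol/L.
#' @param a,b Correction coefficients (defaults 1.56 and 1.22).
#' @return Corrected pK'.
#' @examples
#' correct_pK(7.18, 0.18)  # ~6.74, cf. the working phosphate pK 6.7
#' @export
correct_pK <- function(pK0, I, a = 1.56, b = 1.22) {
  if (any(I < 0)) stop("ionic strength must be >= 0", call. = FALSE)
  if (a <= 0 || b <= 0) stop("correction coefficients must be > 0", call. = FALSE)
  pK0 - a * sqrt(I) + b * I
}
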