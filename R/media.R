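# Medium composition objects and the packaged SBF / DMEM fixtures.

#' Physiological medium composition
#'
#' Total (analytical) ion concentrations of a model physiological fluid,
#' together with its pH, temperature, buffer system and protein content.
#' Phosphate is entered as the dominant input form (`HPO4` for SBF-type
#' recipes, `H2PO4` for DMEM); the speciation solver treats it as total
#' inorganic phosphate.
#'
#' @param totals Named numeric vector of totals in mM. Required names:
#'   `Na`, `K`, `Mg`, `Ca`, `Cl`, `HCO3`, `SO4`, and exactly one of
#'   `HPO4` / `H2PO4`.
#' @param pH Fixed pH of the medium (the solver works at fixed pH).
#' @param temperature_K Absolute temperature; default 310.15 K (37 degC).
#' @param buffer `"tris"` (total Tris given by `tris_mM`, counted as a
#'   monovalent cation in the ionic strength) or `"carbonate"`
#'   (pH held by the CO2/bicarbonate system; no extra cation).
#' @param tris_mM Total Tris concentration when `buffer = "tris"`.
#' @param albumin_g_per_L Serum albumin mass concentration (g/L); 0
#'   disables the protein term entirely.
#' @param albumin_molar_mass Molar mass of albumin (default 66400 g/mol).
#' @return An object of class `cap_medium`.
#' @seealso [sbf_medium()], [dmem_medium()], [speciate()]
#' @export
medium <- function(totals, pH = 7.4, temperature_K = 310.15,
                   buffer = c("tris", "carbonate"), tris_mM = 0,
                   albumin_g_per_L = 0, albumin_molar_mass = 66400) {
  buffer <- match.arg(buffer)
  if (any(totals < 0)) stop("medium(): totals must be >= 0", call. = FALSE)
  if (pH < 0 || pH > 14) stop("medium(): pH must lie in [0, 14]", call. = FALSE)
  if (temperature_K <= 0) stop("medium(): temperature must be > 0", call. = FALSE)
  if (tris_mM < 0 || albumin_g_per_L < 0 || albumin_molar_mass <= 0)
    stop("medium(): negative buffer or protein specification", call. = FALSE)
  need <- c("Na", "K", "Mg", "Ca", "Cl", "HCO3", "SO4")
  missing <- setdiff(need, names(totals))
  if (length(missing))
    stop("medium(): missing totals for ", paste(missing, collapse = ", "),
         call. = FALSE)
  p_form <- intersect(c("HPO4", "H2PO4"), names(totals))
  if (length(p_form) != 1)
    stop("medium(): give total phosphate as exactly one of 'HPO4'/'H2PO4'",
         call. = FALSE)
  structure(list(
    totals = totals, phosphate_form = p_form, pH = pH,
    temperature_K = temperature_K, buffer = buffer, tris_mM = tris_mM,
    albumin_g_per_L = albumin_g_per_L,
    albumin_molar_mass = albumin_molar_mass
  ), class = "cap_medium")
}

#' @export
print.cap_medium <- function(x, ...) {
  cat("Physiological medium (pH", format(x$pH), ", T =",
      format(x$temperature_K), "K, buffer:", x$buffer, ")\n")
  print(x$totals)
  if (x$buffer == "tris") cat("Tris total:", x$tris_mM, "mM\n")
  if (x$albumin_g_per_L > 0)
    cat("Albumin:", x$albumin_g_per_L, "g/L (",
        x$albumin_molar_mass, "g/mol )\n")
  invisible(x)
}

#' Simulated body fluid (SBF) recipe
#'
#' Tris-buffered inorganic salt solution mimicking the ion totals of
#' blood plasma; the static dissolution experiments use it at pH 7.4 and
#' 37 degC. Total Tris defaults to 50 mM, which together with the salt
#' totals reproduces the working ionic strength of 0.207 M.
#'
#' @param tris_mM Total Tris (mM).
#' @return A `cap_medium`.
#' @export
sbf_medium <- function(tris_mM = 50) {
  medium(
    totals = c(Na = 142.6, K = 5.0, Mg = 1.5, Ca = 2.6, Cl = 188.1,
               HCO3 = 5.0, HPO4 = 1.0, SO4 = 0.5),
    pH = 7.4, buffer = "tris", tris_mM = tris_mM
  )
}

#' DMEM-based culture medium
#'
#' Ion totals of Dulbecco's Modified Eagle Medium, carbonate-buffered at
#' pH 7.4 under 5 % CO2. With `albumin_g_per_L = 3.2` it represents the
#' 90 % DMEM + 10 % fetal bovine serum mixture (albumin measured
#' colorimetrically at 3.2 g/L).
#'
#' @param albumin_g_per_L Albumin content; 0 for plain DMEM.
#' @return A `cap_medium`.
#' @export
dmem_medium <- function(albumin_g_per_L = 0) {
  medium(
    totals = c(Na = 153.0, K = 5.4, Mg = 0.5, Ca = 1.8, Cl = 114.4,
               HCO3 = 44.1, H2PO4 = 0.9, SO4 = 0.5),
    pH = 7.4, buffer = "carbonate", albumin_g_per_L = albumin_g_per_L
  )
}

#' @rdname dmem_medium
#' @export
dmem_fbs_medium <- function() dmem_medium(albumin_g_per_L = 3.2)

# ionic strength of a medium from its analytical totals (computed once,
# not iterated with speciation)
medium_ionic_strength <- function(m) {
  buffer_cation <- if (m$buffer == "tris") m$tris_mM else 0
  ionic_strength(m$totals, buffer_cation_mM = buffer_cation)
}
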