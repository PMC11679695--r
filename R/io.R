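# File interfaces. Concentrations are mM, masses g, areas m^2 and times
# days in every file format regardless of internal units. Media,
# protocols and fit results travel as JSON; observables and trajectories
# as CSV.

#' Read / write a medium composition (JSON)
#'
#' The JSON object holds `totals` (component -> mM), `pH`,
#' `temperature_K`, `buffer`, `tris_mM`, `albumin_g_per_L` and
#' `albumin_molar_mass`. Fixtures `sbf.json` and `dmem_fbs.json` ship
#' under `inst/extdata`.
#'
#' @param path File path.
#' @return A [medium()] (`read_medium`); invisibly `path`
#'   (`write_medium`).
#' @examples
#' sbf <- read_medium(system.file("extdata", "sbf.json", package = "capkin"))
#' @export
read_medium <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  medium(totals = unlist(x$totals), pH = x$pH,
         temperature_K = x$temperature_K %||% 310.15,
         buffer = x$buffer, tris_mM = x$tris_mM %||% 0,
         albumin_g_per_L = x$albumin_g_per_L %||% 0,
         albumin_molar_mass = x$albumin_molar_mass %||% 66400)
}

#' @param med A [medium()].
#' @rdname read_medium
#' @export
write_medium <- function(med, path) {
  stopifnot(inherits(med, "cap_medium"))
  jsonlite::write_json(list(
    totals = as.list(med$totals), pH = med$pH,
    temperature_K = med$temperature_K, buffer = med$buffer,
    tris_mM = med$tris_mM, albumin_g_per_L = med$albumin_g_per_L,
    albumin_molar_mass = med$albumin_molar_mass
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a protocol (JSON)
#'
#' @param path File path.
#' @return A [protocol()] (`read_protocol`); invisibly `path`
#'   (`write_protocol`).
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  protocol(
    solution_to_sample_mass_ratio = x$solution_to_sample_mass_ratio,
    solution_density = x$solution_density,
    duration_days = x$duration_days,
    exchange_fraction = x$exchange_fraction,
    exchange_period_days = x$exchange_period_days,
    pH_mode = x$pH_mode, fixed_pH = x$fixed_pH,
    surface_area_mode = x$surface_area_mode,
    s2_seed_fraction = x$s2_seed_fraction %||% 1e-3,
    tris_pKa = x$tris_pKa %||% 7.72,
    solution_volume_mL = x$solution_volume_mL
  )
}

#' @param prot A [protocol()].
#' @rdname read_protocol
#' @export
write_protocol <- function(prot, path) {
  stopifnot(inherits(prot, "cap_protocol"))
  jsonlite::write_json(prot[!vapply(prot, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write observable series (CSV)
#'
#' Columns `kind`, `t_days`, `value`, `sd`, `role`.
#'
#' @param path File path.
#' @return A `cap_observables` data frame (`read_observables`);
#'   invisibly `path` (`write_observables`).
#' @export
read_observables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "t_days", "value", "sd", "role")
  if (!all(need %in% names(df)))
    stop("observables CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$kind), .obs_kinds)
  if (length(bad))
    stop("unknown observable kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(df[need], class = c("cap_observables", "data.frame"))
}

#' @param obs A `cap_observables` data frame.
#' @rdname read_observables
#' @export
write_observables <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a trajectory (CSV)
#'
#' @param path File path.
#' @return A data frame (`read_trajectory`); invisibly `path`
#'   (`write_trajectory`).
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @param traj A `cap_trajectory`.
#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write a fit result (JSON)
#'
#' @param fit A `cap_fit`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "cap_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
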