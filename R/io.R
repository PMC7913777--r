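# Readers and writers for the package's plain-text formats: scan CSV files
# with '#'-prefixed metadata headers, pH-series CSV tables, YAML species and
# network definitions, and schema-versioned JSON fit results.

.SCAN_HEADER_KEYS <- c("rotor_rpm", "wavelength_nm", "channel",
                       "meniscus_cm", "bottom_cm")

#' Read an absorbance scan from CSV
#'
#' The dialect is a set of `# key: value` header lines (`rotor_rpm`,
#' `wavelength_nm`, `channel`, `meniscus_cm`, `bottom_cm`, and optionally
#' `time_s` for velocity scans) followed by `radius_cm,absorbance` rows.
#'
#' @param path File path.
#' @return An [se_scan].
#' @export
read_scan_csv <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in .SCAN_HEADER_KEYS)
    if (is.null(meta[[key]]))
      stop("scan file ", path, " is missing required header '# ", key, ":'")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (identical(tolower(gsub("\\s", "", body[1])), "radius_cm,absorbance"))
    body <- body[-1]
  d <- utils::read.csv(text = paste(body, collapse = "\n"),
                       header = FALSE, col.names = c("radius", "absorbance"))
  if (any(diff(d$radius) <= 0))
    stop("scan file ", path, ": radii are not strictly increasing")
  se_scan(d$radius, d$absorbance,
          rotor_speed = as.numeric(meta$rotor_rpm),
          meniscus = as.numeric(meta$meniscus_cm),
          bottom = as.numeric(meta$bottom_cm),
          wavelength = as.numeric(meta$wavelength_nm),
          channel = meta$channel,
          time = if (!is.null(meta$time_s)) as.numeric(meta$time_s)
                 else NA_real_)
}

#' Write an absorbance scan to CSV
#'
#' @param scan An [se_scan].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "se_scan"))
  con <- file(path, "wb")   # binary mode: LF endings on every platform
  on.exit(close(con))
  hdr <- c(sprintf("# rotor_rpm: %s", format(scan$rotor_speed)),
           sprintf("# wavelength_nm: %s", format(scan$wavelength)),
           sprintf("# channel: %s", scan$channel),
           sprintf("# meniscus_cm: %s", format(scan$meniscus)),
           sprintf("# bottom_cm: %s", format(scan$bottom)))
  if (!is.na(scan$time)) hdr <- c(hdr, sprintf("# time_s: %s",
                                               format(scan$time)))
  writeLines(c(hdr, "radius_cm,absorbance",
               sprintf("%.6f,%.8g", scan$radii, scan$absorbance)),
             con, sep = "\n")
  invisible(path)
}

#' Read a (pH, L_obs) series from CSV
#'
#' Columns: `pH`, `L_obs` (M^-1), optional `SE` and `upper_limit` (0/1).
#'
#' @param path File path.
#' @return Data frame ready for [fit_linkage].
#' @export
read_ph_series_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("pH", "L_obs") %in% names(d)), all(d$L_obs > 0))
  if (any(diff(d$pH) <= 0)) stop("pH values must be strictly increasing")
  if (!is.null(d$upper_limit)) d$upper_limit <- as.logical(d$upper_limit)
  d
}

#' Read species definitions from YAML
#'
#' Each entry carries `name`, `mass_kDa`, `vbar_ml_g`, and optionally
#' `s_S`, `eps_230` and `vbar_sequence_ml_g` (calculated-from-sequence
#' alternative).
#'
#' @param path YAML file; defaults to the packaged species table.
#' @return List of [species] objects, named.
#' @export
read_species_yaml <- function(path = system.file("extdata",
                                                 "species_paper.yaml",
                                                 package = "sedlink")) {
  y <- yaml::read_yaml(path)
  out <- lapply(y$species, function(e)
    species(e$name, molar_mass = e$mass_kDa, vbar = e$vbar_ml_g,
            s = if (!is.null(e$s_S)) e$s_S else NA_real_,
            extinction = if (!is.null(e$eps_230)) e$eps_230 else 0))
  names(out) <- vapply(out, function(s) s$name, "")
  out
}

#' Read a reaction-network definition from YAML
#'
#' Keys mirror the assembly scheme: `L_obs`, `K2`, `K3`, `K4`, `k_off`, and
#' an optional `species` block overriding [scheme_species_table] columns.
#'
#' @param path YAML file.
#' @return A [reaction_network].
#' @export
read_network_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- scheme_species_table()
  if (!is.null(y$species)) {
    for (e in y$species) {
      i <- match(e$name, sp$name)
      if (is.na(i)) stop("unknown species '", e$name, "' in ", path)
      for (f in c("molar_mass", "vbar", "s", "extinction"))
        if (!is.null(e[[f]])) sp[i, f] <- e[[f]]
    }
  }
  reaction_network(L_obs = y$L_obs, K2 = if (is.null(y$K2)) 10 else y$K2,
                   K3 = y$K3, K4 = y$K4,
                   k_off = if (is.null(y$k_off)) 0.01 else y$k_off,
                   species = sp)
}

#' Serialize a fit result to schema-versioned JSON
#'
#' Works for `se_fit`, `linkage_fit`, `itc_fit` and `cs_fit` objects;
#' writes coefficients, standard errors and per-scan/point RMSD at full
#' double precision.
#'
#' @param fit A fit object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(fit, path) {
  payload <- list(schema_version = "sedlink-result-1",
                  class = class(fit)[1])
  if (!is.null(fit$coefficients)) {
    payload$parameters <- as.list(fit$coefficients)
    payload$standard_errors <- as.list(fit$se)
  }
  if (!is.null(fit$rmsd)) payload$rmsd <- fit$rmsd
  if (inherits(fit, "cs_fit")) {
    payload$s_grid <- fit$s
    payload$c_of_s <- fit$c_of_s
  }
  if (!is.null(fit$converged)) payload$converged <- fit$converged
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a result JSON written by [write_result_json]
#'
#' @param path File path.
#' @return Parsed list.
#' @export
read_result_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(out$schema_version))
    stop("not a sedlink result file (no schema_version)")
  out
}
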