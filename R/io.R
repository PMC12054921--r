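## Delimited-text dialect used by every table in the project: comma
## separated, '.' decimal, '#' comment lines, UTF-8, one header line with
## unit-carrying column names.

read_project_table <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) < 2L) stop("no data rows in ", path)
  header <- trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  missing <- setdiff(expected_cols, header)
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path)
  idx <- match(expected_cols, header)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(f) < length(header))
      stop("malformed row at line ", lineno[i], " of ", path)
    v <- suppressWarnings(as.numeric(f[idx]))
    if (anyNA(v))
      stop("non-numeric value at line ", lineno[i], " of ", path)
    v
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- expected_cols
  out
}

write_project_table <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(names(df), collapse = ","), con)
  cols <- lapply(df, function(col)
    format(col, digits = 15, scientific = FALSE, trim = TRUE))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Read and write dispersion tables (complex refractive index)
#'
#' Dispersion tables are comma-separated text with a header line and columns
#' `wavenumber_cm-1`, `n_real`, `n_imag`; lines starting with `#` are
#' comments.  Rows are sorted by wavenumber on read; duplicate wavenumbers
#' and negative `n_imag` (a passivity violation) are rejected.
#'
#' @param path file path.
#' @param n a [refractive_index_spectrum()].
#' @param comments character vector of comment lines to write above the
#'   header.
#' @return `read_dispersion_table()` returns a
#'   [refractive_index_spectrum()]; the writer returns the path invisibly.
#' @export
read_dispersion_table <- function(path) {
  df <- read_project_table(path, c("wavenumber_cm-1", "n_real", "n_imag"))
  df <- df[order(df[["wavenumber_cm-1"]]), ]
  if (anyDuplicated(df[["wavenumber_cm-1"]]))
    stop("duplicate wavenumbers in ", path)
  if (any(df$n_imag < 0))
    stop("negative n_imag in ", path, " (passivity violation)")
  refractive_index_spectrum(df[["wavenumber_cm-1"]], df$n_real, df$n_imag)
}

#' @rdname read_dispersion_table
#' @export
write_dispersion_table <- function(n, path, comments = character()) {
  stopifnot(inherits(n, "refractive_index_spectrum"))
  write_project_table(
    data.frame(`wavenumber_cm-1` = as.numeric(n$grid),
               n_real = n$n_real, n_imag = n$n_imag, check.names = FALSE),
    path, c("complex refractive index; wavenumber in cm^-1", comments))
}

#' Read and write extinction tables
#'
#' Columns `wavenumber_cm-1`, `qext`; same dialect as
#' [read_dispersion_table()].  Negative `qext` is rejected (passivity).
#'
#' @param path file path.
#' @param qext an [extinction_spectrum()].
#' @param comments comment lines for the writer.
#' @return the reader returns an [extinction_spectrum()].
#' @export
read_extinction_table <- function(path) {
  df <- read_project_table(path, c("wavenumber_cm-1", "qext"))
  df <- df[order(df[["wavenumber_cm-1"]]), ]
  if (anyDuplicated(df[["wavenumber_cm-1"]]))
    stop("duplicate wavenumbers in ", path)
  if (any(df$qext < 0))
    stop("negative qext in ", path, " (passivity violation)")
  extinction_spectrum(df[["wavenumber_cm-1"]], df$qext)
}

#' @rdname read_extinction_table
#' @export
write_extinction_table <- function(qext, path, comments = character()) {
  stopifnot(inherits(qext, "extinction_spectrum"))
  write_project_table(
    data.frame(`wavenumber_cm-1` = as.numeric(qext$grid),
               qext = qext$qext, check.names = FALSE),
    path, c("extinction efficiency of a homogeneous sphere", comments))
}

#' Read and write permittivity tables
#'
#' Columns `wavenumber_cm-1`, `eps_real`, `eps_imag`.
#'
#' @param path file path.
#' @param eps a [dielectric_spectrum()].
#' @param comments comment lines for the writer.
#' @return the reader returns a [dielectric_spectrum()].
#' @export
read_dielectric_table <- function(path) {
  df <- read_project_table(path, c("wavenumber_cm-1", "eps_real", "eps_imag"))
  df <- df[order(df[["wavenumber_cm-1"]]), ]
  if (anyDuplicated(df[["wavenumber_cm-1"]]))
    stop("duplicate wavenumbers in ", path)
  if (any(df$eps_imag < 0))
    stop("negative eps_imag in ", path, " (passivity violation)")
  dielectric_spectrum(df[["wavenumber_cm-1"]], df$eps_real, df$eps_imag)
}

#' @rdname read_dielectric_table
#' @export
write_dielectric_table <- function(eps, path, comments = character()) {
  stopifnot(inherits(eps, "dielectric_spectrum"))
  write_project_table(
    data.frame(`wavenumber_cm-1` = as.numeric(eps$grid),
               eps_real = eps$eps_real, eps_imag = eps$eps_imag,
               check.names = FALSE),
    path, c("complex relative permittivity; wavenumber in cm^-1", comments))
}

#' Read and write absorbance tables
#'
#' Columns `wavenumber_cm-1`, `absorbance`.  The detector geometry ratio
#' `G/g` is recorded in a header comment so that the extinction efficiency
#' can be recovered losslessly on read.
#'
#' @param path file path.
#' @param A an [absorbance_spectrum()].
#' @param geom a [detector_geometry()].
#' @param comments extra comment lines for the writer.
#' @return the reader returns a list with `absorbance` (an
#'   [absorbance_spectrum()]) and `G_over_g` (the recorded ratio, `NA` if
#'   the file carries none).
#' @export
write_absorbance_table <- function(A, geom, path, comments = character()) {
  stopifnot(inherits(A, "absorbance_spectrum"),
            inherits(geom, "detector_geometry"))
  write_project_table(
    data.frame(`wavenumber_cm-1` = as.numeric(A$grid),
               absorbance = A$absorbance, check.names = FALSE),
    path, c("apparent (decadic) absorbance",
            sprintf("G_over_g,%.17g", geom$G / geom$g), comments))
}

#' @rdname write_absorbance_table
#' @export
read_absorbance_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  ratio_line <- grep("^# G_over_g,", raw, value = TRUE)
  ratio <- if (length(ratio_line))
    as.numeric(sub("^# G_over_g,", "", ratio_line[1L])) else NA_real_
  df <- read_project_table(path, c("wavenumber_cm-1", "absorbance"))
  df <- df[order(df[["wavenumber_cm-1"]]), ]
  if (anyDuplicated(df[["wavenumber_cm-1"]]))
    stop("duplicate wavenumbers in ", path)
  list(absorbance = absorbance_spectrum(df[["wavenumber_cm-1"]],
                                        df$absorbance),
       G_over_g = ratio)
}

#' Serialize an oscillator set to JSON (and back)
#'
#' Flat JSON record `{eps_inf, bands: [{nu0, nup, gamma}, ...]}` with all
#' wavenumber-like quantities in cm^-1; round-trips are bit-stable for the
#' decimal representation written (`digits = NA`, i.e. full precision).
#'
#' @param set an [oscillator_set()].
#' @param path file path.
#' @return the reader returns an [oscillator_set()].
#' @export
write_oscillator_set <- function(set, path) {
  stopifnot(inherits(set, "oscillator_set"))
  # I(17) significant digits: enough to reproduce every double exactly
  jsonlite::write_json(list(eps_inf = set$eps_inf, bands = set$bands),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_oscillator_set
#' @export
read_oscillator_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$eps_inf) || is.null(x$bands))
    stop("not an oscillator-set record: ", path)
  oscillator_set(x$bands$nu0, x$bands$nup, x$bands$gamma,
                 eps_inf = x$eps_inf)
}

#' Write a complete fit bundle
#'
#' Writes the standard result artifact of a fit: a parameter table
#' (`<prefix>_params.csv`: columns `m`, `nu0`, `nup`, `gamma`), the
#' reconstructed spectra on the fitted grid
#' (`<prefix>_spectra.csv`: permittivity and refractive index, plus the
#' model Qext when the fit was an inversion), and a JSON summary
#' (`<prefix>_summary.json`: objective, convergence, config echo, matching
#' report when a truth is supplied).
#'
#' @param fit a `fit_result` from [reconstruct_from_qext()] or
#'   [fit_permittivity_direct()] (dielectric basis).
#' @param prefix output path prefix.
#' @param truth optional [oscillator_set()]; adds a [match_bands()] report
#'   to the summary.
#' @return character vector of the files written, invisibly.
#' @export
write_fit_bundle <- function(fit, prefix, truth = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$basis != "dielectric")
    stop("fit bundles are defined for the dielectric basis")
  b <- fit$params$bands
  params_path <- paste0(prefix, "_params.csv")
  write_project_table(
    data.frame(m = seq_len(nrow(b)), nu0 = b$nu0, nup = b$nup,
               gamma = b$gamma),
    params_path,
    c("optimized oscillator parameters (cm^-1)",
      sprintf("eps_inf,%.17g", fit$params$eps_inf)))

  grid <- fit$model_spectrum$grid
  eps <- eval_permittivity(fit$params, grid)
  nn <- eps_to_n(eps)
  spectra <- data.frame(`wavenumber_cm-1` = as.numeric(grid),
                        eps_real = eps$eps_real, eps_imag = eps$eps_imag,
                        n_real = nn$n_real, n_imag = nn$n_imag,
                        check.names = FALSE)
  if (inherits(fit$model_spectrum, "extinction_spectrum"))
    spectra$qext_model <- fit$model_spectrum$qext
  spectra_path <- paste0(prefix, "_spectra.csv")
  write_project_table(spectra, spectra_path, "reconstructed optical constants")

  summary_path <- paste0(prefix, "_summary.json")
  summ <- list(objective_S = fit$objective_S,
               initial_S = fit$initial_S,
               converged = fit$converged,
               n_evals = fit$n_evals, n_iter = fit$n_iter,
               basis = fit$basis,
               eps_inf = fit$params$eps_inf,
               config = config_echo(fit$config))
  if (!is.null(truth)) {
    mb <- match_bands(fit$params, truth)
    summ$matching <- list(pairs = mb$pairs,
                          n_unmatched_truth = mb$n_unmatched_truth,
                          n_unmatched_fitted = mb$n_unmatched_fitted,
                          n_discarded = mb$n_discarded)
  }
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(params_path, spectra_path, summary_path))
}

config_echo <- function(config) {
  out <- unclass(config)
  out$explicit_init <- if (is.null(out$explicit_init)) NULL else
    list(eps_inf = out$explicit_init$eps_inf, bands = out$explicit_init$bands)
  out
}

#' Read a fit bundle's parameter table back as an oscillator set
#'
#' @param prefix the prefix passed to [write_fit_bundle()].
#' @return an [oscillator_set()].
#' @export
read_fit_params <- function(prefix) {
  path <- paste0(prefix, "_params.csv")
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  eps_line <- grep("^# eps_inf,", raw, value = TRUE)
  if (!length(eps_line)) stop("no eps_inf record in ", path)
  eps_inf <- as.numeric(sub("^# eps_inf,", "", eps_line[1L]))
  df <- read_project_table(path, c("m", "nu0", "nup", "gamma"))
  oscillator_set(df$nu0, df$nup, df$gamma, eps_inf = eps_inf)
}
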