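#' Default instrument-log column mapping
#'
#' Standard LI-6400-style header names. Every entry can be overridden; only
#' `area`, `photo` and `cond` are mandatory in a log.
#'
#' @return A named character vector mapping roles to header names.
#' @export
default_column_map <- function() {
  c(area = "Area", photo = "Photo", cond = "Cond", trans = "Trmmol",
    ci = "Ci", phipsii = "PhiPS2", label = "Obs")
}

mandatory_roles <- c("area", "photo", "cond")

#' Read a gas-exchange instrument log
#'
#' Tolerates the usual export dialect: banner lines before the header, tab or
#' comma delimiters. The header is the first line whose fields contain all
#' mandatory mapped columns (area, net photosynthesis, stomatal conductance).
#' Original columns and their order are preserved; a `.row` column records
#' the source data-row number for audit.
#'
#' @param path Path to a tab- or comma-delimited log.
#' @param column_map Named character vector; see [default_column_map()].
#' @return A tibble with the log's columns plus `.row`; the resolved
#'   `column_map` is attached as an attribute.
#' @export
read_gas_log <- function(path, column_map = default_column_map()) {
  column_map <- utils::modifyList(as.list(default_column_map()),
                                  as.list(column_map))
  lines <- readLines(path, warn = FALSE)
  need <- unlist(column_map[mandatory_roles])
  header_at <- NA_integer_; delim <- NA_character_
  for (i in seq_along(lines)) {
    for (d in c("\t", ",")) {
      fields <- trimws(strsplit(lines[i], d, fixed = TRUE)[[1]])
      if (all(need %in% fields)) { header_at <- i; delim <- d; break }
    }
    if (!is.na(header_at)) break
  }
  if (is.na(header_at)) {
    found <- paste(utils::head(unique(unlist(
      strsplit(lines[seq_len(min(5, length(lines)))], "[\t,]"))), 20),
      collapse = ", ")
    stop("schema error: no header row with mandatory columns (",
         paste(need, collapse = ", "), "); found fields: ", found,
         call. = FALSE)
  }
  out <- readr::read_delim(path, delim = delim, skip = header_at - 1L,
                           show_col_types = FALSE, progress = FALSE)
  out <- tibble::as_tibble(out)
  out$.row <- seq_len(nrow(out))
  attr(out, "column_map") <- column_map
  out
}

#' Intrinsic water-use efficiency
#'
#' The ratio of net photosynthesis to stomatal conductance, P_N / g_s
#' (umol CO2 mol^-1 H2O). Both rates are per unit leaf area, so iWUE is
#' invariant to any area correction.
#'
#' @param photo_PN Net photosynthesis, umol CO2 m^-2 s^-1.
#' @param cond_gs Stomatal conductance, mol H2O m^-2 s^-1; must be > 0.
#' @return iWUE, same length as the inputs.
#' @examples
#' iwue(10, 0.2) # 50
#' @export
iwue <- function(photo_PN, cond_gs) {
  if (any(!is.finite(cond_gs)) || any(cond_gs <= 0)) {
    stop("undefined-iwue: stomatal conductance must be > 0", call. = FALSE)
  }
  photo_PN / cond_gs
}

resolve_map <- function(data, column_map) {
  map <- attr(data, "column_map")
  if (is.null(map)) map <- as.list(default_column_map())
  map <- utils::modifyList(map, as.list(column_map))
  missing <- unlist(map[mandatory_roles])[!unlist(map[mandatory_roles]) %in% names(data)]
  if (length(missing)) {
    stop("schema error: mandatory column(s) not in data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  map
}

#' Correct per-area gas exchange rates for the true enclosed leaf area
#'
#' The instrument divides molar fluxes by the assumed area S (normally the
#' full gasket aperture). When only `A_L` of leaf was actually enclosed,
#' every per-area rate must be rescaled by the factor S / A_L. The rescaling
#' is applied uniformly to net photosynthesis, stomatal conductance and
#' transpiration; intercellular CO2 and PSII operating efficiency are carried
#' through unchanged (fluorescence ratios are area-independent; Ci is left as
#' reported and flagged). iWUE is reported before and after — it is invariant
#' because numerator and denominator rescale identically.
#'
#' @param data A tibble of log records (e.g. from [read_gas_log()]).
#' @param area The true enclosed area(s) A_L: a single value, a vector with
#'   one value per row, or a data frame with columns `label` and either
#'   `AL_cm2` or `width_cm` (widths are converted via [width_based_area()]),
#'   joined to the log's label column.
#' @param gasket Gasket used to convert widths to areas.
#' @param column_map Overrides for [default_column_map()].
#' @return The input tibble with appended columns `AL_cm2`, `corr_factor`,
#'   `<rate>_corr` for each present rate column, `iWUE` and `iWUE_corr`.
#'   The attribute `ci_uncorrected` is `TRUE` when a Ci column was carried.
#' @examples
#' log <- synth_gas_log(4, seed = 1)$log
#' correct_gas_exchange(log, area = 1.2)
#' @export
correct_gas_exchange <- function(data, area, gasket = gasket_preset("6400-40"),
                                 column_map = list()) {
  map <- resolve_map(data, column_map)
  S <- data[[map$area]]
  al <- resolve_areas(data, area, gasket, map)
  if (any(!is.finite(al)) || any(al <= 0)) {
    stop("invalid-area: A_L must be positive for every row", call. = FALSE)
  }
  if (any(al > S * (1 + 1e-6))) {
    stop("oversized-area error: A_L exceeds the assumed area S on ",
         sum(al > S * (1 + 1e-6)), " row(s); the leaf cannot exceed the gasket",
         call. = FALSE)
  }
  out <- data
  out$AL_cm2 <- al
  out$corr_factor <- S / al
  for (role in c("photo", "cond", "trans")) {
    col <- map[[role]]
    if (!is.null(col) && col %in% names(out)) {
      out[[paste0(col, "_corr")]] <- out[[col]] * out$corr_factor
    }
  }
  out$iWUE <- out[[map$photo]] / out[[map$cond]]
  out$iWUE_corr <- out[[paste0(map$photo, "_corr")]] /
    out[[paste0(map$cond, "_corr")]]
  attr(out, "column_map") <- map
  attr(out, "ci_uncorrected") <- !is.null(map$ci) && map$ci %in% names(out)
  out
}

resolve_areas <- function(data, area, gasket, map) {
  if (is.data.frame(area)) {
    lab_col <- map$label
    if (is.null(lab_col) || !lab_col %in% names(data)) {
      stop("join error: log has no label column '", lab_col,
           "' to join areas by", call. = FALSE)
    }
    if (!"label" %in% names(area)) {
      stop("join error: area table needs a 'label' column", call. = FALSE)
    }
    if ("width_cm" %in% names(area)) {
      area$AL_cm2 <- width_based_area(area$width_cm, gasket = gasket)
    }
    if (!"AL_cm2" %in% names(area)) {
      stop("join error: area table needs 'AL_cm2' or 'width_cm'", call. = FALSE)
    }
    key <- match(data[[lab_col]], area$label)
    if (anyNA(key)) {
      stop("join error: no area for label(s): ",
           paste(unique(data[[lab_col]][is.na(key)]), collapse = ", "),
           call. = FALSE)
    }
    extra <- setdiff(area$label, data[[lab_col]])
    if (length(extra)) {
      stop("join error: area label(s) absent from the log: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    return(area$AL_cm2[key])
  }
  if (is.numeric(area)) {
    if (length(area) == 1L) return(rep(area, nrow(data)))
    if (length(area) == nrow(data)) return(area)
    stop("invalid-area: need one A_L value, or one per row", call. = FALSE)
  }
  stop("invalid-area: `area` must be numeric or a label/area data frame",
       call. = FALSE)
}

#' Correct a whole instrument log file
#'
#' Batch form of [correct_gas_exchange()]: reads the log, resolves one A_L
#' per row (constant, per-row vector, or a label-keyed width/area table),
#' appends the corrected columns, and summarises the correction. Output files
#' are written atomically (temp file, then rename) and the source log is
#' never touched.
#'
#' @param log Path to an instrument log, or an already-read tibble.
#' @inheritParams correct_gas_exchange
#' @param out Optional path for the corrected tab-delimited table.
#' @param report Optional path for the tab-delimited summary report.
#' @return An object of class `corrected_log`: list with `data` (the
#'   corrected tibble) and `report` (one-row tibble with n and the
#'   min/median/max correction factor and the per-area error each row would
#'   have incurred uncorrected).
#' @export
correct_log <- function(log, area, gasket = gasket_preset("6400-40"),
                        column_map = list(), out = NULL, report = NULL) {
  data <- if (is.character(log)) read_gas_log(log, column_map = column_map)
          else tibble::as_tibble(log)
  corrected <- correct_gas_exchange(data, area, gasket = gasket,
                                    column_map = column_map)
  err <- 100 * (corrected$corr_factor - 1)  # error had the row gone uncorrected
  rep_tbl <- tibble::tibble(
    n = nrow(corrected),
    min_factor = min(corrected$corr_factor),
    median_factor = stats::median(corrected$corr_factor),
    max_factor = max(corrected$corr_factor),
    min_uncorrected_error_pct = min(err),
    median_uncorrected_error_pct = stats::median(err),
    max_uncorrected_error_pct = max(err)
  )
  if (!is.null(out)) write_atomic_tsv(corrected, out)
  if (!is.null(report)) write_atomic_tsv(rep_tbl, report)
  structure(list(data = corrected, report = rep_tbl), class = "corrected_log")
}

write_atomic_tsv <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  readr::write_tsv(x, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @export
print.corrected_log <- function(x, ...) {
  cat(sprintf("<corrected_log> %d rows; correction factor %.3f-%.3f (median %.3f)\n",
              x$report$n, x$report$min_factor, x$report$max_factor,
              x$report$median_factor))
  invisible(x)
}

#' @importFrom generics glance
#' @method glance corrected_log
#' @export
glance.corrected_log <- function(x, ...) x$report

#' @importFrom generics tidy
#' @method tidy corrected_log
#' @export
tidy.corrected_log <- function(x, ...) x$data
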