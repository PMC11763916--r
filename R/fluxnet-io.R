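#' Default FLUXNET2015 FULLSET column mapping
#'
#' Maps the canonical variable names used throughout this package to the
#' FLUXNET2015 FULLSET column names of the half-hourly product. Users working
#' with another product variant (e.g. CUT instead of VUT, DT instead of NT
#' partitioning) can pass a modified copy to [read_fluxnet_hh()].
#'
#' @return Named character vector: names are canonical variable names, values
#'   are FLUXNET2015 column names.
#' @examples
#' fluxnet_column_map()[["le"]]
#' @export
fluxnet_column_map <- function() {
  c(
    le        = "LE_F_MDS",
    nee       = "NEE_VUT_REF",
    reco      = "RECO_NT_VUT_REF",
    gpp       = "GPP_NT_VUT_REF",
    ta        = "TA_F",
    vpd       = "VPD_F",
    netrad    = "NETRAD",
    precip    = "P_F",
    co2       = "CO2_F_MDS",
    swc       = "SWC_F_MDS_1",
    sw_in_pot = "SW_IN_POT"
  )
}

FLUXNET_MISSING <- -9999

#' Read a FLUXNET2015-dialect half-hourly CSV
#'
#' Parses one site's half-hourly (30-min) record table. `TIMESTAMP_START` is
#' interpreted as the interval start in local standard time (`YYYYMMDDHHMM`);
#' each interval is half-open, `[start, start + 30 min)`. The missing-value
#' sentinel `-9999` is decoded to `NA`. Mapped columns are renamed to canonical
#' names; unmapped data columns are dropped with a warning.
#'
#' @param path Path to the CSV file.
#' @param site_id Site code attached to every record (e.g. `"CN-Dan"`).
#' @param column_map Named character vector as returned by
#'   [fluxnet_column_map()]. Entries whose column is absent from the file are
#'   silently treated as missing variables.
#' @return A tibble with `site_id`, `timestamp` (POSIXct, UTC-encoded local
#'   standard time), `date`, and one column per mapped variable.
#' @export
read_fluxnet_hh <- function(path, site_id, column_map = fluxnet_column_map()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (!"TIMESTAMP_START" %in% names(raw)) {
    abort("Not a FLUXNET half-hourly table: column TIMESTAMP_START is absent.")
  }
  present <- column_map[column_map %in% names(raw)]
  if (!"le" %in% names(present)) {
    abort("Not a usable half-hourly table: no LE column found under the given column map.")
  }
  known <- c("TIMESTAMP_START", "TIMESTAMP_END", unname(column_map))
  extra <- setdiff(names(raw), known)
  extra <- extra[!grepl("_QC$", extra)]
  if (length(extra) > 0) {
    warn(paste0("Ignoring unmapped column(s): ", paste(extra, collapse = ", ")))
  }

  ts <- as.POSIXct(strptime(sprintf("%012.0f", as.numeric(raw$TIMESTAMP_START)),
                            format = "%Y%m%d%H%M", tz = "UTC"))
  if (anyNA(ts)) abort("Unparseable TIMESTAMP_START values found.")
  if (anyDuplicated(ts)) abort("Duplicate TIMESTAMP_START values: file fails integrity check.")
  if (is.unsorted(ts)) abort("TIMESTAMP_START values are not increasing.")

  out <- tibble(site_id = site_id, timestamp = ts,
                date = as.Date(ts, tz = "UTC"))
  for (canon in names(present)) {
    v <- raw[[present[[canon]]]]
    v[!is.na(v) & v == FLUXNET_MISSING] <- NA_real_
    out[[canon]] <- as.numeric(v)
  }
  out
}

#' Write half-hourly records as a FLUXNET2015-dialect CSV
#'
#' Inverse of [read_fluxnet_hh()]: canonical columns are renamed through
#' `column_map`, timestamps are formatted as `YYYYMMDDHHMM`, and `NA` is
#' encoded as `-9999`. Reading the file back yields identical decoded values.
#'
#' @param records Tibble from [read_fluxnet_hh()] or the synthetic generator.
#' @param path Output file path.
#' @inheritParams read_fluxnet_hh
#' @return `path`, invisibly.
#' @export
write_fluxnet_hh <- function(records, path, column_map = fluxnet_column_map()) {
  stop_if_missing_cols(records, c("timestamp", "le"), "half-hourly records")
  out <- tibble(
    TIMESTAMP_START = format(records$timestamp, "%Y%m%d%H%M", tz = "UTC"),
    TIMESTAMP_END   = format(records$timestamp + 1800, "%Y%m%d%H%M", tz = "UTC")
  )
  for (canon in names(column_map)) {
    if (canon %in% names(records)) {
      v <- records[[canon]]
      v[is.na(v)] <- FLUXNET_MISSING
      out[[column_map[[canon]]]] <- v
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# IGBP land-cover code -> analysis group. Forests collapse to "forest",
# croplands to "cropland", everything else (shrubland, savanna, grassland,
# wetland, ...) to "other".
IGBP_GROUP <- c(
  ENF = "forest", EBF = "forest", DNF = "forest", DBF = "forest", MF = "forest",
  CRO = "cropland", CVM = "cropland",
  GRA = "other", SAV = "other", WSA = "other", OSH = "other", CSH = "other",
  WET = "other", SNO = "other", BSV = "other", URB = "other", WAT = "other"
)

#' Land-cover analysis group for an IGBP class
#'
#' @param igbp_class Character vector of IGBP codes (e.g. `"ENF"`, `"GRA"`).
#' @return Character vector in `{"forest", "cropland", "other"}`; unknown codes
#'   map to `"other"` with a warning.
#' @export
igbp_group <- function(igbp_class) {
  out <- unname(IGBP_GROUP[toupper(igbp_class)])
  if (anyNA(out)) {
    warn(paste0("Unknown IGBP code(s) mapped to 'other': ",
                paste(unique(igbp_class[is.na(out)]), collapse = ", ")))
    out[is.na(out)] <- "other"
  }
  out
}

#' Climate zone from latitude
#'
#' Assigns the four latitude-band climate zones used throughout the analysis:
#' tropical (|lat| 0–23), subtropical (23–35), temperate (35–60), boreal
#' (above 60). Band edges belong to the equatorward zone.
#'
#' @param latitude Numeric vector of latitudes in degrees.
#' @return Character vector in
#'   `{"tropical", "subtropical", "temperate", "boreal"}`.
#' @examples
#' climate_zone(c(0, 30.5, 45, 65))
#' @export
climate_zone <- function(latitude) {
  if (any(abs(latitude) > 90, na.rm = TRUE)) {
    abort("latitude outside [-90, 90]")
  }
  a <- abs(latitude)
  dplyr::case_when(
    a <= 23 ~ "tropical",
    a <= 35 ~ "subtropical",
    a <= 60 ~ "temperate",
    TRUE    ~ "boreal"
  )
}

#' Read a site-metadata table
#'
#' Reads (or accepts) a table with `site_id`, `latitude`, `longitude` and
#' `igbp_class`, validates the coordinates, and derives the `climate_zone`
#' latitude band, the `group` land-cover class and the `hemisphere`
#' (eastern for longitude >= 0).
#'
#' @param path A CSV file path, or a data frame already holding the columns.
#' @return A tibble of site metadata with derived columns.
#' @export
read_site_metadata <- function(path) {
  meta <- if (is.data.frame(path)) as_tibble(path) else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  stop_if_missing_cols(meta, c("site_id", "latitude", "longitude", "igbp_class"),
                       "site metadata")
  if (any(abs(meta$latitude) > 90, na.rm = TRUE)) {
    abort("site metadata: latitude outside [-90, 90]")
  }
  if (any(abs(meta$longitude) > 180, na.rm = TRUE)) {
    abort("site metadata: longitude outside [-180, 180]")
  }
  meta |>
    mutate(
      climate_zone = climate_zone(.data$latitude),
      group = igbp_group(.data$igbp_class),
      hemisphere = ifelse(.data$longitude >= 0, "eastern", "western")
    )
}

#' Reshape half-hourly records to normalized long format
#'
#' @param records Tibble from [read_fluxnet_hh()].
#' @return Tibble with columns `site_id`, `timestamp`, `variable`, `value`.
#' @export
fluxnet_long <- function(records) {
  tidyr::pivot_longer(records,
                      cols = -dplyr::any_of(c("site_id", "timestamp", "date")),
                      names_to = "variable", values_to = "value") |>
    select("site_id", "timestamp", "variable", "value")
}

#' Check that every record's site appears in the metadata
#'
#' @param records Tibble with a `site_id` column.
#' @param metadata Tibble from [read_site_metadata()].
#' @return `records`, invisibly; orphan site ids trigger a warning.
#' @export
check_site_coverage <- function(records, metadata) {
  orphans <- setdiff(unique(records$site_id), metadata$site_id)
  if (length(orphans) > 0) {
    warn(paste0("Records from site(s) absent from metadata: ",
                paste(orphans, collapse = ", ")))
  }
  invisible(records)
}
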