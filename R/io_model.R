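# Data model: plot table, tree/seedling tally table, nested subplot areas.
#
# A plot is one field location of a probability sample; its `weight` is the
# area (km^2) it represents under the design.  A tally row is one stem (or a
# seedling count) observed on a fixed-area subplot; the subplot class fixes
# the per-area expansion factor used everywhere downstream.

SIZE_CLASSES <- c("seedling", "small_tree", "large_tree")

# diameter thresholds (cm) of the nested tally design
SMALL_TREE_MIN_CM <- 2.54
LARGE_TREE_MIN_CM <- 12.7

PLOT_COLUMNS <- c("plot_id", "stratum", "latitude", "longitude",
                  "elevation_m", "mat_c", "tmin_c", "tmax_c", "forested")
TALLY_COLUMNS <- c("plot_id", "species", "size_class", "diameter_cm", "count")

# analysis attribute name -> plot-table column
ATTRIBUTE_COLUMNS <- c(mat = "mat_c", tmin = "tmin_c", tmax = "tmax_c",
                       elevation = "elevation_m", latitude = "latitude")

#' Nested subplot areas
#'
#' Footprint areas (m^2) of the nested tally subplots.  Stems with diameter
#' >= 12.7 cm are tallied on the large subplot, stems of 2.54--12.7 cm on the
#' small subplot, and seedlings (stems < 2.54 cm above a minimum length) are
#' counted on the small-subplot footprint.  The inverse of these areas is the
#' per-stem expansion factor (stems per m^2 = count / area).
#'
#' @param large_tree_m2 area tallying stems >= 12.7 cm, m^2.
#' @param small_tree_m2 area tallying stems of 2.54--12.7 cm, m^2.
#' @param seedling_m2 area on which seedlings are counted, m^2.
#' @return A named list of class `subplot_areas`.
#' @export
subplot_areas <- function(large_tree_m2 = 672.5, small_tree_m2 = 54,
                          seedling_m2 = 54) {
  if (any(c(large_tree_m2, small_tree_m2, seedling_m2) <= 0))
    stop("subplot areas must be positive")
  structure(list(large_tree_m2 = large_tree_m2,
                 small_tree_m2 = small_tree_m2,
                 seedling_m2 = seedling_m2),
            class = "subplot_areas")
}

.area_for_class <- function(size_class, areas) {
  a <- c(seedling = areas$seedling_m2, small_tree = areas$small_tree_m2,
         large_tree = areas$large_tree_m2)
  unname(a[size_class])
}

# map a measured diameter to its tally subplot class; NA diameter -> seedling
.class_from_diameter <- function(diameter_cm) {
  out <- rep(NA_character_, length(diameter_cm))
  out[is.na(diameter_cm)] <- "seedling"
  out[!is.na(diameter_cm) & diameter_cm >= LARGE_TREE_MIN_CM] <- "large_tree"
  out[!is.na(diameter_cm) & diameter_cm >= SMALL_TREE_MIN_CM &
        diameter_cm < LARGE_TREE_MIN_CM] <- "small_tree"
  out
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")))
}

#' Validate a plot table
#'
#' Checks identifiers, finiteness and the forested-plot contract: mean annual
#' temperature must be present for forested plots.  A `weight` column, when
#' present, must be positive; use [assign_weights()] to attach design weights
#' from stratum sampling densities.
#'
#' @param plots data.frame of plot records.
#' @return The validated data.frame (invisibly unchanged apart from type
#'   coercion of `forested` to logical).
#' @export
validate_plots <- function(plots) {
  .require_columns(plots, setdiff(PLOT_COLUMNS, c("longitude", "tmin_c", "tmax_c")),
                   "plot table")
  plots$plot_id <- as.character(plots$plot_id)
  if (anyDuplicated(plots$plot_id))
    stop("plot_id values must be unique; duplicated: ",
         paste(unique(plots$plot_id[duplicated(plots$plot_id)])[1:5],
               collapse = ", "))
  plots$forested <- as.logical(plots$forested)
  if (anyNA(plots$forested))
    stop("forested flag must be TRUE/FALSE for every plot")
  bad_lat <- which(!is.finite(plots$latitude))
  if (length(bad_lat))
    stop("non-finite latitude in plot row(s): ",
         paste(utils::head(bad_lat, 5), collapse = ", "))
  bad_mat <- which(plots$forested & !is.finite(plots$mat_c))
  if (length(bad_mat))
    stop("forested plots must have finite mean annual temperature; row(s): ",
         paste(utils::head(bad_mat, 5), collapse = ", "))
  if ("weight" %in% names(plots)) {
    bad_w <- which(!is.na(plots$weight) & plots$weight <= 0)
    if (length(bad_w))
      stop("plot weights must be positive; row(s): ",
           paste(utils::head(bad_w, 5), collapse = ", "))
  }
  plots
}

#' Validate a tally table against its plot table
#'
#' Enforces the nested-design contract between size class and diameter:
#' `large_tree` requires diameter >= 12.7 cm, `small_tree` requires
#' 2.54 <= diameter < 12.7 cm, and `seedling` rows carry no diameter.  When
#' the `size_class` column is absent or NA it is derived from the diameter.
#'
#' @param tally data.frame of tally records.
#' @param plots validated plot table (membership check for `plot_id`).
#' @return The validated tally data.frame with `size_class` filled in.
#' @export
validate_tally <- function(tally, plots) {
  .require_columns(tally, c("plot_id", "species", "count"), "tally table")
  tally$plot_id <- as.character(tally$plot_id)
  tally$species <- as.character(tally$species)
  if (!"diameter_cm" %in% names(tally)) tally$diameter_cm <- NA_real_
  tally$diameter_cm <- as.numeric(tally$diameter_cm)

  orphan <- which(!(tally$plot_id %in% plots$plot_id))
  if (length(orphan))
    stop("tally rows reference unknown plot_id; row(s): ",
         paste(utils::head(orphan, 5), collapse = ", "))

  derived <- .class_from_diameter(tally$diameter_cm)
  if (!"size_class" %in% names(tally)) {
    tally$size_class <- derived
  } else {
    tally$size_class <- as.character(tally$size_class)
    fill <- is.na(tally$size_class) | tally$size_class == ""
    tally$size_class[fill] <- derived[fill]
  }
  unknown <- which(!(tally$size_class %in% SIZE_CLASSES))
  if (length(unknown))
    stop("unknown size_class (measured stems must be >= 2.54 cm); row(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  # a recorded diameter below 2.54 cm is not a measurable stem (derived is NA)
  contradict <- which(is.na(derived) & !is.na(tally$diameter_cm) |
                        !is.na(derived) & tally$size_class != derived)
  if (length(contradict))
    stop("size_class contradicts diameter in row(s): ",
         paste(utils::head(sort(contradict), 5), collapse = ", "))

  tally$count <- as.integer(tally$count)
  bad_count <- which(is.na(tally$count) | tally$count < 1L)
  if (length(bad_count))
    stop("count must be an integer >= 1; row(s): ",
         paste(utils::head(bad_count, 5), collapse = ", "))
  tally
}

#' Read a plot/tally inventory from CSV
#'
#' Reads the two-table inventory (comma-separated, UTF-8, header row, "."
#' decimal separator), validates both tables and returns them together with
#' the subplot areas that define expansion factors.
#'
#' @param plot_path path to the plot CSV
#'   (`plot_id,stratum,latitude,longitude,elevation_m,mat_c,tmin_c,tmax_c,forested`,
#'   optionally `weight`).
#' @param tally_path path to the tally CSV
#'   (`plot_id,species,size_class,diameter_cm,count`).
#' @param areas a [subplot_areas()] object.
#' @return list with elements `plots`, `tally`, `areas`.
#' @export
read_inventory <- function(plot_path, tally_path, areas = subplot_areas()) {
  if (!file.exists(plot_path)) stop("plot file not found: ", plot_path)
  if (!file.exists(tally_path)) stop("tally file not found: ", tally_path)
  plots <- as.data.frame(data.table::fread(plot_path, na.strings = c("NA", "")))
  tally <- as.data.frame(data.table::fread(tally_path, na.strings = c("NA", "")))
  plots <- validate_plots(plots)
  tally <- validate_tally(tally, plots)
  list(plots = plots, tally = tally, areas = areas)
}

#' Write a plot/tally inventory to CSV
#'
#' Inverse of [read_inventory()]; writing then reading reproduces the records
#' exactly.
#'
#' @param inventory list with `plots` and `tally` data.frames.
#' @param plot_path,tally_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_inventory <- function(inventory, plot_path, tally_path) {
  data.table::fwrite(inventory$plots, plot_path, na = "NA")
  data.table::fwrite(inventory$tally, tally_path, na = "NA")
  invisible(c(plot_path, tally_path))
}

#' Attach design weights from stratum sampling densities
#'
#' Each plot represents the area of its stratum's sampling density (km^2 per
#' plot); e.g. one plot per 24 km^2 in the California--Oregon stratum and one
#' per 26.6 km^2 in Washington.  Because every estimator downstream is a
#' ratio, results are invariant to rescaling all densities by a constant.
#'
#' @param plots plot table.
#' @param stratum_density named numeric vector, km^2 represented per plot,
#'   e.g. `c("CA-OR" = 24, "WA" = 26.6)`.
#' @return The plot table with a `weight` column.
#' @export
assign_weights <- function(plots, stratum_density) {
  if (is.null(names(stratum_density)) || any(names(stratum_density) == ""))
    stop("stratum_density must be a named numeric vector")
  if (any(stratum_density <= 0)) stop("stratum densities must be positive")
  unknown <- setdiff(unique(as.character(plots$stratum)), names(stratum_density))
  if (length(unknown))
    stop("no sampling density configured for stratum/strata: ",
         paste(unknown, collapse = ", "))
  plots$weight <- unname(stratum_density[as.character(plots$stratum)])
  plots
}

# column holding an analysis attribute, with validation
attribute_column <- function(attribute) {
  if (!attribute %in% names(ATTRIBUTE_COLUMNS))
    stop("unknown attribute '", attribute, "'; expected one of: ",
         paste(names(ATTRIBUTE_COLUMNS), collapse = ", "))
  unname(ATTRIBUTE_COLUMNS[attribute])
}

#' Convert a latitude difference in degrees to kilometres
#'
#' One degree of latitude spans 111.195 km (spherical mean); useful for
#' reporting northward shifts in km rather than degrees.
#'
#' @param deg latitude difference in degrees.
#' @return The same difference in km.
#' @export
lat_deg_to_km <- function(deg) deg * 111.195
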