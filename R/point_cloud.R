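#' Nuclei point cloud
#'
#' A `point_cloud` holds the 3D coordinates (in micrometres) of the nucleus
#' centroids of one animal, together with its metadata: animal id, genetic
#' line (e.g. `brp`, `Syt1`, `nSyb`, `repo`) and sex.
#'
#' @param points numeric matrix with three columns (x, y, z), coordinates in
#'   micrometres. All values must be finite. A cloud may be empty.
#' @param animal_id single character string identifying the animal.
#' @param line genetic line label.
#' @param sex one of `"female"`, `"male"`, `"unknown"` (parsed leniently, see
#'   [parse_sex()]).
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(runif(30, 0, 100), 10, 3), "a1", "brp", "female")
#' pc
#' @export
point_cloud <- function(points, animal_id = "animal1", line = "unknown",
                        sex = "unknown") {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(), 0, 3)
  if (ncol(points) != 3) stop("`points` must have 3 columns (x, y, z)")
  if (!is.numeric(points)) stop("coordinates must be numeric")
  if (nrow(points) > 0 && !all(is.finite(points))) {
    stop("all coordinates must be finite (no NA/NaN/Inf)")
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  rownames(points) <- NULL
  structure(
    list(
      animal_id = as.character(animal_id)[1],
      line = as.character(line)[1],
      sex = parse_sex(sex),
      points = points
    ),
    class = "point_cloud"
  )
}

#' Parse a sex label
#'
#' Case-insensitive parsing of `female`/`f` and `male`/`m`; anything else
#' maps to `"unknown"`.
#'
#' @param x character vector of labels.
#' @return character vector over `{"female", "male", "unknown"}`.
#' @export
parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("female", "f")] <- "female"
  out[x %in% c("male", "m")] <- "male"
  out
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf(
    "<point_cloud> animal '%s' (line %s, %s): %d nuclei\n",
    x$animal_id, x$line, x$sex, nrow(x$points)
  ))
  invisible(x)
}

#' @export
as.data.frame.point_cloud <- function(x, ...) {
  data.frame(
    animal_id = rep(x$animal_id, nrow(x$points)),
    line = rep(x$line, nrow(x$points)),
    sex = rep(x$sex, nrow(x$points)),
    x_um = x$points[, 1],
    y_um = x$points[, 2],
    z_um = x$points[, 3],
    stringsAsFactors = FALSE
  )
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

required_cloud_columns <- c("animal_id", "line", "sex", "x_um", "y_um", "z_um")

#' Read per-animal nuclei coordinate tables
#'
#' Reads a CSV of nucleus centroid coordinates, one row per nucleus, with
#' header columns `animal_id, line, sex, x_um, y_um, z_um` (coordinates in
#' micrometres; the decimal separator is always the point, independent of
#' locale). Unknown extra columns are ignored with a warning. Returns one
#' [point_cloud()] per distinct `animal_id`, preserving row order within an
#' animal.
#'
#' @param path path to a CSV file.
#' @return named list of `point_cloud` objects (class `point_cloud_list`).
#' @seealso [write_point_cloud_table()] for the inverse operation.
#' @export
read_point_cloud_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required_cloud_columns, names(df))
  if (length(missing)) {
    stop(
      "point cloud table is missing required column(s): ",
      paste(sprintf("'%s'", missing), collapse = ", ")
    )
  }
  extra <- setdiff(names(df), required_cloud_columns)
  if (length(extra)) {
    warning(
      "ignoring unknown column(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in c("x_um", "y_um", "z_um")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value '%s' in column '%s' at file line %d",
        df[[col]][bad[1]], col, bad[1] + 1L  # +1 for the header line
      ))
    }
    if (anyNA(vals)) {
      stop(sprintf("missing coordinate in column '%s' at file line %d",
                   col, which(is.na(vals))[1] + 1L))
    }
    df[[col]] <- vals
  }
  ids <- unique(df$animal_id)
  clouds <- lapply(ids, function(id) {
    rows <- df[df$animal_id == id, , drop = FALSE]
    point_cloud(
      cbind(rows$x_um, rows$y_um, rows$z_um),
      animal_id = id, line = rows$line[1], sex = rows$sex[1]
    )
  })
  names(clouds) <- ids
  structure(clouds, class = "point_cloud_list")
}

#' Write point clouds to a coordinate table
#'
#' Inverse of [read_point_cloud_table()]: writes a CSV with columns
#' `animal_id, line, sex, x_um, y_um, z_um`, animals ordered by id and
#' points in their stored order.
#'
#' @param clouds a non-empty list of [point_cloud()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_point_cloud_table <- function(clouds, path) {
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  if (!length(clouds)) stop("`clouds` must contain at least one point cloud")
  if (!all(vapply(clouds, inherits, logical(1), "point_cloud"))) {
    stop("all elements of `clouds` must be point_cloud objects")
  }
  ids <- vapply(clouds, `[[`, character(1), "animal_id")
  df <- do.call(rbind, lapply(clouds[order(ids)], as.data.frame))
  ok <- tryCatch(
    {
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    },
    error = function(e) FALSE,
    warning = function(w) FALSE
  )
  if (!ok) stop("cannot write point cloud table to ", path)
  invisible(path)
}

#' @export
print.point_cloud_list <- function(x, ...) {
  cat(sprintf("<point_cloud_list> %d animals\n", length(x)))
  for (pc in x) {
    cat(sprintf(
      "  %-10s line %-8s %-8s %6d nuclei\n",
      pc$animal_id, pc$line, pc$sex, nrow(pc$points)
    ))
  }
  invisible(x)
}
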