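#' Construct a target set
#'
#' @param coords Numeric matrix (or data.frame) with columns x, y, z in
#'   microns, one row per targeted cell centroid.
#' @param weights Nonnegative field-amplitude weights, recycled to the
#'   number of targets (default 1: equal field amplitude everywhere).
#' @return A [TargetSet-class].
#' @examples
#' ts <- targetSet(cbind(x = c(0, 20), y = c(0, 0), z = c(0, 30)))
#' nTargets(ts)
#' @export
targetSet <- function(coords, weights = 1) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have columns x, y, z")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  weights <- rep_len(as.numeric(weights), nrow(coords))
  new("TargetSet", coords = coords, weights = weights)
}

#' Number of targets
#' @param targets A [TargetSet-class].
#' @return Integer count M.
#' @export
nTargets <- function(targets) nrow(targets@coords)

#' Target coordinates and weights
#' @param targets A [TargetSet-class].
#' @return \code{targetCoords}: the M x 3 coordinate matrix (microns);
#'   \code{targetWeights}: the weight vector.
#' @export
targetCoords <- function(targets) targets@coords

#' @rdname targetCoords
#' @export
targetWeights <- function(targets) targets@weights

#' Read / write target lists
#'
#' CSV files use the header \code{x_um,y_um,z_um,weight}; JSON files
#' hold an array of objects with the same fields. A missing weight
#' column defaults to 1.
#'
#' @param path File path; format chosen by extension (.csv or .json).
#' @return \code{readTargets} returns a [TargetSet-class];
#'   \code{writeTargets} returns \code{path} invisibly.
#' @export
readTargets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::fromJSON(path)
  } else {
    d <- utils::read.csv(path)
  }
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(d)))
    stop("target table must have columns x_um, y_um, z_um")
  w <- if ("weight" %in% names(d)) d$weight else 1
  if (!nrow(d)) stop("empty target table: ", path)
  targetSet(cbind(d$x_um, d$y_um, d$z_um), w)
}

#' @rdname readTargets
#' @param targets A [TargetSet-class] to serialize.
#' @export
writeTargets <- function(targets, path) {
  d <- data.frame(x_um = targets@coords[, 1], y_um = targets@coords[, 2],
                  z_um = targets@coords[, 3], weight = targets@weights)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(d, path, digits = NA)
  } else {
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}

setMethod("show", "TargetSet", function(object) {
  z <- object@coords[, 3]
  cat(sprintf("TargetSet: %d targets on %d axial plane(s), z in [%g, %g] um\n",
              nrow(object@coords), length(unique(round(z, 6))),
              min(z), max(z)))
})
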