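# Grid stiffness maps: one measurement slot per 20x20 um cell, failed
# measurements kept as explicit markers ("crosses"), never interpolated.

#' Assemble per-curve fits into a grid stiffness map
#'
#' Each fit is assigned to the half-open cell
#' \eqn{[x, x+\mathrm{cell}) \times [y, y+\mathrm{cell})} containing its
#' stage position (row-major grid, rows indexed by y). Failed fits become
#' `NA` cells with their QC reason recorded. Two results falling in one
#' cell is an error: the protocol takes a single measurement per square.
#'
#' @param fits list of [HertzFit-class] objects carrying stage positions.
#' @param cellSize cell edge (um); default 20.
#' @param origin (x, y) of the map's lower-left corner (um); default: the
#'   cell-aligned corner just below the minimum observed position.
#' @return A [StiffnessMap-class].
#' @examples
#' fld <- simulateTissueField(extent = c(60, 60), backgroundLogSD = 0, seed = 1)
#' fits <- lapply(fld$curves, analyzeCurve)
#' buildStiffnessMap(fits)
#' @export
buildStiffnessMap <- function(fits, cellSize = 20, origin = NULL) {
  stopifnot(length(fits) > 0, all(vapply(fits, is, logical(1), "HertzFit")))
  if (cellSize <= 0) stop("cellSize must be positive")
  pos <- t(vapply(fits, function(f) f@position, numeric(2)))
  if (is.null(origin))
    origin <- floor(apply(pos, 2, min) / cellSize) * cellSize
  ix <- floor((pos[, 1] - origin[1]) / cellSize) + 1L
  iy <- floor((pos[, 2] - origin[2]) / cellSize) + 1L
  if (any(ix < 1) || any(iy < 1))
    stop("positions lie below the map origin")
  key <- paste(iy, ix)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("two measurements fall in grid cell (", dup,
         "): the protocol allows a single measurement per square")
  }
  values <- matrix(NA_real_, nrow = max(iy), ncol = max(ix))
  reasons <- matrix("", nrow = max(iy), ncol = max(ix))
  reasons[] <- "empty"
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (f@qc == "pass") {
      values[iy[i], ix[i]] <- f@Ea
      reasons[iy[i], ix[i]] <- ""
    } else {
      reasons[iy[i], ix[i]] <- f@qcReason
    }
  }
  new("StiffnessMap", origin = unname(origin), cellSize = cellSize,
      values = values, qcReasons = reasons)
}

#' Summarise a stiffness map
#'
#' Counts measured and failed cells and the cells whose modulus exceeds a
#' threshold (default 1 kPa, the tail used to contrast stiff-inclusion
#' tissue against soft tissue), plus the median over passing cells.
#'
#' @param map a [StiffnessMap-class].
#' @param threshold modulus threshold (Pa); default 1000.
#' @return A list: `nTotal`, `nPass`, `nFail`, `nAboveThreshold`,
#'   `fractionAbove`, `median` (`NA` when no cell passed), `medianDefined`.
#' @examples
#' m <- new("StiffnessMap", values = matrix(c(100, 200, 1500, NA), 2),
#'          qcReasons = matrix(c("", "", "", "slip"), 2))
#' mapSummary(m)
#' @export
mapSummary <- function(map, threshold = 1000) {
  stopifnot(is(map, "StiffnessMap"))
  measured <- map@qcReasons != "empty"
  vals <- map@values[measured]
  nTotal <- sum(measured)
  nPass <- sum(!is.na(vals))
  res <- list(
    nTotal = nTotal,
    nPass = nPass,
    nFail = nTotal - nPass,
    nAboveThreshold = sum(vals > threshold, na.rm = TRUE),
    fractionAbove = if (nPass > 0) sum(vals > threshold, na.rm = TRUE) / nPass
                    else NA_real_,
    median = if (nPass > 0) stats::median(vals, na.rm = TRUE) else NA_real_,
    medianDefined = nPass > 0
  )
  res
}

#' Write a stiffness map as a plain-text matrix
#'
#' CSV matrix with `NA(reason)` sentinels for failed cells, preceded by a
#' JSON header line recording the origin, cell size and the half-open
#' row-major grid convention.
#'
#' @param map a [StiffnessMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStiffnessMap <- function(map, path) {
  stopifnot(is(map, "StiffnessMap"))
  hdr <- jsonlite::toJSON(list(origin = map@origin, cell_size_um = map@cellSize,
                               convention = "half-open cells, row-major, rows = y"),
                          auto_unbox = TRUE, digits = NA)
  out <- map@values
  txt <- matrix(sprintf("%.10g", out), nrow = nrow(out))
  bad <- is.na(out)
  txt[bad] <- paste0("NA(", map@qcReasons[bad], ")")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", hdr), con)
  utils::write.table(txt, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
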