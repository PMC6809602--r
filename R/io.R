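# Plain-text curve format: a TSV with a '#'-prefixed key: value header
# block (the shape of a generic vendor text export), columns z_um,
# deflection_nm, segment. Values are written at full double precision so a
# write -> read round trip is lossless.

.headerKeys <- c(probe_radius_um = "probeRadius",
                 spring_constant_N_per_m = "springConstant",
                 trigger_force_nN = "triggerForce",
                 approach_speed_um_per_s = "approachSpeed",
                 retract_speed_um_per_s = "retractSpeed",
                 position_x_um = "posx", position_y_um = "posy",
                 temperature_K = "temperature")

#' Write a force curve to the plain-text TSV dialect
#'
#' @param curve a [ForceCurve-class].
#' @param path output file path.
#' @param sidecar write the generator ground truth (when present) to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @examples
#' fc <- simulateForceCurve(E = 250, noiseSD = 0)
#' p <- tempfile(fileext = ".tsv")
#' writeCurveFile(fc, p)
#' @export
writeCurveFile <- function(curve, path, sidecar = TRUE) {
  stopifnot(is(curve, "ForceCurve"))
  md <- curve@metadata
  num <- function(x) sprintf("%.17g", x)
  k <- curve@springConstant
  hdr <- c(
    paste0("# probe_radius_um: ", num(curve@probeRadius)),
    paste0("# spring_constant_N_per_m: ",
           if (is.na(k)) "uncalibrated" else num(k)),
    paste0("# trigger_force_nN: ", num(md$triggerForce %||% NA)),
    paste0("# approach_speed_um_per_s: ", num(md$approachSpeed %||% NA)),
    paste0("# retract_speed_um_per_s: ", num(md$retractSpeed %||% NA)),
    paste0("# position_x_um: ", num(curve@position[1])),
    paste0("# position_y_um: ", num(curve@position[2])),
    paste0("# temperature_K: ", num(md$temperature %||% NA))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("z_um\tdeflection_nm\tsegment", con)
  writeLines(paste(num(curve@z), num(curve@d), curve@segment, sep = "\t"),
             con)
  if (sidecar && length(curve@groundTruth))
    jsonlite::write_json(curve@groundTruth, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a force curve from the plain-text TSV dialect
#'
#' Errors name the offending line for malformed or duplicated header keys
#' and reject files whose column schema does not match
#' `z_um, deflection_nm, segment`. A `<path>.json` ground-truth sidecar is
#' picked up when present.
#'
#' @param path file path.
#' @param sidecar read the ground-truth sidecar if it exists.
#' @return A [ForceCurve-class].
#' @export
readCurveFile <- function(path, sidecar = TRUE) {
  lines <- readLines(path)
  isHdr <- grepl("^#", lines)
  nHdr <- which(!isHdr)[1] - 1
  if (is.na(nHdr) || nHdr < 1) stop("no header block found in ", path)
  kv <- list()
  for (i in seq_len(nHdr)) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) != 3)
      stop("malformed header at line ", i, " of ", path, ": '", lines[i], "'")
    key <- m[2]
    if (key %in% names(kv))
      stop("duplicate header key '", key, "' at line ", i, " of ", path)
    kv[[key]] <- m[3]
  }
  missing <- setdiff(names(.headerKeys), names(kv))
  if (length(missing))
    stop("missing header key(s) in ", path, ": ",
         paste(missing, collapse = ", "))

  colLine <- lines[nHdr + 1]
  cols <- strsplit(colLine, "\t", fixed = TRUE)[[1]]
  if (!identical(cols, c("z_um", "deflection_nm", "segment")))
    stop("schema error at line ", nHdr + 1, " of ", path,
         ": expected columns 'z_um\tdeflection_nm\tsegment', got '",
         colLine, "'")
  dat <- utils::read.table(text = lines[-seq_len(nHdr + 1)], sep = "\t",
                           col.names = cols,
                           colClasses = c("numeric", "numeric", "character"))
  for (sg in unique(dat$segment)) {
    zz <- dat$z_um[dat$segment == sg]
    if (length(zz) > 1 && !(all(diff(zz) >= 0) || all(diff(zz) <= 0)))
      stop("z is not monotone within segment '", sg, "' in ", path)
  }
  kval <- kv[["spring_constant_N_per_m"]]
  k <- if (identical(kval, "uncalibrated")) NA_real_ else as.numeric(kval)
  gt <- list()
  if (sidecar && file.exists(paste0(path, ".json"))) {
    gt <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    gt <- lapply(gt, function(x) if (identical(x, "NA")) NA else x)
  }
  new("ForceCurve",
      z = dat$z_um, d = dat$deflection_nm, segment = dat$segment,
      probeRadius = as.numeric(kv[["probe_radius_um"]]),
      springConstant = k,
      position = c(as.numeric(kv[["position_x_um"]]),
                   as.numeric(kv[["position_y_um"]])),
      metadata = list(
        approachSpeed = as.numeric(kv[["approach_speed_um_per_s"]]),
        retractSpeed = as.numeric(kv[["retract_speed_um_per_s"]]),
        triggerForce = as.numeric(kv[["trigger_force_nN"]]),
        temperature = as.numeric(kv[["temperature_K"]])),
      groundTruth = gt)
}
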