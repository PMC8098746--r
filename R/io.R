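# Readers and writers for image stacks and the tabular inputs/outputs.
#
# Stacks travel as multi-page TIFF (pages ordered z-fastest within channel).
# The installed TIFF writer cannot emit resolution or description tags, so
# write_stack() records calibration and channel names in a JSON sidecar
# ("<path>.json"); read_stack() resolves calibration with the precedence
# embedded TIFF resolution tags < sidecar < explicit override, logging a
# warning when a required value has to come from the override.

#' Write an image stack to a multi-page TIFF with a JSON metadata sidecar
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim_stack(stack)
  vmax <- 2^stack$bit_depth - 1
  pages <- vector("list", d[["channel"]] * d[["z"]])
  k <- 1L
  for (ci in seq_len(d[["channel"]])) {
    for (z in seq_len(d[["z"]])) {
      pages[[k]] <- stack$voxels[, , z, ci] / vmax
      k <- k + 1L
    }
  }
  bits <- if (stack$bit_depth <= 8) 8L else 16L
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  meta <- list(
    n_channels = unname(d[["channel"]]), n_z = unname(d[["z"]]),
    channel_names = as.list(stack$channel_names),
    pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
    bit_depth = stack$bit_depth, page_order = "z-fastest-within-channel")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Pages are interpreted as all z-planes of channel 1, then channel 2, etc.
#' Calibration is resolved from embedded TIFF resolution tags (if present),
#' then the JSON sidecar written by [write_stack()], then the explicit
#' `pixel_size_um` / `z_step_um` arguments; supplying a value that the file
#' itself lacks is logged as a warning.
#'
#' @param path TIFF path.
#' @param channel_names channel labels; overrides sidecar names. Required when
#'   no sidecar exists and more than one channel is implied by `n_channels`.
#' @param n_channels number of channels when no sidecar exists (default 1).
#' @param pixel_size_um,z_step_um calibration overrides in micrometres.
#' @param bit_depth camera bit depth override.
#' @param channel_roles optional named character vector mapping roles to
#'   channel names, e.g. `c(myelin = "MBP", axon = "NFH")`; every named
#'   channel must exist.
#' @return An [image_stack()], with a `channel_roles` attribute when roles
#'   were given.
#' @export
read_stack <- function(path, channel_names = NULL, n_channels = NULL,
                       pixel_size_um = NULL, z_step_um = NULL,
                       bit_depth = NULL, channel_roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) stop("not readable as TIFF: ", path, " (",
                             conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  meta <- read_sidecar(paste0(path, ".json"))

  # calibration precedence: embedded tags < sidecar < explicit override
  px <- embedded_pixel_size(pages[[1L]])
  src <- if (!is.null(px)) "tiff-tags" else NULL
  if (is.null(px) && !is.null(meta$pixel_size_um)) {
    px <- meta$pixel_size_um; src <- "sidecar"
  }
  if (!is.null(pixel_size_um)) {
    if (is.null(px)) {
      mq_log("warning: %s carries no pixel size; using configured %g um/px",
             path, pixel_size_um)
      warning("no pixel size in file; using configured ", pixel_size_um,
              " um/px", call. = FALSE)
    }
    px <- pixel_size_um; src <- "override"
  }
  if (is.null(px)) stop("pixel size unavailable: none embedded in ", path,
                        " and no pixel_size_um override given")
  zs <- meta$z_step_um
  if (!is.null(z_step_um)) {
    if (is.null(zs)) {
      mq_log("warning: %s carries no z-step; using configured %g um", path,
             z_step_um)
      warning("no z-step in file; using configured ", z_step_um, " um",
              call. = FALSE)
    }
    zs <- z_step_um
  }
  if (is.null(zs)) stop("z-step unavailable for ", path,
                        "; supply z_step_um")

  nc <- n_channels %||% meta$n_channels %||%
    (if (!is.null(channel_names)) length(channel_names) else 1L)
  if (length(pages) %% nc != 0L)
    stop("page count ", length(pages), " is not a multiple of channel count ",
         nc)
  nz <- length(pages) %/% nc
  bd <- bit_depth %||% meta$bit_depth %||%
    attr(pages[[1L]], "bits.per.sample") %||% 16L
  cn <- channel_names %||% unlist(meta$channel_names) %||%
    paste0("ch", seq_len(nc))
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  vmax <- 2^bd - 1
  v <- array(0, dim = c(ny, nx, nz, nc))
  k <- 1L
  for (ci in seq_len(nc)) {
    for (z in seq_len(nz)) {
      pg <- pages[[k]]
      # readTIFF(as.is=TRUE) returns raw integers for integer TIFFs,
      # otherwise [0,1] floats that we rescale to camera counts
      v[, , z, ci] <- if (max(pg) <= 1 && vmax > 1 && !all(pg == round(pg)))
        round(pg * vmax) else pg
      k <- k + 1L
    }
  }
  stk <- image_stack(v, px, zs, cn, bd)
  if (!is.null(channel_roles)) {
    missing_ch <- setdiff(unname(channel_roles), cn)
    if (length(missing_ch))
      stop("channel_roles names absent channels: ",
           paste(missing_ch, collapse = ", "))
    attr(stk, "channel_roles") <- channel_roles
  }
  mq_log("read %s: %d channel(s) x %d plane(s), %g um/px (%s)", path, nc, nz,
         px, src %||% "sidecar")
  stk
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  jsonlite::read_json(path, simplifyVector = FALSE)
}

embedded_pixel_size <- function(page) {
  xr <- attr(page, "x.resolution")
  if (is.null(xr) || !is.numeric(xr) || xr <= 0) return(NULL)
  unit <- attr(page, "resolution.unit") %||% "inch"
  per_um <- switch(unit, inch = xr / 25400, cm = xr / 1e4, NULL)
  if (is.null(per_um)) NULL else 1 / per_um
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tabular I/O ------------------------------------------------------------

#' Read a sheath trace table
#'
#' Long-form CSV with columns `myelinoid_id, cell_id, sheath_id, point_index,
#' x_um, y_um` (optional `z_um`), one row per polyline vertex; or an SWC-like
#' per-cell file (7 whitespace-separated columns: id, type, x, y, z, radius,
#' parent) in which each unbranched root-to-tip path is one sheath. Branched
#' SWC structures are rejected: sheaths are unbranched.
#'
#' @param path CSV or SWC file.
#' @param format `"csv"`, `"swc"`, or `"auto"` (by file extension).
#' @param myelinoid_id,cell_id ids assigned to SWC input (one cell per file).
#' @return A `data.frame` of class `trace_table` with the CSV columns above.
#' @export
read_trace_table <- function(path, format = c("auto", "csv", "swc"),
                             myelinoid_id = "m1", cell_id = "c1") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.swc$", path, ignore.case = TRUE)) "swc" else "csv"
  tab <- if (format == "swc") {
    read_swc_traces(path, myelinoid_id, cell_id)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("empty or unreadable trace ",
                                            "table: ", path, call. = FALSE))
    if (nrow(df) == 0L) stop("empty trace table: ", path)
    df
  }
  validate_trace_table(tab)
}

#' Assemble and validate a trace table from a data frame
#' @param df data frame with columns `myelinoid_id, cell_id, sheath_id,
#'   point_index, x_um, y_um` and optional `z_um`.
#' @return The validated `trace_table`.
#' @export
validate_trace_table <- function(df) {
  need <- c("myelinoid_id", "cell_id", "sheath_id", "point_index",
            "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"z_um" %in% names(df)) df$z_um <- 0
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    stop("trace coordinates must be finite")
  key <- interaction(df$myelinoid_id, df$cell_id, df$sheath_id, drop = TRUE)
  npts <- table(key)
  bad <- names(npts)[npts < 2L]
  if (length(bad))
    stop("polyline(s) with < 2 points: ", paste(bad, collapse = ", "))
  lens <- vapply(split(df, key), function(s) {
    s <- s[order(s$point_index), ]
    sum(sqrt(diff(s$x_um)^2 + diff(s$y_um)^2 + diff(s$z_um)^2))
  }, numeric(1))
  if (any(lens <= 0))
    stop("polyline(s) with zero arc length: ",
         paste(names(lens)[lens <= 0], collapse = ", "))
  class(df) <- c("trace_table", "data.frame")
  df
}

read_swc_traces <- function(path, myelinoid_id, cell_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty SWC file: ", path)
  sw <- utils::read.table(text = lines,
                          col.names = c("id", "type", "x", "y", "z", "radius",
                                        "parent"))
  children <- table(sw$parent[sw$parent > 0])
  if (any(children > 1L))
    stop("branched SWC structure in ", path,
         " (node(s) with multiple children: ",
         paste(names(children)[children > 1L], collapse = ", "),
         "); sheaths are unbranched polylines")
  roots <- sw$id[sw$parent < 0]
  out <- list()
  for (si in seq_along(roots)) {
    ids <- roots[si]
    repeat {
      nxt <- sw$id[sw$parent == ids[length(ids)]]
      if (!length(nxt)) break
      ids <- c(ids, nxt[1L])
    }
    seg <- sw[match(ids, sw$id), ]
    out[[si]] <- data.frame(
      myelinoid_id = myelinoid_id, cell_id = cell_id, sheath_id = si,
      point_index = seq_len(nrow(seg)), x_um = seg$x, y_um = seg$y,
      z_um = seg$z)
  }
  do.call(rbind, out)
}

#' Read a cell-centroid table
#'
#' CSV with columns `myelinoid_id, cell_id, x_um, y_um, is_myelinating`
#' (logical or 0/1).
#'
#' @param path CSV path.
#' @return A `data.frame` of class `centroid_table`.
#' @export
read_centroids <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty centroid table: ", path)
  validate_centroids(df)
}

#' @rdname read_centroids
#' @param df data frame to validate in place of a file.
#' @export
validate_centroids <- function(df) {
  need <- c("myelinoid_id", "cell_id", "x_um", "y_um", "is_myelinating")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("centroid table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    stop("centroid coordinates must be finite")
  dup <- duplicated(df[c("myelinoid_id", "cell_id")])
  if (any(dup)) stop("duplicate cell_id within myelinoid: ",
                     paste(df$cell_id[dup], collapse = ", "))
  df$is_myelinating <- as.logical(df$is_myelinating)
  class(df) <- c("centroid_table", "data.frame")
  df
}

#' Write result records to CSV
#'
#' Records are written with a fixed column order (the union of metadata,
#' measurement, and provenance columns as first encountered), full floating
#' point precision, and `seed` / `param_hash` provenance columns.
#'
#' @param records a data.frame, or list of single-row records with identical
#'   schemas.
#' @param path output CSV path.
#' @param seed seed recorded with the results (may be NA).
#' @param params parameter object whose hash is recorded (may be NULL).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, seed = NA_integer_, params = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (!length(records)) stop("records must be non-empty")
    schemas <- lapply(records, function(r) sort(names(r)))
    if (!all(vapply(schemas, identical, logical(1), schemas[[1L]])))
      stop("records have mixed schemas")
    df <- do.call(rbind, lapply(records, as.data.frame,
                                stringsAsFactors = FALSE))
  }
  if (nrow(df) == 0L) stop("records must be non-empty")
  if (!"seed" %in% names(df)) df$seed <- seed
  if (!"param_hash" %in% names(df))
    df$param_hash <- if (is.null(params)) NA_character_ else param_hash(params)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Load a YAML run configuration with defaults filled in
#'
#' The configuration is a flat YAML map whose keys mirror the fields of
#' [seg_params()] and [sim_params()], plus `channel_roles` (map role -> channel
#' name), `seed`, `out_dir`, and `verbose`.
#'
#' @param path YAML file, or `NULL` for an all-defaults configuration.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config not found: ", path)
    yaml::read_yaml(path)
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$verbose <- cfg$verbose %||% TRUE
  cfg$channel_roles <- cfg$channel_roles %||%
    list(myelin = "MBP", axon = "NFH")
  class(cfg) <- "run_config"
  cfg
}
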