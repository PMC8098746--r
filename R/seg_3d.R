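# 3D object assembly: per-plane 8-connected components joined across
# neighbouring z-planes wherever voxels touch within a 26-connected
# neighbourhood, then volume/diameter measurement and the 3D filter.

#' Connect per-plane objects across z into 3D objects
#'
#' Voxels are connected in-plane by 8-connectivity and across consecutive
#' planes by 26-connectivity (overlap of the 3x3 in-plane neighbourhood).
#' Volume is voxel count times `pixel_size^2 * z_step`; diameter is the exact
#' maximum pairwise distance between member voxel centres in physical
#' coordinates (computed over the per-line extreme voxels, which contain
#' every convex-hull vertex, so the maximum is exact).
#'
#' @param masks logical 3D array `y x x x z` (or a list of plane masks).
#' @param pixel_size_um,z_step_um calibration.
#' @return A list with `labels` (integer 3D array) and `objects`
#'   (data.frame: `label, n_vox, volume_um3, diameter_um, z_min, z_max`).
#' @export
connect_touching_3d <- function(masks, pixel_size_um, z_step_um) {
  if (is.list(masks)) masks <- simplify2array(masks)
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  ny <- dim(masks)[1L]; nx <- dim(masks)[2L]; nz <- dim(masks)[3L]
  labs <- array(0L, dim = dim(masks))
  offset <- 0L
  for (z in seq_len(nz)) {
    l <- label8(masks[, , z] != 0)
    n_plane <- max(l)
    l[l > 0L] <- l[l > 0L] + offset
    labs[, , z] <- l
    offset <- offset + n_plane
  }
  n <- offset
  if (n == 0L)
    return(list(labels = labs,
                objects = data.frame(label = integer(0), n_vox = integer(0),
                                     volume_um3 = numeric(0),
                                     diameter_um = numeric(0),
                                     z_min = integer(0), z_max = integer(0))))
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  prs <- list()
  if (nz > 1L) for (z in seq_len(nz - 1L)) {
    p <- label_pairs(labs[, , z], labs[, , z + 1L], offs)
    if (nrow(p)) prs[[length(prs) + 1L]] <- p
  }
  prs <- if (length(prs)) unique(do.call(rbind, prs)) else
    matrix(integer(0), 0, 2)
  map <- uf_resolve(n, prs)
  sel <- labs > 0L
  labs[sel] <- map[labs[sel]]
  k <- max(map)

  idx <- which(labs > 0L)
  l <- labs[idx]
  nvox <- tabulate(l, k)
  ai <- arrayInd(idx, dim(labs))
  zmin <- as.integer(tapply(ai[, 3L], l, min))
  zmax <- as.integer(tapply(ai[, 3L], l, max))
  diam <- object_diameters(ai, l, k, pixel_size_um, z_step_um)
  list(labels = labs,
       objects = data.frame(label = seq_len(k), n_vox = nvox,
                            volume_um3 = nvox * pixel_size_um^2 * z_step_um,
                            diameter_um = diam, z_min = zmin, z_max = zmax))
}

# exact max-Feret diameter per object: per (y, z) line only the min- and
# max-x voxels can be convex-hull vertices, so the pairwise maximum over
# those candidates equals the maximum over all member voxels
object_diameters <- function(ai, l, k, px, zs) {
  diam <- numeric(k)
  key <- split(seq_along(l), l)
  for (lab in seq_len(k)) {
    rows <- key[[as.character(lab)]]
    if (is.null(rows)) next
    a <- ai[rows, , drop = FALSE]
    line <- paste(a[, 1L], a[, 3L])
    xmin <- tapply(a[, 2L], line, min)
    xmax <- tapply(a[, 2L], line, max)
    ln <- strsplit(names(xmin), " ", fixed = TRUE)
    yy <- as.numeric(vapply(ln, `[`, "", 1L))
    zz <- as.numeric(vapply(ln, `[`, "", 2L))
    pts <- unique(rbind(cbind(yy, xmin, zz), cbind(yy, xmax, zz)))
    P <- cbind(pts[, 1L] * px, pts[, 2L] * px, pts[, 3L] * zs)
    if (nrow(P) == 1L) { diam[lab] <- 0; next }
    if (nrow(P) > 3000L) {
      # thin very large candidate sets through per-plane convex hulls
      keep <- unlist(lapply(split(seq_len(nrow(P)), P[, 3L]), function(r) {
        if (length(r) < 4L) return(r)
        r[unique(grDevices::chull(P[r, 1L], P[r, 2L]))]
      }))
      P <- P[keep, , drop = FALSE]
    }
    d2 <- as.matrix(stats::dist(P))
    diam[lab] <- max(d2)
  }
  diam
}

#' 3D filter: remove small-volume, small-diameter objects
#'
#' An object is removed iff BOTH its volume is `<= min_volume_um3` AND its
#' diameter is `<= min_diameter_um` (boundary equality removes). The
#' conjunction keeps long thin sheaths whose volume is small but whose extent
#' is large.
#'
#' @param objects3d result of [connect_touching_3d()].
#' @param params a [seg_params()].
#' @return `objects3d` with filtered `objects` and non-retained labels zeroed
#'   in `labels`.
#' @export
filter_3d <- function(objects3d, params = seg_params()) {
  obj <- objects3d$objects
  remove <- obj$volume_um3 <= params$min_volume_um3 &
    obj$diameter_um <= params$min_diameter_um
  keep <- obj$label[!remove]
  labs <- objects3d$labels
  labs[!(labs %in% keep)] <- 0L
  list(labels = labs, objects = obj[!remove, , drop = FALSE])
}
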