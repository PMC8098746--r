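# Site-level pipeline: the full per-plane cascade, 3D assembly, NF-H
# quantification, and the normalized myelin volume.

#' Quantify axonal density from the NF-H channel
#'
#' A single global threshold (Otsu on the whole site by default, or a fixed
#' count value) segments the NF-H channel per plane; thresholded voxels are
#' connected across z and their volume summed. Integrated intensity is the
#' sum of raw NF-H intensities over the thresholded volume (default) or over
#' the whole image volume (`nfh_integration = "whole"`).
#'
#' @param stack an [image_stack()] containing the NF-H channel.
#' @param params a [seg_params()].
#' @return List: `nfh_volume_um3`, `nfh_integrated_intensity`, `threshold`.
#' @export
quantify_nfh <- function(stack, params = seg_params()) {
  ch <- get_channel(stack, params$nfh_channel)
  thr <- if (identical(params$nfh_threshold, "otsu"))
    otsu_threshold(ch) else params$nfh_threshold
  mask <- ch > thr
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  vol <- sum(mask) * voxel_volume_um3(stack)
  intens <- if (params$nfh_integration == "whole") sum(ch) else sum(ch[mask])
  list(nfh_volume_um3 = vol, nfh_integrated_intensity = intens,
       threshold = thr)
}

#' Run the full myelin-segmentation pipeline on one acquisition site
#'
#' Executes, per z-plane of the myelin channel: adaptive threshold ->
#' 2D measurement -> Filter Mask 1 -> shrink by `shrink_px` -> Filter Mask 2
#' (on the shrunk objects) -> Keep Marked Objects -> blob subtraction
#' (8-100 um pass, then 4-6 um pass); then 3D assembly by Connect Touching
#' Objects, the 3D volume/diameter filter, and volume summation. The NF-H
#' channel is quantified with [quantify_nfh()] and the normalized myelin
#' volume is myelin volume divided by NF-H integrated intensity.
#'
#' @param stack an [image_stack()] with myelin and NF-H channels.
#' @param params a [seg_params()].
#' @param keep_masks if TRUE, per-stage masks are returned for audit.
#' @param metadata named list copied into the result (cell line, batch,
#'   treatment, timepoint, ids).
#' @return An object of class `myelinoid_result`: site-level myelin volume
#'   (um^3), NF-H volume and integrated intensity, normalized myelin volume
#'   (NA with a warning when NF-H intensity is 0), per-stage object counts,
#'   the retained 3D objects, and provenance (parameter hash).
#' @export
run_pipeline <- function(stack, params = seg_params(), keep_masks = FALSE,
                         metadata = list()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "seg_params"))
  d <- dim_stack(stack)
  px <- stack$pixel_size_um
  r_px <- max(2L, um_to_px(params$adaptive_radius_um, px))
  offset <- scale_counts(params$adaptive_offset, stack$bit_depth)
  nz <- d[["z"]]
  ny <- d[["y"]]; nx <- d[["x"]]

  stages <- c("adaptive", "filter1", "keep_marked", "blob1", "blob2")
  counts <- matrix(0L, nz, length(stages),
                   dimnames = list(NULL, stages))
  adaptive <- array(FALSE, c(ny, nx, nz))
  final2d <- array(FALSE, c(ny, nx, nz))
  audit <- if (keep_masks) vector("list", nz) else NULL

  for (z in seq_len(nz)) {
    plane <- get_plane(stack, params$myelin_channel, z)
    m0 <- adaptive_threshold(plane, r_px, offset)
    adaptive[, , z] <- m0
    meas <- measure_objects_2d(m0, plane, px)
    counts[z, "adaptive"] <- nrow(meas)
    m1 <- filter_mask_1(meas, params)
    counts[z, "filter1"] <- attr(m1, "n_retained")
    shr <- shrink_objects(m1, params$shrink_px)
    meas2 <- measure_objects_2d(shr, plane, px)
    m2 <- filter_mask_2(meas2, params, stack$bit_depth)
    mk <- keep_marked_objects(m1, m2)
    counts[z, "keep_marked"] <- attr(mk, "n_retained")
    # blob subtraction can at most erase objects, never create them: count
    # the surviving parent objects of the keep-marked labeling
    klab <- attr(mk, "labels")
    b1 <- find_blobs(plane, params$blob1_range_um, px, params)
    mk <- subtract_blobs(mk, b1, params$blob_enlarge_px)
    counts[z, "blob1"] <- length(unique(klab[mk]))
    b2 <- find_blobs(plane, params$blob2_range_um, px, params)
    mk <- subtract_blobs(mk, b2, params$blob_enlarge_px)
    counts[z, "blob2"] <- length(unique(klab[mk]))
    final2d[, , z] <- mk
    if (keep_masks)
      audit[[z]] <- list(adaptive = m0, filter1 = m1, shrunk = shr,
                         filter2 = m2, keep_marked = mk,
                         blobs1 = b1, blobs2 = b2)
  }

  o3 <- connect_touching_3d(final2d, px, stack$z_step_um)
  n3_before <- nrow(o3$objects)
  o3 <- filter_3d(o3, params)
  myelin_volume <- sum(o3$objects$volume_um3)
  nfh <- quantify_nfh(stack, params)
  norm_vol <- if (nfh$nfh_integrated_intensity > 0)
    myelin_volume / nfh$nfh_integrated_intensity else {
      warning("NF-H integrated intensity is 0; normalized volume undefined",
              call. = FALSE)
      NA_real_
    }
  mq_log(paste0("run_pipeline: %d 2D objects thresholded, %d 3D objects ",
                "assembled, %d retained; myelin volume %.1f um^3"),
         sum(counts[, "adaptive"]), n3_before, nrow(o3$objects),
         myelin_volume)

  structure(list(
    myelin_volume_um3 = myelin_volume,
    nfh_volume_um3 = nfh$nfh_volume_um3,
    nfh_integrated_intensity = nfh$nfh_integrated_intensity,
    normalized_myelin_volume = norm_vol,
    stage_counts = counts,
    n_objects_3d = nrow(o3$objects),
    objects3d = o3,
    adaptive_mask = adaptive,
    final_mask = o3$labels > 0L,
    metadata = metadata,
    param_hash = param_hash(unclass(params)),
    audit = audit), class = "myelinoid_result")
}

#' @export
print.myelinoid_result <- function(x, ...) {
  cat("myelinoid_result (acquisition site)\n")
  cat(sprintf("  myelin volume:        %.1f um^3 (%d 3D objects)\n",
              x$myelin_volume_um3, x$n_objects_3d))
  cat(sprintf("  NF-H volume:          %.1f um^3\n", x$nfh_volume_um3))
  cat(sprintf("  NF-H integrated int.: %.4g counts\n",
              x$nfh_integrated_intensity))
  cat(sprintf("  normalized volume:    %.4g um^3/count\n",
              x$normalized_myelin_volume))
  invisible(x)
}

#' Aggregate site-level results to one row per myelinoid
#'
#' The myelinoid-level value of each measure is the arithmetic mean over its
#' acquisition sites (typically two images per myelinoid).
#'
#' @param site_rows data.frame with one row per site, containing at least
#'   `myelinoid_id` and the measure columns.
#' @param measures columns to average.
#' @return data.frame with one row per myelinoid.
#' @export
aggregate_sites <- function(site_rows,
                            measures = c("myelin_volume_um3",
                                         "nfh_integrated_intensity",
                                         "normalized_myelin_volume")) {
  stopifnot("myelinoid_id" %in% names(site_rows))
  meta_cols <- setdiff(names(site_rows), measures)
  out <- unique(site_rows[!duplicated(site_rows$myelinoid_id),
                          setdiff(meta_cols, c("site_id", "image_id")),
                          drop = FALSE])
  for (m in intersect(measures, names(site_rows))) {
    agg <- tapply(site_rows[[m]], site_rows$myelinoid_id, mean)
    out[[m]] <- as.numeric(agg[match(out$myelinoid_id, names(agg))])
  }
  rownames(out) <- NULL
  out
}
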