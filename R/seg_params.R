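#' Segmentation parameters
#'
#' Holds every setting of the myelin-segmentation cascade. The filter
#' thresholds default to the printed values of the assay the package
#' re-implements: Filter Mask 1 removes 2D objects with fiber breadth > 16 um,
#' fiber length < 10 um or area < 45 um^2; objects are then shrunk by 4 px and
#' Filter Mask 2 removes shrunk objects with elliptical form factor < 3.7,
#' fiber breadth > 8 um or intensity SD < 1000 counts (16-bit); blobs of
#' width 8-100 um and then 4-6 um are enlarged by 5 px and subtracted; 3D
#' objects with volume <= 450 um^3 AND diameter <= 45 um are removed.
#'
#' Micrometre-specified settings are converted to pixels from the stack
#' calibration (rounding half up); pixel-specified settings (shrink 4 px,
#' enlarge 5 px) are used as printed. The intensity-SD threshold is defined
#' at 16-bit camera counts and rescaled by `(2^bit_depth - 1) / 65535` for
#' other depths (logged).
#'
#' Filter logic within each 2D filter mask is disjunctive by default (an
#' object is removed if ANY criterion fires, modelling sequential filter
#' application); set `filter_logic = "and"` for the conjunctive alternative.
#' The 3D filter is always conjunctive (both volume and diameter small), so
#' long thin sheaths of small volume are kept. All inequalities are strict as
#' printed: `<`/`>` removals leave boundary equality retained; the 3D `<=`
#' removals remove at equality.
#'
#' @param myelin_channel channel segmented ("MBP" or "CNP").
#' @param nfh_channel axonal-density channel.
#' @param adaptive_radius_um local-mean window radius of the adaptive
#'   threshold.
#' @param adaptive_offset threshold offset above the local mean, in counts at
#'   16-bit (rescaled with bit depth).
#' @param f1_max_breadth_um,f1_min_length_um,f1_min_area_um2 Filter Mask 1.
#' @param shrink_px erosion radius (disc), pixels.
#' @param f2_min_eff,f2_max_breadth_um,f2_min_intensity_sd Filter Mask 2.
#' @param blob1_range_um,blob2_range_um blob width ranges of the two passes.
#' @param blob_enlarge_px dilation radius applied to blobs before subtraction.
#' @param blob_n_scales Laplacian-of-Gaussian scales per pass (log-spaced).
#' @param blob_rel_threshold detection threshold relative to the plane's
#'   intensity range.
#' @param blob_max_axis_ratio Hessian-based ridge rejection: detections whose
#'   local principal-curvature ratio exceeds this are discarded (blobs are
#'   isotropic, sheath cross-sections are not).
#' @param blob_overlap pruning threshold on the area overlap of detections.
#' @param min_volume_um3,min_diameter_um 3D filter: objects with volume <=
#'   `min_volume_um3` AND diameter <= `min_diameter_um` are removed.
#' @param nfh_threshold global NF-H threshold in counts, or `"otsu"`.
#' @param nfh_integration `"thresholded"` sums NF-H intensity over the
#'   NF-H-segmented volume (default); `"whole"` over the whole image volume.
#' @param filter_logic `"or"` (disjunctive removal, default) or `"and"`.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(myelin_channel = "MBP",
                       nfh_channel = "NFH",
                       adaptive_radius_um = 20,
                       adaptive_offset = 500,
                       f1_max_breadth_um = 16,
                       f1_min_length_um = 10,
                       f1_min_area_um2 = 45,
                       shrink_px = 4L,
                       f2_min_eff = 3.7,
                       f2_max_breadth_um = 8,
                       f2_min_intensity_sd = 1000,
                       blob1_range_um = c(8, 100),
                       blob2_range_um = c(4, 6),
                       blob_enlarge_px = 5L,
                       blob_n_scales = 10L,
                       blob_rel_threshold = 0.1,
                       blob_max_axis_ratio = 2,
                       blob_overlap = 0.5,
                       min_volume_um3 = 450,
                       min_diameter_um = 45,
                       nfh_threshold = "otsu",
                       nfh_integration = c("thresholded", "whole"),
                       filter_logic = c("or", "and")) {
  p <- as.list(environment())
  p$filter_logic <- match.arg(filter_logic)
  p$nfh_integration <- match.arg(nfh_integration)
  stopifnot(p$adaptive_radius_um > 0, p$shrink_px >= 0,
            p$blob_enlarge_px >= 0, p$blob_n_scales >= 2,
            length(p$blob1_range_um) == 2, diff(p$blob1_range_um) > 0,
            p$blob1_range_um[1] > 0,
            length(p$blob2_range_um) == 2, diff(p$blob2_range_um) > 0,
            p$blob2_range_um[1] > 0)
  class(p) <- "seg_params"
  p
}

#' Rescale count-valued thresholds defined at 16-bit to the stack's bit depth
#' @noRd
scale_counts <- function(value, bit_depth) {
  if (bit_depth == 16L) return(value)
  sc <- (2^bit_depth - 1) / 65535
  mq_log("rescaling 16-bit count threshold %g by %.4g for %d-bit data",
         value, sc, bit_depth)
  value * sc
}
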