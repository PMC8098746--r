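# Ground-truth evaluation of a segmentation run on a synthetic stack.

#' Score a pipeline result against simulator ground truth
#'
#' Object-level matching: each predicted 3D object is assigned to the ground
#' truth sheath with which it shares most voxels and counts as a true
#' positive when more than half of its voxels belong to that sheath;
#' precision is the true-positive fraction of predicted objects. A ground
#' truth sheath counts as recalled when at least half of its voxels are in
#' the final mask. Volume error is the signed relative error of total
#' recovered myelin volume; distractor leakage is the fraction of soma and
#' debris voxels that survive to the final mask.
#'
#' @param result a `myelinoid_result` from [run_pipeline()].
#' @param truth the `ground_truth` of the stack the result was computed on.
#' @return A list: `precision`, `recall`, `volume_rel_error`, `leakage`,
#'   `n_predicted`, `n_truth_sheaths`.
#' @export
evaluate_segmentation <- function(result, truth) {
  stopifnot(inherits(result, "myelinoid_result"),
            inherits(truth, "ground_truth"))
  labs3 <- result$objects3d$labels
  final <- result$final_mask
  sheath_ids <- truth$objects$object_id[truth$objects$class == "sheath"]
  pred_labels <- result$objects3d$objects$label
  n_pred <- length(pred_labels)

  tp <- 0L
  if (n_pred > 0) {
    for (pl in pred_labels) {
      vox <- labs3 == pl
      ids <- truth$object_ids[vox]
      ids <- ids[ids %in% sheath_ids]
      if (!length(ids)) next
      best <- max(tabulate(ids))
      if (best / sum(vox) > 0.5) tp <- tp + 1L
    }
  }
  recalled <- vapply(sheath_ids, function(id) {
    vox <- truth$object_ids == id
    sum(final & vox) / sum(vox) >= 0.5
  }, logical(1))

  distract <- truth$labels == GT_CLASSES[["soma"]] |
    truth$labels == GT_CLASSES[["debris"]]
  leakage <- if (any(distract)) sum(final & distract) / sum(distract) else 0

  list(precision = if (n_pred > 0) tp / n_pred else NA_real_,
       recall = if (length(sheath_ids)) mean(recalled) else NA_real_,
       volume_rel_error = if (truth$sheath_volume_um3 > 0)
         (result$myelin_volume_um3 - truth$sheath_volume_um3) /
           truth$sheath_volume_um3 else NA_real_,
       leakage = leakage,
       n_predicted = n_pred,
       n_truth_sheaths = length(sheath_ids))
}
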