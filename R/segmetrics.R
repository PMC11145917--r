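#' Voxel-wise confusion counts between two masks
#'
#' @param pred,gt [mask_volume()]s (or plain 0/1 arrays) of identical shape.
#' @return list of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, gt) {
  p <- if (is.list(pred)) pred$data else pred
  g <- if (is.list(gt)) gt$data else gt
  if (!identical(dim(p), dim(g))) stop("shape mismatch between pred and gt")
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  tn <- sum(p == 0 & g == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

# both masks empty: perfect agreement by convention, flagged
empty_convention <- function(c) c$TP + c$FP + c$FN == 0

#' Segmentation metrics
#'
#' `dice = 2TP / (2TP + FP + FN)`, `sensitivity = TP / (TP + FN)`,
#' `jaccard = TP / (TP + FP + FN)`. When both masks are empty all three are
#' defined as 1 with attribute `empty = TRUE`.
#'
#' @param c a [confusion()] result.
#' @return numeric scalar in `[0, 1]`.
#' @export
dice <- function(c) {
  if (empty_convention(c)) return(structure(1, empty = TRUE))
  2 * c$TP / (2 * c$TP + c$FP + c$FN)
}

#' @rdname dice
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) return(structure(1, empty = TRUE))
  c$TP / (c$TP + c$FN)
}

#' @rdname dice
#' @export
jaccard <- function(c) {
  if (empty_convention(c)) return(structure(1, empty = TRUE))
  c$TP / (c$TP + c$FP + c$FN)
}
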