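# Defuzzification, label alignment and segmentation accuracy.

#' Hard labels from a soft partition
#'
#' Assigns each pixel the 0-based index of its maximal membership; ties go
#' to the lowest cluster index, giving a deterministic rule.
#'
#' @param U n x c membership matrix, n = prod(dim).
#' @param dim Integer `c(height, width)`; pixels are ordered row-major.
#' @return height x width integer label matrix with values in 0..(c-1).
#' @export
defuzzify <- function(U, dim) {
  dim <- as.integer(dim)
  if (nrow(U) != prod(dim)) {
    stop(sprintf("membership rows (%d) do not match grid %d x %d",
                 nrow(U), dim[1], dim[2]), call. = FALSE)
  }
  lab <- max.col(U, ties.method = "first") - 1L
  unflatten_image(lab, dim)
}

#' Align predicted cluster labels to reference labels
#'
#' Cluster indices are arbitrary, so before accuracy can be computed the
#' predicted labels are relabeled by the permutation of the joint label set
#' that maximises total pixel agreement with the reference (exhaustive
#' search over permutations of the confusion matrix; exact, supported up to
#' 8 distinct labels).
#'
#' @param pred,ref Integer label matrices of identical shape.
#' @return Relabeled copy of `pred`, with the chosen permutation attached as
#'   attribute `"mapping"` (a named integer vector, predicted -> reference).
#' @export
align_labels <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) stop("pred and ref must have the same shape", call. = FALSE)
  classes <- sort(union(unique(as.vector(ref)), unique(as.vector(pred))))
  k <- length(classes)
  if (k > 8) stop("exhaustive label alignment supports at most 8 classes", call. = FALSE)
  pi_ <- match(as.vector(pred), classes)
  ri <- match(as.vector(ref), classes)
  conf <- matrix(0, k, k)
  tab <- table(factor(pi_, levels = seq_len(k)), factor(ri, levels = seq_len(k)))
  conf[] <- as.numeric(tab)
  perms <- all_permutations(k)
  scores <- apply(perms, 1, function(p) sum(conf[cbind(seq_len(k), p)]))
  best <- perms[which.max(scores), ]
  mapped <- classes[best][pi_]
  out <- matrix(as.integer(mapped), nrow(pred), ncol(pred))
  mapping <- stats::setNames(as.integer(classes[best]), classes)
  attr(out, "mapping") <- mapping
  out
}

#' Overall segmentation accuracy
#'
#' Fraction of pixels whose (aligned) predicted label equals the reference
#' label.
#'
#' @param pred,ref Integer label matrices of identical shape; `pred` should
#'   already be aligned (see [align_labels()]).
#' @return Scalar in [0, 1].
#' @export
segmentation_accuracy <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) stop("pred and ref must have the same shape", call. = FALSE)
  mean(pred == ref)
}

#' Per-class segmentation accuracy (Jaccard index)
#'
#' For class j, the ratio |pred_j intersect ref_j| / |pred_j union ref_j| of
#' the two pixel sets. When both sets are empty the class is vacuously
#' perfect and the value is 1.
#'
#' @inheritParams segmentation_accuracy
#' @param class Single class label, or `NULL` for all reference classes.
#' @return Scalar, or a named vector over classes when `class` is `NULL`.
#' @export
per_class_accuracy <- function(pred, ref, class = NULL) {
  if (!all(dim(pred) == dim(ref))) stop("pred and ref must have the same shape", call. = FALSE)
  known <- union(unique(as.vector(ref)), unique(as.vector(pred)))
  jac <- function(j) {
    a <- pred == j
    b <- ref == j
    uni <- sum(a | b)
    if (uni == 0) 1 else sum(a & b) / uni
  }
  if (is.null(class)) {
    cls <- sort(unique(as.vector(ref)))
    return(stats::setNames(vapply(cls, jac, numeric(1)), cls))
  }
  if (!(class %in% known)) stop(sprintf("unknown class %s", class), call. = FALSE)
  jac(class)
}

#' Full accuracy report for a segmentation
#'
#' Aligns the predicted labels to the reference and reports overall and
#' per-class accuracy together with the label mapping used.
#'
#' @inheritParams segmentation_accuracy
#' @return List with `sa`, `per_class` (named Jaccard vector), `mapping` and
#'   the aligned `labels`.
#' @export
evaluate_segmentation <- function(pred, ref) {
  aligned <- align_labels(pred, ref)
  list(sa = segmentation_accuracy(aligned, ref),
       per_class = per_class_accuracy(aligned, ref),
       mapping = attr(aligned, "mapping"),
       labels = aligned)
}
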