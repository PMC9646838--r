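# The core slide-representation algorithm.
#
# A slide's patches are ranked by their predictive score (ties broken by
# higher mean activation, then by patch order). Each of the top-K patches is
# summarised by a modified class-activation map: the importance of the m-th
# activation map is the ReLU of the SUM of the class-objective gradients
# over that map (negative maps are eliminated before combination, unlike
# original Grad-CAM which rectifies the combined map), the class feature map
# is the importance-weighted sum of the activation maps, and its flattened
# values are sorted in descending order. Stacking the K sorted vectors and
# ordering rows by descending row sum yields a fixed K x (H*W) matrix
# whatever the slide's size.

#' Rank patches and keep the top K
#'
#' Orders patches by predictive score (descending); equal scores rank the
#' patch with the higher mean activation first, and remaining ties keep the
#' original patch order.
#'
#' @param scores a [score_patches()] data frame (columns `prob`,
#'   `mean_activation`, optionally `patch_index`).
#' @param k number of patches to keep (>= 1).
#' @return integer vector of 1-based patch indices, length `min(k, n)`.
#' @export
rank_top_k <- function(scores, k) {
  if (k < 1) stop("k must be >= 1")
  n <- nrow(scores)
  idx <- scores$patch_index %||% seq_len(n)
  ord <- order(-scores$prob, -scores$mean_activation, idx)
  idx[ord][seq_len(min(k, n))]
}

bundle_mats <- function(bundle) {
  a <- bundle$activations
  g <- bundle$gradients
  if (!all(dim(a) == dim(g))) stop("activations and gradients differ in shape")
  list(a = a, g = g, H = dim(a)[1], W = dim(a)[2], M = dim(a)[3])
}

#' Importance scores of the activation maps
#'
#' `alpha_m = ReLU(sum_ij dP_C / dA^m_ij)`: the gradients of the class
#' objective are summed over each activation map and clamped at zero, so
#' negatively contributing maps are eliminated before the maps are combined.
#' `reduce = "mean"` divides the sum by `H*W` (the original global-average
#' weighting); `relu = FALSE` keeps signed weights for comparison runs.
#'
#' @param bundle an [activation_bundle()].
#' @param reduce `"sum"` (default) or `"mean"` over each map's gradients.
#' @param relu clamp negative per-map sums at zero (default `TRUE`).
#' @return numeric vector `alpha` of length M.
#' @export
compute_importance <- function(bundle, reduce = c("sum", "mean"), relu = TRUE) {
  reduce <- match.arg(reduce)
  b <- bundle_mats(bundle)
  s <- colSums(matrix(b$g, b$H * b$W, b$M))
  if (reduce == "mean") s <- s / (b$H * b$W)
  if (relu) pmax(s, 0) else s
}

#' Class-specific feature map
#'
#' `T_ij = sum_m alpha_m * A^m_ij`. No rectification is applied here: the
#' ReLU already acted on the importance scores, and exposed activations are
#' post-ReLU, so `T` is non-negative. Set `relu = TRUE` to reproduce the
#' original formulation (rectify the combined map instead).
#'
#' @param alpha importance vector of length M.
#' @param bundle the matching [activation_bundle()].
#' @param relu rectify the combined map (original-style; default `FALSE`).
#' @return `H x W` matrix.
#' @export
class_feature_map <- function(alpha, bundle, relu = FALSE) {
  b <- bundle_mats(bundle)
  if (length(alpha) != b$M)
    stop("alpha length ", length(alpha), " does not match M = ", b$M)
  tm <- matrix(matrix(b$a, b$H * b$W, b$M) %*% alpha, b$H, b$W)
  if (relu) pmax(tm, 0) else tm
}

#' Patch representation vector
#'
#' Flattens the class feature map and sorts the values in descending order.
#'
#' @param tmap `H x W` class feature map.
#' @return numeric vector of length `H*W`, non-increasing.
#' @export
patch_representation <- function(tmap) {
  if (length(tmap) == 0) stop("empty feature map")
  sort(as.vector(tmap), decreasing = TRUE)
}

#' Aggregate patch representations into the slide map
#'
#' Stacks the representation vectors as rows and sorts the rows by
#' descending row sum (stable: tied sums keep their pre-sort order), so the
#' most activated patch representations sit at the top. When fewer than `k`
#' representations are supplied, all-zero rows pad the bottom and
#' `pad_count` records how many.
#'
#' @param reps list of equal-length [patch_representation()] vectors (at
#'   most `k`).
#' @param k the configured top-patch count.
#' @param patch_indices optional 1-based patch index per representation,
#'   kept as row provenance.
#' @param slide_id optional slide identifier.
#' @param hw_dims optional `c(H, W)` of the underlying feature maps, kept as
#'   provenance (and fixing the row length when `reps` is empty).
#' @return an `hm_hipomap`: matrix `X` (`k x length(rep)`), `K`, `H`, `W`
#'   (when known), `pad_count`, and `patch_index` per row (NA for padding).
#' @export
build_hipomap <- function(reps, k, patch_indices = NULL, slide_id = NULL,
                          hw_dims = NULL) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  n <- length(reps)
  if (n > k) stop("more representations (", n, ") than k = ", k)
  if (n > 0) {
    len <- unique(vapply(reps, length, 0L))
    if (length(len) != 1) stop("representations have inconsistent lengths")
  } else len <- if (!is.null(hw_dims)) prod(hw_dims) else 0L
  patch_indices <- patch_indices %||% seq_len(n)
  x <- matrix(0, nrow = k, ncol = len)
  row_idx <- rep(NA_integer_, k)
  if (n > 0) {
    mat <- do.call(rbind, reps)
    ord <- order(-rowSums(mat))          # radix sort: stable on ties
    x[seq_len(n), ] <- mat[ord, , drop = FALSE]
    row_idx[seq_len(n)] <- patch_indices[ord]
  }
  structure(list(X = x, K = k,
                 H = if (!is.null(hw_dims)) hw_dims[1] else NA_integer_,
                 W = if (!is.null(hw_dims)) hw_dims[2] else NA_integer_,
                 pad_count = k - n, patch_index = row_idx,
                 slide_id = slide_id),
            class = "hm_hipomap")
}

#' Slide to fixed-size representation map
#'
#' End-to-end composition: score all patches, keep the top K, compute each
#' selected patch's class feature map from its activation bundle, flatten
#' and sort it, and aggregate the K vectors into the slide map. `K = 50` is
#' the default operating point.
#'
#' @param slide an `hm_slide` (or list of patches).
#' @param model an `hm_patch_model`.
#' @param class_index 1-based target class for scoring and for the class
#'   objective.
#' @param k top-patch count.
#' @param variant `"modified"` (default: ReLU on the per-map gradient sums)
#'   or `"original"` (mean-gradient weights, ReLU on the combined map).
#' @param wrt gradient target, `"prob"` or `"logit"`.
#' @return an `hm_hipomap`.
#' @export
slide_to_hipomap <- function(slide, model, class_index = 1L, k = 50L,
                             variant = c("modified", "original"),
                             wrt = c("prob", "logit")) {
  variant <- match.arg(variant)
  wrt <- match.arg(wrt)
  scores <- score_patches(model, slide, class_index)
  patches <- if (inherits(slide, "hm_slide")) slide$patches else slide
  if (nrow(scores) == 0) {
    d <- if (!is.null(model$act_dim)) model$act_dim[1:2]
         else model$input_dim[1:2] %/% 8L
    return(build_hipomap(list(), k, slide_id = slide$slide_id %||% NULL,
                         hw_dims = d))
  }
  sel <- rank_top_k(scores, k)
  reps <- vector("list", length(sel))
  hw <- NULL
  for (i in seq_along(sel)) {
    bundle <- activation_bundle(model, patches[[sel[i]]], class_index, wrt = wrt)
    if (variant == "modified") {
      alpha <- compute_importance(bundle, reduce = "sum", relu = TRUE)
      tmap <- class_feature_map(alpha, bundle)
    } else {
      alpha <- compute_importance(bundle, reduce = "mean", relu = FALSE)
      tmap <- class_feature_map(alpha, bundle, relu = TRUE)
    }
    hw <- dim(tmap)
    reps[[i]] <- patch_representation(tmap)
  }
  build_hipomap(reps, k, patch_indices = sel,
                slide_id = if (inherits(slide, "hm_slide")) slide$slide_id else NULL,
                hw_dims = hw)
}
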