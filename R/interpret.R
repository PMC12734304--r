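# Model inspection: occlusion testing over axial slice windows and per-layer
# mean-absolute-weight summaries.

#' Occlusion sensitivity profile over axial slice windows
#'
#' Masks consecutive axial slices of every volume with a fill value, then
#' recomputes classification accuracy; the drop from the unmasked baseline
#' localizes the decision-relevant depth range. Slice windows are 0-based and
#' half-open along the depth axis; the default non-overlapping 10-slice
#' windows match the granularity at which slice relevance is usually
#' reported. The input volumes are never modified.
#'
#' @param model a `slim3d_model`.
#' @param volumes list of [volume()]s or 3D arrays.
#' @param labels integer 0/1 labels.
#' @param window_size number of consecutive slices per window.
#' @param stride window stride (equal to `window_size` for non-overlapping
#'   windows).
#' @param fill intensity written into the occluded slices (0 is the
#'   post-normalization background).
#' @return An object of class `slim3d_occlusion`: data frame with
#'   `window_start`, `window_end`, `accuracy`, `drop_from_baseline`, plus
#'   attributes `baseline_accuracy` and `argmax_window`.
#' @export
occlusion_profile <- function(model, volumes, labels, window_size = 10L,
                              stride = window_size, fill = 0) {
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "slim3d_volume")) v$data else v)
  labels <- as.integer(labels)
  depth <- dim(arrs[[1]])[1]
  starts <- seq(0L, depth - 1L, by = stride)
  baseline <- model_evaluate(model, arrs, labels)$accuracy
  acc <- numeric(length(starts))
  ends <- integer(length(starts))
  if (any(starts < 0L | starts >= depth))
    stop("occlusion windows must start inside [0, depth)")
  for (w in seq_along(starts)) {
    s <- starts[w]
    e <- min(s + window_size, depth)
    ends[w] <- e
    if (e == s) {           # empty window: nothing occluded
      acc[w] <- baseline
      next
    }
    masked <- lapply(arrs, function(a) {
      a[(s + 1L):e, , ] <- fill
      a
    })
    acc[w] <- model_evaluate(model, masked, labels)$accuracy
  }
  out <- data.frame(window_start = starts, window_end = ends,
                    accuracy = acc, drop_from_baseline = baseline - acc)
  attr(out, "baseline_accuracy") <- baseline
  attr(out, "argmax_window") <- c(starts[which.max(baseline - acc)],
                                  ends[which.max(baseline - acc)])
  class(out) <- c("slim3d_occlusion", "data.frame")
  out
}

#' Per-layer weight-importance summary
#'
#' For every convolutional (and fully connected) layer, the mean absolute
#' weight value over all its kernel entries, with pruned (masked) channels
#' excluded. Large values flag layers that carry most of the feature
#' extraction.
#'
#' @param model a `slim3d_model`.
#' @return Data frame with `layer`, `mean_abs_weight`, `n_params`.
#' @export
layer_importance <- function(model) {
  stopifnot(inherits(model, "slim3d_model"))
  if (any_masked(model)) model <- compact(model)
  rows <- list()
  for (n in names(model$layers)) {
    l <- model$layers[[n]]
    ws <- switch(l$type,
      pointwise = list(l$params$W),
      depthwise = list(l$params$W),
      dense = list(l$params$W),
      lmf = lapply(grep("^(dw|pw|W)", names(l$params), value = TRUE),
                   function(p) l$params[[p]]),
      NULL)
    if (is.null(ws)) next
    w <- unlist(ws, use.names = FALSE)
    rows[[n]] <- data.frame(layer = n, mean_abs_weight = mean(abs(w)),
                            n_params = length(w))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
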