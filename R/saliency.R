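## 1-D saliency for the convolutional models: gradient x input, and a
## Grad-CAM variant over the last conv block's feature maps.

#' Saliency map for one segment
#'
#' `"grad_input"` returns the elementwise gradient of the output score with
#' respect to the input, multiplied by the input. `"grad_cam"` weights the
#' last conv block's feature maps by their pooled score gradients, rectifies
#' the weighted sum, and linearly upsamples it to the input length; for the
#' dual-branch model the two branches' maps are summed after upsampling.
#' Both outputs align 1:1 with input samples.
#'
#' @param model A fitted network `osa_model` (trees/forests are not
#'   differentiable and are rejected).
#' @param segment Numeric vector of length `input_len`.
#' @param method `"grad_input"` or `"grad_cam"`.
#' @return Numeric vector of the segment length (non-negative for
#'   `"grad_cam"`).
#' @export
saliency_map <- function(model, segment, method = c("grad_input",
                                                    "grad_cam")) {
  method <- match.arg(method)
  if (!inherits(model, "osa_net_model"))
    osa_abort("saliency requires a convolutional model",
              "osadetect_unsupported_error")
  spec <- model$spec
  x <- as.numeric(segment)
  if (length(x) != spec$input_len)
    abort_param("segment length must equal the model input_len")
  X <- matrix(x, nrow = 1L)
  fw <- forward_batch(spec, model$params, model$bn_state, X,
                      training = FALSE, keep_cache = TRUE)
  p <- fw$scores
  dz <- p * (1 - p)             # d score / d preactivation
  bw <- backward_batch(spec, model$params, fw, dz, want_input_grad = TRUE)
  if (method == "grad_input") return(as.numeric(bw$dX) * x)
  out <- numeric(spec$input_len)
  for (b in seq_along(spec$branches)) {
    bc <- fw$cache$branches[[b]]
    L <- bc$L_final
    C <- bc$C_final
    ## feature maps A (L x C) and gradients dA at the last block output
    last <- spec$branches[[b]]$blocks
    blk <- bc$blocks[[last]]
    A <- if (spec$branches[[b]]$use_batch_norm) blk$bn$Y else blk$mp$Y
    dA <- bw$dblock_last[[b]]
    alpha <- colMeans(matrix(dA, nrow = L))        # pooled weights per map
    cam <- pmax(matrix(A, nrow = L) %*% alpha, 0)  # ReLU of weighted sum
    up <- if (L == 1L) rep(as.numeric(cam), spec$input_len) else
      stats::approx(seq(0, 1, length.out = L), as.numeric(cam),
                    xout = seq(0, 1, length.out = spec$input_len))$y
    out <- out + up
  }
  out
}
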