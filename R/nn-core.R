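# Minimal module framework: every layer is a list carrying (a) plain config
# fields, (b) `params`, a named list of parameter environments with value $v
# and accumulated gradient $g, (c) `modules`, a named list of sub-modules, and
# (d) `cache`/`state` environments (reference semantics survive list copies).
# Forward passes cache what the hand-derived backward pass needs only when
# train = TRUE; backward passes return dL/dx and add into parameter gradients.

new_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- if (is.null(dim(value))) numeric(length(value)) else
    array(0, dim(value))
  class(e) <- "nn_param"
  e
}

new_module <- function(class, ..., params = list(), modules = list()) {
  structure(list(..., params = params, modules = modules,
                 cache = new.env(parent = emptyenv()),
                 state = new.env(parent = emptyenv())),
            class = c(class, "nn_module"))
}

#' Apply a network module to an input
#'
#' Generic forward pass. With `train = TRUE` the module caches the
#' intermediates its backward pass needs; with `train = FALSE` (evaluation
#' mode) nothing is cached and normalization layers use their running
#' statistics.
#'
#' @param mod A module created by one of the layer/block/network constructors.
#' @param x Input: a feature map array `(H, W, C, N)` for spatial modules or a
#'   token array `(T, E, N)` for token modules.
#' @param train Logical; cache intermediates for [nn_backward()]?
#' @return Output array of the module.
#' @export
nn_forward <- function(mod, x, train = FALSE) UseMethod("nn_forward")

#' Reverse-mode gradient step through a module
#'
#' Propagates the loss gradient `dy` (same shape as the module's last forward
#' output) back through the module, accumulating parameter gradients in place.
#' The module must have been run forward with `train = TRUE`.
#'
#' @param mod A module.
#' @param dy Gradient of the loss with respect to the module output.
#' @return Gradient of the loss with respect to the module input.
#' @export
nn_backward <- function(mod, dy) UseMethod("nn_backward")

#' Collect the parameters of a module tree
#'
#' @param mod A module.
#' @return Flat named list of parameter environments (each with `$v`, `$g`).
#' @export
nn_parameters <- function(mod) {
  out <- mod$params
  if (length(out)) names(out) <- paste0(class(mod)[1], ".", names(out))
  for (nm in names(mod$modules)) {
    sub <- nn_parameters(mod$modules[[nm]])
    if (length(sub)) {
      names(sub) <- paste0(nm, ".", names(sub))
      out <- c(out, sub)
    }
  }
  out
}

#' Number of trainable parameters in a module
#' @param mod A module.
#' @return Non-negative integer count of scalar parameters.
#' @export
parameter_count <- function(mod) {
  sum(vapply(nn_parameters(mod), function(p) length(p$v), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$g <- if (is.null(dim(p$v))) numeric(length(p$v)) else
    array(0, dim(p$v))
  invisible(NULL)
}

# flat list of all modules in a tree (prefix order), names joined with "."
module_list <- function(mod, prefix = "net") {
  out <- stats::setNames(list(mod), prefix)
  for (nm in names(mod$modules))
    out <- c(out, module_list(mod$modules[[nm]], paste0(prefix, ".", nm)))
  out
}

# He-uniform init for conv kernels, Xavier-uniform for dense projections;
# draws from the current RNG stream so builds are seedable by the caller
init_he <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dims)
}
init_xavier <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  for (p in params) {
    p$m <- p$g * 0
    p$s <- p$g * 0
  }
  invisible(NULL)
}

adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (p in params) {
    p$m <- beta1 * p$m + (1 - beta1) * p$g
    p$s <- beta2 * p$s + (1 - beta2) * p$g^2
    p$v <- p$v - lr * (p$m / bc1) / (sqrt(p$s / bc2) + eps)
  }
  invisible(NULL)
}
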