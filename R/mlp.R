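#' Specification of one per-vessel network
#'
#' Feedforward fully connected network mapping normalized space-time
#' coordinates `(x_hat, t_hat)` to the three dimensionless unknowns
#' `(A*, u*, p*)`, with hyperbolic-tangent hidden activations and a
#' linear output layer. Weights are initialised with the Glorot uniform
#' scheme, deterministically from `init_seed`.
#'
#' @param hidden_layers Number of hidden layers (default 7).
#' @param hidden_width Neurons per hidden layer (default 100).
#' @param init_seed Integer seed for the weight initialisation.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(hidden_layers = 7, hidden_width = 100,
                         init_seed = 1L) {
  if (hidden_layers < 1 || hidden_width < 1)
    abort("network dimensions must be positive integers.")
  structure(list(n_inputs = 2L, hidden_layers = as.integer(hidden_layers),
                 hidden_width = as.integer(hidden_width), n_outputs = 3L,
                 init_seed = as.integer(init_seed)),
            class = "network_spec")
}

#' Build (initialise) a network from its specification
#'
#' @param spec A [network_spec()].
#' @return An object of class `pinn_network`: lists `W`, `b` of weight
#'   matrices (output x input) and bias vectors, plus the spec.
#' @export
build_network <- function(spec) {
  if (!inherits(spec, "network_spec")) abort("`spec` must be a `network_spec`.")
  dims <- c(spec$n_inputs, rep(spec$hidden_width, spec$hidden_layers),
            spec$n_outputs)
  set.seed(spec$init_seed)
  W <- list(); b <- list()
  gain <- 5 / 3     # Glorot-uniform calibrated for tanh activations
  for (l in seq_len(length(dims) - 1L)) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    lim <- gain * sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_out, fan_in)
    b[[l]] <- rep(0, fan_out)
  }
  # affine output map: outputs = out_shift + out_scale * raw outputs.
  # Identity by default; the assembly sets it from the data statistics so
  # each output works at unit scale regardless of its physical amplitude.
  structure(list(W = W, b = b, spec = spec,
                 out_shift = c(0, 0, 0), out_scale = c(1, 1, 1)),
            class = "pinn_network")
}

#' Evaluate a network and the derivatives of its outputs
#'
#' Forward pass over a batch of normalized coordinates, carrying
#' forward-mode tangents with respect to both inputs, so the outputs'
#' exact partial derivatives `d(A*,u*,p*)/d x_hat` and `/d t_hat` come
#' out of the same pass (no finite differencing).
#'
#' @param net A [build_network()] result.
#' @param X `2 x N` matrix of `(x_hat, t_hat)` columns.
#' @param tangents Compute input derivatives (default `TRUE`).
#' @param keep_cache Keep per-layer intermediates for a reverse pass.
#' @return List with `Y` (`3 x N` outputs), and when requested `Yx`,
#'   `Yt` (`3 x N` derivatives) and `cache`.
#' @keywords internal
#' @export
mlp_forward <- function(net, X, tangents = TRUE, keep_cache = FALSE) {
  mlp_fwd_cpp(net$W, net$b, X, net$out_shift, net$out_scale,
              tangents, keep_cache)
}

# Reverse pass through the tangent-carrying forward computation: given the
# adjoints of Y, Yx, Yt, accumulate the gradient of a scalar loss with
# respect to every weight and bias. Second-order terms (d tanh'(a)/da =
# -2 tanh(a) tanh'(a)) enter because the loss depends on input derivatives.
mlp_backward <- function(net, fwd, Gy, Gyx = NULL, Gyt = NULL) {
  empty <- matrix(0, 0, 0)
  mlp_bwd_cpp(net$W, fwd$cache, fwd$last, Gy,
              if (is.null(Gyx)) empty else Gyx,
              if (is.null(Gyt)) empty else Gyt,
              net$out_scale, !is.null(Gyx))
}

# flatten / restore parameters (finite-difference checks, serialization)
net_get_params <- function(net) unlist(c(net$W, net$b), use.names = FALSE)

net_set_params <- function(net, theta) {
  i <- 0L
  for (l in seq_along(net$W)) {
    n <- length(net$W[[l]])
    net$W[[l]][] <- theta[(i + 1L):(i + n)]; i <- i + n
  }
  for (l in seq_along(net$b)) {
    n <- length(net$b[[l]])
    net$b[[l]][] <- theta[(i + 1L):(i + n)]; i <- i + n
  }
  net
}

#' @export
print.pinn_network <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<pinn_network>  2 -> %s -> 3 (tanh), %d parameters\n",
              paste(rep(s$hidden_width, s$hidden_layers), collapse = " -> "),
              length(net_get_params(x))))
  invisible(x)
}
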