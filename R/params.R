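#' Construct a closed-loop network parameter set
#'
#' Creates the full weight/architecture container for the feedback-controlled
#' recurrent network: recurrent weights `W` (N x N), input weights `W_in`
#' (N x 3; target dx, dy and hold channels), readout `W_out` (2 x N, cm/s),
#' feedback weights `F` (N x 2, driven by the delayed cursor error in cm),
#' biases `b` (N) and `b_out` (2), and binary connectivity masks. Weights are
#' initialised uniformly in (-1/sqrt(l), 1/sqrt(l)) with l = N for
#' `W`, `W_in`, `F`, `b` and l = 2 (the output dimensionality) for
#' `W_out`, `b_out`.
#'
#' @param N number of units.
#' @param dt simulation step, ms.
#' @param tau unit time constant, ms.
#' @param delta feedback delay, ms; must be an integer multiple of `dt`.
#' @param seed integer seed for the weight initialisation stream.
#' @param recurrent_prob,feedback_prob connection probabilities used to draw
#'   the binary recurrent/feedback masks (1 = all-to-all, the default).
#' @param feedback if `FALSE`, the feedback pathway is removed entirely
#'   (`F` and its mask fixed at zero).
#' @param recurrent if `FALSE`, recurrent connections are removed
#'   (`W` and its mask fixed at zero).
#' @return An object of class `network_params`.
#' @export
network_params <- function(N = 400, dt = 10, tau = 50, delta = 120,
                           seed = 1, recurrent_prob = 1, feedback_prob = 1,
                           feedback = TRUE, recurrent = TRUE) {
  if (dt <= 0 || tau <= 0) stop("dt and tau must be positive")
  if (abs(delta / dt - round(delta / dt)) > 1e-9)
    stop("delta must be an integer multiple of dt")
  set.seed(seed)
  lim_n <- 1 / sqrt(N)
  lim_o <- 1 / sqrt(2)
  p <- list(
    W     = matrix(stats::runif(N * N, -lim_n, lim_n), N, N),
    W_in  = matrix(stats::runif(N * 3, -lim_n, lim_n), N, 3),
    W_out = matrix(stats::runif(2 * N, -lim_o, lim_o), 2, N),
    F     = matrix(stats::runif(N * 2, -lim_n, lim_n), N, 2),
    b     = stats::runif(N, -lim_n, lim_n),
    b_out = stats::runif(2, -lim_o, lim_o),
    N = N, dt = dt, tau = tau, delta = delta,
    delta_steps = as.integer(round(delta / dt)),
    phi = "relu")
  p$mask_W <- matrix(as.numeric(stats::runif(N * N) < recurrent_prob), N, N)
  p$mask_F <- matrix(as.numeric(stats::runif(N * 2) < feedback_prob), N, 2)
  if (!feedback)  p$mask_F[] <- 0
  if (!recurrent) p$mask_W[] <- 0
  p$W <- p$W * p$mask_W
  p$F <- p$F * p$mask_F
  class(p) <- "network_params"
  p
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> N = %d units, dt = %g ms, tau = %g ms, delay = %g ms (%d steps)\n",
              x$N, x$dt, x$tau, x$delta, x$delta_steps))
  cat(sprintf("  recurrent density %.2f, feedback density %.2f, phi = %s\n",
              mean(x$mask_W), mean(x$mask_F), x$phi))
  invisible(x)
}

# validity check used before simulation
check_params <- function(p) {
  stopifnot(inherits(p, "network_params"))
  N <- p$N
  if (!all(dim(p$W) == c(N, N)) || !all(dim(p$W_in) == c(N, 3)) ||
      !all(dim(p$W_out) == c(2, N)) || !all(dim(p$F) == c(N, 2)))
    stop("parameter dimensions inconsistent with N")
  if (any(p$W[p$mask_W == 0] != 0)) stop("masked recurrent weights must be 0")
  if (any(p$F[p$mask_F == 0] != 0)) stop("masked feedback weights must be 0")
  invisible(TRUE)
}

# deterministic substream derivation: one master seed fans out to named
# streams so every trial/component is reproducible in isolation
substream <- function(master, stream, counter = 0) {
  stream_id <- sum(utf8ToInt(as.character(stream))) %% 1009L
  as.integer((as.numeric(master) * 48271 + stream_id * 69621 + counter * 16807) %%
               2147483647)
}
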