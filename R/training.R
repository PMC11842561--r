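#' Configuration for the gradient-based initial training phase
#'
#' Defaults follow the standard settings: Adam with learning rate 0.001
#' (beta1 = 0.9, beta2 = 0.999), batch size 20, weight regularisation
#' 0.001, activity regularisation 0.002, gradient norm clipped at 0.2, and
#' a three-block schedule of (100, 500, 500) epochs: block 1 trains the
#' feedforward pathway with the feedback weights frozen, block 2 releases
#' all parameters, block 3 adds random velocity-bump perturbations so the
#' network learns online correction.
#'
#' @param alpha Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param batch_size trials per epoch (one parameter update per epoch).
#' @param weight_reg L2-norm penalty weight (beta).
#' @param activity_reg mean-squared-activity penalty weight (gamma).
#' @param grad_clip_norm global gradient-norm clip applied before the
#'   optimiser step.
#' @param epochs integer 3-vector, epochs per block.
#' @param seed master seed for initialisation and trial generation.
#' @param N,dt,tau,delta network architecture settings (see
#'   [network_params()]).
#' @return an object of class `training_config`.
#' @export
training_config <- function(alpha = 0.001, adam_beta1 = 0.9,
                            adam_beta2 = 0.999, batch_size = 20,
                            weight_reg = 0.001, activity_reg = 0.002,
                            grad_clip_norm = 0.2,
                            epochs = c(100, 500, 500), seed = 1,
                            N = 400, dt = 10, tau = 50, delta = 120) {
  stopifnot(length(epochs) == 3, all(epochs >= 0))
  structure(list(alpha = alpha, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = batch_size,
                 weight_reg = weight_reg, activity_reg = activity_reg,
                 grad_clip_norm = grad_clip_norm, epochs = epochs,
                 seed = seed, N = N, dt = dt, tau = tau, delta = delta),
            class = "training_config")
}

frob_norm <- function(M) sqrt(sum(M^2))

#' Loss breakdown for a batch of executed trials
#'
#' The training loss: a mean squared cursor error term
#' `sum(eps^2) / (2 B T)`, a weight penalty `beta * sum(||M||_2)` over the
#' six parameter tensors (Euclidean/Frobenius norm of each tensor, not
#' squared), and an activity penalty `gamma * sum(y^2) / (N B T)`.
#'
#' @param batch_results non-empty list of `trial_result`.
#' @param params a `network_params`.
#' @param config a `training_config`.
#' @return list with `error_term`, `weight_term`, `activity_term`, `total`.
#' @export
compute_loss <- function(batch_results, params, config) {
  if (length(batch_results) == 0) stop("empty batch")
  B <- length(batch_results)
  T <- ncol(batch_results[[1]]$epsilon)
  err <- sum(vapply(batch_results, function(r) sum(r$epsilon^2), numeric(1)))
  act <- sum(vapply(batch_results, function(r) sum(r$y^2), numeric(1)))
  tensors <- list(params$W, params$W_in, params$W_out, params$F,
                  params$b, params$b_out)
  wt <- config$weight_reg * sum(vapply(tensors, frob_norm, numeric(1)))
  error_term <- err / (2 * B * T)
  activity_term <- config$activity_reg * act / (params$N * B * T)
  list(error_term = error_term, weight_term = wt,
       activity_term = activity_term,
       total = error_term + wt + activity_term)
}

default_task_generator <- function(master_seed) {
  function(epoch, n, bumps) {
    lapply(seq_len(n), function(i) {
      s <- substream(master_seed, "spec", (epoch - 1) * n + i)
      tr <- make_random_reach_trial(s)
      if (bumps)
        tr <- apply_bump(tr, substream(master_seed, "bump",
                                       (epoch - 1) * n + i))
      tr
    })
  }
}

# assemble the dense per-trial arrays (plus initial conditions) consumed by
# the C++ gradient kernel
batch_inputs <- function(trials, params, master_seed, epoch) {
  n <- length(trials)
  lapply(seq_len(n), function(i) {
    inp <- trial_inputs(trials[[i]], params)
    set.seed(substream(master_seed, "x0", (epoch - 1) * n + i))
    x0 <- stats::runif(params$N, -0.2, 0.2)
    list(S = inp$S, Pstar = inp$Pstar, bump = inp$bump, rot = inp$rot,
         x0 = x0, p0 = trials[[i]]$p_start)
  })
}

adam_init <- function(params, names) {
  st <- list(t = 0, m = list(), v = list())
  for (nm in names) st$m[[nm]] <- st$v[[nm]] <- params[[nm]] * 0
  st
}

#' Train the closed-loop network (initial gradient phase)
#'
#' Backpropagates through the full closed loop — dynamics, readout,
#' position integration, error, and the delayed feedback path — and applies
#' Adam updates with global gradient-norm clipping. Block 1 freezes the
#' feedback weights, block 3 enables bump perturbations. Weight
#' initialisation is uniform in (-1/sqrt(l), 1/sqrt(l)); masked-out weights
#' stay exactly zero throughout.
#'
#' @param config a `training_config`.
#' @param task_generator optional `function(epoch, n, bumps)` returning a
#'   list of `trial_spec`; defaults to random reaches (with bumps in
#'   block 3).
#' @param params optional pre-built `network_params` (architecture variants).
#' @param feedback,recurrent disable the feedback path / recurrent weights
#'   for the control models.
#' @param verbose print the loss every 25 epochs.
#' @return the trained `network_params`, with the per-epoch loss breakdown
#'   attached as attribute `"history"`.
#' @export
train_initial <- function(config, task_generator = NULL, params = NULL,
                          feedback = TRUE, recurrent = TRUE,
                          verbose = FALSE) {
  if (is.null(params))
    params <- network_params(N = config$N, dt = config$dt, tau = config$tau,
                             delta = config$delta,
                             seed = substream(config$seed, "init"),
                             feedback = feedback, recurrent = recurrent)
  if (is.null(task_generator))
    task_generator <- default_task_generator(config$seed)
  par_names <- c("W", "W_in", "W_out", "F", "b", "b_out")
  adam <- adam_init(params, par_names)
  blocks <- rep(1:3, times = config$epochs)
  history <- vector("list", length(blocks))

  for (epoch in seq_along(blocks)) {
    block <- blocks[epoch]
    trials <- task_generator(epoch, config$batch_size, block == 3)
    inputs <- batch_inputs(trials, params, config$seed, epoch)
    g <- cpp_batch_grad(unclass(params), inputs, config$activity_reg,
                        feedback)
    if (!is.finite(g$error_term))
      stop(sprintf("training diverged (loss not finite) at epoch %d", epoch))

    grads <- list(W = g$gW, W_in = g$gW_in, W_out = g$gW_out, F = g$gF,
                  b = g$gb, b_out = g$gb_out)
    wt <- 0
    for (nm in par_names) {            # gradient of beta * ||M||_2 per tensor
      nrm <- frob_norm(params[[nm]])
      wt <- wt + config$weight_reg * nrm
      if (nrm > 0)
        grads[[nm]] <- grads[[nm]] + config$weight_reg * params[[nm]] / nrm
    }
    grads$W <- grads$W * params$mask_W
    grads$F <- grads$F * params$mask_F
    if (block == 1 || !feedback) grads$F[] <- 0
    if (!recurrent) grads$W[] <- 0

    gn <- sqrt(sum(vapply(grads, function(x) sum(x^2), numeric(1))))
    if (gn > config$grad_clip_norm)
      grads <- lapply(grads, function(x) x * config$grad_clip_norm / gn)

    adam$t <- adam$t + 1
    b1 <- config$adam_beta1; b2 <- config$adam_beta2
    for (nm in par_names) {
      adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * grads[[nm]]
      adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- adam$m[[nm]] / (1 - b1^adam$t)
      vhat <- adam$v[[nm]] / (1 - b2^adam$t)
      params[[nm]] <- params[[nm]] - config$alpha * mhat / (sqrt(vhat) + 1e-8)
    }
    params$W <- params$W * params$mask_W
    params$F <- params$F * params$mask_F

    history[[epoch]] <- data.frame(epoch = epoch, block = block,
                                   error_term = g$error_term,
                                   weight_term = wt,
                                   activity_term = g$activity_term,
                                   total = g$error_term + wt + g$activity_term)
    if (verbose && epoch %% 25 == 0)
      message(sprintf("epoch %4d (block %d): error %.4f, total %.4f",
                      epoch, block, g$error_term,
                      history[[epoch]]$total))
  }
  attr(params, "history") <- do.call(rbind, history)
  attr(params, "training_config") <- config
  params
}

#' Train the no-feedback control model
#'
#' Identical curriculum with the feedback path removed: the feedback
#' weights are fixed at zero and the delayed error never enters the
#' dynamics. This network cannot correct its output online.
#'
#' @inheritParams train_initial
#' @return trained `network_params`.
#' @export
train_no_feedback <- function(config, task_generator = NULL,
                              verbose = FALSE) {
  train_initial(config, task_generator, feedback = FALSE, verbose = verbose)
}

#' Train the no-recurrence control model
#'
#' Identical curriculum with the recurrent weights fixed at zero.
#'
#' @inheritParams train_initial
#' @return trained `network_params`.
#' @export
train_no_recurrence <- function(config, task_generator = NULL,
                                verbose = FALSE) {
  train_initial(config, task_generator, recurrent = FALSE, verbose = verbose)
}

#' Adapt to a rotation by gradient descent (control model)
#'
#' Adaptation achieved by Adam updates of the recurrent weights on the
#' error term of the training loss, instead of the feedback-driven
#' plasticity rule, with the online feedback input disabled throughout
#' (so correction cannot happen within a trial and all compensation must
#' come from re-aiming). Used as the control whose activity change lacks
#' the late feedback peak.
#'
#' @param params trained `network_params`.
#' @param rotation_deg visuomotor rotation, degrees.
#' @param n_updates number of Adam updates (one batch each).
#' @param config a `training_config` supplying the optimiser settings.
#' @param seed master seed for trial generation.
#' @return list with the adapted `params` and a per-trial `trials` log
#'   (take-off errors over the batches, in update order).
#' @export
adapt_by_gradient_descent <- function(params, rotation_deg = 30,
                                      n_updates = 20,
                                      config = training_config(),
                                      seed = 1) {
  sim_params <- params
  sim_params$F <- params$F * 0     # feedback input disabled for simulation
  adam <- adam_init(params, "W")
  rows <- list()
  B <- config$batch_size
  for (u in seq_len(n_updates)) {
    trials <- lapply(seq_len(B), function(i) {
      gi <- (u - 1) * B + i
      make_centerout_trial((gi - 1) %% 8,
                           seed = substream(seed, "gdspec", gi),
                           rotation_deg = rotation_deg)
    })
    inputs <- batch_inputs(trials, params, seed, u)
    for (i in seq_len(B)) {
      gi <- (u - 1) * B + i
      res <- run_trial(sim_params, trials[[i]], substream(seed, "x0", gi))
      rows[[gi]] <- data.frame(update = u, trial = gi,
                               target_deg = 45 * trials[[i]]$target_index,
                               rotation_deg = rotation_deg,
                               takeoff_error_deg = res$takeoff_error,
                               endpoint_error_cm = res$endpoint_error)
    }
    g <- cpp_batch_grad(unclass(sim_params), inputs, 0, FALSE)
    gW <- g$gW * params$mask_W
    gn <- frob_norm(gW)
    if (gn > config$grad_clip_norm) gW <- gW * config$grad_clip_norm / gn
    adam$t <- adam$t + 1
    b1 <- config$adam_beta1; b2 <- config$adam_beta2
    adam$m$W <- b1 * adam$m$W + (1 - b1) * gW
    adam$v$W <- b2 * adam$v$W + (1 - b2) * gW^2
    dW <- -config$alpha * (adam$m$W / (1 - b1^adam$t)) /
      (sqrt(adam$v$W / (1 - b2^adam$t)) + 1e-8)
    params$W <- (params$W + dW) * params$mask_W
    sim_params$W <- params$W
  }
  list(params = params, trials = do.call(rbind, rows))
}
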