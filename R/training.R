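# Minibatch SGD with momentum, per-epoch shuffling, and a constant or
# precision-triggered decaying learning rate.

#' Training hyperparameters
#'
#' Defaults follow the reference experimental setup for this architecture:
#' learning rate 0.0005, momentum 0.9, decay factor 5/6 triggered at
#' training precision 0.85.
#'
#' @param learning_rate initial learning rate, > 0.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param schedule `"constant"` (cross-validation runs) or
#'   `"decay_on_precision"` (holdout runs): once training precision first
#'   reaches `precision_threshold`, the rate is multiplied by `decay_factor`
#'   at the end of each subsequent epoch.
#' @param decay_factor multiplicative decay, default 5/6.
#' @param precision_threshold training precision that triggers decay.
#' @param decay_mode `"repeated"` (every post-threshold epoch) or
#'   `"one_shot"` (a single decay when the threshold is first reached).
#' @param batch_size minibatch size; gradients are averaged over the batch.
#' @param max_epochs hard epoch cap.
#' @param target_accuracy optional early-stop: terminate once training
#'   precision reaches this value.
#' @param seed RNG seed driving initialization-independent shuffling.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 5e-4, momentum = 0.9,
                            schedule = c("constant", "decay_on_precision"),
                            decay_factor = 5 / 6,
                            precision_threshold = 0.85,
                            decay_mode = c("repeated", "one_shot"),
                            batch_size = 32L, max_epochs = 50L,
                            target_accuracy = NULL, seed = 1L) {
  schedule <- match.arg(schedule)
  decay_mode <- match.arg(decay_mode)
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            decay_factor > 0, decay_factor < 1, batch_size >= 1,
            max_epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 schedule = schedule, decay_factor = decay_factor,
                 precision_threshold = precision_threshold,
                 decay_mode = decay_mode, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 target_accuracy = target_accuracy, seed = as.integer(seed)),
            class = "training_config")
}

new_training_state <- function(config) {
  list(epoch = 0L, lr = config$learning_rate, threshold_met = FALSE,
       decayed_once = FALSE,
       history = data.frame(epoch = integer(), loss = numeric(),
                            precision = numeric(), lr = numeric()))
}

#' Momentum parameter update
#'
#' Classical velocity form: `v <- mu * v - eta * g; w <- w + v`, applied per
#' tensor. With `mu = 0` this reduces to plain SGD.
#'
#' @param params a `parameter_set` (with velocity buffers).
#' @param grads gradients shaped like the parameters (from [nn_backward()]).
#' @param lr learning rate eta.
#' @param mu momentum coefficient.
#' @return the updated `parameter_set`.
#' @export
momentum_update <- function(params, grads, lr, mu) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in intersect(c("kernels", "weights", "bias"), names(params[[i]]))) {
      g <- grads[[i]][[if (nm == "bias") "dbias" else paste0("d", nm)]]
      if (!identical(dim(g), dim(params[[i]][[nm]])) ||
          length(g) != length(params[[i]][[nm]]))
        stop(sprintf("gradient shape mismatch in layer %d (%s)", i, nm))
      vnm <- paste0("v_", nm)
      params[[i]][[vnm]] <- mu * params[[i]][[vnm]] - lr * g
      params[[i]][[nm]] <- params[[i]][[nm]] + params[[i]][[vnm]]
    }
  }
  params
}

#' Apply the learning-rate schedule at the end of an epoch
#'
#' Constant schedule: the rate never changes. Decay schedule: once the
#' epoch's training precision has reached the threshold, the rate is
#' multiplied by the decay factor at the end of that and (in `"repeated"`
#' mode) every later epoch, so after `d` post-threshold epochs the rate is
#' `eta0 * decay_factor^d`. The rate never increases.
#'
#' @param state training state (tracks whether the threshold has been met).
#' @param training_precision this epoch's training-set precision.
#' @param config a [training_config()].
#' @return the state with `lr` updated.
#' @export
update_learning_rate <- function(state, training_precision, config) {
  if (config$schedule == "constant") return(state)
  if (training_precision >= config$precision_threshold)
    state$threshold_met <- TRUE
  if (state$threshold_met) {
    if (config$decay_mode == "repeated" || !state$decayed_once) {
      state$lr <- state$lr * config$decay_factor
      state$decayed_once <- TRUE
    }
  }
  state
}

sum_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    for (nm in names(g[[i]])) acc[[i]][[nm]] <- acc[[i]][[nm]] + g[[i]][[nm]]
  }
  acc
}

scale_grads <- function(g, s) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    for (nm in names(g[[i]])) g[[i]][[nm]] <- g[[i]][[nm]] * s
  }
  g
}

#' Run one training epoch
#'
#' Re-shuffles the dataset from the current RNG stream, then for each
#' minibatch runs forward, loss, backward and a momentum update (gradients
#' averaged over the batch; the last batch may be short). Returns the
#' updated parameters plus the epoch's mean loss. The caller owns the RNG
#' state, so a fixed seed upstream makes the whole epoch deterministic.
#'
#' @param dataset a non-empty [patch_dataset()].
#' @param net_config a [network_config()].
#' @param params current `parameter_set`.
#' @param state training state (for the current learning rate).
#' @param config a [training_config()].
#' @return list with `params` and `mean_loss`.
#' @export
run_epoch <- function(dataset, net_config, params, state, config) {
  n <- length(dataset)
  if (n == 0L) stop("run_epoch: empty dataset")
  ord <- sample.int(n)
  losses <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    batch <- ord[pos:min(pos + config$batch_size - 1L, n)]
    acc <- NULL
    for (j in batch) {
      fw <- nn_forward(net_config, params, dataset$patches[j, , ])
      losses[pos + match(j, batch) - 1L] <-
        cross_entropy_loss(fw$probs, dataset$labels[j])
      acc <- sum_grads(acc, nn_backward(net_config, params, fw$cache,
                                        dataset$labels[j]))
    }
    params <- momentum_update(params, scale_grads(acc, 1 / length(batch)),
                              state$lr, config$momentum)
    pos <- pos + length(batch)
  }
  list(params = params, mean_loss = mean(losses))
}

#' Classification precision of the current model on a dataset
#'
#' Fraction of examples whose predicted label matches the true label — the
#' quantity driving both the decay trigger and the termination rule.
#'
#' @param net_config,params network and parameters.
#' @param dataset a [patch_dataset()].
#' @return real in `[0, 1]`.
#' @export
compute_training_precision <- function(net_config, params, dataset) {
  mean(predict_dataset(net_config, params, dataset) == dataset$labels)
}

#' Predicted labels for every patch of a dataset
#'
#' @param net_config,params network and parameters.
#' @param dataset a [patch_dataset()].
#' @return integer vector of 0/1 labels.
#' @export
predict_dataset <- function(net_config, params, dataset) {
  vapply(seq_len(length(dataset)), function(i)
    predict_class(nn_forward(net_config, params, dataset$patches[i, , ])$probs),
    integer(1))
}

#' Train a network
#'
#' Initializes parameters from the seed (unless given), then loops
#' [run_epoch()] until `max_epochs`, or earlier when training precision
#' reaches `target_accuracy`, or when the mean loss improves by less than
#' 1e-6 for 5 consecutive epochs (the convergence rule). A non-finite loss
#' aborts with a diagnostic error carrying the epoch history.
#'
#' @param dataset a [patch_dataset()] whose patch side matches the network.
#' @param net_config a [network_config()].
#' @param config a [training_config()].
#' @param params optional initial `parameter_set`; defaults to
#'   [init_parameters()] from `config$seed`.
#' @param epoch_hook optional `function(params, state)` called after every
#'   epoch (used e.g. to evaluate a fixed test set per iteration).
#' @return list with `params`, `state` (including the per-epoch history of
#'   loss, precision and learning rate) and `stopped` (one of
#'   `"max_epochs"`, `"target_accuracy"`, `"converged"`).
#' @export
train <- function(dataset, net_config, config, params = NULL,
                  epoch_hook = NULL) {
  if (length(dataset) == 0L) stop("train: empty dataset")
  if (is.null(params))
    params <- init_parameters(net_config, seed = config$seed)
  set.seed(config$seed + 1L)  # shuffling stream, distinct from init draws
  state <- new_training_state(config)
  stopped <- "max_epochs"
  stall <- 0L; prev_loss <- Inf
  for (epoch in seq_len(config$max_epochs)) {
    ep <- run_epoch(dataset, net_config, params, state, config)
    params <- ep$params
    if (!is.finite(ep$mean_loss)) {
      err <- simpleError(sprintf(
        "training diverged at epoch %d (non-finite loss); see $state in the condition",
        epoch))
      err$state <- state
      stop(err)
    }
    precision <- compute_training_precision(net_config, params, dataset)
    state$epoch <- epoch
    state$history <- rbind(state$history,
                           data.frame(epoch = epoch, loss = ep$mean_loss,
                                      precision = precision, lr = state$lr))
    state <- update_learning_rate(state, precision, config)
    if (!is.null(epoch_hook)) epoch_hook(params, state)
    if (!is.null(config$target_accuracy) &&
        precision >= config$target_accuracy) { stopped <- "target_accuracy"; break }
    stall <- if (prev_loss - ep$mean_loss < 1e-6) stall + 1L else 0L
    prev_loss <- ep$mean_loss
    if (stall >= 5L) { stopped <- "converged"; break }
  }
  list(params = params, state = state, stopped = stopped)
}
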