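#' @name train-eval
#' @title Training, validation and model-selection protocol
#' @description
#' The experimental protocol: split cases into train/validation/test,
#' train by SGD with momentum and weight decay on per-pixel softmax
#' cross-entropy, snapshot a checkpoint every fixed number of iterations
#' ("observation mirrors"), score every checkpoint on the validation set by
#' cohort global Dice to obtain a Dice curve, pick the checkpoint that
#' maximizes it (earliest iteration on ties), and report per-case and
#' cohort Dice on the held-out test set.  Every step is deterministic given
#' its seeds.
NULL

#' Training configuration
#'
#' Hyperparameter defaults are this package's (the protocol names the knobs
#' but publishes no values): step learning-rate decay by `lr_gamma` at 50%
#' and 75% of `max_iterations`, initial rate `1e-3`, batch size 4, momentum
#' 0.9, weight decay `5e-4`, checkpoints every 5000 iterations (scale
#' `checkpoint_interval` down together with `max_iterations` for desk-scale
#' runs).
#'
#' @param learning_strategy `"step"` (decay at `lr_steps`) or `"fixed"`
#' @param initial_lr positive initial learning rate
#' @param lr_steps fractions of `max_iterations` at which the rate decays
#' @param lr_gamma multiplicative decay factor
#' @param batch_size slices per SGD step
#' @param momentum in `[0, 1)`
#' @param weight_decay non-negative L2 penalty (not applied to biases)
#' @param max_iterations total SGD steps
#' @param checkpoint_interval snapshot period, `<= max_iterations`
#' @param seed RNG seed driving batch sampling and augmentation
#' @param class_weights `NULL` (uniform), `"inverse_freq"` (per-class
#'   weights proportional to inverse pixel frequency on the training set,
#'   capped at 100x the background weight), or a numeric vector of length
#'   n_classes
#' @param augment_flip random left-right flips (off by default)
#' @param precision `"single"` (float32, default) or `"double"`
#' @param verbose print structured log lines (iteration, loss, lr)
#' @return a `training_config`
#' @export
training_config <- function(learning_strategy = c("step", "fixed"),
                            initial_lr = 1e-3, lr_steps = c(0.5, 0.75),
                            lr_gamma = 0.1, batch_size = 4L, momentum = 0.9,
                            weight_decay = 5e-4, max_iterations = 20000L,
                            checkpoint_interval = 5000L, seed = 0L,
                            class_weights = NULL, augment_flip = FALSE,
                            precision = c("single", "double"),
                            verbose = FALSE) {
  learning_strategy <- match.arg(learning_strategy)
  precision <- match.arg(precision)
  max_iterations <- as.integer(max_iterations)
  checkpoint_interval <- as.integer(checkpoint_interval)
  if (max_iterations < 1L) stop_dfcn("training_config: max_iterations >= 1")
  if (checkpoint_interval < 1L || checkpoint_interval > max_iterations) {
    stop_dfcn("training_config: need 1 <= checkpoint_interval <= max_iterations")
  }
  if (initial_lr <= 0) stop_dfcn("training_config: initial_lr must be positive")
  if (momentum < 0 || momentum >= 1) stop_dfcn("training_config: momentum in [0, 1)")
  if (weight_decay < 0) stop_dfcn("training_config: weight_decay >= 0")
  if (batch_size < 1) stop_dfcn("training_config: batch_size >= 1")
  structure(list(learning_strategy = learning_strategy,
                 initial_lr = initial_lr, lr_steps = lr_steps,
                 lr_gamma = lr_gamma, batch_size = as.integer(batch_size),
                 momentum = momentum, weight_decay = weight_decay,
                 max_iterations = max_iterations,
                 checkpoint_interval = checkpoint_interval,
                 seed = as.integer(seed), loss = "softmax_xent",
                 class_weights = class_weights,
                 augment_flip = isTRUE(augment_flip),
                 precision = precision, verbose = isTRUE(verbose)),
            class = "training_config")
}

#' Random three-way dataset split
#'
#' Uniformly random disjoint assignment of case ids into train, validation
#' and test sets of the requested sizes, deterministic in `seed`.
#'
#' @param case_ids vector of case identifiers
#' @param sizes integer vector `(n_train, n_val, n_test)` summing to
#'   `length(case_ids)`
#' @param seed integer
#' @return a `split_spec`: list with `train_cases`, `val_cases`,
#'   `test_cases`, `seed`
#' @export
split_dataset <- function(case_ids, sizes, seed = 0L) {
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(is.na(sizes)) || any(sizes < 0L)) {
    stop_dfcn("split_dataset: sizes must be three non-negative integers")
  }
  if (sum(sizes) != length(case_ids)) {
    stop_dfcn(sprintf(
      "split_dataset: sizes sum to %d but there are %d cases",
      sum(sizes), length(case_ids)))
  }
  perm <- with_seed(seed, sample(case_ids))
  structure(list(train_cases = perm[seq_len(sizes[1])],
                 val_cases = perm[sizes[1] + seq_len(sizes[2])],
                 test_cases = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Flatten a list of cases into a slice pool (list of x = HU matrix,
# y = 0-based integer label matrix).
slice_pool <- function(cases) {
  pool <- list()
  for (cs in cases) {
    if (is.null(cs$slices) || is.null(cs$masks) ||
        length(cs$slices) != length(cs$masks)) {
      stop_dfcn("dataset: each case needs matching slices and masks")
    }
    for (s in seq_along(cs$slices)) {
      pool[[length(pool) + 1L]] <- list(x = cs$slices[[s]], y = cs$masks[[s]])
    }
  }
  pool
}

resolve_class_weights <- function(cw, pool, n_classes) {
  if (is.null(cw)) return(rep(1, n_classes))
  if (is.numeric(cw)) {
    if (length(cw) != n_classes || any(cw <= 0)) {
      stop_dfcn("class_weights: need ", n_classes, " positive values")
    }
    return(cw)
  }
  if (!identical(cw, "inverse_freq")) {
    stop_dfcn("class_weights: NULL, 'inverse_freq' or a numeric vector")
  }
  counts <- rep(0, n_classes)
  for (s in pool) {
    t <- tabulate(as.vector(s$y) + 1L, nbins = n_classes)
    counts <- counts + t
  }
  freq <- counts / sum(counts)
  w <- 1 / pmax(freq, 1e-12)
  w <- pmin(w, 100 * w[1])     # cap relative to background
  w / mean(w)
}

#' Train a network with checkpointing
#'
#' Stochastic gradient descent with momentum and weight decay on per-pixel
#' multinomial (softmax) cross-entropy between the upsampled score maps and
#' the reference masks.  Batches are sampled with replacement from the
#' pooled training slices; a parameter snapshot (`checkpoint`) is recorded
#' every `checkpoint_interval` iterations.  Fully reproducible given
#' `cfg$seed` (and the network's init seed); aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param net a `dfcn_network` (modified copy returned inside the result)
#' @param train_set list of cases, each a list with `slices` (HU matrices)
#'   and `masks` (integer matrices, values in `0..n_classes-1`)
#' @param cfg a [training_config()]
#' @return a `dfcn_checkpoints` object: list of checkpoint records
#'   (`iteration`, `params`, `val_global_dice = NA`), with the trained
#'   network, the architecture, the config and the loss trace as attributes
#' @export
train_network <- function(net, train_set, cfg = training_config()) {
  stopifnot(inherits(net, "dfcn_network"), inherits(cfg, "training_config"))
  if (!is.null(train_set$cases)) train_set <- train_set$cases
  pool <- slice_pool(train_set)
  if (length(pool) == 0) stop_dfcn("train_network: empty training set")
  n_classes <- net$arch$n_classes
  for (s in pool) {
    if (max(s$y) >= n_classes || min(s$y) < 0) {
      stop_dfcn("train_network: mask labels must lie in 0..n_classes-1")
    }
  }
  cw <- resolve_class_weights(cfg$class_weights, pool, n_classes)
  steps_at <- if (cfg$learning_strategy == "step") {
    unique(as.integer(floor(cfg$lr_steps * cfg$max_iterations)))
  } else integer(0)

  vel <- lapply(net$params, function(p)
    list(w = array(0, dim = dim(p$w)), b = rep(0, length(p$b))))
  checkpoints <- list()
  trace_it <- integer(0); trace_loss <- numeric(0); trace_lr <- numeric(0)

  with_seed(cfg$seed, {
    for (it in seq_len(cfg$max_iterations)) {
      lr <- cfg$initial_lr * cfg$lr_gamma^sum(it > steps_at)
      idx <- sample.int(length(pool), cfg$batch_size, replace = TRUE)
      flip <- if (cfg$augment_flip) runif(cfg$batch_size) < 0.5 else
        rep(FALSE, cfg$batch_size)
      gsum <- NULL
      loss <- 0
      for (b in seq_len(cfg$batch_size)) {
        s <- pool[[idx[b]]]
        x <- s$x; y <- s$y
        if (flip[b]) { x <- x[, rev(seq_len(ncol(x)))]
                       y <- y[, rev(seq_len(ncol(y)))] }
        lg <- network_loss_grad(net, x, y, cw, cfg$precision)
        loss <- loss + lg$loss
        if (is.null(gsum)) gsum <- lg$grads
        else for (nm in names(lg$grads)) {
          gsum[[nm]]$w <- gsum[[nm]]$w + lg$grads[[nm]]$w
          gsum[[nm]]$b <- gsum[[nm]]$b + lg$grads[[nm]]$b
        }
      }
      loss <- loss / cfg$batch_size
      if (!is.finite(loss)) {
        stop_dfcn(sprintf(
          "train_network: non-finite loss at iteration %d (lr %g); reduce the learning rate",
          it, lr))
      }
      for (nm in names(gsum)) {
        gw <- gsum[[nm]]$w / cfg$batch_size +
          cfg$weight_decay * net$params[[nm]]$w
        gb <- gsum[[nm]]$b / cfg$batch_size
        vel[[nm]]$w <- cfg$momentum * vel[[nm]]$w + gw
        vel[[nm]]$b <- cfg$momentum * vel[[nm]]$b + gb
        net$params[[nm]]$w <- net$params[[nm]]$w - lr * vel[[nm]]$w
        net$params[[nm]]$b <- net$params[[nm]]$b - lr * vel[[nm]]$b
      }
      trace_it <- c(trace_it, it); trace_loss <- c(trace_loss, loss)
      trace_lr <- c(trace_lr, lr)
      if (cfg$verbose && (it == 1L || it %% 50L == 0L)) {
        message(sprintf("[dfcn train] iter=%d loss=%.5f lr=%g", it, loss, lr))
      }
      if (it %% cfg$checkpoint_interval == 0L) {
        checkpoints[[length(checkpoints) + 1L]] <-
          list(iteration = it, params = net$params,
               val_global_dice = NA_real_)
      }
    }
  })
  structure(checkpoints, class = "dfcn_checkpoints",
            arch = net$arch, net = net, config = cfg,
            loss_trace = data.frame(iteration = trace_it, loss = trace_loss,
                                    lr = trace_lr))
}

#' @export
print.dfcn_checkpoints <- function(x, ...) {
  cat(sprintf("<dfcn_checkpoints> %d snapshot(s) of %s at iterations %s\n",
              length(x), attr(x, "arch")$variant,
              paste(vapply(x, `[[`, numeric(1), "iteration"), collapse = ", ")))
  invisible(x)
}

# Predict every slice of a case and pool into H x W x S label arrays.
predict_case_masks <- function(net, case, precision = "single") {
  lapply(case$slices, function(x) predict_mask(net, x, precision = precision))
}

case_dice_report <- function(pred_masks, ref_masks, classes) {
  dice_report(case_array(pred_masks), case_array(ref_masks), classes,
              scope = "case")
}

#' Validate checkpoints and build the Dice curve
#'
#' Every checkpoint predicts every validation case; the cohort global Dice
#' (mean of per-case pooled global Dice) is recorded against the iteration
#' number, producing the Dice curve used for optimal-model selection.
#'
#' @param checkpoints a `dfcn_checkpoints` from [train_network()]
#' @param val_set list of cases with `slices` and `masks`
#' @param precision engine precision for prediction
#' @return a `dice_curve`: data.frame with columns `iteration` and
#'   `global_dice` (checkpoints carried in an attribute)
#' @export
validate_checkpoints <- function(checkpoints, val_set, precision = "single") {
  stopifnot(inherits(checkpoints, "dfcn_checkpoints"))
  if (length(checkpoints) == 0) stop_dfcn("validate_checkpoints: no checkpoints")
  if (!is.null(val_set$cases)) val_set <- val_set$cases
  if (length(val_set) == 0) stop_dfcn("validate_checkpoints: empty validation set")
  arch <- attr(checkpoints, "arch")
  net <- attr(checkpoints, "net")
  classes <- seq_len(arch$n_classes - 1L)
  gd <- vapply(seq_along(checkpoints), function(k) {
    net$params <- checkpoints[[k]]$params
    reports <- lapply(val_set, function(cs) {
      case_dice_report(predict_case_masks(net, cs, precision), cs$masks,
                       classes)
    })
    aggregate_reports(reports)$global
  }, numeric(1))
  curve <- data.frame(iteration = vapply(checkpoints, `[[`, numeric(1),
                                         "iteration"),
                      global_dice = gd)
  for (k in seq_along(checkpoints)) {
    checkpoints[[k]]$val_global_dice <- gd[k]
  }
  structure(curve, class = c("dice_curve", "data.frame"),
            checkpoints = checkpoints)
}

#' Select the optimal checkpoint from a Dice curve
#'
#' Returns the checkpoint with the maximum validation global Dice; ties
#' break toward the earliest iteration.  Accepts either a `dice_curve` from
#' [validate_checkpoints()] (returns the full checkpoint record) or a plain
#' data.frame with `iteration` and `global_dice` columns (returns the
#' selected row as a record with `params = NULL`).
#'
#' @param curve Dice curve
#' @return list with `iteration`, `val_global_dice` and (if available)
#'   `params`
#' @export
select_optimal <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0) {
    stop_dfcn("select_optimal: empty curve")
  }
  if (is.unsorted(curve$iteration, strictly = TRUE)) {
    stop_dfcn("select_optimal: iterations must be strictly increasing")
  }
  k <- which.max(curve$global_dice)  # first maximum = earliest iteration
  ck <- attr(curve, "checkpoints")
  if (!is.null(ck)) {
    out <- ck[[k]]
    out$val_global_dice <- curve$global_dice[k]
    return(out)
  }
  list(iteration = curve$iteration[k], params = NULL,
       val_global_dice = curve$global_dice[k])
}

#' Evaluate a network on a test set
#'
#' Predicts every case, computes the per-case Dice report over the pooled
#' slices of the case, aggregates into a cohort report, and returns a
#' results table mirroring the per-model evaluation layout: one row per
#' case plus one cohort row, with global and per-structure Dice columns.
#' Per-case wall time is logged informationally.
#'
#' @param net a `dfcn_network`
#' @param test_set list of cases with `slices` and `masks`
#' @param class_names optional names for the structure columns
#' @param precision engine precision
#' @return list with `cohort` (`dice_report`), `per_case` (list of
#'   `dice_report`), and `table` (data.frame)
#' @export
evaluate_test <- function(net, test_set, class_names = NULL,
                          precision = "single") {
  stopifnot(inherits(net, "dfcn_network"))
  if (!is.null(test_set$cases)) test_set <- test_set$cases
  if (length(test_set) == 0) stop_dfcn("evaluate_test: empty test set")
  classes <- seq_len(net$arch$n_classes - 1L)
  if (is.null(class_names)) class_names <- paste0("class", classes)
  per_case <- list()
  rows <- list()
  for (cs in test_set) {
    if (is.null(cs$masks)) stop_dfcn("evaluate_test: case without masks")
    t0 <- proc.time()[["elapsed"]]
    pred <- predict_case_masks(net, cs, precision)
    rep <- case_dice_report(pred, cs$masks, classes)
    secs <- proc.time()[["elapsed"]] - t0
    per_case[[cs$case_id]] <- rep
    row <- data.frame(case_id = cs$case_id, global = rep$global,
                      t(rep$per_class), seconds = secs)
    names(row)[3:(2 + length(classes))] <- class_names
    rows[[length(rows) + 1L]] <- row
  }
  cohort <- aggregate_reports(per_case)
  crow <- data.frame(case_id = "cohort", global = cohort$global,
                     t(cohort$per_class), seconds = NA_real_)
  names(crow)[3:(2 + length(classes))] <- class_names
  list(cohort = cohort, per_case = per_case,
       table = rbind(do.call(rbind, rows), crow))
}

#' Save / load a checkpoint file
#'
#' Checkpoint files embed the architecture, the parameter values, the
#' iteration, a hash of the training configuration and the package version.
#'
#' @param record a checkpoint record (with `params`) or a `dfcn_network`
#' @param arch the `dfcn_arch` (needed when `record` is a bare record)
#' @param path destination `.rds` path
#' @param config optional [training_config()] to hash into the file
#' @return `write_checkpoint`: the path invisibly; `read_checkpoint`: a
#'   `dfcn_network` with attributes `iteration` and `config_hash`
#' @export
write_checkpoint <- function(record, arch, path, config = NULL) {
  params <- if (inherits(record, "dfcn_network")) record$params else record$params
  it <- if (inherits(record, "dfcn_network")) NA_integer_ else record$iteration
  obj <- list(arch = arch, params = params, iteration = it,
              config_hash = if (is.null(config)) NA_character_ else
                config_hash(unclass(config)),
              version = dfcn_version())
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  net <- structure(list(arch = obj$arch, params = obj$params,
                        init_seed = NA_integer_), class = "dfcn_network")
  attr(net, "iteration") <- obj$iteration
  attr(net, "config_hash") <- obj$config_hash
  net
}

#' Write a Dice curve as CSV (and optionally plot it)
#'
#' @param curve a `dice_curve`
#' @param csv_path output CSV path
#' @param plot_path optional PNG path; plotting failures (e.g. no graphics
#'   support) are tolerated silently
#' @return `csv_path`, invisibly
#' @export
write_dice_curve <- function(curve, csv_path, plot_path = NULL) {
  write.csv(as.data.frame(curve)[, c("iteration", "global_dice")], csv_path,
            row.names = FALSE)
  if (!is.null(plot_path)) {
    try({
      grDevices::png(plot_path, width = 640, height = 480)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(curve$iteration, curve$global_dice, type = "b", pch = 19,
           xlab = "iteration", ylab = "validation global Dice",
           main = "Dice curve")
    }, silent = TRUE)
  }
  invisible(csv_path)
}
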