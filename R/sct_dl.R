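# Training and inference for the deep-learning sCT arm. CT targets are
# mapped to [0, 1] via (HU + 1000) / 2000 clipped at 1000 HU (implants
# clip), the inverse is applied at inference. The desk training preset uses
# a constant Adam learning rate suitable for small CPU runs; the
# paper-scale preset keeps the published 0.04 -> 0.01 schedule (realised as
# a linear decay; the published schedule's shape is unstated).

#' Map CT numbers to the unit training range
#' @param hu CT values
#' @return (HU + 1000) / 2000, clipped to [0, 1] (i.e. at -1000 and 1000 HU)
#' @export
ct_to_unit <- function(hu) pmin(pmax((hu + 1000) / 2000, 0), 1)

#' Inverse of \code{\link{ct_to_unit}}
#' @param u values in [0, 1]
#' @return CT values in [-1000, 1000] HU
#' @export
unit_to_ct <- function(u) u * 2000 - 1000

#' Training configuration
#'
#' @param preset "desk" (batch 8, Adam lr decaying 5e-3 to 1e-3) or "paper"
#'   (batch 32, lr decaying 0.04 to 0.01)
#' @param epochs training epochs
#' @param batch_slices slices per batch
#' @param lr_schedule c(start, end); start >= end > 0
#' @param folds cross-validation folds
#' @param seed integer seed (init, shuffling)
#' @return object of class \code{training_config}
#' @export
training_config <- function(preset = c("desk", "paper"), epochs = 20L,
                            batch_slices = NULL, lr_schedule = NULL,
                            folds = 5L, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(batch_slices)) batch_slices <- if (preset == "paper") 32L else 8L
  if (is.null(lr_schedule)) {
    lr_schedule <- if (preset == "paper") c(0.04, 0.01) else c(5e-3, 1e-3)
  }
  if (!(lr_schedule[1] >= lr_schedule[2] && lr_schedule[2] > 0))
    stop_sctpet("learning rate schedule must satisfy start >= end > 0")
  if (folds < 2) stop_sctpet("folds must be >= 2")
  structure(list(preset = preset, loss = "l2", optimizer = "adam",
                 epochs = as.integer(epochs),
                 batch_slices = as.integer(batch_slices),
                 lr_schedule = lr_schedule, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Subject-level cross-validation split
#'
#' Partitions subjects (never individual slices) into k disjoint,
#' exhaustive validation folds.
#' @param subject_ids vector of subject identifiers
#' @param k number of folds
#' @param seed integer seed for the shuffle
#' @return list of k validation-id vectors
#' @export
crossval_split <- function(subject_ids, k = 5L, seed = 1L) {
  if (k < 2 || k > length(subject_ids))
    stop_sctpet("k must be in [2, number of subjects]")
  perm <- with_seed(seed, sample(subject_ids))
  split(perm, rep_len(seq_len(k), length(perm)))
}

# slices: 3D array (h, w, n) -> list of column vectors is avoided; training
# works on index sets into the array
slices_to_batch <- function(slices, idx) {
  h <- dim(slices)[1]; w <- dim(slices)[2]
  matrix(as.vector(slices[, , idx, drop = FALSE]), h * w * length(idx), 1)
}

#' Train the MR-to-CT network
#'
#' L2 loss, Adam, seeded shuffling; deterministic given the seed (within
#' floating-point reduction order). MR inputs are expected in [0, 1]; CT
#' targets are given in HU and mapped through \code{\link{ct_to_unit}}.
#'
#' @param model \code{sct_model} from \code{\link{build_network}}
#' @param mr_slices array (h, w, n) of normalized MR slices
#' @param ct_slices array (h, w, n) of target CT slices (HU), co-registered
#'   with \code{mr_slices}
#' @param cfg \code{training_config}
#' @param verbose print a line every few epochs
#' @return list(model, loss_trace); \code{loss_trace} is a data.frame of
#'   (step, epoch, lr, loss)
#' @export
train_network <- function(model, mr_slices, ct_slices,
                          cfg = training_config(), verbose = FALSE) {
  mr_slices <- as_vol3d(mr_slices); ct_slices <- as_vol3d(ct_slices)
  if (!identical(dim(mr_slices), dim(ct_slices)))
    stop_sctpet("MR and CT slice stacks must be co-registered (equal dims)")
  h <- dim(mr_slices)[1]; w <- dim(mr_slices)[2]; n <- dim(mr_slices)[3]
  tgt <- ct_to_unit(ct_slices)
  if (is.null(model$opt)) model$opt <- adam_init(model)
  bs <- min(cfg$batch_slices, n)
  steps_total <- max(1, ceiling(n / bs)) * cfg$epochs
  step <- 0
  trace <- vector("list", steps_total)
  momentum <- 0.1
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "shuffle", ep), sample(n))
    for (b0 in seq(1, n, by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1, n)]
      nb <- length(idx)
      x <- slices_to_batch(mr_slices, idx)
      y <- slices_to_batch(tgt, idx)
      fw <- nn_forward(model, x, h, w, nb, training = TRUE)
      err <- fw$pred - y
      loss <- mean(err^2)
      dpred <- 2 * err / length(err)
      gr <- nn_backward(model, fw, dpred, h, w, nb)
      step <- step + 1
      lr <- cfg$lr_schedule[1] +
        (cfg$lr_schedule[2] - cfg$lr_schedule[1]) * (step - 1) / max(steps_total - 1, 1)
      model$opt$t <- model$opt$t + 1
      t <- model$opt$t
      for (i in seq_along(model$units)) {
        for (p in c("W", "gamma", "beta")) {
          gname <- paste0("d", p)
          up <- adam_update(model$units[[i]][[p]], gr$units[[i]][[gname]],
                            model$opt$units[[i]][[p]], lr, t = t)
          model$units[[i]][[p]] <- up$par
          model$opt$units[[i]][[p]] <- up$state
        }
        # running BN stats
        ca <- fw$caches[[i]]$bn
        model$units[[i]]$run_mean <- (1 - momentum) * model$units[[i]]$run_mean +
          momentum * ca$mu
        model$units[[i]]$run_var <- (1 - momentum) * model$units[[i]]$run_var +
          momentum * ca$va
      }
      up <- adam_update(model$proj$W, gr$proj$dW, model$opt$proj$W, lr, t = t)
      model$proj$W <- up$par; model$opt$proj$W <- up$state
      up <- adam_update(model$proj$b, gr$proj$db, model$opt$proj$b, lr, t = t)
      model$proj$b <- up$par; model$opt$proj$b <- up$state
      trace[[step]] <- data.frame(step = step, epoch = ep, lr = lr, loss = loss)
    }
    if (verbose && (ep %% 5 == 0 || ep == 1)) {
      message(sprintf("epoch %d/%d loss %.5f", ep, cfg$epochs, loss))
    }
  }
  # batch-norm calibration: replace the momentum running statistics with
  # statistics over the full training set, so inference (which uses running
  # stats) matches the training-mode behaviour
  model <- calibrate_bn(model, mr_slices, batch = bs)
  model$trained <- TRUE
  list(model = model, loss_trace = do.call(rbind, trace[seq_len(step)]))
}

calibrate_bn <- function(model, mr_slices, batch = 8L) {
  h <- dim(mr_slices)[1]; w <- dim(mr_slices)[2]; n <- dim(mr_slices)[3]
  acc_mean <- lapply(model$units, function(u) 0 * u$run_mean)
  acc_sq <- lapply(model$units, function(u) 0 * u$run_var)
  total <- 0
  for (b0 in seq(1, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1, n)
    x <- slices_to_batch(mr_slices, idx)
    fw <- nn_forward(model, x, h, w, length(idx), training = TRUE)
    nr <- length(idx) * h * w
    for (i in seq_along(model$units)) {
      ca <- fw$caches[[i]]$bn
      acc_mean[[i]] <- acc_mean[[i]] + ca$mu * nr
      acc_sq[[i]] <- acc_sq[[i]] + (ca$va + ca$mu^2) * nr
    }
    total <- total + nr
  }
  for (i in seq_along(model$units)) {
    mu <- acc_mean[[i]] / total
    model$units[[i]]$run_mean <- mu
    model$units[[i]]$run_var <- pmax(acc_sq[[i]] / total - mu^2, 1e-8)
  }
  model
}

#' Predict a synthetic CT from a normalized MR volume
#'
#' Slice-wise inference (batch-norm running statistics), restacked and
#' de-normalized to HU.
#' @param model trained \code{sct_model}
#' @param mr_norm normalized MR volume
#' @return sCT volume (HU)
#' @export
predict_sct <- function(model, mr_norm) {
  mr_norm <- as_vol3d(mr_norm)
  h <- dim(mr_norm)[1]; w <- dim(mr_norm)[2]; nz <- dim(mr_norm)[3]
  out <- array(0, dim = dim(mr_norm))
  for (k in seq_len(nz)) {
    x <- matrix(as.vector(mr_norm[, , k]), h * w, 1)
    fw <- nn_forward(model, x, h, w, 1L, training = FALSE)
    out[, , k] <- matrix(unit_to_ct(pmin(pmax(fw$pred, 0), 1)), h, w)
  }
  out
}
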