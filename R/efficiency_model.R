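# Per-position editing-efficiency model: input encoding, the shuffled
# stratified training protocol, prediction and evaluation. The sequence-only
# configuration predicts from the 40-nt context alone; adding endogenous
# factor channels gives the endogenous-context configuration.

#' Encode one site as a 40 x (4 + k) model input
#'
#' Sequence is one-hot over A/C/G/T; each requested factor channel is
#' broadcast along the 40-bp axis as a constant equal to its (normalized)
#' per-site value, except `methylation_per_base`, which lays per-base beta
#' values at their protospacer positions (0 where uncovered).
#'
#' @param site A `be_sites` row.
#' @param annotation One-row slice of a [annotate_sites()] table for this site
#'   (or NULL when `channels` is empty). For a channel named `f`, the column
#'   `f` is used when present, else `f_flag`.
#' @param channels Character vector of factor channel names (may be empty).
#' @param per_base_methylation Optional per-base data.frame (from the
#'   annotation attribute) used by the `methylation_per_base` channel.
#' @return 40 x (4 + length(channels)) numeric matrix; columns named.
#' @export
encode_input <- function(site, annotation = NULL, channels = character(0),
                         per_base_methylation = NULL) {
  bases <- c("A", "C", "G", "T")
  ctx <- strsplit(site$context40, "")[[1]]
  M <- matrix(0, nrow = SEQ_LEN, ncol = 4 + length(channels),
              dimnames = list(NULL, c(bases, channels)))
  for (b in bases) M[ctx == b, b] <- 1
  for (ch in channels) {
    if (ch == "methylation_per_base") {
      v <- numeric(SEQ_LEN)
      if (!is.null(per_base_methylation)) {
        pb <- per_base_methylation[per_base_methylation$site_id == site$site_id &
                                     !is.na(per_base_methylation$beta), ,
                                   drop = FALSE]
        if (nrow(pb) > 0) v[proto_to_context(pb$position)] <- pb$beta
      }
      M[, ch] <- v
      next
    }
    if (is.null(annotation)) stop("missing factor channel: ", ch)
    val <- if (ch %in% names(annotation)) {
      annotation[[ch]]
    } else if (paste0(ch, "_flag") %in% names(annotation)) {
      annotation[[paste0(ch, "_flag")]]
    } else {
      stop("missing factor channel: ", ch)
    }
    if (is.na(val)) val <- 0
    M[, ch] <- val
  }
  M
}

#' Assemble a training dataset for the efficiency model
#'
#' Stacks encoded inputs, per-position efficiency labels and target-position
#' masks over sites; the stratification key is the presence of any endogenous
#' factor flag.
#'
#' @param sites A `be_sites` table.
#' @param summaries List of `be_site_summary` (matched by site_id; sites
#'   without a summary are skipped).
#' @param annotation Optional [annotate_sites()] table.
#' @param cfg A [be_config()]; `factor_channels` picks the channels (use
#'   `character(0)` via `channels` to build a sequence-only dataset).
#' @param channels Overrides `cfg$factor_channels` when not NULL.
#' @return List of class `be_model_dataset`: `X` (n x 40 x C), `Y`, `mask`
#'   (n x 20), `strata`, `site_id`, `channels`.
#' @export
be_model_dataset <- function(sites, summaries, annotation = NULL, cfg,
                             channels = NULL) {
  if (is.null(channels)) channels <- cfg$factor_channels
  channels <- intersect_available_channels(channels, annotation)
  ids <- vapply(summaries, `[[`, character(1), "site_id")
  keep <- which(sites$site_id %in% ids)
  n <- length(keep)
  X <- array(0, c(n, SEQ_LEN, 4 + length(channels)))
  Y <- matrix(0, n, OUT_LEN)
  mask <- matrix(0, n, OUT_LEN)
  strata <- character(n)
  pb <- attr(annotation, "per_base_methylation")
  for (r in seq_len(n)) {
    site <- sites[keep[r], ]
    ann <- if (!is.null(annotation)) {
      annotation[annotation$site_id == site$site_id, , drop = FALSE]
    } else NULL
    X[r, , ] <- encode_input(site, ann, channels, pb)
    s <- summaries[[match(site$site_id, ids)]]
    pp <- s$per_position_efficiency
    mask[r, ] <- as.numeric(!is.na(pp))
    Y[r, ] <- ifelse(is.na(pp), 0, pp)
    flags <- if (!is.null(ann)) {
      unlist(ann[grepl("_flag$", names(ann))])
    } else numeric(0)
    strata[r] <- if (length(flags) > 0 && any(flags == 1, na.rm = TRUE)) {
      "factor"
    } else "no_factor"
  }
  structure(list(X = X, Y = Y, mask = mask, strata = strata,
                 site_id = sites$site_id[keep], channels = channels),
            class = "be_model_dataset")
}

intersect_available_channels <- function(channels, annotation) {
  if (length(channels) == 0) return(character(0))
  if (is.null(annotation)) return(character(0))
  ok <- vapply(channels, function(ch) {
    ch == "methylation_per_base" || ch %in% names(annotation) ||
      paste0(ch, "_flag") %in% names(annotation)
  }, logical(1))
  channels[ok]
}

# Stratified index split: draws `fraction` of each stratum (at least 1 when
# the stratum has >= 2 members). Falls back to an unstratified split with a
# warning when a stratum is empty or singleton.
stratified_split <- function(strata, fraction, seed) {
  n <- length(strata)
  tab <- table(strata)
  with_seed(seed, {
    if (length(tab) < 2 || any(tab < 2)) {
      if (length(tab) > 1) {
        warning("empty or singleton stratum; falling back to unstratified split")
      }
      return(sample(n, max(1, round(fraction * n))))
    }
    unlist(lapply(names(tab), function(s) {
      idx <- which(strata == s)
      sample(idx, max(1, round(fraction * length(idx))))
    }), use.names = FALSE)
  })
}

#' Train the efficiency model under the shuffled stratified protocol
#'
#' Runs `n_shuffles` (default 6) independent 80/20 train/test splits
#' stratified by endogenous-factor presence; within each training split, 20%
#' is held out as a validation set for early stopping and model selection.
#' Reports per-shuffle test Pearson R (pooled over masked positions) and per
#' position.
#'
#' @param dataset A [be_model_dataset()].
#' @param cfg A [be_config()]; `cfg$training` carries the hyperparameters and
#'   `cfg$seed` the base seed (shuffle s uses seed + s).
#' @return List of class `be_efficiency_model`: `net` (network of the shuffle
#'   with the lowest validation loss), `channels`, `metrics` (per-shuffle
#'   data.frame with `shuffle`, `test_r`, `best_epoch`), `per_position_r`
#'   (shuffles x 20 matrix), `control`.
#' @export
train_efficiency_model <- function(dataset, cfg) {
  ctl <- cfg$training
  metrics <- list()
  ppr <- matrix(NA_real_, ctl$n_shuffles, OUT_LEN)
  best <- list(loss = Inf, net = NULL)
  n <- dim(dataset$X)[1]
  if (n < 2) stop("need at least 2 sites to train")
  for (s in seq_len(ctl$n_shuffles)) {
    seed_s <- cfg$seed + s
    test_idx <- stratified_split(dataset$strata, ctl$test_fraction, seed_s)
    train_idx <- setdiff(seq_len(n), test_idx)
    val_local <- stratified_split(dataset$strata[train_idx],
                                  ctl$validation_fraction, seed_s + 7919L)
    val_idx <- train_idx[val_local]
    fit_idx <- c(setdiff(train_idx, val_idx), val_idx)
    sub <- function(M, idx) M[idx, , drop = FALSE]
    Xs <- dataset$X[fit_idx, , , drop = FALSE]
    pos_val <- seq(length(fit_idx) - length(val_idx) + 1, length(fit_idx))
    fit <- cnn_fit(Xs, sub(dataset$Y, fit_idx), sub(dataset$mask, fit_idx),
                   control = ctl, val_idx = pos_val, seed = seed_s)
    pred <- cnn_forward(fit$net, dataset$X[test_idx, , , drop = FALSE])$yhat
    obs <- sub(dataset$Y, test_idx)
    msk <- sub(dataset$mask, test_idx) == 1
    r <- stats::cor(pred[msk], obs[msk])
    for (p in seq_len(OUT_LEN)) {
      col <- msk[, p]
      if (sum(col) >= 3 && stats::sd(obs[col, p]) > 0 &&
          stats::sd(pred[col, p]) > 0) {
        ppr[s, p] <- stats::cor(pred[col, p], obs[col, p])
      }
    }
    metrics[[s]] <- data.frame(shuffle = s, test_r = r,
                               best_epoch = fit$best_epoch,
                               val_loss = fit$best_val_loss)
    if (fit$best_val_loss < best$loss) {
      best <- list(loss = fit$best_val_loss, net = fit$net)
    }
  }
  structure(list(net = best$net, channels = dataset$channels,
                 metrics = do.call(rbind, metrics), per_position_r = ppr,
                 control = ctl),
            class = "be_efficiency_model")
}

#' Predict per-position editing efficiencies
#'
#' @param model A `be_efficiency_model` (or bare `be_cnn`).
#' @param dataset A [be_model_dataset()] (its `X` must match the model's
#'   channels) or a bare n x 40 x C array.
#' @return n x 20 matrix of efficiencies in \[0,1\]; rownames are site ids
#'   when available. Non-target positions are still emitted; mask them with
#'   the dataset's `mask`.
#' @export
predict_efficiency <- function(model, dataset) {
  net <- if (inherits(model, "be_efficiency_model")) model$net else model
  X <- if (is.list(dataset) && !is.null(dataset$X)) dataset$X else dataset
  if (inherits(model, "be_efficiency_model") && is.list(dataset) &&
      !is.null(dataset$channels) &&
      !identical(dataset$channels, model$channels)) {
    stop("channel mismatch: model trained with [",
         paste(model$channels, collapse = ","), "], data has [",
         paste(dataset$channels, collapse = ","), "]")
  }
  if (dim(X)[3] != net$n_channels) {
    stop("channel mismatch: model expects ", net$n_channels,
         " input channels, got ", dim(X)[3])
  }
  yhat <- cnn_forward(net, X)$yhat
  if (is.list(dataset) && !is.null(dataset$site_id)) {
    rownames(yhat) <- dataset$site_id
  }
  yhat
}

#' Evaluate predictions against observations
#'
#' Pooled and per-position Pearson R (with Fisher-z 95% CIs) over masked
#' target positions, optionally split by a per-site grouping.
#'
#' @param pred,obs n x 20 matrices.
#' @param mask n x 20 indicator of valid (target-base) positions.
#' @param group Optional per-site grouping vector (length n).
#' @return List: `pooled` (list r/conf_low/conf_high/n), `per_position`
#'   data.frame, and `per_group` data.frame when `group` is given.
#' @export
evaluate_predictions <- function(pred, obs, mask, group = NULL) {
  msk <- mask == 1
  if (sum(msk) < 3) stop("fewer than 3 masked observations")
  pooled <- pearson_ci(pred[msk], obs[msk])
  per_pos <- do.call(rbind, lapply(seq_len(ncol(obs)), function(p) {
    col <- msk[, p]
    if (sum(col) >= 3 && stats::sd(obs[col, p]) > 0 &&
        stats::sd(pred[col, p]) > 0) {
      ci <- pearson_ci(pred[col, p], obs[col, p])
      data.frame(position = p, r = ci$r, conf_low = ci$conf_low,
                 conf_high = ci$conf_high, n = ci$n)
    } else {
      data.frame(position = p, r = NA_real_, conf_low = NA_real_,
                 conf_high = NA_real_, n = sum(col))
    }
  }))
  out <- list(pooled = pooled, per_position = per_pos)
  if (!is.null(group)) {
    out$per_group <- do.call(rbind, lapply(unique(group), function(g) {
      rows <- group == g
      m <- msk[rows, , drop = FALSE]
      ci <- pearson_ci(pred[rows, , drop = FALSE][m],
                       obs[rows, , drop = FALSE][m])
      data.frame(group = g, r = ci$r, conf_low = ci$conf_low,
                 conf_high = ci$conf_high, n = ci$n)
    }))
  }
  out
}

#' Compare two models' predictions of the same observations
#'
#' Steiger's Z for the two dependent correlations sharing the observed
#' values.
#'
#' @param obs,pred1,pred2 Matched numeric vectors (e.g. masked flattened
#'   per-position efficiencies).
#' @return As [steiger_z_vectors()].
#' @export
compare_models <- function(obs, pred1, pred2) {
  steiger_z_vectors(obs, pred1, pred2)
}

#' Serialize an efficiency model to JSON
#'
#' Self-describing container with the architecture and weights; the inverse
#' of [read_efficiency_model()].
#'
#' @param model A `be_efficiency_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_efficiency_model <- function(model, path) {
  net <- model$net
  payload <- list(
    format = "bequant_efficiency_model",
    channels = model$channels,
    widths = net$widths, filters = net$filters,
    n_channels = net$n_channels, loss = net$loss,
    branches = lapply(net$branches, function(b) {
      list(W = as.vector(b$W), dim = dim(b$W), b = b$b)
    }),
    Wd = as.vector(net$Wd), Wd_dim = dim(net$Wd), bd = net$bd
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an efficiency model written by [write_efficiency_model()]
#'
#' @param path JSON path.
#' @return A `be_efficiency_model` (metrics absent).
#' @export
read_efficiency_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "bequant_efficiency_model")) {
    stop("not an efficiency model file: ", path)
  }
  num <- function(x) as.numeric(unlist(x))
  net <- structure(list(
    branches = lapply(p$branches, function(b) {
      list(W = array(num(b$W), as.integer(unlist(b$dim))), b = num(b$b))
    }),
    Wd = matrix(num(p$Wd), unlist(p$Wd_dim)[1], unlist(p$Wd_dim)[2]),
    bd = num(p$bd),
    widths = as.integer(unlist(p$widths)), filters = as.integer(p$filters),
    n_channels = as.integer(p$n_channels), loss = p$loss
  ), class = "be_cnn")
  structure(list(net = net, channels = as.character(unlist(p$channels)),
                 metrics = NULL,
                 per_position_r = NULL,
                 control = be_training_control(kernel_widths = p$widths,
                                               filters = p$filters)),
            class = "be_efficiency_model")
}
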