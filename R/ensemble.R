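# Hyperparameter search over learning rate (log-uniform in [1e-5, 1e-3])
# and channel count ({2, 4, ..., 64}), maximizing validation ROC-AUC.

sample_config <- function(space) {
  list(lr = 10^stats::runif(1, log10(space$lr[1]), log10(space$lr[2])),
       channels = space$channels[sample.int(length(space$channels), 1L)])
}

# Tree-structured Parzen estimator proposal: completed trials are split by
# objective into a good set (top quarter, at least one) and the rest; a
# candidate batch is drawn from the good-set Parzen density (Gaussian in
# log10-lr, add-one categorical over channels) and the candidate with the
# highest l(x)/g(x) density ratio is proposed. The first two trials are
# random start-up draws.
tpe_propose <- function(trials, space, n_candidates = 24L) {
  if (nrow(trials) < 2L) return(sample_config(space))
  ord <- order(-trials$auc)
  n_good <- max(1L, ceiling(nrow(trials) / 4))
  good <- trials[ord[seq_len(n_good)], , drop = FALSE]
  rest <- trials[ord[-seq_len(n_good)], , drop = FALSE]
  lr_lo <- log10(space$lr[1]); lr_hi <- log10(space$lr[2])
  bw <- max((lr_hi - lr_lo) / 4, 1e-3)
  dens <- function(x, centers) {
    if (!nrow(centers)) return(rep(1 / (lr_hi - lr_lo), length(x)))
    rowMeans(vapply(log10(centers$lr), function(c0)
      stats::dnorm(x, c0, bw), numeric(length(x))))
  }
  cat_w <- function(centers) {
    (tabulate(match(centers$channels, space$channels),
              nbins = length(space$channels)) + 1)
  }
  wl <- cat_w(good); wg <- cat_w(rest)
  cand_lr <- log10(good$lr)[sample.int(nrow(good), n_candidates, replace = TRUE)] +
    stats::rnorm(n_candidates, 0, bw)
  cand_lr <- pmin(pmax(cand_lr, lr_lo), lr_hi)
  cand_ch <- sample(space$channels, n_candidates, replace = TRUE,
                    prob = wl / sum(wl))
  ratio <- dens(cand_lr, good) / pmax(dens(cand_lr, rest), 1e-12) *
    (wl[match(cand_ch, space$channels)] / sum(wl)) /
    (wg[match(cand_ch, space$channels)] / sum(wg))
  best <- which.max(ratio)
  list(lr = 10^cand_lr[best], channels = cand_ch[best])
}

#' Tune CNN hyperparameters on one balanced training set
#'
#' Runs up to `max_trials` training trials (fresh training per trial) and
#' selects the one maximizing validation ROC-AUC; ties keep the earliest
#' trial. The default strategy is a tree-structured Parzen estimator with
#' two random start-up trials; `"random"` gives seeded random search.
#'
#' @param x,y Balanced training maps and labels.
#' @param val_x,val_y Validation maps and labels.
#' @param space Search space: `lr` range and `channels` set.
#' @param max_trials Number of trials (default 3).
#' @param strategy `"tpe"` or `"random"`.
#' @param tc Base [cnn_train_config()]; each trial overrides the learning
#'   rate.
#' @param seed Integer seed for the search and trial training.
#' @return List with the best trained `model`, the chosen `config`, and
#'   the `trials` table.
#' @export
tune_cnn <- function(x, y, val_x, val_y,
                     space = list(lr = c(1e-5, 1e-3),
                                  channels = c(2L, 4L, 8L, 16L, 32L, 64L)),
                     max_trials = 3L, strategy = c("tpe", "random"),
                     tc = cnn_train_config(), seed = 1L) {
  strategy <- match.arg(strategy)
  if (max_trials < 1L) ppi_stop("max_trials must be >= 1")
  trials <- data.frame(lr = numeric(), channels = integer(), auc = numeric())
  models <- vector("list", max_trials)
  for (tr in seq_len(max_trials)) {
    cfg <- with_seed(derive_seed(seed, 300L + tr), {
      if (strategy == "random") sample_config(space) else tpe_propose(trials, space)
    })
    tc_tr <- tc; tc_tr$lr <- cfg$lr; tc_tr$seed <- derive_seed(seed, 400L + tr)
    model <- build_cnn(cnn_config(cfg$channels), seed = derive_seed(seed, 500L + tr))
    model <- cnn_train(model, x, y, val_x, val_y, tc_tr)
    auc <- roc_auc(predict(model, val_x), val_y)$auc
    trials <- rbind(trials, data.frame(lr = cfg$lr, channels = cfg$channels,
                                       auc = auc))
    models[[tr]] <- model
  }
  best <- which.max(trials$auc)   # which.max keeps the first tie
  list(model = models[[best]], config = as.list(trials[best, c("lr", "channels")]),
       trials = trials)
}

#' Fit the five-model undersampling ensemble
#'
#' Trains one CNN per balanced training set (optionally tuning
#' hyperparameters per set) and combines them into an averaging ensemble:
#' the ensemble interaction probability of a pair is the arithmetic mean
#' of the five member probabilities.
#'
#' @param sets List of balanced training sets, each `list(x, y)` (from
#'   [undersample_ensembles()] maps).
#' @param val_x,val_y Shared validation maps and labels.
#' @param tc Base [cnn_train_config()].
#' @param tune Run the hyperparameter search per member (default `TRUE`);
#'   if `FALSE`, `config` is used for every member.
#' @param config [cnn_config()] used when `tune = FALSE`.
#' @param tune_opts Options passed to [tune_cnn()] (`space`, `max_trials`,
#'   `strategy`).
#' @param seed Master seed; members use derived sub-seeds.
#' @return List of class `"ppi_ensemble"` with `models`, `configs` and the
#'   training manifest.
#' @export
fit_ensemble <- function(sets, val_x, val_y, tc = cnn_train_config(),
                         tune = TRUE, config = cnn_config(),
                         tune_opts = list(), seed = 1L) {
  models <- vector("list", length(sets))
  configs <- vector("list", length(sets))
  for (j in seq_along(sets)) {
    sj <- derive_seed(seed, 700L + j)
    if (tune) {
      args <- c(list(x = sets[[j]]$x, y = sets[[j]]$y,
                     val_x = val_x, val_y = val_y, tc = tc, seed = sj),
                tune_opts)
      res <- do.call(tune_cnn, args)
      models[[j]] <- res$model
      configs[[j]] <- res$config
    } else {
      tc_j <- tc; tc_j$seed <- sj
      m <- build_cnn(config, seed = sj)
      models[[j]] <- cnn_train(m, sets[[j]]$x, sets[[j]]$y, val_x, val_y, tc_j)
      configs[[j]] <- list(lr = tc$lr, channels = config$channels)
    }
  }
  structure(list(models = models, configs = configs, seed = seed,
                 tuned = tune),
            class = "ppi_ensemble")
}

#' Per-member and averaged ensemble predictions
#'
#' @param ensemble A `"ppi_ensemble"`.
#' @param x Maps (36 x 32 x n array).
#' @return Matrix of member interaction probabilities (n x k) with the
#'   ensemble mean attached as attribute `"ensemble"`; or use
#'   [predict.ppi_ensemble()] for the mean directly.
#' @export
member_probs <- function(ensemble, x) {
  X <- as_input_matrix(x)
  probs <- vapply(ensemble$models, function(m) predict_probs(m, X)[, 1L],
                  numeric(ncol(X)))
  probs <- matrix(probs, ncol = length(ensemble$models),
                  dimnames = list(NULL, paste0("CNN", seq_along(ensemble$models))))
  attr(probs, "ensemble") <- rowMeans(probs)
  probs
}

#' @rdname member_probs
#' @param object A `"ppi_ensemble"`.
#' @param ... Unused.
#' @export
predict.ppi_ensemble <- function(object, x, ...) {
  rowMeans(member_probs(object, x))
}
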