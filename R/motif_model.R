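# Logistic regression of per-base editing efficiency on the 7-bp sequence
# context around each targeted base.

#' Build per-target-base context examples
#'
#' One example per editing-window target base with a defined per-position
#' efficiency: the 7-nt context (3 bp up, the targeted A/C, 3 bp down, taken
#' from the 40-nt site context) and the observed efficiency. Examples are then
#' split 70/30 into training and test sets by a seeded shuffle.
#'
#' @param sites A `be_sites` table.
#' @param summaries List of `be_site_summary`, matched to `sites` by site_id.
#' @param cfg A [be_config()].
#' @param seed Integer seed for the split shuffle (default `cfg$seed`).
#' @param train_fraction Training share of the split (default 0.7).
#' @return data.frame with columns `site_id`, `position`, `context7`,
#'   `efficiency`, `split` (`"train"`/`"test"`).
#' @export
build_examples <- function(sites, summaries, cfg, seed = cfg$seed,
                           train_fraction = 0.7) {
  ids <- vapply(summaries, `[[`, character(1), "site_id")
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    j <- match(site$site_id, ids)
    if (is.na(j)) next
    pp <- summaries[[j]]$per_position_efficiency
    for (p in target_positions(site, cfg$window)) {
      if (is.na(pp[p])) next
      ci <- proto_to_context(p)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = site$site_id, position = p,
        context7 = substr(site$context40, ci - 3L, ci + 3L),
        efficiency = pp[p], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(site_id = character(0), position = integer(0),
               context7 = character(0), efficiency = numeric(0))
  n <- nrow(df)
  df$split <- character(n)
  if (n > 0) {
    ord <- with_seed(seed, sample.int(n))
    n_train <- floor(train_fraction * n)
    df$split[ord[seq_len(n_train)]] <- "train"
    df$split[ord[-seq_len(n_train)]] <- "test"
  }
  df
}

#' One-hot encode a 7-nt context
#'
#' The six flanking positions are encoded with 4 indicator features each (24
#' features); the constant center base is excluded but checked against the
#' editor's target base.
#'
#' @param context7 Character vector of 7-nt contexts.
#' @param editor `"ABE"` or `"CBE"`.
#' @return Numeric matrix, one row per context, 24 named columns
#'   (`f<flank>_<base>` for flanks -3..-1, +1..+3).
#' @export
encode_context <- function(context7, editor) {
  if (any(nchar(context7) != 7)) stop("context must be 7 nt")
  center <- substr(context7, 4, 4)
  expect <- editor_target_base(editor)
  if (any(center != expect)) {
    stop("center base must be ", expect, " for ", editor, "; got ",
         paste(unique(center[center != expect]), collapse = ","))
  }
  bases <- c("A", "C", "G", "T")
  flanks <- c(-3, -2, -1, 1, 2, 3)
  # syntactic column names (m = upstream, p = downstream) so they survive
  # model formulas untouched
  cname <- function(f, b) sprintf("f%s%d_%s", ifelse(f < 0, "m", "p"), abs(f), b)
  M <- matrix(0, nrow = length(context7), ncol = 24,
              dimnames = list(NULL, as.vector(t(outer(flanks, bases, cname)))))
  for (k in seq_along(flanks)) {
    ch <- substr(context7, 4 + flanks[k], 4 + flanks[k])
    for (b in bases) {
      M[ch == b, cname(flanks[k], b)] <- 1
    }
  }
  M
}

#' Fit the motif logistic model and evaluate on held-out examples
#'
#' Efficiencies are fractional responses in \\[0,1\\], so the logistic model is
#' fit as a fractional (quasi-binomial) logit by iteratively reweighted least
#' squares; responses exactly 0 or 1 are nudged by 1e-6. Performance is the
#' Pearson correlation R between predicted and observed test efficiencies,
#' with variance explained reported as R^2. With more than one distinct
#' position and `position_covariate = TRUE`, position enters as a factor
#' covariate.
#'
#' @param train,test data.frames as from [build_examples()] (the `split`
#'   column is ignored; pass the subsets).
#' @param editor `"ABE"` or `"CBE"`.
#' @param nonzero_only Evaluate only on test examples with nonzero observed
#'   efficiency (the cross-dataset evaluation filter).
#' @param position_covariate Include protospacer position as a factor.
#' @return List of class `be_motif_model`: `fit` (glm), `test_r`,
#'   `variance_explained`, `n_train`, `n_test`, `predictions` (data.frame of
#'   test observations and predictions), `coefficients`.
#' @export
fit_and_evaluate <- function(train, test, editor, nonzero_only = FALSE,
                             position_covariate = TRUE) {
  eps <- 1e-6
  mk <- function(df) {
    X <- encode_context(df$context7, editor)
    # drop one base level per flank to avoid one-hot collinearity
    X <- X[, !grepl("_A$", colnames(X)), drop = FALSE]
    d <- as.data.frame(X)
    d$y <- pmin(pmax(df$efficiency, eps), 1 - eps)
    if (position_covariate && length(unique(df$position)) > 1) {
      d$position <- factor(df$position)
    }
    d
  }
  dtrain <- mk(train)
  fit <- stats::glm(y ~ ., data = dtrain, family = stats::quasibinomial())
  if (!fit$converged) stop("fractional logit did not converge (",
                           fit$iter, " IRLS iterations)")
  dtest <- mk(test)
  if ("position" %in% names(dtest)) {
    dtest$position <- factor(dtest$position,
                             levels = levels(dtrain$position))
  }
  pred <- stats::predict(fit, newdata = dtest, type = "response")
  obs <- test$efficiency
  keep <- if (nonzero_only) obs > 0 else rep(TRUE, length(obs))
  r <- stats::cor(pred[keep], obs[keep])
  structure(list(fit = fit, test_r = r, variance_explained = r^2,
                 n_train = nrow(train), n_test = sum(keep),
                 predictions = data.frame(observed = obs[keep],
                                          predicted = pred[keep]),
                 coefficients = stats::coef(fit)),
            class = "be_motif_model")
}

#' Position-weight matrix of context preference
#'
#' Mean one-hot frequency of each base at each flanking position, weighted by
#' example efficiency (a motif-logo style summary of favorable contexts).
#'
#' @param examples data.frame from [build_examples()].
#' @param editor `"ABE"` or `"CBE"`.
#' @return 4 x 6 matrix (bases x flank positions) of efficiency-weighted base
#'   frequencies, columns summing to 1.
#' @export
motif_pwm <- function(examples, editor) {
  X <- encode_context(examples$context7, editor)
  w <- examples$efficiency
  if (sum(w) == 0) w <- rep(1, length(w))
  wf <- colSums(X * w) / sum(w)
  # encode_context lays features flank-major: 4 consecutive base slots per flank
  M <- matrix(wf, nrow = 4,
              dimnames = list(c("A", "C", "G", "T"),
                              c("-3", "-2", "-1", "+1", "+2", "+3")))
  M
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
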