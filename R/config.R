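#' Run configuration
#'
#' Bundles the editor, its editing window, coverage and allele-proportion
#' filters, factor channels and training hyperparameters used across the
#' pipeline. Window defaults follow the editors' activity windows: protospacer
#' positions 5-7 for ABE and 4-8 for CBE.
#'
#' @param editor `"ABE"` or `"CBE"`.
#' @param window Inclusive 1-based protospacer position range, length-2
#'   integer. Defaults to `c(5, 7)` for ABE and `c(4, 8)` for CBE.
#' @param min_coverage Replicates with fewer aligned reads are excluded from
#'   replicate averaging (default 100).
#' @param allele_proportion_threshold Outcome alleles at or below this
#'   normalized proportion are discarded (default 0.05).
#' @param edited_fraction_min Minimum modified-read fraction (Ne/Nt) a
#'   replicate must reach to enter outcome analyses (default 0.9).
#' @param factor_channels Character vector of endogenous-factor channels fed to
#'   the efficiency model in addition to sequence. Default: `"H3K27ac"` for
#'   ABE, all factors for CBE.
#' @param h3k27ac_flank Flank width (bp) added on each side of the protospacer
#'   when intersecting H3K27ac peaks; 65 or 500 (default 65).
#' @param expression_high_cutoff Threshold on log2(TPM+1) above which a gene is
#'   "high" expression (default 1.5, strict inequality).
#' @param methylation_high_cutoff Site mean beta above which a site is
#'   methylated (default 0.75, strict inequality).
#' @param indel_length_normalize Divide indel-event frequencies by absolute
#'   indel length in the positional profile (default `TRUE`).
#' @param training Named list of efficiency-model hyperparameters; see
#'   [be_training_control()].
#' @param seed Integer RNG seed used by seeded operations when none is given.
#' @return A list of class `be_config`.
#' @export
be_config <- function(editor = c("ABE", "CBE"),
                      window = NULL,
                      min_coverage = 100L,
                      allele_proportion_threshold = 0.05,
                      edited_fraction_min = 0.9,
                      factor_channels = NULL,
                      h3k27ac_flank = 65L,
                      expression_high_cutoff = 1.5,
                      methylation_high_cutoff = 0.75,
                      indel_length_normalize = TRUE,
                      training = be_training_control(),
                      seed = 1L) {
  editor <- match.arg(editor)
  if (is.null(window)) {
    window <- if (editor == "ABE") c(5L, 7L) else c(4L, 8L)
  }
  window <- as.integer(window)
  if (length(window) != 2L || is.na(window[1]) || is.na(window[2]) ||
      window[1] < 1L || window[2] > 20L || window[1] > window[2]) {
    stop("window must satisfy 1 <= start <= end <= 20")
  }
  if (is.null(factor_channels)) {
    factor_channels <- if (editor == "ABE") "H3K27ac" else BE_FACTORS
  }
  structure(list(
    editor = editor,
    window = window,
    min_coverage = as.integer(min_coverage),
    allele_proportion_threshold = allele_proportion_threshold,
    edited_fraction_min = edited_fraction_min,
    factor_channels = factor_channels,
    h3k27ac_flank = as.integer(h3k27ac_flank),
    expression_high_cutoff = expression_high_cutoff,
    methylation_high_cutoff = methylation_high_cutoff,
    indel_length_normalize = isTRUE(indel_length_normalize),
    training = training,
    seed = as.integer(seed)
  ), class = "be_config")
}

#' Known endogenous-factor names
#' @export
BE_FACTORS <- c("expression", "PolII", "CTCF", "DHS", "H3K4me1", "H3K4me3",
                "H3K27ac", "H3K36me3", "methylation", "CRE")

#' Efficiency-model training hyperparameters
#'
#' Architecture and optimization knobs for the convolutional efficiency model.
#' The defaults define a small inception-style network: five parallel
#' convolution branches of kernel widths 1-5 over the 40-bp axis, concatenated,
#' max-pooled by 2, then a dense sigmoid head emitting 20 per-position
#' efficiencies.
#'
#' @param kernel_widths Integer widths of the parallel convolution branches.
#' @param filters Filters per branch.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience on validation loss (epochs).
#' @param validation_fraction Fraction of the training split held out for
#'   early stopping each run.
#' @param n_shuffles Number of independent shuffled train/test splits.
#' @param test_fraction Held-out test fraction per shuffle.
#' @param loss `"mse"` (masked MSE on efficiencies) or `"logit_mse"`.
#' @return Named list of class `be_training_control`.
#' @export
be_training_control <- function(kernel_widths = 1:5, filters = 12L,
                                epochs = 60L, batch_size = 128L,
                                learning_rate = 0.003, patience = 10L,
                                validation_fraction = 0.2, n_shuffles = 6L,
                                test_fraction = 0.2, loss = c("mse", "logit_mse")) {
  structure(list(
    kernel_widths = as.integer(kernel_widths),
    filters = as.integer(filters),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    patience = as.integer(patience),
    validation_fraction = validation_fraction,
    n_shuffles = as.integer(n_shuffles),
    test_fraction = test_fraction,
    loss = match.arg(loss)
  ), class = "be_training_control")
}

#' Read a run configuration from JSON or YAML
#'
#' The file mirrors the fields of [be_config()]; absent fields take their
#' defaults.
#'
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) file.
#' @return A `be_config` object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  train <- do.call(be_training_control, raw$training %||% list())
  raw$training <- NULL
  args <- raw[intersect(names(raw), names(formals(be_config)))]
  do.call(be_config, c(args, list(training = train)))
}

#' Write a run configuration to JSON
#' @param cfg A `be_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass_rec(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Positions of target bases in a window
#'
#' @param site One row of a `be_sites` table (or list with `protospacer`,
#'   `editor`).
#' @param window Length-2 inclusive position range; `NULL` for the whole
#'   protospacer.
#' @return Integer protospacer positions whose reference base is the editor's
#'   target base.
#' @export
target_positions <- function(site, window = NULL) {
  base <- editor_target_base(site$editor)
  chars <- strsplit(site$protospacer, "")[[1]]
  pos <- which(chars == base)
  if (!is.null(window)) pos <- pos[pos >= window[1] & pos <= window[2]]
  pos
}
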