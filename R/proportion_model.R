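# Chain Bayesian-network proportion model: per-position Bernoulli marginals
# plus adjacent-position odds ratios determine the joint distribution of
# editing outcomes.

#' Reconstruct a 2x2 joint from its margins and odds ratio
#'
#' Given marginal edit probabilities p and q of two positions and their odds
#' ratio c = p11 p00 / (p01 p10), solves the Plackett quadratic for the joint:
#' with S = 1 + (p + q)(c - 1), p11 is the smaller root
#' \[S - sqrt(S^2 - 4 c (c - 1) p q)\] / \[2 (c - 1)\] (the only root inside the
#' Frechet bounds for c != 1); c = 1 gives the independent joint p11 = p q.
#' The result is clipped to the Frechet box max(0, p+q-1) <= p11 <= min(p, q).
#'
#' @param p,q Marginal probabilities in (0,1).
#' @param c Odds ratio (> 0).
#' @return Named numeric vector `p11`, `p10`, `p01`, `p00` summing to 1.
#' @export
joint_from_margins_or <- function(p, q, c) {
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) stop("margins must lie in (0,1)")
  if (c <= 0) stop("odds ratio must be positive")
  if (abs(c - 1) < 1e-12) {
    p11 <- p * q
  } else {
    S <- 1 + (p + q) * (c - 1)
    disc <- S^2 - 4 * c * (c - 1) * p * q
    p11 <- (S - sqrt(max(disc, 0))) / (2 * (c - 1))
  }
  p11 <- min(max(p11, max(0, p + q - 1)), min(p, q))
  out <- c(p11 = p11, p10 = p - p11, p01 = q - p11, p00 = 1 - p - q + p11)
  pmax(out, 0)
}

#' Construct a chain proportion model
#'
#' @param positions Ascending protospacer positions of the editable (window
#'   target) bases.
#' @param marginals Per-position edit probabilities P(X_i = 1), clamped into
#'   \[eps, 1 - eps\].
#' @param odds_ratios Adjacent-pair odds ratios, length `length(positions) - 1`
#'   (recycled if length 1).
#' @param eps Marginal clamp (default 1e-6) keeping conditionals finite.
#' @return List of class `be_chain_model`.
#' @export
chain_model <- function(positions, marginals, odds_ratios = 1, eps = 1e-6) {
  n <- length(positions)
  stopifnot(n >= 1, length(marginals) == n)
  if (n > 1) odds_ratios <- rep_len(odds_ratios, n - 1) else odds_ratios <- numeric(0)
  if (any(odds_ratios <= 0)) stop("odds ratios must be positive")
  structure(list(positions = as.integer(positions),
                 marginals = pmin(pmax(marginals, eps), 1 - eps),
                 odds_ratios = odds_ratios, eps = eps),
            class = "be_chain_model")
}

#' Probability of one outcome pattern under the chain model
#'
#' The chain factorization P(X1) prod_i P(X_i | X_{i-1}) with each conditional
#' derived from the 2x2 joint of the adjacent pair.
#'
#' @param model A [chain_model()].
#' @param pattern Binary vector (0/1) over the model's editable positions.
#' @return The pattern's probability.
#' @export
chain_joint <- function(model, pattern) {
  n <- length(model$marginals)
  stopifnot(length(pattern) == n)
  b <- as.integer(pattern)
  m <- model$marginals
  p <- if (b[1] == 1) m[1] else 1 - m[1]
  if (n == 1) return(p)
  for (i in 2:n) {
    J <- joint_from_margins_or(m[i - 1], m[i], model$odds_ratios[i - 1])
    cond <- if (b[i - 1] == 1) {
      c(`1` = J["p11"], `0` = J["p10"]) / max(m[i - 1], model$eps)
    } else {
      c(`1` = J["p01"], `0` = J["p00"]) / max(1 - m[i - 1], model$eps)
    }
    p <- p * unname(if (b[i] == 1) cond[1] else cond[2])
  }
  p
}

# All 2^n binary patterns as an n-column matrix (n <= 12 guarded upstream).
all_patterns <- function(n) {
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  as.matrix(do.call(expand.grid, rep(list(c(0L, 1L)), n)))[, n:1, drop = FALSE]
}

#' Predicted outcome distribution of a site
#'
#' Enumerates all 2^n outcome patterns of the editable positions and scores
#' each with [chain_joint()]. Optionally mirrors the observed-distribution
#' processing (wild-type removal, renormalization, allele-proportion
#' threshold, renormalization) so predictions are comparable with
#' [collapse_outcomes()] output.
#'
#' @param model A [chain_model()] (n <= 12 editable positions).
#' @param site Optional `be_sites` row used to render full 20-position pattern
#'   strings; without it patterns span only the editable positions.
#' @param cfg A [be_config()]; supplies the allele-proportion threshold.
#' @param mimic_observed Apply wild-type removal and the proportion threshold.
#' @return A `be_outcomes` data.frame (provenance `"predicted"`).
#' @export
predict_proportions <- function(model, site = NULL, cfg = be_config(),
                                mimic_observed = FALSE) {
  n <- length(model$marginals)
  if (n > 12) stop("more than 12 editable positions (", n,
                   "); restrict the editing window")
  pats <- all_patterns(n)
  prob <- apply(pats, 1, function(b) chain_joint(model, b))
  pattern_str <- apply(pats, 1, function(b) {
    if (is.null(site)) return(paste(b, collapse = ""))
    proto <- strsplit(site$protospacer, "")[[1]]
    chars <- ifelse(proto == editor_target_base(site$editor), "0", ".")
    chars[model$positions] <- as.character(b)
    paste(chars, collapse = "")
  })
  df <- data.frame(allele = pattern_str, edit_pattern = pattern_str,
                   other_edits = "", proportion = prob,
                   stringsAsFactors = FALSE)
  n_edit <- rowSums(pats == 1L)
  if (mimic_observed) {
    df <- df[n_edit > 0, , drop = FALSE]
    if (nrow(df) > 0 && sum(df$proportion) > 0) {
      df$proportion <- df$proportion / sum(df$proportion)
      df <- df[df$proportion > cfg$allele_proportion_threshold, , drop = FALSE]
    }
  }
  if (nrow(df) > 0) df$proportion <- df$proportion / sum(df$proportion)
  df <- df[order(-df$proportion, df$allele), , drop = FALSE]
  be_outcomes(df,
              site_id = if (is.null(site)) NA_character_ else site$site_id,
              provenance = "predicted")
}

#' Estimate adjacent-position odds ratios from observed outcomes
#'
#' For every site and every adjacent pair of its editable positions, builds a
#' 2x2 co-editing table from the site's outcome distribution (proportions
#' scaled by the site's pooled read count, plus a pseudocount of 0.5 per
#' cell) and computes the log odds ratio. Site-level tables are then combined
#' across sites by inverse-variance (Woolf) weighting on the log scale, which
#' stays consistent under a shared c even when per-site marginals differ
#' (naive count pooling across sites with heterogeneous marginals is
#' non-collapsible and attenuates c; it remains available as
#' `method = "pooled"`). Alleles carrying side edits (unintended
#' substitutions or indels) are excluded by default: a deleted or substituted
#' target base cannot be called edited or unedited.
#'
#' @param outcome_list List of `be_outcomes`; estimating co-editing requires
#'   distributions that retain the wild-type allele
#'   (`collapse_outcomes(..., keep_wildtype = TRUE)`).
#' @param pooling `"global"` (one c shared by all adjacent pairs, default) or
#'   `"pairwise"` (one c per position pair).
#' @param method `"woolf"` (stratified by site, default) or `"pooled"` (raw
#'   cross-site count pooling).
#' @param window Optional length-2 position range restricting the editable
#'   positions (the chain model's domain); `NULL` uses every target position
#'   in the patterns.
#' @param exclude_side_edits Drop alleles with unintended substitutions or
#'   indels before counting.
#' @param pseudocount Added to each 2x2 cell (default 0.5).
#' @return For `"global"` pooling: list `c`, `log_se` (standard error of
#'   log c), `n_strata`. For `"pairwise"`: data.frame `pos_i`, `pos_j`, `c`,
#'   `log_se`, `n_sites`. With no observed pair, c = 1 with a warning.
#' @export
estimate_adjacent_or <- function(outcome_list, pooling = c("global", "pairwise"),
                                 method = c("woolf", "pooled"),
                                 window = NULL, exclude_side_edits = TRUE,
                                 pseudocount = 0.5) {
  pooling <- match.arg(pooling)
  method <- match.arg(method)
  strata <- list() # one element per (site, pair): cells + pair key
  for (oc in outcome_list) {
    if (nrow(oc) == 0) next
    w0 <- attr(oc, "total_reads")
    if (is.null(w0) || is.na(w0)) w0 <- 1
    keep <- if (exclude_side_edits) oc$other_edits == "" else
      rep(TRUE, nrow(oc))
    if (!any(keep)) next
    prop <- oc$proportion[keep] / sum(oc$proportion[keep])
    chars <- do.call(rbind, strsplit(oc$edit_pattern[keep], ""))
    target_pos <- which(chars[1, , drop = TRUE] != ".")
    if (!is.null(window)) {
      target_pos <- target_pos[target_pos >= window[1] &
                                 target_pos <= window[2]]
    }
    if (length(target_pos) < 2) next
    E <- chars[, target_pos, drop = FALSE] == "1"
    for (k in seq_len(length(target_pos) - 1)) {
      cells <- c(p11 = 0, p10 = 0, p01 = 0, p00 = 0)
      for (r in seq_len(nrow(E))) {
        cell <- paste0("p", as.integer(E[r, k]), as.integer(E[r, k + 1]))
        cells[cell] <- cells[cell] + prop[r] * w0
      }
      strata[[length(strata) + 1L]] <- list(
        pair = paste(target_pos[k], target_pos[k + 1], sep = "-"),
        cells = cells)
    }
  }
  combine <- function(sub) {
    if (method == "pooled") {
      cells <- Reduce(`+`, lapply(sub, `[[`, "cells")) + pseudocount
      lo <- log(cells[["p11"]]) + log(cells[["p00"]]) -
        log(cells[["p01"]]) - log(cells[["p10"]])
      list(c = exp(lo), log_se = sqrt(sum(1 / cells)), n = length(sub))
    } else {
      lo <- vapply(sub, function(s) {
        cl <- s$cells + pseudocount
        log(cl[["p11"]]) + log(cl[["p00"]]) - log(cl[["p01"]]) - log(cl[["p10"]])
      }, numeric(1))
      w <- vapply(sub, function(s) 1 / sum(1 / (s$cells + pseudocount)),
                  numeric(1))
      list(c = exp(sum(w * lo) / sum(w)), log_se = sqrt(1 / sum(w)),
           n = length(sub))
    }
  }
  if (pooling == "global") {
    if (length(strata) == 0) {
      warning("no adjacent pair observed; returning c = 1")
      return(list(c = 1, log_se = NA_real_, n_strata = 0L))
    }
    res <- combine(strata)
    list(c = res$c, log_se = res$log_se, n_strata = res$n)
  } else {
    if (length(strata) == 0) {
      warning("no adjacent pair observed")
      return(data.frame(pos_i = integer(0), pos_j = integer(0),
                        c = numeric(0), log_se = numeric(0),
                        n_sites = integer(0)))
    }
    pairs <- vapply(strata, `[[`, character(1), "pair")
    do.call(rbind, lapply(unique(pairs), function(pk) {
      res <- combine(strata[pairs == pk])
      pos <- as.integer(strsplit(pk, "-", fixed = TRUE)[[1]])
      data.frame(pos_i = pos[1], pos_j = pos[2], c = res$c,
                 log_se = res$log_se, n_sites = res$n)
    }))
  }
}

#' Label outcome forms and find the Max-form
#'
#' Edited-forms are the outcome alleles carrying at least one intended
#' transition; the Max-form is the Edited-form with the highest proportion,
#' with deterministic tie-breaking by fewer edited bases, then leftmost edited
#' position, then pattern string order.
#'
#' @param dist A non-empty `be_outcomes`.
#' @param editor `"ABE"` or `"CBE"` (recorded in the output).
#' @return List of class `be_form_labels`: `forms` data.frame (`allele`,
#'   `proportion`, `form` in `{wild-type, Edited-form, other}`), `max_form`
#'   (allele string or NA when no edited allele exists), `editor`.
#' @export
classify_forms <- function(dist, editor) {
  stopifnot(nrow(dist) > 0)
  n_edit <- vapply(gregexpr("1", dist$edit_pattern, fixed = TRUE),
                   function(m) sum(m > 0), numeric(1))
  is_wt <- n_edit == 0 & dist$other_edits == ""
  form <- ifelse(n_edit > 0, "Edited-form", ifelse(is_wt, "wild-type", "other"))
  max_form <- NA_character_
  ed <- which(form == "Edited-form")
  if (length(ed) > 0) {
    first_pos <- vapply(dist$edit_pattern[ed], function(s) {
      as.integer(regexpr("1", s, fixed = TRUE))
    }, integer(1), USE.NAMES = FALSE)
    ord <- order(-dist$proportion[ed], n_edit[ed], first_pos,
                 dist$edit_pattern[ed])
    max_form <- dist$allele[ed[ord[1]]]
  }
  structure(list(forms = data.frame(allele = dist$allele,
                                    proportion = dist$proportion,
                                    form = form, stringsAsFactors = FALSE),
                 max_form = max_form, editor = editor),
            class = "be_form_labels")
}

#' Mutual-information audit of the chain simplification
#'
#' Computes, from an observed or predicted outcome distribution, the pairwise
#' mutual information (in bits, log2) between every pair of editable
#' positions, and for every triple of consecutive editable positions the
#' conditional MI of the outer pair given the middle one. Under a first-order
#' chain the conditional MI vanishes: adjacent dependence carries the distant
#' dependence.
#'
#' @param outcomes A non-empty `be_outcomes` whose proportions cover the full
#'   distribution (wild type included) for unbiased MI.
#' @return List: `pairwise` data.frame (`pos_i`, `pos_j`, `adjacent`,
#'   `mi_bits`), `conditional` data.frame (`pos_i`, `pos_mid`, `pos_k`,
#'   `cmi_bits`).
#' @export
mutual_information_audit <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  chars <- do.call(rbind, strsplit(outcomes$edit_pattern, ""))
  target_pos <- which(chars[1, ] != ".")
  E <- (chars[, target_pos, drop = FALSE] == "1") * 1L
  w <- outcomes$proportion / sum(outcomes$proportion)
  np <- length(target_pos)
  mi2 <- function(i, j) {
    p <- matrix(0, 2, 2)
    for (r in seq_along(w)) p[E[r, i] + 1, E[r, j] + 1] <- p[E[r, i] + 1, E[r, j] + 1] + w[r]
    mi_from_joint(p)
  }
  pairs <- list()
  if (np >= 2) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        pos_i = target_pos[i], pos_j = target_pos[j],
        adjacent = (j == i + 1), mi_bits = mi2(i, j))
    }
  }
  cond <- list()
  if (np >= 3) {
    for (i in 1:(np - 2)) {
      j <- i + 1; k <- i + 2
      p3 <- array(0, c(2, 2, 2))
      for (r in seq_along(w)) {
        p3[E[r, i] + 1, E[r, j] + 1, E[r, k] + 1] <-
          p3[E[r, i] + 1, E[r, j] + 1, E[r, k] + 1] + w[r]
      }
      cmi <- 0
      for (b in 1:2) {
        pm <- sum(p3[, b, ])
        if (pm > 0) cmi <- cmi + pm * mi_from_joint(p3[, b, ] / pm)
      }
      cond[[length(cond) + 1L]] <- data.frame(
        pos_i = target_pos[i], pos_mid = target_pos[j], pos_k = target_pos[k],
        cmi_bits = cmi)
    }
  }
  list(pairwise = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(pos_i = integer(0), pos_j = integer(0),
                    adjacent = logical(0), mi_bits = numeric(0)),
       conditional = if (length(cond)) do.call(rbind, cond) else
         data.frame(pos_i = integer(0), pos_mid = integer(0),
                    pos_k = integer(0), cmi_bits = numeric(0)))
}

mi_from_joint <- function(p) {
  rs <- rowSums(p); cs <- colSums(p)
  mi <- 0
  for (a in seq_along(rs)) for (b in seq_along(cs)) {
    if (p[a, b] > 0) mi <- mi + p[a, b] * log2(p[a, b] / (rs[a] * cs[b]))
  }
  max(mi, 0)
}
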