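# Editing-outcome distributions: replicate concordance filters, allele
# collapsing, endogenous-vs-integrated consistency groups.

#' Edit pattern of one parsed allele
#'
#' A 20-character string over protospacer positions: `.` where the reference
#' base is not the editor's target base, `0` at an unedited target base, `1`
#' at a target base carrying the intended transition. Substitutions other than
#' the intended transition, and indels, do not enter the pattern; they are
#' serialized into a side key so distinct alleles stay distinct.
#' @noRd
allele_pattern <- function(parsed_row, site) {
  proto <- strsplit(site$protospacer, "")[[1]]
  base <- editor_target_base(site$editor)
  pat <- ifelse(proto == base, "0", ".")
  in_proto <- parsed_row$sub_pos >= 1 & parsed_row$sub_pos <= 20
  intended <- in_proto & parsed_row$sub_from == base &
    parsed_row$sub_to == editor_product_base(site$editor)
  pat[parsed_row$sub_pos[intended]] <- "1"
  other_sub <- in_proto & !intended
  side <- character(0)
  if (any(other_sub)) {
    side <- paste0(parsed_row$sub_pos[other_sub],
                   parsed_row$sub_from[other_sub], ">",
                   parsed_row$sub_to[other_sub])
  }
  ev <- parsed_row$indels
  if (nrow(ev) > 0) {
    side <- c(side, sprintf("indel%d@%d", ev$length, ev$position))
  }
  list(pattern = paste(pat, collapse = ""),
       other = paste(sort(side), collapse = ","))
}

be_outcomes <- function(df, site_id, provenance, total_reads = NA_real_) {
  rownames(df) <- NULL
  structure(df, class = c("be_outcomes", "data.frame"),
            site_id = site_id, provenance = provenance,
            total_reads = total_reads)
}

#' Filter outcome replicates by edited fraction and replicate concordance
#'
#' Replicates whose modified-read fraction Ne/Nt falls below
#' `cfg$edited_fraction_min` (default 0.9) are removed. Among the survivors,
#' a replicate is removed as discordant when its mean pairwise
#' Kullback-Leibler divergence to the other replicates' allele distributions
#' (pseudocount 0.5 per allele before normalizing) exceeds the Tukey fence
#' Q3 + 1.5 IQR of those mean-KL values.
#'
#' @param tables List of `be_allele_table` replicates of one site.
#' @param site The matching `be_sites` row.
#' @param cfg A [be_config()].
#' @return List with `retained` (allele tables), `edited_fraction`, `mean_kl`
#'   (named per replicate; KL is NA when fewer than 2 survivors). `retained`
#'   is empty, with a message, when every replicate is filtered out.
#' @export
filter_outcome_replicates <- function(tables, site, cfg) {
  stopifnot(length(tables) >= 1)
  reps <- vapply(tables, `[[`, character(1), "replicate_id")
  parsed <- lapply(tables, parse_alleles, site = site)
  efrac <- vapply(seq_along(tables), function(i) {
    sum(vapply(parsed[[i]], function(p) p$n_reads * p$modified, numeric(1))) /
      tables[[i]]$total_reads
  }, numeric(1))
  names(efrac) <- reps
  keep <- efrac >= cfg$edited_fraction_min
  mean_kl <- rep(NA_real_, length(tables))
  names(mean_kl) <- reps
  idx <- which(keep)
  if (length(idx) >= 2) {
    counts <- lapply(idx, function(i) {
      pat <- vapply(seq_along(parsed[[i]]), function(j) {
        ap <- allele_pattern(parsed[[i]][[j]], site)
        paste0(ap$pattern, "|", ap$other)
      }, character(1))
      nr <- vapply(parsed[[i]], `[[`, numeric(1), "n_reads")
      tapply(nr, pat, sum)
    })
    support <- sort(unique(unlist(lapply(counts, names))))
    probs <- lapply(counts, function(ct) {
      x <- stats::setNames(rep(0, length(support)), support)
      x[names(ct)] <- ct
      x <- x + 0.5
      x / sum(x)
    })
    m <- length(idx)
    kl <- function(p, q) sum(p * log(p / q))
    mk <- vapply(seq_len(m), function(a) {
      mean(vapply(setdiff(seq_len(m), a), function(b) kl(probs[[a]], probs[[b]]),
                  numeric(1)))
    }, numeric(1))
    mean_kl[idx] <- mk
    qs <- stats::quantile(mk, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- qs[2] + 1.5 * (qs[2] - qs[1])
    keep[idx[mk > fence]] <- FALSE
  }
  if (!any(keep)) {
    message("site ", site$site_id, " dropped from outcome analysis: ",
            "no replicate passed the concordance filters")
  }
  list(retained = tables[keep], edited_fraction = efrac, mean_kl = mean_kl)
}

#' Collapse replicate allele tables into an outcome distribution
#'
#' Read counts are pooled across replicates by allele; the wild-type
#' (unmodified) allele is removed and the remainder renormalized to 1; alleles
#' at or below `cfg$allele_proportion_threshold` are then removed and the
#' survivors renormalized again. With `keep_wildtype = TRUE` the wild-type
#' allele is kept and no threshold is applied (the full distribution used for
#' estimating co-editing correlations).
#'
#' @param tables List of `be_allele_table` replicates (typically the output of
#'   [filter_outcome_replicates()]).
#' @param site The matching `be_sites` row.
#' @param cfg A [be_config()].
#' @param keep_wildtype Keep the unmodified allele and skip thresholding.
#' @return A `be_outcomes` data.frame with columns `allele` (pattern plus any
#'   side edits), `edit_pattern`, `other_edits`, `proportion`; attributes
#'   `site_id`, `provenance = "observed"`, `total_reads` (pooled reads before
#'   wild-type removal). Zero rows, with attribute `empty = TRUE`, when no
#'   edited allele remains.
#' @export
collapse_outcomes <- function(tables, site, cfg, keep_wildtype = FALSE) {
  stopifnot(length(tables) >= 1)
  acc <- new.env(parent = emptyenv())
  total <- 0
  for (tb in tables) {
    parsed <- parse_alleles(tb, site)
    total <- total + tb$total_reads
    for (p in parsed) {
      ap <- allele_pattern(p, site)
      key <- paste0(ap$pattern, "|", ap$other)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p$n_reads
    }
  }
  keys <- ls(acc, all.names = TRUE) # patterns may begin with "."
  counts <- vapply(keys, function(k) acc[[k]], numeric(1))
  parts <- strsplit(keys, "|", fixed = TRUE)
  pattern <- vapply(parts, `[[`, character(1), 1)
  other <- vapply(parts, function(x) if (length(x) > 1) x[2] else "", character(1))
  is_wt <- !grepl("1", pattern, fixed = TRUE) & other == ""
  df <- data.frame(edit_pattern = pattern, other_edits = other,
                   n_reads = counts, stringsAsFactors = FALSE)
  if (!keep_wildtype) {
    df <- df[!is_wt, , drop = FALSE]
    if (nrow(df) == 0 || sum(df$n_reads) == 0) {
      out <- be_outcomes(data.frame(allele = character(0),
                                    edit_pattern = character(0),
                                    other_edits = character(0),
                                    proportion = numeric(0)),
                         site$site_id, "observed", total)
      attr(out, "empty") <- TRUE
      return(out)
    }
    df$proportion <- df$n_reads / sum(df$n_reads)
    df <- df[df$proportion > cfg$allele_proportion_threshold, , drop = FALSE]
    if (nrow(df) == 0) {
      out <- be_outcomes(data.frame(allele = character(0),
                                    edit_pattern = character(0),
                                    other_edits = character(0),
                                    proportion = numeric(0)),
                         site$site_id, "observed", total)
      attr(out, "empty") <- TRUE
      return(out)
    }
  }
  df$proportion <- df$n_reads / sum(df$n_reads)
  df$allele <- ifelse(df$other_edits == "", df$edit_pattern,
                      paste0(df$edit_pattern, "|", df$other_edits))
  df <- df[order(-df$proportion, df$allele),
           c("allele", "edit_pattern", "other_edits", "proportion")]
  be_outcomes(df, site$site_id, "observed", total)
}

#' Marginalize an outcome distribution onto edit patterns
#'
#' Sums allele proportions by their intended-edit pattern, optionally
#' restricted to a set of protospacer positions.
#'
#' @param outcomes A `be_outcomes` data.frame.
#' @param positions Optional integer positions (1-20) to restrict the pattern
#'   to; default keeps all 20.
#' @return Named numeric vector of proportions (names are pattern strings).
#' @export
pattern_distribution <- function(outcomes, positions = NULL) {
  if (nrow(outcomes) == 0) return(stats::setNames(numeric(0), character(0)))
  pat <- outcomes$edit_pattern
  if (!is.null(positions)) {
    pat <- vapply(pat, function(s) {
      paste(strsplit(s, "")[[1]][positions], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  tapply_v <- tapply(outcomes$proportion, pat, sum)
  stats::setNames(as.numeric(tapply_v), names(tapply_v))
}

#' Consistency of outcome products between two datasets
#'
#' Compares the allele sets of the same site measured in two datasets
#' (canonically endogenous vs integrated): `Consistent` when the sets are
#' equal, `Endo-bias` when the first strictly contains the second, `Inte-bias`
#' when the second strictly contains the first, `Discordant` when each has
#' alleles the other lacks.
#'
#' @param endo,inte Non-empty `be_outcomes` for the same site.
#' @return One of `"Consistent"`, `"Endo-bias"`, `"Inte-bias"`, `"Discordant"`.
#' @export
classify_outcome_consistency <- function(endo, inte) {
  if (nrow(endo) == 0 || nrow(inte) == 0) {
    stop("empty outcome distribution; cannot classify consistency")
  }
  e <- unique(endo$allele)
  i <- unique(inte$allele)
  e_only <- length(setdiff(e, i)) > 0
  i_only <- length(setdiff(i, e)) > 0
  if (!e_only && !i_only) "Consistent"
  else if (e_only && !i_only) "Endo-bias"
  else if (!e_only && i_only) "Inte-bias"
  else "Discordant"
}

#' Efficiency bias groups from paired endogenous/integrated efficiencies
#'
#' Fits ordinary least squares of endogenous on integrated efficiency and
#' groups sites by their residual d relative to the mean +/- one standard
#' deviation band of the residual distribution (population SD): d > mu + sigma
#' is `Endo-bias`, d < mu - sigma is `Inte-bias`, the rest `Consistent`. A
#' zero-width band (sigma = 0) assigns every site to `Consistent`.
#'
#' @param endo,inte Paired numeric efficiency vectors (>= 3 sites).
#' @param site_id Optional identifiers for the output.
#' @return List of class `be_bias_groups`: `assignment` (named character),
#'   `slope`, `intercept`, `residuals`, `mu`, `sigma`.
#' @export
classify_efficiency_bias <- function(endo, inte, site_id = NULL) {
  if (length(endo) != length(inte)) stop("endo/inte lengths differ")
  if (length(endo) < 3) stop("need at least 3 paired sites")
  if (stats::var(inte) == 0) stop("degenerate regression: zero variance in inte")
  fit <- stats::lm(endo ~ inte)
  d <- stats::residuals(fit)
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2)) # population SD
  if (sigma < 1e-10) sigma <- 0 # numerically exact fit: zero-width band
  grp <- rep("Consistent", length(d))
  if (sigma > 0) {
    grp[d > mu + sigma] <- "Endo-bias"
    grp[d < mu - sigma] <- "Inte-bias"
  }
  names(grp) <- site_id %||% as.character(seq_along(d))
  structure(list(assignment = grp,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = stats::setNames(as.numeric(d), names(grp)),
                 mu = mu, sigma = sigma),
            class = "be_bias_groups")
}

#' Pairwise co-editing proportions
#'
#' Entry (i, j) is the summed proportion of alleles edited at both target
#' positions i and j; the diagonal holds the marginal edit proportion of each
#' position.
#'
#' @param outcomes A non-empty `be_outcomes`.
#' @return Symmetric numeric matrix over the site's target-base positions
#'   (dimnames are protospacer positions).
#' @export
cooccurrence_matrix <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  chars <- do.call(rbind, strsplit(outcomes$edit_pattern, ""))
  target_pos <- which(chars[1, ] != ".")
  E <- (chars[, target_pos, drop = FALSE] == "1") * 1
  M <- t(E) %*% (E * outcomes$proportion)
  dimnames(M) <- list(target_pos, target_pos)
  M
}

#' Distribution of the number of edited target bases per allele
#'
#' @param outcomes A `be_outcomes` (possibly empty).
#' @return Named numeric vector: proportion-weighted histogram over edit
#'   counts; weights sum to 1 for non-empty input.
#' @export
edited_base_count_distribution <- function(outcomes) {
  if (nrow(outcomes) == 0) return(stats::setNames(numeric(0), character(0)))
  k <- vapply(gregexpr("1", outcomes$edit_pattern, fixed = TRUE),
              function(m) sum(m > 0), numeric(1))
  h <- tapply(outcomes$proportion, k, sum)
  stats::setNames(as.numeric(h), names(h))
}
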