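# Per-site editing statistics from allele-frequency tables.

#' The 12 base transitions
#'
#' All ordered substitutions X>Y over A/C/G/T, in fixed reporting order.
#' @export
BE_TRANSITIONS <- {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(to = b, from = b, stringsAsFactors = FALSE)
  g <- g[g$from != g$to, ]
  sort(paste0(g$from, ">", g$to))
}

PURITY_SCOPES <- c("overall", "in_window", "outside_window")

# Parse every allele row of a table into per-read edit calls relative to the
# protospacer. Returns a list with, per row: substitution positions/identities
# (protospacer coords 1-20), indel events (position, signed length), and
# whether the read is modified anywhere in the reference.
parse_alleles <- function(table, site) {
  off <- protospacer_offset(table, site)
  ref <- strsplit(table$reference, "")[[1]]
  rows <- table$rows
  lapply(seq_len(nrow(rows)), function(i) {
    a <- strsplit(rows$aligned_allele[i], "")[[1]]
    mism <- which(a != ref & a != "-")
    sub_pos <- mism - off # protospacer coords; may fall outside 1..20
    sub_from <- ref[mism]
    sub_to <- a[mism]
    events <- empty_indel_events()
    del <- a == "-"
    if (any(del)) {
      runs <- rle(del)
      stops <- cumsum(runs$lengths)
      starts <- stops - runs$lengths + 1L
      k <- which(runs$values)
      events <- rbind(events, data.frame(
        position = starts[k] - off,
        length = -(stops[k] - starts[k] + 1L)
      ))
    }
    ins <- rows$insertions[[i]]
    if (nrow(ins) > 0) {
      events <- rbind(events, data.frame(
        position = ins$position - off,
        length = nchar(ins$seq)
      ))
    }
    list(sub_pos = sub_pos, sub_from = sub_from, sub_to = sub_to,
         indels = events,
         modified = length(mism) > 0 || nrow(events) > 0,
         n_reads = rows$n_reads[i])
  })
}

empty_indel_events <- function() {
  data.frame(position = integer(0), length = integer(0))
}

# Positions (proto coords) occupied by an indel event: a deletion spans its
# deleted bases; a 1-bp-resolution insertion sits at the base it precedes.
indel_event_positions <- function(position, length) {
  if (length < 0) seq(position, position - length - 1L) else position
}

#' Summarize editing outcomes at one site
#'
#' Computes, from one replicate's allele-frequency table, the per-site editing
#' statistics: overall efficiency (reads carrying the intended transition
#' inside the editing window / total reads), per-position efficiency at each
#' target base, modified efficiency (reads with any substitution or indel /
#' total reads), relative proportions of the 12 base transitions in three
#' scopes (whole protospacer, inside window, outside window; each normalized
#' to sum to 1), per-(position, signed length) indel frequencies within the
#' protospacer, and deaminase- (positions 1-11) versus nCas9- (14-20)
#' attributed indel read fractions.
#'
#' @param table A `be_allele_table`.
#' @param site The matching `be_sites` row.
#' @param cfg A [be_config()]; supplies the editor check and window.
#' @return A list of class `be_site_summary`.
#' @export
summarize_site <- function(table, site, cfg) {
  if (site$editor != cfg$editor) {
    stop("site ", site$site_id, " editor ", site$editor,
         " does not match config editor ", cfg$editor)
  }
  parsed <- parse_alleles(table, site)
  w <- cfg$window
  from <- editor_target_base(site$editor)
  to <- editor_product_base(site$editor)
  total <- table$total_reads
  proto <- strsplit(site$protospacer, "")[[1]]
  target_pos <- which(proto == from)

  pp_num <- numeric(20)
  overall_num <- 0
  modified_num <- 0
  trans_num <- matrix(0, nrow = 3, ncol = length(BE_TRANSITIONS),
                      dimnames = list(PURITY_SCOPES, BE_TRANSITIONS))
  indel_num <- list()
  deam_num <- 0
  ncas_num <- 0

  for (p in parsed) {
    nr <- p$n_reads
    in_proto <- p$sub_pos >= 1 & p$sub_pos <= 20
    intended <- in_proto & p$sub_from == from & p$sub_to == to
    ipos <- p$sub_pos[intended]
    if (length(ipos) > 0) pp_num[ipos] <- pp_num[ipos] + nr
    if (any(ipos >= w[1] & ipos <= w[2])) overall_num <- overall_num + nr
    if (p$modified) modified_num <- modified_num + nr
    if (any(in_proto)) {
      keys <- paste0(p$sub_from[in_proto], ">", p$sub_to[in_proto])
      pos <- p$sub_pos[in_proto]
      in_w <- pos >= w[1] & pos <= w[2]
      for (scope_i in 1:3) {
        sel <- switch(scope_i, rep(TRUE, length(pos)), in_w, !in_w)
        for (k in unique(keys[sel])) {
          trans_num[scope_i, k] <- trans_num[scope_i, k] + nr
        }
      }
    }
    if (nrow(p$indels) > 0) {
      hit_deam <- FALSE
      hit_ncas <- FALSE
      for (j in seq_len(nrow(p$indels))) {
        ev_pos <- p$indels$position[j]
        ev_len <- p$indels$length[j]
        if (ev_pos >= 1 && ev_pos <= 20) {
          key <- paste0(ev_pos, ":", ev_len)
          indel_num[[key]] <- (indel_num[[key]] %||% 0) + nr
        }
        occ <- indel_event_positions(ev_pos, ev_len)
        if (any(occ >= 1 & occ <= 11)) hit_deam <- TRUE
        if (any(occ >= 14 & occ <= 20)) hit_ncas <- TRUE
      }
      if (hit_deam) deam_num <- deam_num + nr
      if (hit_ncas) ncas_num <- ncas_num + nr
    }
  }

  pp <- pp_num / total
  pp[setdiff(1:20, target_pos)] <- NA_real_
  # relative proportions from raw read counts: each scope's 12 transitions
  # sum to 1 when any mutated read exists
  trans_prop <- t(apply(trans_num, 1, function(x) {
    s <- sum(x)
    if (s > 0) x / s else rep(NA_real_, length(x))
  }))
  dimnames(trans_prop) <- dimnames(trans_num)

  indels <- if (length(indel_num) > 0) {
    keys <- do.call(rbind, strsplit(names(indel_num), ":", fixed = TRUE))
    data.frame(position = as.integer(keys[, 1]),
               length = as.integer(keys[, 2]),
               frequency = unlist(indel_num, use.names = FALSE) / total)
  } else {
    data.frame(position = integer(0), length = integer(0), frequency = numeric(0))
  }
  indels <- indels[order(indels$position, indels$length), , drop = FALSE]
  rownames(indels) <- NULL

  structure(list(
    site_id = site$site_id,
    editor = site$editor,
    window = w,
    total_reads = total,
    n_replicates = 1L,
    overall_efficiency = overall_num / total,
    per_position_efficiency = pp,
    modified_efficiency = modified_num / total,
    transition_proportions = trans_prop,
    indel_by_position_length = indels,
    deaminase_indel_freq = deam_num / total,
    ncas9_indel_freq = ncas_num / total
  ), class = "be_site_summary")
}

#' Average replicate summaries for one site
#'
#' Replicates with coverage below `cfg$min_coverage` are excluded; the
#' surviving summaries are averaged field-wise (arithmetic mean; indel events
#' absent from a replicate contribute frequency 0). Returns `NULL`, with a
#' message, when no replicate survives.
#'
#' @param summaries List of `be_site_summary` objects for the same site.
#' @param cfg A [be_config()].
#' @return A `be_site_summary` or `NULL` if the site is dropped.
#' @export
average_replicates <- function(summaries, cfg) {
  stopifnot(length(summaries) >= 1)
  ids <- unique(vapply(summaries, `[[`, character(1), "site_id"))
  if (length(ids) != 1) stop("summaries belong to different sites: ",
                             paste(ids, collapse = ", "))
  keep <- vapply(summaries, function(s) s$total_reads >= cfg$min_coverage,
                 logical(1))
  if (!any(keep)) {
    message("site ", ids, " dropped: all ", length(summaries),
            " replicate(s) under coverage ", cfg$min_coverage)
    return(NULL)
  }
  kept <- summaries[keep]
  out <- kept[[1]]
  n <- length(kept)
  mean_field <- function(f) {
    Reduce(`+`, lapply(kept, `[[`, f)) / n
  }
  out$overall_efficiency <- mean_field("overall_efficiency")
  out$modified_efficiency <- mean_field("modified_efficiency")
  out$deaminase_indel_freq <- mean_field("deaminase_indel_freq")
  out$ncas9_indel_freq <- mean_field("ncas9_indel_freq")
  out$per_position_efficiency <-
    Reduce(`+`, lapply(kept, `[[`, "per_position_efficiency")) / n
  tp <- lapply(kept, `[[`, "transition_proportions")
  any_val <- Reduce(`|`, lapply(tp, function(m) !is.na(m[, 1])))
  tp0 <- lapply(tp, function(m) {m[is.na(m)] <- 0; m})
  denom <- Reduce(`+`, lapply(tp, function(m) (!is.na(m[, 1])) * 1))
  tpm <- Reduce(`+`, tp0) / pmax(denom, 1)
  tpm[!any_val, ] <- NA_real_
  out$transition_proportions <- tpm
  # union of indel events, absent -> 0
  allev <- unique(do.call(rbind, lapply(kept, function(s)
    s$indel_by_position_length[, c("position", "length")])))
  if (nrow(allev) > 0) {
    freq <- vapply(seq_len(nrow(allev)), function(i) {
      mean(vapply(kept, function(s) {
        ev <- s$indel_by_position_length
        hit <- ev$position == allev$position[i] & ev$length == allev$length[i]
        if (any(hit)) ev$frequency[hit][1] else 0
      }, numeric(1)))
    }, numeric(1))
    allev$frequency <- freq
    allev <- allev[order(allev$position, allev$length), , drop = FALSE]
    rownames(allev) <- NULL
  } else {
    allev <- data.frame(position = integer(0), length = integer(0),
                        frequency = numeric(0))
  }
  out$indel_by_position_length <- allev
  out$total_reads <- mean(vapply(kept, `[[`, numeric(1), "total_reads"))
  out$n_replicates <- n
  out
}

#' Cross-site positional profile of indel frequencies
#'
#' For each signed indel length, sites are ranked by their total frequency of
#' that length and only sites inside the 25th-75th percentile band (linear
#' interpolation quantiles, boundary-inclusive) are retained; frequencies are
#' optionally normalized by absolute indel length, then averaged per position
#' over retained sites.
#'
#' @param summaries List of `be_site_summary` (>= 4 sites).
#' @param cfg A [be_config()]; `indel_length_normalize` controls the length
#'   normalization.
#' @return data.frame with columns `length`, `position`, `mean_frequency`,
#'   `n_sites` (retained sites for that length).
#' @export
indel_position_profile <- function(summaries, cfg = be_config()) {
  if (length(summaries) < 4) stop("insufficient sites for percentile filter")
  lens <- sort(unique(unlist(lapply(summaries, function(s)
    s$indel_by_position_length$length))))
  out <- list()
  for (L in lens) {
    site_freq <- vapply(summaries, function(s) {
      ev <- s$indel_by_position_length
      sum(ev$frequency[ev$length == L])
    }, numeric(1))
    qs <- stats::quantile(site_freq, c(0.25, 0.75), type = 7, names = FALSE)
    retained <- which(site_freq >= qs[1] & site_freq <= qs[2])
    norm <- if (cfg$indel_length_normalize) abs(L) else 1
    pos_seen <- sort(unique(unlist(lapply(summaries[retained], function(s) {
      ev <- s$indel_by_position_length
      ev$position[ev$length == L]
    }))))
    for (p in pos_seen) {
      mf <- mean(vapply(summaries[retained], function(s) {
        ev <- s$indel_by_position_length
        hit <- ev$length == L & ev$position == p
        if (any(hit)) ev$frequency[hit][1] / norm else 0
      }, numeric(1)))
      out[[length(out) + 1L]] <- data.frame(length = L, position = p,
                                            mean_frequency = mf,
                                            n_sites = length(retained))
    }
  }
  if (length(out) == 0) {
    return(data.frame(length = integer(0), position = integer(0),
                      mean_frequency = numeric(0), n_sites = integer(0)))
  }
  do.call(rbind, out)
}

#' Ratio of base-editing efficiency to indel frequency
#'
#' Per-site ratio of overall editing efficiency to region-attributed indel
#' frequency (deaminase region: protospacer 1-11; nCas9 region: 14-20),
#' summarized across sites by the geometric mean. Sites with zero indel reads
#' in the region are excluded before taking logs.
#'
#' @param summaries List of `be_site_summary`.
#' @param region `"deaminase"` or `"ncas9"`.
#' @return List with `geometric_mean`, `ratios` (named per-site vector) and
#'   `n_excluded` (zero-indel sites).
#' @export
be_indel_ratio <- function(summaries, region = c("deaminase", "ncas9")) {
  region <- match.arg(region)
  field <- if (region == "deaminase") "deaminase_indel_freq" else "ncas9_indel_freq"
  freq <- vapply(summaries, `[[`, numeric(1), field)
  eff <- vapply(summaries, `[[`, numeric(1), "overall_efficiency")
  ids <- vapply(summaries, `[[`, character(1), "site_id")
  keep <- freq > 0
  if (!any(keep)) stop("no site with nonzero ", region, " indel reads")
  ratios <- stats::setNames(eff[keep] / freq[keep], ids[keep])
  list(geometric_mean = exp(mean(log(ratios))),
       ratios = ratios,
       n_excluded = sum(!keep))
}

#' Write site summaries to TSV
#'
#' Flattens a list of `be_site_summary` objects into one row per site with a
#' deterministic column order; [read_summary()] restores the objects
#' bit-exactly for string/integer fields.
#'
#' @param summaries List of `be_site_summary` (possibly empty).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  cols <- summary_columns()
  rows <- lapply(summaries, function(s) {
    row <- data.frame(site_id = s$site_id, editor = s$editor,
                      window_start = s$window[1], window_end = s$window[2],
                      total_reads = s$total_reads, n_replicates = s$n_replicates,
                      overall_efficiency = s$overall_efficiency,
                      modified_efficiency = s$modified_efficiency,
                      deaminase_indel_freq = s$deaminase_indel_freq,
                      ncas9_indel_freq = s$ncas9_indel_freq,
                      stringsAsFactors = FALSE)
    for (i in 1:20) row[[paste0("eff_p", i)]] <- s$per_position_efficiency[i]
    for (sc in PURITY_SCOPES) for (tr in BE_TRANSITIONS) {
      row[[paste0("purity_", sc, "_", sub(">", "to", tr))]] <-
        s$transition_proportions[sc, tr]
    }
    ev <- s$indel_by_position_length
    row$indel_events <- paste(
      sprintf("%d:%d:%.10g", ev$position, ev$length, ev$frequency),
      collapse = ";")
    row
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

summary_columns <- function() {
  c("site_id", "editor", "window_start", "window_end", "total_reads",
    "n_replicates", "overall_efficiency", "modified_efficiency",
    "deaminase_indel_freq", "ncas9_indel_freq",
    paste0("eff_p", 1:20),
    as.vector(t(outer(PURITY_SCOPES, sub(">", "to", BE_TRANSITIONS),
                      function(s, t) paste0("purity_", s, "_", t)))),
    "indel_events")
}

#' Read site summaries written by [write_summary()]
#'
#' @param path TSV path.
#' @return List of `be_site_summary` objects.
#' @export
read_summary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    tp <- matrix(NA_real_, nrow = 3, ncol = length(BE_TRANSITIONS),
                 dimnames = list(PURITY_SCOPES, BE_TRANSITIONS))
    for (sc in PURITY_SCOPES) for (tr in BE_TRANSITIONS) {
      tp[sc, tr] <- r[[paste0("purity_", sc, "_", sub(">", "to", tr))]]
    }
    ev <- if (is.na(r$indel_events) || r$indel_events == "") {
      data.frame(position = integer(0), length = integer(0), frequency = numeric(0))
    } else {
      parts <- do.call(rbind, strsplit(strsplit(r$indel_events, ";")[[1]], ":"))
      data.frame(position = as.integer(parts[, 1]),
                 length = as.integer(parts[, 2]),
                 frequency = as.numeric(parts[, 3]))
    }
    structure(list(
      site_id = as.character(r$site_id), editor = r$editor,
      window = c(r$window_start, r$window_end),
      total_reads = r$total_reads, n_replicates = as.integer(r$n_replicates),
      overall_efficiency = r$overall_efficiency,
      per_position_efficiency = unlist(r[paste0("eff_p", 1:20)], use.names = FALSE),
      modified_efficiency = r$modified_efficiency,
      transition_proportions = tp,
      indel_by_position_length = ev,
      deaminase_indel_freq = r$deaminase_indel_freq,
      ncas9_indel_freq = r$ncas9_indel_freq
    ), class = "be_site_summary")
  })
}
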