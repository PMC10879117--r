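# Convenience drivers chaining the per-site operations over whole datasets;
# these are what the command-line subcommands call.

#' Quantify a dataset of replicate allele tables
#'
#' Summarizes every replicate of every site and averages replicates after the
#' coverage filter.
#'
#' @param tables Named list (per site) of lists of `be_allele_table`
#'   replicates.
#' @param sites A `be_sites` table.
#' @param cfg A [be_config()].
#' @return List: `summaries` (replicate-averaged `be_site_summary`, dropped
#'   sites omitted), `dropped` (site ids).
#' @export
quantify_dataset <- function(tables, sites, cfg) {
  summaries <- list()
  dropped <- character(0)
  for (sid in names(tables)) {
    site <- sites[sites$site_id == sid, ]
    if (nrow(site) != 1) stop("site ", sid, " not found in sites table")
    reps <- lapply(tables[[sid]], summarize_site, site = site, cfg = cfg)
    avg <- average_replicates(reps, cfg)
    if (is.null(avg)) dropped <- c(dropped, sid) else {
      summaries[[sid]] <- avg
    }
  }
  list(summaries = unname(summaries), dropped = dropped)
}

#' Observed outcome distributions for a dataset
#'
#' Applies the replicate concordance filters then collapses replicates into
#' per-site outcome distributions.
#'
#' @inheritParams quantify_dataset
#' @param keep_wildtype Passed to [collapse_outcomes()].
#' @return Named list of `be_outcomes` (sites whose replicates were all
#'   filtered out are omitted).
#' @export
outcome_dataset <- function(tables, sites, cfg, keep_wildtype = FALSE) {
  out <- list()
  for (sid in names(tables)) {
    site <- sites[sites$site_id == sid, ]
    flt <- filter_outcome_replicates(tables[[sid]], site, cfg)
    if (length(flt$retained) == 0) next
    oc <- collapse_outcomes(flt$retained, site, cfg,
                            keep_wildtype = keep_wildtype)
    if (nrow(oc) > 0) out[[sid]] <- oc
  }
  out
}

#' Write outcome distributions to TSV
#'
#' @param outcome_list Named list of `be_outcomes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcome_list, path) {
  rows <- lapply(names(outcome_list), function(sid) {
    oc <- outcome_list[[sid]]
    if (nrow(oc) == 0) return(NULL)
    data.frame(site_id = sid, allele = oc$allele,
               edit_pattern = oc$edit_pattern, other_edits = oc$other_edits,
               proportion = oc$proportion,
               provenance = attr(oc, "provenance") %||% NA_character_,
               total_reads = attr(oc, "total_reads") %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(site_id = character(0), allele = character(0),
                     edit_pattern = character(0), other_edits = character(0),
                     proportion = numeric(0), provenance = character(0),
                     total_reads = numeric(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read outcome distributions written by [write_outcomes()]
#'
#' @param path TSV path.
#' @return Named list of `be_outcomes`.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(site_id = "character",
                                         allele = "character",
                                         edit_pattern = "character",
                                         other_edits = "character"))
  df$other_edits[is.na(df$other_edits)] <- ""
  out <- list()
  for (sid in unique(df$site_id)) {
    sub <- df[df$site_id == sid, , drop = FALSE]
    out[[sid]] <- be_outcomes(
      sub[, c("allele", "edit_pattern", "other_edits", "proportion")],
      site_id = sid, provenance = sub$provenance[1],
      total_reads = sub$total_reads[1])
  }
  out
}
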