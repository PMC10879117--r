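# Allele-frequency tables (CRISPResso2-compatible dialect).
#
# On disk: tab-separated with columns Aligned_Sequence, Reference_Sequence,
# n_deleted, n_inserted, n_mutated, #Reads (extra columns tolerated).
# Insertions appear as '-' columns in Reference_Sequence; in memory they are
# re-expressed as (position, sequence) annotations so that aligned_allele
# always has the length of the ungapped reference and position numbering
# stays stable for per-position statistics.

#' Construct an allele table
#'
#' @param site_id,replicate_id Identifiers.
#' @param reference Ungapped reference sequence (40-nt context or a longer
#'   amplicon containing the protospacer).
#' @param aligned_allele Character vector, one aligned read sequence per
#'   allele, same length as `reference`, `-` marking deleted bases.
#' @param n_reads Non-negative read counts (rows with 0 reads are dropped;
#'   at least one read must remain).
#' @param insertions Optional list (one element per allele) of data.frames
#'   with columns `position` (1-based reference position before which the
#'   bases are inserted) and `seq`.
#' @return A list of class `be_allele_table` with elements `site_id`,
#'   `replicate_id`, `reference`, `rows` (data.frame with `aligned_allele`,
#'   `n_reads`, `n_inserted`, `n_deleted`, list-column `insertions`) and
#'   `total_reads`.
#' @export
be_allele_table <- function(site_id, replicate_id, reference, aligned_allele,
                            n_reads, insertions = NULL) {
  n_reads <- as.numeric(n_reads)
  if (length(aligned_allele) != length(n_reads)) {
    stop("aligned_allele and n_reads lengths differ")
  }
  if (any(is.na(n_reads)) || any(n_reads < 0)) stop("negative or missing read count")
  if (is.null(insertions)) insertions <- rep(list(empty_insertions()), length(n_reads))
  bad <- nchar(aligned_allele) != nchar(reference)
  if (any(bad)) {
    stop("aligned allele length differs from reference for row(s) ",
         paste(which(bad), collapse = ", "))
  }
  keep <- n_reads > 0
  aligned_allele <- aligned_allele[keep]
  insertions <- insertions[keep]
  n_reads <- n_reads[keep]
  if (sum(n_reads) <= 0) stop("no reads in allele table for site ", site_id)
  rows <- data.frame(aligned_allele = aligned_allele, n_reads = n_reads,
                     stringsAsFactors = FALSE)
  rows$n_inserted <- vapply(insertions, function(i) sum(nchar(i$seq)), numeric(1))
  rows$n_deleted <- vapply(gregexpr("-", aligned_allele, fixed = TRUE),
                           function(m) sum(m > 0), numeric(1))
  rows$insertions <- insertions
  structure(list(site_id = as.character(site_id),
                 replicate_id = as.character(replicate_id),
                 reference = toupper(reference),
                 rows = rows,
                 total_reads = sum(n_reads)),
            class = "be_allele_table")
}

empty_insertions <- function() {
  data.frame(position = integer(0), seq = character(0), stringsAsFactors = FALSE)
}

#' Read a CRISPResso2-style allele-frequency table
#'
#' Required columns: `Aligned_Sequence`, `Reference_Sequence`, `#Reads`
#' (read.delim mangles `#Reads` to `X.Reads`; both are accepted). Gap columns
#' in the reference (insertions) are collapsed into per-row insertion
#' annotations.
#'
#' @param path TSV path.
#' @param site_id,replicate_id Identifiers recorded on the table; default to
#'   the file name.
#' @return A `be_allele_table`.
#' @export
read_allele_table <- function(path, site_id = NULL, replicate_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  names(df)[names(df) == "X.Reads"] <- "#Reads"
  required <- c("Aligned_Sequence", "Reference_Sequence", "#Reads")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("allele table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop("no reads: allele table ", path, " is empty")
  if (any(df[["#Reads"]] < 0)) stop("negative read count in ", path)
  base <- sub("\\.[^.]*$", "", basename(path))
  parsed <- lapply(seq_len(nrow(df)), function(i) {
    degap_alignment(df$Aligned_Sequence[i], df$Reference_Sequence[i])
  })
  refs <- vapply(parsed, `[[`, character(1), "reference")
  if (length(unique(refs)) != 1L) {
    stop("rows of ", path, " disagree on the ungapped reference sequence")
  }
  be_allele_table(
    site_id = site_id %||% base,
    replicate_id = replicate_id %||% base,
    reference = refs[1],
    aligned_allele = vapply(parsed, `[[`, character(1), "allele"),
    n_reads = df[["#Reads"]],
    insertions = lapply(parsed, `[[`, "insertions")
  )
}

# Collapse reference gap columns (insertions) out of one aligned pair.
degap_alignment <- function(aligned, reference) {
  a <- strsplit(toupper(aligned), "")[[1]]
  r <- strsplit(toupper(reference), "")[[1]]
  if (length(a) != length(r)) stop("aligned/reference length mismatch")
  gap <- r == "-"
  ins <- empty_insertions()
  if (any(gap)) {
    runs <- rle(gap)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    refpos_before <- cumsum(!gap) # ref chars seen up to each column
    ins <- do.call(rbind, lapply(which(runs$values), function(k) {
      cols <- seq(starts[k], stops[k])
      data.frame(
        # inserted before this 1-based reference position
        position = refpos_before[starts[k]] + 1L,
        seq = paste(a[cols], collapse = ""),
        stringsAsFactors = FALSE
      )
    }))
  }
  list(allele = paste(a[!gap], collapse = ""),
       reference = paste(r[!gap], collapse = ""),
       insertions = ins)
}

#' Write an allele table in the CRISPResso2 dialect
#'
#' Inverse of [read_allele_table()]: insertion annotations are re-expanded
#' into reference gap columns.
#'
#' @param table A `be_allele_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(table, path) {
  rows <- table$rows
  out <- lapply(seq_len(nrow(rows)), function(i) {
    regap_alignment(rows$aligned_allele[i], table$reference, rows$insertions[[i]])
  })
  df <- data.frame(
    Aligned_Sequence = vapply(out, `[[`, character(1), "aligned"),
    Reference_Sequence = vapply(out, `[[`, character(1), "reference"),
    n_deleted = rows$n_deleted,
    n_inserted = rows$n_inserted,
    n_mutated = vapply(seq_len(nrow(rows)), function(i) {
      sum_mismatches(rows$aligned_allele[i], table$reference)
    }, numeric(1)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  df[["#Reads"]] <- rows$n_reads
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

regap_alignment <- function(allele, reference, insertions) {
  if (nrow(insertions) == 0) {
    return(list(aligned = allele, reference = reference))
  }
  a <- strsplit(allele, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  # apply right-to-left so earlier positions stay valid
  ord <- order(insertions$position, decreasing = TRUE)
  for (k in ord) {
    p <- insertions$position[k]
    s <- strsplit(insertions$seq[k], "")[[1]]
    a <- append(a, s, after = p - 1L)
    r <- append(r, rep("-", length(s)), after = p - 1L)
  }
  list(aligned = paste(a, collapse = ""), reference = paste(r, collapse = ""))
}

sum_mismatches <- function(allele, reference) {
  a <- strsplit(allele, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  sum(a != r & a != "-")
}

#' Locate the protospacer inside an allele-table reference
#'
#' The reference may be the 40-nt context or a longer amplicon; positions are
#' always reported relative to the protospacer (1-20).
#'
#' @param table A `be_allele_table`.
#' @param site The matching `be_sites` row.
#' @return 0-based offset such that reference positions `offset + 1 ..
#'   offset + 20` are protospacer positions 1..20.
#' @export
protospacer_offset <- function(table, site) {
  hits <- gregexpr(site$protospacer, table$reference, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    stop("reference/site mismatch: protospacer of ", site$site_id,
         " not found in reference of ", table$site_id)
  }
  if (length(hits) > 1) {
    stop("protospacer of ", site$site_id, " matches the reference more than once")
  }
  as.integer(hits[1]) - 1L
}
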