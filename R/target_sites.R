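#' @keywords internal
"_PACKAGE"

# Coordinate convention (single source of truth):
#   protospacer positions are 1-20 (5'->3'), PAM is 21-23.
#   context40 = 10 bp upstream + 20 bp protospacer + 3 bp PAM + 7 bp downstream.
#   Internal string slices are 1-based inclusive (R substr semantics).
CONTEXT_LEN <- 40L
PROTO_OFFSET <- 10L # context40 positions 11..30 are protospacer 1..20
PAM_OFFSET <- 30L # context40 positions 31..33 are PAM 1..3

#' Map protospacer positions to context40 positions
#'
#' Protospacer positions are 1-based (1-20, PAM at 21-23); the returned indices
#' are 1-based positions into the 40-nt context.
#'
#' @param pos Integer vector of protospacer positions.
#' @return Integer vector of context40 positions.
#' @export
proto_to_context <- function(pos) as.integer(pos) + PROTO_OFFSET

#' Target base of an editor
#'
#' @param editor `"ABE"` or `"CBE"`.
#' @return `"A"` for ABE (A-to-G edits) or `"C"` for CBE (C-to-T edits).
#' @export
editor_target_base <- function(editor) {
  switch(match.arg(editor, c("ABE", "CBE")), ABE = "A", CBE = "C")
}

#' Intended product base of an editor
#' @inheritParams editor_target_base
#' @return `"G"` for ABE, `"T"` for CBE.
#' @export
editor_product_base <- function(editor) {
  switch(match.arg(editor, c("ABE", "CBE")), ABE = "G", CBE = "T")
}

#' Construct a table of target sites
#'
#' A target site is a 20-nt protospacer with an NGG PAM embedded in a 40-nt
#' context (10 bp upstream + protospacer + PAM + 7 bp downstream). Genomic
#' anchors are optional and use 0-based half-open coordinates on the
#' protospacer strand.
#'
#' @param site_id Character vector of unique site identifiers.
#' @param editor `"ABE"` or `"CBE"` (recycled).
#' @param context40 40-nt uppercase DNA strings.
#' @param chrom,start,strand Optional genomic anchor of the protospacer
#'   (0-based half-open start; strand of the original genomic locus).
#' @param dataset `"endogenous"`, `"integrated"` or `"synthetic"` (recycled).
#' @return A `data.frame` of class `be_sites` with columns `site_id`, `editor`,
#'   `protospacer`, `pam`, `context40`, `chrom`, `start`, `strand`, `dataset`.
#' @export
be_sites <- function(site_id, editor, context40,
                     chrom = NA_character_, start = NA_integer_,
                     strand = NA_character_, dataset = "synthetic") {
  n <- length(site_id)
  sites <- data.frame(
    site_id = as.character(site_id),
    editor = rep_len(as.character(editor), n),
    protospacer = substr(context40, PROTO_OFFSET + 1L, PROTO_OFFSET + 20L),
    pam = substr(context40, PAM_OFFSET + 1L, PAM_OFFSET + 3L),
    context40 = as.character(context40),
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    strand = rep_len(as.character(strand), n),
    dataset = rep_len(as.character(dataset), n),
    stringsAsFactors = FALSE
  )
  validate_sites(sites)
}

#' Validate a target-site table
#'
#' Checks sequence lengths, alphabet, editor labels and the consistency of the
#' protospacer/PAM fields with their slices of the 40-nt context. Errors name
#' the offending `site_id`.
#'
#' @param sites A data.frame with at least `site_id`, `editor`, `context40`;
#'   `protospacer`/`pam` are filled in from the context when absent.
#' @return The validated table, classed `be_sites`.
#' @export
validate_sites <- function(sites) {
  required <- c("site_id", "editor", "context40")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    stop("sites table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  }
  bad_len <- nchar(sites$context40) != CONTEXT_LEN
  if (any(bad_len)) {
    stop("context length must be 40 nt; offending site_id: ",
         paste(sites$site_id[bad_len], collapse = ", "))
  }
  bad_alpha <- grepl("[^ACGT]", sites$context40)
  if (any(bad_alpha)) {
    stop("context alphabet must be A/C/G/T; offending site_id: ",
         paste(sites$site_id[bad_alpha], collapse = ", "))
  }
  bad_editor <- !sites$editor %in% c("ABE", "CBE")
  if (any(bad_editor)) {
    stop("editor must be ABE or CBE; offending site_id: ",
         paste(sites$site_id[bad_editor], collapse = ", "))
  }
  ctx_proto <- substr(sites$context40, PROTO_OFFSET + 1L, PROTO_OFFSET + 20L)
  if (!"protospacer" %in% names(sites) || all(is.na(sites$protospacer))) {
    sites$protospacer <- ctx_proto
  } else {
    bad <- !is.na(sites$protospacer) & sites$protospacer != ctx_proto
    if (any(bad)) {
      stop("protospacer/context mismatch for site_id: ",
           paste(sites$site_id[bad], collapse = ", "))
    }
    sites$protospacer <- ctx_proto
  }
  ctx_pam <- substr(sites$context40, PAM_OFFSET + 1L, PAM_OFFSET + 3L)
  if (!"pam" %in% names(sites) || all(is.na(sites$pam))) {
    sites$pam <- ctx_pam
  } else {
    bad <- !is.na(sites$pam) & sites$pam != ctx_pam
    if (any(bad)) {
      stop("pam/context mismatch for site_id: ",
           paste(sites$site_id[bad], collapse = ", "))
    }
    sites$pam <- ctx_pam
  }
  for (col in c("chrom", "start", "strand", "dataset")) {
    if (!col %in% names(sites)) {
      sites[[col]] <- if (col == "start") NA_integer_ else NA_character_
    }
  }
  if (all(is.na(sites$dataset))) sites$dataset <- "synthetic"
  rownames(sites) <- NULL
  class(sites) <- unique(c("be_sites", class(sites)))
  sites
}

#' Read target sites from TSV or FASTA
#'
#' TSV input needs columns `site_id`, `editor`, `context40` (extra columns such
#' as genomic anchors are kept). FASTA headers must be structured as
#' `>site_id editor=ABE [dataset=endogenous]` with the 40-nt context as the
#' sequence.
#'
#' @param path File path.
#' @param format `"auto"` (by extension / leading `>`), `"tsv"` or `"fasta"`.
#' @return A validated `be_sites` table, input order preserved.
#' @export
read_sites <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "tsv"
  }
  if (format == "tsv") {
    sites <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character")
    if ("start" %in% names(sites)) sites$start <- as.integer(sites$start)
  } else {
    lines <- readLines(path)
    hdr_idx <- grep("^>", lines)
    if (length(hdr_idx) == 0) stop("no FASTA records in ", path)
    ends <- c(hdr_idx[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr_idx), function(i) {
      paste(lines[seq(hdr_idx[i] + 1L, ends[i])], collapse = "")
    }, character(1))
    hdr <- sub("^>", "", lines[hdr_idx])
    site_id <- sub("\\s.*$", "", hdr)
    get_tag <- function(tag, default) {
      m <- regmatches(hdr, regexpr(paste0(tag, "=\\S+"), hdr))
      out <- rep(default, length(hdr))
      hit <- grepl(paste0(tag, "="), hdr)
      out[hit] <- sub(paste0(tag, "="), "", m)
      out
    }
    sites <- data.frame(
      site_id = site_id,
      editor = get_tag("editor", NA_character_),
      context40 = toupper(seqs),
      dataset = get_tag("dataset", "synthetic"),
      stringsAsFactors = FALSE
    )
  }
  validate_sites(sites)
}

#' Write target sites to TSV
#'
#' @param sites A `be_sites` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
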