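# Endogenous-factor annotation of target sites: peak overlap, expression,
# DNA methylation, normalization, and factor-vs-efficiency statistics.

# Genomic interval of the protospacer (0-based half-open), widened by `flank`
# bp on each side, as a GRanges. Sites without an anchor yield NA rows.
site_ranges <- function(sites, flank = 0L) {
  ok <- !is.na(sites$chrom) & !is.na(sites$start)
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom[ok],
    ranges = IRanges::IRanges(start = sites$start[ok] + 1L - flank,
                              end = sites$start[ok] + 20L + flank)
  )
  names(gr) <- sites$site_id[ok]
  list(gr = gr, anchored = ok)
}

#' Read a BED file of peak intervals
#'
#' Only the first three columns (chrom, 0-based half-open start/end) are used;
#' extra columns are ignored.
#'
#' @param path BED path.
#' @return A `GRanges` (1-based closed, as is the Bioconductor convention).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  GenomicRanges::GRanges(seqnames = df[[1]],
                         ranges = IRanges::IRanges(start = df[[2]] + 1L,
                                                   end = df[[3]]))
}

#' Read a bedGraph-like per-base methylation file
#'
#' Tab-separated chrom, 0-based start, end, beta; one row per covered base
#' (or short run).
#'
#' @param path File path.
#' @return data.frame with columns `chrom`, `start`, `end`, `beta`.
#' @export
read_methylation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "beta")
  if (any(df$beta < 0 | df$beta > 1)) stop("beta values must lie in [0,1]")
  df
}

#' Read a two-column gene-expression table
#'
#' @param path TSV with header columns `gene` and an expression column (TPM).
#' @return data.frame with columns `gene`, `tpm`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "tpm")
  df
}

#' Flag target sites overlapping factor peaks
#'
#' A site is flagged for a factor when its protospacer interval overlaps at
#' least one peak by >= 1 bp (half-open BED semantics: an abutting peak does
#' not overlap). For H3K27ac the queried interval is widened by
#' `cfg$h3k27ac_flank` bp (65 or 500) on each side of the protospacer to
#' capture longer-range chromatin context.
#'
#' @param sites A `be_sites` table with genomic anchors.
#' @param peaks Named list of `GRanges` (or data.frames with chrom/start/end in
#'   BED coordinates), one per factor.
#' @param cfg A [be_config()].
#' @return data.frame: `site_id` plus one integer 0/1 column per factor
#'   (named `<factor>_flag`); NA where the site lacks a genomic anchor.
#' @export
annotate_peaks <- function(sites, peaks, cfg = be_config()) {
  out <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
  for (factor in names(peaks)) {
    pk <- peaks[[factor]]
    if (is.data.frame(pk)) {
      pk <- GenomicRanges::GRanges(
        seqnames = pk[[1]],
        ranges = IRanges::IRanges(start = pk[[2]] + 1L, end = pk[[3]]))
    }
    flank <- if (factor == "H3K27ac") cfg$h3k27ac_flank else 0L
    sr <- site_ranges(sites, flank = flank)
    flag <- rep(NA_integer_, nrow(sites))
    if (length(sr$gr) > 0) {
      hits <- GenomicRanges::countOverlaps(sr$gr, pk, minoverlap = 1L) > 0
      flag[sr$anchored] <- as.integer(hits)
    }
    if (any(!sr$anchored)) {
      message(sum(!sr$anchored), " site(s) lack a genomic anchor; ", factor,
              " flag undefined")
    }
    out[[paste0(factor, "_flag")]] <- flag
  }
  out
}

#' Annotate sites with gene expression
#'
#' Expression is taken per site from the gene it lies in, on the log2(TPM+1)
#' scale; the binary high/low call uses a strict threshold on that scale
#' (default 1.5), and the continuous value is its min-max normalization across
#' sites. Sites mapping to no gene, or to a gene absent from the expression
#' table, are low with TPM 0.
#'
#' @param sites A `be_sites` table.
#' @param expression data.frame with columns `gene`, `tpm`.
#' @param site_gene Named character vector mapping `site_id` to gene (NA or
#'   missing entries mean intergenic).
#' @param cfg A [be_config()].
#' @return data.frame: `site_id`, `expression` (min-max normalized log2),
#'   `expression_log2` (pre-scaling), `expression_flag` (0/1).
#' @export
annotate_expression <- function(sites, expression, site_gene, cfg = be_config()) {
  tpm <- stats::setNames(expression$tpm, expression$gene)
  gene <- site_gene[sites$site_id]
  val <- rep(0, nrow(sites))
  mapped <- !is.na(gene) & gene %in% names(tpm)
  val[mapped] <- tpm[gene[mapped]]
  l2 <- log2(val + 1)
  cont <- if (length(unique(l2)) > 1) {
    (l2 - min(l2)) / (max(l2) - min(l2))
  } else {
    rep(0, length(l2))
  }
  data.frame(site_id = sites$site_id,
             expression = cont,
             expression_log2 = l2,
             expression_flag = as.integer(l2 > cfg$expression_high_cutoff),
             stringsAsFactors = FALSE)
}

#' Annotate sites with DNA methylation
#'
#' Site-level methylation is the mean beta over covered bases intersecting the
#' protospacer; the methylated flag requires mean beta strictly above
#' `cfg$methylation_high_cutoff` (default 0.75). Per-base calls cover, within
#' the editing window, targeted Cs (CBE) and As inside ACG/CGA motifs (ABE)
#' that intersect a covered record; uncovered bases are unmethylated.
#'
#' @param sites A `be_sites` table with genomic anchors.
#' @param methylation data.frame from [read_methylation()].
#' @param cfg A [be_config()].
#' @return List: `site` data.frame (`site_id`, `methylation` mean beta with 0
#'   for uncovered sites, `methylation_flag`), and `per_base`, a data.frame
#'   with one row per considered base (`site_id`, `position`, `beta`,
#'   `methylated`).
#' @export
annotate_methylation <- function(sites, methylation, cfg = be_config()) {
  site_df <- data.frame(site_id = sites$site_id, methylation = 0,
                        methylation_flag = 0L, stringsAsFactors = FALSE)
  per_base <- list()
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    if (is.na(site$chrom) || is.na(site$start)) {
      site_df$methylation[i] <- NA_real_
      site_df$methylation_flag[i] <- NA_integer_
      next
    }
    # genomic 0-based positions of protospacer bases 1..20 on the stored
    # (protospacer-oriented) anchor; '-' anchors run right-to-left
    gpos <- if (!is.na(site$strand) && site$strand == "-") {
      site$start + (20L - seq_len(20L))
    } else {
      site$start + seq_len(20L) - 1L
    }
    rec <- methylation[methylation$chrom == site$chrom, , drop = FALSE]
    beta_at <- function(g) {
      hit <- rec$start <= g & rec$end > g
      if (any(hit)) mean(rec$beta[hit]) else NA_real_
    }
    betas <- vapply(gpos, beta_at, numeric(1))
    covered <- !is.na(betas)
    if (any(covered)) {
      mb <- mean(betas[covered])
      site_df$methylation[i] <- mb
      site_df$methylation_flag[i] <-
        as.integer(mb > cfg$methylation_high_cutoff)
    }
    w <- cfg$window
    cand <- considered_positions(site, w)
    for (p in cand) {
      per_base[[length(per_base) + 1L]] <- data.frame(
        site_id = site$site_id, position = p,
        beta = if (covered[p]) betas[p] else NA_real_,
        methylated = as.integer(covered[p]),
        stringsAsFactors = FALSE)
    }
  }
  per_base <- if (length(per_base) > 0) do.call(rbind, per_base) else
    data.frame(site_id = character(0), position = integer(0),
               beta = numeric(0), methylated = integer(0))
  list(site = site_df, per_base = per_base)
}

# Window positions whose methylation is interpretable: targeted Cs for CBE;
# for ABE, As inside ACG or CGA trinucleotides (A adjacent to a CpG).
considered_positions <- function(site, window) {
  ctx <- strsplit(site$context40, "")[[1]]
  pos <- window[1]:window[2]
  ctx_i <- proto_to_context(pos)
  if (site$editor == "CBE") {
    pos[ctx[ctx_i] == "C"]
  } else {
    keep <- vapply(seq_along(pos), function(k) {
      i <- ctx_i[k]
      if (ctx[i] != "A") return(FALSE)
      fwd <- i + 2 <= length(ctx) && paste(ctx[i:(i + 2)], collapse = "") == "ACG"
      rev <- i - 2 >= 1 && paste(ctx[(i - 2):i], collapse = "") == "CGA"
      fwd || rev
    }, logical(1))
    pos[keep]
  }
}

#' Min-max normalize a factor
#'
#' Signal-like factors (expression TPM, DNase RPF, histone/CTCF/Pol II fold
#' changes) are log2(x+1)-transformed before min-max scaling to \\[0,1\\];
#' methylation beta values are min-max scaled without the log.
#'
#' @param x Numeric vector with at least two distinct values.
#' @param kind `"signal"` (log2 then min-max) or `"beta"` (min-max only).
#' @return Numeric vector in \\[0,1\\].
#' @export
normalize_factor <- function(x, kind = c("signal", "beta")) {
  kind <- match.arg(kind)
  y <- if (kind == "signal") log2(x + 1) else x
  rng <- range(y)
  if (rng[1] == rng[2]) stop("degenerate min-max: constant input")
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Regression of editing efficiency on an endogenous factor
#'
#' Linear model of per-site efficiency on the factor's continuous value,
#' adjusting for the number of target bases (As or Cs) inside the editing
#' window as a confounder.
#'
#' @param efficiency Numeric per-site efficiencies (n >= 10).
#' @param factor_values Continuous factor values, same length.
#' @param confounder Count of window target bases per site.
#' @param factor_name Label for the output.
#' @return List of class `be_factor_effect`: `factor`, `coefficient`,
#'   `p_value`, `confounder_coefficient`, `n`, `fit`.
#' @export
factor_regression <- function(efficiency, factor_values, confounder,
                              factor_name = "factor") {
  if (length(efficiency) < 10) stop("need at least 10 sites")
  X <- cbind(1, factor_values, confounder)
  if (qr(X)$rank < ncol(X)) stop("collinear inputs in factor regression")
  fit <- stats::lm(efficiency ~ factor_values + confounder)
  sm <- summary(fit)$coefficients
  structure(list(factor = factor_name,
                 coefficient = sm["factor_values", "Estimate"],
                 p_value = sm["factor_values", "Pr(>|t|)"],
                 confounder_coefficient = sm["confounder", "Estimate"],
                 n = length(efficiency), fit = fit),
            class = "be_factor_effect")
}

#' Promoted-motif lists
#'
#' Trinucleotide contexts (1 bp up, target base, 1 bp down) empirically
#' associated with promoted vs inhibited editing.
#' @export
PROMOTED_MOTIFS <- c("TAT", "TAC", "CAT", "GAC", "GAT")

#' @rdname PROMOTED_MOTIFS
#' @export
INHIBITED_MOTIFS <- c("CAG", "AAG", "CAA", "AAA")

#' Promoted-motif ratio per group with a chi-squared test
#'
#' For each group of target-base trinucleotide contexts (e.g. methylated vs
#' unmethylated bases), computes promoted / (promoted + inhibited) counts and
#' tests the 2x2 promoted-by-group table with a chi-squared test without
#' continuity correction. Motifs outside both lists are ignored.
#'
#' @param motifs_by_group Named list of two character vectors of 3-mers.
#' @return List: `ratio` (named per group), `counts` (2x2 matrix), `chisq`
#'   statistic, `p_value`.
#' @export
promoted_motif_ratio <- function(motifs_by_group) {
  stopifnot(length(motifs_by_group) == 2)
  counts <- t(vapply(motifs_by_group, function(m) {
    c(promoted = sum(m %in% PROMOTED_MOTIFS),
      inhibited = sum(m %in% INHIBITED_MOTIFS))
  }, numeric(2)))
  if (any(rowSums(counts) == 0)) {
    stop("zero promoted+inhibited motifs in a group")
  }
  ratio <- counts[, "promoted"] / rowSums(counts)
  test <- stats::chisq.test(counts, correct = FALSE)
  list(ratio = ratio, counts = counts,
       chisq = unname(test$statistic), p_value = test$p.value)
}

#' Assemble the full endogenous annotation of a site set
#'
#' Combines peak flags, expression and methylation into one table and derives
#' the cis-regulatory-element (CRE) flag as the union of the DHS, H3K4me3,
#' H3K27ac and CTCF flags when no explicit CRE track is given (a stand-in
#' categorization, recorded in the `cre_rule` attribute).
#'
#' @param sites A `be_sites` table.
#' @param peaks Named list of peak `GRanges`/data.frames (see
#'   [annotate_peaks()]); may include an explicit `CRE` element.
#' @param expression,site_gene See [annotate_expression()]; optional.
#' @param methylation See [annotate_methylation()]; optional.
#' @param cfg A [be_config()].
#' @return data.frame of class `be_annotation`: `site_id`, continuous columns
#'   (`expression`, `methylation`) and `<factor>_flag` binary columns;
#'   attribute `per_base_methylation` carries the per-base calls.
#' @export
annotate_sites <- function(sites, peaks = list(), expression = NULL,
                           site_gene = NULL, methylation = NULL,
                           cfg = be_config()) {
  ann <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
  cre_rule <- "explicit"
  if (length(peaks) > 0) {
    ann <- merge(ann, annotate_peaks(sites, peaks, cfg), by = "site_id",
                 sort = FALSE)
  }
  if (!is.null(expression)) {
    ann <- merge(ann, annotate_expression(sites, expression, site_gene, cfg),
                 by = "site_id", sort = FALSE)
  }
  per_base <- NULL
  if (!is.null(methylation)) {
    m <- annotate_methylation(sites, methylation, cfg)
    ann <- merge(ann, m$site, by = "site_id", sort = FALSE)
    per_base <- m$per_base
  }
  if (!"CRE_flag" %in% names(ann)) {
    members <- intersect(paste0(c("DHS", "H3K4me3", "H3K27ac", "CTCF"), "_flag"),
                         names(ann))
    if (length(members) > 0) {
      ann$CRE_flag <- as.integer(rowSums(ann[, members, drop = FALSE] == 1, na.rm = TRUE) > 0)
      cre_rule <- paste("union of", paste(members, collapse = ", "))
    }
  }
  ann <- ann[match(sites$site_id, ann$site_id), , drop = FALSE]
  rownames(ann) <- NULL
  structure(ann, class = c("be_annotation", "data.frame"),
            per_base_methylation = per_base, cre_rule = cre_rule)
}
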