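# Ground-truth synthetic data: target sites, endogenous-factor tracks and
# allele-frequency tables drawn from a known chain-Bernoulli editing model
# with superimposed bystander substitutions and 1-bp indels. Every default is
# a fixed study condition of the generator, chosen to emulate endogenous
# editing screens: moderate window efficiencies, sequence-context and
# chromatin effects on the logit scale, positively correlated adjacent
# co-editing, a 1-bp insertion hotspot at protospacer position 18, and
# replicate-level multinomial read noise.

#' Ground-truth parameters for the synthetic generator
#'
#' All effects act on the logit of the per-position intended-edit
#' probability: `intercept + prev_effect[base] + next_effect[base] +
#' position_effect + factor_effects . factors`.
#'
#' @param editor `"ABE"` or `"CBE"`.
#' @param intercept Baseline logit (default -1.2, i.e. ~23% at a neutral
#'   context).
#' @param prev_effect,next_effect Named logit effects of the 5' and 3'
#'   neighbor of the target base; defaults mirror the promoted (T/G up, T/C
#'   down) and inhibited (A up, A/G down) trinucleotide contexts.
#' @param position_amplitude Gaussian position bump (logit) at the window
#'   center.
#' @param factor_effects Named logit coefficients of the continuous factor
#'   annotations (default: H3K27ac 1.0, expression 0.6, methylation -0.8).
#' @param adjacent_or True odds ratio between adjacent editable positions
#'   (default 4).
#' @param bystander_rate Per-read probability of one random unintended
#'   substitution inside the protospacer (default 0.01).
#' @param insertion_rate_p18 Per-read 1-bp insertion probability at position
#'   18 (default 0.01).
#' @param deletion_rate_window Per-read 1-bp deletion probability at each
#'   window position (default 0.002).
#' @param peak_rates Named per-factor probabilities that a site carries a
#'   peak.
#' @param depth Reads per replicate (default 10000).
#' @param replicates Biological replicates per site (default 2).
#' @param overdispersion Dirichlet-style per-replicate jitter of allele
#'   probabilities; 0 (default) is pure multinomial.
#' @return List of class `be_truth`.
#' @export
be_truth <- function(editor = c("ABE", "CBE"),
                     intercept = -1.2,
                     prev_effect = c(A = -0.5, C = 0.1, G = 0.3, T = 0.6),
                     next_effect = c(A = -0.4, C = 0.4, G = -0.5, T = 0.5),
                     position_amplitude = 0.8,
                     factor_effects = c(H3K27ac = 1.0, expression = 0.6,
                                        methylation = -0.8),
                     adjacent_or = 4,
                     bystander_rate = 0.01,
                     insertion_rate_p18 = 0.01,
                     deletion_rate_window = 0.002,
                     peak_rates = c(H3K27ac = 0.4, PolII = 0.3, CTCF = 0.2,
                                    DHS = 0.35, H3K4me1 = 0.3, H3K4me3 = 0.25,
                                    H3K36me3 = 0.2),
                     depth = 10000L,
                     replicates = 2L,
                     overdispersion = 0) {
  structure(list(editor = match.arg(editor), intercept = intercept,
                 prev_effect = prev_effect, next_effect = next_effect,
                 position_amplitude = position_amplitude,
                 factor_effects = factor_effects,
                 adjacent_or = adjacent_or,
                 bystander_rate = bystander_rate,
                 insertion_rate_p18 = insertion_rate_p18,
                 deletion_rate_window = deletion_rate_window,
                 peak_rates = peak_rates,
                 depth = as.integer(depth), replicates = as.integer(replicates),
                 overdispersion = overdispersion),
            class = "be_truth")
}

#' Generate random target sites
#'
#' Random 40-nt contexts with an NGG PAM and at least one target base (A for
#' ABE, C for CBE) inside the editor's window; deterministic per seed.
#'
#' @param n Number of sites.
#' @param editor `"ABE"` or `"CBE"`.
#' @param seed Integer seed.
#' @param cfg A [be_config()] supplying the window.
#' @return A `be_sites` table with synthetic genomic anchors (chromosome
#'   `"chrS"`, sites spaced 1 kb apart).
#' @export
generate_sites <- function(n, editor = c("ABE", "CBE"), seed = 1L,
                           cfg = NULL) {
  editor <- match.arg(editor)
  if (is.null(cfg)) cfg <- be_config(editor)
  stopifnot(n >= 1)
  base <- editor_target_base(editor)
  bases <- c("A", "C", "G", "T")
  w_ctx <- proto_to_context(cfg$window[1]:cfg$window[2])
  with_seed(seed, {
    contexts <- vapply(seq_len(n), function(i) {
      repeat {
        ctx <- sample(bases, CONTEXT_LEN, replace = TRUE)
        ctx[32:33] <- "G" # NGG PAM
        if (any(ctx[w_ctx] == base)) return(paste(ctx, collapse = ""))
      }
    }, character(1))
    be_sites(site_id = sprintf("site_%04d", seq_len(n)),
             editor = editor, context40 = contexts,
             chrom = "chrS", start = 1000L * seq_len(n), strand = "+",
             dataset = "synthetic")
  })
}

#' Generate endogenous-factor annotations and track files
#'
#' Draws per-site factor states from the truth's rates (peak flags,
#' log-normal expression, bimodal methylation), returns the resulting
#' annotation, and optionally writes the corresponding raw BED /
#' expression-TSV / per-base methylation files so the annotation module can
#' be exercised end to end against known flags.
#'
#' @param sites A `be_sites` table (with the synthetic anchors of
#'   [generate_sites()]).
#' @param truth A [be_truth()].
#' @param seed Integer seed.
#' @param dir Optional directory for track files (`<factor>_peaks.bed`,
#'   `expression.tsv`, `methylation.tsv`, `site_gene.tsv`).
#' @param cfg A [be_config()].
#' @return List: `annotation` (data.frame: site_id, `<factor>_flag` columns,
#'   `expression`/`expression_log2`/`expression_flag`, `methylation`/
#'   `methylation_flag`, plus continuous `H3K27ac`), `site_gene`, `tracks`
#'   (paths or NULL), `tpm`, `beta`.
#' @export
generate_annotations <- function(sites, truth, seed = 1L, dir = NULL,
                                 cfg = NULL) {
  if (is.null(cfg)) cfg <- be_config(truth$editor)
  n <- nrow(sites)
  with_seed(seed + 101L, {
    ann <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
    peaks <- list()
    for (factor in names(truth$peak_rates)) {
      flag <- stats::rbinom(n, 1, truth$peak_rates[[factor]])
      ann[[paste0(factor, "_flag")]] <- flag
      hit <- which(flag == 1)
      peaks[[factor]] <- data.frame(chrom = sites$chrom[hit],
                                    start = sites$start[hit] - 10L,
                                    end = sites$start[hit] + 30L)
    }
    # continuous H3K27ac signal consistent with the flag
    if ("H3K27ac_flag" %in% names(ann)) {
      ann$H3K27ac <- ifelse(ann$H3K27ac_flag == 1,
                            stats::runif(n, 0.5, 1), stats::runif(n, 0, 0.25))
    }
    tpm <- stats::rlnorm(n, meanlog = 0.7, sdlog = 1.2)
    genes <- paste0("gene_", sites$site_id)
    l2 <- log2(tpm + 1)
    rng <- range(l2)
    ann$expression <- if (rng[1] < rng[2]) (l2 - rng[1]) / (rng[2] - rng[1]) else 0
    ann$expression_log2 <- l2
    ann$expression_flag <- as.integer(l2 > cfg$expression_high_cutoff)
    beta <- stats::rbeta(n, 0.4, 0.4)
    ann$methylation <- beta
    ann$methylation_flag <- as.integer(beta > cfg$methylation_high_cutoff)
    site_gene <- stats::setNames(genes, sites$site_id)
    tracks <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      tracks <- list()
      for (factor in names(peaks)) {
        f <- file.path(dir, paste0(factor, "_peaks.bed"))
        utils::write.table(peaks[[factor]], f, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        tracks[[factor]] <- f
      }
      f <- file.path(dir, "expression.tsv")
      utils::write.table(data.frame(gene = genes, tpm = tpm), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tracks$expression <- f
      meth <- do.call(rbind, lapply(seq_len(n), function(i) {
        gpos <- sites$start[i] + 0:19
        data.frame(chrom = sites$chrom[i], start = gpos, end = gpos + 1L,
                   beta = round(pmin(pmax(beta[i] +
                     stats::runif(20, -0.02, 0.02), 0), 1), 4))
      }))
      f <- file.path(dir, "methylation.tsv")
      utils::write.table(meth, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      tracks$methylation <- f
      f <- file.path(dir, "site_gene.tsv")
      utils::write.table(data.frame(site_id = sites$site_id, gene = genes), f,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tracks$site_gene <- f
    }
    list(annotation = ann, site_gene = site_gene, tracks = tracks,
         tpm = tpm, beta = beta, peaks = peaks)
  })
}

#' True per-position editing marginals of a site
#'
#' Evaluates the truth's logit model at every window target base of the site.
#'
#' @param site A `be_sites` row.
#' @param truth A [be_truth()].
#' @param annotation_row One-row annotation slice for this site (or NULL:
#'   factor effects drop out).
#' @param cfg A [be_config()].
#' @return List: `positions` (protospacer coords) and `m` (probabilities).
#' @export
true_marginals <- function(site, truth, annotation_row = NULL, cfg = NULL) {
  if (is.null(cfg)) cfg <- be_config(truth$editor)
  pos <- target_positions(site, cfg$window)
  if (length(pos) == 0) return(list(positions = integer(0), m = numeric(0)))
  ctx <- strsplit(site$context40, "")[[1]]
  center <- mean(cfg$window)
  lg <- vapply(pos, function(p) {
    i <- proto_to_context(p)
    eta <- truth$intercept + truth$prev_effect[[ctx[i - 1]]] +
      truth$next_effect[[ctx[i + 1]]] +
      truth$position_amplitude * exp(-(p - center)^2 / 2)
    if (!is.null(annotation_row)) {
      for (f in names(truth$factor_effects)) {
        if (f %in% names(annotation_row)) {
          eta <- eta + truth$factor_effects[[f]] * annotation_row[[f]]
        }
      }
    }
    eta
  }, numeric(1))
  list(positions = pos, m = stats::plogis(lg))
}

#' Sample replicate allele tables for one site
#'
#' Reads are drawn from the chain outcome distribution over the window target
#' bases (true marginals + adjacent odds ratio); independent bystander
#' substitutions and 1-bp indel events are then superimposed at the truth's
#' rates (at most one superimposed event per read; rates are small). Counts
#' per replicate are multinomial at fixed depth.
#'
#' @param site A `be_sites` row.
#' @param truth A [be_truth()].
#' @param marginals Output of [true_marginals()] for this site.
#' @param seed Integer seed.
#' @param n_reads Reads per replicate (default `truth$depth`).
#' @param replicates Number of replicates (default `truth$replicates`).
#' @param dir Optional directory; tables are written as
#'   `<site_id>_rep<j>.tsv` in the CRISPResso2 dialect.
#' @return List of `be_allele_table` (one per replicate); attribute `paths`
#'   when written.
#' @export
sample_allele_tables <- function(site, truth, marginals, seed = 1L,
                                 n_reads = truth$depth,
                                 replicates = truth$replicates, dir = NULL) {
  stopifnot(n_reads >= 1)
  pos <- marginals$positions
  n_pos <- length(pos)
  model <- chain_model(pos, marginals$m, truth$adjacent_or)
  pats <- all_patterns(n_pos)
  probs <- apply(pats, 1, function(b) chain_joint(model, b))
  probs <- probs / sum(probs)
  ctx <- strsplit(site$context40, "")[[1]]
  product <- editor_product_base(site$editor)
  w <- attr(marginals, "window") %||% NULL
  del_pos <- if (n_pos > 0) pos else integer(0)
  # per-read superimposed event probabilities
  p_by <- truth$bystander_rate
  p_ins <- truth$insertion_rate_p18
  p_del <- truth$deletion_rate_window * length(del_pos)
  p_any <- p_by + p_ins + p_del
  tables <- vector("list", replicates)
  paths <- character(0)
  with_seed(seed + 202L, {
    for (rep_j in seq_len(replicates)) {
      pr <- probs
      if (truth$overdispersion > 0) {
        pr <- pr * stats::rgamma(length(pr), shape = 1 / truth$overdispersion,
                                 scale = truth$overdispersion)
        pr <- pr / sum(pr)
      }
      counts <- as.vector(stats::rmultinom(1, n_reads, pr))
      acc <- new.env(parent = emptyenv())
      bump <- function(key, k) {
        if (k > 0) acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + k
      }
      for (g in which(counts > 0)) {
        k <- counts[g]
        edited <- ctx
        ep <- pos[pats[g, ] == 1L]
        if (length(ep) > 0) edited[proto_to_context(ep)] <- product
        base_seq <- paste(edited, collapse = "")
        n_ev <- if (p_any > 0) stats::rbinom(1, k, min(p_any, 1)) else 0L
        bump(paste0("P|", base_seq), k - n_ev)
        if (n_ev > 0) {
          split_ev <- as.vector(stats::rmultinom(1, n_ev,
                                                 c(p_by, p_ins, p_del)))
          # bystander: one random non-intended substitution in protospacer
          if (split_ev[1] > 0) {
            for (i in seq_len(split_ev[1])) {
              p_sub <- sample(1:20, 1)
              ci <- proto_to_context(p_sub)
              # never emit the intended transition as a "bystander": keep the
              # true marginals exact
              excl <- c(edited[ci], ctx[ci])
              if (ctx[ci] == editor_target_base(site$editor)) {
                excl <- c(excl, product)
              }
              alt <- sample(setdiff(c("A", "C", "G", "T"), excl), 1)
              mod <- edited
              mod[ci] <- alt
              bump(paste0("P|", paste(mod, collapse = "")), 1)
            }
          }
          # 1-bp insertion before position 18
          if (split_ev[2] > 0) {
            insbase <- sample(c("A", "C", "G", "T"), 1)
            bump(paste0("I", proto_to_context(18L), insbase, "|", base_seq),
                 split_ev[2])
          }
          # 1-bp deletion at a window target position
          if (split_ev[3] > 0 && length(del_pos) > 0) {
            dp <- if (length(del_pos) == 1) del_pos else sample(del_pos, 1)
            mod <- edited
            mod[proto_to_context(dp)] <- "-"
            bump(paste0("P|", paste(mod, collapse = "")), split_ev[3])
          }
        }
      }
      keys <- ls(acc, all.names = TRUE)
      nr <- vapply(keys, function(k) acc[[k]], numeric(1))
      alleles <- character(length(keys))
      inss <- vector("list", length(keys))
      for (i in seq_along(keys)) {
        if (startsWith(keys[i], "P|")) {
          alleles[i] <- substring(keys[i], 3)
          inss[[i]] <- empty_insertions()
        } else {
          m <- regmatches(keys[i], regexec("^I(\\d+)([ACGT])\\|(.*)$", keys[i]))[[1]]
          alleles[i] <- m[4]
          inss[[i]] <- data.frame(position = as.integer(m[2]), seq = m[3],
                                  stringsAsFactors = FALSE)
        }
      }
      tb <- be_allele_table(site$site_id, paste0("rep", rep_j),
                            site$context40, alleles, nr, inss)
      if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        f <- file.path(dir, paste0(site$site_id, "_rep", rep_j, ".tsv"))
        write_allele_table(tb, f)
        paths <- c(paths, f)
      }
      tables[[rep_j]] <- tb
    }
  })
  if (length(paths) > 0) attr(tables, "paths") <- paths
  tables
}

#' Simulate a complete synthetic dataset
#'
#' Sites, factor annotations (optionally with raw track files) and replicate
#' allele tables, plus the generating truth (including each site's true
#' marginals), as one deterministic function of the seed.
#'
#' @param n_sites Number of sites.
#' @param editor `"ABE"` or `"CBE"`.
#' @param truth A [be_truth()]; its editor is overridden by `editor`.
#' @param seed Integer seed.
#' @param cfg A [be_config()].
#' @param dir Optional output directory (`sites.tsv`, `tracks/`, `alleles/`,
#'   `truth.json`).
#' @return List of class `be_simulation`: `sites`, `annotation`, `site_gene`,
#'   `tables` (list per site of replicate allele tables), `marginals` (list
#'   per site), `truth`, `cfg`, `tracks`.
#' @export
simulate_dataset <- function(n_sites, editor = c("ABE", "CBE"),
                             truth = NULL, seed = 1L, cfg = NULL, dir = NULL) {
  editor <- match.arg(editor)
  if (is.null(truth)) truth <- be_truth(editor)
  truth$editor <- editor
  if (is.null(cfg)) cfg <- be_config(editor, seed = seed)
  sites <- generate_sites(n_sites, editor, seed = seed, cfg = cfg)
  track_dir <- if (!is.null(dir)) file.path(dir, "tracks") else NULL
  ann <- generate_annotations(sites, truth, seed = seed, dir = track_dir,
                              cfg = cfg)
  allele_dir <- if (!is.null(dir)) file.path(dir, "alleles") else NULL
  marginals <- vector("list", n_sites)
  tables <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    marginals[[i]] <- true_marginals(sites[i, ], truth,
                                     ann$annotation[i, ], cfg)
    tables[[i]] <- sample_allele_tables(sites[i, ], truth, marginals[[i]],
                                        seed = seed + i, dir = allele_dir)
  }
  names(marginals) <- sites$site_id
  names(tables) <- sites$site_id
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sites(sites, file.path(dir, "sites.tsv"))
    truth_out <- truth
    truth_out$true_marginals <- lapply(marginals, function(m)
      list(positions = m$positions, m = m$m))
    jsonlite::write_json(unclass_rec(truth_out), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(sites = sites, annotation = ann$annotation,
                 site_gene = ann$site_gene, tables = tables,
                 marginals = marginals, truth = truth, cfg = cfg,
                 tracks = ann$tracks),
            class = "be_simulation")
}
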