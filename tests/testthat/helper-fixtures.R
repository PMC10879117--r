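# Shared fixtures and independent oracles, built in code.

# A context with the protospacer supplied explicitly (10 up + 20 + NGG + 7).
fixture_context <- function(protospacer,
                            up = "TTGACCTTGA", pam = "TGG",
                            down = "ACCTGAC") {
  stopifnot(nchar(protospacer) == 20)
  paste0(up, protospacer, pam, down)
}

fixture_site <- function(protospacer = "GACAAATCGATTCGGATCAG",
                         editor = "ABE", site_id = "s1", ...) {
  be_sites(site_id = site_id, editor = editor,
           context40 = fixture_context(protospacer), ...)
}

# Build an allele table on the 40-nt context from compact edit specs:
# each allele is list(n = reads, sub = c(pos = "X>Y", ...) protospacer
# positions, del = c(pos, len), ins = c(pos, "SEQ")).
fixture_table <- function(site, alleles, replicate_id = "rep1") {
  ref <- strsplit(site$context40, "")[[1]]
  seqs <- character(0)
  reads <- numeric(0)
  inss <- list()
  for (al in alleles) {
    a <- ref
    if (!is.null(al$sub)) {
      for (k in seq_along(al$sub)) {
        p <- as.integer(names(al$sub)[k])
        a[p + 10L] <- sub("^.*>", "", al$sub[k])
      }
    }
    ins <- data.frame(position = integer(0), seq = character(0))
    if (!is.null(al$del)) {
      p <- al$del[[1]]; len <- al$del[[2]]
      a[(p + 10L):(p + 10L + len - 1L)] <- "-"
    }
    if (!is.null(al$ins)) {
      ins <- data.frame(position = al$ins[[1]] + 10L, seq = al$ins[[2]],
                        stringsAsFactors = FALSE)
    }
    seqs <- c(seqs, paste(a, collapse = ""))
    reads <- c(reads, al$n)
    inss[[length(inss) + 1L]] <- ins
  }
  be_allele_table(site$site_id, replicate_id, site$context40, seqs, reads, inss)
}

# ---- Independent read-by-read recount oracle for summarize_site ----------
# Deliberately naive: walks every read's characters one by one.
oracle_recount <- function(table, site, cfg) {
  ref <- strsplit(table$reference, "")[[1]]
  off <- regexpr(site$protospacer, table$reference, fixed = TRUE)[1] - 1L
  from <- if (site$editor == "ABE") "A" else "C"
  to <- if (site$editor == "ABE") "G" else "T"
  w <- cfg$window
  total <- 0
  overall <- 0; modified <- 0
  pp <- numeric(20)
  trans <- list(overall = list(), in_window = list(), outside_window = list())
  for (i in seq_len(nrow(table$rows))) {
    n <- table$rows$n_reads[i]
    total <- total + n
    a <- strsplit(table$rows$aligned_allele[i], "")[[1]]
    any_mut <- FALSE
    got_overall <- FALSE
    seen <- list(overall = character(0), in_window = character(0),
                 outside_window = character(0))
    for (j in seq_along(a)) {
      p <- j - off
      if (a[j] == "-") { any_mut <- TRUE; next }
      if (a[j] != ref[j]) {
        any_mut <- TRUE
        if (p >= 1 && p <= 20) {
          key <- paste0(ref[j], ">", a[j])
          seen$overall <- union(seen$overall, key)
          if (p >= w[1] && p <= w[2]) {
            seen$in_window <- union(seen$in_window, key)
          } else {
            seen$outside_window <- union(seen$outside_window, key)
          }
          if (ref[j] == from && a[j] == to) {
            pp[p] <- pp[p] + n
            if (p >= w[1] && p <= w[2]) got_overall <- TRUE
          }
        }
      }
    }
    if (nrow(table$rows$insertions[[i]]) > 0) any_mut <- TRUE
    if (got_overall) overall <- overall + n
    if (any_mut) modified <- modified + n
    for (sc in names(seen)) for (key in seen[[sc]]) {
      trans[[sc]][[key]] <- (if (is.null(trans[[sc]][[key]])) 0 else
        trans[[sc]][[key]]) + n
    }
  }
  tp <- sapply(names(trans), function(sc) {
    v <- stats::setNames(rep(0, length(BE_TRANSITIONS)), BE_TRANSITIONS)
    for (key in names(trans[[sc]])) v[key] <- trans[[sc]][[key]]
    if (sum(v) > 0) v / sum(v) else rep(NA_real_, length(v))
  })
  list(total = total, overall = overall / total, modified = modified / total,
       per_position = pp / total, transition_proportions = t(tp))
}

# ---- Brute-force Markov chain distribution oracle (n = 3) ----------------
# Builds the two conditional tables explicitly from the pairwise joints and
# enumerates all 8 outcomes by plain multiplication.
oracle_chain3 <- function(m, ors) {
  joint2 <- function(p, q, c) {
    if (abs(c - 1) < 1e-12) p11 <- p * q else {
      S <- 1 + (p + q) * (c - 1)
      p11 <- (S - sqrt(S^2 - 4 * c * (c - 1) * p * q)) / (2 * (c - 1))
    }
    c(p11 = p11, p10 = p - p11, p01 = q - p11, p00 = 1 - p - q + p11)
  }
  J12 <- joint2(m[1], m[2], ors[1])
  J23 <- joint2(m[2], m[3], ors[2])
  # conditionals P(X2 | X1), P(X3 | X2)
  c21 <- matrix(c(J12["p00"] / (1 - m[1]), J12["p01"] / (1 - m[1]),
                  J12["p10"] / m[1], J12["p11"] / m[1]),
                2, 2, byrow = TRUE) # rows: x1 = 0/1; cols: x2 = 0/1
  c32 <- matrix(c(J23["p00"] / (1 - m[2]), J23["p01"] / (1 - m[2]),
                  J23["p10"] / m[2], J23["p11"] / m[2]), 2, 2, byrow = TRUE)
  out <- numeric(8)
  k <- 0
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    k <- k + 1
    p1 <- if (b1 == 1) m[1] else 1 - m[1]
    out[k] <- p1 * c21[b1 + 1, b2 + 1] * c32[b2 + 1, b3 + 1]
    names(out)[k] <- paste0(b1, b2, b3)
  }
  out
}

# ---- Independent dependent-correlation Z (coded from the published
# formula, separate from the package implementation) ------------------------
oracle_steiger <- function(r_jk, r_jh, r_kh, n) {
  fisher <- function(r) 0.5 * log((1 + r) / (1 - r))
  rbar2 <- (r_jk * r_jk + r_jh * r_jh) / 2
  fval <- (1 - r_kh) / (2 * (1 - rbar2))
  if (fval > 1) fval <- 1
  hval <- (1 - fval * rbar2) / (1 - rbar2)
  (fisher(r_jk) - fisher(r_jh)) *
    sqrt((n - 3) / (2 * (1 - r_kh) * hval))
}

# Total variation distance between two named proportion vectors.
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  gv <- function(x) ifelse(is.na(x[keys]), 0, x[keys])
  0.5 * sum(abs(gv(p) - gv(q)))
}
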