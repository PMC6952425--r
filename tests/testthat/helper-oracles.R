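# Independent oracles used to check the package's computations. These are
# deliberately naive (loops, enumeration, closed forms) and share no code
# with the implementation.

# Brute-force fragment-overlap counts: for each bin, count the reads whose
# interval intersects it (same chromosome). 0-based half-open throughout.
oracle_bin_counts <- function(reads, bins) {
  vapply(seq_len(nrow(bins)), function(i) {
    same <- reads$chrom == bins$chrom[i]
    sum(same & reads$start < bins$gend[i] & reads$end > bins$gstart[i])
  }, numeric(1))
}

# Exact hypergeometric upper-tail p by full enumeration: fix a set A of
# size K inside a universe of size N, enumerate every size-n subset B and
# count those with |A intersect B| >= k.
oracle_hyper_p <- function(N, K, n, k) {
  A <- seq_len(K)
  combos <- utils::combn(N, n)
  hits <- sum(apply(combos, 2, function(b) length(intersect(b, A)) >= k))
  hits / ncol(combos)
}

# Position-by-position IUPAC consensus match, no regex.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))
oracle_iupac_hit <- function(seq, consensus) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(consensus, "")[[1]]
  L <- length(s); k <- length(m)
  if (L < k) return(FALSE)
  for (i in seq_len(L - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1] %in% IUPAC_SETS[[m[j]]]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Closed-form expected 5' start rates of the compositional read model, per
# base and strand, over the whole (small) genome. Returns a list with
# matrices rate_plus/rate_minus (positions x 1) in expected fragments per
# base for one library of the given condition. Truncation of the Gaussian
# components at +/-4 sd is included.
oracle_start_rates <- function(genes, cfg, condition, library = "ip") {
  sizes <- attr(genes, "chrom_sizes")
  stopifnot(length(sizes) == 1) # oracle supports single-chromosome toys
  G <- sizes[[1]]
  rp <- numeric(G); rm_ <- numeric(G)
  amps <- cfg$amplitudes
  shift <- 0
  if (!is.null(cfg$tes_shift) && condition %in% names(cfg$tes_shift)) {
    shift <- cfg$tes_shift[[condition]]
  }
  # component weights, exactly as the multinomial normalisation sees them
  w_bg <- cfg$background_rate * G / 1000
  total_w <- w_bg
  comp_w <- list()
  if (library == "ip" && nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      m <- polprof:::class_multipliers(cfg, genes$class[i], condition)
      w <- amps[c("up", "pause", "body", "tes")] * m
      comp_w[[i]] <- w
      total_w <- total_w + sum(w)
    }
  }
  scale <- cfg$depth / total_w
  trunc_gauss <- function(center, sd) {
    # discrete rate over integer rel positions (rounding of the draw)
    rel <- seq(floor(center - 4 * sd) - 1, ceiling(center + 4 * sd) + 1)
    lo <- pnorm(-4); hi <- pnorm(4)
    z_hi <- pmin((rel + 0.5 - center) / sd, 4)
    z_lo <- pmax((rel - 0.5 - center) / sd, -4)
    p <- (pnorm(z_hi) - pnorm(z_lo)) / (hi - lo)
    p[z_hi <= z_lo] <- 0
    list(rel = rel, p = p)
  }
  add_rel <- function(gene_i, rel, p, weight) {
    tssg <- polprof::tss_position(genes[gene_i, ])
    if (genes$strand[gene_i] == "+") {
      pos <- tssg + rel
    } else {
      pos <- tssg - rel
    }
    keep <- pos >= 0 & pos < G
    pos <- pos[keep]; p <- p[keep]
    if (genes$strand[gene_i] == "+") {
      rp[pos + 1] <<- rp[pos + 1] + weight * scale * p
    } else {
      rm_[pos + 1] <<- rm_[pos + 1] + weight * scale * p
    }
  }
  if (library == "ip" && nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      L <- genes$end[i] - genes$start[i]
      w <- comp_w[[i]]
      g1 <- trunc_gauss(cfg$upstream_center, cfg$peak_sd)
      add_rel(i, g1$rel, g1$p, w[["up"]])
      g2 <- trunc_gauss(cfg$pause_center, cfg$peak_sd)
      add_rel(i, g2$rel, g2$p, w[["pause"]])
      if (L > 500) {
        rel <- 500:(L - 1)
        add_rel(i, rel, rep(1 / (L - 500), length(rel)), w[["body"]])
      }
      g3 <- trunc_gauss((L - 1) + shift, cfg$peak_sd)
      add_rel(i, g3$rel, g3$p, w[["tes"]])
    }
  }
  bg_rate <- w_bg * scale / G / 2 # per base per strand
  rp <- rp + bg_rate; rm_ <- rm_ + bg_rate
  list(rate_plus = rp, rate_minus = rm_, scale = scale)
}

# Expected extended-fragment count overlapping each genomic bin, from the
# closed-form start rates (plus-strand fragments cover [s, s+flen), minus
# cover [s-flen+1, s+1), both clipped).
oracle_expected_bin_counts <- function(rates, bins, flen) {
  cp <- cumsum(rates$rate_plus); cm <- cumsum(rates$rate_minus)
  G <- length(rates$rate_plus)
  sum_range <- function(cs, lo, hi) { # inclusive 1-based range with clip
    lo <- max(lo, 1); hi <- min(hi, G)
    if (hi < lo) return(0)
    cs[hi] - if (lo > 1) cs[lo - 1] else 0
  }
  vapply(seq_len(nrow(bins)), function(i) {
    b0 <- bins$gstart[i]; b1 <- bins$gend[i] # 0-based half-open
    # plus-strand start s (0-based) overlaps iff s in (b0-flen, b1)
    plus <- sum_range(cp, b0 - flen + 2, b1)
    # minus-strand start s overlaps iff s in [b0, b1+flen-1)
    minus <- sum_range(cm, b0 + 1, b1 + flen - 1)
    plus + minus
  }, numeric(1))
}
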