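# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately take the slow, explicit route.

# --- Two-locus selection oracle -------------------------------------------
#
# Tracks the nine genotype frequencies directly: selection weighs each
# genotype by its habitat-averaged fitness, then the next generation's
# genotype distribution is computed by enumerating all 81 ordered parent
# pairs and the Mendelian offspring distribution of each pair (independent
# segregation at two unlinked loci; transmission probability of r at a locus
# is the parent's r-allele count at that locus divided by 2).

# Offspring r-allele-count distribution at one locus for parents with counts
# ci, cj in {0,1,2}: convolution of two Bernoulli transmissions.
offspring_one_locus <- function(ci, cj) {
  pi <- ci / 2; pj <- cj / 2
  c(`0` = (1 - pi) * (1 - pj),
    `1` = pi * (1 - pj) + (1 - pi) * pj,
    `2` = pi * pj)
}

# One generation on a 3x3 genotype-frequency matrix G (rows = Bt r-count + 1,
# cols = RNAi r-count + 1).
oracle_step <- function(G, w_trans, w_ref, refuge) {
  w <- refuge * w_ref + (1 - refuge) * w_trans
  Gs <- G * w
  Gs <- Gs / sum(Gs)
  G_next <- matrix(0, 3, 3)
  for (i1 in 0:2) for (j1 in 0:2) for (i2 in 0:2) for (j2 in 0:2) {
    pair_freq <- Gs[i1 + 1, j1 + 1] * Gs[i2 + 1, j2 + 1]
    if (pair_freq == 0) next
    off1 <- offspring_one_locus(i1, i2)
    off2 <- offspring_one_locus(j1, j2)
    G_next <- G_next + pair_freq * outer(off1, off2)
  }
  G_next
}

# Initial genotype matrix at linkage equilibrium / Hardy-Weinberg.
oracle_init <- function(p1, p2) {
  hw <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  outer(hw(p1), hw(p2))
}

# --- Single-locus recursion (marginal oracle) ------------------------------
single_locus_next_p <- function(p, w, refuge, w_ref = c(1, 1, 1),
                                w_trans = w) {
  geno <- c((1 - p)^2, 2 * p * (1 - p), p^2)  # ss, rs, rr
  wr <- refuge * w_ref + (1 - refuge) * w_trans
  sel <- geno * wr
  sel <- sel / sum(sel)
  sum(sel * c(0, 0.5, 1))
}

# --- Naive k-mer matcher ----------------------------------------------------
#
# Character-by-character scan of every (i, j) offset pair on one strand;
# reports maximal exact matches of length >= k as 0-based half-open
# coordinates. N never matches.
naive_matches_one_strand <- function(q, s, k) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  eq <- function(a, b) a == b & a != "N" & b != "N"
  out <- list()
  for (i in seq_along(qc)) {
    for (j in seq_along(sc)) {
      # only start at the beginning of a run
      if (i > 1 && j > 1 && eq(qc[i - 1], sc[j - 1])) next
      len <- 0
      while (i + len <= length(qc) && j + len <= length(sc) &&
             eq(qc[i + len], sc[j + len])) {
        len <- len + 1
      }
      if (len >= k) {
        out[[length(out) + 1]] <- c(query_start = i - 1L,
                                    subject_start = j - 1L, length = len)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_start = integer(), subject_start = integer(),
                      length = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

naive_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# --- Balanced two-way ANOVA sums of squares via projections ----------------
projection_ss <- function(y, a, b) {
  X0 <- matrix(1, length(y), 1)
  Xa <- stats::model.matrix(~ a)
  Xb <- stats::model.matrix(~ b)
  Xab <- stats::model.matrix(~ a * b)
  proj <- function(X) X %*% solve(crossprod(X), crossprod(X, y))
  ss <- function(v) sum(v^2)
  fit0 <- proj(X0); fita <- proj(Xa); fitb <- proj(Xb); fitab <- proj(Xab)
  # balanced design: factor spaces are orthogonal after centering
  c(a = ss(fita - fit0),
    b = ss(fitb - fit0),
    ab = ss(fitab - fit0) - ss(fita - fit0) - ss(fitb - fit0),
    resid = ss(y - fitab))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small fully crossed bioassay tibble from explicit per-cotton counts.
make_records <- function(counts_by_cotton, n_larvae = 50, strain = "SCD",
                         year = "2016", replicates = 1) {
  purrr::imap_dfr(counts_by_cotton, function(counts, cotton) {
    tibble::tibble(strain = strain, cotton = cotton, year = year,
                   replicate = seq_len(replicates),
                   n_larvae = n_larvae,
                   n_normal_pupae = rep_len(counts, replicates))
  })
}
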