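# Independent oracles used across the suite.  Each is a deliberately naive
# implementation (brute force, per-base bit vectors, quadrature) kept free of
# the package's own code paths.

# --- Benjamini-Hochberg by the raw step-up definition -----------------------
oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  o <- order(p)
  ps <- p[o]
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, m * ps[j] / j), numeric(1))
    q[o[i]] <- min(cand)
  }
  q
}

# --- target-decoy threshold by brute-force scan over candidate cut points
#     (observed target scores snapped down to their bin edge) ----------------
oracle_fdr_threshold <- function(target_scores, decoy_scores, breaks, fdr) {
  cands <- sort(unique(breaks[findInterval(target_scores, breaks)]))
  for (t in cands) {
    nt <- sum(target_scores >= t)
    nd <- sum(decoy_scores >= t)
    est <- if (nt == 0) (if (nd == 0) 0 else 1) else nd / nt
    if (est <= fdr) return(list(threshold = t, kept = nt, est = est))
  }
  list(threshold = Inf, kept = 0L, est = NA_real_)
}

# --- beta-binomial pmf by numerical integration of the beta mixture ---------
oracle_betabin_pmf <- function(x, n, alpha, beta) {
  stats::integrate(function(p) stats::dbinom(x, n, p) * stats::dbeta(p, alpha, beta),
                   0, 1, rel.tol = 1e-12)$value
}

# --- two-sample binomial likelihood-ratio test (closed-form MLEs) -----------
oracle_binom_lrt <- function(xa, na_, xb, nb) {
  ll <- function(x, n, p) {
    p <- min(max(p, 1e-12), 1 - 1e-12)
    sum(stats::dbinom(x, n, p, log = TRUE))
  }
  p0 <- sum(xa, xb) / sum(na_, nb)
  pa <- sum(xa) / sum(na_)
  pb <- sum(xb) / sum(nb)
  stat <- max(0, 2 * (ll(xa, na_, pa) + ll(xb, nb, pb) -
                        ll(xa, na_, p0) - ll(xb, nb, p0)))
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# --- per-base bit-vector interval operations on toy genomes -----------------
bits_of <- function(iset) {
  lapply(setNames(names(iset$seqlengths), names(iset$seqlengths)), function(chr) {
    v <- logical(iset$seqlengths[[chr]])
    d <- iset$intervals[iset$intervals$chrom == chr, , drop = FALSE]
    for (k in seq_len(nrow(d))) v[(d$start[k] + 1):d$end[k]] <- TRUE
    v
  })
}

oracle_covered <- function(iset) sum(vapply(bits_of(iset), sum, numeric(1)))

oracle_jaccard <- function(a, b) {
  ba <- bits_of(a); bb <- bits_of(b)
  chrs <- union(names(ba), names(bb))
  inter <- both <- 0
  for (chr in chrs) {
    va <- if (chr %in% names(ba)) ba[[chr]] else logical(0)
    vb <- if (chr %in% names(bb)) bb[[chr]] else logical(0)
    L <- max(length(va), length(vb))
    va <- c(va, logical(L - length(va)))
    vb <- c(vb, logical(L - length(vb)))
    inter <- inter + sum(va & vb)
    both <- both + sum(va | vb)
  }
  if (both == 0) NA_real_ else inter / both
}

oracle_intersect_bases <- function(a, b) {
  ba <- bits_of(a); bb <- bits_of(b)
  sum(vapply(intersect(names(ba), names(bb)),
             function(chr) sum(ba[[chr]] & bb[[chr]]), numeric(1)))
}

oracle_coverage_fraction <- function(query, reference) {
  br <- bits_of(reference)
  d <- query$intervals
  vapply(seq_len(nrow(d)), function(k) {
    v <- br[[d$chrom[k]]]
    if (is.null(v)) return(0)
    mean(v[(d$start[k] + 1):d$end[k]])
  }, numeric(1))
}

oracle_annotate <- function(sites, partition) {
  bs <- bits_of(sites)
  labs <- unique(partition$intervals$label)
  out <- setNames(numeric(length(labs)), labs)
  for (lab in labs) {
    d <- partition$intervals[partition$intervals$label == lab, , drop = FALSE]
    sub <- interval_set(d$chrom, d$start, d$end,
                        seqlengths = partition$seqlengths)
    out[lab] <- oracle_intersect_bases(sites, sub)
  }
  total <- sum(vapply(bs, sum, numeric(1)))
  other <- total - sum(out)
  if (other > 0) out["other"] <- other
  100 * out / total
}

oracle_site_overlap <- function(sites, features) {
  bf <- bits_of(features)
  d <- sites$intervals
  hits <- vapply(seq_len(nrow(d)), function(k) {
    v <- bf[[d$chrom[k]]]
    !is.null(v) && any(v[(d$start[k] + 1):d$end[k]])
  }, logical(1))
  mean(hits)
}

# --- random toy fixtures ----------------------------------------------------
random_interval_set <- function(n, genome, max_w = 400) {
  chrom <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  s <- floor(runif(n) * pmax(genome[chrom] - w, 1))
  interval_set(chrom, s, pmin(s + w, genome[chrom]), seqlengths = genome)
}

make_psms <- function(peptide, sample_id = "S1", ntt = 2L, charge = 2L,
                      mod_state = "unmod", accessions = "P1",
                      is_decoy = FALSE, discriminant = 5) {
  n <- length(peptide)
  data.frame(spectrum_id = sprintf("sp%04d", seq_len(n)),
             sample_id = rep_len(sample_id, n), peptide = peptide,
             charge = rep_len(charge, n), ntt = rep_len(ntt, n),
             mod_state = rep_len(mod_state, n),
             accessions = rep_len(accessions, n),
             is_decoy = rep_len(is_decoy, n),
             discriminant = rep_len(discriminant, n),
             stringsAsFactors = FALSE)
}

# tiny database + PSMs exercising grouping/parsimony/splitting by hand
tiny_inference_fixture <- function() {
  db <- sequence_db(
    c("P1", "P2", "P3", "P4"),
    c("AAAEEEKCCCDDDKGGGFFFK",   # peptides a=AAAEEEK, b=CCCDDDK, c=GGGFFFK
      "AAAEEEKCCCDDDK",          # {a, b}  (subset of P1)
      "HHHIIIKCCCDDDK",          # d=HHHIIIK, b (shares b)
      "AAAEEEKCCCDDDKGGGFFFK")   # identical peptide set as P1
  )
  psms <- make_psms(
    peptide = c("AAAEEEK", "CCCDDDK", "GGGFFFK", "HHHIIIK",
                "AAAEEEK", "CCCDDDK", "HHHIIIK", "CCCDDDK"),
    sample_id = c("S1", "S1", "S1", "S1", "S2", "S2", "S2", "S2"),
    accessions = "x")
  list(db = db, psms = psms)
}
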