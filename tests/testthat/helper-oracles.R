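# Independent oracle implementations and small fixture builders.
# Oracles are deliberately written scalar-wise and from the published
# component formulas, sharing no code with the package internals.

# Weir & Cockerham (1984) per-site theta for two populations, from
# genotype count triples (hom-ref, het, hom-alt), summing the a/b/c
# components allele by allele as in the multi-allele formulation.
wc_theta_oracle <- function(counts1, counts2) {
  n1 <- sum(counts1); n2 <- sum(counts2)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  sum_a <- 0; sum_bc <- 0
  for (allele in c("ref", "alt")) {
    if (allele == "alt") {
      p1 <- (counts1[2] + 2 * counts1[3]) / (2 * n1)
      p2 <- (counts2[2] + 2 * counts2[3]) / (2 * n2)
    } else {
      p1 <- (counts1[2] + 2 * counts1[1]) / (2 * n1)
      p2 <- (counts2[2] + 2 * counts2[1]) / (2 * n2)
    }
    h1 <- counts1[2] / n1
    h2 <- counts2[2] / n2
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    sum_a <- sum_a + a
    sum_bc <- sum_bc + b + cc
  }
  sum_a / (sum_a + sum_bc)
}

# Two-population A/B moment components (Bhatia/Hudson form) per site.
hudson_ab_oracle <- function(p1, p2, n1, n2) {
  A <- (p1 - p2)^2 -
    p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  B <- p1 * (1 - p2) + p2 * (1 - p1)
  c(A = A, B = B)
}

# Exact heterozygote-excess tail probability, conditional on allele
# counts, by direct enumeration of genotype-count configurations weighted
# by multinomial coefficients times 2^het.
hwe_excess_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n2 + n1            # alt copies
  weights <- c()
  hets <- c()
  for (k in 0:min(na, 2 * n - na)) {
    hom_alt <- (na - k) / 2
    if (hom_alt != round(hom_alt) || hom_alt < 0) next
    hom_ref <- n - k - hom_alt
    if (hom_ref < 0) next
    w <- factorial(n) / (factorial(hom_ref) * factorial(k) * factorial(hom_alt)) * 2^k
    weights <- c(weights, w)
    hets <- c(hets, k)
  }
  sum(weights[hets >= n1]) / sum(weights)
}

# Brute-force allele-count likelihood: sum over all 3^N genotype
# configurations of prod(L_i(g_i)) * prod(choose(2, g_i)) / choose(2N, c).
acl_oracle <- function(lik) {
  N <- nrow(lik)
  out <- numeric(2 * N + 1)
  configs <- expand.grid(rep(list(0:2), N))
  for (r in seq_len(nrow(configs))) {
    g <- as.integer(configs[r, ])
    c_tot <- sum(g)
    w <- prod(lik[cbind(seq_len(N), g + 1)]) * prod(choose(2, g))
    out[c_tot + 1] <- out[c_tot + 1] + w
  }
  out <- out / choose(2 * N, 0:(2 * N))
  out / max(out)
}

# Deterministic linear-recursion oracle for the equilibrium pairwise
# heterozygosity of a single Wright-Fisher deme with symmetric two-way
# mutation at rate mu per copy per generation, starting from h0.
drift_mutation_het_oracle <- function(N, mu, generations, h0) {
  h <- h0
  flip <- 2 * mu * (1 - mu)
  for (g in seq_len(generations)) {
    h_mut <- h * (1 - flip) + (1 - h) * flip
    h <- (1 - 1 / (2 * N)) * h_mut + (1 / (2 * N)) * flip
  }
  h
}

# --- fixture builders ---------------------------------------------------

# Single-site two-population genotype matrix from count triples
# (hom-ref, het, hom-alt), with its popmap.
make_pair_matrix <- function(counts_a, counts_b) {
  d <- matrix(c(rep(0L, counts_a[1]), rep(1L, counts_a[2]), rep(2L, counts_a[3]),
                rep(0L, counts_b[1]), rep(1L, counts_b[2]), rep(2L, counts_b[3])),
              ncol = 1)
  x <- genotype_matrix(d)
  pm <- popmap(x$samples, rep(c("A", "B"), c(sum(counts_a), sum(counts_b))))
  list(x = x, pm = pm)
}

# Genotype matrix from an integer matrix (NA allowed), default site table.
toy_geno <- function(d, depth = NULL, samples = NULL) {
  genotype_matrix(d, depth = depth, samples = samples)
}

# GL tensor with likelihood mass concentrated on given true genotypes:
# every non-missing entry has linear likelihoods conf for the true
# genotype and (1-conf)/2 elsewhere. NA genotypes become missing.
toy_gl <- function(geno, conf = 0.999, samples = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  ll <- array(log((1 - conf) / 2), dim = c(n, m, 3))
  for (k in 0:2) {
    sel <- which(geno == k)
    ll[cbind(arrayInd(sel, dim(geno)), k + 1)] <- log(conf)
  }
  miss <- is.na(geno)
  for (k in 1:3) {
    slab <- ll[, , k]
    slab[miss] <- -Inf
    ll[, , k] <- slab
  }
  gl_tensor(ll, samples = samples)
}

# Dirichlet-ish random linear GL triples for n individuals (no missing).
random_gl_matrix <- function(n) {
  lik <- matrix(runif(3 * n, 0.01, 1), n, 3)
  lik / apply(lik, 1, max)
}
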