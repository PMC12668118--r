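# Independent brute-force oracles used by the derived-value tests. These are
# deliberately written as plain loops over definitions, independent of the
# package's vectorized implementations.

# Rank-N-Contrast by explicit enumeration over all anchor/positive pairs.
brute_rnc <- function(Z, y, tau) {
  B <- nrow(Z)
  tot <- 0
  for (i in seq_len(B)) for (j in setdiff(seq_len(B), i)) {
    S <- setdiff(which(abs(y[i] - y) >= abs(y[i] - y[j])), i)
    sim <- function(k) -sqrt(sum((Z[i, ] - Z[k, ])^2)) / tau
    tot <- tot - sim(j) + log(sum(exp(vapply(S, sim, 0))))
  }
  tot / (B * (B - 1))
}

# Multivariate score test assembled from explicit matrix inverses.
brute_gls <- function(Y, C, g) {
  N <- nrow(Y)
  M <- diag(N) - C %*% solve(crossprod(C)) %*% t(C)
  gr <- drop(M %*% g)
  E <- M %*% Y
  Sigma <- crossprod(E) / (N - qr(C)$rank)
  beta <- drop(crossprod(gr, E)) / sum(gr^2)
  stat <- sum(gr^2) * drop(t(beta) %*% solve(Sigma) %*% beta)
  list(beta = beta, stat = stat)
}

# ACAT combined p-value straight from the closed form.
brute_acat <- function(p, w = rep(1 / length(p), length(p))) {
  Tstat <- sum(w * tan((0.5 - p) * pi)) / sum(w)
  0.5 - atan(Tstat) / pi
}

# Greedy clumping by plain iteration over the definition.
brute_clump <- function(ids, chrom, pos, p, G, p_thr, r2_thr, half_window) {
  claimed <- rep(FALSE, length(ids))
  leads <- integer(0)
  members <- list()
  repeat {
    cand <- which(!claimed & !is.na(p) & p < p_thr)
    if (length(cand) == 0) break
    cand <- cand[order(p[cand], chrom[cand], pos[cand])]
    lead <- cand[1]
    claimed[lead] <- TRUE
    mem <- integer(0)
    for (j in which(!claimed)) {
      if (chrom[j] == chrom[lead] && abs(pos[j] - pos[lead]) <= half_window) {
        r2 <- suppressWarnings(stats::cor(G[, lead], G[, j])^2)
        if (!is.na(r2) && r2 >= r2_thr) {
          claimed[j] <- TRUE
          mem <- c(mem, j)
        }
      }
    }
    leads <- c(leads, lead)
    members[[length(members) + 1]] <- mem
  }
  o <- order(p[leads], chrom[leads], pos[leads])
  list(leads = ids[leads][o],
       members = lapply(members[o], function(m) ids[m]))
}

# Small shared synthetic cohort, built once per test run.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_participants = 150, n_variants = 60,
                          n_raw_features = 16, n_causal_variants = 3,
                          effect_dims = 4, effect_size = 0.6, noise_sd = 1,
                          ld_decay = 0.6, seed = 202)
      g <- simulate_genotypes(cfg)
      ch <- simulate_cohort(cfg, g)
      cache <<- list(cfg = cfg, geno = g, features = ch$features,
                     truth = ch$truth)
    }
    cache
  }
})
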