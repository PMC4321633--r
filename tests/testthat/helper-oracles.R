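# Independent oracles used to freeze / cross-check expected values.
# These deliberately avoid the code paths they validate.

# Exhaustive copy-path enumeration for the diploid haplotype-copying model.
# Enumerates every ordered pair of founder copy-paths (H^L each), multiplies
# per-path transition probabilities and per-site emissions, and reads the
# posterior genotype distribution at the masked site directly from the
# joint weights. Feasible only for tiny H and L.
ls_posterior_enum <- function(panel, obs, pos, masked, rho, eps) {
  H <- nrow(panel); L <- ncol(panel)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), L)))  # H^L x L
  np <- nrow(paths)
  # per-path transition probability
  w <- rep(1 / H, np)
  for (t in seq_len(L - 1)) {
    d <- pos[t + 1] - pos[t]
    s <- exp(-rho * d); u <- (1 - s) / H
    stay <- paths[, t + 1] == paths[, t]
    w <- w * ifelse(stay, s + u, u)
  }
  # joint emission over ordered path pairs, site by site
  J <- outer(w, w)
  for (t in seq_len(L)) {
    g <- obs[t]
    if (is.na(g)) next
    a <- panel[paths[, t], t]
    q0 <- ifelse(a == 0, 1 - eps, eps)  # P(true allele 0 | template)
    q1 <- 1 - q0
    M <- switch(as.character(g),
                "0" = outer(q0, q0),
                "1" = outer(q0, q1) + outer(q1, q0),
                "2" = outer(q1, q1))
    J <- J * M
  }
  a <- panel[paths[, masked], masked]
  q0 <- ifelse(a == 0, 1 - eps, eps)
  q1 <- 1 - q0
  p <- c(sum(J * outer(q0, q0)),
         sum(J * (outer(q0, q1) + outer(q1, q0))),
         sum(J * outer(q1, q1)))
  p / sum(p)
}

# random instance generator for the oracle-equivalence checks
random_ls_instance <- function(seed) {
  set.seed(seed)
  repeat {
    H <- sample(2:4, 1)
    L <- sample(3:6, 1)
    if (H^L <= 1024) break
  }
  panel <- matrix(rbinom(H * L, 1, 0.5), H, L)
  pos <- sort(sample.int(1e6, L))
  obs <- sapply(seq_len(L), function(t) sample(c(0L, 1L, 2L, NA), 1))
  masked <- sample.int(L, 1)
  obs[masked] <- NA
  if (all(is.na(obs[-masked]))) obs[if (masked == 1) 2 else 1] <- 1L
  list(panel = panel, obs = obs, pos = pos, masked = masked,
       rho = runif(1, 1e-8, 1e-5), eps = runif(1, 0, 0.2))
}

# Exact heterozygote-count distribution under fixed allele counts, derived
# by enumerating every subset of allele slots for tiny n (true enumeration,
# no closed form): 2n slots, n_a of them carry the minor allele, slots
# (2k-1, 2k) form individual k.
hwe_het_probs_subsets <- function(n, n_a) {
  slots <- 2 * n
  idx <- utils::combn(slots, n_a)
  het_count <- apply(idx, 2, function(s) {
    carrier <- tabulate((s + 1) %/% 2, nbins = n)
    sum(carrier == 1)
  })
  tab <- table(factor(het_count, levels = 0:n))
  as.numeric(tab) / ncol(idx)
}

# binomial-coefficient formulation of the same distribution (independent of
# the package's lgamma route); named by heterozygote count
hwe_het_probs_choose <- function(n, n_a) {
  n_a <- min(n_a, 2 * n - n_a)
  het <- seq.int(n_a %% 2, n_a, by = 2)
  hom_minor <- (n_a - het) / 2
  p <- choose(n, het) * choose(n - het, hom_minor) * 2^het /
    choose(2 * n, n_a)
  stats::setNames(p, het)
}

hwe_p_oracle <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  n_a <- 2 * n_hom_minor + n_het
  probs <- hwe_het_probs_choose(n, n_a)
  obs <- probs[as.character(n_het)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}
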