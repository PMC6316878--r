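# Independent oracles used by the unit and acceptance tests. These
# deliberately take different computational routes than the package code.

# Exact HWE p-value by direct conditional enumeration: P(n1 | n, allele
# count) = n! / (nAA! n1! nBB!) * 2^n1 / C(2n, na), summed over outcomes no
# more probable than the observed one.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- n1 + 2 * min(n0, n2)
  if (na == 0 || 2 * n - na == 0) return(1)
  h <- seq(na %% 2, na, by = 2)
  nAA <- (na - h) / 2
  nBB <- n - nAA - h
  lp <- lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(nBB + 1) +
    h * log(2) - lchoose(2 * n, na)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  po <- pr[match(n1, h)]
  sum(pr[pr <= po * (1 + 1e-9)])
}

# All permutations of a vector (n <= 7 only).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Brute-force Kaplan-Meier: walk distinct times, recomputing the risk set
# from scratch at every step.
km_oracle <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  res <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / at_risk)
    res$surv[i] <- s
  }
  res
}

# Brute-force k-group log-rank: hypergeometric mean/variance terms summed
# over event times, recomputing every risk set directly.
logrank_oracle <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  ut <- sort(unique(time[event]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in ut) {
    nj <- sum(time >= t)
    dj <- sum(time == t & event)
    for (g in seq_len(k)) {
      ng <- sum(time >= t & group == levels(group)[g])
      dg <- sum(time == t & event & group == levels(group)[g])
      O[g] <- O[g] + dg
      E[g] <- E[g] + dj * ng / nj
    }
    if (nj > 1) {
      c_t <- dj * (nj - dj) / (nj - 1)
      for (g in seq_len(k)) {
        for (h in seq_len(k)) {
          ng <- sum(time >= t & group == levels(group)[g]) / nj
          nh <- sum(time >= t & group == levels(group)[h]) / nj
          V[g, h] <- V[g, h] + c_t * ng * ((g == h) - nh)
        }
      }
    }
  }
  z <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  # pseudo-inverse for degenerate variance matrices (e.g. a group with no
  # one at risk at any event time); the statistical substance above stays
  # independent of the implementation under test
  s <- svd(Vk)
  pos <- s$d > max(s$d, 0) * 1e-10
  if (!any(pos)) return(0)
  drop(crossprod(z, s$v[, pos, drop = FALSE] %*%
                      ((t(s$u[, pos, drop = FALSE]) %*% z) / s$d[pos])))
}

# Closed-testing oracles for the multiplicity corrections. Holm is the
# closure of Bonferroni tests, Hommel the closure of Simes tests: the
# adjusted p of hypothesis i is the largest local test p over all subsets
# containing i.
holm_oracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    worst <- 0
    for (mask in seq_len(2^m - 1)) {
      S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (i %in% S) worst <- max(worst, min(length(S) * min(p[S]), 1))
    }
    worst
  }, numeric(1))
}

hommel_oracle <- function(p) {
  m <- length(p)
  simes <- function(ps) min(sort(ps) * length(ps) / seq_along(ps))
  vapply(seq_len(m), function(i) {
    worst <- 0
    for (mask in seq_len(2^m - 1)) {
      S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (i %in% S) worst <- max(worst, min(simes(p[S]), 1))
    }
    worst
  }, numeric(1))
}

# Hochberg and BH by the hand step-up formulas walked explicitly over the
# sorted p-values: adjusted p_(i) = min over j >= i of c_j * p_(j), capped
# at 1, with c_j = m - j + 1 (Hochberg) or m / j (BH).
hochberg_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, (m - (i:m) + 1) * ps[i:m])
  out <- numeric(m)
  out[o] <- adj
  out
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, (m / (i:m)) * ps[i:m])
  out <- numeric(m)
  out[o] <- adj
  out
}

# Shared tiny cohort builder for pipeline tests: genotype matrix plus a
# consistent clinical table.
make_cohort <- function(n_samples = 120, n_variants = 12, seed = 11,
                        effect_map = NULL, maf = 0.3, ...) {
  cfg <- simulation_config(
    n_samples = n_samples, n_variants = n_variants,
    maf_vector = maf, effect_map = effect_map, seed = seed,
    baseline_hazard = 0.004, ...
  )
  c(simulate_cohort(cfg), list(cfg = cfg))
}

# Evidence table granting every variant a rankable profile (medium level
# when significant) so panel membership reflects significance alone.
make_evidence <- function(variant_ids) {
  data.frame(variant_id = variant_ids,
             variant_class = "intronic-intergenic",
             pharmgkb_status = "no-data",
             clinvar_status = "drug-response",
             cancer_related = FALSE,
             cadd_phred = 25,
             stringsAsFactors = FALSE)
}
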