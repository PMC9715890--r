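# Shared fixture builders; everything is generated in code.

# Minimal valid cohort data.frame; override columns as needed.
cohort_df <- function(n = 4, t_stage = 1:4, nodes_examined = 10,
                      nodes_positive = 0, survival_months = 24, event = 0) {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    t_stage = rep_len(t_stage, n),
    nodes_examined = rep_len(nodes_examined, n),
    nodes_positive = rep_len(nodes_positive, n),
    survival_months = rep_len(survival_months, n),
    event = rep_len(event, n),
    stringsAsFactors = FALSE
  )
}

# Cohort encoding published per-stage pN0/pN+ counts; only the counts
# matter for rate arithmetic, so node/survival details are arbitrary.
counts_cohort <- function(pn0, pnp) {
  rows <- lapply(seq_along(pn0), function(t) {
    n <- pn0[t] + pnp[t]
    cohort_df(n, t_stage = t, nodes_examined = 10,
              nodes_positive = rep(c(0L, 1L), c(pn0[t], pnp[t])))
  })
  df <- do.call(rbind, rows)
  df$patient_id <- sprintf("P%05d", seq_len(nrow(df)))
  as_cohort(df)
}

# Table of per-stage pN0/pN+ counts from the two published cohorts
seer_counts <- list(pn0 = c(171L, 169L, 340L, 125L),
                    pnp = c(39L, 69L, 211L, 146L))
inst_counts <- list(pn0 = c(116L, 171L, 260L, 196L),
                    pnp = c(34L, 117L, 255L, 255L))

# Observed pN+ fitting pairs: latent-positive patients drawn from the
# beta-binomial, keeping those staged node positive (m >= 1).
sim_pnp_pairs <- function(n_keep, alpha, beta, e_sampler, seed) {
  set.seed(seed)
  m_out <- integer(0); e_out <- integer(0)
  while (length(m_out) < n_keep) {
    e <- e_sampler(2L * n_keep)
    m <- rbetabinom(length(e), e, alpha, beta)
    keep <- m >= 1L
    m_out <- c(m_out, m[keep]); e_out <- c(e_out, e[keep])
  }
  list(m = m_out[seq_len(n_keep)], e = e_out[seq_len(n_keep)])
}

# Brute-force grid search over log-spaced shapes: independent oracle for
# the MLE. Returns the argmax and the maximum of the same objective the
# fit reports.
grid_argmax_loglik <- function(m, e, n_grid = 200, lo = 0.01, hi = 100,
                               conditioning = "observed") {
  kept <- exclude_all_positive(m, e)
  m <- kept$m; e <- kept$e
  key <- paste(m, e)
  w <- as.numeric(table(key))
  um <- as.numeric(vapply(strsplit(names(table(key)), " "), `[`, "", 1))
  ue <- as.numeric(vapply(strsplit(names(table(key)), " "), `[`, "", 2))
  shapes <- exp(seq(log(lo), log(hi), length.out = n_grid))
  ll <- matrix(0, n_grid, n_grid)  # rows alpha, cols beta
  A <- matrix(shapes, n_grid, n_grid)
  B <- matrix(shapes, n_grid, n_grid, byrow = TRUE)
  lden <- lbeta(A, B)
  for (j in seq_along(um)) {
    lp <- lchoose(ue[j], um[j]) + lbeta(A + um[j], B + ue[j] - um[j]) - lden
    if (conditioning == "observed") {
      p0 <- exp(lbeta(A, B + ue[j]) - lden)
      pe <- exp(lbeta(A + ue[j], B) - lden)
      lp <- lp - log(pmax(1 - p0 - pe, 1e-300))
    }
    ll <- ll + w[j] * lp
  }
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  list(alpha = shapes[best[1]], beta = shapes[best[2]], max_ll = max(ll))
}
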