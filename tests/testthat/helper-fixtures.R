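# Builders for in-memory fixtures and independent numerical oracles.

make_wells <- function(n_live, n_added = 10, n_progeny = 0,
                       treatment_id = "T1", species = "C_elegans",
                       trial_id = "t1", n_dead = 0, duration_h = 96) {
  n <- length(n_live)
  data.frame(
    well_id = sprintf("w%03d", seq_len(n)),
    treatment_id = rep_len(treatment_id, n),
    species = rep_len(species, n),
    trial_id = rep_len(trial_id, n),
    n_added = rep_len(n_added, n),
    n_live_adults = n_live,
    n_dead = rep_len(n_dead, n),
    n_progeny = rep_len(n_progeny, n),
    duration_h = rep_len(duration_h, n),
    stringsAsFactors = FALSE)
}

# Ordinary least squares by explicit normal equations; independent of the
# lm.fit path used by the package. Columns are equilibrated to unit norm
# before solving (an exact reparametrization; polynomial designs in
# concentrations up to ~10^4 are otherwise numerically singular).
normal_equations <- function(X, y) {
  d <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, d, "/")
  as.numeric(solve(t(Xs) %*% Xs, t(Xs) %*% y) / d)
}

# Smallest positive root by sign-change scan: coarse bracket, then an
# exhaustive fine grid (step `step`) inside the bracket; returns the
# midpoint of the fine sign change. Independent of uniroot.
grid_root <- function(f, upper, step = 1e-4, coarse_n = 1e5) {
  xs <- seq(upper / coarse_n, upper, length.out = coarse_n)
  fx <- f(xs)
  i <- which(fx[-1] * fx[-length(fx)] <= 0)
  if (length(i) == 0) return(NA_real_)
  lo <- xs[i[1]]; hi <- xs[i[1] + 1]
  fine <- seq(lo, hi, by = step)
  ff <- f(fine)
  j <- which(ff[-1] * ff[-length(ff)] <= 0)[1]
  (fine[j] + fine[j + 1]) / 2
}

# Letter-display invariant: groups share a letter iff their pairwise
# difference is non-significant.
cld_invariant_holds <- function(p_matrix, letters_out, alpha = 0.05) {
  m <- attr(letters_out, "membership")
  g <- rownames(p_matrix)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i >= j) next
    share <- any(m[i, ] & m[j, ])
    sig <- p_matrix[i, j] <= alpha
    if (share == sig) return(FALSE)
  }
  TRUE
}

random_p_matrix <- function(k) {
  p <- matrix(NA_real_, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  vals <- stats::runif(k * (k - 1) / 2)
  p[upper.tri(p)] <- vals
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  p
}
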