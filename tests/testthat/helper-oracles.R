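# Independent oracles used across the suite.

# Brute-force Gamma GLM: generic numerical maximization of the same
# likelihood over (coefficients, log shape), independent of the IRLS path.
brute_force_gamma_fit <- function(y, X) {
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    shape <- exp(par[length(par)])
    mu <- exp(drop(X %*% beta))
    if (!all(is.finite(mu)) || any(mu <= 0) || !is.finite(shape) ||
        shape <= 0) return(1e12)
    ll <- gamma_loglik(y, mu, shape)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  init <- c(stats::coef(stats::lm(log(y) ~ X - 1)), 0)
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  list(coefficients = opt$par[seq_len(ncol(X))],
       shape = exp(opt$par[length(opt$par)]),
       loglik = -opt$value)
}

# Does a letter assignment satisfy the CLD property: two levels share a
# letter iff their p-value exceeds alpha?
cld_valid <- function(letter_strings, p_matrix, alpha) {
  k <- length(letter_strings)
  sets <- strsplit(letter_strings, "")
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    share <- length(intersect(sets[[i]], sets[[j]])) > 0
    if (share != (p_matrix[i, j] > alpha)) return(FALSE)
  }
  all(lengths(sets) > 0)
}

# Exhaustive minimal CLD oracle: the minimum number of letters is the
# minimum number of cliques of the non-significance graph that cover all
# its edges and all vertices. Feasible for k <= 5.
min_cld_letters <- function(p_matrix, alpha) {
  k <- nrow(p_matrix)
  adj <- p_matrix > alpha
  diag(adj) <- TRUE
  subsets <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(k, sz, simplify = FALSE)), recursive = FALSE)
  is_clique <- vapply(subsets, function(s)
    all(adj[s, s, drop = FALSE]), TRUE)
  cliques <- subsets[is_clique]
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  covers <- function(chosen) {
    cl <- cliques[chosen]
    vert_ok <- all(seq_len(k) %in% unlist(cl))
    if (!vert_ok) return(FALSE)
    if (nrow(edges) == 0) return(TRUE)
    all(apply(edges, 1, function(e)
      any(vapply(cl, function(s) all(e %in% s), TRUE))))
  }
  for (r in seq_along(cliques)) {
    for (chosen in utils::combn(length(cliques), r, simplify = FALSE)) {
      if (covers(chosen)) return(r)
    }
  }
  stop("no cover found")  # unreachable: singletons always cover
}

# All significance patterns on k levels, as symmetric p matrices with
# entries 0.01 (significant) or 0.5 (not), at alpha = 0.05.
all_p_matrices <- function(k) {
  npair <- choose(k, 2)
  pairs <- utils::combn(k, 2)
  lapply(seq_len(2^npair) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npair)]
    p <- matrix(0.5, k, k)
    for (m in seq_len(npair)) if (bits[m] == 1L)
      p[pairs[1, m], pairs[2, m]] <- p[pairs[2, m], pairs[1, m]] <- 0.01
    p
  })
}

# Small deterministic fixture dataset from the generator defaults.
fixture_data <- function(n = 12, seed = 42)
  simulate_dataset(sim_config(n = n, seed = seed))
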