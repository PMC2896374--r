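# Independent oracles and small fixture builders shared by the tests.
# The oracles deliberately use naive explicit formulas (matrix inverses,
# direct clade enumeration) so they share no code path with the package.

# Explicit-inverse GLS: beta = (X'V^-1 X)^-1 X'V^-1 y, ML sigma2, and the
# multivariate-normal log-likelihood, all via solve() and det().
gls_oracle <- function(y, X, V) {
  X <- as.matrix(X)
  n <- length(y)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / n
  ll <- -0.5 * n * log(2 * pi * sigma2) -
    0.5 * determinant(V, logarithm = TRUE)$modulus - 0.5 * n
  list(beta = drop(beta), sigma2 = sigma2, log_likelihood = as.numeric(ll))
}

# Classical OLS R^2 via lm(), used to check the whitened-space r-squared
# in the identity-covariance limit.
ols_r2_oracle <- function(y, X) {
  d <- as.data.frame(X[, -1, drop = FALSE])
  summary(stats::lm(y ~ ., data = d))$r.squared
}

# Brute-force clade frequencies of a rooted tree sample using
# ape::prop.part (an implementation independent of the package's
# consensus machinery). Returns a named numeric vector: canonical
# comma-joined sorted tip sets -> sample frequency.
clade_freq_oracle <- function(trees) {
  trees <- unclass(trees)
  n <- length(trees)
  tab <- new.env(parent = emptyenv())
  for (tr in trees) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    for (s in pp) {
      key <- paste(sort(labs[s]), collapse = ",")
      tab[[key]] <- (if (is.null(tab[[key]])) 0 else tab[[key]]) + 1
    }
  }
  out <- vapply(ls(tab), function(k) tab[[k]], 0) / n
  out
}

# Random small tree with branch lengths, for property tests.
random_tree <- function(n_tips, seed = NULL) {
  simulate_yule_tree(n_tips, birth_rate = 1, seed = seed)
}

# A tiny fixed 4-taxon balanced tree used across tests.
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
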