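# Seeded synthetic data with the exact statistical structure the
# comparative analysis assumes: Yule (pure-birth) trees, Brownian-
# motion tip traits under a lambda-transformed covariance, binary and
# ordinal predictors, and perturbed tree samples for consensus tests.
#
# Random-number contract: every simulator takes an integer seed and
# uses R's default Mersenne-Twister stream; a dataset-level root seed
# fans out to independent per-component sub-seeds (tree, predictors,
# noise) so changing one component's model does not perturb the others.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

substream_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(2147483646L, n)))
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starting from a root split into two lineages at time zero, waiting
#' times between speciation events are exponential with rate (number of
#' extant lineages) x \code{birth_rate}, the splitting lineage is chosen
#' uniformly, and after the n-th lineage appears one further waiting
#' time elapses before the present. The result is rooted and
#' ultrametric with expected depth \eqn{\sum_{k=2}^{n} 1/(k\,b)}.
#'
#' @param n_tips Number of leaves (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @return An ultrametric \code{phylo} tree with leaves
#'   \code{t1..tn}.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(is.numeric(n_tips), length(n_tips) == 1L, n_tips >= 2,
            n_tips == round(n_tips),
            is.numeric(birth_rate), length(birth_rate) == 1L, birth_rate > 0)
  n_tips <- as.integer(n_tips)
  with_seed(seed, {
    # node bookkeeping in creation order; node 0 is the root
    parent <- c(0L, 0L)          # parent of node i
    tstart <- c(0, 0)            # time the edge above node i begins
    split_time <- c(NA_real_, NA_real_)
    active <- c(1L, 2L)
    t <- 0
    cnt <- 2L
    while (length(active) < n_tips) {
      kk <- length(active)
      t <- t + stats::rexp(1L, kk * birth_rate)
      i <- active[sample.int(kk, 1L)]
      split_time[i] <- t
      parent <- c(parent, i, i)
      tstart <- c(tstart, t, t)
      split_time <- c(split_time, NA_real_, NA_real_)
      active <- c(setdiff(active, i), cnt + 1L, cnt + 2L)
      cnt <- cnt + 2L
    }
    t_end <- t + stats::rexp(1L, n_tips * birth_rate)
    is_tip <- is.na(split_time)
    end_time <- ifelse(is_tip, t_end, split_time)
    tips <- sort(which(is_tip))
    internals <- sort(which(!is_tip))
    # phylo numbering: tips 1..n, root n+1, then internal nodes
    id <- integer(cnt + 1L)       # index shifted by 1 so root (0) fits
    id[1L] <- n_tips + 1L         # root
    id[tips + 1L] <- seq_len(n_tips)
    if (length(internals)) id[internals + 1L] <- n_tips + 1L + seq_along(internals)
    edge <- cbind(id[parent + 1L], id[seq_len(cnt) + 1L])
    tr <- list(edge = edge,
               edge.length = end_time - tstart,
               tip.label = paste0("t", seq_len(n_tips)),
               Nnode = n_tips - 1L)
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    tr
  })
}

# lower-triangular factor of a covariance matrix; Cholesky with an
# eigenvalue fallback for PSD-but-singular matrices
cov_factor <- function(V, tol = 1e-10) {
  f <- try(t(chol(V)), silent = TRUE)
  if (!inherits(f, "try-error")) return(f)
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1)) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(V))
}

#' Simulate Brownian-motion tip traits on a tree
#'
#' One draw from a zero-mean multivariate normal whose covariance is
#' \code{sigma2} times the lambda-transformed phylogenetic covariance
#' of the tree. Draws use a Cholesky factor; positive semi-definite but
#' singular covariances (e.g. duplicated tips) fall back to an
#' eigen-decomposition with negative eigenvalues clipped at zero
#' (tolerance 1e-10).
#'
#' @param tree A \code{phylo} tree with branch lengths.
#' @param lambda Pagel's lambda in [0, 1] applied to the covariance.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_bm_traits <- function(tree, lambda = 1, sigma2 = 1, seed = NULL) {
  stopifnot(sigma2 > 0, lambda >= 0, lambda <= 1)
  V <- sigma2 * lambda_transform(vcv_matrix(tree), lambda)
  L <- cov_factor(V)
  with_seed(seed, {
    x <- drop(L %*% stats::rnorm(nrow(V)))
    names(x) <- rownames(V)
    x
  })
}

#' Simulate a full regression dataset with known truth
#'
#' Generates a Yule tree, tip predictors shaped like the auk/penguin
#' table (an ordinal clutch size coded 1/2 and three binary 0/1
#' predictors), and a continuous response
#' \eqn{y = X\beta + \epsilon,\; \epsilon \sim N(0, \sigma^2
#' V_\lambda)} with Brownian noise on the lambda-transformed tree
#' covariance. The generating parameters are returned as a truth
#' record for recovery scoring.
#'
#' By default predictors are drawn independently of the tree; with
#' \code{phylo_predictors = TRUE} each predictor is instead obtained by
#' thresholding a latent Brownian trait at its median, giving
#' phylogenetically clumped predictors like the real data.
#'
#' @param n_tips Number of species.
#' @param birth_rate Yule speciation rate.
#' @param true_lambda Generating Pagel's lambda in [0, 1].
#' @param true_beta Coefficients (intercept, clutch_size, foraging,
#'   activity, nest).
#' @param sigma2 Brownian rate of the residual noise.
#' @param predictor_probs Probabilities: \code{clutch2} (clutch of 2)
#'   and Bernoulli-1 probabilities for \code{foraging},
#'   \code{activity}, \code{nest}.
#' @param phylo_predictors Use threshold-Brownian (phylogenetically
#'   autocorrelated) predictors instead of independent draws.
#' @param seed Integer root seed; fans out to tree/predictor/noise
#'   sub-streams.
#' @return A list with \code{tree}, \code{traits} (data frame:
#'   species, y, clutch_size, foraging, activity, nest) and
#'   \code{truth} (the generating parameters).
#' @export
simulate_regression_dataset <- function(n_tips = 33,
                                        birth_rate = 1,
                                        true_lambda = 1,
                                        true_beta = c(0, -8, 2, -3.5, -4),
                                        sigma2 = 10,
                                        predictor_probs = list(clutch2 = 0.5,
                                                               foraging = 0.5,
                                                               activity = 0.5,
                                                               nest = 0.5),
                                        phylo_predictors = FALSE,
                                        seed = NULL) {
  stopifnot(length(true_beta) == 5L, sigma2 > 0,
            true_lambda >= 0, true_lambda <= 1)
  seeds <- substream_seeds(seed, 3L)
  tree <- simulate_yule_tree(n_tips, birth_rate, seeds[[1]])
  pnames <- c("clutch_size", "foraging", "activity", "nest")
  probs <- c(predictor_probs$clutch2, predictor_probs$foraging,
             predictor_probs$activity, predictor_probs$nest)
  draw_predictors <- function() {
    if (phylo_predictors) {
      cols <- lapply(seq_along(pnames), function(j) {
        z <- drop(cov_factor(vcv_matrix(tree)) %*% stats::rnorm(n_tips))
        as.integer(z > stats::median(z))
      })
    } else {
      cols <- lapply(probs, function(p) stats::rbinom(n_tips, 1L, p))
    }
    m <- do.call(cbind, cols)
    colnames(m) <- pnames
    m[, "clutch_size"] <- m[, "clutch_size"] + 1L  # coded 1/2
    m
  }
  P <- with_seed(seeds[[2]], {
    for (attempt in seq_len(100L)) {
      m <- draw_predictors()
      if (all(apply(m, 2, function(col) length(unique(col)) > 1L))) break
      m <- NULL
    }
    if (is.null(m)) {
      stop("degenerate predictor after 100 resampling attempts", call. = FALSE)
    }
    m
  })
  X <- cbind("(Intercept)" = 1, P)
  eps <- simulate_bm_traits(tree, true_lambda, sigma2, seeds[[3]])
  y <- drop(X %*% true_beta) + eps[tree$tip.label]
  traits <- data.frame(species = tree$tip.label, y = unname(y),
                       P, stringsAsFactors = FALSE)
  list(tree = tree, traits = traits,
       truth = list(n_tips = n_tips, birth_rate = birth_rate,
                    true_lambda = true_lambda, true_beta = true_beta,
                    sigma2 = sigma2, predictor_probs = predictor_probs,
                    phylo_predictors = phylo_predictors, seed = seed))
}

#' Write a simulated dataset to disk
#'
#' Emits the trait table in the same tab-delimited format the pipeline
#' consumes plus a sidecar key-value truth file with the generating
#' parameters.
#'
#' @param sim Output of [simulate_regression_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traits_path <- file.path(dir, "traits.tsv")
  tree_path <- file.path(dir, "tree.nwk")
  truth_path <- file.path(dir, "truth.txt")
  utils::write.table(sim$traits, traits_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(write_newick(sim$tree), tree_path)
  tr <- sim$truth
  writeLines(c(
    sprintf("n_tips: %d", tr$n_tips),
    sprintf("birth_rate: %s", format(tr$birth_rate)),
    sprintf("true_lambda: %s", format(tr$true_lambda)),
    sprintf("true_beta: %s", paste(format(tr$true_beta), collapse = " ")),
    sprintf("sigma2: %s", format(tr$sigma2)),
    sprintf("phylo_predictors: %s", tr$phylo_predictors),
    sprintf("seed: %s", if (is.null(tr$seed)) "NA" else format(tr$seed))
  ), truth_path)
  invisible(c(traits_path, tree_path, truth_path))
}

# one nearest-neighbour interchange at edge (u, v): swap a random child
# of v with a random sibling of v
nni_at <- function(tree, u, v) {
  kids_v <- tree$edge[tree$edge[, 1] == v, 2]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
  if (!length(kids_v) || !length(sibs)) return(tree)
  c1 <- kids_v[sample.int(length(kids_v), 1L)]
  s1 <- sibs[sample.int(length(sibs), 1L)]
  tree$edge[tree$edge[, 2] == c1, 1] <- u
  tree$edge[tree$edge[, 2] == s1, 1] <- v
  tree
}

#' Simulate a sample of perturbed trees
#'
#' Produces \code{n_trees} copies of a base tree, each internal edge of
#' each copy independently subjected to a nearest-neighbour interchange
#' with probability \code{perturb_prob}. Used to exercise the
#' majority-rule consensus: for small perturbation probabilities every
#' base-tree clade keeps a sample frequency above one half.
#'
#' @param base_tree A rooted \code{phylo} tree (>= 4 leaves if
#'   \code{perturb_prob > 0}).
#' @param n_trees Number of trees to generate (>= 1).
#' @param perturb_prob Per-internal-edge NNI probability in [0, 1].
#' @param seed Optional integer seed.
#' @return A \code{multiPhylo} sample.
#' @export
simulate_tree_sample <- function(base_tree, n_trees, perturb_prob = 0,
                                 seed = NULL) {
  validate_tree(base_tree)
  stopifnot(n_trees >= 1, perturb_prob >= 0, perturb_prob <= 1)
  if (perturb_prob > 0 && length(base_tree$tip.label) < 4L) {
    stop("need at least 4 leaves to perturb a tree by NNI", call. = FALSE)
  }
  ntip <- length(base_tree$tip.label)
  with_seed(seed, {
    out <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      tr <- base_tree
      if (perturb_prob > 0) {
        # internal edges: both endpoints internal
        internal <- which(tr$edge[, 2] > ntip)
        for (r in internal) {
          if (stats::runif(1) < perturb_prob) {
            tr <- nni_at(tr, tr$edge[r, 1], tr$edge[r, 2])
          }
        }
        attr(tr, "order") <- NULL  # edge rows were rewired in place
        tr <- ape::reorder.phylo(tr, "cladewise")
      }
      out[[i]] <- tr
    }
    class(out) <- "multiPhylo"
    out
  })
}
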