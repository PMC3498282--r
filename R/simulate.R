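# Seeded generators for synthetic trees and alignments with the statistical
# structure the diversification analysis assumes.  All generators are
# crown-conditioned: the process starts with two lineages at the crown, so
# the oldest branching time equals the crown age.  Conditioning on a tip
# count uses simple rejection (adequate at desk scale; can be biased for
# extreme parameters -- see the package vignette).

#' Inter-node waiting times and ages of a crown-conditioned pure-birth tree
#'
#' Draws the durations d_i ~ Exp(i * lambda) for i = 2..n-1 (each ending in
#' a speciation event) plus a censored final interval d_n ~ Exp(n * lambda)
#' with n lineages, and returns the node ages measured backward from the
#' present.  This is the exact generative counterpart of the pure-birth
#' likelihood used by the model fits.
#'
#' @param n_tips Number of extant tips, >= 3.
#' @param lambda Speciation rate, > 0.
#' @return Numeric vector of n_tips - 1 ages, decreasing; first element is
#'   the crown age.
#' @export
sim_yule_ages <- function(n_tips, lambda) {
  if (n_tips < 3L) stop("'n_tips' must be >= 3")
  .check_rate(lambda, "lambda")
  d <- stats::rexp(n_tips - 1L, rate = (2:n_tips) * lambda)
  rev(cumsum(rev(d)))
}

# Assemble a binary ultrametric phylo from decreasing event ages
# (ages[1] = crown).  At each event a uniformly chosen extant lineage
# splits.  Node ids: tips 1..n, internals n+1..2n-1 in order of decreasing
# age (root = n+1), matching ape conventions.
.tree_from_event_ages <- function(ages) {
  n <- length(ages) + 1L
  parent <- integer(0)
  child <- integer(0)
  length_ <- numeric(0)
  # "open" lineages: parent internal node id and its age
  open_parent <- c(n + 1L, n + 1L)
  open_age <- c(ages[1L], ages[1L])
  next_internal <- n + 2L
  if (n > 2L) {
    for (k in 2:(n - 1L)) {
      j <- sample.int(length(open_parent), 1L)
      node <- next_internal
      next_internal <- next_internal + 1L
      parent <- c(parent, open_parent[j])
      child <- c(child, node)
      length_ <- c(length_, open_age[j] - ages[k])
      open_parent <- c(open_parent[-j], node, node)
      open_age <- c(open_age[-j], ages[k], ages[k])
    }
  }
  # remaining open lineages become tips at age 0
  tip_ids <- seq_len(n)
  parent <- c(parent, open_parent)
  child <- c(child, tip_ids)
  length_ <- c(length_, open_age)
  tree <- list(edge = cbind(parent, child, deparse.level = 0),
               edge.length = length_,
               tip.label = paste0("t", tip_ids),
               Nnode = n - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Simulate a crown-conditioned pure-birth (Yule) tree
#'
#' Exponential waiting times with rate i * lambda while i lineages exist; a
#' uniformly chosen lineage splits at each event.  Either condition on the
#' number of extant tips (`n_tips`) or run the process over a fixed crown
#' age (`crown_age`), in which case the tip count is random.
#'
#' @param n_tips Number of extant tips (>= 3); exactly one of `n_tips` and
#'   `crown_age` must be given.
#' @param lambda Speciation rate, > 0.
#' @param crown_age Fixed crown age (time-stopped variant).
#' @param seed Optional integer seed for reproducibility.
#' @return An ultrametric `"phylo"` object.
#' @export
#' @examples
#' tr <- simulate_yule(n_tips = 10, lambda = 0.2, seed = 1)
#' check_ultrametric(tr)
simulate_yule <- function(n_tips = NULL, lambda, crown_age = NULL, seed = NULL) {
  .check_rate(lambda, "lambda")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_tips) == is.null(crown_age))
    stop("give exactly one of 'n_tips' or 'crown_age'")
  if (!is.null(n_tips)) {
    ages <- sim_yule_ages(n_tips, lambda)
  } else {
    if (crown_age <= 0) stop("'crown_age' must be positive")
    # forward pass over a fixed window; number of events random
    t <- 0
    i <- 2L
    ev <- numeric(0)
    repeat {
      w <- stats::rexp(1L, rate = i * lambda)
      if (t + w >= crown_age) break
      t <- t + w
      ev <- c(ev, t)
      i <- i + 1L
    }
    if (length(ev) < 1L)
      return(simulate_yule(crown_age = crown_age, lambda = lambda))
    ages <- c(crown_age, crown_age - ev)
  }
  .tree_from_event_ages(ages)
}

#' Simulate a reconstructed constant-rate birth-death tree
#'
#' Forward simulation with speciation rate `lambda` and extinction rate
#' `mu < lambda`, starting from two crown lineages.  Histories that go
#' extinct are rejected and the process restarted; the simulation stops
#' when the extant count first reaches `n_tips`, followed by a censored
#' waiting interval, and extinct lineages are pruned to give the
#' reconstructed ultrametric tree.
#'
#' @param n_tips Number of surviving tips, >= 3.
#' @param lambda Speciation rate, > 0.
#' @param mu Extinction rate, `0 <= mu < lambda`.
#' @param seed Optional integer seed.
#' @param max_tries Rejection cap; exceeding it (acceptance below ~1e-4)
#'   raises an error advising a parameter change.
#' @return An ultrametric `"phylo"` object with `n_tips` tips.
#' @export
simulate_birth_death <- function(n_tips, lambda, mu, seed = NULL,
                                 max_tries = 10000L) {
  .check_rate(lambda, "lambda")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0 || mu >= lambda)
    stop("'mu' must satisfy 0 <= mu < lambda")
  if (n_tips < 3L) stop("'n_tips' must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    res <- .sim_bd_once(n_tips, lambda, mu)
    if (!is.null(res)) return(res)
  }
  stop("birth-death rejection sampling failed after ", max_tries,
       " tries; acceptance rate is too low -- reduce mu/lambda or n_tips")
}

# One forward birth-death attempt; NULL on extinction.
.sim_bd_once <- function(n_tips, lambda, mu) {
  # lineage bookkeeping: parent node id (0 = root child), birth time, alive
  parent <- c(0L, 0L)
  birth <- c(0, 0)
  alive <- c(TRUE, TRUE)
  # per-lineage records for tree assembly: each lineage either splits
  # (becomes internal), dies (extinct tip) or survives (extant tip)
  end_time <- c(NA_real_, NA_real_)
  children <- vector("list", 2L)
  t <- 0
  repeat {
    k <- sum(alive)
    if (k == 0L) return(NULL)
    if (k == n_tips) break
    t <- t + stats::rexp(1L, rate = k * (lambda + mu))
    idx <- which(alive)
    j <- idx[sample.int(length(idx), 1L)]
    if (stats::runif(1L) < lambda / (lambda + mu)) {
      m <- length(parent)
      parent <- c(parent, j, j)
      birth <- c(birth, t, t)
      alive[j] <- FALSE
      alive <- c(alive, TRUE, TRUE)
      end_time[j] <- t
      end_time <- c(end_time, NA_real_, NA_real_)
      children[[j]] <- c(m + 1L, m + 2L)
      children <- c(children, vector("list", 2L))
    } else {
      alive[j] <- FALSE
      end_time[j] <- t
      children[j] <- list(NULL)   # extinct tip
    }
  }
  present <- t + stats::rexp(1L, rate = n_tips * (lambda + mu))
  end_time[alive] <- present
  .bd_assemble(parent, birth, end_time, children, alive, present)
}

# Build the reconstructed tree: Newick assembled recursively over surviving
# lineages only, with unary pass-throughs collapsed by branch summation.
.bd_assemble <- function(parent, birth, end_time, children, alive, present) {
  survives <- logical(length(parent))
  ord <- order(birth, decreasing = TRUE)   # children before parents
  for (j in ord) {
    kids <- children[[j]]
    survives[j] <- if (is.null(kids)) alive[j] else any(survives[kids])
  }
  tip_counter <- new.env()
  tip_counter$i <- 0L
  subtree <- function(j, stem_top) {
    # stem_top: time at which the edge leading to lineage j starts
    kids <- children[[j]]
    if (is.null(kids)) {
      tip_counter$i <- tip_counter$i + 1L
      return(sprintf("t%d:%.12g", tip_counter$i, end_time[j] - stem_top))
    }
    sk <- kids[survives[kids]]
    if (length(sk) == 2L) {
      sprintf("(%s,%s):%.12g",
              subtree(sk[1L], end_time[j]), subtree(sk[2L], end_time[j]),
              end_time[j] - stem_top)
    } else {
      subtree(sk, stem_top)  # collapse unary node, lengths summed
    }
  }
  roots <- which(parent == 0L & survives)
  if (length(roots) == 2L) {
    nwk <- sprintf("(%s,%s);", subtree(roots[1L], 0), subtree(roots[2L], 0))
  } else {
    # crown lineage died out: reconstructed root is deeper inside one side;
    # strip the root-edge remnant by re-rooting at the first surviving split
    nwk <- sprintf("%s;", sub(":[0-9.eE+-]+$", "", subtree(roots, 0)))
  }
  tr <- ape::read.tree(text = nwk)
  tr$root.edge <- NULL
  tr
}

#' Simulate a crown-conditioned two-rate pure-birth tree
#'
#' Pure birth over a fixed crown-age window with per-lineage rate `r1` for
#' ages older than `shift_age` and `r2` for younger ages.  The tip count is
#' conditioned on `n_tips` by rejection over the fixed window (a fixed
#' observation window is what makes a shift at a given age before the
#' present well defined).
#'
#' @param n_tips Number of extant tips, >= 3.
#' @param r1 Rate in the old phase (ages > `shift_age`), > 0.
#' @param r2 Rate in the recent phase, > 0.
#' @param shift_age Age of the rate shift, inside (0, `crown_age`).
#' @param crown_age Crown age of the simulated tree, > 0.
#' @param seed Optional integer seed.
#' @param max_tries Rejection cap.
#' @return An ultrametric `"phylo"` object.
#' @export
simulate_rate_shift <- function(n_tips, r1, r2, shift_age, crown_age,
                                seed = NULL, max_tries = 200000L) {
  .check_rate(r1, "r1"); .check_rate(r2, "r2")
  if (n_tips < 3L) stop("'n_tips' must be >= 3")
  if (!is.numeric(crown_age) || crown_age <= 0) stop("'crown_age' must be positive")
  if (!is.numeric(shift_age) || shift_age <= 0 || shift_age >= crown_age)
    stop("'shift_age' must lie strictly inside (0, crown_age)")
  if (!is.null(seed)) set.seed(seed)
  t_shift <- crown_age - shift_age    # forward time of the shift
  for (try in seq_len(max_tries)) {
    t <- 0
    k <- 2L
    ev <- numeric(0)
    repeat {
      rate_now <- if (t < t_shift) r1 else r2
      w <- stats::rexp(1L, rate = k * rate_now)
      if (t < t_shift && t + w > t_shift) { t <- t_shift; next }  # memoryless restart
      t <- t + w
      if (t >= crown_age) break
      ev <- c(ev, t)
      k <- k + 1L
      if (k > n_tips) break
    }
    if (k == n_tips && t >= crown_age)
      return(.tree_from_event_ages(c(crown_age, crown_age - ev)))
  }
  stop("rate-shift rejection sampling failed after ", max_tries,
       " tries; the requested (rates, crown_age, n_tips) combination is too unlikely")
}

#' Simulate a nucleotide alignment along a dated tree under HKY(+Gamma)
#'
#' Sequences evolve along the tree by HKY85 transition probabilities
#' (transition/transversion parameter `kappa`, stationary `base_freqs`),
#' with expected `rate_per_unit` substitutions per site per unit branch
#' length.  Optional among-site rate variation uses a discrete (4-category)
#' gamma approximation with shape `gamma_alpha`.  The root sequence is
#' drawn from `base_freqs`.  Simulation is delegated to
#' [phangorn::simSeq()].
#'
#' @param tree A `"phylo"` object with branch lengths in time units.
#' @param length Number of sites, >= 1.
#' @param kappa Transition/transversion rate parameter, > 0.
#' @param base_freqs Stationary frequencies (A, C, G, T), non-negative,
#'   summing to 1.
#' @param gamma_alpha Optional gamma shape for among-site rate variation.
#' @param rate_per_unit Expected substitutions per site per unit branch
#'   length (>= 0; 0 returns identical rows).
#' @param seed Optional integer seed.
#' @return A character matrix (taxa x sites) of upper-case bases, class
#'   `"alignment"`.
#' @export
simulate_alignment <- function(tree, length, kappa = 2, base_freqs = rep(0.25, 4),
                               gamma_alpha = NULL, rate_per_unit = 1,
                               seed = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (length < 1L) stop("'length' must be >= 1")
  .check_rate(kappa, "kappa")
  if (length(base_freqs) != 4L || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-8)
    stop("'base_freqs' must be 4 non-negative values summing to 1")
  if (rate_per_unit < 0) stop("'rate_per_unit' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- tree
  tr$edge.length <- tr$edge.length * rate_per_unit
  Q <- c(1, kappa, 1, 1, kappa, 1)  # AC, AG, AT, CG, CT, GT
  if (is.null(gamma_alpha)) {
    sim <- phangorn::simSeq(tr, l = length, Q = Q, bf = base_freqs, type = "DNA")
  } else {
    if (gamma_alpha <= 0) stop("'gamma_alpha' must be positive")
    rates <- phangorn::discrete.gamma(gamma_alpha, 4L)
    cat_of <- sample.int(4L, length, replace = TRUE)
    parts <- lapply(1:4, function(cc) {
      nn <- sum(cat_of == cc)
      if (nn == 0L) return(NULL)
      as.character(phangorn::simSeq(tr, l = nn, Q = Q, bf = base_freqs,
                                    type = "DNA", rate = rates[cc]))
    })
    parts <- Filter(Negate(is.null), parts)
    m <- do.call(cbind, parts)
    return(.as_alignment(toupper(m)))
  }
  .as_alignment(toupper(as.character(sim)))
}

.as_alignment <- function(m) {
  stopifnot(is.matrix(m))
  structure(m, class = c("alignment", class(m)))
}
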