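# Pairwise distance matrices (uncorrected and HKY85 maximum likelihood)
# with group summaries, alignment variability statistics, and the global
# molecular-clock likelihood-ratio test.

.VALID_BASES <- c("A", "C", "G", "T")

# Coerce a sequence argument to an upper-case character vector of symbols.
.seq_chars <- function(s) {
  if (is.character(s) && length(s) == 1L) s <- strsplit(s, "", fixed = TRUE)[[1]]
  toupper(as.character(s))
}

#' Uncorrected (p) distance between two aligned sequences
#'
#' Proportion of mismatching sites among sites where both sequences carry an
#' unambiguous base; sites with a gap or ambiguity code in either sequence
#' are excluded (pairwise deletion).
#'
#' @param seq_a,seq_b Aligned sequences of equal length, as single strings
#'   or character vectors of symbols.
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' p_distance("ACGT", "ACGA")   # 0.25
#' p_distance("AC-T", "ACGA")   # 1/3 (gap site excluded)
p_distance <- function(seq_a, seq_b) {
  a <- .seq_chars(seq_a); b <- .seq_chars(seq_b)
  if (length(a) != length(b))
    stop("sequences have different lengths (", length(a), " vs ", length(b), ")")
  ok <- a %in% .VALID_BASES & b %in% .VALID_BASES
  if (!any(ok)) stop("no comparable sites between the two sequences")
  mean(a[ok] != b[ok])
}

# 4x4 pair-count matrix over unambiguous sites (rows seq_a, cols seq_b).
.pair_counts <- function(a, b) {
  ok <- a %in% .VALID_BASES & b %in% .VALID_BASES
  table(factor(a[ok], .VALID_BASES), factor(b[ok], .VALID_BASES))
}

# HKY85 rate matrix scaled to one expected substitution per unit time.
.hky_q <- function(kappa, pi) {
  s <- matrix(1, 4, 4)
  s[1, 3] <- s[3, 1] <- kappa  # A<->G
  s[2, 4] <- s[4, 2] <- kappa  # C<->T
  Q <- s * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Transition probabilities exp(Q d) via eigendecomposition (Q is
# diagonalisable for any valid HKY parameters).
.hky_p <- function(eig, d) {
  P <- Re(eig$vectors %*% (exp(eig$values * d) * eig$inv))
  P[P < 0] <- 0
  P
}

#' HKY85 maximum-likelihood distance between two aligned sequences
#'
#' The expected number of substitutions per site under the HKY85 model,
#' maximising the pairwise likelihood over the distance and (by default)
#' the transition/transversion parameter kappa jointly.  Base frequencies
#' default to the empirical frequencies of the pair.  No among-site rate
#' variation is applied (a per-pair gamma shape is not identifiable; fix
#' `gamma_alpha` to impose one).
#'
#' Saturated pairs, for which the likelihood keeps increasing as the
#' distance grows without bound, are reported as `NA` with attribute
#' `saturated = TRUE` rather than as a fabricated large number.
#'
#' @param seq_a,seq_b Aligned sequences of equal length.
#' @param kappa Fixed transition/transversion parameter, or `NULL` (default)
#'   to estimate it by ML jointly with the distance.
#' @param base_freqs Stationary frequencies (A, C, G, T), or `NULL` for the
#'   empirical frequencies of the pair.
#' @param gamma_alpha Optional gamma shape; rates are then integrated over a
#'   discrete 4-category approximation.
#' @param max_distance Upper search bound (substitutions/site); optima at
#'   the bound are treated as saturated.
#' @return Distance in substitutions per site, or `NA` for saturated pairs.
#' @export
hky_distance <- function(seq_a, seq_b, kappa = NULL, base_freqs = NULL,
                         gamma_alpha = NULL, max_distance = 10) {
  a <- .seq_chars(seq_a); b <- .seq_chars(seq_b)
  if (length(a) != length(b))
    stop("sequences have different lengths (", length(a), " vs ", length(b), ")")
  N <- .pair_counts(a, b)
  if (sum(N) == 0) stop("no comparable sites between the two sequences")
  if (sum(N) == sum(diag(N))) return(0)
  if (is.null(base_freqs)) {
    pi <- (rowSums(N) + colSums(N)) / (2 * sum(N))
    pi <- pmax(pi, 1e-6)
    pi <- pi / sum(pi)
  } else {
    if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
        abs(sum(base_freqs) - 1) > 1e-8)
      stop("'base_freqs' must be 4 positive values summing to 1")
    pi <- base_freqs
  }
  rates <- if (is.null(gamma_alpha)) 1 else phangorn::discrete.gamma(gamma_alpha, 4L)
  lnl_d <- function(d, kap) {
    eig <- .hky_eig(kap, pi)
    P <- 0
    for (r in rates) P <- P + .hky_p(eig, d * r) / length(rates)
    L <- pi * P
    v <- sum(N * log(L))
    if (!is.finite(v)) -1e10 else v
  }
  opt_d <- function(kap)
    stats::optimize(lnl_d, c(1e-9, max_distance), kap = kap,
                    maximum = TRUE, tol = 1e-10)
  if (is.null(kappa)) {
    outer <- stats::optimize(function(lk) opt_d(exp(lk))$objective,
                             c(log(0.02), log(100)), maximum = TRUE,
                             tol = 1e-8)
    kappa <- exp(outer$maximum)
  }
  res <- opt_d(kappa)
  d <- res$maximum
  if (d > max_distance * 0.99)
    return(structure(NA_real_, saturated = TRUE))
  d
}

.hky_eig <- function(kappa, pi) {
  Q <- .hky_q(kappa, pi)
  eig <- eigen(Q)
  list(values = eig$values, vectors = eig$vectors, inv = solve(eig$vectors))
}

#' Pairwise distance matrices with optional group assignment
#'
#' Computes both the uncorrected (p) and the HKY85 ML distance between every
#' pair of sequences in an alignment.
#'
#' @param aln An alignment: character matrix (taxa x sites) with rownames,
#'   or a named character vector of equal-length strings.
#' @param groups Optional named character vector or data frame
#'   (columns `taxon`, `group`) assigning each taxon to a group.
#' @param ... Passed on to [hky_distance()] (e.g. fixed `kappa`).
#' @return An object of class `"distance_matrix"`: list with `labels`,
#'   `uncorrected` and `model_corrected` (symmetric matrices, proportions;
#'   saturated HKY pairs are `NA`), and `group_assignment`.
#' @export
distance_matrix <- function(aln, groups = NULL, ...) {
  m <- .aln_matrix(aln)
  labels <- rownames(m)
  n <- nrow(m)
  unco <- hky <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      unco[i, j] <- unco[j, i] <- p_distance(m[i, ], m[j, ])
      hh <- hky_distance(m[i, ], m[j, ], ...)
      hky[i, j] <- hky[j, i] <- as.numeric(hh)
    }
  }
  ga <- NULL
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      ga <- stats::setNames(as.character(groups$group), as.character(groups$taxon))
    } else ga <- groups
    missing <- setdiff(labels, names(ga))
    if (length(missing))
      stop("no group assignment for: ", paste(missing, collapse = ", "))
    ga <- ga[labels]
  }
  structure(list(labels = labels, uncorrected = unco, model_corrected = hky,
                 group_assignment = ga),
            class = "distance_matrix")
}

.aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else if (is.character(aln)) {
    if (is.null(names(aln))) stop("alignment sequences must be named")
    lens <- nchar(aln)
    if (length(unique(lens)) != 1L)
      stop("alignment rows have unequal lengths: ",
           paste(range(lens), collapse = " to "))
    m <- do.call(rbind, lapply(aln, .seq_chars))
    rownames(m) <- names(aln)
  } else stop("unsupported alignment representation")
  if (nrow(m) < 2L) stop("alignment needs at least 2 sequences")
  if (is.null(rownames(m))) stop("alignment rows must be labelled")
  m
}

#' Within- and between-group mean distances
#'
#' Arithmetic means over unordered pairs (self-pairs excluded), reported as
#' percentages for both the uncorrected and the model-corrected matrices.
#' A singleton group has no within-group pairs; its within-mean is `NA`
#' (flagged, never reported as zero).  Pairs with saturated (NA) corrected
#' distances are dropped from the corrected means.
#'
#' @param dm A `"distance_matrix"` with a group assignment.
#' @return A list with data frames `within` (columns `group`, `n`,
#'   `mean_uncorrected_pct`, `mean_hky_pct`) and `between` (one row per
#'   unordered group pair).
#' @export
group_distance_summary <- function(dm) {
  if (!inherits(dm, "distance_matrix")) stop("'dm' must be a distance_matrix")
  ga <- dm$group_assignment
  if (is.null(ga)) stop("distance matrix carries no group assignment")
  groups <- unique(unname(ga))
  pair_mean <- function(mat, rows, cols) {
    v <- mat[rows, cols, drop = FALSE]
    if (identical(rows, cols)) v <- v[upper.tri(v)]
    100 * mean(v, na.rm = TRUE)
  }
  within <- do.call(rbind, lapply(groups, function(g) {
    idx <- which(ga == g)
    data.frame(group = g, n = length(idx),
               mean_uncorrected_pct = if (length(idx) < 2L) NA_real_ else
                 pair_mean(dm$uncorrected, idx, idx),
               mean_hky_pct = if (length(idx) < 2L) NA_real_ else
                 pair_mean(dm$model_corrected, idx, idx))
  }))
  between <- NULL
  if (length(groups) > 1L) {
    combos <- utils::combn(groups, 2L)
    between <- do.call(rbind, lapply(seq_len(ncol(combos)), function(c_) {
      g1 <- combos[1L, c_]; g2 <- combos[2L, c_]
      i1 <- which(ga == g1); i2 <- which(ga == g2)
      data.frame(group_1 = g1, group_2 = g2,
                 mean_uncorrected_pct = pair_mean(dm$uncorrected, i1, i2),
                 mean_hky_pct = pair_mean(dm$model_corrected, i1, i2))
    }))
  }
  list(within = within, between = between)
}

#' Write a distance matrix in the combined below/above-diagonal layout
#'
#' Uncorrected distances below the diagonal, model-corrected above (both as
#' percentages, 2 decimals), with within-group mean columns appended when a
#' group assignment is present.
#'
#' @param dm A `"distance_matrix"`.
#' @param file Output path (TSV).
#' @export
write_distance_tsv <- function(dm, file) {
  n <- length(dm$labels)
  m <- matrix("", n, n, dimnames = list(dm$labels, dm$labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- if (i > j) dm$uncorrected[i, j] else dm$model_corrected[i, j]
    m[i, j] <- ifelse(is.na(v), "NA", formatC(100 * v, format = "f", digits = 2))
  }
  df <- data.frame(taxon = dm$labels, m, check.names = FALSE)
  if (!is.null(dm$group_assignment)) {
    s <- group_distance_summary(dm)
    w <- s$within[match(dm$group_assignment, s$within$group), ]
    df$within_group_unco <- formatC(w$mean_uncorrected_pct, format = "f", digits = 2)
    df$within_group_hky <- formatC(w$mean_hky_pct, format = "f", digits = 2)
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Alignment variability statistics
#'
#' A site is variable if it shows at least two distinct unambiguous bases;
#' it is parsimony-informative (PI) if at least two states each occur in at
#' least two sequences.  Gaps and ambiguity codes never count as states.
#'
#' @param aln An alignment (see [distance_matrix()] for accepted forms).
#' @return A list with `n_sites`, `variable_sites`, `parsimony_informative`
#'   and `pct_pi` (percentage of all sites).
#' @export
alignment_stats <- function(aln) {
  m <- .aln_matrix(aln)
  variable <- 0L
  pi_count <- 0L
  for (s in seq_len(ncol(m))) {
    tab <- table(m[, s][m[, s] %in% .VALID_BASES])
    if (length(tab) >= 2L) {
      variable <- variable + 1L
      if (sum(tab >= 2L) >= 2L) pi_count <- pi_count + 1L
    }
  }
  list(n_sites = ncol(m), variable_sites = variable,
       parsimony_informative = pi_count,
       pct_pi = 100 * pi_count / ncol(m))
}

#' Global molecular-clock likelihood-ratio test
#'
#' Compares externally computed tree log-likelihoods with and without a
#' rate-constant (clock) constraint: the statistic is
#' `2 * (lnL_free - lnL_clock)`, referred to a chi-square distribution.
#' The degrees of freedom (number of constrained rate parameters) depend on
#' the tree and model and must be supplied; no default is assumed.
#'
#' @param lnL_clock Log-likelihood with the clock enforced.
#' @param lnL_free Log-likelihood without the clock (must be >= `lnL_clock`
#'   up to rounding, as the models are nested).
#' @param df Degrees of freedom, >= 1.
#' @return An object of class `"clock_lrt"`: list with `lnL_clock`,
#'   `lnL_free`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' clock_lrt(-13893, -13767, df = 40)$statistic  # 252
clock_lrt <- function(lnL_clock, lnL_free, df) {
  if (!is.numeric(df) || length(df) != 1L || df < 1)
    stop("'df' must be >= 1")
  if (lnL_free < lnL_clock)
    stop("lnL_free < lnL_clock violates the nesting of the clock model")
  stat <- 2 * (lnL_free - lnL_clock)
  structure(list(lnL_clock = lnL_clock, lnL_free = lnL_free,
                 statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "clock_lrt")
}

#' @export
print.clock_lrt <- function(x, ...) {
  cat(sprintf("Molecular-clock LRT: chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, as.integer(x$df), x$p_value))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Gapped sequences with IUPAC codes are accepted; rows must have equal
#' length.
#'
#' @param path Path to a FASTA file.
#' @return A character matrix (taxa x sites), class `"alignment"`.
#' @export
read_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("FASTA sequences have unequal lengths; not an alignment")
  m <- toupper(as.character(as.matrix(seqs)))
  .as_alignment(m)
}

#' Write an alignment to FASTA
#'
#' @param aln Alignment (character matrix or named strings).
#' @param file Output path.
#' @export
write_fasta <- function(aln, file) {
  m <- .aln_matrix(aln)
  lines <- character(0)
  for (i in seq_len(nrow(m)))
    lines <- c(lines, paste0(">", rownames(m)[i]), paste(m[i, ], collapse = ""))
  writeLines(lines, file)
  invisible(file)
}
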