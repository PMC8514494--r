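#' Exact and approximate Wilcoxon signed-rank test
#'
#' Two-tailed paired signed-rank test. Zero differences are discarded
#' (reducing the effective n) and tied absolute differences receive
#' midranks. For `n <= 25` retained pairs the null distribution of the
#' positive-rank sum is enumerated exactly by dynamic programming over the
#' (mid)ranks, so ties are handled exactly; above that a normal
#' approximation with continuity and tie corrections is used. The
#' two-tailed p-value doubles the smaller tail (capped at 1).
#'
#' @param pre,post Paired measurements, equal length.
#' @param mode `"auto"` (exact up to n = 25), `"exact"` or `"approx"`.
#' @param zeroes `"discard"` (drop zero differences, the default) or
#'   `"pratt"` (rank them, then drop their contribution).
#' @return List with `wPos`, `wNeg`, `n` (retained pairs), `p`, `method`.
#' @examples
#' wilcoxonSignedRank(rep(0, 13), 1:13)$p   # 2 / 2^13
#' @export
wilcoxonSignedRank <- function(pre, post, mode = c("auto", "exact", "approx"),
                               zeroes = c("discard", "pratt")) {
  mode <- match.arg(mode)
  zeroes <- match.arg(zeroes)
  stopifnot(length(pre) == length(post))
  d <- post - pre
  if (all(d == 0)) stop("degenerate: all differences are zero")
  if (zeroes == "discard") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  wPos <- sum(r[d > 0])
  wNeg <- sum(r[d < 0])
  exact <- switch(mode, exact = TRUE, approx = FALSE, auto = n <= 25L)
  if (exact) {
    # distribution of W+ over all 2^n sign assignments; ranks doubled so
    # midranks become integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- numeric(total + 1L)   # cnt[s + 1] = #assignments with 2*W+ = s
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), cnt[seq_len(total + 1L - ri)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * wPos))
    pLo <- sum(probs[seq_len(w2 + 1L)])
    pHi <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (wPos - mu - sign(wPos - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(wPos = wPos, wNeg = wNeg, n = n, p = p, method = method)
}

#' Two-tailed paired t-test
#'
#' Thin wrapper around [stats::t.test()] returning the statistic, degrees
#' of freedom and two-tailed p-value for post - pre.
#'
#' @param pre,post Paired measurements, equal length, n >= 2.
#' @return List with `t`, `df`, `p`, `meanDiff`.
#' @export
pairedT <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- post - pre
  if (sd(d) == 0) {
    # degenerate: constant differences; t is 0/0 for no change at all
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0, meanDiff = mean(d)))
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanDiff = unname(ht$estimate))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into the K^2 statistic, referred to a chi-squared
#' distribution with 2 df. Requires n >= 8.
#'
#' @param values Numeric vector, n >= 8, non-constant.
#' @return List with `k2`, `p`, `zSkew`, `zKurt`.
#' @export
dagostinoPearson <- function(values) {
  n <- length(values)
  if (n < 8) stop("D'Agostino-Pearson requires n >= 8")
  if (sd(values) == 0) stop("constant values: test undefined")
  x <- values - mean(values)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zSkew <- delta * asinh(y / alpha)
  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  zKurt <- ((1 - 2 / (9 * a)) -
              ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- zSkew^2 + zKurt^2
  list(k2 = k2, p = pchisq(k2, df = 2, lower.tail = FALSE),
       zSkew = zSkew, zKurt = zKurt)
}

#' Lilliefors (Kolmogorov-Smirnov) normality test
#'
#' Kolmogorov-Smirnov test against a normal with estimated parameters,
#' with the Dallal-Wilkinson p-value approximation, via
#' [nortest::lillie.test()].
#'
#' @param values Numeric vector, n >= 5.
#' @return List with `d` (KS statistic) and `p`.
#' @export
lillieforsKS <- function(values) {
  if (length(values) < 5) stop("Lilliefors test requires n >= 5")
  if (sd(values) == 0) stop("constant values: test undefined")
  ht <- nortest::lillie.test(values)
  list(d = unname(ht$statistic), p = ht$p.value)
}

#' Volcano configuration
#'
#' @param s0 Minimal-fold-change regularizer added to the standard error
#'   in the denominator of the paired t statistic (default 0.1).
#' @param fdr Target permutation false discovery rate (default 0.05).
#' @param nPermutations Number of sign-flip permutations; the full set of
#'   `2^n` flips is enumerated instead whenever `2^n` does not exceed
#'   this count (default 10000).
#' @param seed Seed for the permutation draw.
#' @return A list of class `volcanoConfig`.
#' @export
volcanoConfig <- function(s0 = 0.1, fdr = 0.05, nPermutations = 10000,
                          seed = 1L) {
  stopifnot(s0 >= 0, fdr > 0, fdr < 1, nPermutations >= 1)
  structure(list(s0 = s0, fdr = fdr,
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed)),
            class = "volcanoConfig")
}

.s0Stat <- function(d, s0) {
  n <- ncol(d)
  md <- rowMeans(d)
  se <- sqrt(pmax(rowSums(d * d) - n * md^2, 0) / (n - 1)) / sqrt(n)
  md / (se + s0)
}

#' Paired s0-moderated volcano analysis with permutation FDR
#'
#' For each metabolite the paired difference post - pre across subjects is
#' summarised by the s0-moderated t statistic
#' `t_s0 = mean(d) / (se(d) + s0)`; `s0 = 0` recovers the ordinary paired
#' t statistic. Significance is assessed Perseus-style: subject sign-flip
#' permutations (applied jointly to all metabolites) give a null ensemble
#' of |t_s0|, and for each candidate cutoff the FDR is estimated as the
#' mean permuted exceedance count over the observed exceedance count; the
#' largest set of metabolites whose cutoff keeps the estimated FDR at or
#' below the target is called significant.
#'
#' @param pre,post Matrices, metabolites x subjects, matched dimensions.
#' @param config [volcanoConfig()].
#' @return `data.frame` with one row per metabolite: `meanDiff`, `tS0`,
#'   `negLog10P` (from the ordinary paired t), `significant`.
#' @export
s0Volcano <- function(pre, post, config = volcanoConfig()) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post)))
    stop("pre and post must have matching dimensions")
  stopifnot(inherits(config, "volcanoConfig"))
  d <- post - pre
  n <- ncol(d)
  if (n < 2) stop("need at least 2 subjects")
  tObs <- .s0Stat(d, config$s0)
  t0 <- .s0Stat(d, 0)
  pPlain <- 2 * pt(-abs(t0), df = n - 1)

  if (2^n <= config$nPermutations) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(config$seed)
    flips <- matrix(sample(c(-1, 1), config$nPermutations * n,
                           replace = TRUE),
                    config$nPermutations, n)
  }
  absObs <- abs(tObs)
  ord <- order(absObs, decreasing = TRUE)
  exceedPerm <- numeric(length(absObs))   # mean permuted count >= cutoff
  permAbs <- matrix(0, nrow(flips), length(absObs))
  for (b in seq_len(nrow(flips))) {
    db <- sweep(d, 2L, flips[b, ], `*`)
    permAbs[b, ] <- abs(.s0Stat(db, config$s0))
  }
  sortedPerm <- sort(as.vector(permAbs))
  B <- nrow(flips)
  m <- length(absObs)
  fdrAt <- function(cut, k) {
    # k = number of observed stats >= cut
    nPerm <- length(sortedPerm) -
      findInterval(cut, sortedPerm, left.open = TRUE)
    (nPerm / B) / k
  }
  sig <- logical(m)
  best <- 0L
  for (j in seq_len(m)) {
    cut <- absObs[ord[j]]
    if (fdrAt(cut, j) <= config$fdr) best <- j
  }
  if (best > 0L) sig[ord[seq_len(best)]] <- TRUE
  data.frame(meanDiff = rowMeans(d), tS0 = tObs,
             negLog10P = -log10(pPlain), significant = sig,
             row.names = rownames(d))
}

#' Shared-control bootstrap effect sizes
#'
#' Estimation-statistics summary of each group against a common control:
#' the difference of means with a percentile bootstrap confidence
#' interval, resampling group and control independently with replacement.
#' Deterministic given the seed.
#'
#' @param control Numeric vector, the shared control (e.g. the pre-dose
#'   time-point).
#' @param groups Named list of numeric vectors (e.g. one per post-dose
#'   time-point).
#' @param nBoot Bootstrap replicates (default 5000, >= 1000 recommended).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return `data.frame` with `group`, `meanDiff`, `lower`, `upper`, `n`.
#' @export
sharedControlBootstrap <- function(control, groups, nBoot = 5000,
                                   seed = 1L, conf = 0.95) {
  if (!is.list(groups)) groups <- list(group = groups)
  if (any(lengths(groups) == 0L) || length(control) == 0L)
    stop("empty group or control")
  if (nBoot < 1) stop("nBoot must be >= 1")
  a <- (1 - conf) / 2
  set.seed(seed)
  out <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    bd <- vapply(seq_len(nBoot), function(b) {
      mean(sample(g, replace = TRUE)) - mean(sample(control, replace = TRUE))
    }, 0)
    ci <- quantile(bd, c(a, 1 - a), names = FALSE, type = 7)
    data.frame(group = names(groups)[i] %||% as.character(i),
               meanDiff = mean(g) - mean(control),
               lower = ci[1], upper = ci[2], n = length(g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || a == "") b else a

#' Principal component analysis of profile or kinetic-constant matrices
#'
#' Column-centred (and optionally standard-scaled) PCA via the singular
#' value decomposition. Rows with missing values are dropped before the
#' decomposition. Used both for whole-metabolome sample profiles and for
#' the volunteer x (k2, k3, k4, k5) kinetic-constant matrix.
#'
#' @param mat Numeric matrix, observations in rows.
#' @param nComponents Number of components to return (default
#'   `min(dim)`).
#' @param standardScale Scale columns to unit variance (default TRUE;
#'   constant columns are an error when scaling).
#' @return List with `scores` (rows x components), `loadings`
#'   (orthonormal, variables x components), `explainedVariance`
#'   (proportions, non-increasing), `dropped` (row indices removed for
#'   missingness).
#' @export
pcaAnalysis <- function(mat, nComponents = NULL, standardScale = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 rows")
  cc <- complete.cases(mat)
  dropped <- which(!cc)
  mat <- mat[cc, , drop = FALSE]
  if (nrow(mat) < 2) stop("fewer than 2 complete rows")
  if (standardScale && any(apply(mat, 2, sd) == 0))
    stop("constant column: cannot standard-scale")
  pc <- prcomp(mat, center = TRUE, scale. = standardScale)
  k <- if (is.null(nComponents)) length(pc$sdev)
       else min(nComponents, length(pc$sdev))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explainedVariance = ev[seq_len(k)],
       dropped = dropped)
}

#' Pairwise correlations among caffeine conversion constants
#'
#' Pearson correlation matrix of the fitted conversion/elimination
#' constants `k2..k5` across volunteer profiles, the quantity used to read
#' off metabolic phenotype structure (e.g. whether paraxanthine conversion
#' and direct elimination trade off).
#'
#' @param kmat Matrix or data.frame, volunteer profiles x constants, with
#'   columns `k2..k5` (any matrix of constants is accepted).
#' @return Correlation matrix.
#' @export
kCorrelationSummary <- function(kmat) {
  kmat <- as.matrix(kmat)
  if (nrow(kmat) < 3) stop("need at least 3 profiles")
  cor(kmat)
}

#' Collect fitted conversion constants from a list of fits
#'
#' @param fits List of [KineticFit-class] objects.
#' @param which Constant names to extract (default `k2..k5`).
#' @return Matrix, profiles x constants.
#' @export
kineticConstantMatrix <- function(fits, which = c("k2", "k3", "k4", "k5")) {
  t(vapply(fits, function(f) fittedRates(f)[which],
           numeric(length(which))))
}
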