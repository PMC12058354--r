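#' Hill number of order q
#'
#' Effective number of equally abundant taxa. `q = 0` is the observed
#' richness; `q = 1` (the continuous limit) is the exponential of the
#' Shannon entropy, used here as the evenness summary; general `q >= 0`
#' follows \eqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}}. Zero counts are dropped
#' before normalising.
#'
#' @param counts Non-negative abundances with a positive sum.
#' @param q Diversity order (default 1).
#' @return The Hill number, a value in `[1, richness]`.
#' @examples
#' hill_number(rep(3, 5), q = 1)   # 5: maximal evenness
#' hill_number(c(75, 25), q = 1)   # ~1.7548
#' @export
hill_number <- function(counts, q = 1) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop("hill_number is undefined for all-zero counts")
  }
  if (q < 0) stop("q must be >= 0")
  p <- counts / sum(counts)
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-10) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Exact sample-based rarefaction
#'
#' Expected taxon richness in `t` of `T` sampling units, computed from the
#' incidence frequencies \eqn{Y_i} (number of units in which taxon i was
#' detected) by the exact hypergeometric formula
#' \deqn{E[S(t)] = \sum_i \left[1 - \binom{T - Y_i}{t} / \binom{T}{t}\right].}
#' This equals the average richness over all \eqn{\binom{T}{t}} subsets of
#' the sampling units, without resampling.
#'
#' @param incidence Integer vector of incidence frequencies, each in
#'   `[0, n_samples]`.
#' @param n_samples Total number of sampling units `T`.
#' @param t Subset sizes at which to evaluate (vectorised); each in
#'   `[1, n_samples]`. Default: `1:n_samples`.
#' @return Numeric vector of expected richness values, one per `t`.
#' @export
rarefy_exact <- function(incidence, n_samples, t = seq_len(n_samples)) {
  if (any(incidence != round(incidence)) || any(incidence < 0)) {
    stop("incidence frequencies must be non-negative integers")
  }
  if (any(incidence > n_samples)) {
    stop("incidence frequency exceeds the number of samples")
  }
  if (any(t < 1 | t > n_samples)) {
    stop("t must lie in [1, n_samples]")
  }
  vapply(t, function(tt) {
    # lchoose is finite-safe: choose(T-Y, t) = 0 when T-Y < t
    sum(1 - exp(lchoose(n_samples - incidence, tt) - lchoose(n_samples, tt)))
  }, numeric(1))
}

#' Accumulation curve from incidence frequencies
#'
#' @inheritParams rarefy_exact
#' @return A data frame with columns `sites` (1..T) and `richness`.
#' @export
accumulation_curve <- function(incidence, n_samples) {
  data.frame(sites = seq_len(n_samples),
             richness = rarefy_exact(incidence, n_samples))
}

.accum_models <- list(
  asymptotic = list(
    formula = richness ~ Asym + (R0 - Asym) * exp(-exp(lrc) * sites),
    npar = 3L,
    lower = c(Asym = 1e-8, R0 = -Inf, lrc = -Inf),
    start = function(t, S) {
      list(Asym = 1.05 * max(S), R0 = S[1], lrc = 0)
    }
  ),
  logistic = list(
    formula = richness ~ Asym / (1 + exp((xmid - sites) / scal)),
    npar = 3L,
    lower = c(Asym = 1e-8, xmid = -Inf, scal = 1e-8),
    start = function(t, S) {
      Asym <- 1.05 * max(S)
      # two-point slope estimate on the logit scale
      z <- pmin(pmax(S / Asym, 0.02), 0.98)
      lg <- log(z / (1 - z))
      scal <- (t[length(t)] - t[1]) / (lg[length(lg)] - lg[1])
      if (!is.finite(scal) || scal <= 0) scal <- diff(range(t)) / 4
      list(Asym = Asym, xmid = median(t), scal = scal)
    }
  ),
  lomolino = list(
    formula = richness ~ Asym / (1 + slope^log(xmid / sites)),
    npar = 3L,
    lower = c(Asym = 1e-8, xmid = 1e-8, slope = 1e-8),
    start = function(t, S) {
      Asym <- 1.05 * max(S)
      xmid <- median(t)
      # slope from the first point: Asym/S - 1 = slope^log(xmid/t)
      r <- Asym / max(S[1], 0.5) - 1
      lsl <- log(max(r, 1e-3)) / log(max(xmid / t[1], 1.01))
      slope <- exp(min(max(lsl, 0.05), 3))
      list(Asym = Asym, xmid = xmid, slope = slope)
    }
  )
)

#' Fit a nonlinear taxa-accumulation model
#'
#' Fits one of three classical accumulation models to curve points
#' `(sites, richness)` by nonlinear least squares:
#' * `asymptotic` (asymptotic regression):
#'   \eqn{S(t) = Asym + (R_0 - Asym)\,e^{-e^{lrc} t}}
#' * `logistic`: \eqn{S(t) = Asym / (1 + e^{(xmid - t)/scal})}
#' * `lomolino`: \eqn{S(t) = Asym / (1 + slope^{\log(xmid/t)})}
#'
#' Starting values come from documented self-start heuristics
#' (`Asym = 1.05 max(S)`, `R0 = S(1)`, `lrc = 0`, `xmid = median(t)`, and
#' two-point slope estimates for `scal`/`slope`); optimisation uses
#' Levenberg-Marquardt least squares. The reported AIC uses the Gaussian
#' likelihood convention \eqn{n \ln(2\pi RSS/n) + n + 2(p + 1)} with `p`
#' model parameters, so values are comparable across the three models
#' fitted to the same points. Non-convergence is flagged, not hidden.
#'
#' @param curve A data frame with columns `sites` and `richness` (see
#'   [accumulation_curve()]), or a numeric vector of site counts when
#'   `richness` is given separately.
#' @param model One of `"asymptotic"`, `"logistic"`, `"lomolino"`.
#' @param richness Richness values when `curve` is a plain vector.
#' @return An object of class `accum_fit`: list with `model`, `coef`,
#'   `asymptote`, `rss`, `aic`, `fitted`, `converged`, `message`.
#' @export
fit_accumulation <- function(curve, model = c("asymptotic", "logistic",
                                              "lomolino"),
                             richness = NULL) {
  model <- match.arg(model)
  if (!is.null(richness)) {
    curve <- data.frame(sites = curve, richness = richness)
  }
  if (!all(c("sites", "richness") %in% names(curve))) {
    stop("curve must have 'sites' and 'richness' columns")
  }
  if (nrow(curve) < 3L) stop("at least 3 curve points are required")
  spec <- .accum_models[[model]]
  n <- nrow(curve)
  # residual sums of squares below this floor are treated as an exact fit
  # when computing the Gaussian AIC, keeping it finite and comparable
  rss_floor <- 1e-12
  aic_of <- function(rss) {
    n * log(2 * pi * max(rss, rss_floor) / n) + n + 2 * (spec$npar + 1)
  }

  S <- curve$richness
  if (model == "asymptotic" && diff(range(S)) < 1e-12) {
    # degenerate flat curve: the least-squares solution is Asym = R0 = c
    co <- c(Asym = S[1], R0 = S[1], lrc = 0)
    return(structure(list(model = model, coef = co, asymptote = S[1],
                          rss = 0, aic = aic_of(0), fitted = S,
                          converged = S[1] > 0,
                          message = "constant curve (exact fit)"),
                     class = "accum_fit"))
  }

  starts <- list(spec$start(curve$sites, S))
  jitter <- starts[[1]]
  jitter[["Asym"]] <- jitter[["Asym"]] * 1.2 + 1
  starts[[2]] <- jitter
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(spec$formula, data = curve, start = start,
                          lower = spec$lower[names(start)],
                          control = minpack.lm::nls.lm.control(
                            maxiter = 1000, ftol = 1e-15, ptol = 1e-15))),
      error = function(e) e
    )
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    return(structure(list(model = model, coef = unlist(starts[[1]]),
                          asymptote = NA_real_, rss = NA_real_,
                          aic = Inf, fitted = rep(NA_real_, n),
                          converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "accum_fit"))
  }
  co <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  converged <- isTRUE(fit$convInfo$isConv) && co[["Asym"]] > 0
  structure(list(model = model, coef = co, asymptote = unname(co[["Asym"]]),
                 rss = rss, aic = aic_of(rss), fitted = stats::fitted(fit),
                 converged = converged, message = fit$convInfo$stopMessage),
            class = "accum_fit")
}

#' @export
print.accum_fit <- function(x, ...) {
  cat("accumulation model '", x$model, "': asymptote = ",
      format(x$asymptote, digits = 4), ", RSS = ",
      format(x$rss, digits = 4), ", AIC = ", format(x$aic, digits = 4),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Fit all accumulation models to one curve
#'
#' @inheritParams fit_accumulation
#' @param models Models to fit (default all three).
#' @return A named list of `accum_fit` objects.
#' @export
fit_accumulation_all <- function(curve, models = names(.accum_models)) {
  setNames(lapply(models, function(m) fit_accumulation(curve, m)), models)
}

#' Select the accumulation model with the lowest AIC
#'
#' Non-converged fits are discarded; among the converged ones the fit with
#' the lowest AIC wins, ties broken first by fewer parameters, then by
#' model name order.
#'
#' @param fits A list of `accum_fit` objects.
#' @return The selected `accum_fit`.
#' @export
select_best_model <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0L) stop("no converged accumulation fit to select from")
  npar <- vapply(fits, function(f) length(f$coef), integer(1))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  nm <- vapply(fits, `[[`, character(1), "model")
  fits[[order(aic, npar, nm)[1]]]
}

#' Jaccard beta-diversity partition of a site pair
#'
#' Decomposes the pairwise Jaccard dissimilarity into its additive turnover
#' and nestedness components. With `a` shared taxa and `b`, `c` taxa unique
#' to either site:
#' \deqn{\beta_{jac} = \frac{b + c}{a + b + c},\quad
#'       \beta_{jtu} = \frac{2\min(b, c)}{a + 2\min(b, c)},\quad
#'       \beta_{jne} = \beta_{jac} - \beta_{jtu}.}
#' The partition is symmetric in the two sites and each component lies in
#' `[0, 1]`.
#'
#' @param x,y Presence sets: character vectors of taxon names, or logical
#'   (0/1) vectors over a common taxon universe.
#' @return Named numeric vector `c(beta_jac, beta_jtu, beta_jnes)`.
#' @export
beta_pair <- function(x, y) {
  if (is.logical(x) || is.numeric(x)) {
    if (length(x) != length(y)) {
      stop("presence vectors must share a common taxon universe")
    }
    universe <- names(x) %||% as.character(seq_along(x))
    x <- universe[as.logical(x)]
    y <- universe[as.logical(y)]
  }
  a <- length(intersect(x, y))
  b <- length(setdiff(x, y))
  cc <- length(setdiff(y, x))
  if (a + b + cc == 0L) {
    stop("beta_pair is undefined when both sites are empty")
  }
  jac <- (b + cc) / (a + b + cc)
  jtu <- if (min(b, cc) == 0L) 0 else 2 * min(b, cc) / (a + 2 * min(b, cc))
  c(beta_jac = jac, beta_jtu = jtu, beta_jnes = jac - jtu)
}

#' Pairwise Jaccard partition over a community matrix
#'
#' @param comm A `community_matrix` or a samples-by-taxa matrix (counts or
#'   presence/absence; any positive entry counts as presence).
#' @return A list of three `dist` objects: `beta_jac`, `beta_jtu`,
#'   `beta_jnes`.
#' @export
beta_pair_matrix <- function(comm) {
  pa <- presence_absence(comm)
  n <- nrow(pa)
  mats <- lapply(1:3, function(i) matrix(0, n, n,
                                         dimnames = list(rownames(pa),
                                                         rownames(pa))))
  names(mats) <- c("beta_jac", "beta_jtu", "beta_jnes")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      bp <- beta_pair(pa[i, ] > 0, pa[j, ] > 0)
      for (k in names(mats)) mats[[k]][i, j] <- mats[[k]][j, i] <- bp[[k]]
    }
  }
  lapply(mats, as.dist)
}

# Gower-centred inner-product matrix of a distance matrix:
# G = (I - 11'/n) (-0.5 D^2) (I - 11'/n)
.gower_center <- function(d) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8)) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities among model terms by
#' the distance-based linear-model approach: the Gower-centred
#' inner-product matrix `G` of the distances is projected onto the
#' sequentially nested design (type-I sums of squares, terms in the order
#' given), term sums of squares are traces of `(H_j - H_(j-1)) G`, and the
#' pseudo-F of each term uses the residual mean square of the full model.
#' Significance comes from free permutation of the samples (rows and
#' columns of `G` permuted together); p-values use the add-one convention
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`, so they can never fall below
#' `1/(n_perm + 1)`.
#'
#' @param d A `dist` or square symmetric zero-diagonal distance matrix.
#' @param data Data frame of sample variables, rows aligned with `d`.
#' @param terms Character vector of term names (columns of `data`), fitted
#'   sequentially in this order. Each term must have at least two levels.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations (default 1).
#' @return An object of class `permanova`: a list with `table` (data frame
#'   with Df, SumOfSqs, R2, F, p per term plus Residual and Total rows),
#'   `n_perm` and `seed`.
#' @export
permanova <- function(d, data, terms, n_perm = 999L, seed = 1L) {
  G <- .gower_center(d)
  n <- nrow(G)
  if (nrow(data) != n) stop("'data' rows must align with the distance matrix")
  miss <- setdiff(terms, names(data))
  if (length(miss)) stop("term(s) not in data: ", paste(miss, collapse = ", "))
  for (tm in terms) {
    data[[tm]] <- factor(data[[tm]])
    if (nlevels(data[[tm]]) < 2L) {
      stop("term '", tm, "' has fewer than two levels")
    }
  }
  # projector onto the column space of X via QR; tolerant of aliased
  # (rank-deficient) designs, whose redundant columns contribute nothing
  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H_prev <- matrix(1 / n, n, n)           # intercept-only hat
  dH <- list()
  for (i in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[seq_len(i)], collapse = "+")))
    X <- model.matrix(f, data)
    H <- hat(X)
    dH[[i]] <- H - H_prev
    H_prev <- H
  }
  # the trace of each projector increment is the term's degrees of freedom
  df <- vapply(dH, function(D) round(sum(diag(D))), numeric(1))
  M_res <- diag(n) - H_prev
  df_res <- n - round(sum(diag(H_prev)))
  ss_total <- sum(diag(G))

  term_ss <- function(Gm) {
    vapply(dH, function(D) sum(D * Gm), numeric(1))   # trace(D G), symmetric
  }
  ss <- term_ss(G)
  ss_res <- sum(M_res * G)
  Fobs <- (ss / df) / (ss_res / df_res)

  exceed <- rep(0L, length(terms))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      Gp <- G[p, p]
      ssp <- term_ss(Gp)
      ssp_res <- sum(M_res * Gp)
      Fp <- (ssp / df) / (ssp_res / df_res)
      exceed <- exceed + (Fp >= Fobs - 1e-12)
    }
  })
  pval <- (1 + exceed) / (1 + n_perm)
  table <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df, df_res, n - 1),
    SumOfSqs = c(ss, ss_res, ss_total),
    R2 = c(ss, ss_res, ss_total) / ss_total,
    F = c(Fobs, NA, NA),
    p = c(pval, NA, NA)
  )
  structure(list(table = table, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat("PERMANOVA (sequential sums of squares,", x$n_perm,
      "free permutations, seed", paste0(x$seed, ")\n"))
  tab <- x$table
  tab$SumOfSqs <- round(tab$SumOfSqs, digits)
  tab$R2 <- round(tab$R2, digits)
  tab$F <- round(tab$F, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Principal coordinates analysis (PCoA)
#'
#' Metric ordination of a dissimilarity matrix: the Gower-centred matrix of
#' `-0.5 D^2` is eigendecomposed; coordinates are the eigenvectors scaled
#' by the square roots of their (positive) eigenvalues, so Euclidean
#' distances between points reproduce the input distances when those are
#' Euclidean-embeddable. Negative eigenvalues (possible for semi-metric
#' dissimilarities such as the Jaccard turnover component) are reported and
#' their axes dropped.
#'
#' @param d A `dist` or square symmetric zero-diagonal matrix.
#' @param n_axes Number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending), `prop_explained`
#'   (per returned axis, relative to the sum of positive eigenvalues) and
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = NULL) {
  G <- .gower_center(d)
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  if (length(pos) == 0L) {
    coords <- matrix(0, nrow(G), 0)
    rownames(coords) <- rownames(as.matrix(d))
    return(structure(list(coordinates = coords, eigenvalues = ev,
                          prop_explained = numeric(0),
                          negative_eigenvalues = ev[ev < -tol]),
                     class = "pcoa_result"))
  }
  keep <- if (is.null(n_axes)) pos else pos[seq_len(min(n_axes, length(pos)))]
  coords <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev[keep]), length(keep))
  rownames(coords) <- rownames(as.matrix(d))
  colnames(coords) <- paste0("Axis", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = ev,
                 prop_explained = ev[keep] / sum(ev[pos]),
                 negative_eigenvalues = ev[ev < -tol]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates),
      "axes;", length(x$negative_eigenvalues), "negative eigenvalue(s)\n")
  if (ncol(x$coordinates)) {
    cat("proportion explained:",
        paste(round(100 * x$prop_explained, 1), "%", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Power of a balanced one-way ANOVA
#'
#' Exact power of the F test for a balanced one-way design with `k` groups
#' of `n` samples each and Cohen effect size `f`: the test statistic is
#' noncentral F with `k - 1` and `k(n - 1)` degrees of freedom and
#' noncentrality \eqn{\lambda = k n f^2}.
#'
#' @param n Samples per group (may be non-integer; vectorised).
#' @param k Number of groups.
#' @param f Cohen effect size.
#' @param alpha Significance level.
#' @return Power in `(0, 1)`.
#' @export
anova_power <- function(n, k, f, alpha = 0.05) {
  if (k < 2) stop("k must be >= 2")
  if (f <= 0) stop("effect size f must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  vapply(n, function(ni) {
    if (ni <= 1) return(NA_real_)
    v <- k * (ni - 1)
    pf(qf(1 - alpha, k - 1, v), k - 1, v, ncp = k * ni * f^2,
       lower.tail = FALSE)
  }, numeric(1))
}

#' Sample size per group for a balanced one-way ANOVA
#'
#' Inverts the noncentral-F power function. The design equation
#' `power(n) = target_power` is first solved for a continuous `n` by root
#' finding (the quantity the standard power calculators return); the
#' reported per-group sample size `n` is then the smallest integer
#' `n >= 2` whose power reaches the target, so `power(n) >= target_power`
#' and `power(n - 1) < target_power` always hold. The continuous solution
#' is returned as `n_exact` for transparency; note that rounding `n_exact`
#' down gives a design that fails the target (its attained power is also
#' returned).
#'
#' @param k Number of groups.
#' @param f Cohen effect size (dimensionless).
#' @param alpha Significance level (default 0.05).
#' @param target_power Desired power (default 0.8).
#' @return An object of class `power_result`: list with `n` (minimal
#'   integer design size), `n_exact` (continuous solution),
#'   `power_at_n`, `power_at_floor` (power at `floor(n_exact)`) and the
#'   inputs.
#' @export
anova_power_n <- function(k, f, alpha = 0.05, target_power = 0.8) {
  if (target_power <= 0 || target_power >= 1) {
    stop("target_power must be in (0, 1)")
  }
  anova_power(2, k, f, alpha)   # validates k, f, alpha
  root <- uniroot(function(n) anova_power(n, k, f, alpha) - target_power,
                  lower = 1 + 1e-9, upper = 1e7, tol = 1e-9)
  n_exact <- root$root
  n <- max(2L, as.integer(ceiling(n_exact - 1e-9)))
  while (anova_power(n, k, f, alpha) < target_power) n <- n + 1L
  structure(list(n = n, n_exact = n_exact,
                 power_at_n = anova_power(n, k, f, alpha),
                 power_at_floor = anova_power(max(2L, floor(n_exact)),
                                              k, f, alpha),
                 k = k, f = f, alpha = alpha, target_power = target_power),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("balanced one-way ANOVA power: k =", x$k, ", f =", x$f,
      ", alpha =", x$alpha, ", target power =", x$target_power, "\n")
  cat("  continuous solution n per group =", format(x$n_exact, digits = 5),
      "-> required n =", x$n,
      sprintf("(attained power %.3f)\n", x$power_at_n))
  invisible(x)
}
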