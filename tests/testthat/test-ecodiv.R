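test_that("Hill numbers reduce to richness and exponential Shannon", {
  expect_equal(hill_number(rep(4, 5), q = 1), 5)
  expect_equal(hill_number(c(1, 1, 2), q = 0), 3)
  expect_equal(hill_number(c(75, 25), q = 1), exp(0.5623351), tolerance = 1e-6)
  expect_equal(hill_number(c(3, 0, 3), q = 2), 2)   # zeros dropped
  expect_error(hill_number(c(0, 0)), "all-zero")
})

test_that("q1 never exceeds q0, with equality only under perfect evenness", {
  set.seed(21)
  for (i in 1:200) {
    x <- rpois(sample(2:10, 1), lambda = 5) + sample(0:1, 1)
    if (sum(x) == 0) next
    q0 <- hill_number(x, 0)
    q1 <- hill_number(x, 1)
    expect_lte(q1, q0 + 1e-12)
    even <- length(unique(x[x > 0])) == 1L
    if (even) expect_equal(q1, q0) else expect_lt(q1, q0)
  }
})

test_that("exact rarefaction equals the all-subsets average (exhaustive)", {
  set.seed(8)
  for (T in 2:6) {
    Y <- sample(0:T, size = 12, replace = TRUE)
    m <- incidence_matrix_from_Y(Y, T)
    for (t in 1:T) {
      expect_equal(rarefy_exact(Y, T, t), rarefaction_subset_oracle(m, t),
                   tolerance = 1e-12, info = paste("T =", T, "t =", t))
    }
  }
})

test_that("rarefaction endpoints and monotonicity hold", {
  Y <- c(5, 3, 1, 0, 2, 6)
  T <- 6
  curve <- rarefy_exact(Y, T)
  expect_equal(curve[T], sum(Y > 0))        # t = T: observed richness
  expect_equal(curve[1], sum(Y) / T)        # t = 1: mean per-sample richness
  expect_true(all(diff(curve) >= -1e-12))
  expect_error(rarefy_exact(Y, T, 0), "t must lie")
  expect_error(rarefy_exact(c(7, 1), 6), "exceeds")
})

test_that("the asymptotic model recovers exact parameters", {
  t <- 1:6
  S <- 50 + (5 - 50) * exp(-exp(0) * t)
  fit <- fit_accumulation(t, model = "asymptotic", richness = S)
  expect_true(fit$converged)
  expect_equal(fit$asymptote, 50, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)

  flat <- fit_accumulation(1:5, model = "asymptotic",
                           richness = rep(20, 5))
  expect_equal(flat$asymptote, 20, tolerance = 1e-3)
})

test_that("AIC selection identifies the generating model", {
  t <- 1:8
  S <- 40 / (1 + exp((3 - t) / 1.2))       # exact logistic curve
  fits <- fit_accumulation_all(data.frame(sites = t, richness = S))
  best <- select_best_model(fits)
  expect_equal(best$model, "logistic")
})

test_that("model selection breaks ties by parameter count then name", {
  mk <- function(model, aic, npar = 3L) {
    structure(list(model = model, coef = setNames(rep(1, npar),
                                                  paste0("p", 1:npar)),
                   asymptote = 1, rss = 1, aic = aic, converged = TRUE),
              class = "accum_fit")
  }
  expect_equal(select_best_model(list(mk("lomolino", 10)))$model, "lomolino")
  expect_equal(select_best_model(list(mk("a", 10), mk("b", 12)))$model, "a")
  expect_equal(select_best_model(list(mk("four", 10, 4L),
                                      mk("three", 10, 3L)))$model, "three")
  expect_error(select_best_model(list(structure(list(converged = FALSE),
                                                class = "accum_fit"))),
               "no converged")
})

test_that("the Jaccard partition matches hand-computed cases", {
  expect_equal(beta_pair(c("a", "b"), c("a", "b")),
               c(beta_jac = 0, beta_jtu = 0, beta_jnes = 0))
  expect_equal(beta_pair(c("a", "b"), c("c", "d")),
               c(beta_jac = 1, beta_jtu = 1, beta_jnes = 0))
  bp <- beta_pair(c("a", "b", "c"), c("a", "b", "c", "d", "e"))
  expect_equal(unname(bp), c(0.4, 0, 0.4))
  expect_error(beta_pair(character(0), character(0)), "both sites")
  # logical input over a shared universe
  expect_equal(beta_pair(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE)),
               beta_pair(c("t1", "t2"), c("t1", "t3")))
})

test_that("beta_jac agrees with vegan's binary Jaccard on matrices", {
  skip_if_not_installed("vegan")
  set.seed(4)
  m <- matrix(rpois(60, 1), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  m[1, ] <- m[1, ] + 1   # no empty site
  mine <- beta_pair_matrix(m)$beta_jac
  ref <- vegan::vegdist(presence_absence(m), method = "jaccard",
                        binary = TRUE)
  expect_equal(as.matrix(mine), as.matrix(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PERMANOVA matches adonis2 and detects constructed structure", {
  skip_if_not_installed("vegan")
  set.seed(2)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  d <- dist(pts)
  meta <- data.frame(sample_id = paste0("s", 1:20),
                     habitat = rep(c("open", "woody"), each = 10),
                     replicate = factor(rep(1:5, 4)))
  res <- permanova(d, meta, c("habitat", "replicate"),
                   n_perm = 999, seed = 11)
  tab <- res$table
  expect_gt(tab$R2[tab$term == "habitat"], 0.5)
  expect_equal(tab$p[tab$term == "habitat"], 1 / 1000)
  expect_equal(sum(tab$R2[tab$term != "Total"]), 1, tolerance = 1e-9)

  va <- vegan::adonis2(d ~ habitat + replicate, data = meta,
                       permutations = 99, by = "terms")
  expect_equal(tab$SumOfSqs[1:2], va$SumOfSqs[1:2], tolerance = 1e-9)
  expect_equal(tab$F[1:2], va$F[1:2], tolerance = 1e-9)

  expect_error(permanova(d, meta, "missing_term"), "not in data")
  meta$const <- "x"
  expect_error(permanova(d, meta, "const"), "fewer than two levels")
})

test_that("single-term PERMANOVA partitions the total variance", {
  set.seed(3)
  d <- dist(matrix(rnorm(16), 8, 2))
  meta <- data.frame(sample_id = letters[1:8],
                     habitat = rep(c("a", "b"), 4))
  tab <- permanova(d, meta, "habitat", n_perm = 99, seed = 1)$table
  expect_equal(tab$R2[1] + tab$R2[2], 1, tolerance = 1e-9)
  expect_gte(tab$p[1], 1 / 100)
})

test_that("PCoA embeds Euclidean geometry exactly", {
  # two samples at distance 2: one axis, coordinates +/- 1
  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  p2 <- pcoa(d2)
  expect_equal(ncol(p2$coordinates), 1L)
  expect_equal(sort(unname(p2$coordinates[, 1])), c(-1, 1))

  set.seed(6)
  pts <- matrix(rnorm(10), 5, 2)
  d <- dist(pts)
  emb <- pcoa(d)
  expect_lt(max(abs(dist(emb$coordinates) - d)), 1e-9)
  expect_true(all(diff(emb$eigenvalues) <= 1e-9))   # descending

  zero <- matrix(0, 3, 3)
  expect_equal(ncol(pcoa(zero)$coordinates), 0L)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ANOVA sample size satisfies the minimality contract", {
  res <- anova_power_n(k = 3, f = 0.75, alpha = 0.05, target_power = 0.8)
  expect_gte(anova_power(res$n, 3, 0.75), 0.8)
  expect_lt(anova_power(res$n - 1, 3, 0.75), 0.8)
  expect_equal(res$n_exact, 6.8144, tolerance = 1e-4)

  # doubling the effect size cannot increase the requirement
  res2 <- anova_power_n(k = 3, f = 1.5, alpha = 0.05, target_power = 0.8)
  expect_lte(res2$n, res$n)
  expect_error(anova_power_n(3, f = -1), "effect size")
})

test_that("required sample size is nonincreasing in effect size and alpha", {
  ns_f <- vapply(c(0.3, 0.5, 0.75, 1, 1.5),
                 function(f) anova_power_n(3, f)$n_exact, numeric(1))
  expect_true(all(diff(ns_f) < 0))
  ns_a <- vapply(c(0.01, 0.05, 0.1),
                 function(a) anova_power_n(3, 0.75, alpha = a)$n_exact,
                 numeric(1))
  expect_true(all(diff(ns_a) < 0))
})
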