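make_panel <- function(calls) {
  map <- tibble::tibble(marker_id = colnames(calls), chr = "C1",
                        pos_cM = seq_len(ncol(calls)) * 10)
  genotype_panel(calls, map)
}

fake_rqr_fit <- function(beta, tau = 0.5) {
  structure(list(tau = tau, lambda = 0.5, mu_hat = 0, beta_hat = beta,
                 n_nonzero = sum(beta != 0)), class = "rqr_fit")
}

test_that("GEBVs are the genotype-weighted effect sums", {
  calls <- matrix(c(0L, 1L, 2L, 2L, 0L, 1L), 2, 3, byrow = TRUE,
                  dimnames = list(c("A1", "A2"), c("m1", "m2", "m3")))
  panel <- make_panel(calls)
  # all effects zero -> all GEBV zero
  g0 <- compute_gebv(panel, list(alpha1 = fake_rqr_fit(c(m1 = 0, m2 = 0, m3 = 0))))
  expect_equal(g0$u_alpha1, c(0, 0))
  # single marker: x = 2, beta = 3 -> u = 6
  g1 <- compute_gebv(
    make_panel(matrix(2L, 1, 1, dimnames = list("A1", "m1"))),
    list(alpha1 = fake_rqr_fit(c(m1 = 3))))
  expect_equal(g1$u_alpha1, 6)
  # random instance against a direct matrix-product oracle
  set.seed(12)
  calls5 <- matrix(sample(0:2, 20, TRUE), 5, 4,
                   dimnames = list(paste0("A", 1:5), paste0("m", 1:4)))
  beta <- rnorm(4); names(beta) <- paste0("m", 1:4)
  g5 <- compute_gebv(make_panel(calls5), list(alpha2 = fake_rqr_fit(beta)))
  expect_equal(g5$u_alpha2, drop(calls5 %*% beta), ignore_attr = TRUE)
})

test_that("GEBV computation is linear in the effects", {
  set.seed(13)
  calls <- matrix(sample(0:2, 24, TRUE), 6, 4,
                  dimnames = list(paste0("A", 1:6), paste0("m", 1:4)))
  panel <- make_panel(calls)
  b1 <- rnorm(4); b2 <- rnorm(4)
  names(b1) <- names(b2) <- paste0("m", 1:4)
  g <- function(b) compute_gebv(panel, list(alpha1 = fake_rqr_fit(b)))$u_alpha1
  expect_equal(g(2 * b1 - 3 * b2), 2 * g(b1) - 3 * g(b2), tolerance = 1e-12)
})

test_that("marker misalignment between panel and fit is an error", {
  calls <- matrix(1L, 2, 2, dimnames = list(c("A1", "A2"), c("m1", "m2")))
  bad <- fake_rqr_fit(c(mX = 1, mY = 2))
  expect_error(compute_gebv(make_panel(calls), list(alpha1 = bad)),
               class = "growthqr_alignment_error")
})

test_that("genomic curves reduce to the population curve at zero GEBV", {
  means <- c(alpha1 = 90, alpha2 = 113, alpha3 = 32)
  g <- tibble::tibble(animal_id = paste0("A", 1:4),
                      u_alpha1 = 0, u_alpha2 = 0, u_alpha3 = 0)
  attr(g, "tau") <- 0.5
  ages <- seq(0, 150, by = 10)
  crv <- genomic_curve(means, g, ages)
  expect_equal(crv$mean, logistic_predict(ages, 90, 113, 32))
  expect_true(all(diff(crv$mean) > 0))
})

test_that("asymptote and inflection identities hold with shifted parameters", {
  means <- c(alpha1 = 90, alpha2 = 113, alpha3 = 32)
  g <- tibble::tibble(animal_id = "A1", u_alpha1 = 10, u_alpha2 = 0,
                      u_alpha3 = 0)
  attr(g, "tau") <- 0.2
  # at the mean inflection age the shifted asymptote is halved
  crv <- genomic_curve(means, g, ages = 113)
  expect_equal(crv$mean, (90 + 10) / 2)
  # large ages approach the mean of the shifted asymptotes
  g2 <- tibble::tibble(animal_id = c("A1", "A2"), u_alpha1 = c(10, -20),
                       u_alpha2 = 0, u_alpha3 = 0)
  crv2 <- genomic_curve(means, g2, ages = 5000)
  expect_equal(crv2$mean, mean(c(100, 70)), tolerance = 1e-10)
})

test_that("animals with non-positive shifted growth scale are excluded", {
  means <- c(alpha1 = 90, alpha2 = 113, alpha3 = 32)
  g <- tibble::tibble(animal_id = c("A1", "A2"), u_alpha1 = 0, u_alpha2 = 0,
                      u_alpha3 = c(0, -32))
  expect_warning(crv <- genomic_curve(means, g, ages = 113),
                 "non-positive")
  expect_equal(crv$mean, 45)
})

test_that("marker ranking keeps ceiling(fraction * p) by |effect| with index ties", {
  set.seed(14)
  p <- 237
  beta <- rnorm(p); names(beta) <- sprintf("m%03d", 1:p)
  map <- tibble::tibble(marker_id = names(beta), chr = "C1",
                        pos_cM = seq_len(p))
  rk <- rank_markers(fake_rqr_fit(beta), map, fraction = 0.025)
  expect_equal(nrow(rk), 6L)                      # ceil(0.025 * 237)
  expect_equal(rk$effect_abs, unname(sort(abs(beta), decreasing = TRUE)[1:6]))
  expect_true(all(diff(rk$effect_abs) <= 0))
  # p = 40 -> a single marker
  beta40 <- rnorm(40); names(beta40) <- sprintf("m%03d", 1:40)
  rk40 <- rank_markers(fake_rqr_fit(beta40), map[1:40, ], fraction = 0.025)
  expect_equal(nrow(rk40), 1L)
  # equal |effect| straddling the cutoff: the lower-index marker survives
  beta_tie <- c(m1 = 5, m2 = -3, m3 = 3, m4 = 1)
  rk_tie <- rank_markers(fake_rqr_fit(beta_tie), map[1:4, ], fraction = 0.5)
  expect_equal(rk_tie$marker_id, c("m1", "m2"))
})

test_that("ranked markers carry bootstrap inference and map annotation", {
  beta <- c(m1 = 4, m2 = 0.1)
  map <- tibble::tibble(marker_id = c("m1", "m2"), chr = c("C1", "C2"),
                        pos_cM = c(12.5, 40))
  boot <- structure(list(table = tibble::tibble(
    marker_id = c("m1", "m2"), estimate = beta, se = c(1, 2),
    p_value = c(0.01, 0.9))), class = "bootstrap_summary")
  rk <- rank_markers(fake_rqr_fit(beta), map, boot = boot, fraction = 0.5)
  expect_equal(rk$marker_id, "m1")
  expect_equal(rk$se, 1)
  expect_equal(rk$p_value, 0.01)
  expect_equal(rk$chr, "C1")
  expect_equal(rk$pos_cM, 12.5)
})

test_that("identical bootstrap replicates give a zero-width band on the mean curve", {
  calls <- matrix(sample(0:2, 12, TRUE), 4, 3,
                  dimnames = list(paste0("A", 1:4), paste0("m", 1:3)))
  panel <- make_panel(calls)
  beta <- c(m1 = 1, m2 = -0.5, m3 = 0)
  B <- matrix(rep(beta, each = 10), 10, 3, dimnames = list(NULL, names(beta)))
  boot <- structure(list(replicates = B, reps_used = 10L, tau = 0.5,
                         lambda = 0.5, point_fit = fake_rqr_fit(beta)),
                    class = "bootstrap_summary")
  means <- c(alpha1 = 90, alpha2 = 113, alpha3 = 32)
  crv <- curve_confidence_band(list(alpha1 = boot), panel, means,
                               ages = c(0, 75, 150))
  expect_equal(crv$low, crv$mean, tolerance = 1e-12)
  expect_equal(crv$high, crv$mean, tolerance = 1e-12)
})

test_that("asymptote-only uncertainty widens the band with age", {
  set.seed(15)
  calls <- matrix(sample(0:2, 30, TRUE), 10, 3,
                  dimnames = list(paste0("A", 1:10), paste0("m", 1:3)))
  panel <- make_panel(calls)
  B <- matrix(rnorm(60, 0, 2), 20, 3,
              dimnames = list(NULL, paste0("m", 1:3)))
  boot <- structure(list(replicates = B, reps_used = 20L, tau = 0.5,
                         lambda = 0, point_fit = fake_rqr_fit(
                           c(m1 = 0, m2 = 0, m3 = 0))),
                    class = "bootstrap_summary")
  means <- c(alpha1 = 90, alpha2 = 113, alpha3 = 32)
  crv <- curve_confidence_band(list(alpha1 = boot), panel, means,
                               ages = c(0, 150))
  width <- crv$high - crv$low
  expect_gt(width[2], width[1])
  expect_true(all(crv$low <= crv$mean & crv$mean <= crv$high))
})

test_that("the band endpoints are the stated percentile curves", {
  calls <- matrix(1L, 2, 1, dimnames = list(c("A1", "A2"), "m1"))
  panel <- make_panel(calls)
  # 200 replicates with known spread on the asymptote trait
  B <- matrix(seq(-1, 1, length.out = 200), 200, 1,
              dimnames = list(NULL, "m1"))
  boot <- structure(list(replicates = B, reps_used = 200L, tau = 0.5,
                         lambda = 0, point_fit = fake_rqr_fit(c(m1 = 0))),
                    class = "bootstrap_summary")
  means <- c(alpha1 = 90, alpha2 = 113, alpha3 = 32)
  crv <- curve_confidence_band(list(alpha1 = boot), panel, means,
                               ages = 5000, level = 0.95)
  # at a huge age the curve equals the shifted asymptote: 90 + 1 * beta
  expect_equal(crv$low, 90 + quantile(B[, 1], 0.025, names = FALSE),
               tolerance = 1e-6)
  expect_equal(crv$high, 90 + quantile(B[, 1], 0.975, names = FALSE),
               tolerance = 1e-6)
  expect_error(curve_confidence_band(
    list(alpha1 = structure(list(replicates = B[1, , drop = FALSE],
                                 reps_used = 1L, tau = 0.5, lambda = 0),
                            class = "bootstrap_summary")),
    panel, means, ages = 100), class = "growthqr_domain_error")
})

test_that("tidiers expose fits as tibbles", {
  set.seed(16)
  y <- rnorm(20, 50, 5)
  X <- matrix(sample(0:2, 40, TRUE), 20, 2,
              dimnames = list(NULL, c("m1", "m2")))
  fit <- solve_rqr(y, X, 0.2, 0.5)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "m1", "m2"))
  expect_equal(td$estimate[1], fit$mu_hat)
  gl <- glance(fit)
  expect_equal(gl$tau, 0.2)
  expect_equal(gl$objective, fit$objective)
  expect_equal(gl$n, 20L)
})
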