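#' Configuration for the F2-cross simulator
#'
#' Describes a simulated F2 population with logistic weight trajectories.
#' The defaults mirror the study design this package targets: 345 animals
#' genotyped at 237 SNPs over six chromosomes (SSC1 n=56, SSC4 n=54,
#' SSC7 n=59, SSC8 n=31, SSC17 n=25, SSCX n=12; the X is simulated as
#' autosomal), weights recorded at 0, 21, 42, 63, 77, 105 and 150 days,
#' population-mean curve parameters (89.43 kg, 113.18 d, 32.03 d), and a
#' measurement-noise standard deviation that increases with age (the fan
#' shape of real weight-age data).
#'
#' @param n_animals Number of F2 animals.
#' @param chromosomes Tibble with columns `chr`, `n_markers`, `length_cM`.
#'   Markers are placed evenly along each chromosome.
#' @param base_params Named vector `c(alpha1, alpha2, alpha3)` of
#'   population-mean curve parameters (kg, days, days).
#' @param ages Measurement ages in days.
#' @param residual_sd_by_age Non-decreasing vector of weight-noise SDs (kg),
#'   one per age.
#' @param true_effects Named list (by trait) of named numeric vectors
#'   mapping marker ids to additive per-allele effects on that trait, in
#'   trait units. Default: no marker effects.
#' @param covariate_effects Named list (by trait) of lists with named
#'   numeric vectors `sex`, `lot`, `halothane` giving additive level shifts.
#'   Defaults give the males a heavier mature weight, small lot effects, and
#'   a halothane-carrier shift.
#' @param trait_noise_sd Named vector of SDs for animal-level trait
#'   deviations around the genetic value; default zero (all trait variation
#'   is marker- and covariate-driven).
#' @param het_scale Non-negative scalar coupling the animal-level trait
#'   noise SD to the mean genotype at that trait's effect markers
#'   (`sd_i = sd * (1 + het_scale * xbar_i / 2)`). With `het_scale > 0`
#'   marker effects differ across quantiles of the trait distribution;
#'   default 0 (quantile-homogeneous effects).
#' @param seed Integer seed; all outputs are deterministic given the config.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_animals = 345L,
                       chromosomes = default_chromosomes(),
                       base_params = c(alpha1 = 89.43, alpha2 = 113.18, alpha3 = 32.03),
                       ages = c(0, 21, 42, 63, 77, 105, 150),
                       residual_sd_by_age = c(0.25, 0.75, 1.25, 1.75, 2.25, 2.75, 3.25),
                       true_effects = list(),
                       covariate_effects = default_covariate_effects(),
                       trait_noise_sd = c(alpha1 = 0, alpha2 = 0, alpha3 = 0),
                       het_scale = 0,
                       seed = 1L) {
  chromosomes <- tibble::as_tibble(chromosomes)
  if (any(chromosomes$n_markers <= 0) || any(chromosomes$length_cM <= 0)) {
    abort("Marker counts and chromosome lengths must be positive.",
          class = "growthqr_config_error")
  }
  if (length(residual_sd_by_age) != length(ages) ||
      is.unsorted(residual_sd_by_age)) {
    abort("`residual_sd_by_age` must be non-decreasing, one SD per age.",
          class = "growthqr_config_error")
  }
  if (base_params[["alpha1"]] <= 0 || base_params[["alpha3"]] <= 0) {
    abort("Base alpha1 and alpha3 must be positive.", class = "growthqr_config_error")
  }
  if (het_scale < 0) abort("`het_scale` must be non-negative.",
                           class = "growthqr_config_error")
  structure(
    list(n_animals = as.integer(n_animals), chromosomes = chromosomes,
         base_params = base_params, ages = ages,
         residual_sd_by_age = residual_sd_by_age,
         true_effects = true_effects, covariate_effects = covariate_effects,
         trait_noise_sd = trait_noise_sd, het_scale = het_scale,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default chromosome layout (six pig chromosomes, 237 SNPs)
#' @return Tibble with columns `chr`, `n_markers`, `length_cM`.
#' @export
default_chromosomes <- function() {
  tibble::tibble(
    chr = c("SSC1", "SSC4", "SSC7", "SSC8", "SSC17", "SSCX"),
    n_markers = c(56L, 54L, 59L, 31L, 25L, 12L),
    length_cM = c(160, 130, 150, 120, 70, 100)
  )
}

default_covariate_effects <- function() {
  list(
    alpha1 = list(sex = c(female = 0, male = 6),
                  lot = c(L1 = 0, L2 = 1.5, L3 = -1, L4 = 0.5, L5 = -0.5),
                  halothane = c(NN = 0, Nn = -2)),
    alpha2 = list(sex = c(female = 0, male = 3)),
    alpha3 = list(sex = c(female = 0, male = 1))
  )
}

## Haldane map function: recombination fraction for a distance d in cM
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Simulate F2-cross genotypes
#'
#' Founder line A is fixed for the allele coded 2 and line B for the allele
#' coded 0 at every marker, so all F1s are heterozygous. Each F2 genotype is
#' the sum of two F1 gametes; a gamete's founder-origin sequence follows a
#' Markov walk along each chromosome with Haldane recombination fractions
#' `r = (1 - exp(-2d/100))/2` between adjacent markers `d` cM apart.
#' Per-locus genotypes therefore segregate 1:2:1 and linked markers show
#' map-distance-driven LD.
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()]; deterministic given `config$seed`.
#' @export
simulate_genotypes <- function(config) {
  chrs <- config$chromosomes
  map <- purrr::pmap_dfr(chrs, function(chr, n_markers, length_cM) {
    tibble::tibble(
      chr = chr,
      pos_cM = if (n_markers == 1L) length_cM / 2 else
        seq(0, length_cM, length.out = n_markers)
    )
  })
  map$marker_id <- sprintf("%s_M%03d", map$chr, stats::ave(
    seq_len(nrow(map)), map$chr, FUN = seq_along))
  n <- config$n_animals
  calls <- withr::with_seed(config$seed, {
    out <- matrix(0L, n, nrow(map))
    col0 <- 0L
    for (ci in seq_len(nrow(chrs))) {
      m <- chrs$n_markers[ci]
      pos <- map$pos_cM[map$chr == chrs$chr[ci]]
      r <- haldane_r(diff(pos))
      g1 <- sim_gametes(n, m, r)
      g2 <- sim_gametes(n, m, r)
      out[, col0 + seq_len(m)] <- g1 + g2
      col0 <- col0 + m
    }
    out
  })
  rownames(calls) <- sprintf("A%04d", seq_len(n))
  colnames(calls) <- map$marker_id
  genotype_panel(calls, map[c("marker_id", "chr", "pos_cM")])
}

## n gametes over m linked markers: 1 = allele from founder line A, 0 = line B
sim_gametes <- function(n, m, r) {
  g <- matrix(0L, n, m)
  g[, 1L] <- as.integer(runif(n) < 0.5)
  if (m > 1L) {
    for (j in 2L:m) {
      swap <- runif(n) < r[j - 1L]
      g[, j] <- ifelse(swap, 1L - g[, j - 1L], g[, j - 1L])
    }
  }
  g
}

#' Simulate weight-age phenotypes on a genotype panel
#'
#' Per animal, the true curve parameters are the base parameters plus the
#' additive marker effects (`sum_k x_ik * effect_k` per trait), plus the
#' configured covariate shifts, plus optional animal-level trait noise
#' (heteroscedastic across genotypes when `het_scale > 0`). Weights at the
#' configured ages are the logistic curve through the true parameters plus
#' Gaussian noise with the age-indexed SD schedule; non-positive draws are
#' resampled so weights stay strictly positive.
#'
#' @param panel A [genotype_panel()], typically from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return List with `records` (long tibble `animal_id`, `age_days`,
#'   `weight_kg`), `covariates` (tibble `animal_id`, `sex`, `lot`,
#'   `halothane`), and `truth` (tibble of true per-animal parameters plus
#'   the config's effect maps as attribute `true_effects`).
#' @export
simulate_phenotypes <- function(panel, config) {
  n <- length(panel$animal_ids)
  withr::with_seed(config$seed + 1L, {
    covariates <- tibble::tibble(
      animal_id = panel$animal_ids,
      sex = sample(c("female", "male"), n, replace = TRUE),
      lot = sample(paste0("L", 1:5), n, replace = TRUE),
      halothane = sample(c("NN", "Nn"), n, replace = TRUE, prob = c(0.7, 0.3))
    )
    par <- matrix(rep(config$base_params[traits], each = n), n, 3L,
                  dimnames = list(panel$animal_ids, traits))
    for (tr in traits) {
      eff <- config$true_effects[[tr]]
      if (length(eff) > 0) {
        missing <- setdiff(names(eff), panel$marker_ids)
        if (length(missing) > 0) {
          abort(sprintf("Effect marker(s) not in panel: %s.",
                        paste(missing, collapse = ", ")),
                class = "growthqr_config_error")
        }
        par[, tr] <- par[, tr] +
          drop(panel$calls[, names(eff), drop = FALSE] %*% eff)
      }
      cov_eff <- config$covariate_effects[[tr]]
      for (v in names(cov_eff)) {
        shift <- cov_eff[[v]][covariates[[v]]]
        shift[is.na(shift)] <- 0
        par[, tr] <- par[, tr] + shift
      }
      sd_tr <- if (tr %in% names(config$trait_noise_sd))
        config$trait_noise_sd[[tr]] else 0
      if (sd_tr > 0) {
        sd_i <- rep(sd_tr, n)
        if (config$het_scale > 0 && length(config$true_effects[[tr]]) > 0) {
          xbar <- rowMeans(panel$calls[, names(config$true_effects[[tr]]),
                                       drop = FALSE])
          sd_i <- sd_tr * (1 + config$het_scale * xbar / 2)
        }
        par[, tr] <- par[, tr] + rnorm(n, 0, sd_i)
      }
    }
    if (any(par[, "alpha1"] <= 0) || any(par[, "alpha3"] <= 0)) {
      abort("Configured effects drive alpha1 or alpha3 non-positive.",
            class = "growthqr_config_error")
    }
    records <- tidyr::expand_grid(animal_id = panel$animal_ids,
                                  age_days = config$ages)
    i <- match(records$animal_id, panel$animal_ids)
    j <- match(records$age_days, config$ages)
    mu <- logistic_predict(records$age_days, par[i, "alpha1"],
                           par[i, "alpha2"], par[i, "alpha3"])
    sdv <- config$residual_sd_by_age[j]
    w <- unname(mu + rnorm(length(mu), 0, sdv))
    bad <- which(w <= 0)
    while (length(bad) > 0) {
      w[bad] <- mu[bad] + rnorm(length(bad), 0, sdv[bad])
      bad <- bad[w[bad] <= 0]
    }
    records$weight_kg <- w
    truth <- tibble::as_tibble(par, rownames = "animal_id")
    attr(truth, "true_effects") <- config$true_effects
    list(records = as_growth_records(records), covariates = covariates,
         truth = truth)
  })
}

#' Simulate a complete F2 dataset
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return List with `panel`, `records`, `covariates`, `truth`.
#' @export
simulate_f2 <- function(config = sim_config()) {
  panel <- simulate_genotypes(config)
  ph <- simulate_phenotypes(panel, config)
  c(list(panel = panel), ph)
}
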