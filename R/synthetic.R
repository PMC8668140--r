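#' Reference per-region Fos means and SEMs
#'
#' Published group means and SEMs of Fos+ cell counts per region, condition
#' and sex, used to calibrate the synthetic generator to a realistic scale.
#' Values are per-animal averages of Fos-immunoreactive cells per image.
#'
#' @return Tibble with columns `region, condition, sex, mean, sem` (132 rows:
#'   11 regions x 6 conditions x 2 sexes).
#' @export
fos_reference_means <- function() {
  conds <- condition_codes()
  # per region: mean,sem for (AN,AB,AL,COT,BOT,BLT) x (F,M)
  vals <- list(
    "vmPFC"  = c(244,37, 229,72, 244,20, 239,33, 266,41, 272,51,
                 246,37, 241,32, 268,52, 212,31, 249,44, 221,43),
    "aIC"    = c(183,32, 187,40, 198,20, 215,22, 212,50, 206,27,
                 232,32, 193,14, 223,31, 176,26, 227,21, 174,24),
    "gIC5/6" = c(100,38,  87,44, 197,29, 178,77, 206,44, 206,70,
                  81,45,  86,26, 162,53, 145,23, 144,55,  99,72),
    "gIC4"   = c(134,66,  85,28, 262,23, 253,82, 255,23, 267,89,
                 148,82,  98,64, 225,69, 184,27, 121,45,  79,43),
    "NAcC"   = c( 91,30,  98,35, 133, 7,  98,20, 100,62, 109,29,
                 110, 1,  76,18, 123,26,  99,34, 101,21,  64,29),
    "NAcS"   = c(117,39, 123,36, 125,19, 107,33, 171,78, 141,68,
                 120,26,  90,17, 153,38, 113,41, 124,52, 118,52),
    "SON"    = c(  7, 5,  14, 8,  11, 9,  10,12, 112,34, 112, 3,
                  10,10,   2, 1,  21, 6,  27,27,   5, 2,  45,70),
    "BLA"    = c( 34, 8,  32, 8,  56,16,  53, 8,  67,25,  58,15,
                  52,19,  24, 5,  61,10,  42, 3,  52, 6,  41,15),
    "CeA"    = c( 44,22,  42,26, 133,40, 108,33, 191,73, 199,58,
                  30, 7,  42,60, 142,19, 115,60,  62,48,  48,28),
    "PVN"    = c(113,51, 103,26, 122,51, 143,29, 230,102, 226,96,
                  95,36, 107,28,  91,20,  74,45, 141,39, 134,70),
    "VTA"    = c( 63,17,  50,13,  84,30,  92,16,  93,29,  52,15,
                  63,22,  69,15, 118,22,  66,30,  83,13,  51, 9)
  )
  rows <- lapply(names(vals), function(reg) {
    v <- matrix(vals[[reg]], ncol = 2, byrow = TRUE)
    tibble::tibble(
      region = reg,
      condition = rep(conds, each = 2),
      sex = rep(c("F", "M"), times = 6),
      mean = v[, 1],
      sem = v[, 2]
    )
  })
  dplyr::bind_rows(rows)
}

#' Build a positive-definite correlation matrix with planted edges
#'
#' Constructs a symmetric unit-diagonal matrix with the requested pairwise
#' correlations and zeros elsewhere, then repairs it to the nearest
#' positive-definite correlation matrix when the planted set is not jointly
#' feasible. The default repair clips eigenvalues below `min_eig` and
#' rescales back to unit diagonal; `method = "higham"` uses the Higham
#' alternating-projections routine from the Matrix package instead. Achieved
#' values and deviations from the planted targets are attached; a deviation
#' above 0.05 triggers a warning with the achieved value.
#'
#' @param regions Character vector of node names.
#' @param planted_edges Data frame with columns `region_a, region_b,
#'   target_r` (|target_r| < 1), or `NULL` for the identity.
#' @param min_eig Minimum eigenvalue after repair.
#' @param method `"clip"` (default) or `"higham"`.
#' @return Correlation matrix with attributes `deviation` (max absolute
#'   deviation from planted targets) and `planted` (the input edge table).
#' @export
make_correlation_target <- function(regions, planted_edges = NULL,
                                    min_eig = 1e-8,
                                    method = c("clip", "higham")) {
  method <- match.arg(method)
  k <- length(regions)
  R <- diag(k)
  dimnames(R) <- list(regions, regions)
  if (!is.null(planted_edges) && nrow(planted_edges) > 0) {
    require_columns(planted_edges, c("region_a", "region_b", "target_r"),
                    "planted edge table")
    if (any(abs(planted_edges$target_r) >= 1)) {
      stop_value("planted |target_r| must be < 1")
    }
    ia <- match(planted_edges$region_a, regions)
    ib <- match(planted_edges$region_b, regions)
    if (any(is.na(ia)) || any(is.na(ib))) stop_value("planted edge names unknown")
    if (any(ia == ib)) stop_value("planted edges must join distinct regions")
    R[cbind(ia, ib)] <- planted_edges$target_r
    R[cbind(ib, ia)] <- planted_edges$target_r
  }
  if (min(eigen(R, symmetric = TRUE)$values) < min_eig) {
    if (method == "clip") {
      # rescaling to unit diagonal can push the smallest eigenvalue back
      # under the floor, so clip-and-rescale until it holds
      for (it in 1:50) {
        ev <- eigen(R, symmetric = TRUE)
        if (min(ev$values) >= min_eig) break
        R <- stats::cov2cor(
          ev$vectors %*% diag(pmax(ev$values, 2 * min_eig)) %*% t(ev$vectors))
      }
    } else {
      R <- as.matrix(Matrix::nearPD(R, corr = TRUE,
                                    eig.tol = min_eig)$mat)
    }
    dimnames(R) <- list(regions, regions)
  }
  dev <- 0
  if (!is.null(planted_edges) && nrow(planted_edges) > 0) {
    ia <- match(planted_edges$region_a, regions)
    ib <- match(planted_edges$region_b, regions)
    achieved <- R[cbind(ia, ib)]
    dev <- max(abs(achieved - planted_edges$target_r))
    if (dev > 0.05) {
      warn(sprintf(
        "planted edge set infeasible; max deviation %.3f (achieved: %s)",
        dev, paste(sprintf("%s-%s %.3f", planted_edges$region_a,
                           planted_edges$region_b, achieved),
                   collapse = ", ")))
    }
  }
  attr(R, "deviation") <- dev
  attr(R, "planted") <- planted_edges
  R
}

#' Configuration for the synthetic Fos generator
#'
#' Defaults calibrate cell means and SDs to the published group summaries
#' ([fos_reference_means()]), with SD recovered from the printed SEM as
#' `sem * sqrt(sem_n)`. `sem_n = 4` reflects the modal group size of the
#' published figure legends (ranges of 3-4 animals per sex per condition);
#' exact per-cell group sizes were not published, so this is the midpoint
#' convention. Group size `n_per_group` is per sex per condition, so the
#' pooled-sex n per condition is `2 * n_per_group`.
#'
#' @param regions Region codes (default registry).
#' @param conditions Condition codes to simulate.
#' @param calibration Tibble `region, condition, sex, mean, sd`; defaults to
#'   the published means with `sd = sem * sqrt(sem_n)`.
#' @param sem_n Group size assumed when converting SEM to SD.
#' @param n_per_group Subjects per sex per condition; either a single number
#'   or a named vector `c(F = ..., M = ...)` for unbalanced sexes.
#' @param planted_edges Named list (by condition) of data frames
#'   `region_a, region_b, target_r`: the condition-specific correlation
#'   structure to plant. Conditions not named get no planted edges.
#' @param sex_shift Multiplier applied to female cell means (default 1, i.e.
#'   sexes differ only through the calibration table itself).
#' @param seed Default seed used by [simulate_fos()] when none is given.
#' @return A `synthetic_fos_config` list.
#' @export
synthetic_fos_config <- function(regions = region_registry(),
                                 conditions = condition_codes(),
                                 calibration = NULL,
                                 sem_n = 4,
                                 n_per_group = 4,
                                 planted_edges = list(),
                                 sex_shift = 1,
                                 seed = NULL) {
  if (is.null(calibration)) {
    calibration <- fos_reference_means()
    calibration$sd <- calibration$sem * sqrt(sem_n)
  }
  require_columns(calibration, c("region", "condition", "sex", "mean", "sd"),
                  "calibration table")
  if (length(n_per_group) == 1L) {
    n_per_group <- c(F = unname(n_per_group), M = unname(n_per_group))
  }
  if (!all(c("F", "M") %in% names(n_per_group))) {
    stop_value("n_per_group must be a single number or named c(F = , M = )")
  }
  if (sum(n_per_group) < 3) stop_value("pooled n must be >= 3 for correlation")
  if (!all(names(planted_edges) %in% conditions)) {
    stop_value("planted_edges names must be condition codes")
  }
  structure(list(regions = regions, conditions = conditions,
                 calibration = tibble::as_tibble(calibration),
                 n_per_group = n_per_group,
                 planted_edges = planted_edges,
                 sex_shift = sex_shift, seed = seed),
            class = "synthetic_fos_config")
}

censored_normal_mean <- function(mu, sd) {
  # E[max(0, X)], X ~ N(mu, sd): the expected cell mean after clamping at 0
  ifelse(sd == 0, pmax(mu, 0),
         mu * stats::pnorm(mu / sd) + sd * stats::dnorm(mu / sd))
}

#' Simulate a per-subject Fos count table with planted correlations
#'
#' For each condition, subjects of each sex are drawn from a multivariate
#' Gaussian whose correlation matrix is the planted (PD-repaired) target for
#' that condition and whose per-region means and SDs come from the
#' calibration table; draws are clamped at 0, since Fos counts cannot be
#' negative. Clamping biases low-mean cells upward; the analytically expected
#' post-clamp cell means are reported in the ground-truth metadata so that
#' calibration checks can account for it. Output is deterministic given the
#' seed.
#'
#' @param config A [synthetic_fos_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @return A validated `fos_table` with attribute `truth`: list with the
#'   per-condition target correlation matrices, planted edges, expected
#'   post-clamp cell means and the seed used.
#' @export
simulate_fos <- function(config, seed = config$seed) {
  if (!inherits(config, "synthetic_fos_config")) {
    stop_usage("config must come from synthetic_fos_config()")
  }
  if (!is.null(seed)) set.seed(seed)
  regs <- config$regions
  k <- length(regs)
  targets <- lapply(stats::setNames(config$conditions, config$conditions),
                    function(cond) {
                      make_correlation_target(regs, config$planted_edges[[cond]])
                    })
  rows <- list()
  for (cond in config$conditions) {
    R <- targets[[cond]]
    for (sx in c("F", "M")) {
      cal <- config$calibration[config$calibration$condition == cond &
                                config$calibration$sex == sx, ]
      cal <- cal[match(regs, cal$region), ]
      if (any(is.na(cal$mean))) {
        stop_value(sprintf("calibration missing cells for %s/%s", cond, sx))
      }
      n_sx <- config$n_per_group[[sx]]
      if (n_sx == 0L) next
      mu <- cal$mean * if (sx == "F") config$sex_shift else 1
      sd <- cal$sd
      z <- MASS::mvrnorm(n_sx, mu = rep(0, k), Sigma = R)
      z <- matrix(z, ncol = k)
      x <- sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
      x <- pmax(x, 0)
      ids <- sprintf("%s_%s%02d", cond, sx, seq_len(n_sx))
      rows[[paste(cond, sx)]] <- tibble::tibble(
        subject_id = rep(ids, each = k),
        sex = sx,
        condition = cond,
        region = rep(regs, times = n_sx),
        fos_count = as.vector(t(x))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- validate_fos_table(out, regions = regs, conditions = config$conditions)
  cal <- config$calibration
  cal$mean_shifted <- cal$mean * ifelse(cal$sex == "F", config$sex_shift, 1)
  cal$expected_mean <- censored_normal_mean(cal$mean_shifted, cal$sd)
  attr(out, "truth") <- list(
    targets = targets,
    planted_edges = config$planted_edges,
    expected_cell_means = cal,
    n_per_group = config$n_per_group,
    seed = seed
  )
  out
}

#' Configuration for the synthetic behavior generator
#'
#' The generator emulates the two behavioral cohorts of a CTA dose-response
#' study. The drinking/nausea cohort receives NaCl (dose 0, condition BOT:
#' Boost paired with NaCl) or LiCl at 19/38/80 mg/kg (condition BLT) and the
#' expected day-2/day-1 intake ratio follows a non-increasing dose curve with
#' ratio 1 at dose 0. The USV cohort covers the three task conditions with
#' condition- and sex-specific call rates; many animals do not vocalize at
#' all, which the zero-inflation probabilities `p55`/`p22` capture. Nausea
#' block scores come from a dose-shifted latent Gaussian cut at fixed
#' thresholds, so scores increase stochastically with dose.
#'
#' @param n_per_dose Animals per sex per dose group.
#' @param n_per_task Animals per sex per task condition (USV cohort).
#' @param doses LiCl doses in mg/kg (0 = NaCl control).
#' @param dose_ratio_curve Named expected D2/D1 ratio per dose; must be
#'   non-increasing in dose and 1 at dose 0.
#' @param intake_per_kg_mean Named (`F`, `M`) mean day-1 intake in mL/kg;
#'   females drink more per kg than males by default.
#' @param intake_cv Lognormal coefficient of variation of day-1 intake.
#' @param ratio_cv Lognormal noise on the realized D2/D1 ratio.
#' @param weight_mean,weight_sd Named (`F`, `M`) body-weight parameters (g).
#' @param usv_rates Named list per task condition of per-sex lists with
#'   `p55, rate55, p22, rate22`: probability the animal vocalizes in that
#'   channel at all, and its mean calls per minute when it does.
#' @param usv_size Negative-binomial dispersion of per-minute call counts.
#' @param nausea_beta Latent-scale shift per mg/kg LiCl.
#' @param nausea_cuts Latent cutpoints mapping to scores 1, 2, 3.
#' @param nausea_subject_sd SD of the per-subject latent intercept.
#' @param conditioning_dose Dose (mg/kg) used in the task arm.
#' @param seed Default seed for [simulate_behavior()].
#' @return A `synthetic_behavior_config` list.
#' @export
synthetic_behavior_config <- function(
    n_per_dose = 8,
    n_per_task = 8,
    doses = licl_doses(),
    dose_ratio_curve = c("0" = 1.0, "19" = 0.65, "38" = 0.45, "80" = 0.30),
    intake_per_kg_mean = c(F = 45, M = 35),
    intake_cv = 0.25,
    ratio_cv = 0.20,
    weight_mean = c(F = 250, M = 350),
    weight_sd = c(F = 20, M = 30),
    usv_rates = NULL,
    usv_size = 1.5,
    nausea_beta = 0.045,
    nausea_cuts = c(1.5, 2.5, 3.5),
    nausea_subject_sd = 0.5,
    conditioning_dose = 38,
    seed = NULL) {
  if (!all(as.character(doses) %in% names(dose_ratio_curve))) {
    stop_value("dose_ratio_curve must name every dose")
  }
  curve <- dose_ratio_curve[as.character(sort(doses))]
  if (any(diff(curve) > 0)) {
    stop_value("expected D2/D1 must be non-increasing in dose")
  }
  if (any(dose_ratio_curve < 0)) stop_value("ratios must be >= 0")
  if (is.null(usv_rates)) {
    usv_rates <- list(
      COT = list(F = list(p55 = 0.35, rate55 = 4, p22 = 0.25, rate22 = 1),
                 M = list(p55 = 0.20, rate55 = 4, p22 = 0.10, rate22 = 1)),
      BOT = list(F = list(p55 = 0.60, rate55 = 18, p22 = 0.25, rate22 = 1),
                 M = list(p55 = 0.55, rate55 = 18, p22 = 0.15, rate22 = 1)),
      BLT = list(F = list(p55 = 0.45, rate55 = 7, p22 = 0.60, rate22 = 3),
                 M = list(p55 = 0.35, rate55 = 7, p22 = 0.20, rate22 = 3))
    )
  }
  structure(list(n_per_dose = n_per_dose, n_per_task = n_per_task,
                 doses = doses, dose_ratio_curve = dose_ratio_curve,
                 intake_per_kg_mean = intake_per_kg_mean,
                 intake_cv = intake_cv, ratio_cv = ratio_cv,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 usv_rates = usv_rates, usv_size = usv_size,
                 nausea_beta = nausea_beta, nausea_cuts = nausea_cuts,
                 nausea_subject_sd = nausea_subject_sd,
                 conditioning_dose = conditioning_dose, seed = seed),
            class = "synthetic_behavior_config")
}

rlnorm_mean_cv <- function(n, mean, cv) {
  # lognormal with the requested arithmetic mean and coefficient of variation
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate behavioral records: drinking, USVs and nausea observations
#'
#' See [synthetic_behavior_config()] for the generative model. Output is
#' deterministic given the seed.
#'
#' @param config A [synthetic_behavior_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @return List with `behavior` (one row per drinking-cohort animal: weight,
#'   day-1/day-2 intake, dose, estrous state), `usv` (wide per-minute call
#'   counts for the task cohort) and `nausea` (long block scores for the
#'   three nausea behaviors in the drinking cohort), plus a `truth` attribute
#'   with the config and seed.
#' @export
simulate_behavior <- function(config, seed = config$seed) {
  if (!inherits(config, "synthetic_behavior_config")) {
    stop_usage("config must come from synthetic_behavior_config()")
  }
  if (!is.null(seed)) set.seed(seed)

  # drinking + nausea cohort: one group per dose per sex
  beh <- list(); nau <- list()
  for (dose in config$doses) {
    for (sx in c("F", "M")) {
      n <- config$n_per_dose
      ids <- sprintf("D%g_%s%02d", dose, sx, seq_len(n))
      w <- stats::rnorm(n, config$weight_mean[[sx]], config$weight_sd[[sx]])
      w <- pmax(w, 150)
      d1 <- rlnorm_mean_cv(n, config$intake_per_kg_mean[[sx]], config$intake_cv) *
        (w / 1000)
      ratio <- config$dose_ratio_curve[[as.character(dose)]]
      d2 <- d1 * rlnorm_mean_cv(n, max(ratio, 1e-6), config$ratio_cv)
      beh[[paste(dose, sx)]] <- tibble::tibble(
        subject_id = ids, sex = sx,
        condition = if (dose == 0) "BOT" else "BLT",
        body_weight = w, intake_d1 = d1, intake_d2 = d2,
        licl_dose = dose,
        estrous_state = if (sx == "F") {
          sample(c("high_E2", "low_E2"), n, replace = TRUE)
        } else NA_character_
      )
      # nausea: latent Gaussian, per-subject intercept, cut into 0..3
      for (bh in c("pica", "LOB", "ptosis")) {
        intercept <- stats::rnorm(n, 0, config$nausea_subject_sd)
        latent <- matrix(stats::rnorm(n * 24, config$nausea_beta * dose, 1),
                         nrow = n) + intercept
        score <- matrix(findInterval(latent, config$nausea_cuts), nrow = n)
        nau[[paste(dose, sx, bh)]] <- tibble::tibble(
          subject_id = rep(ids, each = 24),
          behavior = bh,
          epoch_index = rep(rep(0:11, each = 2), times = n),
          block_index = rep(rep(0:1, times = 12), times = n),
          score = as.integer(t(score))
        )
      }
    }
  }

  # USV cohort: task conditions, zero-inflated negative-binomial counts
  usv <- list()
  for (cond in names(config$usv_rates)) {
    for (sx in c("F", "M")) {
      n <- config$n_per_task
      ids <- sprintf("U%s_%s%02d", cond, sx, seq_len(n))
      pars <- config$usv_rates[[cond]][[sx]]
      emit55 <- stats::rbinom(n, 1, pars$p55)
      emit22 <- stats::rbinom(n, 1, pars$p22)
      c55 <- matrix(stats::rnbinom(n * 10, size = config$usv_size,
                                   mu = pars$rate55), nrow = n) * emit55
      c22 <- matrix(stats::rnbinom(n * 10, size = config$usv_size,
                                   mu = pars$rate22), nrow = n) * emit22
      row <- tibble::as_tibble(cbind(c55, c22),
                               .name_repair = ~ c(paste0("min55_", 1:10),
                                                  paste0("min22_", 1:10)))
      usv[[paste(cond, sx)]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = ids, sex = sx, condition = cond), row)
    }
  }

  out <- list(behavior = dplyr::bind_rows(beh),
              usv = dplyr::bind_rows(usv),
              nausea = dplyr::bind_rows(nau))
  attr(out, "truth") <- list(config = config, seed = seed)
  out
}
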