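#' Draw normalized tie distances from the continuous circle model
#'
#' Inverse-CDF sampling from the density \eqn{f(t;\eta) = \eta e^{\eta t} /
#' (e^\eta - 1)} on \[0, 1\]:
#' \eqn{t = \log\{1 + u(e^\eta - 1)\}/\eta} with \eqn{u} uniform on (0, 1);
#' uniform draws at \eqn{\eta = 0}. Uses R's current RNG stream; seed it
#' (e.g. with [withr::with_seed()]) for reproducibility.
#'
#' @param eta Circle-model parameter.
#' @param L Number of draws.
#' @return Numeric vector of `L` distances in (0, 1), whose mean converges
#'   to [mean_distance_curve()]`(eta)`.
#' @export
sample_tie_distances <- function(eta, L) {
  stopifnot(is.numeric(eta), length(eta) == 1, is.finite(eta),
            is.numeric(L), length(L) == 1, L >= 1)
  u <- runif(L)
  if (abs(eta) < 1e-10) return(u)
  log1p(u * expm1(eta)) / eta
}

#' Planted linear predictor for eta
#'
#' Builds each ego's true \eqn{\eta} from demographic covariates:
#' \deqn{\eta = \beta_0 + \beta_{ego} L + \beta_{grp} G + \beta_{sp} I_{chimp}
#'   + \beta_{sex} I_{male} + \beta_{hab} I_{zoo} + \beta_{age} z(age)
#'   + \beta_{sp \times age} I_{chimp} z(age) + \beta_{sp \times sex}
#'   I_{chimp} I_{male} + \epsilon,}
#' with age standardized to the cohort mean/SD and
#' \eqn{\epsilon \sim N(0, \mathrm{noise\_sd}^2)} drawn from the current
#' RNG stream.
#'
#' @param covariates Data frame with columns `ego_size`, `group_size`,
#'   `species` (`"chimpanzee"`/`"bonobo"` or 0/1), `sex` (`"male"`/
#'   `"female"` or 0/1), `habitat` (`"zoo"`/`"sanctuary"` or 0/1) and
#'   `age` (years).
#' @param coefficients Named list/vector with entries `intercept`,
#'   `ego_size`, `group_size`, `species`, `sex`, `habitat`, `age`,
#'   `species_age`, `species_sex`. Missing entries default to 0.
#' @param noise_sd Standard deviation of the Gaussian noise (0 for exact
#'   linear values).
#' @return Numeric vector of planted \eqn{\eta} values, with the age
#'   standardization recorded in attributes `age_mean` and `age_sd`.
#' @export
eta_linear_predictor <- function(covariates, coefficients, noise_sd = 0) {
  cf <- utils::modifyList(
    list(intercept = 0, ego_size = 0, group_size = 0, species = 0, sex = 0,
         habitat = 0, age = 0, species_age = 0, species_sex = 0),
    as.list(coefficients)
  )
  ind <- function(x, one) if (is.numeric(x)) as.numeric(x) else as.numeric(x == one)
  chimp <- ind(covariates$species, "chimpanzee")
  male <- ind(covariates$sex, "male")
  zoo <- ind(covariates$habitat, "zoo")
  age_mean <- mean(covariates$age)
  age_sd <- stats::sd(covariates$age)
  age_z <- if (is.na(age_sd) || age_sd == 0) {
    rep(0, nrow(covariates))
  } else {
    (covariates$age - age_mean) / age_sd
  }
  eta <- cf$intercept +
    cf$ego_size * covariates$ego_size +
    cf$group_size * covariates$group_size +
    cf$species * chimp +
    cf$sex * male +
    cf$habitat * zoo +
    cf$age * age_z +
    cf$species_age * chimp * age_z +
    cf$species_sex * chimp * male
  if (noise_sd > 0) eta <- eta + rnorm(nrow(covariates), 0, noise_sd)
  structure(eta, age_mean = age_mean, age_sd = age_sd)
}

#' Configuration of a synthetic grooming cohort
#'
#' Collects the parameters of the cohort generator. Defaults describe a
#' plausible captive *Pan* study population: mixed-species multi-group
#' cohort, groups of 8–20 animals, a dominant positive ego-network-size
#' effect on \eqn{\eta}, a negative species-by-age interaction for
#' chimpanzees, and grooming weights on a 1–50 interaction-count scale.
#'
#' @param n_groups Number of groups.
#' @param group_size_range Integer min/max group size; minimum must be at
#'   least 6 so generated groups pass the size filter by construction.
#' @param species_mix Proportion of groups that are bonobo (groups are
#'   single-species, as in real *Pan* housing).
#' @param habitat_mix Proportion of groups housed in zoos (vs sanctuary).
#' @param p_male Probability an individual is male.
#' @param age_range Min/max age in years (ages drawn uniformly).
#' @param coefficients Linear effects on \eqn{\eta}; see
#'   [eta_linear_predictor()].
#' @param group_intercepts Optional numeric vector (length `n_groups`)
#'   overriding `coefficients$intercept` per group — used to plant
#'   group-level mean \eqn{\eta}.
#' @param ego_size_range Optional integer min/max for the number of groomed
#'   partners per ego (default: uniform on \[5, group size - 1\]); the upper
#'   end is clipped to group size - 1 and the lower end must be at least 5.
#' @param noise_sd SD of the per-ego Gaussian noise on \eqn{\eta}.
#' @param weight_scale `c(s_min_target, s_max_target)`: the weight values
#'   that normalized distances 1 and 0 map to.
#' @param integer_weights Round weights to integers (floor 1), emulating
#'   interaction counts.
#' @param block_structure Plant two communities per group (partner choice
#'   biased within blocks) for modularity experiments.
#' @param block_within_ratio Within- vs between-block partner-choice odds
#'   ratio; scalar or per-group vector. Ignored unless `block_structure`.
#' @param seed Integer seed; fully determines the cohort.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_groups = 6,
                             group_size_range = c(8, 20),
                             species_mix = 0.5,
                             habitat_mix = 0.5,
                             p_male = 0.36,
                             age_range = c(5, 45),
                             coefficients = list(intercept = 2,
                                                 ego_size = 0.15,
                                                 species_age = -0.3),
                             group_intercepts = NULL,
                             ego_size_range = NULL,
                             noise_sd = 0.5,
                             weight_scale = c(1, 50),
                             integer_weights = FALSE,
                             block_structure = FALSE,
                             block_within_ratio = 5,
                             seed = 1L) {
  if (group_size_range[1] < 6) {
    abort("minimum group size must be >= 6 so generated groups pass the size filter")
  }
  if (!is.null(group_intercepts) && length(group_intercepts) != n_groups) {
    abort("`group_intercepts` must have one value per group")
  }
  stopifnot(weight_scale[1] > 0, weight_scale[2] > weight_scale[1])
  if (!is.null(ego_size_range) && ego_size_range[1] < 5) {
    abort("minimum ego size must be >= 5 so generated egos pass the partner filter")
  }
  structure(
    list(
      n_groups = n_groups, group_size_range = group_size_range,
      species_mix = species_mix, habitat_mix = habitat_mix, p_male = p_male,
      age_range = age_range, coefficients = coefficients,
      group_intercepts = group_intercepts, ego_size_range = ego_size_range,
      noise_sd = noise_sd,
      weight_scale = weight_scale, integer_weights = integer_weights,
      block_structure = block_structure,
      block_within_ratio = block_within_ratio,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic grooming cohort with planted eta
#'
#' For every ego: draw its number of partners L uniformly in
#' \[5, group size - 1\], compute its planted \eqn{\eta} from the covariate
#' linear predictor, draw L normalized distances by inverse-CDF sampling,
#' map them to weights \eqn{s = s_{max} - t (s_{max} - s_{min})}, optionally
#' round to integer counts (floor 1), and emit interaction records in the
#' exact schema [read_interactions()] consumes, plus metadata and a truth
#' table. Every generated group has at least 6 members and every ego at
#' least 5 partners, so [apply_filters()] retains everything by
#' construction.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort`: tibbles `interactions`,
#'   `metadata`, `truth` (per-ego `eta_true`, `L_true`, covariates, block
#'   label and the age standardization used), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  gsr <- cfg$group_size_range
  size_choices <- seq(as.integer(gsr[1]), as.integer(gsr[2]))
  sizes <- size_choices[sample.int(length(size_choices), cfg$n_groups,
                                   replace = TRUE)]
  group_ids <- sprintf("g%02d", seq_len(cfg$n_groups))
  species_g <- ifelse(runif(cfg$n_groups) < cfg$species_mix,
                      "bonobo", "chimpanzee")
  habitat_g <- ifelse(runif(cfg$n_groups) < cfg$habitat_mix,
                      "zoo", "sanctuary")
  ratio_g <- rep_len(cfg$block_within_ratio, cfg$n_groups)

  meta <- purrr::pmap_dfr(
    list(group_ids, sizes, species_g, habitat_g),
    function(g, n, sp, hab) {
      tibble(
        individual_id = sprintf("%s_i%02d", g, seq_len(n)),
        group_id = g,
        species = sp,
        sex = ifelse(runif(n) < cfg$p_male, "male", "female"),
        age = round(runif(n, cfg$age_range[1], cfg$age_range[2]), 1),
        habitat = hab
      )
    }
  )

  size_of <- setNames(sizes, group_ids)
  egos <- meta %>%
    mutate(
      group_size = unname(size_of[group_id]),
      ego_size = purrr::map_int(group_size, function(n) {
        esr <- cfg$ego_size_range %||% c(5L, n - 1L)
        # explicit indexing: sample(5L, 1) would draw from 1:5
        choices <- seq(as.integer(esr[1]), as.integer(min(esr[2], n - 1L)))
        choices[sample.int(length(choices), 1L)]
      }),
      block = 0L
    )
  if (cfg$block_structure) {
    egos <- egos %>%
      group_by(group_id) %>%
      mutate(block = as.integer(row_number() > dplyr::n() / 2)) %>%
      ungroup()
  }

  coefs <- cfg$coefficients
  eta_true <- eta_linear_predictor(egos, coefs, noise_sd = cfg$noise_sd)
  if (!is.null(cfg$group_intercepts)) {
    base_int <- coefs$intercept %||% 0
    shift <- setNames(cfg$group_intercepts - base_int, group_ids)
    eta_true <- eta_true + unname(shift[egos$group_id])
  }
  age_mean <- attr(eta_true, "age_mean")
  age_sd <- attr(eta_true, "age_sd")
  egos$eta_true <- as.numeric(eta_true)

  smin <- cfg$weight_scale[1]
  smax <- cfg$weight_scale[2]
  blk_of <- setNames(egos$block, egos$individual_id)
  ratio_of <- setNames(ratio_g, group_ids)
  interactions <- purrr::pmap_dfr(
    list(egos$individual_id, egos$group_id, egos$ego_size, egos$eta_true,
         egos$block),
    function(id, g, L, eta, blk) {
      others <- setdiff(meta$individual_id[meta$group_id == g], id)
      prob <- if (cfg$block_structure) {
        ifelse(blk_of[others] == blk, unname(ratio_of[g]), 1)
      } else {
        rep(1, length(others))
      }
      partners <- sample(others, L, replace = FALSE, prob = prob)
      t_vals <- sample_tie_distances(eta, L)
      w <- smax - t_vals * (smax - smin)
      if (cfg$integer_weights) w <- pmax(1, round(w))
      tibble(group_id = g, actor_id = id, receiver_id = partners, weight = w)
    }
  )

  truth <- egos %>%
    mutate(ego_id = individual_id, L_true = ego_size,
           age_mean = age_mean, age_sd = age_sd) %>%
    select(ego_id, group_id, eta_true, L_true, species, sex, age, habitat,
           group_size, block, age_mean, age_sd)

  structure(
    list(interactions = interactions, metadata = meta, truth = truth,
         config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic grooming cohort: %d groups, %d individuals, %d directed ties (seed %d)\n",
    length(unique(x$metadata$group_id)), nrow(x$metadata),
    nrow(x$interactions), x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `interactions.csv`, `metadata.csv` and `truth.csv` in the schemas
#' [read_interactions()] and [read_metadata()] consume.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("interactions.csv", "metadata.csv", "truth.csv"))
  readr::write_csv(cohort$interactions, paths[1])
  readr::write_csv(cohort$metadata, paths[2])
  readr::write_csv(cohort$truth, paths[3])
  invisible(paths)
}
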