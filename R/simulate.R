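## Synthetic questionnaire-data generator.
##
## Two generative chains share the count and cognition machinery:
##
## * a group-mixture chain (the default study configuration): participants
##   belong to latent engagement groups; a health propensity (group shift +
##   unit Gaussian) drives health cognitions, baseline and follow-up health
##   counts; a lifestyle-engagement latent drives lifestyle cognitions and
##   activity counts; groups may couple the two via a negative "conflict"
##   weight (lifestyle activity depresses follow-up health behavior) and an
##   interaction term between two designated activities supplies a
##   nonlinearity that a linear model cannot represent.
##
## * a planted-increment chain: four orthogonal participant factors (one per
##   predictor type that carries signal) combine into the health propensity
##   with weights computed analytically from the count-link attenuation, so
##   that hierarchical regression of the health index on the factors has
##   prescribed population delta-R-squared at each step.

HEALTH_COUNT_LOADING <- 0.8     # log-rate (or scaled-Gaussian) units per SD of propensity
LIFESTYLE_COUNT_LOADING <- 0.7  # same, per SD of the lifestyle latent
LIFESTYLE_LATENT_LOADING <- 0.8 # per-activity share of the common lifestyle latent
MAX_LOG_RATE <- log(100)        # cap on two-week expected counts

## Activities that track the common lifestyle-engagement (social/leisure)
## latent; the remaining activities vary independently of it.
DEFAULT_SOCIAL_BEHAVIORS <- c("visit_friend", "clubbing", "meal_out", "cinema",
                              "shopping", "buy_clothes", "walk", "countryside")

DEFAULT_BASE_RATES <- c(
  exercise = 5, smoking = 4, getting_drunk = 3, eat_fruit = 8, fast_food = 3,
  buy_magazine = 2, buy_newspaper = 2, read_pleasure = 4, vitamin_pills = 5,
  visit_friend = 5, meal_out = 2, attend_lectures = 8, sleep_7hours = 8,
  buy_clothes = 2, no_lie_in = 7, cinema = 1.5, walk = 4,
  independent_study = 7, write_letter = 1.5, recycle_bottles = 2,
  countryside = 1.5, library = 4, avoid_meat = 3, rent_video = 2,
  shopping = 3, visit_parents = 1.5, clubbing = 2, tidy_room = 3)

#' Specify one latent participant group
#'
#' @param label group label.
#' @param proportion expected fraction of the sample in `(0, 1]`.
#' @param engagement_shift additive shift of the latent health propensity, in
#'   SD units of its unit-Gaussian participant component.
#' @param cognition_loadings named list with elements `health_cognitions` and
#'   `lifestyle_cognitions`: scale points of cognition score per SD of the
#'   driving latent.
#' @param lifestyle_conflict weight of the lifestyle-engagement latent in the
#'   follow-up health propensity; negative values plant the conflict
#'   mechanism (busy lifestyles depress health behavior).
#' @param personality_shift named numeric offsets (SD units) for any of the
#'   five personality scales; unnamed scales default to 0.
#' @param smoker_profile if `TRUE`, the group gets a large positive shift on
#'   baseline and follow-up smoking counts and strongly negative
#'   avoid-smoking cognitions (a committed-smoker signature).
#' @param lifestyle_shift additive shift of the lifestyle-engagement latent.
#' @param lifestyle_profile named numeric per-activity log-rate shifts (e.g.
#'   `c(clubbing = 0.9)`), also reflected in that activity's cognitions.
#' @param cognition_offsets named numeric offsets (scale points) per
#'   cognition construct (`intention`, `attitude`, `norm`, `pbc`) applied to
#'   every behavior's cognitions for this group.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(label, proportion, engagement_shift = 0,
                       cognition_loadings = list(health_cognitions = 1.0,
                                                 lifestyle_cognitions = 0.8),
                       lifestyle_conflict = 0,
                       personality_shift = c(),
                       smoker_profile = FALSE,
                       lifestyle_shift = 0,
                       lifestyle_profile = c(),
                       cognition_offsets = c()) {
  stopifnot(proportion > 0, proportion <= 1)
  personality_shift <- unlist(personality_shift)
  cognition_offsets <- unlist(cognition_offsets)
  lifestyle_profile <- unlist(lifestyle_profile)
  ps <- stats::setNames(numeric(length(PERSONALITY_SCALES)), PERSONALITY_SCALES)
  ps[names(personality_shift)] <- personality_shift
  co <- stats::setNames(numeric(length(COGNITION_CONSTRUCTS)), COGNITION_CONSTRUCTS)
  co[names(cognition_offsets)] <- cognition_offsets
  structure(list(label = label, proportion = proportion,
                 engagement_shift = engagement_shift,
                 cognition_loadings = cognition_loadings,
                 lifestyle_conflict = lifestyle_conflict,
                 personality_shift = ps,
                 smoker_profile = isTRUE(smoker_profile),
                 lifestyle_shift = lifestyle_shift,
                 lifestyle_profile = lifestyle_profile,
                 cognition_offsets = co),
            class = "group_spec")
}

#' Build a simulation configuration
#'
#' @param n_participants sample size (must be at least 4 per group).
#' @param groups list of [group_spec()] objects; proportions must sum to 1.
#' @param noise_sd residual SD of cognition scores (scale points) and, for
#'   the `rounded_gaussian` link, of the count noise; must be positive.
#' @param nonlinearity_strength weight of the interaction between the two
#'   `nonlinearity_pair` activities in the health propensity (0 disables it).
#' @param count_link `"poisson_log"` (counts Poisson with log link, the
#'   default) or `"rounded_gaussian"` (rounded truncated Gaussian with
#'   Poisson-like mean-variance scaling, for variance control).
#' @param seed default seed used by [generate_dataset()].
#' @param catalog behavior catalog to simulate.
#' @param planted_increments optional numeric vector
#'   `c(health_cognitions =, personality =, lifestyle =, baseline_health =)`
#'   of population incremental variance fractions of the health index; when
#'   supplied the orthogonal-factor chain is used and group shifts are
#'   ignored.
#' @param assignment `"quota"` (deterministic largest-remainder group sizes,
#'   the default, for stable fixtures) or `"multinomial"` (sampled sizes).
#' @param null_behaviors lifestyle behaviors generated as pure noise,
#'   unrelated to any latent (useful as planted-null variables in salience
#'   experiments).
#' @param social_behaviors lifestyle activities that load on the common
#'   lifestyle-engagement latent (the group-mixture chain only; other
#'   activities vary independently, shaped only by group profiles).
#' @param base_rates named per-behavior expected two-week counts; defaults
#'   are calibrated so roughly half the sample engages in each behavior.
#' @param nonlinearity_pair the two lifestyle activities whose interaction
#'   enters the propensity.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants, groups, noise_sd = 0.8,
                              nonlinearity_strength = 0,
                              count_link = c("poisson_log", "rounded_gaussian"),
                              seed = 1L,
                              catalog = default_catalog(),
                              planted_increments = NULL,
                              assignment = c("quota", "multinomial"),
                              null_behaviors = c("rent_video", "avoid_meat",
                                                 "write_letter"),
                              social_behaviors = DEFAULT_SOCIAL_BEHAVIORS,
                              base_rates = NULL,
                              nonlinearity_pair = c("clubbing", "visit_friend")) {
  count_link <- match.arg(count_link)
  assignment <- match.arg(assignment)
  stopifnot(all(vapply(groups, inherits, logical(1), "group_spec")))
  props <- vapply(groups, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9) {
    stop("group proportions must sum to 1 (got ", sum(props), ")",
         call. = FALSE)
  }
  if (n_participants < 4L * length(groups)) {
    stop("n_participants must be at least 4 per group", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  beh <- catalog$behaviors$name
  rates <- DEFAULT_BASE_RATES[beh]
  names(rates) <- beh
  rates[is.na(rates)] <- ifelse(catalog$behaviors$is_health[is.na(rates)], 5, 3)
  if (!is.null(base_rates)) rates[names(base_rates)] <- base_rates
  if (!is.null(planted_increments)) {
    want <- c("health_cognitions", "personality", "lifestyle", "baseline_health")
    if (!setequal(names(planted_increments), want)) {
      stop("planted_increments must be named: ", paste(want, collapse = ", "),
           call. = FALSE)
    }
    planted_increments <- planted_increments[want]
    if (any(planted_increments < 0) || sum(planted_increments) >= 1) {
      stop("planted_increments must be nonnegative and sum to < 1",
           call. = FALSE)
    }
  }
  nonlinearity_pair <- intersect(nonlinearity_pair, lifestyle_names(catalog))
  structure(list(n_participants = as.integer(n_participants), groups = groups,
                 noise_sd = noise_sd,
                 nonlinearity_strength = nonlinearity_strength,
                 count_link = count_link, seed = as.integer(seed),
                 catalog = catalog, planted_increments = planted_increments,
                 assignment = assignment, null_behaviors = null_behaviors,
                 social_behaviors = intersect(social_behaviors,
                                              lifestyle_names(catalog)),
                 base_rates = rates, nonlinearity_pair = nonlinearity_pair),
            class = "simulation_config")
}

#' The default study configuration
#'
#' Four latent groups with the study's unequal sizes (92, 50, 64 and 5 of
#' 211 under quota assignment) and qualitatively distinct signatures:
#' a high-engagement group with strong normative cognitions; a
#' moderate-engagement group distinguished by weak subjective norms; a
#' low-engagement, socially active group in which lifestyle activity
#' conflicts with health behavior and action initiation (ACS hesitation) is
#' poor; and a very small very-low-engagement group of committed smokers
#' with external locus of control, high preoccupation and low self-efficacy.
#'
#' @param n_participants sample size (default 211).
#' @param seed default generation seed.
#' @return a `simulation_config`.
#' @export
default_study_config <- function(n_participants = 211, seed = 1L) {
  loadings <- list(health_cognitions = 0.6, lifestyle_cognitions = 0.8)
  groups <- list(
    group_spec("high", 92 / 211, engagement_shift = 0.9,
               cognition_loadings = loadings,
               cognition_offsets = c(norm = 0.95, intention = 0.5)),
    group_spec("moderate", 50 / 211, engagement_shift = 0.35,
               cognition_loadings = loadings,
               cognition_offsets = c(norm = -1.45)),
    group_spec("low", 64 / 211, engagement_shift = -1.0,
               cognition_loadings = loadings,
               lifestyle_conflict = -0.4, lifestyle_shift = 0.6,
               lifestyle_profile = c(clubbing = 1.8, visit_friend = 1.4,
                                     attend_lectures = -1.4, no_lie_in = -1.4,
                                     library = -1.1, independent_study = -1.1),
               cognition_offsets = c(intention = -0.65),
               personality_shift = c(acs_hesit = -1.3)),
    group_spec("very_low", 5 / 211, engagement_shift = -2.4,
               cognition_loadings = loadings,
               lifestyle_conflict = -0.4, lifestyle_shift = -1.2,
               smoker_profile = TRUE,
               lifestyle_profile = c(vitamin_pills = 1.8, cinema = -2.0,
                                     library = -2.0, shopping = -1.5,
                                     independent_study = -1.8,
                                     attend_lectures = -1.5, no_lie_in = -1.3,
                                     buy_newspaper = -1.8, buy_magazine = -1.3,
                                     walk = -1.3),
               cognition_offsets = c(pbc = -2.0, attitude = -1.1),
               personality_shift = c(locus = 1.5, acs_preocc = 1.8,
                                     self_eff = -2.2)))
  simulation_config(n_participants, groups, nonlinearity_strength = 0.25,
                    seed = seed)
}

#' Configuration with planted block-wise incremental validity
#'
#' A single-group configuration in which four orthogonal participant factors
#' feed the health index with prescribed population incremental variance
#' fractions, after analytically correcting for the attenuation introduced by
#' the count link. The defaults plant increments of 0.18 (health cognitions),
#' 0 (personality), 0.24 (lifestyle, split across its cognitions and
#' activities) and 0.29 (baseline health behaviors).
#'
#' @param n_participants sample size (default 2000).
#' @param increments named planted increments; see
#'   [simulation_config()]'s `planted_increments`.
#' @param seed default generation seed.
#' @return a `simulation_config`.
#' @export
incremental_config <- function(n_participants = 2000,
                               increments = c(health_cognitions = 0.18,
                                              personality = 0,
                                              lifestyle = 0.24,
                                              baseline_health = 0.29),
                               seed = 1L) {
  simulation_config(n_participants,
                    groups = list(group_spec("all", 1)),
                    planted_increments = increments,
                    nonlinearity_strength = 0,
                    seed = seed)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation config: n=", x$n_participants, ", ", length(x$groups),
      " group(s), link=", x$count_link,
      if (!is.null(x$planted_increments)) " (planted increments)", "\n",
      sep = "")
  invisible(x)
}

## Deterministic largest-remainder allocation of n rows to proportions.
quota_sizes <- function(n, props) {
  raw <- n * props
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_idx <- order(raw - sizes, decreasing = TRUE)
    sizes[order_idx[seq_len(rem)]] <- sizes[order_idx[seq_len(rem)]] + 1
  }
  as.integer(sizes)
}

## Count sampler for one behavior column. `signal` is the systematic effect
## in log-rate units (poisson_log) or per-sqrt(rate) units (rounded_gaussian,
## a linear-additive channel whose only extra noise is `noise_sd`-scaled
## Gaussian plus rounding -- useful for variance control and for noise-free
## limiting cases).
sample_counts <- function(rate, signal, link, noise_sd) {
  if (link == "poisson_log") {
    m <- exp(pmin(log(rate) + signal, MAX_LOG_RATE))
    stats::rpois(length(signal), m)
  } else {
    pmax(0, round(rate + sqrt(rate) *
                    (signal + stats::rnorm(length(signal), 0, noise_sd))))
  }
}

## Attenuation of the health index relative to the latent propensity for a
## given link: r_j = cor(count_j, propensity), rho2 = squared correlation of
## the index (mean of 5 z-scores) with the propensity.
index_attenuation <- function(rates, b, link, noise_sd = 1) {
  if (link == "poisson_log") {
    m <- rates * exp(b^2 / 2)
    r <- b / sqrt(1 / m + exp(b^2) - 1)
  } else {
    r <- b / sqrt(b^2 + noise_sd^2 + 1 / (12 * rates))
  }
  rbar <- mean(r)
  rho2 <- rbar^2 / (rbar^2 + sum(1 - r^2) / length(r)^2)
  list(r = r, rho2 = rho2)
}

clip_score <- function(x) round(pmin(7, pmax(1, x)), 3)

#' Generate a synthetic dataset with ground truth
#'
#' Deterministic given `(config, seed)`. Returns the raw dataset in the CSV
#' schema together with the generating ground truth (group labels, latent
#' propensities, planted increments) for recovery experiments.
#'
#' @param config a `simulation_config`.
#' @param seed integer seed (defaults to `config$seed`).
#' @return a list with elements `raw` (a `raw_dataset`) and `truth` (class
#'   `ground_truth`: `group_labels`, `group_names`, `latent_propensity`,
#'   `lifestyle_latent`, `planted_increments`).
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(seed, "generate_dataset"), generate_dataset_(config))
}

generate_dataset_ <- function(config) {
  n <- config$n_participants
  catalog <- config$catalog
  G <- length(config$groups)
  props <- vapply(config$groups, `[[`, numeric(1), "proportion")

  if (config$assignment == "quota") {
    sizes <- quota_sizes(n, props)
    if (any(sizes == 0)) {
      stop("degenerate configuration: group '",
           config$groups[[which(sizes == 0)[1]]]$label,
           "' has expected size 0 at n = ", n, call. = FALSE)
    }
    labels <- sample(rep.int(seq_len(G), sizes))
  } else {
    labels <- sample.int(G, n, replace = TRUE, prob = props)
  }

  if (is.null(config$planted_increments)) {
    out <- generate_group_chain(config, labels)
  } else {
    out <- generate_planted_chain(config, labels)
  }

  raw <- raw_dataset(pid = sprintf("P%04d", seq_len(n)),
                     baseline_counts = out$baseline,
                     cognitions = out$cognitions,
                     personality = out$personality,
                     followup_counts = out$followup,
                     catalog = catalog)
  truth <- structure(list(group_labels = labels,
                          group_names = vapply(config$groups, `[[`,
                                               character(1), "label"),
                          latent_propensity = out$propensity,
                          lifestyle_latent = out$lifestyle,
                          factors = out$factors,
                          planted_increments = config$planted_increments),
                     class = "ground_truth")
  list(raw = raw, truth = truth)
}

## Shared scaffolding: allocate the output matrices for a catalog.
empty_matrices <- function(n, catalog) {
  beh <- catalog$behaviors$name
  list(baseline = matrix(0L, n, length(beh),
                         dimnames = list(NULL, paste0("beh_", beh, "_t1"))),
       followup = matrix(0L, n, length(beh),
                         dimnames = list(NULL, paste0("beh_", beh, "_t2"))),
       cognitions = matrix(0, n, 4L * length(beh),
                           dimnames = list(NULL, cognition_colnames(catalog))),
       personality = matrix(0, n, length(PERSONALITY_SCALES),
                            dimnames = list(NULL,
                                            paste0("pers_", PERSONALITY_SCALES))))
}

generate_group_chain <- function(config, labels) {
  n <- config$n_participants
  catalog <- config$catalog
  beh_tab <- catalog$behaviors
  groups <- config$groups
  noise_sd <- config$noise_sd
  link <- config$count_link
  rates <- config$base_rates

  g_field <- function(field) vapply(groups, `[[`, numeric(1), field)[labels]
  shift <- g_field("engagement_shift")
  lshift <- g_field("lifestyle_shift")
  conflict <- g_field("lifestyle_conflict")
  smoker <- vapply(groups, `[[`, logical(1), "smoker_profile")[labels]
  l_health <- vapply(groups, function(g) g$cognition_loadings$health_cognitions,
                     numeric(1))[labels]
  l_life <- vapply(groups, function(g) g$cognition_loadings$lifestyle_cognitions,
                   numeric(1))[labels]
  pshift <- t(vapply(groups, `[[`, numeric(length(PERSONALITY_SCALES)),
                     "personality_shift"))[labels, , drop = FALSE]
  coff <- t(vapply(groups, `[[`, numeric(length(COGNITION_CONSTRUCTS)),
                   "cognition_offsets"))[labels, , drop = FALSE]
  colnames(coff) <- COGNITION_CONSTRUCTS

  p <- shift + stats::rnorm(n)    # health propensity
  l <- lshift + stats::rnorm(n)   # lifestyle-engagement latent

  life <- lifestyle_names(catalog)
  prof <- matrix(0, n, length(life), dimnames = list(NULL, life))
  for (gi in seq_along(groups)) {
    lp <- groups[[gi]]$lifestyle_profile
    if (length(lp)) {
      rows <- labels == gi
      for (b in names(lp)) prof[rows, b] <- lp[[b]]
    }
  }
  load_life <- stats::setNames(numeric(length(life)), life)
  load_life[intersect(config$social_behaviors, life)] <- LIFESTYLE_LATENT_LOADING
  load_life[intersect(config$null_behaviors, life)] <- 0
  ## per-activity shared latent (noise enters through the count link and the
  ## cognition residuals)
  shared <- outer(l, load_life) + prof

  ## nonlinearity: standardized interaction of the two designated activities
  t_nl <- 0
  if (config$nonlinearity_strength != 0 && length(config$nonlinearity_pair) == 2) {
    tt <- shared[, config$nonlinearity_pair[1]] * shared[, config$nonlinearity_pair[2]]
    if (stats::sd(tt) > 0) t_nl <- (tt - mean(tt)) / stats::sd(tt)
  }

  h <- p + conflict * l + config$nonlinearity_strength * t_nl
  h_c <- (h - mean(h)) / stats::sd(h)
  p_c <- (p - mean(p)) / stats::sd(p)

  out <- empty_matrices(n, catalog)
  risk <- risk_names(catalog)

  for (j in seq_len(nrow(beh_tab))) {
    b <- beh_tab$name[j]
    s <- if (b %in% risk) -1 else 1
    if (beh_tab$is_health[j]) {
      bump <- if (b == "smoking") ifelse(smoker, 2.0, 0) else 0
      sig2 <- HEALTH_COUNT_LOADING * s * h_c + bump
      sig1 <- HEALTH_COUNT_LOADING * s * p_c + bump
    } else {
      sig2 <- LIFESTYLE_COUNT_LOADING * shared[, b]
      sig1 <- sig2
    }
    out$followup[, paste0("beh_", b, "_t2")] <-
      sample_counts(rates[b], sig2, link, noise_sd)
    out$baseline[, paste0("beh_", b, "_t1")] <-
      sample_counts(rates[b], sig1, link, noise_sd)
  }

  for (j in seq_len(nrow(beh_tab))) {
    b <- beh_tab$name[j]
    driver <- if (beh_tab$is_health[j]) l_health * p else l_life * shared[, b]
    extra <- if (b == "smoking") ifelse(smoker, -2.8, 0) else 0
    for (con in COGNITION_CONSTRUCTS) {
      val <- 4 + driver + coff[, con] + extra + stats::rnorm(n, 0, noise_sd)
      out$cognitions[, paste0("cog_", b, "_", con)] <- clip_score(val)
    }
  }

  for (k in seq_along(PERSONALITY_SCALES)) {
    out$personality[, k] <- round(pshift[, k] + stats::rnorm(n), 3)
  }

  c(out, list(propensity = h, lifestyle = l))
}

generate_planted_chain <- function(config, labels) {
  n <- config$n_participants
  catalog <- config$catalog
  beh_tab <- catalog$behaviors
  noise_sd <- config$noise_sd
  link <- config$count_link
  rates <- config$base_rates
  t_inc <- config$planted_increments

  health <- health_names(catalog)
  att <- index_attenuation(rates[health], HEALTH_COUNT_LOADING, link, noise_sd)
  c2 <- t_inc / att$rho2
  if (sum(c2) > 0.98) {
    stop("planted increments too large for the count link: the index can ",
         "carry at most rho^2 = ", round(att$rho2, 3),
         " of propensity variance", call. = FALSE)
  }
  cw <- sqrt(c2)

  u_cog <- stats::rnorm(n)
  u_pers <- stats::rnorm(n)
  u_life <- stats::rnorm(n)
  u_base <- stats::rnorm(n)
  h <- cw[["health_cognitions"]] * u_cog + cw[["personality"]] * u_pers +
    cw[["lifestyle"]] * u_life + cw[["baseline_health"]] * u_base +
    sqrt(1 - sum(c2)) * stats::rnorm(n)

  out <- empty_matrices(n, catalog)
  risk <- risk_names(catalog)

  for (j in seq_len(nrow(beh_tab))) {
    b <- beh_tab$name[j]
    s <- if (b %in% risk) -1 else 1
    if (beh_tab$is_health[j]) {
      sig2 <- HEALTH_COUNT_LOADING * s * h
      sig1 <- HEALTH_COUNT_LOADING * s * u_base
    } else {
      sig2 <- LIFESTYLE_COUNT_LOADING * u_life
      sig1 <- sig2
    }
    out$followup[, paste0("beh_", b, "_t2")] <-
      sample_counts(rates[b], sig2, link, noise_sd)
    out$baseline[, paste0("beh_", b, "_t1")] <-
      sample_counts(rates[b], sig1, link, noise_sd)
  }

  for (j in seq_len(nrow(beh_tab))) {
    b <- beh_tab$name[j]
    driver <- if (beh_tab$is_health[j]) 1.0 * u_cog else 0.8 * u_life
    for (con in COGNITION_CONSTRUCTS) {
      val <- 4 + driver + stats::rnorm(n, 0, noise_sd)
      out$cognitions[, paste0("cog_", b, "_", con)] <- clip_score(val)
    }
  }

  for (k in seq_along(PERSONALITY_SCALES)) {
    out$personality[, k] <- round(0.8 * u_pers + 0.6 * stats::rnorm(n), 3)
  }

  c(out, list(propensity = h, lifestyle = u_life,
              factors = cbind(u_cog = u_cog, u_pers = u_pers,
                              u_life = u_life, u_base = u_base)))
}

#' Read or write a simulation configuration as YAML
#'
#' The YAML schema mirrors [simulation_config()] field-for-field, with groups
#' given as a list of group records.
#'
#' @param path YAML file path.
#' @return a `simulation_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- lapply(y$groups, function(g) {
    do.call(group_spec, c(list(label = g$label, proportion = g$proportion),
                          g[setdiff(names(g), c("label", "proportion"))]))
  })
  args <- y[setdiff(names(y), "groups")]
  args$planted_increments <- if (!is.null(args$planted_increments))
    unlist(args$planted_increments)
  do.call(simulation_config, c(list(groups = groups), args))
}

#' @rdname read_sim_config
#' @param config a `simulation_config` to serialize.
#' @export
write_sim_config <- function(config, path) {
  groups <- lapply(config$groups, function(g) {
    list(label = g$label, proportion = g$proportion,
         engagement_shift = g$engagement_shift,
         cognition_loadings = g$cognition_loadings,
         lifestyle_conflict = g$lifestyle_conflict,
         personality_shift = as.list(g$personality_shift),
         smoker_profile = g$smoker_profile,
         lifestyle_shift = g$lifestyle_shift,
         lifestyle_profile = as.list(g$lifestyle_profile),
         cognition_offsets = as.list(g$cognition_offsets))
  })
  y <- list(n_participants = config$n_participants, groups = groups,
            noise_sd = config$noise_sd,
            nonlinearity_strength = config$nonlinearity_strength,
            count_link = config$count_link, seed = config$seed,
            assignment = config$assignment,
            null_behaviors = as.list(config$null_behaviors))
  if (!is.null(config$planted_increments)) {
    y$planted_increments <- as.list(config$planted_increments)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
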