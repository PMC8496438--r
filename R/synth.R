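#' @title Synthetic intraoperative cohort generator
#' @name synthetic_cohort
#' @description
#' Generates seeded cohorts with the statistical structure the evaluation
#' assumes: per-patient monitoring durations around a 194-min median,
#' mean-reverting MAP around a normotensive baseline (an Ornstein-Uhlenbeck
#' process discretized on the 20-s grid), and Poisson-arriving hypotensive
#' episodes. Each episode is a raised-cosine dip below the 65-mmHg
#' threshold, preceded by a smooth prodromal decline and followed by a
#' smooth recovery, so that event boundaries are well defined on the grid
#' and a trend-following predictor has a pre-event signature to detect.
#' Patient-to-patient event burden is overdispersed through a gamma frailty
#' on the episode rate, reproducing a cohort in which roughly a quarter of
#' patients stay event-free while the median affected patient has several
#' events.
NULL

#' Synthetic cohort configuration
#'
#' Defaults target the cohort summaries the evaluation is designed around:
#' ~31 patients, median monitoring ~194 min, ~77% of patients with at least
#' one hypotensive event, a median of ~4 events per affected cohort, median
#' below-threshold duration ~2.67 min, and median time-weighted average
#' burden of a few tenths of a mmHg.
#'
#' @param n_patients Number of patients.
#' @param monitoring_median Median monitoring duration, minutes (lognormal).
#' @param monitoring_sdlog Log-scale SD of monitoring duration.
#' @param baseline_map Normotensive MAP baseline, mmHg.
#' @param ou_theta Mean-reversion rate of the MAP noise process, 1/min.
#' @param ou_sigma Diffusion of the MAP noise process, mmHg/sqrt(min). The
#'   stationary SD is `ou_sigma / sqrt(2 * ou_theta)`.
#' @param episode_rate Baseline hypotensive-episode rate, events/hour.
#' @param frailty_shape Shape of the mean-1 gamma frailty multiplying each
#'   patient's episode rate (smaller = more overdispersion).
#' @param depth_shape,depth_mean Gamma parameters of the episode depth
#'   below the threshold at nadir, mmHg.
#' @param below_median,below_sdlog Lognormal parameters of the designed
#'   below-threshold duration per episode, minutes.
#' @param prodrome_drop Prodromal MAP decline before the dip, mmHg.
#' @param prodrome_min Duration of the prodromal decline, minutes.
#' @param recovery_min Duration of the post-dip recovery ramp, minutes.
#' @param dropout_prob Probability that a sample is flagged poor quality.
#' @param map_threshold Hypotension threshold, mmHg.
#' @param seed Master seed; per-patient substreams are derived from it so
#'   the cohort is reproducible independent of generation order.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 31,
                         monitoring_median = 194,
                         monitoring_sdlog = 0.6,
                         baseline_map = 80,
                         ou_theta = 0.2,
                         ou_sigma = 1.4,
                         episode_rate = 4,
                         frailty_shape = 0.8,
                         depth_shape = 1.6,
                         depth_mean = 8,
                         below_median = 2.67,
                         below_sdlog = 0.8,
                         prodrome_drop = 11,
                         prodrome_min = 10,
                         recovery_min = 3,
                         dropout_prob = 0.02,
                         map_threshold = 65,
                         seed = 1) {
  sc <- as.list(environment())
  nonneg <- c("ou_theta", "ou_sigma", "episode_rate", "dropout_prob")
  for (nm in nonneg) {
    if (sc[[nm]] < 0) stop("'", nm, "' must be nonnegative", call. = FALSE)
  }
  if (sc$dropout_prob >= 1) stop("dropout_prob must be < 1", call. = FALSE)
  if (sc$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (sc$baseline_map <= sc$map_threshold) {
    stop("baseline_map must exceed map_threshold", call. = FALSE)
  }
  structure(sc, class = "synth_config")
}

#' Prediction-index model
#'
#' The surrogate is a transparent trend-following early-warning index: it fits
#' a least-squares MAP trend over the preceding `trend_window` minutes,
#' extrapolates it `lead` minutes ahead, and maps the predicted MAP through
#' a logistic centred at `midpoint` so that the score rises towards 100 as
#' predicted MAP falls below the threshold. The null model emits i.i.d.
#' uniform scores and serves as a negative control.
#'
#' @param kind `"surrogate"` or `"null"`.
#' @param lead Forecast horizon of the surrogate, minutes.
#' @param midpoint Logistic centre, mmHg.
#' @param slope Logistic steepness, index units per mmHg (> 0).
#' @param noise_sd SD of additive index noise, index units.
#' @param trend_window Trend-fit window, minutes.
#' @return An object of class `index_model`.
#' @export
index_model <- function(kind = c("surrogate", "null"), lead = 5,
                        midpoint = 65, slope = 0.5, noise_sd = 3,
                        trend_window = 3) {
  kind <- match.arg(kind)
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, lead = lead, midpoint = midpoint,
                 slope = slope, noise_sd = noise_sd,
                 trend_window = trend_window),
            class = "index_model")
}

# deterministic deficit profile of one episode, evaluated at grid times
# (minutes): prodromal raised-cosine ramp, full-period raised-cosine dip of
# width dip_w crossing the threshold, then a recovery ramp
.episode_drop <- function(t_min, onset, dip_w, amplitude, ramp_drop,
                          ramp_in, ramp_out) {
  drop <- numeric(length(t_min))
  ix <- t_min >= onset - ramp_in & t_min < onset
  drop[ix] <- ramp_drop *
    (1 - cos(pi * (t_min[ix] - onset + ramp_in) / ramp_in)) / 2
  ix <- t_min >= onset & t_min <= onset + dip_w
  drop[ix] <- ramp_drop +
    amplitude * (1 - cos(2 * pi * (t_min[ix] - onset) / dip_w)) / 2
  ix <- t_min > onset + dip_w & t_min <= onset + dip_w + ramp_out
  drop[ix] <- ramp_drop *
    (1 + cos(pi * (t_min[ix] - onset - dip_w) / ramp_out)) / 2
  drop
}

#' Generate one MAP trajectory on the 20-s grid
#'
#' Mean-reverting noise (exact OU discretization) around the baseline, with
#' hypotensive episodes superposed as smooth deficits. Episode arrivals are
#' a Poisson process at `rate` events/hour, thinned so episode supports do
#' not overlap and fit inside the record. Fully reproducible from `seed`.
#'
#' @param config A [synth_config].
#' @param duration_min Monitoring duration, minutes.
#' @param seed Seed for this trajectory.
#' @param rate Episode rate, events/hour (defaults to the config's; per-
#'   patient frailty is applied by [generate_cohort()]).
#' @return Data frame `t_s`, `map`; zero rows when `duration_min <= 0`. The
#'   kept episode parameters are attached as attribute `"episodes"`.
#' @export
generate_map_trajectory <- function(config, duration_min,
                                    seed = config$seed,
                                    rate = config$episode_rate) {
  if (duration_min <= 0) {
    return(data.frame(t_s = numeric(), map = numeric()))
  }
  set.seed(seed)
  n <- max(1L, as.integer(round(duration_min * 3)))
  t_min <- (seq_len(n) - 1L) / 3
  # exact OU discretization: stationary start, AR(1) recursion
  sd_stat <- if (config$ou_theta > 0) {
    config$ou_sigma / sqrt(2 * config$ou_theta)
  } else 0
  alpha <- exp(-config$ou_theta / 3)
  if (sd_stat > 0) {
    innov <- stats::rnorm(n, 0, sd_stat * sqrt(1 - alpha^2))
    innov[1L] <- stats::rnorm(1, 0, sd_stat)
    ou <- as.numeric(stats::filter(innov, alpha, method = "recursive"))
  } else {
    ou <- numeric(n)
  }
  # Poisson episode arrivals, thinned to non-overlapping supports
  h <- config$baseline_map - config$prodrome_drop - config$map_threshold
  h <- max(h, 0.5)
  episodes <- data.frame(onset = numeric(), dip_w = numeric(),
                         depth = numeric(), below_target = numeric())
  if (rate > 0) {
    k <- stats::rpois(1, rate * duration_min / 60)
    if (k > 0) {
      cand <- sort(stats::runif(k, 0, duration_min))
      depth <- stats::rgamma(k, shape = config$depth_shape,
                             scale = config$depth_mean / config$depth_shape)
      depth <- pmax(depth, 0.5)
      below <- stats::rlnorm(k, log(config$below_median), config$below_sdlog)
      cfrac <- h / (h + depth)
      gfrac <- acos(1 - 2 * cfrac) / pi   # sub-threshold fraction = 1 - gfrac
      dip_w <- below / (1 - gfrac)
      last_end <- -Inf
      for (j in seq_len(k)) {
        s0 <- cand[j] - config$prodrome_min
        s1 <- cand[j] + dip_w[j] + config$recovery_min
        if (s0 >= max(1, last_end + 2) && s1 <= duration_min - 1) {
          episodes <- rbind(episodes, data.frame(
            onset = cand[j], dip_w = dip_w[j], depth = depth[j],
            below_target = below[j]))
          last_end <- s1
        }
      }
    }
  }
  drop <- numeric(n)
  if (nrow(episodes)) {
    for (j in seq_len(nrow(episodes))) {
      drop <- drop + .episode_drop(
        t_min, episodes$onset[j], episodes$dip_w[j],
        h + episodes$depth[j], config$prodrome_drop,
        config$prodrome_min, config$recovery_min)
    }
  }
  map <- pmin(pmax(config$baseline_map + ou - drop, 25), 200)
  out <- data.frame(t_s = t_min * 60, map = map)
  attr(out, "episodes") <- episodes
  out
}

#' Surrogate prediction index for a record
#'
#' At each sample, fits the least-squares MAP trend over the preceding
#' `trend_window` minutes, extrapolates to `lead` minutes ahead, and maps
#' the prediction through `100 * plogis(slope * (midpoint - predicted))`,
#' plus optional noise, clipped to \[0, 100\]. The score is absent (`NA`)
#' until the trend window is filled and wherever a grid gap interrupts it.
#' With `noise_sd = 0` the score is monotone decreasing in the predicted
#' MAP.
#'
#' @param record Single-patient data frame (needs `t_s`, `map`).
#' @param model An [index_model] of kind `"surrogate"`.
#' @param seed Seed for the additive noise.
#' @return Numeric score vector aligned with the record's samples.
#' @export
surrogate_index <- function(record, model = index_model(), seed = 1) {
  n <- nrow(record)
  if (n == 0L) return(numeric(0))
  t <- record$t_s
  y <- record$map
  w <- as.integer(round(model$trend_window * 3))
  scores <- rep(NA_real_, n)
  if (n >= w && w >= 2L) {
    bad_step <- c(0, cumsum(diff(t) > 22))
    ct <- cumsum(t); cy <- cumsum(y)
    cty <- cumsum(t * y); ctt <- cumsum(t * t)
    j <- w:n
    i0 <- j - w + 1L
    wsum <- function(cs) cs[j] - c(0, cs)[i0]
    st <- wsum(ct); sy <- wsum(cy); sty <- wsum(cty); stt <- wsum(ctt)
    den <- w * stt - st^2
    b <- (w * sty - st * sy) / den
    a <- (sy - b * st) / w
    pred <- a + b * (t[j] + model$lead * 60)
    ok <- bad_step[j] - bad_step[i0] == 0
    val <- 100 * stats::plogis(model$slope * (model$midpoint - pred))
    scores[j[ok]] <- val[ok]
  }
  if (model$noise_sd > 0) {
    set.seed(seed)
    noise <- stats::rnorm(n, 0, model$noise_sd)
    scores <- scores + noise
  }
  pmin(pmax(scores, 0), 100)
}

#' Uniform null index (negative control)
#'
#' i.i.d. uniform scores on \[0, 100\], exchangeable with the labels by
#' construction, so downstream AUC concentrates at 0.5.
#'
#' @param record Single-patient data frame.
#' @param seed Seed.
#' @return Numeric score vector.
#' @export
null_index <- function(record, seed = 1) {
  if (nrow(record) == 0L) return(numeric(0))
  set.seed(seed)
  stats::runif(nrow(record), 0, 100)
}

#' Generate a full synthetic cohort
#'
#' One record per patient: lognormal monitoring duration, gamma frailty on
#' the episode rate, MAP trajectory, heart rate (its own mean-reverting
#' process around 73 beats/min, so occasional bradycardic runs occur),
#' systolic/diastolic pressures consistent with MAP, quality dropouts, and
#' scores from the supplied index model. Deterministic given
#' `config$seed`: each patient draws from a substream keyed by patient
#' index.
#'
#' @param config A [synth_config].
#' @param model An [index_model].
#' @return A [hemo_cohort] data frame.
#' @export
generate_cohort <- function(config = synth_config(),
                            model = index_model()) {
  recs <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    base <- substream_seed(config$seed, i)
    set.seed(base)
    duration <- stats::rlnorm(1, log(config$monitoring_median),
                              config$monitoring_sdlog)
    duration <- min(max(duration, 60), 600)
    frailty <- stats::rgamma(1, shape = config$frailty_shape,
                             rate = config$frailty_shape)
    traj <- generate_map_trajectory(config, duration,
                                    seed = substream_seed(base, 1),
                                    rate = config$episode_rate * frailty)
    n <- nrow(traj)
    set.seed(substream_seed(base, 2))
    alpha <- exp(-0.3 / 3)
    hr_innov <- stats::rnorm(n, 0, 7 * sqrt(1 - alpha^2))
    hr_innov[1L] <- stats::rnorm(1, 0, 7)
    hr <- 73 + as.numeric(stats::filter(hr_innov, alpha,
                                        method = "recursive"))
    hr <- pmin(pmax(hr, 30), 180)
    pp <- pmax(25, 42 + 0.25 * (traj$map - config$baseline_map) +
                 stats::rnorm(n, 0, 1.5))
    quality_ok <- stats::runif(n) >= config$dropout_prob
    rec <- data.frame(
      patient_id = sprintf("P%02d", i),
      t_s = traj$t_s,
      map = traj$map,
      sbp = traj$map + 2 * pp / 3,
      dbp = traj$map - pp / 3,
      hr = hr,
      score = NA_real_,
      quality_ok = quality_ok,
      stringsAsFactors = FALSE
    )
    rec$score <- if (model$kind == "surrogate") {
      surrogate_index(rec, model, seed = substream_seed(base, 3))
    } else {
      null_index(rec, seed = substream_seed(base, 3))
    }
    recs[[i]] <- rec
  }
  as_hemo_cohort(do.call(rbind, recs))
}
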