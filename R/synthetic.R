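# Synthetic lower-limb kinematics.
#
# Profiles are fixture design, not measured data: peak angles respect the
# qualitative posture descriptions (symmetric kneeling, heels-up vs
# flatfoot squatting, chair vs floor sitting, a hip-hinge stoop with knee
# flexion below 90 degrees, quiet standing) and the defining property that
# high-flexion postures exceed 120 degrees of knee flexion.  Trials follow
# the protocol shape: stand, descend, hold the fully flexed pose for 5 s,
# ascend, stand, with an optional lead-in/lead-out step for the non-seated
# postures.
#
# Because every channel is min-max normalized per trial and warped
# independently by DTW downstream, absolute amplitudes and phase timing
# carry little information; what separates classes after normalization is
# the *structure* of each waveform.  Profiles therefore encode the
# secondary movements that distinguish the postures: mid-hold weight
# shifts (dips toward baseline of class-specific depth, count and joint
# distribution, e.g. the rock-back onto flexed toes in dorsiflexed
# kneeling, the lean onto the hands in supported kneeling, or the settle
# on chair contact) and sign structure (plantarflexion is negative, so
# heels-up squatting and plantarflexed kneeling invert the ankle
# waveform).  Dip counts and placements are deliberately the primary
# class signatures: unlike depths, they survive both subject-level
# amplitude scaling and DTW's absorption of monotone shape differences.

#' Kinematic profiles for the twelve posture classes
#'
#' Per class and channel: the standing baseline angle, the peak angle at
#' full flexion (degrees, flexion positive), phase durations (descend /
#' hold / ascend, seconds) with their jitter, peak jitter, measurement
#' noise, and whether a lead-in/out step is performed.  Values are
#' synthetic fixture parameters chosen for class separability under the
#' posture definitions; they are not measurements.
#'
#' @return Named list of profiles, one per canonical class.  Each profile
#'   has `baseline` and `peak` (named 6-vectors, degrees), `dip_count`
#'   and `dip_depth` (named 6-vectors: number and relative depth of
#'   mid-hold excursions toward baseline), `overshoot` (named 6-vector:
#'   sustained settle-back fraction after first contact), `descend`,
#'   `hold`, `ascend` (s), `time_jitter` (s, sd), `peak_jitter` (degrees,
#'   sd), `dip_jitter` (relative sd on motif depths), `noise_sd`
#'   (degrees), `steps` (logical).
#' @export
class_profiles <- function() {
  base <- c(r_knee = 5, l_knee = 5, r_ankle = 0, l_ankle = 0,
            r_hip = 5, l_hip = 5)
  v6 <- function(rk, lk, ra, la, rh, lh)
    c(r_knee = rk, l_knee = lk, r_ankle = ra, l_ankle = la,
      r_hip = rh, l_hip = lh)
  zero <- v6(0, 0, 0, 0, 0, 0)
  prof <- function(pk, dips = zero, depth = zero, overshoot = zero,
                   steps = TRUE, hold = 5, descend = 1.5, ascend = 1.5,
                   time_jitter = 0.15, peak_jitter = 2, dip_jitter = 0.08,
                   noise_sd = 0.5)
    list(baseline = base, peak = pk, dip_count = dips, dip_depth = depth,
         overshoot = overshoot, descend = descend, hold = hold,
         ascend = ascend, time_jitter = time_jitter,
         peak_jitter = peak_jitter, dip_jitter = dip_jitter,
         noise_sd = noise_sd, steps = steps)
  list(
    # dorsiflexed kneeling: rock-back onto the flexed toes mid-hold
    DK  = prof(v6(140, 140,  70,  70,  55,  55),
               dips  = v6(1, 1, 1, 1, 0, 0),
               depth = v6(0.12, 0.12, 0.20, 0.20, 0, 0)),
    # plantarflexed kneeling: inverted (negative) ankle, otherwise still
    PK  = prof(v6(135, 135, -25, -25,  50,  50)),
    # supported kneeling: one deep lean forward onto the hands mid-hold
    SK  = prof(v6(125, 125,  10,  10,  90,  90),
               dips  = v6(0, 0, 0, 0, 1, 1),
               depth = v6(0, 0, 0, 0, 0.50, 0.50)),
    # flatfoot squat: dorsiflexed ankles; two counterbalance weight shifts
    FS  = prof(v6(140, 140,  38,  38, 115, 115),
               dips  = v6(0, 0, 1, 1, 2, 2),
               depth = v6(0, 0, 0.35, 0.35, 0.25, 0.25)),
    # heels-up squat: plantarflexed (negative) ankles, balance wobble
    HS  = prof(v6(150, 150, -20, -20, 100, 100),
               dips  = v6(1, 1, 1, 1, 0, 0),
               depth = v6(0.15, 0.15, 0.30, 0.30, 0, 0)),
    # child-sized chair: two settle adjustments on the low seat
    CCS = prof(v6(127, 127,  14,  14,  98,  98),
               dips  = v6(2, 2, 0, 0, 2, 2),
               depth = v6(0.20, 0.20, 0, 0, 0.20, 0.20),
               steps = FALSE),
    # adult-sized chair: one settle on contact, knees and hips together
    ACS = prof(v6( 90,  90,   8,   8,  90,  90),
               dips  = v6(1, 1, 0, 0, 1, 1),
               depth = v6(0.25, 0.25, 0, 0, 0.25, 0.25),
               steps = FALSE),
    # crossed-leg sitting: crossing the left leg under mid-descent
    CLS = prof(v6(130, 138,  30,  34,  70,  72),
               dips  = v6(0, 1, 0, 0, 1, 1),
               depth = v6(0, 0.40, 0, 0, 0.25, 0.25),
               steps = FALSE),
    # side sitting: lateral asymmetry, one ankle tucked (plantarflexed)
    SS  = prof(v6(122, 142, -12,  22,  74,  60), steps = FALSE),
    # stooping: one smooth hip hinge, knees below 90, short hold
    STP = prof(v6( 70,  70,  12,  12,  95,  95), hold = 3,
               descend = 1.2, ascend = 1.2),
    # quiet standing: baseline plus slow postural sway
    STD = prof(base + c(2, 2, 1, 1, 2, 2), steps = FALSE, hold = 5,
               descend = 1, ascend = 1, peak_jitter = 0.5,
               noise_sd = 0.4)
    # WLK is generated by generate_gait(), not a stand-hold-stand profile
  )
}

raised_cosine <- function(u) (1 - cos(pi * u)) / 2

# One smooth bump 0 -> 1 -> 0 over n samples (half-cosine up and down).
bump <- function(n) raised_cosine(2 * pmin(seq(0, 1, length.out = n),
                                           1 - seq(0, 1, length.out = n)))

# Compact raised-cosine bump of unit height at `centre` on grid `h`.
hold_bump <- function(h, centre, w = 0.22) {
  out <- numeric(length(h))
  in_dip <- abs(h - centre) <= w / 2
  out[in_dip] <- (1 + cos(2 * pi * (h[in_dip] - centre) / w)) / 2
  out
}

# Descend / hold / ascend profile with hold-phase structure: `dips`
# excursions toward baseline of relative depth `depth`, an optional
# sustained `overshoot` settle-back after first contact, and an optional
# subject-idiosyncratic extra adjustment (`quirk` depth at `quirk_centre`).
phase_profile <- function(b, p, n_descend, n_hold, n_ascend,
                          dips = 0L, depth = 0, overshoot = 0,
                          quirk = 0, quirk_centre = 0.5) {
  h <- seq(0, 1, length.out = n_hold)
  hold <- rep(p, n_hold)
  if (overshoot > 0) {
    step <- raised_cosine(pmin(pmax((h - 0.08) / 0.12, 0), 1))
    hold <- hold - (p - b) * overshoot * step
  }
  if (dips > 0 && depth > 0) {
    for (i in seq_len(dips)) {
      hold <- hold - (p - b) * depth * hold_bump(h, i / (dips + 1))
    }
  }
  if (quirk != 0)
    hold <- hold - (p - b) * quirk * hold_bump(h, quirk_centre, w = 0.18)
  rise_to <- hold[n_hold]   # ascend from wherever the hold settled
  c(b + (p - b) * raised_cosine(seq(0, 1, length.out = n_descend)),
    hold,
    rise_to + (b - rise_to) * raised_cosine(seq(0, 1, length.out = n_ascend)))
}

# Half-stride step bump prepended/appended around the posture phases.
step_bump <- function(n, knee_amp = 45, hip_amp = 22, ankle_amp = 12) {
  list(r_knee = knee_amp * bump(n), l_knee = 0.8 * knee_amp * bump(n),
       r_ankle = ankle_amp * bump(n), l_ankle = 0.8 * ankle_amp * bump(n),
       r_hip = hip_amp * bump(n), l_hip = 0.8 * hip_amp * bump(n))
}

#' Generate one synthetic posture trial
#'
#' Builds a smooth stand / descend / hold / ascend / stand angle profile
#' per channel from a class profile (raised-cosine ramps), with trial
#' jitter on phase durations and peak depth, per-subject depth and tempo
#' offsets, additive Gaussian measurement noise, and (for classes
#' performed mid-walk) an optional lead-in and lead-out step.
#' Deterministic given `seed`.
#'
#' @param class_id Canonical class code (not WLK; see [generate_gait()]).
#' @param profile Class profile, see [class_profiles()].
#' @param subject Optional list with `id`, `depth_offset` (degrees added
#'   to flexed-channel peaks) and `tempo` (duration multiplier).
#' @param seed Integer seed.
#' @param sample_rate Hz (default 60).
#' @param segmented If `TRUE`, omit the lead-in/out steps and flanking
#'   standing, as a manually segmented trial would.
#' @return An unlabelled-normalization `movement_sequence` with `label`
#'   and `subject_id` set.
#' @export
generate_trial <- function(class_id, profile = class_profiles()[[class_id]],
                           subject = NULL, seed = 1L, sample_rate = 60,
                           segmented = FALSE) {
  if (is.null(profile)) stop("no profile for class ", class_id)
  if (profile$descend <= 0 || profile$hold <= 0 || profile$ascend <= 0)
    stop("phase durations must be positive")
  depth <- if (is.null(subject)) 0 else subject$depth_offset
  tempo <- if (is.null(subject)) 1 else subject$tempo
  sid <- if (is.null(subject)) "synthetic" else subject$id
  with_local_seed(seed, {
    jit <- function(x) max(0.2, x * tempo + stats::rnorm(1, 0, profile$time_jitter))
    n_desc <- max(6L, round(jit(profile$descend) * sample_rate))
    n_hold <- max(6L, round(jit(profile$hold) * sample_rate))
    n_asc <- max(6L, round(jit(profile$ascend) * sample_rate))
    n_stand <- max(4L, round(0.5 * sample_rate))
    n_step <- max(6L, round(0.8 * tempo * sample_rate))
    steps <- step_bump(n_step)
    # movement depth also scales the secondary adjustments, which is what
    # survives per-channel min-max normalization
    style <- exp(depth / 25)
    channels <- lapply(mdtw_channels(), function(ch) {
      b <- profile$baseline[[ch]]
      p <- profile$peak[[ch]] + stats::rnorm(1, 0, profile$peak_jitter)
      # subject depth offset applies to channels that actually flex
      if (abs(profile$peak[[ch]] - b) > 15) p <- p + depth
      dd <- profile$dip_depth[[ch]] * style *
        (1 + stats::rnorm(1, 0, profile$dip_jitter))
      ov <- profile$overshoot[[ch]] * style *
        (1 + stats::rnorm(1, 0, profile$dip_jitter))
      qd <- if (is.null(subject$quirk_depth)) 0
            else subject$quirk_depth[[ch]]
      qc <- if (is.null(subject$quirk_centre)) 0.5
            else subject$quirk_centre[[ch]]
      core <- phase_profile(b, p, n_desc, n_hold, n_asc,
                            dips = profile$dip_count[[ch]],
                            depth = max(0, min(dd, 0.8)),
                            overshoot = max(0, min(ov, 0.6)),
                            quirk = qd, quirk_centre = qc)
      x <- if (segmented) core
      else if (profile$steps)
        c(b + steps[[ch]], rep(b, n_stand), core, rep(b, n_stand),
          b + steps[[ch]])
      else c(rep(b, n_stand), core, rep(b, n_stand))
      x + stats::rnorm(length(x), 0, profile$noise_sd)
    })
    movement_sequence(do.call(rbind, channels), label = class_id,
                      subject_id = sid, sample_rate = sample_rate)
  })
}

#' Generate a synthetic multi-stride walking trial
#'
#' Concatenated gait cycles: periodic knee-flexion bumps (swing phase)
#' with clear extension troughs at the cycle boundaries, plus smaller hip
#' and ankle oscillations.  [segment_gait_cycles()] recovers exactly
#' `n_strides` cycles from the result.
#'
#' @param n_strides Number of strides (>= 1).
#' @param subject,seed,sample_rate As in [generate_trial()].
#' @param stride_duration Seconds per stride (default 1.1).
#' @param noise_sd Measurement noise (degrees).
#' @return A `movement_sequence` labelled `WLK`.
#' @export
generate_gait <- function(n_strides, subject = NULL, seed = 1L,
                          sample_rate = 60, stride_duration = 1.1,
                          noise_sd = 0.4) {
  stopifnot(n_strides >= 1)
  depth <- if (is.null(subject)) 0 else subject$depth_offset / 3
  tempo <- if (is.null(subject)) 1 else subject$tempo
  sid <- if (is.null(subject)) "synthetic" else subject$id
  with_local_seed(seed, {
    n <- max(12L, round(stride_duration * tempo * sample_rate))
    u <- seq(0, 1, length.out = n)
    # smooth compact bump of unit height centred at `centre`, zero outside
    cos_bump <- function(centre, width) {
      ifelse(abs(u - centre) <= width / 2,
             (1 + cos(2 * pi * (u - centre) / width)) / 2, 0)
    }
    one_stride <- function() {
      knee_amp <- 62 + depth + stats::rnorm(1, 0, 2)
      # small stance-phase flexion wave (kept below the segmentation
      # prominence threshold) plus the dominant swing-phase bump
      knee <- 5 + 2.5 * cos_bump(0.18, 0.36) + knee_amp * cos_bump(0.68, 0.55)
      hip <- 25 * sin(2 * pi * u) + 10
      ankle <- 10 * sin(2 * pi * u + pi / 3)
      list(knee = knee, hip = hip, ankle = ankle)
    }
    strides <- lapply(seq_len(n_strides), function(i) one_stride())
    cat_ch <- function(f) unlist(lapply(strides, `[[`, f))
    knee <- cat_ch("knee"); hip <- cat_ch("hip"); ankle <- cat_ch("ankle")
    lag <- round(n / 2)
    shift <- function(x) c(x[(lag + 1):length(x)], x[1:lag])
    ang <- rbind(r_knee = knee, l_knee = shift(knee),
                 r_ankle = ankle, l_ankle = shift(ankle),
                 r_hip = hip, l_hip = shift(hip))
    ang <- ang + stats::rnorm(length(ang), 0, noise_sd)
    movement_sequence(ang, label = "WLK", subject_id = sid,
                      sample_rate = sample_rate)
  })
}

# Documented seed fan-out: any single subject or trial is regenerable in
# isolation from the master seed.
subject_seed <- function(master_seed, s)
  (master_seed + 7919L * s) %% 2147483647L
trial_seed <- function(master_seed, s, counter)
  (master_seed + 7919L * s + 104729L * counter) %% 2147483647L

draw_subjects <- function(n, master_seed, depth_sd, tempo_sd,
                          quirk_sd = 0.15) {
  lapply(seq_len(n), function(s) {
    with_local_seed(subject_seed(master_seed, s), list(
      id = sprintf("S%02d", s),
      depth_offset = stats::rnorm(1, 0, depth_sd),
      tempo = exp(stats::rnorm(1, 0, tempo_sd)),
      # idiosyncratic movement habit: a personal mid-hold adjustment per
      # channel, constant across that subject's trials
      quirk_depth = stats::setNames(stats::rnorm(6, 0, quirk_sd),
                                    mdtw_channels()),
      quirk_centre = stats::setNames(stats::runif(6, 0.3, 0.7),
                                     mdtw_channels())))
  })
}

#' Generate a synthetic study cohort
#'
#' Emulates the study design at configurable scale: subjects receive
#' per-subject depth and tempo offsets drawn once; each build subject
#' contributes segmented trials (turned into templates via the standard
#' preprocessing) and unsegmented movement sequences of every class; a
#' disjoint subject subset is reserved as novel participants whose
#' sequences enter no template.  Walking contributes single-stride
#' templates and queries (segmented gait cycles) plus held-aside
#' multi-stride sequences for failure-mode analysis.  Deterministic given
#' `master_seed`.
#'
#' @param n_subjects Total subjects (>= 2).
#' @param trials_per_class Trials per subject and class (default 3).
#' @param n_novel Subjects reserved as novel participants (default 30%
#'   of `n_subjects`, at least 1).
#' @param depth_sd Between-subject flexion-depth sd, degrees (default
#'   10); the depth offset also scales the relative depth of each
#'   subject's secondary adjustments.
#' @param tempo_sd Between-subject log-tempo sd (default 0.15).
#' @param quirk_sd Sd of the per-subject idiosyncratic mid-hold
#'   adjustment depth (relative units, default 0.15); this is the
#'   component of inter-subject variability that a subject's own
#'   templates capture and a novel subject's do not.
#' @param master_seed Integer master seed; per-subject and per-trial
#'   seeds derive from it by a fixed counter scheme.
#' @param profiles Class profiles (default [class_profiles()]).
#' @return List: `library` (a `template_library` from build subjects),
#'   `build_queries` and `novel_queries` (lists of normalized movement
#'   sequences with true labels attached), `walking_sequences`
#'   (normalized multi-stride walking queries), `subjects`, `build_ids`,
#'   `novel_ids`.
#' @export
generate_cohort <- function(n_subjects = 10L, trials_per_class = 3L,
                            n_novel = max(1L, round(0.3 * n_subjects)),
                            depth_sd = 10, tempo_sd = 0.15,
                            quirk_sd = 0.15, master_seed = 1L,
                            profiles = class_profiles()) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (n_novel >= n_subjects)
    stop("fewer subjects than requested novel split")
  subjects <- draw_subjects(n_subjects, master_seed, depth_sd, tempo_sd,
                            quirk_sd)
  build <- seq_len(n_subjects - n_novel)
  novel <- setdiff(seq_len(n_subjects), build)

  templates <- list()
  build_queries <- list()
  novel_queries <- list()
  walking <- list()

  for (s in seq_len(n_subjects)) {
    sub <- subjects[[s]]
    counter <- 0L
    for (cl in names(profiles)) {
      for (r in seq_len(trials_per_class)) {
        counter <- counter + 1L
        sd_trial <- trial_seed(master_seed, s, counter)
        if (s %in% build) {
          seg <- generate_trial(cl, profiles[[cl]], sub, sd_trial,
                                segmented = TRUE)
          templates[[length(templates) + 1L]] <-
            build_template(seg, id = sprintf("%s_%s_%02d", cl, sub$id, r))
        }
        unseg <- generate_trial(cl, profiles[[cl]], sub, sd_trial,
                                segmented = FALSE)
        q <- normalize_sequence(unseg)
        if (s %in% build)
          build_queries[[length(build_queries) + 1L]] <- q
        else novel_queries[[length(novel_queries) + 1L]] <- q
      }
    }
    # walking: full-length walks (several strides, as a 10 m self-paced
    # walk yields); templates and stride queries come from segmented
    # single cycles, while the full trials are kept as the multi-stride
    # sequences for the failure-mode analysis
    for (r in seq_len(trials_per_class)) {
      counter <- counter + 1L
      gs <- trial_seed(master_seed, s, counter)
      trial <- generate_gait(8L, sub, gs)
      cycles <- segment_gait_cycles(trial)
      if (s %in% build) {
        # first cycle becomes a single-stride template, the second the
        # held-in walking query; the full trial is kept for the
        # multi-stride failure-mode analysis
        templates[[length(templates) + 1L]] <-
          build_template(cycles[[1L]],
                         id = sprintf("WLK_%s_%02d", sub$id, r))
        build_queries[[length(build_queries) + 1L]] <-
          normalize_sequence(cycles[[2L]])
        walking[[length(walking) + 1L]] <- normalize_sequence(trial)
      } else {
        novel_queries[[length(novel_queries) + 1L]] <-
          normalize_sequence(cycles[[1L]])
      }
    }
  }
  list(library = template_library(
         templates,
         provenance = list(master_seed = master_seed,
                           n_subjects = n_subjects,
                           trials_per_class = trials_per_class,
                           depth_sd = depth_sd, tempo_sd = tempo_sd,
                           quirk_sd = quirk_sd,
                           build_ids = vapply(subjects[build], `[[`,
                                              character(1), "id"),
                           novel_ids = vapply(subjects[novel], `[[`,
                                              character(1), "id"))),
       build_queries = build_queries,
       novel_queries = novel_queries,
       walking_sequences = walking,
       subjects = subjects,
       build_ids = build, novel_ids = novel)
}

#' True labels of a query list
#' @param queries List of labelled `movement_sequence`s.
#' @return Character vector of labels.
#' @export
query_labels <- function(queries)
  vapply(queries, function(q) q$label, character(1))
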