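#' Coat state score
#'
#' Seven body parts (head, neck, dorsal coat, ventral coat, tail, forepaws,
#' hind paws) are each scored 0 (well groomed), 0.5 (intermediate) or 1
#' (deteriorated); the total score is their sum (0-7).
#'
#' @param part_scores numeric vector of exactly 7 part scores, each in
#'   `{0, 0.5, 1}`.
#' @return the total coat state score.
#' @export
#' @examples
#' coat_state_score(c(0, 0.5, 0.5, 0.5, 0, 0, 0))
coat_state_score <- function(part_scores) {
  if (length(part_scores) != 7L)
    stop("exactly 7 body-part scores are required")
  if (!all(part_scores %in% c(0, 0.5, 1)))
    stop("part scores must be 0, 0.5 or 1")
  sum(part_scores)
}

#' Weight gain relative to week 0
#'
#' @param weight_now current body weight (g).
#' @param weight_week0 reference body weight at week 0 (g), positive.
#' @return percent change, `100 * (now - week0) / week0`. Vectorized.
#' @export
#' @examples
#' weight_gain_pct(22, 20)
weight_gain_pct <- function(weight_now, weight_week0) {
  if (any(!is.na(weight_week0) & weight_week0 <= 0))
    stop("reference weight must be positive")
  100 * (weight_now - weight_week0) / weight_week0
}

#' Sucrose preference
#'
#' Percent of total fluid consumed as sucrose solution. An animal with zero
#' total fluid intake that week yields `NA` (excluded).
#'
#' @param sucrose_ml,water_ml consumed volumes (mL), non-negative. Vectorized.
#' @return preference in percent, or `NA` where sucrose + water = 0.
#' @export
#' @examples
#' sucrose_preference(0.6, 0.4)
sucrose_preference <- function(sucrose_ml, water_ml) {
  if (any(sucrose_ml < 0, na.rm = TRUE) || any(water_ml < 0, na.rm = TRUE))
    stop("volumes must be non-negative")
  total <- sucrose_ml + water_ml
  ifelse(!is.na(total) & total > 0, 100 * sucrose_ml / total, NA_real_)
}

## hours of the 5 x 1 h post-challenge window (clock hours, mod 24)
post_window_hours <- function(challenge_start = 23, challenge_duration = 1,
                              post_hours = 5) {
  (challenge_start + challenge_duration + seq_len(post_hours) - 1) %% 24
}

#' Residual avoidance from PhenoTyper zone-time traces
#'
#' The overnight PhenoTyper session applies a 1 h light challenge over the
#' food zone at 11 p.m. Residual avoidance (RA) for an animal is the signed
#' percent deviation of its total zone time during the 5 h following the
#' challenge from the mean of the sex- and week-matched control animals:
#' `RA = s * 100 * (T - Tc) / Tc`, with `s = +1` for the shelter zone (more
#' shelter time = avoidance) and `s = -1` for the food zone (less food-zone
#' time = avoidance). Control animals therefore have mean RA 0 by
#' construction, and stressed animals score positive.
#'
#' @param traces long data.frame with columns `animal_id`, `week`,
#'   `bin_start_hour` (clock hour, half-open bins `[h, h+1)`), `zone`
#'   (`"SZ"`/`"FZ"`), `minutes` (0-60).
#' @param meta data.frame with `animal_id`, `sex`, `group`.
#' @param zone `"SZ"` or `"FZ"`.
#' @param control_group reference group label.
#' @param challenge_start clock hour of challenge onset (default 23).
#' @param challenge_duration challenge length in hours (default 1).
#' @param post_hours length of the scored post-challenge window (default 5).
#' @return data.frame `animal_id`, `week`, `ra` (percent); animals whose
#'   trace does not cover the challenge hour and the full post window get
#'   `NA`.
#' @export
residual_avoidance <- function(traces, meta, zone = c("SZ", "FZ"),
                               control_group = "CRS0",
                               challenge_start = 23, challenge_duration = 1,
                               post_hours = 5) {
  zone <- match.arg(zone)
  need <- c("animal_id", "week", "bin_start_hour", "zone", "minutes")
  if (!all(need %in% names(traces)))
    stop("traces must have columns ", paste(need, collapse = ", "))
  post <- post_window_hours(challenge_start, challenge_duration, post_hours)
  required_bins <- c(challenge_start, post)

  tz <- traces[traces$zone == zone, , drop = FALSE]
  key <- interaction(tz$animal_id, tz$week, drop = TRUE)
  covered <- tapply(tz$bin_start_hour, key,
                    function(h) all(required_bins %in% h))
  total <- tapply(tz$minutes[tz$bin_start_hour %in% post],
                  droplevels(key[tz$bin_start_hour %in% post]), sum)

  out <- unique(tz[c("animal_id", "week")])
  k <- as.character(interaction(out$animal_id, out$week, drop = TRUE))
  out$total <- total[k]
  out$total[!covered[k] | is.na(covered[k])] <- NA
  out <- merge(out, meta[c("animal_id", "sex", "group")],
               by = "animal_id", sort = FALSE)

  s <- if (zone == "SZ") 1 else -1
  out$ra <- NA_real_
  for (w in unique(out$week)) for (sx in unique(out$sex)) {
    cell <- out$week == w & out$sex == sx
    ctrl <- out$total[cell & out$group == control_group]
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) == 0L)
      stop("no control animals for sex ", sx, ", week ", w)
    tc <- mean(ctrl)
    if (tc == 0)
      stop("control mean zone time is zero for sex ", sx, ", week ", w)
    out$ra[cell] <- s * 100 * (out$total[cell] - tc) / tc
  }
  out[order(out$week, out$animal_id), c("animal_id", "week", "ra")]
}

#' Integrated Z-emotionality score
#'
#' Guilloux-style behavioral integration: each of five weekly measures (coat
#' state, weight gain, shelter-zone RA, food-zone RA, sucrose preference) is
#' z-scored against the sex- and week-matched control animals and aligned so
#' that higher z means greater emotionality (deficit direction: coat state
#' and both RA scores enter with +1, weight gain and sucrose preference with
#' -1, since stress blunts weight gain and sucrose intake). The per-animal
#' Z-emotionality is the mean of the available aligned z-scores.
#'
#' @param behavior data.frame with columns `animal_id`, `sex`, `group`,
#'   `week`, plus the measure columns `coat_state`, `weight_gain_pct`,
#'   `ra_sz`, `ra_fz`, `sucrose_pref_pct` (any subset of measures present is
#'   used; missing values per animal are dropped from its mean).
#' @param control_group reference group label.
#' @return numeric vector of Z scores aligned to `behavior` rows.
#' @export
z_emotionality <- function(behavior, control_group = "CRS0") {
  measures <- c(coat_state = 1, ra_sz = 1, ra_fz = 1,
                weight_gain_pct = -1, sucrose_pref_pct = -1)
  present <- intersect(names(measures), names(behavior))
  if (length(present) == 0L)
    stop("no recognized behavioral measure columns present")
  week <- if ("week" %in% names(behavior)) behavior$week else 0L
  stratum <- interaction(behavior$sex, week, drop = TRUE)

  z <- matrix(NA_real_, nrow(behavior), length(present),
              dimnames = list(NULL, present))
  for (st in levels(stratum)) {
    rows <- which(stratum == st)
    ctrl <- rows[behavior$group[rows] == control_group]
    for (m in present) {
      x <- behavior[[m]]
      mu <- mean(x[ctrl], na.rm = TRUE)
      sdev <- stats::sd(x[ctrl], na.rm = TRUE)
      if (!is.finite(sdev) || sdev == 0) {
        warning("zero control SD for measure '", m, "' in stratum ", st,
                "; measure dropped there")
        next
      }
      z[rows, m] <- measures[m] * (x[rows] - mu) / sdev
    }
  }
  rowMeans(z, na.rm = TRUE)
}
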